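#' @include AllClasses.R synthetic-traces.R
NULL

.SCHEMA <- c(traces = "ZnFate-traces v1", truth = "ZnFate-truth v1",
             events = "ZnFate-events v1", fates = "ZnFate-fates v1")

.writeVersioned <- function(df, path, schema) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", .SCHEMA[[schema]]), con)
  utils::write.csv(df, con, row.names = FALSE)
}

.readVersioned <- function(path, schema) {
  first <- readLines(path, n = 1L)
  if (!identical(first, paste0("# ", .SCHEMA[[schema]])))
    stop("unknown or missing schema version in ", path,
         " (expected '", .SCHEMA[[schema]], "')")
  utils::read.csv(path, comment.char = "#")
}

#' Write / read a trace ensemble as versioned CSV
#'
#' Long format with columns cell_id, parent_id, well, condition, t_hours,
#' cdk2_ratio; division events go to a companion events CSV (cell_id,
#' t_hours) and ground truth, when present, to a truth CSV. Readers reject
#' files whose schema line does not match.
#'
#' @param ensemble a [TraceEnsemble-class].
#' @param dir output directory (created if needed).
#' @return `writeTraceCSV` returns the directory invisibly; `readTraceCSV`
#'   returns a [TraceEnsemble-class].
#' @export
writeTraceCSV <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rd <- rowData(ensemble)
  tt <- traceTimes(ensemble)
  R <- cdk2Ratios(ensemble)
  long <- data.frame(
    cell_id = rep(rd$cell_id, each = length(tt)),
    parent_id = rep(rd$parent_id, each = length(tt)),
    well = rep(rd$well, each = length(tt)),
    condition = rep(rd$condition, each = length(tt)),
    t_hours = rep(tt, times = nrow(R)),
    cdk2_ratio = as.vector(t(R)))
  .writeVersioned(long, file.path(dir, "traces.csv"), "traces")
  div <- divisionTimes(ensemble)
  ev <- data.frame(cell_id = rep(rd$cell_id, lengths(div)),
                   t_hours = unlist(div, use.names = FALSE))
  .writeVersioned(ev, file.path(dir, "events.csv"), "events")
  tr <- groundTruth(ensemble)
  if (!is.null(tr))
    .writeVersioned(as.data.frame(tr), file.path(dir, "truth.csv"), "truth")
  invisible(dir)
}

#' @rdname writeTraceCSV
#' @export
readTraceCSV <- function(dir) {
  long <- .readVersioned(file.path(dir, "traces.csv"), "traces")
  ev <- .readVersioned(file.path(dir, "events.csv"), "events")
  ids <- unique(long$cell_id)
  tt <- sort(unique(long$t_hours))
  R <- matrix(NA_real_, length(ids), length(tt),
              dimnames = list(ids, NULL))
  R[cbind(match(long$cell_id, ids), match(long$t_hours, tt))] <- long$cdk2_ratio
  firstRow <- long[!duplicated(long$cell_id), ]
  firstRow <- firstRow[match(ids, firstRow$cell_id), ]
  divs <- lapply(ids, function(id) sort(ev$t_hours[ev$cell_id == id]))
  se <- SummarizedExperiment(
    assays = list(ratio = R),
    rowData = DataFrame(cell_id = ids, condition = firstRow$condition,
                        well = firstRow$well,
                        parent_id = as.character(firstRow$parent_id),
                        first_mitosis = vapply(divs, function(d)
                          if (length(d)) d[1] else NA_real_, numeric(1)),
                        divisions = NumericList(divs)),
    colData = DataFrame(frame = seq_along(tt), t_hours = tt))
  rownames(se) <- ids
  truthPath <- file.path(dir, "truth.csv")
  if (file.exists(truthPath))
    metadata(se)$truth <- DataFrame(.readVersioned(truthPath, "truth"))
  new("TraceEnsemble", se)
}

#' Write fate records as versioned CSV
#'
#' @param records the `DataFrame` from [classifyFate()] or
#'   [binByMitosisWindow()].
#' @param path output file.
#' @export
writeFateCSV <- function(records, path) {
  .writeVersioned(as.data.frame(records), path, "fates")
  invisible(path)
}

#' @rdname writeFateCSV
#' @export
readFateCSV <- function(path) {
  DataFrame(.readVersioned(path, "fates"))
}

#' Write / read a movie as multi-page TIFF (one file per channel)
#'
#' Frames are stored as 16-bit grayscale pages, intensities clipped to
#' `[0, 1]`; a JSON sidecar records the frame times.
#'
#' @param movie a [Movie-class].
#' @param dir output directory.
#' @export
writeMovieTIFF <- function(movie, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  toPages <- function(a) lapply(seq_len(dim(a)[3]), function(f)
    pmin(pmax(a[, , f], 0), 1))
  tiff::writeTIFF(toPages(movie@h2b), file.path(dir, "h2b.tif"),
                  bits.per.sample = 16L)
  tiff::writeTIFF(toPages(movie@cdk2), file.path(dir, "cdk2.tif"),
                  bits.per.sample = 16L)
  jsonlite::write_json(list(frame_times = movie@frameTimes),
                       file.path(dir, "movie.json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(dir)
}

#' @rdname writeMovieTIFF
#' @export
readMovieTIFF <- function(dir) {
  rd <- function(p) {
    pages <- tiff::readTIFF(p, all = TRUE)
    array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  }
  meta <- jsonlite::read_json(file.path(dir, "movie.json"),
                              simplifyVector = TRUE)
  new("Movie", h2b = rd(file.path(dir, "h2b.tif")),
      cdk2 = rd(file.path(dir, "cdk2.tif")),
      frameTimes = as.numeric(meta$frame_times),
      truth = DataFrame())
}

#' Write label masks as 16-bit TIFF
#'
#' @param masks list of [LabelMask-class].
#' @param path output TIFF (one page per frame; pixel value = label).
#' @export
writeMaskTIFF <- function(masks, path) {
  pages <- lapply(masks, function(m) m@labels / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeMaskTIFF
#' @export
readMaskTIFF <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) {
    lab <- matrix(as.integer(round(p * 65535)), nrow(p), ncol(p))
    .maskFromLabels(lab, matrix(0, nrow(p), ncol(p)))
  })
}

#' Serialize a SyntheticConfig to / from a plain list
#'
#' Round-trips through YAML or JSON for run provenance.
#'
#' @param config a [SyntheticConfig-class].
#' @return `configToList` a named list; `configFromList` a
#'   [SyntheticConfig-class].
#' @export
configToList <- function(config) {
  list(seed = config@seed, frameInterval = config@frameInterval,
       duration = config@duration, imageSize = config@imageSize,
       nCellsInitial = config@nCellsInitial, noiseSd = config@noiseSd,
       fateMixture = lapply(config@fateMixture, as.list),
       windowMixtures = lapply(config@windowMixtures,
                               function(w) lapply(w, as.list)),
       stallConditions = config@stallConditions,
       cycleLength = config@cycleLength,
       stallPlateau = config@stallPlateau,
       commitShape = config@commitShape,
       perturbationTime = config@perturbationTime)
}

#' @rdname configToList
#' @param x a list from `configToList` (or parsed YAML/JSON).
#' @export
configFromList <- function(x) {
  relist <- function(l) vapply(l, as.numeric, numeric(1))
  syntheticConfig(
    seed = x$seed, frameInterval = x$frameInterval, duration = x$duration,
    imageSize = unlist(x$imageSize), nCellsInitial = x$nCellsInitial,
    noiseSd = x$noiseSd,
    fateMixture = lapply(x$fateMixture, relist),
    windowMixtures = lapply(x$windowMixtures, function(w) lapply(w, relist)),
    stallConditions = unlist(x$stallConditions),
    cycleLength = x$cycleLength, stallPlateau = x$stallPlateau,
    commitShape = x$commitShape,
    perturbationTime = if (is.null(x$perturbationTime)) NA_real_
                       else as.numeric(x$perturbationTime))
}

#' Write / read run configuration YAML
#'
#' @param config a [SyntheticConfig-class].
#' @param path YAML file.
#' @export
writeConfigYAML <- function(config, path) {
  yaml::write_yaml(configToList(config), path)
  invisible(path)
}

#' @rdname writeConfigYAML
#' @export
readConfigYAML <- function(path) {
  configFromList(yaml::read_yaml(path))
}

#' Write / read calibration parameters as JSON
#'
#' The JSON record carries the inputs and the derived quantities (dynamic
#' range, fractional saturation, zinc concentration).
#'
#' @param p a [CalibrationParams-class].
#' @param path JSON file.
#' @export
writeCalibrationJSON <- function(p, path) {
  zn <- tryCatch(znConcentration(p), error = function(e) NA_real_)
  jsonlite::write_json(
    list(R_rest = p@rRest, R_min = p@rMin, R_max = p@rMax,
         K_D_pM = p@kd, hill_n = p@hillN,
         dynamic_range = dynamicRange(p),
         fractional_saturation = fractionalSaturation(p),
         zn_pM = zn),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCalibrationJSON
#' @export
readCalibrationJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibrationParams(rRest = x$R_rest, rMin = x$R_min, rMax = x$R_max,
                    kd = x$K_D_pM, hillN = x$hill_n)
}
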