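#' @include AllClasses.R synthetic-movie.R fixed-cell.R
NULL

## lay n cells out on 4x4 grids across as many fields as needed
.layoutFields <- function(n, fieldSize, spacing = 64, jitter = 6) {
  perField <- (fieldSize[1] %/% spacing) * (fieldSize[2] %/% spacing)
  nFields <- ceiling(n / perField)
  gx <- seq(spacing / 2, fieldSize[1] - spacing / 2, by = spacing)
  gy <- seq(spacing / 2, fieldSize[2] - spacing / 2, by = spacing)
  grid <- expand.grid(x = gx, y = gy)
  out <- do.call(rbind, lapply(seq_len(nFields), function(f) {
    k <- if (f < nFields) nrow(grid) else n - (nFields - 1L) * nrow(grid)
    data.frame(field = f, x = grid$x[seq_len(k)], y = grid$y[seq_len(k)])
  }))
  out$x <- out$x + stats::runif(n, -jitter, jitter)
  out$y <- out$y + stats::runif(n, -jitter, jitter)
  out
}

#' Render fixed-cell fields with planted nuclear foci and a bimodal pRb
#' population
#'
#' Generates multi-channel fixed-cell images: a nuclear (Hoechst) channel
#' for segmentation, a foci-marker channel (53BP1 or RPA2 style puncta), and
#' a pRb channel whose per-cell intensity is drawn from a well-separated
#' hypo/hyper log-normal mixture. Exactly `round(fracPositive[s] * n_s)`
#' cells of each pRb stratum carry one or more planted foci whose area and
#' eccentricity lie strictly inside the detection filters, so recovery of
#' the positive fraction is falsifiable against exact truth.
#'
#' @param nCells total cells to render.
#' @param fracPositive named numeric, fraction of damage-positive cells per
#'   pRb stratum, `c(hypo=, hyper=)`. The defaults are the zinc-deficient
#'   53BP1 condition: 87% of cycling (hyper-pRb) cells positive, 10% of
#'   quiescent cells.
#' @param fracHyper fraction of cells in the hyper-pRb (cycling) stratum.
#' @param fociSpec list with `areaRange` (px^2, must sit strictly inside
#'   `params$areaRange`) and `maxPerCell`.
#' @param params the [fociParams()] the images will be analyzed with;
#'   planting outside its filters is rejected.
#' @param config a [SyntheticConfig-class] (seed, image size, noise).
#' @return list with `fields` (list of per-field channel lists: `nuclear`,
#'   `marker`, `prb`), `truth` (per-cell `DataFrame`) and `foci` (per-focus
#'   `DataFrame`).
#' @examples
#' sim <- generateFociImage(32, c(hypo = 0, hyper = 1),
#'                          config = syntheticConfig(seed = 2))
#' sum(sim$truth$positive)
#' @export
generateFociImage <- function(nCells,
                              fracPositive = c(hypo = 0.10, hyper = 0.87),
                              fracHyper = 0.4,
                              fociSpec = list(areaRange = c(30, 100),
                                              maxPerCell = 3L),
                              params = fociParams("53BP1"),
                              config = syntheticConfig()) {
  stopifnot(all(fracPositive >= 0), all(fracPositive <= 1),
            all(c("hypo", "hyper") %in% names(fracPositive)))
  if (fociSpec$areaRange[1] < params$areaRange[1] ||
      fociSpec$areaRange[2] > params$areaRange[2])
    stop("fociSpec area range must lie inside the detection filter range")
  set.seed(config@seed)
  d <- config@imageSize
  lay <- .layoutFields(nCells, d)
  radius <- stats::runif(nCells, 9, 11)

  nHyper <- round(fracHyper * nCells)
  prbClass <- sample(rep(c("hyper", "hypo"), c(nHyper, nCells - nHyper)))
  prbMean <- ifelse(prbClass == "hyper",
                    stats::rlnorm(nCells, log(0.45), 0.2),
                    stats::rlnorm(nCells, log(0.08), 0.2))
  prbMean <- pmin(prbMean, 0.95)

  positive <- logical(nCells)
  for (s in c("hypo", "hyper")) {
    idx <- which(prbClass == s)
    nPos <- round(fracPositive[[s]] * length(idx))
    positive[sample(idx, nPos)] <- TRUE
  }

  fociRows <- list()
  fields <- lapply(seq_len(max(lay$field)), function(f)
    list(nuclear = matrix(0, d[1], d[2]),
         marker = matrix(0, d[1], d[2]),
         prb = matrix(0, d[1], d[2])))

  rMin <- sqrt(fociSpec$areaRange[1] / pi)
  rMax <- sqrt(fociSpec$areaRange[2] / pi)
  for (i in seq_len(nCells)) {
    f <- lay$field[i]
    fields[[f]]$nuclear <- .paintDisc(fields[[f]]$nuclear, lay$x[i], lay$y[i],
                                      radius[i], 0.55)
    fields[[f]]$marker <- .paintDisc(fields[[f]]$marker, lay$x[i], lay$y[i],
                                     radius[i], 0.30)
    fields[[f]]$prb <- .paintDisc(fields[[f]]$prb, lay$x[i], lay$y[i],
                                  radius[i], prbMean[i])
    if (!positive[i]) next
    k <- sample.int(fociSpec$maxPerCell, 1L)
    placed <- matrix(numeric(0), 0, 2)
    for (j in seq_len(k)) {
      fr <- stats::runif(1, rMin, rMax)
      for (try in 1:20) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, 0, max(0, radius[i] - fr - 2))
        px <- lay$x[i] + rad * cos(ang)
        py <- lay$y[i] + rad * sin(ang)
        if (!nrow(placed) ||
            min(sqrt((placed[, 1] - px)^2 + (placed[, 2] - py)^2)) >
              2 * fr + 3) break
      }
      if (nrow(placed) &&
          min(sqrt((placed[, 1] - px)^2 + (placed[, 2] - py)^2)) <=
            2 * fr + 3) next
      placed <- rbind(placed, c(px, py))
      fields[[f]]$marker <- .paintDisc(fields[[f]]$marker, px, py, fr, 1.0)
      fociRows[[length(fociRows) + 1L]] <- data.frame(
        cell_id = i, field = f, x = px, y = py, radius = fr,
        area = pi * fr^2)
    }
  }

  for (f in seq_along(fields)) {
    fields[[f]]$nuclear <- as.matrix(EBImage::gblur(
      EBImage::Image(fields[[f]]$nuclear), sigma = 1))
    fields[[f]]$marker <- as.matrix(EBImage::gblur(
      EBImage::Image(fields[[f]]$marker), sigma = 0.8))
    fields[[f]]$prb <- as.matrix(EBImage::gblur(
      EBImage::Image(fields[[f]]$prb), sigma = 1))
    if (config@noiseSd > 0)
      for (ch in names(fields[[f]]))
        fields[[f]][[ch]] <- pmax(fields[[f]][[ch]] +
          stats::rnorm(prod(d), sd = config@noiseSd * 0.4), 0)
  }

  nFociPerCell <- tabulate(vapply(fociRows, function(r) r$cell_id,
                                  numeric(1)), nbins = nCells)
  truth <- DataFrame(cell_id = seq_len(nCells), field = lay$field,
                     x = lay$x, y = lay$y, radius = radius,
                     prb_class = prbClass, prb_mean = prbMean,
                     positive = positive, n_foci = nFociPerCell)
  foci <- if (length(fociRows)) DataFrame(do.call(rbind, fociRows)) else
    DataFrame(cell_id = integer(0), field = integer(0), x = numeric(0),
              y = numeric(0), radius = numeric(0), area = numeric(0))
  list(fields = fields, truth = truth, foci = foci)
}

#' Render an EdU / propidium-iodide population with known phase mixture
#'
#' Generates fixed-cell fields with a PI (DNA) channel whose integrated
#' nuclear intensity is bimodal at the 2N and 4N centres (S-phase cells
#' intermediate) and an EdU channel in which S-phase cells are bright, plus
#' a smooth additive background gradient to exercise block background
#' subtraction.
#'
#' @param nCells total cells.
#' @param phaseMixture named probabilities over `G0/G1`, `S`, `G2/M`,
#'   summing to 1.
#' @param backgroundGradient peak amplitude of the additive linear EdU
#'   background plane (0 disables it).
#' @param config a [SyntheticConfig-class].
#' @param dnaPixel2N per-pixel PI intensity of a 2N nucleus (4N is twice
#'   that).
#' @param eduLevel mean EdU intensity painted on S-phase nuclei.
#' @return list with `fields` (per-field `pi` and `edu` matrices) and
#'   `truth` (per-cell phase, DNA class and planted intensities).
#' @export
generateEdUPIPopulation <- function(nCells,
                                    phaseMixture = c(`G0/G1` = 0.5, S = 0.3,
                                                     `G2/M` = 0.2),
                                    backgroundGradient = 0.1,
                                    config = syntheticConfig(),
                                    dnaPixel2N = 0.2,
                                    eduLevel = 0.6) {
  stopifnot(abs(sum(phaseMixture) - 1) < 1e-9, all(phaseMixture >= 0),
            all(c("G0/G1", "S", "G2/M") %in% names(phaseMixture)))
  if (max(phaseMixture) == 1 && nCells < 50)
    warning("degenerate mixture at small n: DNA modes cannot be estimated")
  set.seed(config@seed)
  d <- config@imageSize
  lay <- .layoutFields(nCells, d)
  radius <- stats::runif(nCells, 9, 11)
  phases <- c("G0/G1", "S", "G2/M")
  counts <- .allocateCounts(nCells, phaseMixture[phases])
  phase <- sample(rep(phases, counts))
  dnaFactor <- ifelse(phase == "G0/G1", 1,
               ifelse(phase == "G2/M", 2, NA))
  dnaFactor[phase == "S"] <- stats::runif(sum(phase == "S"), 1.3, 1.7)
  dnaFactor <- dnaFactor * stats::rnorm(nCells, 1, 0.03)
  dnaClass <- ifelse(phase == "G0/G1", "2N",
              ifelse(phase == "G2/M", "4N", "intermediate"))

  fields <- lapply(seq_len(max(lay$field)), function(f)
    list(pi = matrix(0, d[1], d[2]), edu = matrix(0, d[1], d[2])))
  for (i in seq_len(nCells)) {
    f <- lay$field[i]
    ## integrated DNA is the planted quantity: per-pixel value compensates
    ## for the nuclear area so 2N/4N totals are tight regardless of radius
    fields[[f]]$pi <- .paintDisc(fields[[f]]$pi, lay$x[i], lay$y[i],
                                 radius[i],
                                 dnaPixel2N * dnaFactor[i] *
                                   (100 / radius[i]^2))
    eduVal <- if (phase[i] == "S") eduLevel else 0.02
    fields[[f]]$edu <- .paintDisc(fields[[f]]$edu, lay$x[i], lay$y[i],
                                  radius[i], eduVal)
  }
  grad <- outer(seq_len(d[1]) / d[1], seq_len(d[2]) / d[2],
                function(a, b) (a + b) / 2) * backgroundGradient
  for (f in seq_along(fields)) {
    fields[[f]]$pi <- as.matrix(EBImage::gblur(
      EBImage::Image(fields[[f]]$pi), sigma = 1))
    fields[[f]]$edu <- as.matrix(EBImage::gblur(
      EBImage::Image(fields[[f]]$edu), sigma = 1)) + grad
    if (config@noiseSd > 0) {
      fields[[f]]$pi <- pmax(fields[[f]]$pi +
        stats::rnorm(prod(d), sd = config@noiseSd * 0.3), 0)
      fields[[f]]$edu <- pmax(fields[[f]]$edu +
        stats::rnorm(prod(d), sd = config@noiseSd * 0.3), 0)
    }
  }
  truth <- DataFrame(cell_id = seq_len(nCells), field = lay$field,
                     x = lay$x, y = lay$y, radius = radius,
                     phase = phase, dna_class = dnaClass,
                     dna_factor = dnaFactor,
                     edu_level = ifelse(phase == "S", eduLevel, 0.02))
  list(fields = fields, truth = truth)
}
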