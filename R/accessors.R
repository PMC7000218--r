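#' @include AllClasses.R AllGenerics.R
NULL

#' Extract the ratio matrix of an ensemble
#'
#' @param x a [TraceEnsemble-class].
#' @return numeric matrix, cells x frames, of CDK2 (or FRET) ratios.
#' @export
cdk2Ratios <- function(x) {
  stopifnot(is(x, "TraceEnsemble"))
  assay(x, "ratio")
}

#' Acquisition times of an ensemble or movie
#'
#' @param x a [TraceEnsemble-class] or [Movie-class].
#' @return numeric vector of frame times in hours.
#' @export
traceTimes <- function(x) {
  if (is(x, "Movie")) return(x@frameTimes)
  stopifnot(is(x, "TraceEnsemble"))
  colData(x)$t_hours
}

#' Recorded division times per cell
#'
#' Division (mitosis) events recorded along each trace, in hours. For
#' synthetic ensembles these are the events the generator planted; for traces
#' quantified from movies they come from mitosis detection.
#'
#' @param x a [TraceEnsemble-class].
#' @return an [IRanges::NumericList], one element per cell.
#' @export
setMethod("divisionTimes", "TraceEnsemble", function(x, ...) {
  rowData(x)$divisions
})

#' Ground truth of a synthetic object
#'
#' @param x a [TraceEnsemble-class] or [Movie-class] produced by the
#'   synthetic generators.
#' @return a `DataFrame` of per-cell truth (fate, commit time, plateau, ...),
#'   or `NULL` when the object carries no truth.
#' @export
setMethod("groundTruth", "TraceEnsemble", function(x, ...) metadata(x)$truth)

#' @rdname groundTruth
#' @export
setMethod("groundTruth", "Movie", function(x, ...) x@truth)

#' LabelMask accessors
#'
#' `labelImage()` returns the integer label matrix, `maskFeatures()` the
#' per-label feature table (optionally re-measured on another intensity
#' image), `nLabels()` the number of segmented regions.
#'
#' @param x a [LabelMask-class].
#' @param image optional numeric matrix; when supplied, mean/total intensity
#'   are measured on it instead of the segmentation channel.
#' @name LabelMask-accessors
NULL

#' @rdname LabelMask-accessors
#' @export
setMethod("labelImage", "LabelMask", function(x) x@labels)

#' @rdname LabelMask-accessors
#' @export
setMethod("nLabels", "LabelMask", function(x) nrow(x@features))

#' @rdname LabelMask-accessors
#' @export
setMethod("maskFeatures", "LabelMask", function(x, image = NULL, ...) {
  if (is.null(image)) return(x@features)
  stopifnot(identical(dim(image), dim(x@labels)))
  fts <- x@features
  lab <- x@labels
  sel <- lab > 0
  sums <- rowsum(as.numeric(image[sel]), lab[sel])
  idx <- match(fts$label, as.integer(rownames(sums)))
  fts$totalIntensity <- as.numeric(sums[idx, 1L])
  fts$meanIntensity <- fts$totalIntensity / fts$area
  fts
})

#' Track node table
#' @param graph a [TrackGraph-class].
#' @return `DataFrame` (frame, label, track).
#' @export
trackNodes <- function(graph) {
  stopifnot(is(graph, "TrackGraph"))
  graph@nodes
}

#' Accepted division events of a track graph
#' @param graph a [TrackGraph-class].
#' @return `DataFrame` (frame, mother, daughter1, daughter2, intensityFold,
#'   areaFold).
#' @export
trackDivisions <- function(graph) {
  stopifnot(is(graph, "TrackGraph"))
  graph@divisions
}

#' Movie channel accessors
#' @param x a [Movie-class].
#' @return numeric array (x, y, frame).
#' @export
h2bChannel <- function(x) { stopifnot(is(x, "Movie")); x@h2b }

#' @rdname h2bChannel
#' @export
cdk2Channel <- function(x) { stopifnot(is(x, "Movie")); x@cdk2 }

## show methods -------------------------------------------------------------

setMethod("show", "TraceEnsemble", function(object) {
  cat(sprintf("TraceEnsemble: %d cells x %d frames (%.1f h at %.0f-min cadence)\n",
              nrow(object), ncol(object),
              max(traceTimes(object)),
              60 * diff(traceTimes(object)[1:2])))
  conds <- table(rowData(object)$condition)
  cat("  conditions:", paste(sprintf("%s (%d)", names(conds), conds),
                             collapse = ", "), "\n")
  nd <- sum(lengths(divisionTimes(object)))
  cat(sprintf("  recorded divisions: %d; ground truth: %s\n", nd,
              if (is.null(groundTruth(object))) "absent" else "present"))
})

setMethod("show", "AlignedTraces", function(object) {
  cat(sprintf("AlignedTraces: %d cells on [%.1f, %.1f] h around mitosis (%d excluded)\n",
              nrow(object@ratio), min(object@relTime), max(object@relTime),
              length(object@excluded)))
})

setMethod("show", "LabelMask", function(object) {
  cat(sprintf("LabelMask: %d nuclei in a %d x %d frame\n",
              nLabels(object), nrow(object@labels), ncol(object@labels)))
})

setMethod("show", "TrackGraph", function(object) {
  cat(sprintf("TrackGraph: %d tracks over %d frames, %d division events\n",
              length(unique(object@nodes$track)),
              length(unique(object@nodes$frame)),
              nrow(object@divisions)))
})

setMethod("show", "CalibrationParams", function(object) {
  cat(sprintf("CalibrationParams: R_rest=%.3f in [R_min=%.3f, R_max=%.3f], K_D=%.0f pM, n=%.2f\n",
              object@rRest, object@rMin, object@rMax, object@kd, object@hillN))
})

setMethod("show", "Movie", function(object) {
  d <- dim(object@h2b)
  cat(sprintf("Movie: %d x %d px, %d frames, 2 channels (H2B, CDK2)\n",
              d[1], d[2], d[3]))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf("SyntheticConfig: seed=%d, %.1f h at %.2f h/frame, %d x %d px\n",
              object@seed, object@duration, object@frameInterval,
              object@imageSize[1], object@imageSize[2]))
  cat("  conditions:", paste(names(object@fateMixture), collapse = ", "), "\n")
})
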