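#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom IRanges NumericList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

## ---------------------------------------------------------------------------
## SyntheticConfig
## ---------------------------------------------------------------------------

#' Configuration of the synthetic experiment generator
#'
#' `SyntheticConfig` bundles every parameter of the synthetic movie/trace
#' generators: acquisition geometry (frame interval, duration, field size),
#' the condition-specific fate mixtures, the cell-cycle length distribution,
#' the stall plateau, and the shape of the post-mitosis CDK2 commitment ramp.
#' Identical configurations (including `seed`) produce bit-identical output.
#'
#' @slot seed integer RNG seed.
#' @slot frameInterval numeric, hours between frames (default 0.2, i.e. 12 min).
#' @slot duration numeric, total imaging time in hours (default 60).
#' @slot imageSize integer(2), field size in pixels.
#' @slot nCellsInitial integer, founder cells per rendered field.
#' @slot noiseSd numeric, additive Gaussian noise (trace-ratio units and
#'   normalized image-intensity units).
#' @slot fateMixture named list; per condition a numeric(3) probability vector
#'   `c(inc=, emerge=, low=)`.
#' @slot windowMixtures named list (by condition) of lists keyed by window
#'   start (hours relative to the perturbation) giving a fate mixture for
#'   cells whose first mitosis falls in that 4-h window.
#' @slot stallConditions character, conditions in which committed cells stall
#'   at `stallPlateau` instead of completing the cycle.
#' @slot cycleLength list with `mode` (hours) and `sigma` (log-scale
#'   dispersion) of the log-normal inter-mitotic time distribution.
#' @slot stallPlateau numeric, CDK2 ratio at which stalled cells plateau.
#' @slot commitShape list with `baseline` (post-mitosis CDK2 ratio),
#'   `riseRate` (ratio units/h) and `maxRatio` (pre-mitosis ceiling).
#' @slot perturbationTime numeric, hours; `NA` when no scheduled perturbation.
#'
#' @seealso [syntheticConfig()] for the user-facing constructor with the
#'   study-condition defaults.
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(
    seed = "integer",
    frameInterval = "numeric",
    duration = "numeric",
    imageSize = "integer",
    nCellsInitial = "integer",
    noiseSd = "numeric",
    fateMixture = "list",
    windowMixtures = "list",
    stallConditions = "character",
    cycleLength = "list",
    stallPlateau = "numeric",
    commitShape = "list",
    perturbationTime = "numeric"
  )
)

.checkMixture <- function(p, what) {
  if (length(p) != 3L || is.null(names(p)) ||
      !setequal(names(p), c("inc", "emerge", "low")))
    return(sprintf("%s must be a named numeric(3) with names inc/emerge/low", what))
  if (any(p < 0) || any(p > 1))
    return(sprintf("%s components must lie in [0, 1]", what))
  if (abs(sum(p) - 1) > 1e-9)
    return(sprintf("%s must sum to 1 (got %.12f)", what, sum(p)))
  NULL
}

setValidity("SyntheticConfig", function(object) {
  msgs <- character()
  if (object@frameInterval <= 0) msgs <- c(msgs, "frameInterval must be > 0")
  if (object@duration < object@frameInterval)
    msgs <- c(msgs, "duration must be >= frameInterval")
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
  if (length(object@imageSize) != 2L || any(object@imageSize < 32L))
    msgs <- c(msgs, "imageSize must be two dimensions >= 32 px")
  for (cond in names(object@fateMixture)) {
    m <- .checkMixture(object@fateMixture[[cond]], paste0("fateMixture$", cond))
    if (!is.null(m)) msgs <- c(msgs, m)
  }
  for (cond in names(object@windowMixtures)) {
    wm <- object@windowMixtures[[cond]]
    for (w in names(wm)) {
      m <- .checkMixture(wm[[w]], sprintf("windowMixtures$%s$`%s`", cond, w))
      if (!is.null(m)) msgs <- c(msgs, m)
    }
  }
  if (!is.list(object@cycleLength) || is.null(object@cycleLength$mode) ||
      object@cycleLength$mode <= 0)
    msgs <- c(msgs, "cycleLength$mode must be a positive number of hours")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## TraceEnsemble
## ---------------------------------------------------------------------------

#' Ensemble of single-cell CDK2 reporter traces
#'
#' A `TraceEnsemble` is a [SummarizedExperiment] with one row per cell
#' lineage and one column per movie frame. The `"ratio"` assay holds the
#' cytoplasmic/nuclear CDK2 reporter ratio; `rowData` carries the condition,
#' well, parent link and the recorded division (mitosis) times of each trace;
#' `colData` carries the frame index and acquisition time in hours. Synthetic
#' ensembles additionally store the generating `SyntheticConfig` and a
#' ground-truth `DataFrame` in `metadata()`.
#'
#' @seealso [generateTraceEnsemble()], [classifyFate()], [divisionTimes()]
#' @exportClass TraceEnsemble
setClass("TraceEnsemble", contains = "SummarizedExperiment")

setValidity("TraceEnsemble", function(object) {
  msgs <- character()
  if (!"ratio" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "TraceEnsemble requires a 'ratio' assay")
  need <- c("cell_id", "condition", "divisions")
  if (!all(need %in% colnames(rowData(object))))
    msgs <- c(msgs, paste("rowData must contain", paste(need, collapse = ", ")))
  if (!"t_hours" %in% colnames(colData(object)))
    msgs <- c(msgs, "colData must contain t_hours")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## AlignedTraces
## ---------------------------------------------------------------------------

#' Mitosis-aligned trace ensemble
#'
#' Produced by [alignToMitosis()]: the ratio matrix re-indexed on a common
#' time axis relative to the chosen mitosis of each cell (time 0 = mitosis).
#' Samples outside a cell's observation span are `NA`. Cells lacking the
#' requested mitosis are excluded and listed in `excluded`.
#'
#' @slot ratio numeric matrix, cells x relative frames.
#' @slot relTime numeric, hours relative to mitosis (one per column).
#' @slot mitosisTime numeric, absolute hour of the alignment mitosis per cell.
#' @slot divisionsAfter [IRanges::NumericList] of later division times
#'   (hours after the alignment mitosis) per cell.
#' @slot info per-cell `DataFrame` (cell_id, condition, well).
#' @slot excluded character, cell ids without the requested event.
#' @exportClass AlignedTraces
setClass("AlignedTraces",
  representation(
    ratio = "matrix",
    relTime = "numeric",
    mitosisTime = "numeric",
    divisionsAfter = "NumericList",
    info = "DataFrame",
    excluded = "character"
  )
)

setValidity("AlignedTraces", function(object) {
  if (ncol(object@ratio) != length(object@relTime))
    return("relTime length must match ratio columns")
  if (nrow(object@ratio) != length(object@mitosisTime))
    return("one mitosisTime per row required")
  TRUE
})

## ---------------------------------------------------------------------------
## LabelMask
## ---------------------------------------------------------------------------

#' Labeled nuclear segmentation of one frame
#'
#' Integer label image (0 = background) plus per-label features measured on
#' the segmentation channel: centroid, area, mean and total intensity.
#'
#' @slot labels integer matrix; positive labels, unique within the frame.
#' @slot features `DataFrame` with columns label, cx, cy, area, meanIntensity,
#'   totalIntensity (one row per label, ordered by label).
#' @exportClass LabelMask
setClass("LabelMask",
  representation(labels = "matrix", features = "DataFrame"))

setValidity("LabelMask", function(object) {
  labs <- object@features$label
  if (length(labs) && any(duplicated(labs)))
    return("labels must be unique within a frame")
  if (length(labs) && any(labs <= 0))
    return("labels must be positive")
  if (sum(object@features$area) > length(object@labels))
    return("sum of region areas exceeds image area")
  TRUE
})

## ---------------------------------------------------------------------------
## RingMask
## ---------------------------------------------------------------------------

#' Perinuclear ring masks
#'
#' For each nucleus, the band of pixels within `width` px (Euclidean) outside
#' its boundary, excluding pixels inside any nucleus and pixels contested by
#' a neighbouring nucleus' ring. Rings clipped at the image border are
#' flagged but still returned.
#'
#' @slot rings integer matrix; 0 = background, otherwise the label whose ring
#'   the pixel belongs to (rings are pairwise disjoint by construction).
#' @slot width integer ring width in px.
#' @slot clipped integer vector of labels whose ring touches the image border.
#' @exportClass RingMask
setClass("RingMask",
  representation(rings = "matrix", width = "integer", clipped = "integer"))

## ---------------------------------------------------------------------------
## TrackGraph
## ---------------------------------------------------------------------------

#' Frame-to-frame identity graph over labeled nuclei
#'
#' @slot nodes `DataFrame` (frame, label, track): every segmented region and
#'   the identity track it belongs to.
#' @slot divisions `DataFrame` (frame, mother, daughter1, daughter2,
#'   intensityFold, areaFold): accepted mitosis events; `frame` is the first
#'   frame of the daughters, mother tracks end on the previous frame.
#' @exportClass TrackGraph
setClass("TrackGraph",
  representation(nodes = "DataFrame", divisions = "DataFrame"))

setValidity("TrackGraph", function(object) {
  nd <- object@nodes
  if (nrow(nd) && anyDuplicated(paste(nd$frame, nd$track)))
    return("a track may occupy at most one region per frame")
  TRUE
})

## ---------------------------------------------------------------------------
## CalibrationParams
## ---------------------------------------------------------------------------

#' FRET zinc-sensor calibration parameters
#'
#' Houses the resting, chelated-minimum and zinc-saturated FRET ratios of a
#' genetically encoded sensor together with its in-situ binding constants.
#' The inverse Hill model converts a resting ratio into a free Zn2+
#' concentration; see [znConcentration()].
#'
#' @slot rRest numeric, resting FRET ratio.
#' @slot rMin numeric, ratio under exhaustive chelation.
#' @slot rMax numeric, ratio under saturating Zn2+.
#' @slot kd numeric, apparent dissociation constant in pM (default 5300).
#' @slot hillN numeric, Hill coefficient (default 0.29).
#' @exportClass CalibrationParams
setClass("CalibrationParams",
  representation(rRest = "numeric", rMin = "numeric", rMax = "numeric",
                 kd = "numeric", hillN = "numeric"))

setValidity("CalibrationParams", function(object) {
  msgs <- character()
  if (object@rMin >= object@rMax) msgs <- c(msgs, "rMin must be < rMax")
  if (object@rRest < object@rMin || object@rRest > object@rMax)
    msgs <- c(msgs, "rRest must satisfy rMin <= rRest <= rMax")
  if (object@kd <= 0) msgs <- c(msgs, "kd must be > 0")
  if (object@hillN <= 0 || object@hillN > 2)
    msgs <- c(msgs, "hillN must lie in (0, 2]")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Movie
## ---------------------------------------------------------------------------

#' Two-channel synthetic time-lapse movie
#'
#' H2B (nuclear marker) and CDK2-reporter channels rendered from a
#' [TraceEnsemble], with the per-frame ground-truth blob table.
#'
#' @slot h2b numeric array (x, y, frame), normalized intensities.
#' @slot cdk2 numeric array (x, y, frame).
#' @slot frameTimes numeric, acquisition time of each frame in hours.
#' @slot truth `DataFrame` (frame, cell_id, x, y, radius, ratio): programmed
#'   position, nuclear radius and reporter ratio of every rendered blob.
#' @exportClass Movie
setClass("Movie",
  representation(h2b = "array", cdk2 = "array", frameTimes = "numeric",
                 truth = "DataFrame"))

setValidity("Movie", function(object) {
  if (dim(object@h2b)[3] != length(object@frameTimes))
    return("frameTimes must match the number of frames")
  if (!identical(dim(object@h2b), dim(object@cdk2)))
    return("channel dimensions must agree")
  TRUE
})
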