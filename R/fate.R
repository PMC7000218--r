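#' @include AllClasses.R accessors.R
NULL

#' Fate-classifier settings
#'
#' Thresholds of the post-mitosis CDK2 fate classifier. A cell whose ratio
#' first crosses `commitThreshold` within `decisionWindow` hours of mitosis
#' is CDK2inc; a later crossing is CDK2emerge; no crossing is CDK2low. Cells
#' observed for less than `minFollowup` hours after mitosis are
#' unclassifiable. Stall detection declares a cell stalled when, after
#' commitment, its ratio remains inside
#' `[commitThreshold - 0.1, stallHighThreshold)` for at least `stallHold`
#' hours through the end of the trace with no further mitosis.
#'
#' @param commitThreshold CDK2 ratio marking cell-cycle commitment (default 1).
#' @param decisionWindow hours after mitosis separating inc from emerge
#'   (default 4).
#' @param minFollowup minimum post-mitosis observation, hours (default 10).
#' @param stallHighThreshold upper ratio bound of the stall band (default 1.5).
#' @param stallHold minimum terminal hold, hours (default 8).
#' @return a list of class `classifierConfig`.
#' @export
classifierConfig <- function(commitThreshold = 1.0, decisionWindow = 4,
                             minFollowup = 10, stallHighThreshold = 1.5,
                             stallHold = 8) {
  stopifnot(commitThreshold < stallHighThreshold,
            decisionWindow > 0, minFollowup > 0, stallHold > 0)
  structure(list(commitThreshold = commitThreshold,
                 decisionWindow = decisionWindow,
                 minFollowup = minFollowup,
                 stallHighThreshold = stallHighThreshold,
                 stallHold = stallHold),
            class = "classifierConfig")
}

#' Align traces to a mitosis event
#'
#' Re-zeroes each cell's time axis to its `event`-th recorded division.
#' Cells lacking that event are excluded and reported in the `excluded` slot.
#' Aligning an already aligned object is the identity.
#'
#' @param x a [TraceEnsemble-class] (or an [AlignedTraces-class], returned
#'   unchanged).
#' @param event which mitosis to align to (1 = first).
#' @param ... unused.
#' @return an [AlignedTraces-class].
#' @export
setMethod("alignToMitosis", "TraceEnsemble", function(x, event = 1L, ...) {
  divs <- divisionTimes(x)
  has <- lengths(divs) >= event
  excluded <- rowData(x)$cell_id[!has]
  tt <- traceTimes(x)
  dt <- if (length(tt) > 1) tt[2] - tt[1] else 1
  keep <- which(has)
  mt <- vapply(divs[keep], function(d) d[[event]], numeric(1))
  ## common relative grid covering every aligned cell
  relMin <- if (length(keep)) min(tt) - max(mt) else 0
  relMax <- if (length(keep)) max(tt) - min(mt) else 0
  rel <- seq(round(relMin / dt), round(relMax / dt)) * dt
  mat <- matrix(NA_real_, length(keep), length(rel))
  R <- cdk2Ratios(x)
  off0 <- round((tt[1] - 0) / dt)
  for (j in seq_along(keep)) {
    shift <- round(mt[j] / dt)
    cols <- round(rel / dt) + shift + 1L - off0
    ok <- cols >= 1L & cols <= length(tt)
    mat[j, ok] <- R[keep[j], cols[ok]]
  }
  rownames(mat) <- rowData(x)$cell_id[keep]
  after <- lapply(seq_along(keep), function(j) {
    d <- divs[[keep[j]]]
    d[d > mt[j] + 1e-9] - mt[j]
  })
  new("AlignedTraces",
      ratio = mat, relTime = rel, mitosisTime = mt,
      divisionsAfter = NumericList(after),
      info = DataFrame(cell_id = rowData(x)$cell_id[keep],
                       condition = rowData(x)$condition[keep],
                       well = rowData(x)$well[keep]),
      excluded = as.character(excluded))
})

#' @rdname alignToMitosis
#' @export
setMethod("alignToMitosis", "AlignedTraces", function(x, event = 1L, ...) x)

## Stall decision on one aligned post-mitosis series.
.stallOne <- function(trel, r, commitTime, divisionsAfter, config) {
  if (is.na(commitTime) || length(divisionsAfter) > 0)
    return(list(stalled = FALSE, plateau = NA_real_))
  band <- !is.na(r) & r >= config$commitThreshold - 0.1 &
    r < config$stallHighThreshold
  post <- trel >= commitTime - 1e-9 & !is.na(r)
  if (!any(post)) return(list(stalled = FALSE, plateau = NA_real_))
  idx <- which(post)
  inb <- band[idx]
  ## longest terminal run inside the band
  lastOut <- if (any(!inb)) max(which(!inb)) else 0L
  runIdx <- idx[seq.int(lastOut + 1L, length(inb))]
  if (lastOut >= length(inb))
    return(list(stalled = FALSE, plateau = NA_real_))
  hold <- trel[runIdx[length(runIdx)]] - trel[runIdx[1L]]
  if (hold < config$stallHold)
    return(list(stalled = FALSE, plateau = NA_real_))
  tEnd <- trel[runIdx[length(runIdx)]]
  tail <- runIdx[trel[runIdx] >= tEnd - config$stallHold]
  list(stalled = TRUE, plateau = stats::median(r[tail]))
}

#' Detect an S-phase stall on a single aligned trace
#'
#' A committed cell is stalled when its CDK2 ratio stays within
#' `[commitThreshold - 0.1, stallHighThreshold)` for at least `stallHold`
#' hours through the end of the trace, with no mitosis after commitment.
#' The plateau estimate is the median ratio over the final `stallHold` hours
#' of the hold.
#'
#' @param trel time relative to mitosis, hours.
#' @param r ratio series (same length).
#' @param commitTime hours after mitosis at which the commit threshold was
#'   first crossed.
#' @param divisionsAfter division times after the aligned mitosis (hours,
#'   relative); any division vetoes a stall.
#' @param config a [classifierConfig()].
#' @return list with `stalled` (logical) and `plateau` (ratio or `NA`).
#' @export
detectStall <- function(trel, r, commitTime, divisionsAfter = numeric(0),
                        config = classifierConfig()) {
  stopifnot(length(trel) == length(r))
  .stallOne(trel, r, commitTime, divisionsAfter, config)
}

#' Classify post-mitosis cell fates
#'
#' Applies the CDK2inc / CDK2emerge / CDK2low taxonomy to every aligned
#' trace: the first upward crossing of `commitThreshold` after mitosis sets
#' the commit time; a crossing within `decisionWindow` hours is CDK2inc, a
#' later one CDK2emerge, and no crossing CDK2low. Cells with less than
#' `minFollowup` hours of post-mitosis observation are labelled
#' `unclassifiable` and excluded from fraction denominators. Stall detection
#' ([detectStall()]) runs on every committed cell.
#'
#' @param x a [TraceEnsemble-class] (aligned internally to its first
#'   mitosis) or an [AlignedTraces-class].
#' @param config a [classifierConfig()].
#' @param event which mitosis to align to when `x` is an ensemble.
#' @param ... unused.
#' @return a `DataFrame` with one row per aligned cell: `cell_id`, `fate`,
#'   `commit_time`, `stalled`, `plateau_ratio`. Cells excluded at alignment
#'   are listed in `metadata(result)$excluded`.
#' @examples
#' ens <- generateTraceEnsemble(syntheticConfig(seed = 1), "ZD", 200)
#' rec <- classifyFate(ens)
#' fateFractions(rec)
#' @export
setMethod("classifyFate", "AlignedTraces", function(x, config = classifierConfig(), ...) {
  n <- nrow(x@ratio)
  fate <- character(n)
  commit <- rep(NA_real_, n)
  stalled <- logical(n)
  plateau <- rep(NA_real_, n)
  trel <- x@relTime
  for (i in seq_len(n)) {
    r <- x@ratio[i, ]
    obs <- which(!is.na(r) & trel > 1e-9)
    if (!length(obs) || trel[obs[length(obs)]] < config$minFollowup) {
      fate[i] <- "unclassifiable"
      next
    }
    cross <- obs[r[obs] >= config$commitThreshold]
    if (!length(cross)) {
      fate[i] <- "CDK2low"
      next
    }
    ct <- trel[cross[1L]]
    commit[i] <- ct
    fate[i] <- if (ct <= config$decisionWindow) "CDK2inc" else "CDK2emerge"
    st <- .stallOne(trel, r, ct, x@divisionsAfter[[i]], config)
    stalled[i] <- st$stalled
    plateau[i] <- st$plateau
  }
  out <- DataFrame(cell_id = x@info$cell_id,
                   condition = x@info$condition,
                   fate = fate, commit_time = commit,
                   stalled = stalled, plateau_ratio = plateau)
  metadata(out)$excluded <- x@excluded
  metadata(out)$config <- config
  out
})

#' @rdname classifyFate
#' @export
setMethod("classifyFate", "TraceEnsemble", function(x, config = classifierConfig(),
                                                    event = 1L, ...) {
  classifyFate(alignToMitosis(x, event = event), config = config)
})

#' Fate fractions over classifiable cells
#'
#' @param records the `DataFrame` returned by [classifyFate()].
#' @param percent return percentages instead of proportions.
#' @return named numeric over CDK2inc / CDK2emerge / CDK2low summing to 1
#'   (or 100), with attribute `n` = number of classifiable cells.
#' @export
fateFractions <- function(records, percent = FALSE) {
  cl <- records$fate[records$fate != "unclassifiable"]
  n <- length(cl)
  f <- c(CDK2inc = sum(cl == "CDK2inc"),
         CDK2emerge = sum(cl == "CDK2emerge"),
         CDK2low = sum(cl == "CDK2low")) / max(n, 1L)
  if (percent) f <- 100 * f
  attr(f, "n") <- n
  f
}

#' Bin cells by when their first mitosis fell relative to a perturbation
#'
#' Partitions cells into half-open `[a, a + window)` bins of first-mitosis
#' time relative to `tPerturb` (a mitosis exactly at the perturbation falls
#' in the first post-perturbation bin), classifies fates within each bin,
#' and reports per-bin fate fractions. Cells whose first mitosis falls
#' outside `range` are excluded and counted.
#'
#' @param ensemble a [TraceEnsemble-class].
#' @param tPerturb perturbation time, hours (absolute movie time).
#' @param window bin width in hours (> 0, default 4).
#' @param range numeric(2), bin span in hours relative to `tPerturb`
#'   (default `c(-4, 16)`).
#' @param config a [classifierConfig()].
#' @return a `DataFrame` of fate records with a `window_bin` label column;
#'   `metadata()` carries `summary` (per-bin fractions and counts) and
#'   `n_excluded`.
#' @export
binByMitosisWindow <- function(ensemble, tPerturb, window = 4,
                               range = c(-4, 16),
                               config = classifierConfig()) {
  if (window <= 0) stop("window must be > 0")
  aligned <- alignToMitosis(ensemble, event = 1L)
  rec <- classifyFate(aligned, config = config)
  rel <- aligned@mitosisTime - tPerturb
  inR <- rel >= range[1] & rel < range[2]
  starts <- range[1] + window * floor((rel - range[1]) / window)
  lab <- sprintf("[%g,%g)", starts, starts + window)
  rec$window_bin <- ifelse(inR, lab, NA_character_)
  rec$mitosis_rel <- rel
  out <- rec[inR, ]
  binLevels <- sprintf("[%g,%g)", seq(range[1], range[2] - window, by = window),
                       seq(range[1] + window, range[2], by = window))
  summ <- do.call(rbind, lapply(binLevels, function(bl) {
    f <- fateFractions(out[out$window_bin == bl, , drop = FALSE])
    data.frame(window_bin = bl, n = attr(f, "n"),
               CDK2inc = f[["CDK2inc"]], CDK2emerge = f[["CDK2emerge"]],
               CDK2low = f[["CDK2low"]])
  }))
  metadata(out)$summary <- summ
  metadata(out)$n_excluded <- sum(!inR) + length(aligned@excluded)
  out
}

#' Inter-mitotic times and their histogram mode
#'
#' Durations between consecutive recorded divisions along each lineage
#' (including mother-to-daughter chains via `parent_id`). The mode is the
#' centre of the tallest 1-h histogram bin (bins centred on integer hours).
#'
#' @param ensemble a [TraceEnsemble-class].
#' @param binWidth histogram bin width, hours.
#' @return list with `durations` (hours) and `mode` (`NA` when fewer than
#'   one duration exists).
#' @export
intermitoticTimes <- function(ensemble, binWidth = 1) {
  divs <- divisionTimes(ensemble)
  rd <- rowData(ensemble)
  durations <- unlist(lapply(seq_along(divs), function(i) {
    d <- sort(divs[[i]])
    pid <- rd$parent_id[i]
    if (!is.na(pid)) {
      j <- match(pid, rd$cell_id)
      if (!is.na(j) && length(divs[[j]]))
        d <- c(max(divs[[j]]), d)   # birth of this lineage = mother's division
    }
    if (length(d) >= 2) diff(d) else numeric(0)
  }), use.names = FALSE)
  if (!length(durations)) return(list(durations = numeric(0), mode = NA_real_))
  breaks <- seq(binWidth / 2, ceiling(max(durations)) + binWidth, by = binWidth)
  breaks <- c(0, breaks[breaks > 0])
  h <- graphics::hist(durations, breaks = breaks, plot = FALSE)
  list(durations = durations, mode = h$mids[which.max(h$counts)])
}

#' Order traces for heatmap display
#'
#' Resamples nothing (traces share the frame grid) but orders rows either by
#' mean ratio over the final `finalWindow` hours (`end_activity`, ascending:
#' CDK2-low at the top) or by first-mitosis time (`mitosis_time`). Ties are
#' broken by cell id; the ordering is invariant to the input row order.
#'
#' @param ensemble a [TraceEnsemble-class].
#' @param mode `"end_activity"` or `"mitosis_time"`.
#' @param finalWindow hours at the end of imaging used by `end_activity`.
#' @return the ratio matrix with rows reordered; `attr(, "order")` gives the
#'   cell ids in display order.
#' @export
sortHeatmap <- function(ensemble, mode = c("end_activity", "mitosis_time"),
                        finalWindow = 2) {
  mode <- match.arg(mode)
  R <- cdk2Ratios(ensemble)
  tt <- traceTimes(ensemble)
  ids <- rowData(ensemble)$cell_id
  key <- if (mode == "end_activity") {
    sel <- tt >= max(tt) - finalWindow
    rowMeans(R[, sel, drop = FALSE], na.rm = TRUE)
  } else {
    vapply(divisionTimes(ensemble), function(d)
      if (length(d)) min(d) else Inf, numeric(1))
  }
  ord <- order(key, ids)
  out <- R[ord, , drop = FALSE]
  rownames(out) <- ids[ord]
  attr(out, "order") <- ids[ord]
  out
}

#' CDK2 ratio density at a fixed time
#'
#' Normalized histogram of the instantaneous CDK2 ratio across all cells
#' alive at hour `at`; the density integrates to 1 over the binned support.
#'
#' @param ensemble a [TraceEnsemble-class].
#' @param at hour to slice at (nearest frame used).
#' @param bins number of bins or an explicit break vector.
#' @return `DataFrame` (bin_left, bin_right, density).
#' @export
cdk2Density <- function(ensemble, at, bins = 40) {
  tt <- traceTimes(ensemble)
  j <- which.min(abs(tt - at))
  v <- cdk2Ratios(ensemble)[, j]
  v <- v[!is.na(v)]
  if (!length(v)) stop("no cells alive at the requested hour")
  breaks <- if (length(bins) > 1) bins else
    seq(min(v), max(v) + 1e-9, length.out = bins + 1L)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  DataFrame(bin_left = utils::head(h$breaks, -1),
            bin_right = utils::tail(h$breaks, -1),
            density = h$density)
}
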