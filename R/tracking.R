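#' @include AllClasses.R accessors.R segmentation.R
NULL

#' Tracking parameters
#'
#' @param maxDisplacement gate: maximum centroid displacement per frame, px.
#' @return parameter list for [trackCells()].
#' @export
trackingParams <- function(maxDisplacement = 10) {
  stopifnot(maxDisplacement > 0)
  list(maxDisplacement = maxDisplacement)
}

#' Mitosis-detection parameters
#'
#' A 1-to-2 split is accepted as a mitosis only when, over the `window`
#' frames before the split, the mother's mean H2B intensity rose by at least
#' `intensityRise` and her area fell to at most `areaFall` of its earlier
#' value (the chromatin-condensation signature). `gate` is the maximum
#' distance (px) between a newborn region and its candidate mother.
#'
#' @param window frames before the split used for the fold changes.
#' @param intensityRise minimum mean-intensity fold change (default 1.3).
#' @param areaFall maximum area fold change (default 0.6).
#' @param gate mother-daughter association distance, px.
#' @return parameter list for [detectMitosis()].
#' @export
mitosisParams <- function(window = 3L, intensityRise = 1.3, areaFall = 0.6,
                          gate = 15) {
  stopifnot(window >= 1, intensityRise > 1, areaFall < 1, gate > 0)
  list(window = as.integer(window), intensityRise = intensityRise,
       areaFall = areaFall, gate = gate)
}

#' Track nuclei across frames by gated nearest-centroid assignment
#'
#' Greedy globally-nearest assignment between consecutive frames: the
#' closest (previous region, current region) pair within the displacement
#' gate is linked first, then the next closest among the remaining, and so
#' on. Unmatched current-frame regions start new tracks; unmatched
#' previous-frame regions terminate.
#'
#' @param masks list of [LabelMask-class], one per frame in temporal order.
#' @param params see [trackingParams()].
#' @return a [TrackGraph-class] (no division edges yet; see
#'   [detectMitosis()]).
#' @export
trackCells <- function(masks, params = trackingParams()) {
  if (!length(masks)) stop("at least one frame required")
  gate <- params$maxDisplacement
  nodes <- list()
  nextTrack <- 1L
  prev <- NULL   # data.frame: label, cx, cy, track
  for (f in seq_along(masks)) {
    ft <- masks[[f]]@features
    cur <- data.frame(label = ft$label, cx = ft$cx, cy = ft$cy,
                      track = NA_integer_)
    if (!is.null(prev) && nrow(prev) && nrow(cur)) {
      dmat <- outer(prev$cx, cur$cx, "-")^2 + outer(prev$cy, cur$cy, "-")^2
      dmat <- sqrt(dmat)
      repeat {
        m <- which.min(dmat)
        if (!length(m) || !is.finite(dmat[m]) || dmat[m] > gate) break
        i <- (m - 1L) %% nrow(prev) + 1L
        j <- (m - 1L) %/% nrow(prev) + 1L
        cur$track[j] <- prev$track[i]
        dmat[i, ] <- Inf
        dmat[, j] <- Inf
      }
    }
    newborn <- is.na(cur$track)
    if (any(newborn)) {
      cur$track[newborn] <- seq.int(nextTrack, length.out = sum(newborn))
      nextTrack <- nextTrack + sum(newborn)
    }
    nodes[[f]] <- data.frame(frame = f, label = cur$label, track = cur$track)
    prev <- cur
  }
  nodes <- do.call(rbind, nodes)
  new("TrackGraph",
      nodes = DataFrame(frame = nodes$frame, label = nodes$label,
                        track = nodes$track),
      divisions = DataFrame(frame = integer(0), mother = integer(0),
                            daughter1 = integer(0), daughter2 = integer(0),
                            intensityFold = numeric(0),
                            areaFold = numeric(0)))
}

## per-(frame, label) feature lookup across a mask list
.nodeFeature <- function(masks, frame, label, what) {
  ft <- masks[[frame]]@features
  ft[[what]][match(label, ft$label)]
}

#' Detect mitoses from track births and the condensation signature
#'
#' Every track born after the first frame is a candidate daughter. Its
#' nearest track in the previous frame (within `gate`) is the candidate
#' mother; the mother's own continuation in the birth frame is the second
#' daughter. The split is accepted as a mitosis only if the mother shows the
#' chromatin-condensation signature: mean H2B intensity up by at least
#' `intensityRise` and area down to at most `areaFall` over the `window`
#' frames before the split. Accepted splits cut the mother's track at the
#' split: her continuation is relabelled as a new daughter track. Rejected
#' splits leave the newborn as an unrelated track.
#'
#' @param graph a [TrackGraph-class] from [trackCells()].
#' @param masks the list of [LabelMask-class] the graph was built on.
#' @param params see [mitosisParams()].
#' @return a list: `graph` (updated [TrackGraph-class] with division rows
#'   and daughter track ids) and `events` (the division `DataFrame`).
#' @export
detectMitosis <- function(graph, masks, params = mitosisParams()) {
  nodes <- as.data.frame(graph@nodes)
  nfr <- length(masks)
  birth <- stats::aggregate(frame ~ track, nodes, min)
  events <- list()
  nextTrack <- max(nodes$track) + 1L
  pendingPair <- list()   # "frame:mother" -> event index awaiting daughter2
  for (k in which(birth$frame > 1L)) {
    f <- birth$frame[k]
    dtrack <- birth$track[k]
    dlab <- nodes$label[nodes$track == dtrack & nodes$frame == f]
    dxy <- c(.nodeFeature(masks, f, dlab, "cx"),
             .nodeFeature(masks, f, dlab, "cy"))
    prevNodes <- nodes[nodes$frame == f - 1L, ]
    if (!nrow(prevNodes)) next
    px <- .nodeFeature(masks, f - 1L, prevNodes$label, "cx")
    py <- .nodeFeature(masks, f - 1L, prevNodes$label, "cy")
    dd <- sqrt((px - dxy[1])^2 + (py - dxy[2])^2)
    if (min(dd) > params$gate) next
    mother <- prevNodes$track[which.min(dd)]
    if (mother == dtrack) next
    key <- paste0(f, ":", mother)
    if (!is.null(pendingPair[[key]])) {
      ## mother terminated at the split and this is her second newborn
      events[[pendingPair[[key]]]]$daughter2 <- dtrack
      pendingPair[[key]] <- NULL
      next
    }
    ## condensation signature over the window before the split
    mNodes <- nodes[nodes$track == mother & nodes$frame < f, ]
    mNodes <- mNodes[order(mNodes$frame), ]
    if (nrow(mNodes) < params$window + 1L) next
    fLate <- mNodes$frame[nrow(mNodes)]
    if (fLate != f - 1L) next
    fEarly <- fLate - params$window
    early <- mNodes[mNodes$frame == fEarly, ]
    if (!nrow(early)) next
    iLate <- .nodeFeature(masks, fLate, mNodes$label[nrow(mNodes)], "meanIntensity")
    aLate <- .nodeFeature(masks, fLate, mNodes$label[nrow(mNodes)], "area")
    iEarly <- .nodeFeature(masks, fEarly, early$label, "meanIntensity")
    aEarly <- .nodeFeature(masks, fEarly, early$label, "area")
    iFold <- iLate / iEarly
    aFold <- aLate / aEarly
    if (is.na(iFold) || is.na(aFold) ||
        iFold < params$intensityRise || aFold > params$areaFall) next
    ## accept: cut the mother's continuation into a second daughter track
    contSel <- nodes$track == mother & nodes$frame >= f
    d2 <- if (any(contSel)) {
      nodes$track[contSel] <- nextTrack
      nextTrack <- nextTrack + 1L
      nextTrack - 1L
    } else NA_integer_
    events[[length(events) + 1L]] <- data.frame(
      frame = f, mother = mother, daughter1 = dtrack,
      daughter2 = d2, intensityFold = iFold, areaFold = aFold)
    if (is.na(d2)) pendingPair[[key]] <- length(events)
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(frame = integer(0), mother = integer(0),
               daughter1 = integer(0), daughter2 = integer(0),
               intensityFold = numeric(0), areaFold = numeric(0))
  g <- new("TrackGraph",
           nodes = DataFrame(frame = nodes$frame, label = nodes$label,
                             track = nodes$track),
           divisions = DataFrame(ev))
  list(graph = g, events = g@divisions)
}
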