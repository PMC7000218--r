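#' @include AllClasses.R accessors.R segmentation.R
NULL

#' Perinuclear ring masks for cytoplasmic reporter quantification
#'
#' Draws, for every nucleus, a ring `width` pixels wide immediately outside
#' the nuclear boundary (Euclidean dilation minus the nuclei). Pixels inside
#' any nucleus are never part of a ring, and pixels reachable from more than
#' one nucleus (contested between neighbours) are dropped from both rings,
#' so rings are pairwise disjoint. Rings truncated by the image border are
#' flagged in `clipped` but still returned.
#'
#' @param mask a [LabelMask-class].
#' @param width ring width in pixels (default 3).
#' @return a [RingMask-class].
#' @export
perinuclearRing <- function(mask, width = 3L) {
  stopifnot(is(mask, "LabelMask"), width >= 1)
  width <- as.integer(width)
  lab <- mask@labels
  d <- dim(lab)
  rings <- matrix(0L, d[1], d[2])
  claims <- matrix(0L, d[1], d[2])
  brush <- EBImage::makeBrush(2L * width + 1L, shape = "disc")
  labs <- mask@features$label
  anyNuc <- lab > 0
  boxes <- lapply(labs, function(l) {
    w <- which(lab == l, arr.ind = TRUE)
    rbind(pmax(1L, c(min(w[, 1]), min(w[, 2])) - width - 1L),
          pmin(d, c(max(w[, 1]), max(w[, 2])) + width + 1L))
  })
  dils <- vector("list", length(labs))
  clipped <- integer(0)
  for (k in seq_along(labs)) {
    b <- boxes[[k]]
    sub <- lab[b[1, 1]:b[2, 1], b[1, 2]:b[2, 2]] == labs[k]
    dil <- EBImage::dilate(EBImage::Image(sub * 1), brush) > 0
    dils[[k]] <- dil
    claims[b[1, 1]:b[2, 1], b[1, 2]:b[2, 2]] <-
      claims[b[1, 1]:b[2, 1], b[1, 2]:b[2, 2]] + dil
    ## border clipping: the dilated support hits the image edge
    w <- which(lab == labs[k], arr.ind = TRUE)
    if (min(w[, 1]) <= width || min(w[, 2]) <= width ||
        max(w[, 1]) > d[1] - width || max(w[, 2]) > d[2] - width)
      clipped <- c(clipped, labs[k])
  }
  for (k in seq_along(labs)) {
    b <- boxes[[k]]
    ri <- b[1, 1]:b[2, 1]; ci <- b[1, 2]:b[2, 2]
    ring <- dils[[k]] & !anyNuc[ri, ci] & claims[ri, ci] == 1L
    sub <- rings[ri, ci]
    sub[ring] <- labs[k]
    rings[ri, ci] <- sub
  }
  new("RingMask", rings = rings, width = width, clipped = clipped)
}

#' Quantify nuclear and ring intensities of a reporter channel
#'
#' @param mask a [LabelMask-class].
#' @param ring a [RingMask-class] from [perinuclearRing()].
#' @param image numeric matrix, the reporter channel.
#' @param stat cytoplasmic statistic over the ring: `"median"` (robust to
#'   bleed-through from neighbours, the default) or `"mean"`.
#' @return `DataFrame` (label, nuc_mean, ring_value, cdk2_ratio).
#' @export
ringQuantify <- function(mask, ring, image, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  stopifnot(identical(dim(image), dim(mask@labels)))
  labs <- mask@features$label
  lab <- mask@labels
  nuc <- vapply(labs, function(l) mean(image[lab == l]), numeric(1))
  rv <- vapply(labs, function(l) {
    px <- image[ring@rings == l]
    if (!length(px)) return(NA_real_)
    if (stat == "median") stats::median(px) else mean(px)
  }, numeric(1))
  DataFrame(label = labs, nuc_mean = nuc, ring_value = rv,
            cdk2_ratio = cdk2Ratio(rv, nuc))
}

#' CDK2 translocation-reporter activity ratio
#'
#' Ratio of cytoplasmic to nuclear reporter fluorescence; rises as CDK2
#' activity drives the reporter out of the nucleus.
#'
#' @param cytoMean cytoplasmic (perinuclear ring) intensity.
#' @param nucMean nuclear intensity; must be > 0.
#' @return `cytoMean / nucMean` (vectorized).
#' @export
cdk2Ratio <- function(cytoMean, nucMean) {
  if (any(!is.na(nucMean) & nucMean <= 0))
    stop("nuclear mean must be > 0: ratio undefined")
  cytoMean / nucMean
}

#' Background-subtracted FRET ratio
#'
#' `(FRET_cell - FRET_background) / (CFP_cell - CFP_background)`. Negative
#' background-subtracted numerators are clipped at a small epsilon to avoid
#' sign flips from noise.
#'
#' @param fretCell,cfpCell mean FRET / CFP intensities of the cell.
#' @param fretBg,cfpBg background intensities (dark-region estimates).
#' @param eps clip floor for the numerator.
#' @return the FRET ratio (vectorized).
#' @export
fretRatio <- function(fretCell, cfpCell, fretBg = 0, cfpBg = 0, eps = 1e-9) {
  if (any(cfpCell <= cfpBg))
    stop("CFP signal at or below background: ratio undefined")
  num <- pmax(fretCell - fretBg, 0)
  num / (cfpCell - cfpBg)
}

#' Mean reporter ratio in a window before mitosis
#'
#' @param t sample times, hours.
#' @param r ratio series (same length as `t`).
#' @param tMitosis hour of the mitosis.
#' @param window window length, hours (default 1): samples in
#'   `(tMitosis - window, tMitosis)` are averaged.
#' @return mean ratio over the in-window samples.
#' @export
premitosisAverage <- function(t, r, tMitosis, window = 1) {
  stopifnot(length(t) == length(r))
  if (is.na(tMitosis)) stop("no mitosis supplied")
  sel <- t > tMitosis - window & t < tMitosis & !is.na(r)
  if (!any(sel)) stop("no samples in the pre-mitosis window")
  mean(r[sel])
}

#' Quantify a rendered movie through segmentation, tracking and ring masks
#'
#' Runs the image pipeline end to end on a [Movie-class]: per-frame nuclear
#' segmentation on the H2B channel, perinuclear rings, and CDK2 ratio
#' quantification on the reporter channel.
#'
#' @param movie a [Movie-class].
#' @param segParams segmentation parameters, see [segmentationParams()].
#' @param ringWidth ring width in px.
#' @param stat cytoplasmic statistic, see [ringQuantify()].
#' @return `DataFrame` (frame, t_hours, label, nuc_mean, ring_value,
#'   cdk2_ratio).
#' @export
quantifyMovie <- function(movie, segParams = segmentationParams(),
                          ringWidth = 3L, stat = "median") {
  stopifnot(is(movie, "Movie"))
  nfr <- dim(movie@h2b)[3]
  res <- vector("list", nfr)
  for (f in seq_len(nfr)) {
    m <- segmentNuclei(movie@h2b[, , f], segParams)
    if (nLabels(m) == 0L) next
    rg <- perinuclearRing(m, width = ringWidth)
    q <- ringQuantify(m, rg, movie@cdk2[, , f], stat = stat)
    q$frame <- f
    q$t_hours <- movie@frameTimes[f]
    res[[f]] <- q
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(DataFrame(label = integer(0), nuc_mean = numeric(0),
                     ring_value = numeric(0), cdk2_ratio = numeric(0),
                     frame = integer(0), t_hours = numeric(0)))
  do.call(rbind, res)
}
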