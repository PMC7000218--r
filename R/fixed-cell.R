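#' @include AllClasses.R segmentation.R
#' @importFrom mclust Mclust mclustBIC predict.Mclust
NULL

#' Foci-detection parameters
#'
#' Size/shape filters for nuclear foci. Defaults follow the marker: 53BP1
#' (double-strand break) foci admit areas of 10-200 px^2, RPA2 (single-strand
#' break / replication stress) foci 10-100 px^2; both require eccentricity
#' < 0.6 (0 is a perfect circle).
#'
#' @param marker `"53BP1"` or `"RPA2"` (sets `areaRange`).
#' @param cropSize side of the per-cell analysis square, px (default 140).
#' @param areaRange numeric(2), admissible focus area in px^2.
#' @param eccentricityMax maximum eccentricity (default 0.6).
#' @param sensitivity local-threshold sensitivity on the normalized crop
#'   scale, in (0, 1); a candidate pixel must exceed its local mean by
#'   `(1 - sensitivity)` of the crop's dynamic range.
#' @return parameter list for [detectFoci()].
#' @export
fociParams <- function(marker = c("53BP1", "RPA2"), cropSize = 140L,
                       areaRange = NULL, eccentricityMax = 0.6,
                       sensitivity = 0.5) {
  marker <- match.arg(marker)
  if (is.null(areaRange))
    areaRange <- if (marker == "RPA2") c(10, 100) else c(10, 200)
  stopifnot(areaRange[1] < areaRange[2], eccentricityMax >= 0,
            eccentricityMax < 1, sensitivity > 0, sensitivity < 1)
  list(marker = marker, cropSize = as.integer(cropSize),
       areaRange = areaRange, eccentricityMax = eccentricityMax,
       sensitivity = sensitivity)
}

#' Detect nuclear foci per cell
#'
#' For each nucleus a `cropSize` square is centred on its centroid (clipped
#' at the borders). Within the (lightly smoothed) crop, candidate pixels
#' exceed the cell's median nuclear intensity by `(1 - sensitivity)` of the
#' contrast between that background and the brightest structure in the
#' crop, with an absolute contrast floor of 0.15 (normalized units) so that
#' featureless crops yield no candidates; candidates are labelled
#' (8-connected) and filtered by
#' `areaRange` and `eccentricityMax`, and only components overlapping the
#' cell's own nucleus are kept.
#'
#' @param image numeric matrix, the foci-marker channel.
#' @param mask a [LabelMask-class] of the nuclei.
#' @param params see [fociParams()].
#' @return `DataFrame` (cell_id, x, y, area, eccentricity), one row per
#'   retained focus; zero rows is a valid result.
#' @export
detectFoci <- function(image, mask, params = fociParams()) {
  stopifnot(identical(dim(image), dim(mask@labels)))
  d <- dim(image)
  half <- params$cropSize %/% 2L
  ft <- mask@features
  out <- list()
  for (k in seq_len(nrow(ft))) {
    cx <- round(ft$cx[k]); cy <- round(ft$cy[k])
    xi <- max(1L, cx - half):min(d[1], cx + half)
    yi <- max(1L, cy - half):min(d[2], cy + half)
    crop <- image[xi, yi, drop = FALSE]
    if (diff(range(crop)) <= 0) next
    sm <- as.matrix(EBImage::gblur(EBImage::Image(crop), sigma = 1))
    nucCropSel <- mask@labels[xi, yi, drop = FALSE] == ft$label[k]
    nucMed <- stats::median(sm[nucCropSel])
    ## threshold: a sensitivity-scaled fraction of the contrast between the
    ## nuclear background and the brightest structure in the crop, with an
    ## absolute floor so featureless crops yield no candidates
    thr <- nucMed + max((1 - params$sensitivity) * (max(sm) - nucMed), 0.15)
    cand <- sm > thr
    if (!any(cand)) next
    lab <- labelComponents(cand, connectivity = 8L)
    nl <- max(lab)
    if (nl == 0L) next
    nucCrop <- nucCropSel
    fts <- EBImage::computeFeatures.moment(lab, as.matrix(crop))
    if (is.null(dim(fts))) fts <- matrix(fts, nrow = 1,
                                         dimnames = list(NULL, names(fts)))
    areas <- tabulate(lab[lab > 0], nbins = nl)
    for (l in seq_len(nl)) {
      a <- areas[l]
      if (a < params$areaRange[1] || a > params$areaRange[2]) next
      if (fts[l, "m.eccentricity"] >= params$eccentricityMax) next
      if (!any(nucCrop[lab == l])) next
      out[[length(out) + 1L]] <- data.frame(
        cell_id = ft$label[k],
        x = fts[l, "m.cx"] + xi[1] - 1, y = fts[l, "m.cy"] + yi[1] - 1,
        area = a, eccentricity = fts[l, "m.eccentricity"])
    }
  }
  if (!length(out))
    return(DataFrame(cell_id = integer(0), x = numeric(0), y = numeric(0),
                     area = numeric(0), eccentricity = numeric(0)))
  DataFrame(do.call(rbind, out))
}

#' Fraction of damage-positive cells per stratum
#'
#' A cell is damage-positive when it carries one or more detected foci.
#'
#' @param fociCount integer vector, foci per cell.
#' @param stratifyBy factor/character of the same length (e.g. pRb class);
#'   `NULL` for a single overall stratum.
#' @return `DataFrame` (stratum, n, fraction). Empty strata are omitted with
#'   a warning.
#' @export
damageFraction <- function(fociCount, stratifyBy = NULL) {
  if (is.null(stratifyBy)) stratifyBy <- rep("all", length(fociCount))
  stopifnot(length(fociCount) == length(stratifyBy))
  lv <- unique(as.character(stratifyBy))
  empty <- setdiff(lv, as.character(stratifyBy))
  if (length(empty))
    warning("empty strata omitted: ", paste(empty, collapse = ", "))
  res <- lapply(lv, function(s) {
    sel <- stratifyBy == s
    data.frame(stratum = s, n = sum(sel),
               fraction = mean(fociCount[sel] >= 1))
  })
  DataFrame(do.call(rbind, res))
}

#' Classify cells as hypo- or hyper-phosphorylated Rb
#'
#' Two-component Gaussian mixture on log mean pRb intensity
#' ([mclust::Mclust]); the boundary sits at equal posterior probability and
#' the higher-mean component is labelled `hyper` (cycling), the lower
#' `hypo` (quiescent). The split is scale-invariant. If the intensity
#' distribution does not support two components the result is single-class
#' with a warning.
#'
#' @param prbMean numeric vector of per-cell mean pRb intensities (> 0).
#' @return list with `class` (factor hypo/hyper per cell) and `boundary`
#'   (intensity at equal posterior, `NA` for single-class results).
#' @export
classifyPRb <- function(prbMean) {
  stopifnot(all(prbMean > 0))
  if (length(prbMean) < 20)
    stop("at least 20 cells required for mixture estimation")
  lx <- log(prbMean)
  if (stats::sd(lx) < 1e-9) {
    warning("constant pRb intensities: single-class result")
    return(list(class = factor(rep("hypo", length(lx)),
                               levels = c("hypo", "hyper")),
                boundary = NA_real_))
  }
  fit2 <- mclust::Mclust(lx, G = 2, modelNames = "V", verbose = FALSE)
  fit1 <- mclust::Mclust(lx, G = 1, modelNames = "X", verbose = FALSE)
  if (is.null(fit2) || (!is.null(fit1) && fit1$bic >= fit2$bic)) {
    warning("pRb intensities look unimodal: single-class result")
    return(list(class = factor(rep("hypo", length(lx)),
                               levels = c("hypo", "hyper")),
                boundary = NA_real_))
  }
  hi <- which.max(fit2$parameters$mean)
  cls <- ifelse(fit2$classification == hi, "hyper", "hypo")
  ## boundary: equal-posterior point between the two means
  mus <- fit2$parameters$mean
  grid <- seq(min(mus), max(mus), length.out = 512)
  post <- mclust::predict.Mclust(fit2, newdata = grid)$z
  cross <- which(diff(sign(post[, hi] - 0.5)) != 0)
  boundary <- if (length(cross)) exp(grid[cross[1]]) else NA_real_
  list(class = factor(cls, levels = c("hypo", "hyper")), boundary = boundary)
}

#' Block-wise percentile background subtraction
#'
#' Divides the image into a `blocks x blocks` grid of equal tiles, takes the
#' lowest `percentile` intensity of each tile as its background, subtracts
#' it from the tile and clips negatives at zero. Used to remove the smooth
#' residual background of EdU stains before intensity quantification.
#'
#' @param image numeric matrix, at least `blocks` px in each dimension.
#' @param blocks grid size per side (default 11).
#' @param percentile background quantile in each tile (default 0.05).
#' @return corrected matrix of the same size.
#' @export
blockBackgroundSubtract <- function(image, blocks = 11L, percentile = 0.05) {
  d <- dim(image)
  if (any(d < blocks)) stop("image smaller than the block grid")
  xi <- cut(seq_len(d[1]), blocks, labels = FALSE)
  yi <- cut(seq_len(d[2]), blocks, labels = FALSE)
  out <- image
  for (i in seq_len(blocks)) for (j in seq_len(blocks)) {
    sel1 <- xi == i; sel2 <- yi == j
    tile <- image[sel1, sel2, drop = FALSE]
    bg <- stats::quantile(tile, percentile, names = FALSE)
    out[sel1, sel2] <- pmax(tile - bg, 0)
  }
  out
}

## two dominant modes of a numeric vector by kernel density
.twoModes <- function(v) {
  ## narrow bandwidth: the default rule smears tight 2N/4N peaks into the
  ## broad S-phase plateau between them
  dens <- stats::density(v, bw = stats::bw.nrd0(v) / 3, n = 512)
  y <- dens$y
  pk <- which(diff(sign(diff(y))) == -2) + 1L
  pk <- pk[y[pk] > 0.05 * max(y)]
  if (length(pk) < 2L) {
    return(list(centers = dens$x[pk[which.max(y[pk])]], single = TRUE))
  }
  pk <- pk[order(y[pk], decreasing = TRUE)]
  ## the two tallest peaks separated by at least 40% in location
  c1 <- dens$x[pk[1]]
  rest <- dens$x[pk[-1]]
  far <- rest[abs(rest - c1) > 0.4 * c1]
  if (!length(far)) return(list(centers = c1, single = TRUE))
  ctr <- sort(c(c1, far[1]))
  list(centers = ctr, single = FALSE)
}

#' Integrated DNA content and 2N/4N gating
#'
#' Integrated (summed) nuclear PI intensity per cell; the 2N and 4N centres
#' are the two dominant modes of its distribution, gates extend +/-
#' `gateHalfWidth` around each centre and cells between the gates are
#' `intermediate`. A single-mode population is gated 2N-only with the 4N
#' flag raised.
#'
#' @param mask a [LabelMask-class].
#' @param piImage numeric matrix, the DNA (PI) channel.
#' @param gateHalfWidth relative half width of each gate (default 0.25).
#' @param minCells minimum population for mode finding (default 50).
#' @return list with `table` (`DataFrame`: label, integrated, dna_class),
#'   `centers` (named numeric), and `singleMode` flag.
#' @export
integratedDNA <- function(mask, piImage, gateHalfWidth = 0.25,
                          minCells = 50L) {
  fts <- maskFeatures(mask, piImage)
  if (nrow(fts) < minCells)
    stop("at least ", minCells, " cells required for mode finding")
  v <- fts$totalIntensity
  md <- .twoModes(v)
  if (md$single) {
    warning("single DNA mode: 4N gate undefined")
    c2 <- md$centers[1]
    cls <- ifelse(abs(v - c2) <= gateHalfWidth * c2, "2N", "intermediate")
    return(list(table = DataFrame(label = fts$label, integrated = v,
                                  dna_class = cls),
                centers = c(`2N` = c2, `4N` = NA_real_), singleMode = TRUE))
  }
  c2 <- md$centers[1]; c4 <- md$centers[2]
  cls <- rep("intermediate", length(v))
  cls[abs(v - c2) <= gateHalfWidth * c2] <- "2N"
  cls[abs(v - c4) <= gateHalfWidth * c4] <- "4N"
  list(table = DataFrame(label = fts$label, integrated = v, dna_class = cls),
       centers = c(`2N` = c2, `4N` = c4), singleMode = FALSE)
}

#' Estimate an EdU-positivity threshold from the negative mode
#'
#' Mean + 3 sd of the EdU-negative population, with the mode of the density
#' as the negative-mode centre and a reflected-MAD estimate of its sd.
#'
#' @param edu numeric vector of background-corrected mean EdU intensities.
#' @return threshold intensity.
#' @export
eduThresholdFromNegatives <- function(edu) {
  dens <- stats::density(edu, n = 512)
  m <- dens$x[which.max(dens$y)]
  below <- edu[edu < m]
  if (!length(below)) return(m)
  s <- stats::median(m - below) / 0.6745
  m + 3 * s
}

#' Cell-cycle phase gating on the EdU vs DNA plane
#'
#' EdU-negative 2N cells are G0/G1; EdU-negative 4N cells are G2/M;
#' EdU-positive cells are S; EdU-negative intermediate-DNA cells are
#' reported as `unclassified`.
#'
#' @param edu background-corrected mean EdU intensity per cell.
#' @param dnaClass per-cell `"2N"` / `"intermediate"` / `"4N"` from
#'   [integratedDNA()].
#' @param eduThreshold positivity threshold; estimated with
#'   [eduThresholdFromNegatives()] when `NULL`.
#' @return factor with levels G0/G1, S, G2/M, unclassified.
#' @export
classifyPhase <- function(edu, dnaClass, eduThreshold = NULL) {
  stopifnot(length(edu) == length(dnaClass))
  if (is.null(eduThreshold)) eduThreshold <- eduThresholdFromNegatives(edu)
  pos <- edu > eduThreshold
  phase <- ifelse(pos, "S",
           ifelse(dnaClass == "2N", "G0/G1",
           ifelse(dnaClass == "4N", "G2/M", "unclassified")))
  factor(phase, levels = c("G0/G1", "S", "G2/M", "unclassified"))
}

#' Pair preserved CDK2 reporter ratios with p21 intensities
#'
#' For fixed-cell experiments in which the CDK2 sensor fluorescence survives
#' fixation: returns per-cell (CDK2 ratio, p21 intensity) pairs and their
#' Spearman rank correlation. Cells missing either measurement are dropped
#' and counted.
#'
#' @param cdk2 per-cell CDK2 ratios.
#' @param p21 per-cell mean p21 intensities (same length/order).
#' @param cellId optional cell identifiers.
#' @return `DataFrame` (cell_id, cdk2_ratio, p21_mean) with
#'   `metadata()$rho` (Spearman, `NA` when undefined) and
#'   `metadata()$n_dropped`.
#' @export
p21VsCdk2 <- function(cdk2, p21, cellId = seq_along(cdk2)) {
  stopifnot(length(cdk2) == length(p21), length(cellId) == length(cdk2))
  ok <- !is.na(cdk2) & !is.na(p21)
  out <- DataFrame(cell_id = cellId[ok], cdk2_ratio = cdk2[ok],
                   p21_mean = p21[ok])
  rho <- if (nrow(out) >= 3 && stats::sd(out$p21_mean) > 0 &&
             stats::sd(out$cdk2_ratio) > 0)
    stats::cor(out$cdk2_ratio, out$p21_mean, method = "spearman")
  else NA_real_
  metadata(out)$rho <- rho
  metadata(out)$n_dropped <- sum(!ok)
  out
}
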