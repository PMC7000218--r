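test_that("block background subtraction zeroes constants and keeps size", {
  img <- matrix(0.37, 44, 44)
  out <- blockBackgroundSubtract(img)
  expect_equal(dim(out), dim(img))
  expect_true(all(out == 0))
  expect_error(blockBackgroundSubtract(matrix(0, 8, 8)), "smaller")
})

test_that("spots planted on a gradient survive block subtraction", {
  set.seed(1)
  d <- 132
  grad <- outer(seq_len(d) / d, seq_len(d) / d, function(a, b) 0.2 * (a + b))
  img <- grad
  spots <- rbind(c(30, 30), c(70, 100), c(110, 50))
  for (k in seq_len(nrow(spots)))
    img <- testDisc(img, spots[k, 1], spots[k, 2], 4, 0.8)
  corr <- blockBackgroundSubtract(img)
  for (k in seq_len(nrow(spots))) {
    sel <- (row(img) - spots[k, 1])^2 + (col(img) - spots[k, 2])^2 <= 4
    planted <- 0.8 - grad[spots[k, 1], spots[k, 2]]
    ## corrected spot ~= spot minus the local background it sat on
    expect_lt(abs(mean(corr[sel]) - planted) / planted, 0.05)
  }
})

test_that("block subtraction is idempotent up to the per-block floor", {
  set.seed(7)
  img <- matrix(stats::runif(66 * 66, 0, 1), 66, 66)
  once <- blockBackgroundSubtract(img)
  twice <- blockBackgroundSubtract(once)
  xi <- cut(seq_len(66), 11, labels = FALSE)
  yi <- cut(seq_len(66), 11, labels = FALSE)
  for (i in 1:11) for (j in 1:11) {
    tile <- once[xi == i, yi == j]
    floor5 <- stats::quantile(tile, 0.05, names = FALSE)
    expect_lte(max(abs(twice[xi == i, yi == j] - tile)), floor5 + 1e-12)
  }
})

test_that("integrated DNA of a uniform nucleus is exactly value times area", {
  lab <- matrix(0L, 120, 120)
  centres <- expand.grid(x = c(20, 60, 100), y = c(20, 60, 100))
  for (k in seq_len(nrow(centres)))
    lab[(row(lab) - centres$x[k])^2 + (col(lab) - centres$y[k])^2 <= 36] <-
      as.integer(k)
  img <- matrix(0.31, 120, 120)
  m <- maskFromLabels(lab)
  fts <- maskFeatures(m, img)
  expect_equal(fts$totalIntensity, 0.31 * fts$area)
})

test_that("2N/4N mode centres are recovered at ratio two", {
  cfg <- syntheticConfig(seed = 41)
  sim <- generateEdUPIPopulation(240, c(`G0/G1` = 0.6, S = 0, `G2/M` = 0.4),
                                 backgroundGradient = 0, config = cfg)
  ints <- unlist(lapply(sim$fields, function(fld)
    maskFeatures(segmentNuclei(fld$pi), fld$pi)$totalIntensity))
  ## histogram-mode oracle, independent of the package's density peaks
  h <- hist(ints, breaks = 40, plot = FALSE)
  top <- order(h$counts, decreasing = TRUE)
  m1 <- h$mids[top[1]]
  m2 <- h$mids[top[which(abs(h$mids[top] / m1 - 1) > 0.4)[1]]]
  expect_lt(abs(max(m1, m2) / min(m1, m2) - 2), 0.1)
  ## package route through integratedDNA on one pooled mask
  lab <- matrix(0L, 1, 1)
  md <- ZnFate:::.twoModes(ints)
  expect_false(md$single)
  expect_lt(abs(md$centers[2] / md$centers[1] - 2), 0.1)
})

test_that("an all-2N population flags the undefined 4N gate", {
  cfg <- syntheticConfig(seed = 43)
  sim <- generateEdUPIPopulation(64, c(`G0/G1` = 1, S = 0, `G2/M` = 0),
                                 backgroundGradient = 0, config = cfg)
  fld <- sim$fields[[1]]
  mask <- segmentNuclei(fld$pi)
  expect_warning(res <- integratedDNA(mask, fld$pi, minCells = 10),
                 "single DNA mode")
  expect_true(res$singleMode)
  expect_true(all(res$table$dna_class %in% c("2N", "intermediate")))
  expect_true(is.na(res$centers[["4N"]]))
  ## and the EdU-positive fraction is zero
  edu <- blockBackgroundSubtract(fld$edu)
  eduM <- maskFeatures(mask, edu)$meanIntensity
  phase <- classifyPhase(eduM, res$table$dna_class,
                         eduThreshold = eduThresholdFromNegatives(eduM))
  ## a mean+3sd threshold admits a small false-positive tail by design
  expect_lte(sum(phase == "S"), ceiling(0.02 * length(eduM)))
  expect_equal(sum(sim$truth$phase == "S"), 0L)
})

test_that("phase gates follow the EdU-by-DNA rules", {
  edu <- c(0.01, 0.5, 0.01, 0.5, 0.02)
  dna <- c("2N", "intermediate", "4N", "2N", "intermediate")
  ph <- classifyPhase(edu, dna, eduThreshold = 0.2)
  expect_equal(as.character(ph),
               c("G0/G1", "S", "G2/M", "S", "unclassified"))
  expect_equal(length(levels(ph)), 4L)
})

test_that("a planted phase mixture is recovered through the image pipeline", {
  cfg <- syntheticConfig(seed = 45)
  mix <- c(`G0/G1` = 0.5, S = 0.3, `G2/M` = 0.2)
  sim <- generateEdUPIPopulation(320, mix, config = cfg)
  ints <- numeric(0); eduM <- numeric(0)
  for (fld in sim$fields) {
    mask <- segmentNuclei(fld$pi)
    ints <- c(ints, maskFeatures(mask, fld$pi)$totalIntensity)
    eduM <- c(eduM, maskFeatures(mask,
                                 blockBackgroundSubtract(fld$edu))$meanIntensity)
  }
  md <- ZnFate:::.twoModes(ints)
  cls <- rep("intermediate", length(ints))
  cls[abs(ints - md$centers[1]) <= 0.25 * md$centers[1]] <- "2N"
  cls[abs(ints - md$centers[2]) <= 0.25 * md$centers[2]] <- "4N"
  ph <- classifyPhase(eduM, cls)
  frac <- prop.table(table(ph))[c("G0/G1", "S", "G2/M")]
  for (nm in names(mix)) {
    ci <- binomCI(mix[[nm]], length(ints))
    expect_gte(frac[[nm]], ci[1] - 0.02)
    expect_lte(frac[[nm]], ci[2] + 0.02)
  }
  ## the four phase fractions partition the population
  expect_equal(sum(prop.table(table(ph))), 1, tolerance = 1e-9)
})

test_that("pRb mixture split is accurate and scale-invariant", {
  set.seed(9)
  truth <- rep(c("hypo", "hyper"), c(120, 80))
  x <- ifelse(truth == "hyper", stats::rlnorm(200, log(0.45), 0.2),
              stats::rlnorm(200, log(0.08), 0.2))
  cl <- classifyPRb(x)
  expect_lt(mean(as.character(cl$class) != truth), 0.02)
  cl10 <- classifyPRb(10 * x)
  expect_equal(as.character(cl$class), as.character(cl10$class))
  expect_warning(classifyPRb(rep(0.3, 30)), "single-class")
  expect_error(classifyPRb(c(1, 2, 3)), "at least 20")
})

test_that("foci filters enforce the size and shape windows", {
  img <- matrix(0.05, 180, 180)
  lab <- matrix(0L, 180, 180)
  lab[(row(lab) - 90)^2 + (col(lab) - 90)^2 <= 625] <- 1L  # r=25 nucleus
  img[lab == 1L] <- 0.3
  ## a compact focus (area ~50) and an elongated one (ecc ~0.93, area ~50)
  img <- testDisc(img, 82, 82, 4, 1.0)
  img <- testEllipse(img, 100, 100, 11, 1.6, 1.0)
  m <- maskFromLabels(lab, img)
  foci <- detectFoci(img, m, fociParams("53BP1"))
  expect_equal(nrow(foci), 1L)
  expect_lt(abs(foci$x - 82), 2)
  expect_gt(foci$area, 10); expect_lt(foci$area, 200)
  expect_lt(foci$eccentricity, 0.6)
  ## a uniform nucleus has no foci
  img0 <- matrix(0.05, 180, 180); img0[lab == 1L] <- 0.3
  expect_equal(nrow(detectFoci(img0, m, fociParams("53BP1"))), 0L)
})

test_that("foci recovery on truth images reaches 95% precision and recall", {
  cfg <- syntheticConfig(seed = 47)
  sim <- generateFociImage(64, c(hypo = 0.5, hyper = 0.5), config = cfg)
  detected <- list()
  for (f in seq_along(sim$fields)) {
    fld <- sim$fields[[f]]
    mask <- segmentNuclei(fld$nuclear)
    foci <- as.data.frame(detectFoci(fld$marker, mask, fociParams("53BP1")))
    if (nrow(foci)) { foci$field <- f; detected[[length(detected) + 1L]] <- foci }
  }
  det <- do.call(rbind, detected)
  planted <- as.data.frame(sim$foci)
  matchCount <- 0L
  for (i in seq_len(nrow(planted))) {
    cand <- det[det$field == planted$field[i], ]
    if (nrow(cand) &&
        min(sqrt((cand$x - planted$x[i])^2 + (cand$y - planted$y[i])^2)) <= 3)
      matchCount <- matchCount + 1L
  }
  recall <- matchCount / nrow(planted)
  precision <- matchCount / nrow(det)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("damage fractions are exact, stratified and permutation-invariant", {
  counts <- c(0, 2, 1, 0, 0, 3)
  strata <- c("a", "a", "b", "b", "a", "b")
  df <- as.data.frame(damageFraction(counts, strata))
  expect_equal(df$fraction[df$stratum == "a"], 1 / 3)
  expect_equal(df$fraction[df$stratum == "b"], 2 / 3)
  perm <- sample(seq_along(counts))
  df2 <- as.data.frame(damageFraction(counts[perm], strata[perm]))
  expect_equal(df[order(df$stratum), ], df2[order(df2$stratum), ],
               ignore_attr = TRUE)
  expect_equal(as.data.frame(damageFraction(rep(0, 5)))$fraction, 0)
})

test_that("generator guards: positivity bounds and filter-compatible spec", {
  cfg <- syntheticConfig(seed = 49)
  expect_error(generateFociImage(10, c(hypo = 0, hyper = 1),
                                 fociSpec = list(areaRange = c(5, 300),
                                                 maxPerCell = 2L),
                                 config = cfg),
               "inside the detection filter")
  simAll <- generateFociImage(48, c(hypo = 1, hyper = 1), config = cfg)
  expect_equal(sum(simAll$truth$positive), 48L)
  simNone <- generateFociImage(32, c(hypo = 0, hyper = 0), config = cfg)
  expect_equal(nrow(simNone$foci), 0L)
})

test_that("p21 pairing reports anticorrelation and degenerate inputs", {
  set.seed(3)
  ratio <- stats::runif(200, 0.3, 2)
  p21 <- 1 / ratio * exp(stats::rnorm(200, 0, 0.2))
  tab <- p21VsCdk2(ratio, p21)
  expect_lt(S4Vectors::metadata(tab)$rho, 0)
  empty <- p21VsCdk2(numeric(0), numeric(0))
  expect_equal(nrow(empty), 0L)
  const <- p21VsCdk2(ratio[1:10], rep(2, 10))
  expect_true(is.na(S4Vectors::metadata(const)$rho))
  dropped <- p21VsCdk2(c(1, NA, 2), c(1, 2, NA))
  expect_equal(S4Vectors::metadata(dropped)$n_dropped, 2L)
})
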