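test_that("ring area matches the annulus oracle for a centred nucleus", {
  lab <- matrix(0L, 101, 101)
  lab[(row(lab) - 51)^2 + (col(lab) - 51)^2 <= 100] <- 1L
  m <- maskFromLabels(lab)
  rg <- perinuclearRing(m, width = 3)
  got <- sum(rg@rings == 1L)
  expect_lt(abs(got - pi * (13^2 - 10^2)) / (pi * (13^2 - 10^2)), 0.10)
  ## brute-force oracle: background pixels within Euclidean 3 of the nucleus
  bnd <- which(lab == 1L, arr.ind = TRUE)
  bg <- which(lab == 0L, arr.ind = TRUE)
  near <- vapply(seq_len(nrow(bg)), function(i) {
    min((bg[i, 1] - bnd[, 1])^2 + (bg[i, 2] - bnd[, 2])^2) <= 9
  }, logical(1))
  oracle <- sum(near)
  expect_lte(abs(got - oracle) / oracle, 0.12)
  ## no ring pixel may sit more than 3 px (Chebyshev) from the nucleus
  ringPix <- which(rg@rings == 1L, arr.ind = TRUE)
  cheb <- vapply(seq_len(nrow(ringPix)), function(i)
    min(pmax(abs(ringPix[i, 1] - bnd[, 1]), abs(ringPix[i, 2] - bnd[, 2]))),
    numeric(1))
  expect_true(all(cheb <= 3))
  expect_length(rg@clipped, 0)
})

test_that("rings of adjacent nuclei stay disjoint and avoid each other", {
  lab <- matrix(0L, 80, 80)
  lab[(row(lab) - 30)^2 + (col(lab) - 40)^2 <= 64] <- 1L
  sel2 <- (row(lab) - 48)^2 + (col(lab) - 40)^2 <= 64 & lab == 0L
  lab[sel2] <- 2L
  m <- maskFromLabels(lab)
  rg <- perinuclearRing(m, width = 3)
  ## rings never overlap a nucleus
  expect_equal(sum(rg@rings > 0 & lab > 0), 0L)
  ## contested pixels (within 3 px of both) are claimed by neither
  for (lb in 1:2) {
    own <- which(lab == lb, arr.ind = TRUE)
    other <- which(lab == (3L - lb), arr.ind = TRUE)
    ring <- which(rg@rings == lb, arr.ind = TRUE)
    for (i in seq_len(nrow(ring))) {
      dOther <- min(sqrt((ring[i, 1] - other[, 1])^2 +
                         (ring[i, 2] - other[, 2])^2))
      expect_gt(dOther, 3)
    }
  }
})

test_that("a corner nucleus yields a clipped, flagged ring", {
  lab <- matrix(0L, 60, 60)
  lab[(row(lab) - 5)^2 + (col(lab) - 5)^2 <= 49] <- 1L
  m <- maskFromLabels(lab)
  rg <- perinuclearRing(m, width = 3)
  expect_true(1L %in% rg@clipped)
  expect_gt(sum(rg@rings == 1L), 0)
})

test_that("reporter ratios behave at the trivial anchors", {
  expect_equal(cdk2Ratio(1.4, 1.4), 1)
  expect_equal(cdk2Ratio(0, 2), 0)
  expect_error(cdk2Ratio(1, 0), "undefined")
  expect_equal(fretRatio(200, 100), 2)
  expect_equal(fretRatio(50, 120, fretBg = 50, cfpBg = 20), 0)
  expect_error(fretRatio(10, 5, cfpBg = 5), "background")
  ## gain invariance after background subtraction
  expect_equal(fretRatio(10 * 180, 10 * 90, 10 * 30, 10 * 40),
               fretRatio(180, 90, 30, 40))
})

test_that("pre-mitosis averages use the open one-hour window", {
  t <- seq(0, 2, by = 0.2)
  r <- 1 + pmax(0, t - 1)   # 1.0 rising to 2.0 over the final hour
  ## in-window samples: t = 1.2, 1.4, 1.6, 1.8 -> mean 1.5
  expect_equal(premitosisAverage(t, r, tMitosis = 2), 1.5)
  expect_equal(premitosisAverage(t, rep(1.4, length(t)), 2), 1.4)
  ## a single in-window sample is returned as-is
  expect_equal(premitosisAverage(c(-2, 0.05), c(3, 7), tMitosis = 0.1), 7)
  expect_error(premitosisAverage(t, r, tMitosis = NA), "no mitosis")
  expect_error(premitosisAverage(t, r, tMitosis = 0), "window")
})

test_that("ring quantification recovers a painted cytoplasm/nucleus ratio", {
  img <- matrix(0, 80, 80)
  img <- testDisc(img, 40, 40, 14, 0.3 * 1.6)   # cytoplasm first
  img <- testDisc(img, 40, 40, 9, 0.3)          # nucleus on top
  lab <- matrix(0L, 80, 80)
  lab[(row(lab) - 40)^2 + (col(lab) - 40)^2 <= 81] <- 1L
  m <- maskFromLabels(lab, img)
  q <- ringQuantify(m, perinuclearRing(m), img)
  expect_equal(q$cdk2_ratio, 1.6, tolerance = 0.02)
  qMean <- ringQuantify(m, perinuclearRing(m), img, stat = "mean")
  expect_equal(qMean$cdk2_ratio, 1.6, tolerance = 0.02)
})
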