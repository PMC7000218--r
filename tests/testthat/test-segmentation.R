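test_that("a blank image segments to zero labels without error", {
  m <- segmentNuclei(matrix(0, 64, 64))
  expect_equal(nLabels(m), 0L)
  expect_true(all(labelImage(m) == 0L))
})

test_that("planted non-touching discs are recovered with 1-px centroids", {
  img <- matrix(0, 160, 160)
  centers <- rbind(c(35, 35), c(35, 120), c(100, 40), c(120, 120), c(80, 80))
  for (k in seq_len(nrow(centers)))
    img <- testDisc(img, centers[k, 1], centers[k, 2], 10, 0.5)
  img <- as.matrix(EBImage::gblur(EBImage::Image(img), 1))
  m <- segmentNuclei(img)
  expect_equal(nLabels(m), nrow(centers))
  fts <- maskFeatures(m)
  for (k in seq_len(nrow(centers))) {
    dd <- sqrt((fts$cx - centers[k, 1])^2 + (fts$cy - centers[k, 2])^2)
    expect_lt(min(dd), 1)
  }
})

test_that("watershed splits two overlapping discs into two labels", {
  img <- matrix(0, 96, 96)
  ## centres 16 px apart with radius 10: ~20% overlap of the radii
  img <- testDisc(img, 40, 48, 10, 0.5)
  img <- testDisc(img, 56, 48, 10, 0.5)
  img <- as.matrix(EBImage::gblur(EBImage::Image(img), 1))
  m <- segmentNuclei(img)
  expect_equal(nLabels(m), 2L)
  fts <- maskFeatures(m)
  expect_lt(min(abs(fts$cx - 40)), 2.5)
  expect_lt(min(abs(fts$cx - 56)), 2.5)
})

test_that("regions below the minimum area are removed", {
  img <- matrix(0, 96, 96)
  img <- testDisc(img, 30, 30, 10, 0.6)   # area ~314
  img <- testDisc(img, 70, 70, 3, 0.6)    # area ~28 < 50
  m <- segmentNuclei(img, segmentationParams(minArea = 50))
  expect_equal(nLabels(m), 1L)
  expect_lt(abs(maskFeatures(m)$cx - 30), 2)
})

test_that("component labeling honours the connectivity choice", {
  bin <- matrix(0, 8, 8)
  bin[2, 2] <- 1; bin[3, 3] <- 1   # touch only diagonally
  expect_equal(max(labelComponents(bin, connectivity = 8L)), 1L)
  expect_equal(max(labelComponents(bin, connectivity = 4L)), 2L)
  ## oracle agreement on a random blob field
  set.seed(42)
  rnd <- matrix(stats::rbinom(900, 1, 0.3), 30, 30)
  expect_equal(max(labelComponents(rnd, 8L)), floodCount(rnd))
})

test_that("label masks report consistent areas and intensities", {
  img <- matrix(0, 64, 64)
  img <- testDisc(img, 32, 32, 8, 0.7)
  m <- segmentNuclei(img)
  fts <- maskFeatures(m)
  expect_equal(fts$area, sum(labelImage(m) > 0))
  expect_equal(fts$totalIntensity, sum(img[labelImage(m) > 0]))
  ## re-measuring on another channel
  other <- matrix(2, 64, 64)
  fts2 <- maskFeatures(m, other)
  expect_equal(fts2$meanIntensity, 2)
})

test_that("proliferation curves normalize to the first frame", {
  mk <- function(n) {
    img <- matrix(0, 128, 128)
    at <- cbind(c(30, 30, 95, 95), c(30, 95, 30, 95))[seq_len(n), , drop = FALSE]
    for (k in seq_len(n)) img <- testDisc(img, at[k, 1], at[k, 2], 9, 0.5)
    segmentNuclei(img)
  }
  expect_equal(proliferationCurve(list(mk(2), mk(2), mk(2))), c(1, 1, 1))
  expect_equal(proliferationCurve(list(mk(2), mk(4)))[2], 2)
  expect_error(proliferationCurve(list(mk(0), mk(2))), "normalization")
})
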