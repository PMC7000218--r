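## build a LabelMask sequence from per-frame centre tables
maskSeq <- function(frames, size = 96, r = 8, value = 0.5) {
  lapply(frames, function(centres) {
    img <- matrix(0, size, size)
    if (!is.null(centres))
      for (k in seq_len(nrow(centres)))
        img <- testDisc(img, centres[k, 1], centres[k, 2], r,
                        if (ncol(centres) > 2) centres[k, 3] else value)
    segmentNuclei(img)
  })
}

test_that("a static scene yields one track spanning every frame", {
  frames <- replicate(6, rbind(c(30, 30), c(70, 70)), simplify = FALSE)
  g <- trackCells(maskSeq(frames))
  nd <- as.data.frame(trackNodes(g))
  expect_equal(length(unique(nd$track)), 2L)
  spans <- tapply(nd$frame, nd$track, function(f) length(unique(f)))
  expect_true(all(spans == 6))
})

test_that("slow motion within the gate keeps a single unbroken track", {
  frames <- lapply(0:9, function(k) rbind(c(20 + k, 40)))
  g <- trackCells(maskSeq(frames), trackingParams(maxDisplacement = 5))
  nd <- as.data.frame(trackNodes(g))
  expect_equal(length(unique(nd$track)), 1L)
  expect_equal(sort(unique(nd$frame)), 1:10)
})

test_that("a disappearing cell terminates its track at the last visible frame", {
  frames <- c(lapply(1:4, function(k) rbind(c(40, 40), c(75, 75))),
              lapply(5:6, function(k) rbind(c(40, 40))))
  g <- trackCells(maskSeq(frames))
  nd <- as.data.frame(trackNodes(g))
  ends <- tapply(nd$frame, nd$track, max)
  expect_setequal(as.integer(ends), c(4L, 6L))
})

test_that("a jump beyond the gate starts a new track", {
  frames <- list(rbind(c(20, 20)), rbind(c(60, 60)))
  g <- trackCells(maskSeq(frames), trackingParams(maxDisplacement = 10))
  expect_equal(length(unique(trackNodes(g)$track)), 2L)
})

test_that("splits without the condensation signature are not mitoses", {
  ## an over-segmentation artefact: a blob splits with constant intensity
  ## and no pre-split condensation
  pre <- lapply(1:5, function(k) rbind(c(48, 48)))
  post <- lapply(1:3, function(k) rbind(c(38, 48), c(58, 48)))
  masks <- maskSeq(c(pre, post))
  res <- detectMitosis(trackCells(masks), masks)
  expect_equal(nrow(res$events), 0L)
  ## precision 1.0: no division edges at all
  expect_equal(nrow(trackDivisions(res$graph)), 0L)
})

test_that("a rendered division is detected at the split frame", {
  cfg <- syntheticConfig(seed = 21, duration = 8, noiseSd = 0.02,
                         nCellsInitial = 2)
  ens <- generateTraceEnsemble(cfg, "MM", 2)
  mov <- renderMovie(ens, cfg)
  masks <- lapply(seq_len(dim(h2bChannel(mov))[3]),
                  function(f) segmentNuclei(h2bChannel(mov)[, , f]))
  res <- detectMitosis(trackCells(masks), masks)
  trueFrames <- round(unlist(as.list(divisionTimes(ens))) / 0.2) + 1L
  trueFrames <- trueFrames[trueFrames < dim(h2bChannel(mov))[3]]
  expect_equal(nrow(res$events), length(trueFrames))
  for (f in trueFrames)
    expect_true(any(abs(res$events$frame - (f + 1L)) <= 1))
  expect_true(all(res$events$intensityFold >= 1.3))
  expect_true(all(res$events$areaFold <= 0.6))
})

test_that("track partitions are invariant to frame-wise label permutation", {
  frames <- replicate(4, rbind(c(25, 25), c(45, 60), c(70, 30)),
                      simplify = FALSE)
  masks <- maskSeq(frames)
  ## relabel each frame's regions in reverse order
  masksPerm <- lapply(masks, function(m) {
    lab <- labelImage(m)
    n <- nLabels(m)
    newlab <- lab
    newlab[lab > 0] <- n + 1L - lab[lab > 0]
    maskFromLabels(newlab)
  })
  sizes <- function(g) sort(as.integer(table(trackNodes(g)$track)))
  expect_equal(sizes(trackCells(masks)), sizes(trackCells(masksPerm)))
})
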