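tt24 <- seq(0, 24, by = 0.2)

test_that("alignment re-zeroes at the requested mitosis and is idempotent", {
  r <- rbind(rampTrace(tt24, c(0, 20, 24), c(2, 2, 0.5)),
             rep(0.5, length(tt24)))
  ens <- makeEnsemble(r, tt24, list(20, numeric(0)))
  al <- alignToMitosis(ens)
  expect_equal(al@excluded, "t002")   # the never-dividing cell
  j <- which(abs(al@relTime) < 1e-9)
  expect_equal(unname(al@ratio[1, j]), r[1, which(tt24 == 20)])
  expect_identical(alignToMitosis(al), al)
})

test_that("fate taxonomy: prompt, delayed and absent commitment", {
  mk <- function(cross) {
    v <- rampTrace(tt24, c(0, 5, 5 + cross - (0.5 / 0.35), 5 + cross, 24),
                   c(2, 0.5, 0.5, 1.0, 2.2))
    v
  }
  r <- rbind(mk(2), rampTrace(tt24, c(0, 5, 24), c(2, 0.5, 0.5)), mk(8))
  ens <- makeEnsemble(r, tt24, list(5, 5, 5))
  rec <- classifyFate(ens)
  expect_equal(rec$fate, c("CDK2inc", "CDK2low", "CDK2emerge"))
  expect_equal(rec$commit_time[1], 2, tolerance = 0.11)
  expect_equal(rec$commit_time[3], 8, tolerance = 0.11)
  expect_true(is.na(rec$commit_time[2]))
})

test_that("short post-mitosis followup is unclassifiable, not misclassified", {
  r <- rbind(rampTrace(tt24, c(0, 20, 24), c(2, 0.5, 0.5)))
  ens <- makeEnsemble(r, tt24, list(20))   # only 4 h of followup
  rec <- classifyFate(ens)
  expect_equal(rec$fate, "unclassifiable")
  f <- fateFractions(rec)
  expect_equal(attr(f, "n"), 0L)
})

test_that("stall detection needs the hold band, the duration and no division", {
  t60 <- seq(0, 60, by = 0.2)
  stallTrace <- rampTrace(t60, c(0, 10, 10.5, 12, 60), c(2, 0.5, 0.5, 1.2, 1.2))
  cyclingTrace <- rampTrace(t60, c(0, 10, 10.5, 14, 23, 23.2, 60),
                            c(2, 0.5, 0.5, 2.2, 2.2, 0.5, 0.5))
  transient <- rampTrace(t60, c(0, 10, 10.5, 12, 16, 17, 60),
                         c(2, 0.5, 0.5, 1.2, 1.2, 0.5, 0.5))
  ens <- makeEnsemble(rbind(stallTrace, cyclingTrace, transient), t60,
                      list(10, c(10, 23), 10))
  rec <- classifyFate(ens)
  expect_true(rec$stalled[1])
  expect_equal(rec$plateau_ratio[1], 1.2, tolerance = 1e-6)
  expect_false(rec$stalled[2])   # reached 2.2 and divided again
  expect_false(rec$stalled[3])   # held only ~4 h
})

test_that("fate fractions partition classifiable cells and sum to one", {
  cfg <- syntheticConfig(seed = 2)
  ens <- generateTraceEnsemble(cfg, "MM", 300)
  f <- fateFractions(classifyFate(ens))
  expect_equal(sum(f), 1, tolerance = 1e-9)
  expect_true(all(f >= 0 & f <= 1))
})

test_that("raising the commit threshold never raises the CDK2inc fraction", {
  cfg <- syntheticConfig(seed = 4)
  ens <- generateTraceEnsemble(cfg, "ZD", 400)
  al <- alignToMitosis(ens)
  incAt <- vapply(c(0.8, 1.0, 1.2, 1.4), function(thr) {
    cc <- classifierConfig(commitThreshold = thr)
    unname(fateFractions(classifyFate(al, config = cc))[["CDK2inc"]])
  }, numeric(1))
  expect_true(all(diff(incAt) <= 1e-12))
})

test_that("classification is invariant to time shifts and channel gain", {
  r <- rbind(rampTrace(tt24, c(0, 5, 7, 9, 24), c(2, 0.5, 0.5, 1.3, 1.3)))
  ens <- makeEnsemble(r, tt24, list(5))
  base <- classifyFate(ens)$fate
  ## uniform time shift of grid and divisions together
  ensShift <- makeEnsemble(r, tt24 + 7, list(12))
  expect_equal(classifyFate(ensShift)$fate, base)
  ## a common gain on both channels cancels in the ratio by construction
  expect_equal(cdk2Ratio(3 * 1.3, 3 * 1.0), cdk2Ratio(1.3, 1.0))
})

test_that("mixture recovery across seeds stays within exact binomial bands", {
  mix <- defaultFateMixtures()$ZD
  inside <- 0L
  for (s in 1:5) {
    ens <- generateTraceEnsemble(syntheticConfig(seed = s), "ZD", 2000)
    f <- fateFractions(classifyFate(ens))
    n <- attr(f, "n")
    ok <- TRUE
    for (cls in c("CDK2inc", "CDK2emerge", "CDK2low")) {
      p <- mix[[sub("CDK2", "", cls)]]
      ci <- binomCI(p, n)
      ok <- ok && f[[cls]] >= ci[1] && f[[cls]] <= ci[2]
    }
    inside <- inside + ok
  }
  expect_gte(inside, 4L)
})

test_that("mitosis-window binning uses half-open windows from the boundary", {
  t30 <- seq(0, 30, by = 0.2)
  flat <- function() rampTrace(t30, c(0, 30), c(0.5, 0.5))
  r <- rbind(flat(), flat(), flat())
  ## mitoses exactly at, just before, and well after the perturbation (t=8)
  ens <- makeEnsemble(r, t30, list(8, 7.8, 14))
  rec <- binByMitosisWindow(ens, tPerturb = 8)
  expect_equal(rec$window_bin, c("[0,4)", "[-4,0)", "[4,8)"))
  expect_error(binByMitosisWindow(ens, 8, window = 0), "window")
})

test_that("inter-mitotic times follow lineage chains", {
  t30 <- seq(0, 30, by = 0.2)
  r <- rbind(rampTrace(t30, c(0, 30), c(1, 1)),
             rampTrace(t30, c(0, 30), c(1, 1)))
  ens <- makeEnsemble(r, t30, list(c(10, 23), numeric(0)))
  imt <- intermitoticTimes(ens)
  expect_equal(imt$durations, 13)
  expect_equal(imt$mode, 13)
  ## mother-daughter chain via parent_id
  ens2 <- makeEnsemble(r, t30, list(10, 21), parent = c(NA, "t001"))
  expect_equal(intermitoticTimes(ens2)$durations, 11)
  ## at most one division anywhere: empty result
  ens3 <- makeEnsemble(r, t30, list(10, numeric(0)))
  expect_length(intermitoticTimes(ens3)$durations, 0)
  expect_true(is.na(intermitoticTimes(ens3)$mode))
})

test_that("heatmap ordering is deterministic and matches the sort key", {
  t10 <- seq(0, 10, by = 0.2)
  r <- rbind(a = rampTrace(t10, c(0, 10), c(1.3, 1.3)),
             b = rampTrace(t10, c(0, 10), c(0.5, 0.5)),
             c = rampTrace(t10, c(0, 10), c(0.9, 0.9)))
  ens <- makeEnsemble(r, t10, list(9, 2, 5))
  byEnd <- sortHeatmap(ens, "end_activity")
  expect_equal(attr(byEnd, "order"), c("t002", "t003", "t001"))
  byMit <- sortHeatmap(ens, "mitosis_time")
  expect_equal(attr(byMit, "order"), c("t002", "t003", "t001"))
  ## permuting the input rows leaves the displayed values unchanged
  ensPerm <- makeEnsemble(r[c(3, 1, 2), ], t10, list(5, 9, 2))
  byEndPerm <- sortHeatmap(ensPerm, "end_activity")
  expect_equal(`attributes<-`(byEndPerm, list(dim = dim(byEndPerm))),
               `attributes<-`(byEnd, list(dim = dim(byEnd))))
})

test_that("ratio densities integrate to one and find planted modes", {
  t10 <- seq(0, 10, by = 0.2)
  r <- rbind(matrix(0.5, 30, length(t10)), matrix(1.25, 20, length(t10)))
  ens <- makeEnsemble(r, t10, rep(list(numeric(0)), 50))
  d <- cdk2Density(ens, at = 5, bins = 15)
  widths <- d$bin_right - d$bin_left
  expect_equal(sum(d$density * widths), 1, tolerance = 1e-9)
  top2 <- order(d$density, decreasing = TRUE)[1:2]
  ctr <- sort((d$bin_left + d$bin_right)[top2] / 2)
  expect_lt(abs(ctr[1] - 0.5), 0.1)
  expect_lt(abs(ctr[2] - 1.25), 0.1)
  ## single occupied bin carries all mass
  ensOne <- makeEnsemble(matrix(0.5, 5, length(t10)), t10,
                         rep(list(numeric(0)), 5))
  d1 <- cdk2Density(ensOne, at = 2, bins = c(0, 0.4, 0.6, 1))
  expect_equal(sum(d1$density * (d1$bin_right - d1$bin_left)), 1)
  expect_equal(sum(d1$density > 0), 1L)
})
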