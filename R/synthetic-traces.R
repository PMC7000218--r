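#' @include AllClasses.R accessors.R
NULL

#' Default condition-specific fate mixtures
#'
#' Probability of each post-mitosis fate (CDK2inc / CDK2emerge / CDK2low) per
#' growth condition. ZD (zinc-deficient, 3 uM TPA), MM (Chelex-stripped
#' minimal medium) and ZR (zinc-replete) mixtures anchor the reported CDK2inc
#' and CDK2low fractions; the inc/emerge split in MM and ZR is a free choice
#' because only the quiescent fraction is reliably reported there. The
#' `.p21ko` entries model the p21-null genotype, whose spontaneous quiescence
#' is strongly reduced in replete media but essentially unchanged in ZD.
#'
#' @return named list of `c(inc=, emerge=, low=)` probability vectors.
#' @export
defaultFateMixtures <- function() {
  list(
    ZD       = c(inc = 0.09, emerge = 0.50, low = 0.41),
    MM       = c(inc = 0.56, emerge = 0.27, low = 0.17),
    ZR       = c(inc = 0.60, emerge = 0.26, low = 0.14),
    ZD.p21ko = c(inc = 0.08, emerge = 0.50, low = 0.42),
    MM.p21ko = c(inc = 0.64, emerge = 0.28, low = 0.08),
    ZR.p21ko = c(inc = 0.70, emerge = 0.25, low = 0.05)
  )
}

#' Default window-conditioned fate mixtures for the scheduled-perturbation
#' experiment
#'
#' In the zinc-removal scheduling experiment cells grow in replete medium and
#' the chelator is added at a fixed hour; a cell's fate depends on when its
#' mitosis falls relative to that addition. Keys are the start (hours,
#' relative to the perturbation) of each 4-h mitosis window. The CDK2inc
#' series (43/30/17/5%) and the pre-window quiescent fraction (15%) follow
#' the reported window-resolved fractions; the remaining mass is split so
#' that quiescence grows smoothly with time since zinc removal.
#'
#' @return list with one entry, `ZD.schedule`, as used by
#'   [generateTraceEnsemble()] together with `perturbationTime`.
#' @export
defaultWindowMixtures <- function() {
  list(ZD.schedule = list(
    `-4` = c(inc = 0.50, emerge = 0.35, low = 0.15),
    `0`  = c(inc = 0.43, emerge = 0.37, low = 0.20),
    `4`  = c(inc = 0.30, emerge = 0.35, low = 0.35),
    `8`  = c(inc = 0.17, emerge = 0.28, low = 0.55),
    `12` = c(inc = 0.05, emerge = 0.20, low = 0.75)
  ))
}

#' Build a synthetic-experiment configuration
#'
#' Constructor for [SyntheticConfig-class] with the study-condition defaults:
#' 12-min frame interval, 60-h movies, log-normal inter-mitotic times with a
#' 13-h mode, a CDK2 commitment ramp from a 0.5 post-mitosis baseline to a
#' 2.2 ceiling, and a 1.2 stall plateau in zinc-deficient conditions.
#'
#' @param seed integer RNG seed.
#' @param frameInterval hours between frames.
#' @param duration total imaging time, hours.
#' @param imageSize integer(2) field size in px.
#' @param nCellsInitial founder cells per rendered field.
#' @param noiseSd additive Gaussian noise sd.
#' @param fateMixture see [defaultFateMixtures()].
#' @param windowMixtures see [defaultWindowMixtures()].
#' @param stallConditions conditions whose committed cells stall.
#' @param cycleLength list(mode, sigma) of the log-normal cycle length.
#' @param stallPlateau CDK2 ratio of the stall plateau.
#' @param commitShape list(baseline, riseRate, maxRatio).
#' @param perturbationTime hour of the scheduled perturbation (`NA` = none).
#' @return a validated [SyntheticConfig-class].
#' @examples
#' cfg <- syntheticConfig(seed = 7)
#' cfg
#' @export
syntheticConfig <- function(seed = 1L,
                            frameInterval = 0.2,
                            duration = 60,
                            imageSize = c(256L, 256L),
                            nCellsInitial = 9L,
                            noiseSd = 0.05,
                            fateMixture = defaultFateMixtures(),
                            windowMixtures = defaultWindowMixtures(),
                            stallConditions = c("ZD", "ZD.p21ko", "ZD.schedule"),
                            cycleLength = list(mode = 13, sigma = 0.15),
                            stallPlateau = 1.2,
                            commitShape = list(baseline = 0.5, riseRate = 0.35,
                                               maxRatio = 2.2),
                            perturbationTime = NA_real_) {
  new("SyntheticConfig",
      seed = as.integer(seed),
      frameInterval = frameInterval,
      duration = duration,
      imageSize = as.integer(imageSize),
      nCellsInitial = as.integer(nCellsInitial),
      noiseSd = noiseSd,
      fateMixture = fateMixture,
      windowMixtures = windowMixtures,
      stallConditions = stallConditions,
      cycleLength = cycleLength,
      stallPlateau = stallPlateau,
      commitShape = commitShape,
      perturbationTime = perturbationTime)
}

## Largest-remainder (Hare) apportionment of n items to probabilities p.
.allocateCounts <- function(n, p) {
  raw <- n * p
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1L
  }
  as.integer(k)
}

## Log-normal cycle lengths parameterized by mode m and log-sd s:
## mode = exp(mu - s^2)  =>  mu = log(m) + s^2.
.rCycleLength <- function(n, cycleLength) {
  s <- cycleLength$sigma
  stats::rlnorm(n, meanlog = log(cycleLength$mode) + s^2, sdlog = s)
}

#' Generate a synthetic ensemble of CDK2 traces with known ground truth
#'
#' Draws `nCells` single-cell lineage traces for one growth condition. Each
#' trace carries a first tracked mitosis on the frame grid; the post-mitosis
#' trajectory follows the fate template (prompt commitment, delayed
#' commitment, or sustained low activity), with committed cells either
#' completing further cycles (replete conditions) or rising to the stall
#' plateau and holding it (zinc-deficient conditions). Gaussian noise of
#' `noiseSd` is added and the trace clipped at zero.
#'
#' Fates are apportioned to the mixture by largest-remainder allocation and
#' then assigned to cells by a seeded random permutation, so the planted
#' composition matches the mixture to within one cell per class.
#'
#' For schedule-conditioned conditions (present in `windowMixtures`, with a
#' finite `perturbationTime` in `config`), each cell's first mitosis is drawn
#' uniformly on the frame grid across the 4-h windows spanning
#' `perturbationTime - 4` to `perturbationTime + 16` hours, and its fate is
#' drawn from that window's mixture.
#'
#' @param config a [SyntheticConfig-class].
#' @param condition a condition label present in `config`'s `fateMixture`
#'   (or `windowMixtures`).
#' @param nCells number of traces (>= 0).
#' @return a [TraceEnsemble-class]; `groundTruth()` returns the per-cell
#'   truth (fate, first mitosis, commit time, stall status, plateau).
#' @examples
#' ens <- generateTraceEnsemble(syntheticConfig(seed = 7), "ZD", 50)
#' table(groundTruth(ens)$true_fate)
#' @export
generateTraceEnsemble <- function(config, condition, nCells) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  if (length(nCells) != 1L || is.na(nCells) || nCells < 0)
    stop("nCells must be a single non-negative count")
  nCells <- as.integer(nCells)
  schedule <- condition %in% names(config@windowMixtures) &&
    is.finite(config@perturbationTime)
  if (!schedule && !condition %in% names(config@fateMixture))
    stop("unknown condition label: ", condition)

  dt <- config@frameInterval
  tt <- seq(0, config@duration, by = dt)
  nf <- length(tt)
  shp <- config@commitShape
  b <- shp$baseline; rho <- shp$riseRate; M <- shp$maxRatio
  stalls <- condition %in% config@stallConditions

  if (nCells == 0L) {
    se <- SummarizedExperiment(
      assays = list(ratio = matrix(numeric(0), 0, nf)),
      rowData = DataFrame(cell_id = character(0), condition = character(0),
                          well = integer(0), parent_id = character(0),
                          first_mitosis = numeric(0),
                          divisions = NumericList()),
      colData = DataFrame(frame = seq_len(nf), t_hours = tt))
    metadata(se)$config <- config
    metadata(se)$truth <- DataFrame(cell_id = character(0),
                                    true_fate = character(0),
                                    first_mitosis = numeric(0),
                                    true_commit = numeric(0),
                                    stalled = logical(0),
                                    true_plateau = numeric(0))
    return(new("TraceEnsemble", se))
  }

  set.seed(config@seed)
  ids <- sprintf("c%05d", seq_len(nCells))

  ## -- first mitosis times (snapped to the frame grid) and fate labels -----
  if (schedule) {
    wm <- config@windowMixtures[[condition]]
    wstart <- sort(as.numeric(names(wm)))
    lo <- config@perturbationTime + min(wstart)
    hi <- config@perturbationTime + max(wstart) + 4
    fr <- which(tt >= lo & tt < hi)
    m1 <- tt[sample(fr, nCells, replace = TRUE)]
    win <- wstart[findInterval(m1 - config@perturbationTime, c(wstart, max(wstart) + 4),
                               rightmost.closed = FALSE)]
    fate <- character(nCells)
    for (w in wstart) {
      sel <- which(win == w)
      p <- wm[[as.character(w)]]
      counts <- .allocateCounts(length(sel), p)
      fate[sel] <- sample(rep(c("inc", "emerge", "low"), counts))
    }
  } else {
    lo <- min(2, 0.3 * config@duration)
    hi <- min(18, 0.9 * config@duration)
    fr <- which(tt >= lo & tt <= hi)
    if (!length(fr)) fr <- max(2L, round(nf / 2))
    m1 <- tt[sample(fr, nCells, replace = TRUE)]
    p <- config@fateMixture[[condition]]
    counts <- .allocateCounts(nCells, p[c("inc", "emerge", "low")])
    fate <- sample(rep(c("inc", "emerge", "low"), counts))
  }

  ## -- per-cell trajectory -------------------------------------------------
  ratio <- matrix(NA_real_, nCells, nf)
  divisions <- vector("list", nCells)
  commit <- rep(NA_real_, nCells)
  stalled <- logical(nCells)
  plateau <- rep(NA_real_, nCells)

  for (i in seq_len(nCells)) {
    m <- m1[i]
    r <- numeric(nf)
    pre <- tt < m
    ## founder observed mid-cycle: ramp up to maxRatio at its division
    r[pre] <- pmax(0.8, M - rho * (m - tt[pre]))
    divs <- m
    post <- !pre
    tp <- tt[post] - m               # hours since first mitosis
    if (fate[i] == "low") {
      r[post] <- b + stats::runif(1, -0.05, 0.05)
    } else {
      cmt <- if (fate[i] == "inc") stats::runif(1, 0.8, 3.8)
             else stats::runif(1, 4.0, 20.0)
      commit[i] <- cmt
      lead <- (1 - b) / rho          # hours to ramp from baseline to ratio 1
      s <- max(0, cmt - lead)
      slope <- (1 - b) / (cmt - s)
      ramp <- b + slope * pmax(0, tp - s)
      if (stalls) {
        r[post] <- pmin(ramp, config@stallPlateau)
        stalled[i] <- TRUE
        plateau[i] <- config@stallPlateau
      } else {
        ## complete further cycles: divisions spaced by log-normal lengths
        L <- .rCycleLength(8L, config@cycleLength)
        dnext <- m + cumsum(L)
        dnext <- dnext[dnext <= config@duration]
        ## snap to frame grid
        dnext <- tt[pmin(nf, round(dnext / dt) + 1L)]
        dnext <- dnext[dnext > m]
        cyc <- r[post]
        bounds <- c(m, dnext, Inf)
        for (k in seq_len(length(bounds) - 1L)) {
          inseg <- tp > (bounds[k] - m) - 1e-9 & tp <= (bounds[k + 1L] - m) + 1e-9
          if (!any(inseg)) next
          if (k == 1L) {
            cyc[inseg] <- pmin(ramp[inseg], M)
          } else {
            ts <- tp[inseg] - (bounds[k] - m)
            span <- if (is.finite(bounds[k + 1L]))
              bounds[k + 1L] - bounds[k] else config@cycleLength$mode
            sl <- (M - b) / max(span - 1, 2)
            cyc[inseg] <- pmin(b + sl * pmax(0, ts - 1), M)
          }
        }
        r[post] <- cyc
        divs <- c(divs, dnext)
      }
    }
    if (config@noiseSd > 0) r <- r + stats::rnorm(nf, sd = config@noiseSd)
    ratio[i, ] <- pmax(r, 0)
    divisions[[i]] <- divs
  }

  se <- SummarizedExperiment(
    assays = list(ratio = ratio),
    rowData = DataFrame(cell_id = ids, condition = condition,
                        well = rep_len(1:4, nCells),
                        parent_id = NA_character_,
                        first_mitosis = m1,
                        divisions = NumericList(divisions)),
    colData = DataFrame(frame = seq_len(nf), t_hours = tt))
  rownames(se) <- ids
  metadata(se)$config <- config
  metadata(se)$truth <- DataFrame(
    cell_id = ids,
    true_fate = paste0("CDK2", fate),
    first_mitosis = m1,
    true_commit = commit,
    stalled = stalled,
    true_plateau = plateau)
  if (schedule)
    metadata(se)$truth$window_start <- win - 0  # relative to perturbation
  new("TraceEnsemble", se)
}
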