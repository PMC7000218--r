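#' @include AllClasses.R synthetic-traces.R
NULL

## Reflect coordinates into [lo, hi] (soft wall for random walks).
.reflect <- function(x, lo, hi) {
  L <- hi - lo
  abs(((x - lo) %% (2 * L)) - L) * -1 + L + lo - 0  # fold
}

## Add a filled disc to a frame (value overwrites where the disc is brighter).
.paintDisc <- function(frame, cx, cy, r, value) {
  d <- dim(frame)
  xi <- max(1L, floor(cx - r)):min(d[1], ceiling(cx + r))
  yi <- max(1L, floor(cy - r)):min(d[2], ceiling(cy + r))
  if (!length(xi) || !length(yi)) return(frame)
  sub <- frame[xi, yi, drop = FALSE]
  inside <- outer((xi - cx)^2, (yi - cy)^2, "+") <= r^2
  sub[inside] <- pmax(sub[inside], value)
  frame[xi, yi] <- sub
  frame
}

## Add an annulus (ring of cytoplasm) between radii r0 and r1.
.paintAnnulus <- function(frame, cx, cy, r0, r1, value) {
  d <- dim(frame)
  xi <- max(1L, floor(cx - r1)):min(d[1], ceiling(cx + r1))
  yi <- max(1L, floor(cy - r1)):min(d[2], ceiling(cy + r1))
  if (!length(xi) || !length(yi)) return(frame)
  sub <- frame[xi, yi, drop = FALSE]
  rr <- outer((xi - cx)^2, (yi - cy)^2, "+")
  band <- rr > r0^2 & rr <= r1^2
  sub[band] <- pmax(sub[band], value)
  frame[xi, yi] <- sub
  frame
}

#' Render a two-channel movie from a trace ensemble
#'
#' Renders each lineage as a smoothed nuclear blob on the H2B channel and as
#' nucleus + perinuclear cytoplasm on the CDK2-reporter channel, with
#' per-frame Gaussian random-walk motion (sd 1 px). In the `condWindow`
#' frames before each division the nucleus condenses: total H2B intensity
#' rises by >= 30% while area falls by >= 40% (mean intensity therefore
#' rises ~2.4x), after which the blob splits into two daughters. The
#' off-trace daughter persists as a silent, non-dividing blob at the
#' post-mitosis baseline ratio so that object counts behave like a real
#' field. On the CDK2 channel the cytoplasmic annulus is painted at
#' `ratio x` the nuclear level, so ring-mean / nuclear-mean recovers the
#' programmed ratio.
#'
#' @param ensemble a [TraceEnsemble-class] whose time grid matches `config`.
#' @param config the [SyntheticConfig-class] used to generate it.
#' @param condWindow frames of pre-division condensation (default 3).
#' @return a [Movie-class]; `groundTruth()` lists every rendered blob per
#'   frame with its programmed position, radius and ratio.
#' @examples
#' cfg <- syntheticConfig(seed = 3, duration = 8, noiseSd = 0)
#' ens <- generateTraceEnsemble(cfg, "MM", 4)
#' mov <- renderMovie(ens, cfg)
#' @export
renderMovie <- function(ensemble, config, condWindow = 3L) {
  stopifnot(is(ensemble, "TraceEnsemble"), is(config, "SyntheticConfig"))
  tt <- traceTimes(ensemble)
  if (max(abs(diff(tt) - config@frameInterval)) > 1e-9)
    stop("ensemble time grid does not match config frame grid")
  set.seed(config@seed + 1L)
  d <- config@imageSize
  nf <- length(tt)
  n <- nrow(ensemble)
  R <- cdk2Ratios(ensemble)
  divs <- divisionTimes(ensemble)
  dt <- config@frameInterval
  wallOuter <- min(40, min(d) %/% 4)
  margin <- wallOuter + 4

  ## founder positions on a jittered grid
  ng <- ceiling(sqrt(n))
  gx <- seq(margin, d[1] - margin, length.out = max(ng, 2))
  gy <- seq(margin, d[2] - margin, length.out = max(ng, 2))
  grid <- expand.grid(x = gx, y = gy)[seq_len(n), , drop = FALSE]
  baseR <- stats::runif(n, 9, 11)

  blobs <- lapply(seq_len(n), function(i) {
    walk <- matrix(stats::rnorm(2L * nf, sd = 1), ncol = 2)
    pos <- cbind(grid$x[i] + cumsum(walk[, 1]) + stats::runif(1, -4, 4),
                 grid$y[i] + cumsum(walk[, 2]) + stats::runif(1, -4, 4))
    ## founder walks are reflected at a wide wall so that division offsets
    ## (up to ~22 px) can never push a daughter off the field or fold it
    ## back onto its sibling
    pos[, 1] <- .reflect(pos[, 1], wallOuter, d[1] - wallOuter)
    pos[, 2] <- .reflect(pos[, 2], wallOuter, d[2] - wallOuter)
    list(id = rowData(ensemble)$cell_id[i], pos = pos, r = baseR[i],
         ratio = R[i, ], divFrames = round(divs[[i]] / dt) + 1L,
         silent = FALSE)
  })

  ## silent sibling blobs for each division; the tracked daughter shifts a
  ## short distance (within the tracking gate), the sibling a longer one
  sibs <- list()
  for (i in seq_len(n)) {
    for (fd in blobs[[i]]$divFrames) {
      if (fd >= nf) next
      theta <- stats::runif(1, 0, 2 * pi)
      u <- c(cos(theta), sin(theta))
      walk <- matrix(stats::rnorm(2L * nf, sd = 1), ncol = 2)
      start <- blobs[[i]]$pos[fd, ] + 12 * u
      pos <- matrix(NA_real_, nf, 2)
      later <- (fd + 1L):nf
      drift <- 0.35 * pmin(seq_along(later), 30)
      pos[later, ] <- cbind(start[1] + cumsum(walk[later, 1]) + drift * u[1],
                            start[2] + cumsum(walk[later, 2]) + drift * u[2])
      rat <- rep(NA_real_, nf)
      rat[later] <- config@commitShape$baseline +
        stats::rnorm(length(later), sd = config@noiseSd)
      sibs[[length(sibs) + 1L]] <- list(
        id = sprintf("%s.sib%d", blobs[[i]]$id, fd),
        pos = pos, r = blobs[[i]]$r * 0.78, ratio = pmax(rat, 0),
        divFrames = integer(0), silent = TRUE)
      blobs[[i]]$pos[later, ] <- blobs[[i]]$pos[later, , drop = FALSE] -
        outer(6 + drift, u)
    }
  }
  blobs <- c(blobs, sibs)

  h2b <- array(0, dim = c(d[1], d[2], nf))
  cdk <- array(0, dim = c(d[1], d[2], nf))
  truth <- list()
  h2bLevel <- 0.40
  nucLevel <- 0.30

  wall <- 17
  for (bi in seq_along(blobs)) {
    blobs[[bi]]$pos[, 1] <- .reflect(blobs[[bi]]$pos[, 1], wall, d[1] - wall)
    blobs[[bi]]$pos[, 2] <- .reflect(blobs[[bi]]$pos[, 2], wall, d[2] - wall)
  }
  for (b in blobs) {
    live <- which(!is.na(b$pos[, 1]))
    if (any(b$pos[live, 1] < 16 | b$pos[live, 1] > d[1] - 15 |
            b$pos[live, 2] < 16 | b$pos[live, 2] > d[2] - 15))
      stop("cell position leaves the field: enlarge imageSize or margin")
    for (f in live) {
      rScale <- 1; iScale <- 1
      nxt <- b$divFrames[b$divFrames >= f]
      if (length(nxt) && (nxt[1] - f) < condWindow) {
        ## condensation ramp: painted area -> 0.40x (measured, with blur
        ## halo, ~0.5x) and total intensity -> ~1.35x
        prog <- 1 - (nxt[1] - f) / condWindow
        rScale <- 1 - prog * (1 - sqrt(0.40))
        iScale <- 1 + prog * 2.4
      }
      ## daughters are born small and regrow over ~20 frames
      prevDiv <- b$divFrames[b$divFrames < f]
      grow <- if (length(prevDiv)) min(1, 0.78 + 0.011 * (f - max(prevDiv)))
              else 1
      r <- b$r * rScale * grow
      h2b[, , f] <- .paintDisc(h2b[, , f], b$pos[f, 1], b$pos[f, 2], r,
                               h2bLevel * iScale)
      rat <- b$ratio[f]
      cdk[, , f] <- .paintAnnulus(cdk[, , f], b$pos[f, 1], b$pos[f, 2],
                                  r, r + 6, nucLevel * rat)
      cdk[, , f] <- .paintDisc(cdk[, , f], b$pos[f, 1], b$pos[f, 2], r,
                               nucLevel)
      truth[[length(truth) + 1L]] <- data.frame(
        frame = f, cell_id = b$id, x = b$pos[f, 1], y = b$pos[f, 2],
        radius = r, ratio = rat)
    }
  }

  for (f in seq_len(nf)) {
    h2b[, , f] <- as.matrix(EBImage::gblur(EBImage::Image(h2b[, , f]), sigma = 1))
    cdk[, , f] <- as.matrix(EBImage::gblur(EBImage::Image(cdk[, , f]), sigma = 0.5))
    if (config@noiseSd > 0) {
      h2b[, , f] <- pmax(h2b[, , f] +
        stats::rnorm(prod(d), sd = config@noiseSd * 0.5), 0)
      cdk[, , f] <- pmax(cdk[, , f] +
        stats::rnorm(prod(d), sd = config@noiseSd * 0.5), 0)
    }
  }

  new("Movie", h2b = h2b, cdk2 = cdk, frameTimes = tt,
      truth = DataFrame(do.call(rbind, truth)))
}
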