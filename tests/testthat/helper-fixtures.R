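## Shared fixtures: hand-built ensembles, independent oracles, tiny painters.
## Everything is generated in code; no binary fixtures.

suppressPackageStartupMessages({
  library(S4Vectors)
  library(SummarizedExperiment)
  library(IRanges)
})

## Build a TraceEnsemble from a ratio matrix and per-cell division times.
makeEnsemble <- function(ratio, times, divisions,
                         condition = "test", parent = NULL) {
  n <- nrow(ratio)
  ids <- sprintf("t%03d", seq_len(n))
  if (is.null(parent)) parent <- rep(NA_character_, n)
  se <- SummarizedExperiment(
    assays = list(ratio = ratio),
    rowData = DataFrame(cell_id = ids, condition = condition,
                        well = rep_len(1L, n), parent_id = parent,
                        first_mitosis = vapply(divisions, function(d)
                          if (length(d)) d[1] else NA_real_, numeric(1)),
                        divisions = NumericList(divisions)),
    colData = DataFrame(frame = seq_along(times), t_hours = times))
  rownames(se) <- ids
  new("TraceEnsemble", se)
}

## A single-cell trace on a regular grid following a piecewise-linear shape.
rampTrace <- function(times, knots, values) {
  stats::approx(knots, values, xout = times, rule = 2)$y
}

## Independent flood-fill component counter (BFS, 8-connectivity), used as
## an oracle against the package's labeling.
floodCount <- function(bin) {
  bin <- bin > 0
  d <- dim(bin)
  seen <- matrix(FALSE, d[1], d[2])
  count <- 0L
  for (i0 in seq_len(d[1])) for (j0 in seq_len(d[2])) {
    if (!bin[i0, j0] || seen[i0, j0]) next
    count <- count + 1L
    queue <- matrix(c(i0, j0), ncol = 2)
    seen[i0, j0] <- TRUE
    while (nrow(queue)) {
      p <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
            bin[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
  }
  count
}

## Paint a hard-edged disc (no blur) -- independent of the package painters.
testDisc <- function(img, cx, cy, r, value) {
  d <- dim(img)
  xs <- row(img); ys <- col(img)
  img[(xs - cx)^2 + (ys - cy)^2 <= r^2] <- value
  img
}

## Paint an axis-aligned ellipse.
testEllipse <- function(img, cx, cy, a, b, value) {
  xs <- row(img); ys <- col(img)
  img[((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1] <- value
  img
}

## LabelMask straight from a label matrix plus an intensity image.
maskFromLabels <- function(lab, image = NULL) {
  if (is.null(image)) image <- matrix(0, nrow(lab), ncol(lab))
  ZnFate:::.maskFromLabels(lab, image)
}

## Exact two-sided binomial 95% CI for an observed proportion at size n.
binomCI <- function(p, n) {
  stats::qbinom(c(0.025, 0.975), n, p) / n
}
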