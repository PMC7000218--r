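---
title: "Quantifying zinc-deficiency-induced quiescence from single-cell imaging"
author: "ZnFate maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying zinc-deficiency-induced quiescence from single-cell imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ZnFate)
```

## The biology and the measurement problem

Proliferating epithelial cells continuously decide, at each mitosis, whether
to commit to another cycle or to enter a reversible quiescent state (G0).
A CDK2 substrate translocation reporter makes this decision visible in
living cells: when CDK2 activity is low the reporter is nuclear, and as
activity rises through the cycle it moves to the cytosol, so the
cytoplasmic-to-nuclear fluorescence ratio acts as a molecular timer. Cells
born with rising CDK2 activity (CDK2^inc^) are committed; cells that keep a
low ratio after mitosis (CDK2^low^) are quiescent; cells that commit only
after a delay are CDK2^emerge^.

Mild zinc deficiency — imposed with a low-micromolar cell-permeant chelator
while mitogens stay saturating — reshapes this decision drastically: few
cells are born committed, many enter quiescence directly, and cells that do
attempt re-entry rise only to an intermediate CDK2 activity (a ratio near
1.2), hold it without ever dividing, and show S-phase features (active DNA
synthesis defects, replication-stress and double-strand-break foci).
ZnFate implements the full measurement chain needed to make those
statements quantitative, together with a synthetic-data generator that
provides exact ground truth for every stage.

## Pipeline and models

### Segmentation, tracking, mitosis

Nuclei are segmented per frame from the H2B channel: local-mean adaptive
threshold (window ≈ 2 nuclear diameters, configurable offset), hole
filling, a watershed on the distance transform to split touching nuclei
(h-maxima suppression via the `tolerance` parameter), and a minimum-area
filter. Identities are propagated by greedy globally-nearest centroid
assignment under a per-frame displacement gate (default 10 px at the
synthetic scale). We deliberately do not close gaps across missing frames:
at a 12-min cadence single-frame dropouts are rare in the data this
emulates, and gap closing would complicate the identity model. Optimal
(Hungarian) assignment was considered and left out — at the planted cell
densities greedy matching is exact in practice, and the tracking tests
compare against that expectation.

A track birth adjacent to an existing track is only promoted to a mitosis
if the mother shows the chromatin condensation signature over the `w = 3`
frames before the split: mean H2B intensity fold ≥ `r_I = 1.3` and area
fold ≤ `r_A = 0.6`. These thresholds are declared package defaults (exposed
in `mitosisParams()`), not literature-derived constants: the source
analyses describe the criteria qualitatively (intensity rise plus nuclear
shrinkage before the H2B signal splits in two) without printing values.
Splits without the signature — e.g. over-segmentation artefacts — start
unrelated tracks, which is what gives the detector its measured precision
of 1.0 on adversarial fixtures.

### Reporter quantification

The cytosolic CDK2 reporter signal is sampled on a ring 3 px wide
immediately outside each nucleus. Ring construction uses Euclidean dilation
(a disc structuring element): for a radius-10 nucleus this yields the
expected annulus area of about π((r+3)² − r²) ≈ 217 px², and every ring
pixel is within Chebyshev distance 3 of its nucleus. Pixels inside any
nucleus are never ring pixels, and pixels reachable from two nuclei are
contested and dropped from both rings, so rings are pairwise disjoint. The
cytosolic statistic defaults to the ring **median** rather than the mean —
robust to bleed-through from a bright neighbour — and is switchable to the
mean for strict parity with mean-based pipelines. For live-cell FRET the
same ring geometry serves as the cytosolic region; background is the
darkest portion of non-cell pixels, replacing the manually drawn dark ROIs
an interactive analysis would use. Background-subtracted numerators are
clipped at a small epsilon so noise cannot flip a ratio's sign.

### Fate classification

Traces are aligned computationally to a chosen mitosis (`alignToMitosis()`,
idempotent) and classified by the first upward crossing of the commitment
threshold: crossing within 4 h → CDK2inc, later → CDK2emerge, never →
CDK2low. Default threshold 1.0 (cytoplasmic = nuclear): the published
trace figures place the dashed classification threshold near unity, but
the exact value is config-exposed (`classifierConfig()`). Two denominator
decisions matter and are explicit:

* Cells with less than `minFollowup = 10` h of post-mitosis observation are
  `unclassifiable` and excluded from fraction denominators, avoiding
  censoring bias; fractions therefore refer to cells with a tracked mitosis
  and adequate followup, and `fateFractions()` reports that n.
* Cells that never divide during imaging are excluded from mitosis-aligned
  fractions but still count in proliferation summaries.

Stall detection: a committed cell is stalled when its ratio stays in
`[commit − 0.1, 1.5)` for ≥ 8 h through trace end with no further mitosis;
the plateau estimate is the median over the final 8 h. The plateau value
(~1.2) is what the data show; the band and hold parameters are declared
detection rules, config-exposed, because no printed rule exists to adopt.

Window binning around a perturbation uses half-open `[a, a + 4)` intervals
of first-mitosis time relative to the perturbation instant; a mitosis at
exactly the perturbation time falls in the first post-perturbation window.
This convention makes the partition unambiguous.

### Zinc sensor calibration

With resting, chelated-minimum and saturated ratios R_rest, R_min, R_max,
the package computes dynamic range DR = R_max/R_min, fractional saturation
FS = (R_rest − R_min)/(R_max − R_min), and the inverse Hill concentration

$$[\mathrm{Zn}^{2+}] = K_D\left(\frac{R_{rest}-R_{min}}{R_{max}-R_{rest}}\right)^{1/n},\qquad K_D = 5300\ \mathrm{pM},\ n = 0.29.$$

The inverse is strictly monotone on (R_min, R_max), returns 0 pM at
R_min, diverges at R_max (an error), and exactly inverts the forward
response `hillResponse()` — the round-trip is tested to 1e-6 relative. At
FS = 1/2 the Hill argument is 1 and the result is K_D for any exponent;
this analytic identity anchors the calibration tests.

### Fixed-cell assays

Foci detection crops a 140×140-px square around each nucleus, smooths
lightly, and thresholds at the cell's median nuclear intensity plus
`(1 − sensitivity)` of the contrast to the brightest structure in the crop
(absolute floor 0.15 in normalized units so featureless crops stay empty;
`sensitivity` defaults to 0.5). Candidates are filtered by area — 10–100
px² for RPA2, 10–200 px² for 53BP1 — and moment-ellipse eccentricity < 0.6,
and must overlap their own nucleus. Requiring nuclear overlap (rather than
mere presence in the crop) is a deliberate reading of an underspecified
step; it prevents a neighbour's focus from scoring the wrong cell, at a
small risk of divergence from analyses that accept crop-wide puncta.

The hypo/hyper-pRb split is a two-component Gaussian mixture on
log-intensity (via mclust) with the boundary at equal posterior, rather
than a fixed cutoff: the underlying populations are bimodal but no
threshold is printed, and the mixture split is scale-invariant by
construction. EdU background is removed by dividing the image into an
11-by-11 grid of equal tiles and subtracting each tile's 5th-percentile
intensity (clipped at zero) — "11 × 11 blocks" is read as a grid of 121
tiles, not 11-px tiles; the block count is a parameter if the other
reading is ever wanted. DNA content is the integrated nuclear PI intensity;
2N/4N centres are the two dominant kernel-density modes (bandwidth set to a
third of the default rule — the default over-smooths tight 2N/4N peaks into
the broad S-phase plateau between them), gates extend ±25% around each
centre, and phases follow the EdU-by-DNA rules: EdU⁻2N → G0/G1, EdU⁻4N →
G2/M, EdU⁺ → S, EdU⁻ intermediate → unclassified. The EdU threshold is the
negative-mode mean + 3 sd with a reflected-MAD sd estimate; by construction
this admits a ≲1% false-positive tail, which the tests allow for.

## The synthetic generator: what it emulates, and what it does not

`syntheticConfig()` fixes the study conditions: 12-min frame interval, 60-h
duration, log-normal inter-mitotic times parameterized by mode (13 h) and
log-dispersion (0.15) to capture the right-skew of real cycle lengths, a
post-mitosis baseline ratio of 0.5 rising at 0.35 h⁻¹ to a ceiling of 2.2,
and a stall plateau of 1.2. Condition fate mixtures are anchored to the
reported fractions where those are reliable (ZD 9/50/41; MM and ZR anchored
on their quiescent fractions 17% and 14%, with the inc/emerge split a free
choice since the printed inc/emerge pairs are mutually inconsistent;
p21-null ZD anchored at 42% quiescent). The scheduled-perturbation
condition draws each cell's fate from a window-conditioned mixture (CDK2inc
series 43/30/17/5% after removal, 15% quiescent in the window just before).
CDK2emerge commitment delays are uniform on (4, 20) h — no delay
distribution is reported, so the least-informative simple choice is used.

Fates are apportioned by largest-remainder allocation of expected counts
and then assigned to cells by a seeded random permutation. This is a
variance-reduction choice made at design time: recovery tests then measure
classifier error rather than multinomial sampling noise, while the planted
composition still sits trivially inside any binomial confidence band.

Movies render nuclei as smoothed discs (radius 9–11 px at 256², the
smallest geometry at which a 3-px ring is well defined) with per-frame
Gaussian random-walk motion (sd 1 px) reflected at soft field walls, a
pre-division condensation ramp (painted area → 0.40×, total intensity →
~1.35×, hence mean intensity ≳2×), and a post-division split into two
daughters that drift apart before wandering independently. The reporter
channel paints the cytoplasmic annulus at the programmed ratio times the
nuclear level, so quantification can be checked against truth to ±0.05.
Noise is additive Gaussian on both channels, clipped at zero.

Deliberately **not** emulated: point-spread functions, shot noise,
photobleaching, cell-shape irregularity, dense-culture collisions or
crossing trajectories, focus drift, or fluorophore crosstalk. Passing
tests therefore demonstrate the correctness of the measurement chain on
well-posed inputs and the internal consistency of the statistical
machinery — not robustness to every pathology of real microscopy data.

## Numerical choices and degenerate inputs

* All division times snap to the frame grid; classification is invariant to
  uniform time shifts and to common multiplicative gain on both channels.
* Crossing detection is first-sample-above-threshold; with default noise
  (sd 0.05) and slope, the induced jitter is well under one frame interval.
* An all-zero image segments to an empty mask (not an error); an empty
  first frame makes the proliferation curve error out, since normalization
  to initial density is undefined.
* Ties in heatmap sorting break by cell id, making row order deterministic
  and permutation-invariant.
* Single-mode DNA populations flag the undefined 4N gate instead of
  guessing; constant or unimodal pRb intensities yield a single-class
  result with a warning.
* Problem sizes in the shipped tests and acceptance script — 2000 traces
  per condition, 1600 schedule traces, 960 rendered fixed cells, 400
  cycling lineages (≈1100 completed cycles), 500 stalled traces — were
  chosen so that exact binomial 95% bands at those n are tight relative to
  the fractions being recovered.

## Limitations

Tracking has no gap closing and greedy assignment can in principle swap
adjacent identities in dense fields; the mitosis thresholds and stall rule
are declared defaults, not fitted constants; the FRET background model
replaces manual dark-ROI selection with an automatic percentile estimate;
and the fixed-cell analysis assumes roughly circular nuclei. Each knob is
exposed through its parameter object so real-data users can recalibrate
without touching code.
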