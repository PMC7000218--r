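# ZnFate

Single-cell image analysis of zinc-deficiency-induced quiescence and
cell-cycle stalling.

Zinc is an essential micronutrient, and mild cytosolic Zn²⁺ deficiency stops
mammalian cell proliferation without killing cells. At the single-cell level
this arrest is heterogeneous: depending on where a cell is in its cycle when
zinc becomes limiting, it either enters quiescence (G0) straight out of
mitosis or re-enters the cycle and stalls in S phase at an intermediate CDK2
activity, accumulating replication-associated DNA damage. ZnFate packages
the quantitative pipeline needed to observe and classify these behaviours —
for microscopists and quantitative cell biologists who track CDK2 reporter
cell lines (e.g. MCF10A expressing DHB-Venus and H2B) through multi-day
time-lapse experiments, and for anyone who wants a fully synthetic,
ground-truthed benchmark of such a pipeline.

## What it computes

* **Segmentation and tracking.** Nuclei are segmented from the H2B channel
  by local-mean adaptive thresholding plus a watershed split of touching
  cells, then linked frame to frame by gated nearest-centroid assignment.
  A 1→2 track split is accepted as a mitosis only with the chromatin
  condensation signature: mean H2B intensity up ≥1.3× and nuclear area down
  to ≤0.6× over the three frames before the split.
* **CDK2 activity.** The translocation reporter's activity is the
  cytoplasmic/nuclear fluorescence ratio, with the cytoplasm sampled on a
  3-px perinuclear ring clipped against neighbouring cells:
  `CDK2 ratio = I_ring / I_nucleus`. Traces are computationally aligned to
  mitosis and classified: first crossing of the commitment threshold
  (default ratio 1.0) within 4 h → **CDK2inc**; later → **CDK2emerge**;
  never → **CDK2low** (quiescent). Committed cells whose ratio holds an
  intermediate plateau (~1.2) to the end of the movie with no further
  division are flagged as S-phase **stalled**.
* **Perturbation timing.** Cells are binned by when their first mitosis
  fell in half-open 4-h windows around a scheduled zinc-removal time, and
  per-window fate fractions are reported.
* **Zinc calibration.** FRET sensor ratios convert to concentrations via
  the inverse Hill model
  `[Zn²⁺] = K_D ((R_rest − R_min)/(R_max − R_rest))^(1/n)` with
  K_D = 5300 pM and n = 0.29, plus dynamic range `R_max/R_min` and
  fractional saturation `(R_rest − R_min)/(R_max − R_min)`.
* **Fixed-cell assays.** 53BP1/RPA2 focus detection in 140×140-px per-cell
  crops with area (10–200 / 10–100 px²) and eccentricity (<0.6) filters,
  damage fractions stratified by a two-component hypo/hyper-pRb split,
  11×11-block 5th-percentile EdU background subtraction, integrated DNA
  content with 2N/4N mode gating, and EdU-vs-DNA cell-cycle phase calls.
* **Synthetic data.** `generateTraceEnsemble()`, `renderMovie()`,
  `generateFociImage()` and `generateEdUPIPopulation()` emulate the
  experiments (12-min cadence, 60-h movies, condition-specific fate
  mixtures, condensation-then-split divisions, planted foci and DNA/EdU
  populations) with exact per-cell ground truth, so every stage above is
  testable end to end.

## Worked example

```r
library(ZnFate)

cfg <- syntheticConfig(seed = 1)                   # 60 h at 12-min cadence
ens <- generateTraceEnsemble(cfg, "ZD", 2000)      # zinc-deficient medium
ens
#> TraceEnsemble: 2000 cells x 301 frames (60.0 h at 12-min cadence)
#>   conditions: ZD (2000)
#>   recorded divisions: 2000; ground truth: present

rec <- classifyFate(ens)                           # align to mitosis + classify
round(fateFractions(rec, percent = TRUE), 1)
#>    CDK2inc CDK2emerge    CDK2low
#>        9.2       49.8       41.0
```

Under zinc deficiency only ~9% of cells are born committed (CDK2inc) while
~41% are born quiescent (CDK2low); the CDK2emerge remainder attempt cycle
re-entry and stall — `rec$stalled` marks them, and
`mean(rec$plateau_ratio[rec$stalled])` sits at the characteristic
intermediate plateau of ≈1.2.

```r
p <- calibrationParams(rRest = 2, rMin = 1, rMax = 3)
znConcentration(p)
#> [1] 5300
```

A resting ratio midway between the chelated minimum and the saturated
maximum puts the sensor at half saturation, so the inverse Hill model
returns exactly K_D (5300 pM) regardless of the Hill coefficient.

A thin command-line wrapper is installed at `inst/scripts/znfate`
(subcommands `simulate`, `classify`, `windows`, `calibrate`, `report`,
`segment`, `track`, `trace`, `foci`, `edu`).

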