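---
title: "Methods: quantifying Ca2+ and PS dynamics in necrotic-cell time-lapse recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying Ca2+ and PS dynamics in necrotic-cell time-lapse recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(necroquant)
```

## The measurement model

During excitotoxic necrosis of *C. elegans* touch neurons, three events
unfold in order: a transient rise of cytoplasmic Ca²⁺ (reported by a
GCaMP-type indicator), cell swelling (visible as a growing cell body), and
the exposure of phosphatidylserine (PS) on the outer membrane leaflet
(reported by a secreted PS-binding fusion that decorates the cell surface
as a ring). `necroquant` quantifies these from two-channel 2-D image
series plus user-supplied ROIs.

**Region formulas.** All intensities are raw pixel sums; nothing is
background-subtracted before ratioing. For a region with total signal $S$
over $A$ pixels, the unit intensity is $U = S/A$. The cell-surface PS
signal lives in the donut between two nested polygons:

$$\mathrm{UPS} = \frac{S_\mathrm{outer} - S_\mathrm{inner}}
                      {A_\mathrm{outer} - A_\mathrm{inner}}, \qquad
  \mathrm{RPS} = \frac{\mathrm{UPS}}{U_\mathrm{background}}, \qquad
  \mathrm{Ca}_R = \frac{U_\mathrm{cell}}{U_\mathrm{background}}.$$

The background region is a nearby disk of equivalent area
(`matched_background_disk()` adjusts its radius until the rasterized
pixel areas agree within a caller-set tolerance, default 5%, since exact
pixel-count equality is not generally achievable). A ratio of 1 means no
enrichment. Ratios are invariant under rescaling the whole image
(`k * image`), but **not** under adding an offset — deliberately so, since
the definitions use raw ratios; camera offsets should be dealt with
upstream.

**Pixel-inclusion rule.** A pixel belongs to a polygon iff its center is
inside under the even-odd rule, with centers exactly on the boundary
counted as inside. Coordinates are 1-based (column = x, row = y) with
pixel centers on the integer lattice, matching R's matrix indexing. The
test suite enforces exact agreement with an independently coded
per-pixel oracle under the same rule. Nested-polygon validity is checked
(inner vertices strictly inside the outer polygon); partially overlapping
polygons are rejected rather than clipped, because a clipped donut would
silently change the measured area.

## Event detection and integrals

The published event timings were read by eye; the package replaces this
with explicit criteria, all config-exposed:

- **Ca²⁺ onset**: first time the trace exceeds `threshold_fold` for at
  least `min_run` consecutive samples. Defaults 1.2 and 2: 1.2-fold is
  the ceiling that ER-pool-deficient (*crt-1*-like) traces never exceed,
  so sustained excursions above it indicate genuine ER-driven release;
  two consecutive samples reject single-frame focus artifacts.
- **Swelling onset**: first time the equivalent radius exceeds
  `fold_threshold` × initial radius (default 1.02, which with the
  generator's growth rate detects within one sampling interval).
- **PS onset**: same sustained-rise criterion applied to the RPS trace.

**Integration** is the trapezoid rule on the native irregular grid with
no smoothing. Windows (minutes post-first embryonic division): overall
560–800, period 1 560–695 (up to the mean time swelling becomes visible),
period 2 696–800 (PS becomes detectable), full recording 560–900. Window
edges are linearly interpolated; traces not covering a bound are
truncated with a warning. Two modes exist because it is ambiguous whether
published integrals interpolated across missing time points:
`"interpolate"` (default) integrates the piecewise-linear interpolant to
the exact bounds; `"observed"` sums only observed intervals. Curves with
fewer than 10 time points are excluded from integral analysis unless
`allow_short = TRUE`, mirroring the curve-inclusion rule of the recording
protocol.

Trapezoid integration is exact on piecewise-linear traces, additive
across abutting windows, and invariant under grid refinement; the tests
assert all three (the latter two to 1e-9 relative).

## Cohort statistics

`normalize_to_reference()` divides each cell's RPS by the reference
cohort mean, so the reference normalizes to exactly 1.
`grouped_count_summary()` partitions animals into consecutive groups
(default 10 per group; 15 or 25 are used for some genotypes) and reports
the mean of group means ± s.e.m. over groups — s.e.m. denominators are
groups for counts and cells for intensities, following the two different
scoring conventions. `ps_positive_fraction()` scores live cells with RPS
above a positivity threshold; the threshold is not defined by the source
measurements (they scored by eye), so the default 1.5 is deliberately
midway between the no-enrichment value 1 and clear rings at ≥ 2, and
`reproduce_paper()` reports a 1.2–2.0 sensitivity range alongside.

`log_integral_regression()` fits OLS of $\log \int \mathrm{PS}$ on
$\log \int \mathrm{Ca}$ and returns slope, intercept, Pearson r and
$R^2 = r^2$. Natural logarithms are used: r, $R^2$ and the slope of a
log–log fit are base-invariant, only the intercept changes with base.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes;
it is phenomenological, not biophysical.

- **Ca²⁺ traces**: baseline 1 (raised by `reuptake_block`, the
  thapsigargin-like parameter) plus 2–4 transient bumps with
  half-Gaussian rise (4–8 min) and exponential decay (15–30 min) — the
  simplest smooth shape matching peaks that gradually return to basal
  level. Peak folds are drawn from [1.4, 5], the observed necrotic
  range, then scaled by `er_release_gain` (1 = full ER release; 0 =
  *crt-1*-like; dantrolene dose lowers it as `max(0, 1 − 0.22·dose)` so
  the 4 µM dose nearly abolishes release). `peak_cap` truncates the
  trace *after* noise as well as before, because the capped genotype is
  defined by its observed values never exceeding 1.2-fold.
- **Swelling**: threshold crossing of the running integral of
  $(\mathrm{Ca}_R - 1)$, echoing the threshold language of the Ca²⁺
  hypothesis of necrosis. The default threshold (90 fold·min) was
  calibrated once so the default necrotic cohort's mean swelling onset
  lands near 695 min, and is not otherwise meaningful. The radius then
  grows linearly to 2.5× over 150 min.
- **PS**: onset `ps_delay` (15 min) after swelling; the RPS trace rises
  as a saturating exponential (τ = 25 min) to a plateau. The plateau is
  solved in closed form so that the trapezoidal integral of RPS over the
  recording grid equals
  $\exp(b_0 + b_1 \log \int \mathrm{Ca}_R)$ *exactly* (defaults
  $b_1 = 1$, $b_0 = \log 1.6$, keeping every target above the
  baseline-only integral). The design was genuinely open here: one could
  couple the *plateau* to the Ca integral instead, but the published
  correlation is between the two integrals, so the integral coupling is
  the invariant the generator guarantees; noise-free cohorts return the
  programmed slope to numerical precision, and the plateau relation
  holds exactly only across cells with equal PS onset and ramp. A
  consequence worth knowing: under dose series the PS *integral* is
  guaranteed monotone in the dose, while the derived plateau need not be
  (later onsets shrink the ramp area it is divided by).
- **Rendering**: cells are disks on an additive background plane of known
  unit intensity; the Ca channel fills the disk with
  $\mathrm{Ca}_R \times$ background, the PS channel fills only a 2–4 px
  ring at the boundary. Centers are offset from the pixel lattice so
  that 256-gon ROIs and rendered masks agree to rasterization tolerance;
  round trips recover programmed ratios within 2% noise-free.
- **Dropout**: the only acquisition pathology modeled is random loss of
  time points (embryos drifting out of focus), which exercises the
  10-point rule. No motion, bleaching, or z-sectioning is simulated;
  images are single-plane 2-D.

Determinism: every draw derives from the scenario seed plus a fixed
per-cell offset, so identical configurations give bit-identical tables;
dose series with a shared seed reuse the same underlying draws, which is
what makes per-cell dose monotonicity testable.

What passing synthetic tests does **not** show: performance on real
microscopy (out-of-focus light, segmentation error, reporter maturation
kinetics, engulfment removing cells from view), nor any claim that the
phenomenological couplings are mechanistically correct.

## Supplementary-workbook reproduction

`load_supplementary()` reads the quantitative per-figure data either from
an `.xlsx` workbook or a directory of per-sheet CSVs, mapping sheet names
to figure keys through `extdata/s1_sheet_map.json` (data-driven because
workbook-internal naming varies; unknown sheets are kept raw with a
warning, never fatally). Expected columns: `Fig2E` (embryo, time_min,
ca_integral, ps_integral — cumulative integrals at successive observed
time points, 60 rows pooled from 4 recordings), `S1FigD`/`S3FigC`
(genotype, cell, window, ca_integral), `Fig3C` (dose_uM, animal,
n_necrotic), `Fig5C`/`Fig5F`/`Fig9B` (genotype, rps), `Fig6C` (genotype,
dose_ug_ml, rps), `Fig7C` (genotype, cell, rps of live cells), `S3FigAB`
(genotype, cell, time_min, ca_r).

`reproduce_paper()` recomputes each printed summary value with the
package's own operations and reports computed vs printed with relative
tolerances (5% for ratios and correlations, printed-rounding equality for
the count mean, bound checks for values printed as ceilings). For the
integral correlation it evaluates both pooling conventions — cumulative
integrals at each time point versus per-interval increments — and records
which one it reports. The published workbook is an external input; the
package ships no copy of it. `write_synthetic_s1_data()` emits a
clearly-labelled synthetic stand-in with the same schema (generated by
the scene generator) so the loader and report machinery are fully
exercised in the test suite; its numbers carry the study's structure, not
its measurements.

## Numerical choices and problem sizes

Degenerate inputs are rejected rather than repaired: polygons with zero
rasterized area, non-nested annuli, non-positive backgrounds, windows
outside the trace support, non-positive values passed to the log
regression (reported with the offending pair indices). Ties in the
even-odd test are broken toward inclusion. The test suite exercises 100
random images up to 32×32 against the per-pixel oracle, render round
trips at 96–112 px with ~10–15 frames, and 20 seeded noisy cohorts of 5
cells for coupling recovery — sizes chosen so the full suite runs in
about a minute on one CPU while every property is still tested at
realistic geometry.

## Limitations

ROIs are inputs; no segmentation or tracking is provided (the original
measurements drew ROIs by hand, and correspondence over time is given).
The generator's couplings are phenomenological. Statistical convenience
stops at Welch t-tests (`cohort_t_test()`); no multiple-testing
correction is applied anywhere because none is part of the analysis
conventions implemented here.
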