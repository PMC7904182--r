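# necroquant

Quantification of cytoplasmic Ca²⁺ and surface-phosphatidylserine (PS)
dynamics in fluorescence time-lapse recordings of cells undergoing
excitotoxic necrosis — the setting is *C. elegans* touch-neuron
degeneration, where a cytoplasmic Ca²⁺ indicator (GCaMP-type) and a
secreted PS reporter (MFG-E8 fusion) are followed through embryogenesis,
but the operations are generic to any two-channel recording of a dying
cell.

The package is aimed at microscopists and analysts who have per-frame ROI
outlines and want reproducible, scriptable versions of the standard
manual measurements:

- **Region quantification.** A cell body is outlined by a closed polygon;
  the membrane PS signal by two nested polygons whose "donut" is the cell
  surface. With total signal `S` and pixel area `A` of each region, the
  unit surface intensity is
  `UPS = (S_outer − S_inner) / (A_outer − A_inner)`, and the
  background-relative intensities are `RPS = UPS / U_background` and
  `Ca_R = U_cell / U_background`, where `U_background` is the unit
  intensity of a nearby region of equivalent size. A value of 1 means no
  enrichment over background. Pixels belong to a region iff their centers
  fall inside the polygon (even-odd rule, boundary inclusive).
- **Event timing.** Onset of the Ca²⁺ rise (first sustained excursion
  above a fold threshold, default 1.2), of cell swelling (equivalent
  radius exceeding a fold of its initial value), and of PS appearance.
- **Windowed integrals.** Trapezoidal integration of relative-intensity
  traces on their native irregular grid (2.5-min sampling from 560–680
  min, 5-min from 685–900 min post-first embryonic division, by default),
  over named windows: 560–800 (overall), 560–695 (pre-swelling), 696–800
  (post-swelling). Curves need ≥ 10 time points to qualify.
- **Cohort statistics.** Reference-normalized intensities, grouped
  necrotic-cell count summaries (mean of group means ± s.e.m.),
  PS-positive live-cell fractions, dose–response tables, and ordinary
  least squares of `log(∫PS)` on `log(∫Ca)` with Pearson r and R².
- **A ground-truthed synthetic generator.** `simulate_cohort()` and
  `render_frames()` produce two-channel image stacks and trace tables
  with known event times, integrals, and a programmed log-linear
  Ca→PS coupling, for every genotype/drug scenario (necrotic `mec-4(d)`
  reference, ER-release-deficient `crt-1`-like, wild-type, dantrolene and
  thapsigargin dose series), so the whole pipeline is testable without
  microscopy data.

## Worked example

```r
library(necroquant)

co <- simulate_cohort(scenario_mec4d(seed = 1))
co$truth[, c("cell", "ca_onset", "swelling_onset", "ps_onset",
             "ca_integral", "ps_integral")]
#>            cell ca_onset swelling_onset ps_onset ca_integral ps_integral
#> 1 mec-4d_cell01    627.5          667.5    682.5       639.1      1022.5
#> 2 mec-4d_cell02    615.0          657.5    672.5       518.4       829.5
#> 3 mec-4d_cell03    602.5          735.0    750.0       485.0       776.0
#> 4 mec-4d_cell04    700.0          740.0    755.0       521.8       834.8

cl <- co$cells[[1]]
detect_onset(cl$ca, threshold_fold = 1.2, min_run = 2)   # 627.5 min
detect_swelling(cl$radius$time, cl$radius$radius)        # 670 min
integrate_trace(cl$ca, time_windows()$overall)           # 537.7 fold·min

keep <- !is.na(co$truth$swelling_onset)
log_integral_regression(co$truth$ca_integral[keep],
                        co$truth$ps_integral[keep])
#> <loglog_regression> n=4  slope=1  intercept=0.47  r=1  R2=1
```

Each row is one simulated necrotic neuron: the Ca²⁺ rise precedes
swelling, which precedes PS exposure; event times are minutes post-first
embryonic division, integrals are fold·minutes. The regression recovers
the generator's programmed coupling (slope 1, intercept log 1.6 ≈ 0.47)
exactly because this cohort is noise-free. Comparing a wild-type cohort's
Ca integrals against the necrotic cohort with `integral_ratio()` gives the
percent-of-reference summary used for genotype comparisons:

```r
integral_ratio(simulate_cohort(scenario_wildtype(seed = 2))$truth$ca_integral,
               co$truth$ca_integral)$ratio_pct
#> 71.9
```

`run_pipeline(pipeline_config())` chains
simulate → quantify → events/integrals → cohort statistics and writes CSV
tables plus a JSON manifest. `reproduce_paper(path)` recomputes the
published summary statistics from the quantitative supplementary workbook
(or a directory of per-sheet CSVs; see the vignette for the expected
layout) and reports each recomputed value against its printed reference.

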