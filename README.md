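# chemotaxkit

Quantification toolkit for leukocyte directed-migration experiments. It
implements, as tested reusable R functions, the standard readouts of a
chemotaxis study of T lymphocytes:

- **Track statistics** from time-lapse chemotaxis-chamber recordings:
  velocity along the total path (um/min), the **directional meandering
  index** (DMI) — the cosine of the angle between a track's net
  start-to-end displacement and the gradient axis, so `+1` is migration
  straight toward the chemoattractant and `-1` straight away — plus the
  standard exclusion filters (objects `< 16 um^3`, static objects, tracks
  `< 50 um`) and selection of ~60-min tracks from the middle of a
  recording.
- **Front–rear polarization** of segmented cells: the centroid-based
  polarization index `1 - |(X_signal/X_object) * (Y_signal/Y_object)|`,
  and aspect-ratio gating of imaging-flow populations (polarized `< 0.5`,
  unpolarized `> 0.8`, minor/major of the moment-equivalent ellipse).
- **Membrane-biosensor kinetics**: per-frame ratio of the mean intensity
  of the 50% of the cell perimeter facing the chemokine source over the
  mean intensity of the 50% of the cell area facing the source, and the
  series relative to stimulation onset (t = 0 ratio normalized to 1).
- **Binding and enzyme assays**: SPR background correction and
  steady-state affinity fitting of `Req = Rmax / (1 + KD / C)` by
  nonlinear least squares (log-parameterized), percent-of-maximal
  binding, vesicle-sedimentation fraction bound
  `pellet / (pellet + supernatant)`, and kinase activity as fold over the
  zero-protein baseline.
- **Group statistics**: mean ± s.e.m. summaries, exact/approximate
  Mann–Whitney rank-sum and Welch t comparisons, chemokine-induced
  transmigration (total − random), and normalization to a reference
  group's mean.
- **Seeded synthetic generators** for every assay (biased persistent
  random-walk tracks, elliptical cells with controlled membrane
  enrichment and signal-centroid offset, Langmuir isotherms,
  aspect-ratio populations), so the full pipeline runs and is testable
  with no experimental data.

## Worked example

Simulate a chemotaxing ("WT") and a bias-free ("DKO") group, filter,
compute per-track metrics, and compare DMI between groups:

```r
library(chemotaxkit)

cfg <- jsonlite::read_json(
  system.file("extdata", "demo-config.json", package = "chemotaxkit"),
  simplifyVector = TRUE, simplifyDataFrame = FALSE)
cfg$out_dir <- tempfile("demo")
report <- run_pipeline(cfg)

report$summaries
#>            metric group  n       mean          sem
#> 1             dmi   DKO 30 -0.2463382 1.193179e-01
#> 2 velocity_um_min   DKO 30 11.9914532 3.705756e-02
#> 3             dmi    WT 30  0.9999479 1.250394e-05
#> 4 velocity_um_min    WT 30 12.0257191 4.164356e-02

report$comparison[c("statistic", "p_value", "method")]
#> $statistic
#> [1] 900
#> $p_value
#> [1] 3.019859e-11
#> $method
#> [1] "rank_sum_normal"
```

The biased group migrates up the gradient (mean DMI near 1 — endpoint
DMI saturates over a 2-h walk; see the vignette), the unbiased group is
directionless, and both move at ~12 um/min; the rank-sum test separates
the groups decisively. `cfg$out_dir` now holds `tracks.csv`,
`metrics.csv`, `summary.csv` and a conservation-checked `report.json`.

Fitting a steady-state SPR isotherm:

```r
iso <- simulate_isotherm(isotherm_sim_params(kd = 3.16, rmax = 100))
fit_isotherm(iso)
#> <isotherm_fit> KD = 3.16 uM, Rmax = 100 RU, RSS = 9.45e-19 (converged, 14 iter)
```

A command-line front end is installed at
`system.file("cli", "chemotaxkit", package = "chemotaxkit")` with
subcommands `simulate-tracks`, `analyze-tracks`, `fit-spr`,
`kinase-fold`, and `report`; see `?chemotax_cli`.

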