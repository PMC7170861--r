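---
title: "Quantifying chemotaxis, polarization and lipid binding with chemotaxkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chemotaxis, polarization and lipid binding with chemotaxkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemotaxkit)
```

chemotaxkit quantifies the standard readouts of leukocyte
directed-migration experiments: chemotaxis-chamber track statistics,
front–rear polarization of imaged cells, membrane-biosensor kinetics,
and the lipid-binding and kinase assays that accompany them. This
vignette explains each model and metric, the tunable parameters and
their defaults, what the synthetic generators do and do not emulate,
and the numerical choices made where the procedures as usually
described leave the details open.

## Track metrics

A *track* is a time-ordered sequence of cell-centroid positions
(minutes, micrometres). Two per-track statistics carry the biology:

- **Velocity** is total path length over duration (um/min) — centroid
  movement *along the path*, not net displacement over time, so a
  fast-but-wandering cell has high velocity.
- The **directional meandering index (DMI)** is the cosine of the angle
  between the net start-to-end displacement and the gradient axis:
  `+1` means migration straight toward the chemoattractant reservoir,
  `-1` straight away, `0` perpendicular. It is computed from endpoints
  only, not per-step averages, and is invariant under joint rotation of
  track and axis and under translation (tested to 1e-9). A
  zero-displacement track has no migration angle; the DMI is returned
  as `NA` rather than 0 so degenerate tracks cannot dilute group means
  (the static filter normally removes them first). A sine-of-bearing
  variant is exposed (`method = "sine_bearing"`); under the documented
  bearing convention (angle measured from the gradient axis) it
  coincides with the cosine form.

### Exclusion filters

`filter_criteria()` encodes the conventional exclusions, applied in a
fixed order with the first applicable reason reported:

| rule | default | rationale |
|---|---|---|
| volume | `< 16` um^3 | segmentation debris is smaller than a lymphocyte |
| static | net displacement `< 2` um | sub-cell-diameter displacement over >= 1 h is immobility |
| short | path length `< 50` um | too little movement for directional statistics |

Where the usual description leaves a choice, the package fixes a
default and exposes it as a parameter: "static" is not defined
operationally anywhere standard, so it is net displacement below a
threshold (2 um); "track length" is read as total path length (the
tracking-software notion), with `length_measure = "net_displacement"`
one parameter away; the order of rules is configurable
(`rule_order`). Tracks without a volume attribute skip the volume rule
with a warning — the 3D volume comes from imaging software this package
does not replace. Filtering is idempotent: re-filtering the retained
set changes nothing (tested).

`select_analysis_window()` emulates selecting ~60-min tracks "from the
middle" of a ~2-h recording: a track is kept when its duration is
within `target_duration * (1 ± duration_tolerance)` (60 min ± 20%) and
its temporal midpoint lies in the central half of the recording span;
output is sorted by descending path length. The exact manual rule used
at the microscope is unrecoverable, so this operationalization was
chosen as the simplest one that honors both stated properties
(duration ~60 min, middle of the video) and is documented rather than
hidden.

## The synthetic track generator

No public tracking data accompany this kind of assay, so the package
ships a generator whose *statistical structure* matches what the
analysis assumes: frames every 45 s (dt = 0.75 min) for 120 min. The
walk model is deliberately the simplest one with independent
persistence and bias knobs — the direction of step *k* is

```
d_k = normalize( persistence * d_(k-1) + bias * g + (1 - persistence - bias) * u_k )
```

with `g` the unit gradient direction and `u_k` a uniformly random unit
vector; the step length is `dt` times a truncated-normal (>= 0) speed
draw. `persistence + bias <= 1` is enforced. Chemokine exposure
multiplies the speed scale by `chemokinesis_factor` (default 12/6.9)
without touching direction, separating chemokinesis from chemotaxis.
Default speeds (6.9 um/min basal, ~12 um/min with chemokine) echo the
magnitudes reported for chemokine-treated T cells; they are stand-ins,
not calibrated fits — no per-cell speed or turning-angle distributions
are available to fit.

All randomness flows from one explicit seed per call (no global RNG
state); per track the generator draws `n_steps + 1` uniform angles,
then the speeds, a documented order that an independent
re-implementation reproduces to 1e-12 in the test suite.

**What a green test establishes — and what it does not.** The
generator validates the *analysis*: DMI is mean-zero for unbiased
walks, monotone in bias (tested on the grid `{0, 0.2, ..., 1}` with
persistence 0, since `persistence + bias <= 1`), exactly 1 for fully
biased noise-free walks, and velocity recovers the generating speed.
It does not reproduce per-cell experimental values: endpoint DMI of a
drift walk saturates toward 1 as duration grows (random components
average out over ~160 steps), so simulated group means sit closer to 1
than the 0.7–0.8 typical of real chemotaxing lymphocytes, whose
heterogeneity the model does not attempt to capture. Pseudopod
morphology, membrane dynamics and excitable-network models are
explicitly out of scope.

## Polarization imaging

Images are binary masks plus aligned intensity channels; pixel
coordinates are 1-based row/column indices (origin at the top-left
pixel, x rightward, y downward) — the examples below behave
identically under any integer-origin convention, but the choice is
fixed and documented because one metric depends on it.

The **polarization index** compares the intensity-weighted signal
centroid to the geometric object centroid *in absolute coordinates*:
`1 - |(X_signal/X_object) * (Y_signal/Y_object)|`. It is implemented
verbatim: 0 when the centroids coincide, unclamped (negative values
are reported as-is). Because the formula divides by the object's
coordinates it is origin-dependent — the same cell crops to a
different index in a different frame position. The package therefore
(a) refuses zero coordinates with an error explaining the
origin-dependence, and (b) exposes `centroid_displacement()` — the
Euclidean distance between the two centroids in micrometres — as a
clearly-labelled translation-invariant companion that is *not* the
ratio formula. Fidelity first, a sane alternative second.

**Aspect ratio** is minor/major of the mask's second-central-moment
equivalent ellipse, in (0, 1] (higher = rounder), matching the
orientation of imaging-flow-cytometry scores; invariant under 90°
rotation and uniform scaling within a 0.02 discretization tolerance.
Cells gate as polarized below 0.5 and unpolarized above 0.8; the
interval [0.5, 0.8] is kept as an explicit *intermediate* class rather
than silently dropped, so the three percentages always sum to 100.
Image-based focus gating is replaced by an `in_focus` flag carried on
records; percentages are computed over in-focus records only.

The image generator draws a filled ellipse and constructs the channel
so both quantitative knobs are *exact* before noise: perimeter-band
(8-connected boundary) mean over interior mean equals
`membrane_enrichment`, and a linear intensity tilt solved from the
weighted second-moment matrix places the signal centroid exactly
`signal_offset` pixels from the object centroid. The feasible offset
is limited to roughly a quarter of the semi-axis (intensities must
stay positive); larger requests error rather than clip. Images are
single-plane 2D; confocal stacks are not emulated because every
quantified metric is 2D.

## Biosensor front ratio

For a cell stimulated by a chemokine point source, each frame's
readout is the intensity of the 50% of the cell *perimeter* facing the
source divided by the intensity of the 50% of the cell *area* facing
the source. Numerical choices, since the usual phrasing pins none of
them down:

- "Facing the source" is a projection rank, not a half-plane cut:
  every mask pixel is scored by `(p - centroid) · source_direction`,
  and the front set is exactly the top `ceiling(n/2)` pixels (ties
  broken by ascending pixel index, so the partition is deterministic).
  This keeps "50%" exact for asymmetric shapes.
- "Intensity" is the *mean* over each pixel set (dimensionless,
  size-independent ratio); a sum-based mode sits behind
  `mode = "sum"`.
- The perimeter is the 1-pixel 8-connected boundary band.

The ratio is 1 for any uniform-intensity cell regardless of shape or
direction (tested over 50 random rotated ellipses, exactly), invariant
to uniform intensity scaling, and stable under joint 90° rotation of
image and source within a 0.05 discretization tolerance. A series is
normalized to its t = 0 frame (`relative[0] = 1`), and
`group_mean_series()` gives per-timepoint mean ± s.e.m. across cells
on a shared time grid. No motion correction is attempted between
frames — the intended use case has actin polymerization arrested, and
masks are per-frame inputs anyway.

## Steady-state affinity fitting

Equilibrium SPR responses follow the 1:1 Langmuir isotherm
`Req = Rmax / (1 + KD / C)`. After element-wise background subtraction
of carrier-lipid responses, `fit_isotherm()` minimizes the residual
sum of squares over `(KD, Rmax)` parameterized on the log scale, so
positivity is structural rather than constrained. Defaults: start at
`KD = median(C)`, `Rmax = max(Req)`; stop at relative parameter change
below 1e-10 or 500 iterations; unweighted residuals (weights are a
parameter — whether published fits weighted them is typically
unstated). Noise-free recovery is exact to ~1e-6 relative across a KD
grid spanning 0.1–50 uM, fitted KD scales correctly under joint
rescaling of concentrations, and under 2% Gaussian noise the median of
200 seeded fits stays within 5% of truth (all tested). Association /
dissociation kinetics are deliberately not modelled: only steady-state
analysis is in scope. Percent-of-maximal binding divides by an
observed saturation response when one exists, else by the fitted
`Rmax` — both modes are supported because "measured at saturation"
presupposes an observed plateau that sparse titrations may lack.

Sedimentation assays reduce to `pellet / (pellet + supernatant)` from
band intensities (densitometry itself is out of scope), and kinase
dose–response tables are normalized so the zero-protein row is exactly
1.

## Group statistics

Summaries are mean ± s.e.m. (sample s.d., n − 1 denominator).
Two-group comparisons are two-sided: Mann–Whitney rank-sum — exact
when both groups have n ≤ 20 (exact null distribution without ties; a
midrank enumeration when ties make that distribution inapplicable and
the enumeration is small; full enumeration at the top of the n ≤ 20
range with ties is combinatorially infeasible, so the tie-corrected
normal approximation takes over there) — or Welch's t test. The test
suite checks the rank-sum p-value against an independent full
enumeration for n ≤ 8. Chemokine-induced transmigration is total
minus random migration, reported as-is (negative differences are
information, not errors), and per-experiment normalization divides by
the reference group's mean so that group's normalized mean is exactly
1.

## Pipeline and formats

`run_pipeline()` chains simulate/read → filter → metrics → summaries →
comparison, writes plain-text artifacts, and returns a report in which
record counts are conserved at every stage (input = retained +
rejected; violation is an error, not a warning). Configurations reject
unknown keys, and every stochastic stage requires an explicit seed —
identical config gives byte-identical outputs (tested). Numeric CSV
output is written at full precision so oracle comparisons are exact.
All writes are atomic (temp file + rename), so interrupted runs never
leave truncated tables.

Tracks and isotherms travel as documented CSV dialects. Images are
serialized as plain-text pages (headerless CSV matrices) plus a JSON
sidecar rather than multi-page TIFF: no TIFF library is available in
the supported dependency set, and the plain-text form keeps fixtures
diffable; the mask + channels + metadata contract and round-trip
guarantees are unchanged.

## Known limitations

- The walk model is a stationary drift-diffusion caricature: no
  heterogeneity between cells, no speed–turning coupling, no response
  kinetics; its endpoint DMI saturates with duration (see above).
- The polarization-index formula's origin-dependence is inherited by
  design; cross-study comparability requires a shared crop convention.
- Aspect-ratio gating assumes the moment-ellipse convention; an
  intensity-weighted variant of commercial software would differ in
  the third decimal for compact cells but is not reproduced.
- Exact rank-sum p-values with heavy ties near n = 20 per group fall
  back to the normal approximation (documented above).
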