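---
title: "Multiview ground-cover traits: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiview ground-cover traits: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-field simulator does and does not emulate, and the choices made
where the design was genuinely open.

## 1. The multiview ground-cover image

A drone flying a dense grid photographs every field plot from 30–50
viewpoints with zenith angles mostly between 0° and 20°. Each view is
segmented into plant and soil pixels, cut to the plot polygon, and
resampled into a common plot coordinate frame at threefold resolution
(`resample_to_plot()`); the per-pixel mean over views
(`aggregate_views()`) is the multiview image, with values in [0, 1].
Pixels that are plant in every view (dense canopy, prostrate leaves near
the soil) stay at 1; pixels covered only under some viewing angles —
erect leaves whose footprint shifts with the view through parallax — take
intermediate values. That fractional signature is the raw material for
all three traits.

Assumptions inherited by everything downstream:

- camera poses and intrinsics are known (structure-from-motion is treated
  as an upstream supplier; the package back-projects with a plain pinhole
  model on distortion-corrected inputs);
- views are only aggregated when the buffered plot is fully visible
  (`denominator = "n_views"`), because the mean divides by a single view
  count and partially visible plots would bias it low — a per-pixel
  denominator mode exists for unusual flight plans;
- coregistration between views is good to ~1–2 px; the affine fit in
  `backproject_polygon()` warns above a 2 px corner residual.

**Buffering.** Plot polygons are shrunk by
`B = tan(AOV/2)·h_canopy + E_ref` before sampling so that neither
georeferencing error nor leaning neighbours contaminate a plot
(`min_buffer()`). At the operational 0.25 m buffer, 40° angle of view and
0.1 m georeferencing precision this supports canopies to ~0.41 m
(`max_canopy_height()`) — ample for seedling wheat.

**Resampling.** Nearest-neighbour interpolation is used for the binary
masks; the threefold oversampling exists precisely to absorb the
round-off that nearest-neighbour sampling would otherwise cost, and any
smoother interpolation would manufacture fractional values that the
aggregation step is supposed to create from viewing geometry, not from
resampling.

## 2. Pixel segmentation

Wheat leaves at a 3 mm ground sampling distance are narrower than a
pixel; most plant pixels are mixtures, and a camera's Bayer mosaic means
only half the pixel positions carry measured green values. The classifier
therefore works only at the green Bayer positions of a (virtual) mosaic,
with red and blue replaced by the mean of the two adjacent same-channel
pixels (`extract_color_features()`). Seventeen predictors are used: raw
R, G, B on the 12-bit scale, XYZ, linearised sRGB, HSV and CIE La\*b\*
(D65 white point — standard colorimetry defaults, chosen here because no
other white point is implied by the data), and the chromatic-coordinate
indices ExG = 2g − r − b and ExR = 1.4r − g. The exact index formulas
vary across the remote-sensing literature; the sum-normalised forms used
here are the common ones and are documented so the feature schema is
reproducible.

The ensemble is a 55-tree random forest with minimum split size 4,
minimum leaf size 6, 6 candidate features per split, and maximum depth
95, backed by `ranger` (its `min.node.size` expresses the leaf size; the
split size is recorded with the model but the backend has no separate
knob for it). Class decision is majority vote. Predictions exist only at
green positions; the red/blue gaps are filled from the 3×3 neighbourhood
and one binary 3×3 opening removes isolated detections
(`segment_image()`). Opening is idempotent, so repeated application is
harmless.

## 3. Trait extraction

### GS30

Around the beginning of stem elongation, pseudostems erect; erect plant
parts produce wider fractional halos, so the *distribution* of multiview
values changes even when total cover changes smoothly. The ten
ground-cover percentiles `mvGC_10 … mvGC_100` (strict thresholds; the
100% threshold is degenerate-but-faithful at exactly 0) feed an RBF
support-vector regression against the thermal-time offset ΔGDD_GS30,
with cost 32 and gamma 0.125 and training pairs filtered to ±20 GDD
around the reference GS30 — the window where the structural signal lives.
Features and response are standardised internally; the constant
`mvgc_100` column would otherwise disable the backend's own scaling
wholesale and degenerate the kernel.

Per plot, a line `ΔĜDD = a·GDD + b` through the index estimates of
campaigns near the transition dates GS30 at `−b/a`
(`gs30_timepoint()`). One numerical subtlety is handled explicitly: far
from its training support an RBF regressor saturates back towards the
training mean, which is ≈ 0 on this centred index — so campaigns long
before or after the transition can *look* like they sit at GS30 and
flatten the fitted line. The ±20 window is therefore applied as a
contiguous run anchored at the steepest adjacent-campaign index increase,
on both the index axis and the thermal-time axis (the index responds to
GDD with slope ≈ 1, so the same window is meaningful on both). Campaigns
with spatial repeatability below 0.5 are discarded before the fit; plots
with fewer than two usable campaigns, or a nonpositive slope, are flagged
rather than extrapolated.

### Plant count

Before canopy closure each plant (or clump) is a local intensity maximum
of the multiview image. Peaks above `i_peak` (default 0.30) separated by
at least `d_min` (default 25 mm / effective GSD) seed a watershed
partition of the cover above `i_thresh` (default 0.10), implemented as
seeded region growing restricted to the superlevel set. The
thresholds are configuration, not constants, because no canonical values
exist for them; the defaults were chosen once as the obvious
operating point (a tenth of full cover separates plants from noise, 25 mm
is a plausible minimal plant spacing within a sowing row) and are not
tuned per data set. Plateau maxima collapse to their centroid and ties
break by scan order, so peak detection is deterministic.

Region areas predict plants through `N̂ = Σ_j (a_W·A_j + b_W)` after
calibration against truth counts (manual positions in high-resolution
imagery, or simulator truth). The intercept is summed per region as the
relation is written; because that reading is ambiguous, the
apply-it-once alternative is attached to every prediction as a
diagnostic attribute. Calibration supports stratification (e.g. 5/10/15
days before GS30) via a grouping column. The per-plot trait is the
median of three spatially corrected time-point estimates — robust to one
corrupted campaign.

### Shoot count

The apparent leaf area `LA = Σ mvImg²` squares the fractions before
summing so that the off-nadir-heavy zenith distribution of gridded drone
flights does not inflate the blur halo into fake leaf area; the exponent
is exposed in `apparent_leaf_area()` (default 2) for other viewing
geometries. LA saturates with shoot count as cover closes, which the
package models as a logistic in `log1p(N_S)` with the asymptote fixed at
the LA of 90% cover (cover above 50% is rare before GS30, so genotype
differences in the asymptote are negligible) and midpoint/scale linear
in ΔGDD_GS30. The logistic admits several algebraically similar
parameterisations; the standard `xmid`/`scal` one,
`LA = Asym / (1 + exp((xmid − log1p(N_S))/scal))`, is used — it is the
one those names come from. Groups use a ±12.5 GDD aggregation window;
the group regressions run on each group's *observed mean* ΔGDD rather
than the nominal bin centre, because partially filled edge bins would
otherwise bias the slopes. Closed-form inversion turns LA into shoots;
an inverse-exponential `N_S,t = N_S − exp(−a·ΔGDD)` fitted on
−200 ≤ ΔGDD < 0 (the range the relation was developed for) yields the
final shoot count and tillering rate, with a median fallback when fewer
than three time points survive the filter.

Nonlinear fits use Levenberg–Marquardt least squares with five
deterministic starts on an even lattice over data-driven ranges and a
1e−8 relative tolerance; the early-time negative values the dynamics
model can produce are clamped at zero for reporting only, never during
fitting.

## 4. Spatial correction and quantitative genetics

Time-point traits are corrected per campaign with
`value ~ smooth2D(x, y) + random(row) + random(range) +
random(genotype)`, the smooth being a tensor-product penalized B-spline
surface with second-order difference penalties and knots per direction
equal to ⌈2/3 × plots-in-direction⌉. Smoothness is selected by REML via
`mgcv` — the same criterion a grid search would optimise, handled by a
better optimiser. This surface is a deliberate approximation of the
PSANOVA decomposition used by dedicated field-trial software: identical
in effect (smooth spatial denoising) and much simpler; rows/ranges are
not nested in replication, as the model is written. Corrected values are
intercept + genotype effect + residual, so genotype signal and residual
noise survive while surface and row/range trends are stripped.

Repeatability and heritability use the generalized (Cullis) form
`H² = 1 − v̄_ΔBLUP / (2σ̂²_g)`, valid for unbalanced mixed models. From
the spline fit the full posterior covariance of the genotype
coefficients is available and the mean pairwise variance of BLUP
differences is computed exactly; from `lme4` fits only the conditional
variance diagonals are exposed, so covariances between BLUPs are ignored
there — standard practice, and exact for balanced designs. Two
behaviours of this estimator are worth knowing: it is mildly
conservative relative to the balanced closed form
`σ²_g/(σ²_g + σ²_e/r)` at small trial sizes, and under a true zero
genotype variance its REML estimate is half-normal rather than zero, so
single-trial "null" heritabilities of 0.1–0.3 occur at 36 genotypes × 2
replications; the tests therefore check averages over simulations.
Heritabilities are clamped to [0, 1] and variance components bounded at
zero.

Multi-environment heritability fits year and replication-within-year as
fixed and genotype as random (`Yr/R | G`, collapsing to `Yr | G` with a
single replication); only genotypes present in every year-site enter,
and replications can be subsampled (first-k, deterministic) to compare
against manual protocols. Genotype-by-year interaction is deliberately
not modelled; with two or three years
it would be barely identifiable and would change the comparison, not
improve it. Relative efficiency of indirect selection is
`RE = √H²_HTFP · r_G / √H²_manual`, with an explicit infinite-RE flag
when the manual heritability is zero — a situation that actually occurs
for manual plant counts on one-meter rows.

## 5. The synthetic-field simulator

The simulator exists so every stage can be tested against exact ground
truth. It emulates:

- **genotype development** — main-stem leaves appear at
  `(GDD − t₀)/P`; tiller *n* exists while `a·N_leaves − b·n > 0` and
  carries that many leaves; plot leaf area is the single-leaf area times
  the leaf count. Leaf appearance divides thermal time by the
  phyllochron — the only form dimensionally consistent with a
  phyllochron measured in GDD per
  leaf. The tiller constants a = 1.0, b = 2.5 have no published values
  for this material; they were set once so the first tiller appears
  after ~3 main-stem leaves (standard wheat ontogeny) and are
  configurable;
- **parameter spreads** of elite material — phyllochron centred on
  70–80 GDD (bounds 54–98), emergence 75–140 GDD, single-leaf area
  300–380 mm² (bounds 200–500), GS30 spread configurable between a
  <10-day fast spring and a ~20-day contrasting-site spread;
- **field structure** — randomized complete blocks, plants
  Poisson-placed along 0.125 m rows with a clumping parameter, plot-level
  GS30 noise (4 GDD) and an optional planar field trend;
- **viewing geometry** — per-view zenith angles 0–20° peaking near 10°,
  each plant a flat-top disk whose footprint shifts by
  `tan(zenith)·erect_height` along the view azimuth, so averaging views
  yields exactly the fractional annulus the method exploits; in the
  pipeline the erect height ramps logistically (±15 GDD scale) through
  GS30, encoding pseudostem erection. A projection factor (0.4 in the
  pipeline, 1 in the bookkeeping contract of `render_views()`) keeps
  simulated cover below canopy closure before GS30, as in real seedling
  stands;
- **campaign cadence** — flights every 25 GDD (~2–3 per week at spring
  temperatures).

It deliberately does **not** emulate: real leaf shapes or 3-D canopies
(no radiative transfer), shadows or radiometric variation beyond a
two-class colour model, tiller abortion after GS30, soil-moisture or
freezing effects, weather-station gaps, or structure-from-motion errors
beyond a fixed coregistration assumption. Passing tests therefore show
the *algorithms* are correct and well-calibrated under the stated
geometry and noise — not that the segmentation or SVR would meet the
same numbers on arbitrary field imagery.

A fast path (`sim_percentile_trajectories()`) generates the percentile
vectors directly from a smooth cover/shape model with a GDD-equivalent
noise knob (`noise_gdd`). This is how GS30 recovery is tested at scale:
at the default 10 GDD injected noise, a 72-plot, 20-day-spread trial is
recovered with RMSE ≈ 8 GDD (below the injected noise, because the zero
crossing averages over campaigns), falling to ≈ 2 GDD as the noise is
removed — the residual floor being campaign spacing and transition
sharpness, not the estimator.

## 6. Problem sizes, determinism, degenerate inputs

Test and fixture sizes were chosen as the smallest trials at which each
property is statistically meaningful: 200×200 px images for the exact
multiview-algebra oracles, 50 plots for watershed counting, 72 plots
(36 genotypes × 2 reps) for GS30 recovery and the quantitative-genetic
closed forms, 100 plots for shoot-dynamics noise recovery, and a
4-genotype × 2-rep, 6-campaign fixture (9 mm GSD) for the end-to-end
determinism contract. The fixture's GS30 accuracy is intentionally
unimpressive: with eight plots and a ~60 GDD spread the SVR partly
conflates between-plot cover level with thermal time, the same regime a
short-transition year shows on real trials; the fixture's job is
bit-identical reruns, and GS30 accuracy is certified on the 72-plot
trial instead.

All randomness flows from one seed per entry point (trials derive
per-module substreams by fixed offsets; nonlinear fits use deterministic
multi-starts; peak ties break by scan order), so `run_pipeline()` reruns
are bit-identical and the test suite asserts that. Degenerate inputs
have defined behaviour throughout: days with missing hours are rejected
by name (the daily divisor is fixed at 24), sub-freezing days clamp to
zero GDD, empty peak sets mean zero plants, leaf areas at or above the
logistic asymptote clamp to 0.999·Asym with a warning, single-class
training sets and zero-variance calibrations error, and unresolvable
GS30 plots carry a status instead of a number.

## 7. Known limitations

- The GeoTIFF/GeoJSON interfaces carry geometry but not coordinate
  reference systems; coordinates are assumed metric planar before any
  statistics, and rasters are plain matrices.
- The spatial surface approximates, not reproduces, PSANOVA; variance
  partitions differ in detail even when corrected values agree closely.
- The SVR index, like any flexible regressor trained on one nursery,
  absorbs site characteristics; blocked cross-validation
  (`cv_gs30()` by genotype or year-site) is provided precisely because
  random-split errors flatter it.
- Watershed counting degrades with clumping (multiple plants per
  region is handled in calibration, but a single region spanning many
  plants stretches the linear model) and with cover past closure, where
  peaks merge.
- The simulator's two-class colour model makes pixel classification
  easier than field imagery with shadows, residue and specular soil;
  the F1 ≥ 0.95 segmentation bound is a property of the synthetic
  scenes.
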