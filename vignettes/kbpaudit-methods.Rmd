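---
title: "Methods: knowledge-based plan auditing with kbpaudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knowledge-based plan auditing with kbpaudit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbpaudit)
```

## Scope and assumptions

`kbpaudit` audits prostate VMAT treatment plans in three layers: a voxel
dose–volume metric engine, a plan-quality layer (coverage rule, Paddick
conformity index, homogeneity index, OAR constraint template), and a
knowledge-based planning (KBP) layer that predicts achievable OAR dose
metrics from patient geometry and flags plans falling outside a 95%
prediction band. The package assumes:

* one dose grid per (summed) plan, in Gy, on an axis-aligned voxel grid
  in physical cm coordinates;
* binary structure masks on the *same* grid — any resampling (trilinear
  for dose, nearest-neighbour for masks) belongs to ingest, never to the
  metric engine;
* the two-series prostate protocol when constraints are evaluated: 46 Gy
  in 23 fractions to the pelvic target (PTV46: prostate, seminal
  vesicles, nodes) plus a 30 Gy boost to the prostate (PTV76), with the
  OAR constraints applied to the voxelwise *sum* of the series.

## Dose–volume conventions

The engine computes VxGy (volume receiving at least x Gy, in cc or in %
of the structure), Dq% (minimum dose to the hottest q% of the structure),
Davg and Dmax. Three conventions fix the discrete definitions; all
oracles, tests and documentation follow them:

* **Inclusive threshold.** A voxel counts toward VxGy when its dose is
  `>= x`, matching the cumulative "receiving at least" semantics.
* **Rank quantile.** Dq% sorts the structure's voxel doses descending and
  returns the dose at rank `ceiling(q/100 × N)`. No interpolation is
  applied; the value is always a dose actually present in the structure,
  `D100%` is the structure minimum, and the function is non-increasing in
  q. Interpolating conventions differ by at most one voxel's dose step.
* **Binary masks.** No partial-voxel (fractional occupancy) weighting:
  each voxel is in or out. Treatment planning systems typically weight
  boundary voxels, so metrics of very small structures can differ from
  TPS values by a boundary layer; at the default 2 mm grid this is a
  sub-percent effect for organs of tens of cc and above.

`Dmax` is the single hottest voxel, not a near-maximum volume variant
(e.g. D0.03cc); the choice is visible wherever a template limit targets
`Dmax`.

The cumulative DVH (`cumulative_dvh`) uses 0.05 Gy bins by default —
finer than any clinically reported precision (0.1 Gy / 0.1 cc) — but every
reported metric is computed directly from the voxels, never read back off
a binned histogram.

## Plan-quality indices

Coverage follows the 95%/107% acceptance rule: D95% of the target must
reach 95% of the prescription and Dmax must stay below 107%. The Paddick
conformity index is

$$\mathrm{PCI} = \frac{TV_{PIV}^2}{TV \cdot PIV},$$

with `TV` the target volume, `PIV` the volume of the whole grid at or
above a reference isodose, and `TV_PIV` their intersection. The reference
isodose defaults to **95% of the prescription**, tying conformity to the
same level as the coverage rule; clinics that define conformity at the
100% isodose can pass `reference_isodose = prescription`. The choice
matters: the two definitions differ whenever the dose gradient at the
target edge is shallow. If no voxel reaches the isodose the index is
defined as 0 with a warning. The homogeneity index is
`HI = (D2% − D98%)/D50%`, zero for a perfectly uniform target dose and
invariant under uniform dose rescaling.

The default constraint template carries the clinical planning limits for
the summed plan (peritoneal cavity Dmax < 54 Gy, V45Gy < 150 cc,
V15Gy < 830 cc; rectum V40/V60/V70/V75Gy < 40/50/25/5 %; bladder
V60/V70Gy < 50/25 %; anal canal V55Gy < 100 %; femoral heads
V52Gy < 10 %). It is an ordinary data frame, editable in code or as a
YAML file, and missing structures are reported as `not_evaluated` rather
than failing the audit.

## The KBP layer

The model registry pairs seven OAR metrics with one geometric predictor
each: rectum and bladder V60Gy(%) and V70Gy(%) against their overlap
fraction with PTV76; cavity Davg against the cavity→PTV46 centroid
distance; cavity V45Gy(cc) against the cavity/PTV46 overlap fraction; and
cavity V15Gy(cc) against the product of overlap volume and cavity volume.
Design choices where the convention was genuinely open:

* **Distances are 3D.** Centroid distances are full 3D Euclidean
  distances between unweighted centers of mass of the binary masks;
  in-plane-only distances would differ for cranio-caudally offset
  structures.
* **Units of the product predictor.** `V_OV × V_Cav` is taken as absolute
  overlap volume (cc) times absolute cavity volume (cc), unit cc². The
  alternative reading (fraction × volume) is a rescaling by `1/V_Cav`;
  since the model is refit per clinic the fit quality is unaffected, but
  serialized coefficients are only comparable under a fixed convention,
  so the choice is recorded in the model files.
* **Prediction, not confidence, intervals.** The 95% band reported for a
  new plan is the t-based prediction interval for a *single new
  observation*, `ŷ ± t·s·√(1 + 1/n + (x−x̄)²/Sxx)`. A mean-response
  confidence interval would shrink to zero with the training-cohort size
  and flag nearly every plan; the clinical question — "is this one plan's
  achieved dose compatible with what the model predicts?" — is a
  prediction-interval question.
* **Flag direction.** Only `achieved > upper bound` raises the
  suboptimality alert; an achieved value below the lower bound means
  better-than-predicted sparing and is reported as informational
  (`below_lower`). No multiple-testing adjustment is applied across the
  seven models: the flags are advisory screening, not hypothesis tests.
* **Fitting.** Plain ordinary least squares (no robust weighting, no
  intercept suppression), requiring n ≥ 3 and a non-constant predictor.
  Models store `A`, `B`, `n`, `R²`, the residual standard deviation
  `s = √(SSE/(n−2))`, `x̄` and `Sxx` — sufficient statistics for the
  interval — so a serialized model file reloads without refitting and
  reproduces predictions exactly.

## Cohort comparison

`compare_cohorts` reports, per metric, Mean and sample SD (n−1
denominator) of each arm, the mean difference Δ on *unrounded* means, and
a two-sided Mann–Whitney p-value with significance at p < 0.05. Printing
rounds to one decimal; because Δ is computed before rounding, a printed
table can show a Δ that differs by one least digit from the difference of
the printed means — real published tables exhibit exactly this, so the
shipped clinic summary (`clinic_cohort_summary()`) carries a
`delta_consistent` flag.

The Mann–Whitney statistic uses midranks for ties. For
`max(n_a, n_b) ≤ 8` the two-sided p comes from exhaustive enumeration of
all `choose(n_a + n_b, n_a)` labelings of the observed ranks (exact and
deterministic, valid under ties); larger samples use the normal
approximation with tie correction and a 0.5 continuity correction. The
switch point keeps enumeration below ~13 000 labelings. On continuous
data with both samples of at least 6, the two routes agree within 0.02 —
a property the test suite measures rather than assumes. Base R's
`wilcox.test` cannot compute exact p-values under ties, which is why the
test is implemented here; `wilcox.test` serves as an independent oracle
in the tests wherever the conventions coincide.

`exceedance_rate` returns the unrounded percentage of plans failing one
template entry; formatting helpers round for display.

## The synthetic phantom and cohort generator

The phantom emulates the geometry the predictors consume: two nested
ellipsoidal targets (PTV76 clipped into PTV46), a posterior rectal tube,
an anterior–superior bladder sphere, and a large superior peritoneal
cavity from which the CTVs (targets shrunk by a 0.5 cm margin), bladder
and rectum are carved out — so the cavity can overlap the PTV margin
shell but never the CTV core, mirroring how the cavity is delineated
clinically. The default grid is 64×64×64 voxels at 0.2 cm isotropic
spacing: desk-scale (every metric in well under a second) with below-2%
discretization error on analytic ellipsoid volumes. At 12.8 cm of axis
extent the default structure volumes are necessarily smaller than real
pelvic anatomy (PTV46 ≈ 85 cc rather than ≈ 1000 cc); what the phantom
controls faithfully are the predictor ranges — overlap fractions from 0
to the geometric maximum, centroid distances up to the grid diagonal —
and those, not absolute volumes, drive the models. Requested overlap
fractions are realised by bisecting the OAR position along the line to
the target centroid; on a discrete grid the achieved fraction moves in
voxel-sized lumps, so the generator reports the closest achievable
geometry and callers read the achieved value back with
`overlap_fraction()` (0% and 100% are achieved exactly).

The dose model gives each treatment series its dose as a plateau inside
its target and an exponential falloff `exp(−d/L)` outside, with `d` the
exact 3D Euclidean distance to the nearest target voxel and `L` defaulting
to 1 cm — the scale of a VMAT penumbra-plus-scatter falloff — plus
optional Gaussian noise (default SD 0.2 Gy) clipped at 0 Gy. The distance
transform combines per-slice 2D Euclidean distance maps over the z offset,
which is exact and needs only equal in-plane spacing. This field is
deliberately simple: it has no arc geometry, no low-dose bath asymmetry,
no build-up — so passing metric tests on it validates the *engine
arithmetic*, not dosimetric realism.

Training cohorts for the model layer are generated at the feature level:
per model, predictors drawn uniformly over plausible clinical ranges and
responses on a true line plus Gaussian scatter, with the ground truth
returned for recovery tests. A full optimizer cannot be (and should not
be) recreated here; feature-level cohorts exercise exactly the statistical
structure the model layer assumes — linearity plus homoscedastic scatter.
The default truth table (slopes, intercepts, noise SDs, predictor ranges)
is chosen once so that simulated responses land in the ranges a prostate
VMAT cohort exhibits (rectum/bladder V60Gy of a few tens of %, cavity
mean doses of 10–25 Gy, cavity V15Gy of a few hundred cc). Consequences
of the design: generated responses are *not* clipped at physical bounds
(clipping would break the linearity that recovery tests verify), and
passing tests demonstrate correct estimation and calibration under the
model's own assumptions — not that any clinic's dose–geometry relation is
truly linear.

## Validation strategy and problem sizes

The test suite validates each layer against an independent route: metric
engine versus exhaustive voxel-loop oracles on 50 randomized 64³
phantoms; OLS and intervals versus `predict.lm` and a grid-search SSE
minimizer; interval calibration by 2000-replicate simulation (empirical
95% coverage required in [93%, 97%]); Mann–Whitney asymptotics versus
full enumeration over ~200 random datasets with samples of 6–8; and the
end-to-end simulate → fit → audit chain over 2000 seeds, where plans
drawn from the fitted model's own population must fall outside the 95%
band at about the nominal 5% rate (accepted in [2.5%, 7.5%]; the
suboptimal direction alone accounts for half of it). These sizes keep the
whole suite around a minute while making the binomial acceptance bands
comfortably wider than Monte-Carlo noise.

## Known limitations

* Binary masks and nearest-slice contour rasterization make boundary
  voxels all-or-nothing; very small structures (penile bulb-sized) carry
  the largest relative discretization error.
* The DICOM-RT reader is deliberately minimal: explicit-VR little-endian,
  identity orientation, uniform slice spacing, uncompressed integer dose
  grids. Anything else is rejected with an explicit error rather than
  silently reinterpreted.
* Fitted coefficients are clinic-specific; models trained on one
  center's plans transfer only as far as its planning practice does.
  Refitting on local cohorts is the intended use.
* The model layer is univariate and linear by design; nonlinear or
  multivariate KBP variants are out of scope.
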