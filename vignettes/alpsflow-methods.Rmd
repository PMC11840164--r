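---
title: "Models and methods behind alpsflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind alpsflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpsflow)
```

## The scientific problem

The glymphatic system clears interstitial solutes (amyloid-beta, tau,
alpha-synuclein) from brain parenchyma along perivascular spaces. Diffusion
tensor image analysis along the perivascular space (DTI-ALPS) is a
non-invasive surrogate of that transport. At the level of the lateral
ventricle body, deep medullary veins — and the perivascular spaces around
them — run left-right (x), projection fibers run inferior-superior (z) and
association fibers anterior-posterior (y). In a projection-fiber voxel both
Dxx and Dyy are perpendicular to the tract; in an association-fiber voxel
Dxx and Dzz are. Any *extra* x-diffusivity common to both fiber systems is
therefore attributable to the perivascular channel, and the index

$$\mathrm{ALPS} \;=\; \frac{\mathrm{mean}(D_{xx}^{proj},\,
D_{xx}^{assoc})}{\mathrm{mean}(D_{yy}^{proj},\, D_{zz}^{assoc})}$$

equals 1 when x is just another perpendicular direction and rises above 1
with perivascular water movement. In Parkinson's disease the index is
reported lower than in controls, and its relationship to cognition appears
to be mediated by regional cortical grey-matter volume. `alpsflow`
implements the full analytical chain — signal model, tensor fit, ROI
extraction, index, group statistics, partial correlations, ROC, and
bootstrap mediation — and, because no imaging data ship with it, a
synthetic-data layer with exact ground truth for every stage.

## Diffusion signal model and tensor estimation

Signals follow the monoexponential tensor model
$S = S_0 \exp(-b\, g^\top D g)$ with $D$ symmetric, in mm²/s, and unit
gradient directions $g$. Estimation is ordinary least squares on
log-signals over the six unique tensor elements plus $\log S_0$ —
deterministic, exactly invertible on noise-free input (tested to 1e-10
relative error) and adequate at the signal-to-noise ratios simulated here.
Weighted least squares would reduce the log-transform bias at low SNR but
introduces an iteration/weighting choice; it is deliberately not the
default.

Practical details that matter:

* Non-positive signals cannot be log-transformed; those measurements are
  dropped with a warning. A voxel needs at least 7 usable measurements,
  including a b = 0 reference, whose directions span the 6-dimensional
  space of quadratic forms; otherwise it is flagged as failed and excluded
  from the mask.
* Negative fitted diagonal elements are retained, not clamped — clamping
  would bias ROI means asymmetrically — but the voxel is excluded from the
  mask, so downstream ROI means use only well-behaved fits. Counts of
  dropped and flagged voxels are always reported.
* Direction sets use a deterministic spherical Fibonacci lattice. The
  6-point lattice happens to be rank-deficient for the tensor design, so
  generated schemes require at least 7 directions; the classic 6-direction
  DTI set (which does span the space) is exercised in the tests.
* Coordinate convention, fixed and documented: x = left-right
  (perivascular axis), y = anterior-posterior (association fibers),
  z = inferior-superior (projection fibers). Phantoms are generated in this
  canonical frame; NIfTI output carries an identity-scaled affine with the
  voxel size and no reorientation logic.

## The ALPS computation

ROI-mean diffusivities are arithmetic means of Dxx, Dyy, Dzz over ROI
voxels passing the fit mask; the voxel count used is part of the result.
The index is computed separately per hemisphere and averaged. The
"mean" index is taken as the arithmetic mean of the two hemispheric
indices (not the index of averaged diffusivities); on the synthetic
phantoms the two coincide, and the former matches how left/right/mean
values are conventionally tabulated.

Published studies place the four ROIs manually on real anatomy. Here ROIs
are reproducible geometric objects — 3×3×3 axis-aligned boxes by default —
placed wholly inside the phantom's fiber compartments, and can also be
supplied as integer label volumes (codes 1–4) or a YAML geometry file.

Test-retest agreement of repeated ROI placement is summarized by the
intraclass correlation. The ICC family member is fixed to the two-way
mixed-effects, absolute-agreement, single-measure form (ICC(A,1)): ROI
re-placement by the same rater is a fixed "session" effect, absolute
agreement (not mere consistency) is what matters for a ratio index, and
single placements are what enter the analysis. The label is stored in the
result so the choice is auditable.

## The diffusion phantom

Each hemisphere contains one projection compartment,
$D = \mathrm{diag}(g + d_r,\, d_r,\, d_a)$, and one association
compartment, $D = \mathrm{diag}(g + d_r,\, d_a,\, d_r)$, in an isotropic
background. $d_a$ and $d_r$ are the axial and radial fiber diffusivities
(defaults 1.4e-3 and 0.4e-3 mm²/s, typical deep white matter); the
perivascular parameter $g \ge 0$ is an additive x-diffusivity shared by
both compartments — the minimal mechanism that moves the ALPS numerator
while leaving the denominator fixed. The ground truth is closed-form:

$$\mathrm{ALPS}_{true} = \frac{g + d_r}{d_r},$$

independent of $d_a$, and invertible (`g_for_alps()`) to generate phantoms
at any target index, e.g. 1.45 (patients) or 1.64 (controls). The full
generate → fit → extract → index chain reproduces this closed form to 1e-8
without noise, is strictly monotone in $g$, and yields exactly equal
hemispheric indices on mirrored phantoms; `g` may also differ by
hemisphere.

The acquisition default mirrors a clinical glymphatic protocol — one b = 0
plus 128 directions at b = 1000 s/mm², 2 mm isotropic voxels. Noise is
Rician by default (magnitude of a complex Gaussian, $\sigma = S_0/\mathrm{SNR}$,
SNR 30 at b = 0), with a Gaussian option for analytic checks. Phantoms do
not emulate whole-brain anatomy, partial-volume mixtures, motion or eddy
distortions, or atlas normalization: passing phantom tests demonstrates
correctness of the estimator and index arithmetic, not robustness to real
acquisition artifacts (preprocessing of real data is out of scope).

## The synthetic cohort

`generate_cohort()` emulates a study of 51 patients and 30 controls with
the published marginal conditions:

* Hemispheric ALPS drawn bivariate-normal per group — patients left
  1.46 ± 0.19 and right 1.44 ± 0.18, controls 1.62 ± 0.17 and 1.66 ± 0.20 —
  with left-right correlation 0.69, the value at which the across-hemisphere
  mean has SD 0.17 in both groups, as published for the mean index.
* Demographics from the published table: age 61.65 ± 8.27 vs 59.2 ± 5.90
  years, male proportion 28/51 vs 11/30, education 12.3 ± 3.7 vs 13.0 ± 3.2
  years. Total intracranial volume, not published, is 1450 ± 130 cm³
  (typical adult values). Sex is encoded 0/1; covariate loadings on
  volumes and MMSE default to zero so adjustment code paths can be tested
  inert or active.
* Six cortical regions at plausible volume scales. Within the patient
  group each volume follows $m_j = \mu_j + a_j (x - \bar x) + u_j$, with
  slopes $a_j$ set so the implied ALPS-volume correlations sit at the
  published 0.38–0.47 range given the ALPS spread; residual SDs are derived
  from the stated marginal SDs.
* MMSE follows $y = 23.9 + c' (x-\bar x) + \sum_j b_j (m_j - \mu_j) + e$,
  rounded and clamped to [0, 30] (with a warning if more than 20% of values
  clamp). Only the anterior cingulate and orbital inferior frontal regions
  carry $b_j > 0$; with a total effect of 14 MMSE points per index unit —
  which reproduces the published ALPS–MMSE partial correlation of ~0.54 —
  their true proportions mediated are exactly 17.49% and 32.24%. The
  generating coefficients (pre-rounding) are emitted as ground-truth
  metadata with every cohort. Rounding and ceiling-clamping shift recovered
  proportions by well under one percentage point at these settings.
* Controls sit near the MMSE ceiling (28.4 ± 1.4): the study reports MMSE
  and runs all correlation/mediation analyses within the patient group
  only, and the patient structural model extrapolated to control-level
  ALPS would pile up against the scale maximum.

Generation is deterministic: the same spec and seed give bit-identical
tables, and the CSV writer (10 significant digits) gives byte-identical
files.

## The statistics battery

* **Normality gate.** Each outcome is routed by the Shapiro–Wilk test at
  alpha = 0.05: ANCOVA when normal, the Quade rank analysis of covariance
  otherwise. Which route was taken is recorded in every report, since the
  gate itself is data-dependent.
* **ANCOVA.** `y ~ group + covariates`; the group term is tested by the
  extra-sum-of-squares F (equivalently Type III for a single two-level
  factor; on the balanced synthetic designs Type I and III coincide).
  Adjusted means are evaluated at covariate means.
* **Quade.** Outcome and covariates are midrank-transformed, outcome ranks
  are regressed on covariate ranks, and the residuals go into a one-way
  ANOVA on group — invariant to monotone transforms of the outcome. Both
  routes hold their nominal 5% type-I error within ±2 points at 1000
  seeded replicates.
* **Chi-square** for categorical contrasts, without Yates correction by
  default (a flag enables it); doubling all cells doubles the statistic.
* **Partial correlation** by double residualization (identical to the
  recursive formula, both asserted to 1e-12 in tests), t-based p with
  df = n − 2 − k. The three published covariate sets are wired into the
  pipeline: age/sex/education for ALPS–cognition, age/sex/TIV for
  ALPS–volume, and age/sex/education/TIV for volume–cognition.
* **ROC/AUC** by the Mann–Whitney midrank construction (ties count one
  half), with controls as the positive class so that higher ALPS predicts
  control status; agrees with the binormal closed form
  $\Phi(\Delta\mu/\sqrt{\sigma_1^2+\sigma_2^2})$ in simulation.
* **Benjamini–Hochberg** step-up adjustment, applied within two families
  that mirror the analysis structure: the six ALPS–volume correlations
  form one family and the six volume–cognition correlations another
  (family boundaries are not dictated by the analysis itself; this choice
  is recorded here). All p-values are two-sided.

## Mediation

Simple mediation per region: $a$ from `m ~ x + covariates`, $b$ and $c'$
from `y ~ x + m + covariates`, total $c$ from `y ~ x + covariates`, all
OLS with intercepts and the covariate set age/sex/education/TIV. On any
single sample $c = c' + ab$ exactly (asserted to 1e-10). The proportion
mediated is $100\,ab/c$ — under OLS identical to $ab/(ab + c')$ — flagged
as unstable under inconsistent mediation ($|ab| > |c|$ or opposite signs).

The confidence interval for $ab$ is a percentile case-resampling bootstrap
(default 5000 resamples, mandatory seed): the simplest member of the
Preacher–Hayes family, chosen over bias-corrected variants for
transparency. Degenerate resamples (zero variance in x or mediator) are
redrawn and counted, capped at 1% of draws. Coverage of the true indirect
effect is 92–98% over 200 seeded simulations in the test suite, and CI
width shrinks as roughly $1/\sqrt n$.

One identifiability edge case: if the mediator is an *exact* linear
function of x, the `y ~ x + m` design is singular and $b$, $c'$ are not
separately identified. The package then attributes the shared effect to
the mediator path ($b$ from `y ~ m + covariates`, $c'$ by difference) and
raises the collinearity warning — the natural reading of a noise-free
chain, and triggered only on exact aliasing. One mediator per model, run
separately per region; parallel multiple-mediator decompositions are out
of scope.

## Pipeline and reproducibility

`run_full_pipeline()` chains phantom → tensor → ALPS → cohort → statistics
→ mediation from a single YAML/list config. Every stage's seed is derived
from the master seed by a stable string hash of the stage name, so adding
a stage never perturbs earlier stages' randomness, and two runs from the
same config are byte-identical (asserted in the tests). The config is
echoed verbatim into the output directory; all floating-point table output
is written at 10 significant digits; the run report traces every statistic
to a results row and records the ANCOVA/Quade routing decisions.

## Numerical choices and test problem sizes

Noise-free equality tolerances are 1e-10 relative (tensor round trip,
mediation decomposition) or 1e-8 (full phantom chain, which accumulates a
QR solve per voxel); oracle identities are held to 1e-12. Stochastic
checks are seeded and sized to converge well inside their bands: type-I
calibration at 1000 replicates, bootstrap coverage over 200 runs of 1000
resamples at n = 200, proportion-mediated recovery over 200 cohorts of 500
patients, AUC at 10⁴ subjects per group, phantom Monte-Carlo recovery at
25 replicates per level. These sizes are the package's own choices for
stable yet fast checks; the generator defaults themselves (group sizes,
SNR, noise model) always stay at the study conditions above.

## Known limitations

* Phantoms are piecewise-constant and noise-free in geometry: no partial
  volume, no crossing fibers, no spatially varying SNR. They validate the
  arithmetic chain, not robustness to anatomy.
* The cohort generator is linear-Gaussian with an ordinal outcome bolted
  on by rounding/clamping; real MMSE floors/ceilings and skewed education
  distributions are only coarsely emulated.
* The published study's own subject-level results (its F values, exact r
  values, mediation CIs) depend on data that are not available; the
  package reproduces the *statistical machinery* and the quantities that
  follow from printed distribution parameters, not subject-level numbers.
* The ICC of repeated manual ROI placement has no synthetic analogue with
  a defensible noise level, so the published coefficient is not a
  recovery target; the estimator itself is validated against a hand
  ANOVA-table oracle.
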