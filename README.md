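# alpsflow

Diffusion tensor image analysis along the perivascular space (DTI-ALPS) is
a widely used MRI surrogate of glymphatic function — the brain's
perivascular fluid-clearance pathway whose failure is implicated in
Parkinson's disease and other neurodegenerative conditions. At the level
of the lateral ventricle body, perivascular spaces run left–right (x),
projection fibers inferior–superior (z) and association fibers
anterior–posterior (y), so the index

```
ALPS = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)
```

compares x-diffusivity against the fiber-perpendicular diffusivities in
the same voxels: 1 means no preferential perivascular diffusion, larger
values mean more.

`alpsflow` is an R package for researchers who want this entire analytical
chain as tested, reproducible code:

* **Signal model and tensor estimation** — monoexponential tensor model
  `S = S0 exp(-b gᵀDg)`, log-linear least-squares fit, voxel-wise volume
  fitting with failure masks; NIfTI and FSL bval/bvec I/O.
* **The index** — ROI handling (boxes, label volumes, YAML geometry),
  directional diffusivity extraction, per-hemisphere and mean ALPS,
  test–retest ICC (two-way mixed, absolute agreement, single measures).
* **Synthetic data with exact ground truth** — two-compartment diffusion
  phantoms whose true ALPS is the closed form `(g + d_radial)/d_radial`,
  and patient/control cohorts (51 vs 30 by default, matching published
  group distributions) with a known ALPS → grey-matter → cognition
  mediation structure.
* **Cohort statistics** — Shapiro–Wilk-gated ANCOVA / Quade rank analysis
  of covariance, chi-square, partial correlation with the three standard
  covariate sets, Mann–Whitney ROC/AUC, Benjamini–Hochberg correction.
* **Preacher–Hayes mediation** — OLS paths, percentile bootstrap CI for
  the indirect effect, proportion mediated.
* **One-command pipeline** — `run_full_pipeline()` (or the
  `inst/cli/alpsflow` script) chains everything from a YAML config with
  per-stage derived seeds and byte-identical reruns.

## Worked example

```r
library(alpsflow)

## a noisy phantom generated at ground-truth ALPS 1.45, fitted and read back
spec    <- phantom_spec(g = g_for_alps(1.45), noise = "rician", snr = 30, seed = 42)
phantom <- generate_phantom(spec)
field   <- fit_volume(phantom$dwi)
compute_subject_alps(field, phantom$rois)
#> <alps_result> left 1.4620  right 1.4621  mean 1.4621 (108 ROI voxels)

## a synthetic cohort at the published group conditions
cohort <- generate_cohort(cohort_spec(seed = 7))
group_compare(cohort$alps_m, cohort$group, as.matrix(cohort[c("age", "sex")]))
#> <group_comparison> ancova: F(1, 77) = 23.890, p = 5.439e-06
roc_auc(cohort$alps_m, cohort$group, positive = "NC")
#> <roc_result> AUC = 0.790 (30 positive vs 51 negative)

pd <- cohort[cohort$group == "PD", ]
partial_correlation(pd$alps_m, pd$mmse, as.matrix(pd[c("age", "sex", "education")]))
#> <partial_corr> r = 0.670 (df = 46, p = 1.884e-07)

med <- mediate_regions(cohort,
                       c("gmv_anterior_cingulate", "gmv_orbital_inf_frontal"),
                       n_boot = 5000, seed = 17)
med[, c("mediator", "indirect", "ci_lower", "ci_upper", "proportion_mediated")]
```

Reading the numbers: the fitted phantom recovers its ground-truth index
(1.4621 vs 1.45, the gap being Rician-noise bias at SNR 30 averaged over
108 ROI voxels); the age/sex-adjusted ANCOVA separates the groups
decisively; an AUC of 0.79 says a randomly chosen control out-scores a
randomly chosen patient 79% of the time; the partial correlation links
higher ALPS to better cognition within patients after covariate
adjustment; and the mediation rows decompose that total effect into the
part routed through each region's grey-matter volume, with a bootstrap CI
for the indirect effect (single cohorts of n = 51 estimate these
proportions with considerable sampling noise — the generating values are
17.49% and 32.24%).

The full pipeline, from a config file to a directory of CSV/JSON artifacts
and a run report:

```r
run_full_pipeline(system.file("extdata", "demo_run.yaml", package = "alpsflow"),
                  out_dir = "demo_out")
#> [phantom] 4 phantoms fitted; mean |ALPS - target| = 0.0072
#> [cohort] 51 PD + 30 NC subjects generated
#> [stats] 22 tests; routing: alps_l=quade, alps_r=ancova, alps_m=ancova
#> [mediation] 2 mediators; proportions mediated: 43.0%, 31.3%
```

See `vignettes/alpsflow-methods.Rmd` for the models, calibration of the
generators, and the reasoning behind every methodological choice.

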