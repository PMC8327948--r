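# cranmod

Modularity and integration analysis of 3D cranial landmark configurations
for wild/domestic mammal pairs.

The neural crest hypothesis proposes that selection for tameness perturbed
neural crest cell development, producing the trait suite known as the
domestication syndrome. Since cranial bones derive from either neural crest
(NC) or mesoderm (MD), the hypothesis predicts (i) NC/MD modular
structuring of cranial shape covariance, (ii) higher shape disparity in
domesticates, particularly in NC elements, and (iii) lower integration
magnitudes within and between modules in domesticates. `cranmod` is for
morphometricians who want to run this full battery of tests on landmark
data — or on simulated data with known ground truth — as a single, seeded,
reproducible pipeline.

## What it computes

For a pair dataset (specimens x landmarks x 3, wild/domestic labels, NC/MD
module map, bilateral pairing), in order:

- **Generalized Procrustes analysis**: iterative centring, unit
  centroid-size scaling (CS = sqrt of summed squared deviations from the
  centroid) and proper rotation to the consensus; **object symmetry**:
  joint superimposition of each configuration with its mirrored relabelled
  copy, the symmetric component being the average of the two.
- **Allometry**: shape ~ log(CS) across all 3p coordinates,
  R² = SS_model/SS_total, residual-randomization (RRPP) p-values; residuals
  form the allometry-corrected branch. Every statistic below is reported
  for both branches.
- **Covariance ratio**: CR = ||S12||_F / sqrt(||S11*||_F ||S22*||_F)
  (within-block diagonals zeroed); CR < 1 = modular; landmark-permutation
  null, left-tailed.
- **Two-block PLS (singular warps)**: SVD of the between-module covariance;
  r-PLS is the first-axis score correlation; row-permutation null,
  right-tailed; effect size z = (r_obs − mean r_perm)/sd r_perm, compared
  across analyses by two-sample z-tests.
- **Eigenvalue dispersion**: relative eigenvalue SD of the module
  correlation matrix, in [0, 1]; a trait-count-independent integration
  magnitude.
- **Disparity**: Procrustes variance (trace of the group covariance,
  n divisor), module values divided by landmark count; group contrasts by
  residual permutation.
- **Downstream**: PCA (eigenvalues sum to Procrustes variance), PC1–PLS1
  alignment correlations, cross-pair dispersion t-contrasts,
  disparity ~ integration * form regressions and variance-ratio F tests.

A synthetic generator (`simulate_dataset()`, `study_presets()`)
produces bilaterally symmetric datasets with block-structured covariance,
allometry, group offsets and known dispersion ratios, so every stage can be
validated against ground truth; `recover_covariance_params()` estimates the
generating parameters back through the superimposition.

## Worked example

```r
library(cranmod)

prm <- synthetic_params(seed = 42)          # 26 landmarks, 30 + 30 specimens
sim <- simulate_dataset(prm)
sim$dataset
#> landmark_dataset 'synthetic_pair': 60 specimens (30 wild / 30 domestic), 26 landmarks x 3D

sym <- symmetric_component(sim$dataset, sim$pairing)
fit <- procrustes_anova(sym, n_perm = 999, seed = 1)
fit
#> Procrustes ANOVA (shape ~ log CS): R2 = 0.1551, F = 10.648, Z = 17.44, p = 0.001 (999 perms)

res <- allometry_residuals(fit)             # allometry-corrected branch
modularity_test(res, sim$map, n_perm = 999, seed = 2)
#> CR modularity test: CR = 0.7374, Z = -5.38, p = 0.001 (999 perms)

two_block_pls(res, sim$map, n_perm = 999, seed = 3)
#> two-block PLS: r-PLS = 0.9107, Z = 6.40, p = 0.001 (999 perms)

eigenvalue_dispersion(res, sim$map, "NC")
#> eigenvalue dispersion (NC, 42 variables): 0.2249
eigenvalue_dispersion(res, sim$map, "MD")
#> eigenvalue dispersion (MD, 36 variables): 0.3797

disparity_test(res, n_perm = 999, seed = 4)
#> Procrustes variance by group:
#>     wild domestic
#> 0.018588 0.035810
#> pairwise p-values (999 perms):
#>           wild domestic
#> wild     1.000    0.001
#> domestic 0.001    1.000
```

Reading: size explains ~16% of symmetric shape variance; after removing it,
the NC/MD partition is strongly modular (CR = 0.74, p = 0.001) yet the two
modules remain highly integrated along their leading covariation axis
(r-PLS = 0.91); the MD module is more internally integrated than NC (0.38
vs 0.22); and the domestic group holds about twice the shape variance of
the wild group (0.036 vs 0.019, p = 0.001) — the qualitative pattern the
generator encodes.

`run_pair()` wraps this chain (both branches, plus PCA, PC1–PLS1 and
per-form PLS) into one seeded report; `run_study()` aggregates reports into
the cross-pair contrasts. The numbered scripts under `analysis/` are the
study workflow: `01_simulate.R` writes the six study-sized pairs as CSV,
`02_run_pairs.R` produces the per-pair reports, `03_study_summary.R` the
cross-pair synthesis, and `04_calibration.R` the calibration and
ground-truth recovery tables, all under `results/`.

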