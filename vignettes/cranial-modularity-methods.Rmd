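---
title: "Methods: modularity and integration of cranial landmark data in wild/domestic pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modularity and integration of cranial landmark data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cranmod)
```

## The scientific problem

The domestication syndrome is the recurrent suite of traits — shortened
rostra, reduced teeth, floppy ears, depigmentation — observed across
unrelated domesticated mammals. The neural crest hypothesis attributes the
syndrome to mild deficits in neural crest cell development arising from
selection for tameness. Because cranial bones derive from two embryonic
tissues (neural crest rostrally, mesoderm caudally), the hypothesis makes
testable morphological predictions: cranial landmarks should covary in a
neural-crest (NC) versus mesoderm (MD) modular pattern, and NC-derived
elements should show elevated shape disparity and altered integration
magnitudes in domesticates relative to their wild relatives.

`cranmod` implements the full statistical chain used to test these
predictions on 3D cranial landmark configurations from wild/domestic pairs:
Procrustes superimposition with object-symmetry decomposition, allometric
correction, the covariance-ratio (CR) modularity test, two-block partial
least squares (2B-PLS, "singular warps") integration with permutation
effect sizes, eigenvalue-dispersion integration magnitudes,
Procrustes-variance disparity with permutation contrasts, and the
cross-pair syntheses (t-contrasts, effect-size comparisons, and
disparity–integration regressions). A synthetic landmark generator with
known covariance structure provides ground truth for every stage.

## Data model and superimposition

A pair dataset is `n` specimens x `p` landmarks x 3 coordinates with a
wild/domestic label per specimen, an a-priori NC/MD assignment per landmark,
and a bilateral pairing table (left/right counterparts plus midline
landmarks). Pairs are analysed separately end to end; wild and domestic
specimens of one pair share a single joint superimposition, and module
statistics are computed by subsetting that joint fit rather than refitting
each module (`subset_module()`); refitting a subset changes the coordinates
and is deliberately not done.

`gpa()` is the standard iterative superimposition: each configuration is
centred, scaled to unit centroid size, and rotated onto the running
consensus by proper orthogonal Procrustes rotation; the consensus is
re-estimated until its root-mean-square change falls below `tol = 1e-10`
(cap `max_iter = 100`; typical convergence is 3–6 iterations). Rotations are
constrained to determinant +1. If a configuration fits dramatically better
(4x in squared distance) under a reflection, an error is raised: mirrored
digitisation is a data defect, not a parameter to fit. No tangent-space
projection is applied by default — at intraspecific scales of shape
variation the projection changes nothing above numerical noise — but
`project_tangent()` makes the step available explicitly.

For object-symmetric structures, `symmetric_component()` mirrors each
configuration across the plane normal to a configurable axis (default the
second axis), relabels left/right partners, and superimposes the `2n`
copies jointly; the per-specimen average of its two aligned copies is the
symmetric component, and the residual from the average is the asymmetric
component, so the two reconstruct the aligned original exactly. After the
joint fit the sample is rotated so the estimated symmetry plane (the best
improper-orthogonal self-map of the consensus) coincides with the
coordinate plane; midline landmarks are not constrained onto the plane, and
drift beyond 0.05 shape units only warns.

## Allometry

`procrustes_anova()` regresses all `3p` coordinates on natural-log centroid
size and accumulates sums of squares over coordinates; R² is the fraction of
total shape variance explained by size. Significance uses residual
randomization (RRPP): residuals of the intercept-only reduced model are
permuted across specimens, re-added to the reduced fit, and the model
refitted; the p-value counts the observed statistic among the permutations,
so `p >= 1/(n_perm + 1)`. Allometry-corrected shapes are the residuals with
the grand mean added back (`allometry_residuals()`), and every downstream
statistic is reported for both the uncorrected and corrected branches — the
pooled-fit residuals are the default, with per-group fits available through
the grouping arguments. Allometric vectors are compared between groups by
the angle between per-group slope vectors, with an RRPP null built from the
common-slope model; centroid sizes are compared with Welch's t-test on the
log scale.

## Covariation statistics

**Covariance ratio.** From the `3p x 3p` covariance matrix partitioned by
module, CR is the Frobenius magnitude of the between-module block relative
to the geometric mean of the within-module blocks with their diagonals
zeroed. CR < 1 indicates modular structure. The null reassigns whole
landmarks (x, y, z kept together) to modules of the original sizes; small CR
is significant, so the p-value is the left-tail proportion. The statistic
never inverts the covariance matrix and is well defined in the usual
rank-deficient regime (`n << 3p`).

**Two-block PLS.** The between-module covariance matrix is decomposed by
SVD; specimens are projected on the paired first singular vectors and
`r_pls` is the correlation of those scores. The null permutes specimens in
one block relative to the other (right tail significant). The permutation
effect size is `z = (r_obs - mean(r_perm)) / sd(r_perm)` on the raw
correlation scale (no Fisher transform; the observed value is included in
the reference distribution). Because these z-scores are standardized
deviates with unit sampling scale, two analyses are compared with
`(z_i - z_j)/sqrt(2)` and a two-sided normal p-value
(`compare_pls_effects()`); pairs digitised on a reduced landmark set are
excluded from this comparison by a configuration flag, since effect sizes
across different trait counts are not commensurable.

**Eigenvalue dispersion.** Within-module integration magnitude is the
relative eigenvalue standard deviation of the module's coordinate
correlation matrix: the population SD of the eigenvalues divided by
`sqrt(N - 1)` for `N` variables, which is 0 for an identity matrix, 1 for a
rank-one matrix, and exactly rho for an exchangeable matrix. The
normalization by variable count is itself the correction that makes modules
with unequal landmark numbers comparable; no further division by landmark
count is applied.

**Disparity.** Procrustes variance is the summed squared deviation from the
group mean divided by group size `n` — the n-divisor convention, not the
unbiased `n - 1` — so PCA eigenvalues (also n-divisor) sum exactly to it.
Module disparities are additionally divided by the module's landmark count
(`p_module`, not `3 p_module`; the choice only rescales both modules by the
same constant) for cross-module comparison. Group contrasts permute
group-mean-centred residual vectors among specimens and compare absolute
differences in Procrustes variance.

All permutation engines take explicit seeds; identical seeded runs
reproduce every number bit-identically, and the per-pair driver
(`run_pair()`) derives stage seeds from one base seed by fixed offsets.

## The synthetic generator

`simulate_dataset()` emulates the data structure the pipeline assumes. A
seeded template places paired landmarks mirrored across the symmetry plane
and midline landmarks on it, with the NC block rostral and the MD block
caudal (contiguous anatomical blocks, as in real crania), scaled to unit
centroid size. Shape deviations are drawn in the *half representation* (one
member of each bilateral pair plus the midline landmarks) from a
block-exchangeable correlation — `rho_within_nc`, `rho_within_md`,
`rho_between`, checked positive semi-definite at construction — scaled by
`sigma_shape` (default 0.02 Procrustes units; domestic specimens multiplied
by `disparity_scale_domestic`), then mirrored to the other side so the
generating signal lives entirely in the symmetric subspace. On top of this
come an allometric displacement (a fixed symmetric direction times centred
log size), a fixed symmetric mean offset for domestics, and antisymmetric
noise built by antisymmetrizing iid perturbations. Each configuration is
then randomly rotated, translated, and scaled to its target centroid size,
so written files exercise the full superimposition path.

The six presets in `study_presets()` mirror the study sizes of six
wild/domestic pairs — 41/22, 45/25, 22/28, 133/83, 18/86 and 14/21
domestic/wild specimens with 60, 26 and 62 landmarks — and the qualitative
effect pattern of the study system: modular NC/MD covariance everywhere,
MD more strongly correlated within-module than NC (so MD shows higher
integration magnitude), elevated domestic dispersion except in the horse
pair, and allometric signal spanning roughly 6–24% of shape variance with
the pig pair strongest. The landmark geometry and the module split are
synthetic; no published landmark table is reproduced. Sample sizes are the
published ones; correlation levels (0.35/0.55/0.15) and `sigma_shape` are
the package's own choices of realistic intraspecific magnitudes, fixed once.

### Parameter recovery through the superimposition

Superimposition is a projection: centring, unit-size scaling and rotation
remove seven similarity dimensions evaluated at the mean shape, and the
all-variables common factor of an exchangeable correlation lies largely
inside the translation span. Naive averages of sample correlations after
GPA are therefore strongly biased. `recover_covariance_params()` instead
fits the generating model *through* the projection: the expected aligned
covariance is `P W Sigma(theta) W' P`, with `W` the half-to-full symmetric
embedding and `P` the similarity-complement projector at the template, and
the four coefficients of `Sigma(theta)` (noise, NC, MD and between blocks)
are solved by least squares; correlations are coefficient ratios. The
domestic/wild variance ratio additionally inverts the first-order shrinkage
of the unit-sphere scaling (observed variance ≈ V/(1+V)), which otherwise
biases the ratio low by ~8% at the simulated magnitudes. At 500 specimens
per group the recovered correlations are unbiased with sampling SD ≈ 0.02
(the chi-square fluctuation of the common factor), and the variance ratio
is recovered within a few percent.

### What superimposed data can and cannot show

Two properties of Procrustes data shape how the generator's calibration
checks are constructed, and both matter for interpreting real analyses:

- *Bilateral duplication.* The symmetric component represents each
  bilateral pair twice; the left copy is an exact mirror of the right. This
  inflates within-module covariation relative to any landmark-permutation
  null. Calibration checks (e.g. CR ≈ 1 under exchangeable correlation)
  therefore run on the deduplicated half landmark set (`half_landmarks()`).
- *Superimposition-induced covariance.* Removing the seven similarity
  dimensions induces structured covariance whose loadings follow the
  template geometry; with spatially contiguous modules this mimics modular
  structure. On null data (no generating covariance at all) the CR test
  over-rejects substantially end-to-end while being exactly calibrated on
  the generating deviations, and the PLS test is mildly affected. The test
  suite asserts uniform p-values at the level each test actually permutes
  (generating deviations for CR/PLS; group labels end-to-end for the
  disparity contrast, which is immune) and asserts the induced
  over-rejection as a documented property. Consequently, a small CR with a
  significant landmark-permutation p on real superimposed data supports
  modularity relative to that null, but the null itself is generous;
  between-pair comparisons of CR magnitude are safer than absolute
  calibration claims.

## Numerical and design choices

- GPA: `tol = 1e-10` on consensus RMS change, `max_iter = 100`; unit
  centroid-size scaling without full-Procrustes scaling refinement.
- Permutation p-values always count the observed statistic (minimum
  `1/(n_perm + 1)`); default `n_perm = 999` in the drivers, 499 in the
  reproduction script, 99–199 in simulation-heavy tests.
- Tail orientation is explicit: the modularity test is left-tailed (small
  CR), PLS right-tailed (large r).
- The PC1–PLS1 alignment correlation is reported as an absolute value (axis
  signs are arbitrary) for both block score sets, the NC block leading.
- Degenerate inputs error early with context: missing coordinates name the
  specimen and landmark; zero-variance variables are named; zero-variance
  t-test and regression inputs are refused rather than returning infinite
  statistics (identical inputs, however, return t = 0, p = 1).
- The cross-pair dispersion contrasts are paired t-tests across pairs
  (pair x form units for the pooled NC-vs-MD contrast). The
  disparity–integration regressions use `lm(integration ~ disparity * form)`
  on pair x module x form observations, reporting per-form slopes, the
  interaction F with both degrees of freedom printed explicitly, and the
  variance-ratio F between forms' disparities.

## Problem sizes in the shipped checks

The test suite simulates at the sizes that keep it informative yet quick:
type-I calibration uses 200 replicates of 50 x 30 exchangeable draws at 199
permutations; power uses 100 replicates of the strong-signal conditions
(rho within 0.6, between 0.05, 50+50 specimens); recovery uses one dataset
of 500 per group; the brute-force rotation oracle uses three 5-landmark
pairs. The reproduction script runs all six presets at 499 permutations.
The full suite completes in well under five minutes on one core.

## Limitations

- The generator's exchangeable block correlations are a deliberately coarse
  stand-in for real cranial covariance (no spatially graded correlation, no
  measurement-error model, no semilandmarks); passing recovery and power
  checks demonstrates the statistics, not anatomical realism.
- Matching (paired-structure) symmetry, 2D data, sliding semilandmarks, and
  >2 modules are out of scope (the CR and PLS internals take explicit
  variable index sets, so a >2-module extension is structurally
  straightforward).
- `compare_pls_effects()` uses the unit-scale normal approximation for
  z-score differences; exact small-sample standard errors for the
  standardized deviates are not estimated.
- Phylogenetic non-independence between pairs is ignored in the cross-pair
  t-contrasts and regressions, as in the study design this mirrors.
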