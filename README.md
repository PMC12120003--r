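# wmhsgm

Multivariate covariance-pattern analysis of how white-matter
hyperintensity (WMH) burden relates to subcortical gray-matter (SGM)
volumes in aging cohorts, and mediation analysis of how that pattern
links age to cognition.

## Who this is for

Researchers with a subject x variable table of FreeSurfer-style
subcortical volumes (bilateral caudate, putamen, pallidum, hippocampus,
nucleus accumbens, amygdala, thalamus), a total WMH lesion volume,
demographic/vascular covariates and neuropsychological scores, who want
to ask: *is there a regionally distributed pattern of SGM volume
associated with global WMH burden, and does expression of that pattern
mediate age-related cognitive slowing?*

## The method

1. **Scaled Subprofile Model (SSM).** Natural-log the 14 region volumes,
   double-center the subject x region matrix (removing each subject's
   mean — the global-size adjustment — and each region's mean — the
   group profile), and take the principal components of the residuals:

   `R = log V − rowMeans − colMeans`, `R = U D Vᵀ`,

   giving orthonormal regional loadings `V`, participant scores `U D`,
   and eigenvalues `d²/(n−1)`.

2. **BIC pattern selection.** For k = 1..k_max, regress log WMH on the
   first k component scores and compute
   `BIC(k) = n·ln(RSS/n) + (k+1)·ln(n)`. The minimizing k defines the
   combined pattern: regional weights `w ∝ Σ βⱼ vⱼ` (unit norm, signed so
   expression rises with log WMH) and z-scored per-subject expression.

3. **Bootstrap weight CIs.** Resample subjects with replacement, rerun
   the whole chain at fixed k, sign-align each replicate to the point
   estimate, and take empirical 2.5/97.5 percentiles per region; a CI
   excluding zero flags a region as a significant contributor.

4. **Mediation.** Simple (age → pattern → outcome) and serial
   (age → pattern → log TMT-A → outcome) OLS path models with
   covariates, completely standardized effects, and percentile-bootstrap
   CIs for the indirect effects `a₁b₁`, `a₂b₂`, `a₁d₂₁b₂`.

A synthetic-cohort generator with planted topography (negative weights
on bilateral putamen and left accumbens, positive on bilateral caudate)
and planted path coefficients makes every stage testable by parameter
recovery; `generate_null_cohort()` provides type-I-error harnesses.

## Worked example

```r
library(wmhsgm)

params <- cohort_params(seed = 42L)     # 178 subjects, study-scale defaults
cohort <- generate_cohort(params)

decomp  <- ssm_decompose(double_center(log_volume_matrix(cohort)))
pattern <- select_pattern(decomp, log_wmh(cohort))
pattern
#> WMH-related pattern: 1 components (BIC-selected)
#>   R^2 = 0.294 (adj. 0.290), F(1,176) = 73.25
#>   most negative: putamen_l, putamen_r | most positive: caudate_l, caudate_r
```

The pattern explains 29% of the variance in log WMH in this simulated
cohort, with the planted striatal topography: volume *reductions* in
bilateral putamen (and left accumbens) and *relative increases* in
bilateral caudate with greater WMH burden.

```r
bw <- bootstrap_pattern(cohort, k_fixed = pattern$k_selected,
                        n_boot = 1000, seed = 7)
head(as.data.frame(bw), 4)
#>      region weight ci_low ci_high significant
#>   caudate_l  0.457  0.441   0.472        TRUE
#>   caudate_r  0.453  0.441   0.465        TRUE
#>   putamen_l -0.487 -0.502  -0.470        TRUE
#>   putamen_r -0.484 -0.498  -0.469        TRUE

cohort <- preprocess_cognition(cohort)
cohort$pattern_expression <- pattern$expression
fit <- fit_mediation(cohort,
                     mediation_spec("age", "pattern_expression", "log_tmt_a",
                                    n_boot = 1000, seed = 3))
fit
#> Simple mediation: age -> pattern_expression -> log_tmt_a (n = 178, 1000 bootstrap replicates)
#>     path estimate    se        p
#>       a1    0.431 0.069 3.70e-09
#>       b1    0.339 0.077 1.79e-05
#>  c_prime    0.189 0.077 1.50e-02
#>  c_total    0.335 0.073 8.72e-06
#>   effect estimate boot_se ci_low ci_high significant
#>   ind_m1    0.146   0.039  0.077   0.233        TRUE
#>  c_prime    0.189   0.074  0.043   0.335        TRUE
#>  c_total    0.335   0.068  0.206   0.468        TRUE
```

Older age predicts greater pattern expression (`a1`), which predicts
slower processing speed (`b1`); the indirect effect `a1*b1 = 0.146` is
the completely standardized share of the age effect carried by the
pattern, with a percentile-bootstrap CI excluding zero.

`run_full_analysis(run_config(...))` sequences all stages and writes
CSV/JSON outputs plus a checksummed manifest; a thin command-line
dispatcher with `simulate`/`ssm`/`select`/`bootstrap`/`mediate`/`run-all`
subcommands lives at `inst/cli/wmhsgm.R`.

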