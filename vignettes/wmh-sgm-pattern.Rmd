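---
title: "Deriving and validating a WMH-related subcortical covariance pattern"
author: "wmhsgm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating a WMH-related subcortical covariance pattern}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmhsgm)
```

## The scientific problem

White-matter hyperintensities (WMH) are a radiological marker of
small-vessel cerebrovascular disease that accumulates with age. Rather
than relating WMH burden to each subcortical structure separately —
which costs power to multiple-comparison correction and ignores the
covariance among structures — this package treats the question as a
*pattern* problem: find a single regional weight vector over the 14
deep gray-matter structures whose per-subject expression tracks total
log WMH volume, then ask whether expression of that pattern carries
part of the age effect on cognition.

## The model

### Scaled Subprofile Model

Let $V_{ij}$ be the volume (mm³) of region $j$ in subject $i$. The SSM
works on $Y = \log V$ after **double centering**:

$$R_{ij} = Y_{ij} - \bar Y_{i\cdot} - \bar Y_{\cdot j} + \bar Y_{\cdot\cdot}.$$

Removing the subject mean $\bar Y_{i\cdot}$ absorbs global brain size
(a multiplicative factor on all volumes becomes an additive constant
after the log and is annihilated exactly — `express_pattern()` is
invariant to doubling every volume, and the test suite asserts this).
Removing the region mean absorbs the group-average regional profile.
Row and column centering commute, so the order is immaterial; TIV is
deliberately *not* regressed out of the volumes — subject-mean
centering is the global-size adjustment, and TIV enters only as a
mediation covariate.

The principal components of $R$ (computed by SVD) give orthonormal
regional loadings, participant scores, and eigenvalues
$d_k^2/(n-1)$. The sign of each component is fixed deterministically:
the largest-magnitude loading element is made positive.

### BIC selection of the combined pattern

For $k = 1, \dots, k_{\max}$ we fit
$\log\text{WMH} \sim 1 + s_1 + \dots + s_k$ by OLS and compute the
Gaussian-likelihood form

$$\mathrm{BIC}(k) = n \ln(\mathrm{RSS}/n) + (k+1)\ln n,$$

counting the intercept but not the error variance; since the omitted
$\sigma^2$ term is a constant offset across $k$, the argmin is
unaffected. Candidates are the *nested* leading-$k$ sets, not all
$2^K$ subsets — the components are ordered by explained volume
covariance, and the nested search is the one whose selected model is
"the first $k$ components". Ties within $10^{-9}$ resolve to the
smaller $k$ (parsimony). The default cap is
$k_{\max} = \min(n-2,\, p-1,\, 10)$; with 14 regions the component
space is small and the cap rarely binds.

The combined weights are $w \propto \sum_j \beta_j v_j$,
unit-normalized. All magnitude information lives in the expression
scores, which are z-scored; the global sign is anchored so that
expression correlates nonnegatively with log WMH, making "higher
expression = more WMH-like brain" a stable convention. Negative
weights therefore mark regions whose volume *decreases* with WMH
burden.

Two equivalent routes produce expression scores: the regression route
(z-scored $\sum_j \beta_j s_j$) and the projection route
(row-center a subject's log volumes, subtract the stored training
region means, project onto $w$, standardize by the stored training
mean/SD). They agree to machine precision on training data, and the
projection route scores new subjects without refitting.

### Bootstrap CIs for the weights

Subjects (never regions) are resampled with replacement; each
replicate reruns the entire chain at the point estimate's $k$.
Holding $k$ fixed keeps model-selection variability out of the weight
CIs (a `reselect = TRUE` mode exists for sensitivity analysis).
Replicates are sign-aligned to the point estimate by dot product;
replicates essentially orthogonal to it ($|w_b \cdot w_0| <
10^{-12}$) or with rank-deficient designs are discarded and counted,
with a warning if more than 1% fail. Intervals are plain percentile
(2.5/97.5), matching the convention used for the mediation indirect
effects, and are recomputable order statistics of the stored
replicate matrix.

A calibration caveat established by the package's own Monte-Carlo
harness: on *null* cohorts (no planted pattern) the per-region
flag rate is far below the nominal 5% (about 0.4%). Under a global
null the normalized, sign-aligned weight vector is not an identified
estimand, so replicate distributions are diffuse and the intervals
are conservative. The procedure over-covers rather than
under-covers; regions it flags on null data are rare.

### Mediation models

Simple ($x \to m \to y$) and serial ($x \to m_1 \to m_2 \to y$) path
models are fit by OLS on listwise-complete rows with the same
covariates in every equation, which makes the decomposition

$$c_{\text{total}} = c' + \textstyle\sum \text{indirect}$$

an exact in-sample identity (asserted at $10^{-8}$). Effects are
*completely standardized*: predictor, mediators, outcome and
continuous covariates are z-scored; binary covariates stay 0/1 — they
only absorb variance, and standardizing them would not change the
reported effects of interest. The bootstrap re-standardizes within
each replicate, treating standardization as part of the estimator
(the conservative choice); SEs are replicate SDs and CIs are
percentile bounds. Per-path p-values come from OLS t-tests on the
standardized point-estimate design. Two-tailed $\alpha = 0.05$ with
no multiplicity correction across outcome models — a deliberate
caveat, not an oversight.

Outcome conventions: timed scores (TMT-A, TMT-B, GPT) are
log-transformed to normalize right-skew. Set shifting is measured two
ways: in *simple* models, where processing speed is not otherwise in
the model, TMT-B is residualized on **raw** TMT-A (z-scored OLS
residual); in *serial* models log TMT-A is already a mediator, so the
outcome is log TMT-B directly. The residualization uses raw scores
even though the models use logs — the residual is defined on the
scale the tests are scored on.

## The synthetic cohort generator

`generate_cohort()` is first-class, tested code, not a fixture
factory. Its defaults describe a healthy older-adult cohort of
$n = 178$: age 69.77 (SD 10.22) years; WMH marginal mean 6.68, SD
10.28 mL, generated log-normally (mean < SD implies right skew, and
the pipeline log-transforms WMH anyway); covariate marginals (sex
50.6% women, education 16.72 ± 2.80 y, APOE ε4 31.5%, hypertension
33.1%, high cholesterol 70.2%, smoking 39.9%, BMI 25.21 ± 3.87,
VO₂max 24.43 ± 5.81, GDS 1.01 ± 1.58 as a negative-binomial count,
scan-test interval 56.49 ± 46.69 d as a gamma variable). One TMT-B
and one GPT score are missing by default, so listwise deletion is
exercised.

The planted structure: a latent pattern score
$s = a\,z(\text{age}) + \sqrt{1-a^2}\,\varepsilon$ with $a = 0.492$;
log volumes $= \mu_j + g_i + s_i w_j + \epsilon_{ij}$ with planted
topography $w$ (−1 bilateral putamen, −0.7 left accumbens, +0.8
bilateral caudate, mean-removed, unit-normalized — magnitudes are
design choices; only the signs are constrained by the substantive
claim); log WMH coupled to $s$ at $r = \sqrt{0.389} \approx 0.624$,
the multiple correlation implied by the pattern regression's
$R^2$; log TMT-A $= 0.234\,s + 0.262\,z(\text{age}) + \varepsilon$;
each downstream outcome driven by standardized log TMT-A (slopes
−0.278 SRT CLTR, +0.539 log TMT-B, −0.287 LNS, −0.347 SCWT, +0.182
GPT — back-derived from the serial indirect effects divided by
$a \cdot 0.234$) plus its direct age path, then placed on natural
test scales (timed scores exponentiated from the log scale, so the
pipeline's own log-transform step is exercised). Residual variances
close each standardized variable to unit variance. Per-subject
global scale $g_i$ (SD 0.1, a realistic ~10% whole-brain size
dispersion) also drives TIV, its natural observable. Residual
regional noise defaults to SD 0.1 on the log scale, typical of
inter-individual volumetric dispersion after size adjustment.

What the generator does *not* emulate: covariate–pattern confounding
(covariates are independent of $s$ by default), WMH–TIV or sex–TIV
couplings, spatial autocorrelation between homologous regions beyond
the planted component, measurement floor/ceiling effects in the
cognitive tests, and longitudinal structure. Passing recovery tests
therefore shows the *estimator chain* is correct under the stated
generative model, not that real cohorts satisfy that model.

`generate_null_cohort()` keeps every marginal but removes the pattern
from the volumes and severs all paths through $s$ (WMH independent of
volumes, cognition driven by age alone); it backs the type-I
harnesses.

## Numerical choices and degenerate inputs

- Nonpositive volumes, WMH, or timed scores are domain errors naming
  the subject/column; region volumes may not be imputed.
- `ssm_decompose()` requires $n \ge 3$ subjects and $p \ge 2$
  regions; it keeps $K = \min(n-1, p-1)$ components, the rank bound
  of the double-centered matrix.
- Bootstrap replicates are declared degenerate when the $k$-th
  singular value falls below $10^{-10}$ of the first, when the
  regression design is rank-deficient, or when the replicate weight
  vector is orthogonal to the point estimate.
- A numerically perfect TMT-B ~ TMT-A fit (residual SD below
  $10^{-10}$ of the outcome SD) yields zero residuals rather than
  amplified noise; residualization requires at least 3 complete
  pairs.
- Mediation requires at least `10 + #predictors` complete rows;
  collinear designs raise an error naming the offending columns.

## Problem sizes and verification

The package verifies itself at these scales, chosen to make
Monte-Carlo error small relative to the assertion margins while
keeping the default suite comfortably interactive: algebraic
identities on ~100 random matrices; topography recovery over 100
cohorts of $n = 1000$ at coupling 0.6 (cosine ≥ 0.95 expected in ≥
95); bootstrap calibration over 100 null and 100 planted cohorts of
$n = 500$ with 1000 replicates each; indirect-effect recovery at
$n = 5000$ and percentile-CI coverage over 500 simulations at
$n = 500$ with 1000 replicates; and a 200-repetition study-scale
($n = 178$) check that the qualitative result structure — positive
age→pattern and pattern→speed paths, significant serial indirect
effects for memory, shifting, working memory and inhibition, and a
non-significant reversed (fine-motor-first) serial model — emerges in
the majority of repetitions. Pipeline defaults use 1000 bootstrap
replicates; analyses of real data should raise `n_boot` (e.g. to
10,000) via the run configuration.

## Known limitations

- Percentile (not BCa) intervals throughout; with strongly skewed
  bootstrap distributions BCa would differ.
- The nested-first-$k$ search cannot select, say, components {1, 3}
  without component 2; exhaustive search over subsets is not
  implemented.
- The mediation models are cross-sectional path models; nothing here
  licenses causal interpretation, and no sensitivity analysis for
  unmeasured confounding is provided.
- The null-cohort bootstrap calibration documented above: region
  flags are conservative under a global null.
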