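---
title: "Methods: Gaussian-process normative modeling of volumetric brain data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Gaussian-process normative modeling of volumetric brain data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpnorm)
```

## The model

`gpnorm` asks a single-case question: given a healthy reference sample,
how unusual is *this* subject's gray matter volume at *this* voxel,
once age, sex, global brain volumes and scanner field strength are
accounted for?

Each voxel j gets its own generative model of the observed volume
y_ij of subject i:

    y_ij = g(x_i) + e_ij,    e_ij ~ N(0, sigma_j^2)

where x_i is the subject's covariate vector (local models:
age, sex, tgmv, twmv, tcsf, fstr; global models: age, sex, ticv, fstr)
and g is a latent function with a zero-mean Gaussian-process prior.
Smoothness across covariate space is encoded by the squared-exponential
ARD kernel

    k(x_p, x_q) = a * exp(-1/2 * sum_d (x_pd - x_qd)^2 / l_d^2),

one amplitude a and one length scale l_d per covariate. Small fitted
l_d means the latent volume surface varies quickly along covariate d;
a very large l_d effectively removes the covariate (automatic relevance
determination). Hyperparameters (a, l, sigma^2) are chosen per voxel by
maximizing the exact log marginal likelihood (evidence)

    log p(y | X) = -1/2 y' (K + sigma^2 I)^-1 y
                   - 1/2 log |K + sigma^2 I| - n/2 log(2 pi),

which trades data fit against model complexity without cross-validation.

For a new subject with covariates x*, the closed-form predictive
distribution of the observed volume has mean g* and variance
u^2 = latent posterior variance + sigma^2. The package's central output
is the z-score of that predictive distribution,

    delta = (y* - g*) / u,

assembled across all in-mask voxels into a Normative Probability Map
(NPM). Negative delta means less volume than the normative prediction
(atrophy), positive means more. Because u^2 varies across voxels and
subjects — it grows in sparsely sampled corners of covariate space and
in noisy voxels — the same prediction error can be strong or weak
evidence of abnormality; delta makes exactly that correction (doubling
u at fixed error halves delta). Global z-scores for tgmv, twmv and tcsf
are produced the same way by the three global GPs.

Per-voxel predictive log-densities can additionally be combined, under
a conditional-independence assumption across voxels, into a naive-Bayes
posterior over user-specified disease states with user-supplied priors
(`naive_bayes_posterior()`); the package supplies the healthy-state
likelihood (`healthy_log_likelihood()`), while alternative disease
likelihood maps must come from the user since no disease data are
modeled here.

## Numerical and design choices

Several choices are not dictated by the model and were fixed once, as
follows.

**Covariate standardization.** Covariates are z-standardized per column
with *training* statistics; test covariates always reuse the training
shift and scale. Binary columns (sex, fstr) coded 0/1 are standardized
like any other. This puts all length scales on a comparable unit so the
common initialization log l = 0 is sensible and ARD comparisons across
covariates are meaningful. Reported length scales are therefore in
standardized-covariate units.

**Target centering.** The GP prior mean is zero, which is only sensible
on centered data; training targets are centered by their mean and the
mean is added back at prediction.

**Optimization.** The evidence is optimized over log(a), log(l),
log(sigma^2) with L-BFGS and analytic gradients. Initialization:
log a = log var(y), log sigma^2 = log(var(y)/2), log l = 0, with up to
3 restarts jittering each log-parameter by N(0, 0.5^2). The evidence
surface is multimodal in general; restarts protect against the common
small-length-scale local optimum. Every stochastic routine takes an
explicit integer seed (restart r uses seed + r - 1; voxel j uses
xor(seed, j)), so runs are reproducible and voxels are independent of
processing order.

**Jitter.** 1e-8 * a is added to the covariance diagonal before
Cholesky factorization, escalating tenfold up to 1e-2 * a before the
kernel is declared ill-conditioned.

**Box–Cox.** Modulated VBM intensities are right-skewed; each voxel is
transformed by f_lambda(y) = (y^lambda - 1)/lambda (log y at
lambda = 0) before GP fitting. lambda maximizes the profile
log-likelihood -(n/2) log sigma_lambda^2 + (lambda - 1) sum log y over
[-3, 3] by bounded scalar search; sigma_lambda^2 is the ML residual
variance about the transformed mean (intercept-only), because the
transform is a modeling step *prior* to — and independent of — the GP
regression. To keep the data scale interpretable the transform is
rescaled by the first-order Taylor factor f'_lambda(mu) = mu^(lambda-1)
around the training mean mu, so Var(f_lambda(y)/f'_lambda(mu)) ~
Var(y). lambda, mu and any positivity shift (epsilon = 1e-4 added when
a voxel contains non-positive values) are estimated on training data
only and replayed verbatim on test data; nothing is re-estimated at
prediction time. Residual normality can be audited with
`normality_report()` (Q–Q correlation, skewness, raw kurtosis — a
normal sample sits near 3). Global volume models are fit untransformed
by default (configurable), as skewness is a voxel-level phenomenon in
this data class.

**Masking and geometry.** When no mask is given, a voxel is modeled if
its training-sample mean exceeds 0.05, matching the usual absolute
threshold for modulated gray matter maps. Voxels are ordered by the
volume's row-major linear index and that order is stored in the model
container. All output volumes are NaN outside the mask so that "no
model" is never confused with delta = 0. The engine models whatever
grid it is given; resampling and smoothing are preprocessing and out of
scope.

## The trajectory simulator

Because the package's claims concern single-case inference, validation
needs data with known ground truth. The simulator generates
cross-sectional cohorts from a two-level mixed-effects ensemble of
lifespan trajectories: each subject follows

    y(t) = theta0 + theta1 t + theta2 t^2        (healthy)
    y(t) = ... + theta3 * max(0, t - theta4)     (diseased)

with subject parameters drawn from N(theta_mean, diag(theta_var)),
i.i.d. Gaussian observation noise, and one observation per subject at
an age drawn uniformly from [20, 90] years. The bundled presets fix the
study conditions used by all package tests:

| preset | E(theta) | Var(theta) | noise var |
|---|---|---|---|
| `fig2_large` | (0.92, 4e-3, 1e-4) | (6e-3, 1e-6, 2e-10) | 0.01 |
| `fig2_small` | (0.92, 4e-3, 1e-4) | (6e-4, 1e-7, 2e-11) | 6e-6 |
| `fig3_disease` | (..., -0.02, 65) | (..., 1e-4, 20) | 2e-5 |

The large/small individual-difference parameter sets and the two noise
levels are part of the same published simulation design; the presets
pair large differences with the large noise level and small differences
with the small one, and either entry can be overridden independently
(e.g. `ensemble_spec("fig2_large", noise_var = 2e-5)`, which the
disease-detection comparison uses so that healthy and diseased cohorts
share one noise level). The onset entry 20 in the disease preset is
read as a variance (onset SD ~ 4.5 years); the source is ambiguous
between variance and SD, and the variance reading keeps onsets tightly
clustered around 65 as depicted. Onset ages are not truncated to the
age range: an onset outside [20, 90] simply means the hinge is never
(or always) active.

Covariates are built as x_k = r * z(theta_k) + sqrt(1 - r^2) * e with
independent standard-normal e, so corr(x_k, theta_k) converges to the
target r; at r = 1 the covariate is exactly the standardized parameter.
The standardization z() uses the ensemble's *population* mean and SD
rather than the cohort's sample moments: independently simulated
cohorts then map parameters to covariates identically, which matters
when a model trained on one cohort scores another (sample-moment
standardization injects a small systematic covariate shift between
cohorts that is invisible at high noise but dominates delta when the
predictive uncertainty is tiny).

What the simulator does *not* emulate: spatial covariance between
voxels (the phantom writer adds independent voxel noise), longitudinal
designs, non-Gaussian noise, scanner batch structure beyond a binary
field-strength flag, and any real anatomy. Tests passing on these
cohorts demonstrate the statistical machinery — calibration of delta,
the advantage of informed covariates, detection ordering — not
performance on real MRI.

## What the validation computes

The test suite regenerates everything from code; the problem sizes are
chosen to keep a full run inside a few minutes while leaving the
Monte-Carlo tolerances meaningful:

- evidence values and gradients against a dense linear-algebra oracle
  and central finite differences (n <= 8);
- calibration: 10,000 held-out z-scores under a known generative GP
  (mean ~ 0, variance in [0.9, 1.1], 4–6% below the one-tailed 5%
  cut-off of -1.645);
- simulator moment recovery at n = 640 and the covariate-correlation
  sweep r in {0, 0.25, 0.5, 0.75, 1} against Fisher-z intervals;
- GP-vs-GLM test MAE on independent healthy ensembles (median over 20
  seeds, n = 640 train / 640 test, r = 0.75);
- post-onset detection AUC of delta versus the raw and age-corrected
  single-case t (median over 20 seeds at r in {0.75, 1}), with
  pre-onset groups age-matched below 50 years, where onset (mean 65,
  SD ~ 4.5) has essentially never occurred, because pre-onset subjects
  are mechanically younger than the healthy cohort at large;
- Box–Cox lambda recovery (lognormal -> ~0, normal -> ~1) and skewness
  reduction;
- the uncertainty profile over training sizes {40, 80, 160, 320, 640}:
  the across-subject SD of u falls with sample size while its mean
  moves comparatively little.

The GP fits inside the large simulation loops use a single optimizer
start: on these ensembles the evidence surface is well-behaved and the
default initialization converges to the same optimum as multi-restart
runs, at a third of the cost. The default for real data remains 3
restarts.

## Single-case baselines

For comparison the package implements the classical alternatives: the
sample z-score against control mean and SD; the single-case t,
t = (mean_c - y_p) / (s_c * sqrt(1/n + 1)), i.e. the two-sample pooled
t with group sizes (n, 1); and covariate-corrected variants that
residualize controls and patient with control-estimated GLM
coefficients before applying the t. ROC analysis uses the
midrank Mann–Whitney statistic; delta is negated before ROC so that
"larger score = more diseased" holds for every method. As the GP's
information vanishes (amplitude to 0), delta degenerates to the sample
z-score — the GP approach is a strict generalization that spends its
advantage only when covariates carry information.

## Known limitations

- Exact GP inference is O(n^3) per voxel; the intended regime is
  reference samples up to a few thousand subjects. No sparse
  approximations are provided.
- Voxels are modeled independently; no spatial regularization of
  hyperparameters or multiple-comparison control on NPMs is included.
- Disease-state priors for the naive-Bayes posterior are a required
  user input; the package has no opinion on their elicitation.
- The Box–Cox profile likelihood conditions on an intercept-only model;
  if strong covariate effects themselves induce skewness, lambda will
  partially absorb them.
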