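---
title: "Modelling the residual reserve index: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the residual reserve index: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Cognitive reserve is the hypothesised capacity that lets some people
sustain cognition despite brain ageing or pathology. The residual
approach operationalises it as the part of an episodic-memory composite
that brain structure and demographics cannot explain: memory is
decomposed into an orthogonal brain component (MEMB), a demographic
component (MEMD), a residual reserve component (MEMR), and fixed
measurement error. The analytical question `rrisem` is built around is
whether the protective effect of MEMR on executive-function (EF) change
differs by sex — a three-way MEMR x MEMB x sex moderation of the EF
intercept and slope — and whether any such difference depends on brain
amyloid burden (a four-way extension with Centiloid).

Participant-level data for this design are access-controlled, so the
package pairs the estimator with a synthetic-cohort generator that
reproduces the assumed statistical structure with known ("planted")
truth. Every stage is therefore testable end to end: simulate, describe,
decompose, fit growth curves, fit the joint moderation model, probe, and
recover the planted values.

# The models

## Stage 1 — memory decomposition

Three ICV-adjusted brain volumes (grey matter, hippocampus, white-matter
hyperintensities) are standardized in-stage and each measures a
single-indicator latent brain factor with error variance fixed at 0.10
(10% unreliability on the unit scale). The memory composite is regressed
simultaneously on the three brain latents (freely estimated weights, so
MEMB is their fitted linear combination), on observed
demographic/methodological covariates (education years, number of prior
assessments, the months containing them, their product, withdrawn and
deceased flags; MEMD is their fitted combination), and on a residual
latent MEMR with free variance. The memory error variance is fixed at
0.1365. MEMB, MEMD and MEMR are mutually orthogonal by construction, and
sex is deliberately *not* residualised out, so sex differences in
reserve remain visible in MEMR.

Two scale decisions are deliberate. First, the 0.1365 error is fixed on
the raw composite scale (the composite is already near unit variance, SD
about 0.91): fixing it after internally standardizing memory would force
the three free components to sum to 1 − 0.1365, a constraint the
construction does not imply, and would distort the free MEMR variance.
Second, only the brain indicators are standardized in-stage, which makes
all variance components invariant to affine rescaling of the raw
volumes.

Component scores: the MEMB score is the regression (posterior-mean)
combination of the brain latents given the indicators alone; the MEMR
score is the memory residual after subtracting the fitted demographic
part and that brain score. Because the brain score is a projection on
the indicators only, the residual is uncorrelated with it in the
population — the property the reserve index needs.

## Stage 2 — executive-function growth

EF composites at up to seven 18-month visits, T = −3..+3 anchored at the
first MRI, load on latent intercept and slope factors. Bases: intercept
all ones; linear T; quadratic adds T²; logarithmic sign(T)·ln(1+|T|),
chosen because pre-baseline visits make ln(T) undefined and the basis
must stay zero at T = 0 so the intercept keeps its meaning. The time
unit is one 18-month visit interval (slopes are per 18 months).
Residual variances are constrained equal across visits by default
(parsimony; a free-per-visit option exists). Form comparison fits all
requested bases by FIML on identical cases and applies the parsimony
rule: if every converged form is adequate (CFI ≥ 0.95, RMSEA ≤ 0.06,
SRMR ≤ 0.08), take the fewest parameters with BIC as tie-break,
otherwise the lowest BIC.

## Stage 3 — the joint moderation model

The decomposition, the linear growth curve and the structural
regressions are estimated simultaneously: EF intercept and slope are
regressed on MEMR, MEMB, MEMD, female sex, APOE e4 allele count
(numeric 0/1/2), age centred at 70, the sex-by-APOE control, and the
products MEMR x MEMB, MEMR x sex, MEMB x sex, MEMR x MEMB x sex (11
predictors per outcome; the amyloid extension adds Centiloid — entered
raw, uncentred — and all its interactions up to the four-way, 21
predictors per outcome). Observed covariates are conditioned on
(fixed-x). Coefficients are reported raw and standardized
(STDYX-style: each coefficient times SD(predictor)/SD(outcome), with
latent SDs from the fitted variances, observed moments from the
sample, and product-term moments from the normal-theory factorisation
of the orthogonal zero-mean latents).

# Estimation

All likelihoods are full-information ML: each subject contributes the
multivariate-normal density of its observed subvector, accumulated per
missing-data pattern from sufficient statistics (O(1) in n per
evaluation for linear models). Saturated (H1) models for the chi-square
use the same machinery; the CFI/TLI baseline is the independence model
with free means and variances.

Latent interactions make the marginal distribution non-normal, so the
joint model integrates over the two interacting latents numerically.
Two structural facts keep this exact and fast. First, conditional on
(MEMR, MEMB) the model is linear Gaussian and its conditional
covariance does not depend on the conditioning point, so the exponent
at every quadrature node is a degree-(2,2) polynomial in the node
coordinates: all subjects in a missing-data pattern are evaluated with
one matrix product against a shared 9-term node basis. Second, node
locations use per-subject adaptive recentring — the Gaussian posterior
of the latents under the linear part of the model, computed at a
reference parameter value and then held fixed — so the quadrature is
exact for Gaussian integrands and node-refinement converges fast (the
joint-model likelihood moves by ~1e-4 between 5 and 15 nodes per
dimension and ~1e-5 on further doubling; the one-latent
`marginal_loglik_interaction()` path, which recentres at the exact
per-subject mode, changes by less than 1e-6 when nodes double). Because
the node locations do not move with the parameters, the discretised
likelihood stays smooth with an exactly computable gradient.

The gradient is assembled analytically from posterior node moments: the
likelihood depends on the parameters only through a small set of
assembly matrices (means, covariate loadings, latent coefficient
vectors, the conditional covariance), whose Jacobian is closed-form for
the mean-side parameters and finite-differenced for the covariance-side
ones. The same machinery yields per-subject score vectors, giving both
a scores-based (OPG) information estimate and near-Newton
(Levenberg-damped Fisher scoring) optimisation steps at gradient cost;
BFGS and a scaled PORT pass serve as fallbacks. Variances are optimised
on the log scale and covariance blocks through Cholesky factors, so
implied matrices stay positive definite without clamping. Convergence
is declared when the relative gradient max-norm (max |g| / max(1,
|logL|)) falls below 1e-5 for the linear engine and 1e-4 for the joint
model; relative log-likelihood tolerances are 1e-10 and 1e-9. Starting
values are closed-form method-of-moments/two-stage values (indicator
moments, OLS of memory on covariates and indicators corrected for the
fixed unreliability, per-subject least-squares growth summaries, and
the factor-score regression for the structural block), which makes
convergence reproducible.

Standard errors come from the inverse observed information
(finite-differenced analytic gradient) by default; the scores-based
(OPG) estimate is available for Monte-Carlo loops. A caveat found while
calibrating the package: at small n (a few hundred) the OPG estimate
overstates the three-way coefficient's SE by ~40%, making its Wald test
severely conservative, so calibration experiments use the observed
information. Two-sided normal p-values on est/SE are reported
throughout; no multiplicity adjustment is applied.

# Fit statistics

Chi-square is 2(LL_sat − LL_model) with df the parameter-count gap;
CFI and TLI use the independence baseline (TLI reported uncapped);
RMSEA uses sqrt(max(chi2 − df, 0)/(df·(n−1))) with a 90% CI by
bisection inversion of the noncentral chi-square CDF to 1e-8 (an
`n_convention = "n"` switch exists because software conventions
differ); SRMR is the root mean square of the SD-standardized residual
variances and covariances; AIC/BIC are standard and aBIC substitutes
(n+2)/24 for n.

# The synthetic cohort

The generator draws baseline covariates from the configured marginals
(defaults: n = 997, 55.4% female, APOE counts 65.1/29.2/5.7%, age
72.79 (6.60), sex-specific education 13.33 (3.18) male / 12.63 (2.95)
female, prior-assessment exposure with mean 2.34 visits over a
right-skewed months interval, Centiloid as a shifted gamma with mean
28.78 and SD 42.83), correlated brain latents on the standardized scale
with 10% indicator unreliability, and the memory composite as
MEMB + MEMD + MEMR + N(0, 0.1365) with component variances 0.25, ~0.11
and 0.30 (total variance ~0.83, matching a composite SD near 0.91). EF
intercept and slope are built from planted standardized coefficients —
the full published coefficient structure by default, including −0.190
(intercept) and −0.069 (slope) on the three-way term — converted to raw
scale through predictor moments estimated once by large-n Monte Carlo,
with total intercept/slope variances 0.70 and 0.02, residual
correlation −0.2, and per-visit EF residual variance 0.057. Attrition
is a per-visit withdrawal hazard (logit loadings on the standardized
intercept/slope deviations) plus a death hazard with a male multiplier,
giving monotone dropout, roughly 28%/5% withdrawn/deceased and about
5 visits per subject.

Two configurations are canonical. The default emulates the reference
cohort's descriptives, including features that sit *outside* the
estimation model family: a female MEMR advantage (a sex shift the model
deliberately leaves in the residual), a lognormal WMH marginal, and
informative dropout. `model_faithful = TRUE` zeroes these. Recovery and
type-I experiments use the faithful configuration because a
parametric-bootstrap study must generate from the fitted model family;
the realism features exist to exercise descriptives and to document
robustness, not to define the recovery estimand. In particular,
informative dropout that loads on the growth deviations makes the
withdrawn/deceased flags — which are MEMD regressors — endogenous and
biases the MEMD slope coefficient by about +0.05 standardized. That is
a real property of such designs (it is why those flags are included as
regressors at all), and a known limitation of what passing recovery
tests demonstrate: they validate the estimator under the model's
missing-at-random assumptions, not under latent-dependent dropout.
Other real-data features the generator does not emulate: item-level
test structure, diagnosis strata, tau or longitudinal amyloid, and
non-normal EF residuals.

# Problem sizes used by the test suite and acceptance script

Monte-Carlo sizes are chosen to keep statistical resolution while
staying affordable: decomposition recovery at n = 5000 over 50
replicates; joint-model recovery at n = 997 over 50 replicates with 7
quadrature nodes per dimension; type-I calibration of the three-way
slope test over 400 replicates at n = 300 with 5 nodes; growth-form
selection over 50 replicates at n = 997. Coverage is assessed pooled
across the structural parameters (per-parameter coverage at 50
replicates carries about ±0.04 binomial noise). The acceptance script
re-runs the same machinery at reduced replicate counts and also
reports the engine identities (FIML sufficient-statistic equality, the
hand-derived missing-data marginal, quadrature degeneracy and
node-refinement) computed from scratch.

# Numerical choices and degenerate inputs

Variance parameters live on the log scale with a floor of exp(−18); a
variance estimated at that boundary is reported with a warning rather
than treated as aliasing. Non-positive-definite implied covariances
during optimisation return a large finite barrier so line searches back
off. Identification is checked by the rank of the information matrix at
the optimum; rank-deficient directions dominated by boundary variances
are warnings, anything else is an error naming the aliased labels.
Single-sex cohorts are rejected by the joint model (sex terms would be
aliased); factor sign indeterminacy does not arise because brain
indicator loadings are fixed at 1 and weights are regressions, not
rotations. Empty observed subvectors contribute zero to the likelihood
with a warning.

# Open design choices resolved here

The interaction set follows the published coefficient tables (MEMB in
all latent products, MEMD in none). APOE enters as an allele count, not
dummies. Centiloid enters raw. Binary covariates are standardized by
their SDs (STDYX) by default, with an option to leave them raw. Months
between first assessment and first MRI enters untransformed. The
general `marginal_loglik_interaction()` path integrates one latent
(covering products of that latent with observed moderators or one other
linear variable); the joint model's two-latent marginalisation is
implemented by its own structured path, and the two agree on their
common ground (a test checks the structured path against the
closed-form linear reduction and node-refinement).
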