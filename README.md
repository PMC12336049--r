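# rrisem

Residual reserve index structural equation modelling for longitudinal
cognitive-ageing cohorts.

## The problem

Cognitive reserve — the capacity that lets some people sustain cognition
despite brain ageing or pathology — can be operationalised as a
*residual*: the part of an episodic-memory composite that brain
structure and demographics cannot explain. `rrisem` implements that
construction and the longitudinal analysis built on it, for
biostatisticians and cognitive-ageing researchers who want the full
pipeline as tested, reusable code:

1. **Decomposition.** The memory composite is split into orthogonal
   latent components,

   `mem = MEMB + MEMD + MEMR + e,  Var(e) = 0.1365 (fixed)`,

   where MEMB is a freely weighted combination of three latent brain
   factors (grey-matter, hippocampal and white-matter-hyperintensity
   volumes, each measured with error variance fixed at 0.10 on the
   standardized scale), MEMD is a linear combination of demographic and
   methodological covariates, and MEMR — the residual reserve index —
   is the free-variance residual.

2. **Growth.** Executive function over up to seven 18-month visits
   (T = −3..+3 around the first MRI) follows a latent growth curve;
   linear, quadratic and logarithmic time bases are compared with a
   full fit battery (chi-square, CFI, TLI, RMSEA with 90% CI, SRMR,
   AIC/BIC/aBIC) under full-information maximum likelihood.

3. **Moderation.** EF intercept and slope are regressed jointly on
   MEMR, MEMB, MEMD, sex, APOE e4 count, centred age and all their
   2-/3-way products (optionally the Centiloid amyloid extension up to
   the four-way MEMR x MEMB x sex x Abeta). The latent MEMR x MEMB
   product is marginalised with per-subject-adaptive Gauss-Hermite
   quadrature; the key test is the three-way MEMR x MEMB x sex term,
   probed with simple slopes and model-predicted trajectory grids.

Because the motivating participant-level data are access-controlled,
the package ships a synthetic-cohort generator with planted truth
(realistic marginals, informative attrition, known standardized
structural effects), so every stage is verifiable by parameter-recovery
simulation.

## Worked example

```r
library(rrisem)

cfg <- generator_config(seed = 1, model_faithful = TRUE)  # n = 997
cohort <- generate_cohort(cfg)
cohort
#> cohort: 997 subjects, 5257 EF observations over T in {-3..3} (18-month visits)
#>   female: 57.0%; withdrawn: 27.0%; deceased: 3.7%
#>   planted truth attached

dec <- decompose(cohort, se = "none")
variance_table(dec)
#>   component variance share
#> 1      memb    0.243 0.291
#> 2      memd    0.161 0.193
#> 3      memr    0.295 0.353
#> 4     error    0.137 0.163
```

The variance column is on the memory-composite scale: here about 35% of
memory variance is residual reserve, 29% brain, 19% demographic, and
16% the fixed measurement error (planted component variances: 0.25,
~0.11, 0.30).

```r
cmp <- compare_growth_forms(cohort)
cmp$selected
#> [1] "linear"

fit <- fit_analytical(cohort, nodes = 15)
test_threeway(fit)[, c("outcome", "est", "se", "z", "p", "std")]
#>      outcome     est     se     z        p     std
#> 11 intercept -0.9339 0.1583 -5.90 3.65e-09 -0.2270
#> 22     slope  0.0597 0.0453  1.32 1.88e-01  0.0869
```

The planted standardized three-way values are −0.190 (intercept) and
−0.069 (slope); a single cohort estimates them with standard errors of
roughly 0.04 and 0.07 on the standardized scale, so the intercept term
is recovered well here while the slope term is dominated by sampling
noise — which is exactly what `recovery_experiment()` quantifies: over
50 replicate cohorts at n = 997 the maximum absolute bias across all 22
structural coefficients is 0.012 standardized with pooled 95% CI
coverage of 0.95. The probing surface comes from `simple_slopes(fit)`
and `predict_trajectories(fit)` (predicted EF at T = −3..+3 for each
sex by MEMB-level by MEMR-level cell at −1/0/+1 SD under a reference
profile). `run_pipeline()` chains all stages from one configuration and
writes tidy CSV/JSON outputs; `render_report()` produces a markdown
summary.

## Scope

The package consumes composite scores and ICV-adjusted volumes as
numbers; image processing, PET quantification, item-level test
harmonisation and clinical diagnosis are out of scope.
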