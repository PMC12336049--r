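# Synthetic cohort: configuration validation, planted structure,
# reproducibility, attrition behaviour.

test_that("configuration invariants are enforced", {
  expect_error(generator_config(apoe_probs = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(generator_config(n_subjects = 0), "n_subjects")
  expect_error(generator_config(prop_female = 1.2), "prop_female")
  expect_error(generator_config(age_sd = 0), "sds")
  expect_error(attrition_config(base_dropout_hazard = 1.2), ".")
  expect_error(planted_truth(brain_corr = matrix(c(1, 2, 2, 1, 1, 1,
                                                   2, 1, 1), 3, 3)),
               "positive definite")
})

test_that("setting the seed reproduces the cohort bit-for-bit", {
  cfg <- generator_config(n_subjects = 120, seed = 99)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$baseline, c2$baseline)
  expect_identical(c1$visits, c2$visits)
  c3 <- generate_cohort(generator_config(n_subjects = 120, seed = 100))
  expect_false(identical(c1$visits, c3$visits))
})

test_that("baseline marginals track the configured values", {
  co <- generate_cohort(generator_config(n_subjects = 997, seed = 12))
  b <- co$baseline
  # Centiloid sample mean within 3 SE of the configured 28.78 (42.83)
  expect_lt(abs(mean(b$centiloid) - 28.78), 3 * 42.83 / sqrt(997))
  expect_lt(abs(mean(b$age_first_mri) - 72.79), 3 * 6.60 / sqrt(997))
  expect_lt(abs(mean(b$sex_female) - 552 / 997), 3 * 0.5 / sqrt(997))
  # WMH marginal is right-skewed (SD of the same order as the mean)
  expect_gt(sd(b$wmh_vol) / mean(b$wmh_vol), 0.8)
  # male death exceeds female death in expectation
  big <- generate_cohort(generator_config(n_subjects = 8000, seed = 5))
  expect_gt(mean(big$baseline$deceased[big$baseline$sex_female == 0]),
            mean(big$baseline$deceased[big$baseline$sex_female == 1]))
})

test_that("sample moments converge to the configured marginals at root-n rate", {
  err <- sapply(c(500, 8000), function(n) {
    co <- generate_cohort(generator_config(n_subjects = n, seed = 31))
    b <- co$baseline
    abs(mean(b$education_years) -
          (13.33 * 445 / 997 + 12.63 * 552 / 997))
  })
  expect_lt(err[2], err[1] + 0.05)
  expect_lt(err[2], 3.1 / sqrt(8000) * 3)
})

test_that("planted MEMR is orthogonal to MEMB and MEMD", {
  co <- generate_cohort(generator_config(n_subjects = 6000,
                                         model_faithful = TRUE, seed = 41))
  tr <- co$truth
  n <- length(tr$memr)
  expect_lt(abs(cor(tr$memr, tr$memb)), 3 / sqrt(n))
  expect_lt(abs(cor(tr$memr, tr$memd)), 3 / sqrt(n))
})

test_that("zero effects and zero noise give flat identical trajectories", {
  tr0 <- planted_truth(zero = TRUE,
                       ef_intercept_var = 1e-12, ef_slope_var = 1e-12,
                       ef_residual_var_per_visit = 1e-12,
                       ef_slope_mean = 0, memr_sex_shift = 0)
  cfg <- generator_config(n_subjects = 60, planted = tr0,
                          attrition = attrition_config(
                            base_dropout_hazard = 0, death_prob = 0),
                          seed = 8)
  co <- generate_cohort(cfg)
  # every EF value equals the common intercept: flat and identical
  expect_lt(max(abs(co$visits$ef - tr0$ef_intercept_mean)), 1e-4)
  # and with a nonzero mean slope, trajectories are exactly linear in T
  tr1 <- planted_truth(zero = TRUE,
                       ef_intercept_var = 1e-12, ef_slope_var = 1e-12,
                       ef_residual_var_per_visit = 1e-12,
                       memr_sex_shift = 0)
  co1 <- generate_cohort(generator_config(n_subjects = 40, planted = tr1,
                                          attrition = attrition_config(
                                            base_dropout_hazard = 0,
                                            death_prob = 0),
                                          seed = 9))
  pred <- tr1$ef_intercept_mean + tr1$ef_slope_mean * co1$visits$T
  expect_lt(max(abs(co1$visits$ef - pred)), 1e-4)
})

test_that("large-n regression on true latents recovers a planted slope effect", {
  # average over independent draws: the three-way collinearity inflates
  # the partialled OLS variance, so a single draw is too noisy for the
  # +/- 0.005 check
  bhats <- sapply(0:2, function(k) {
    cfg <- generator_config(n_subjects = 100000, model_faithful = TRUE,
                            attrition = attrition_config(
                              base_dropout_hazard = 0, death_prob = 0),
                            seed = 77 + k)
    co <- generate_cohort(cfg)
    tr <- co$truth
    b <- co$baseline
    des <- list(memr = tr$memr, memb = tr$memb, memd = tr$memd,
                female = b$sex_female, apoe = b$apoe4_count,
                age_c = b$age_first_mri - 70)
    X <- rrisem:::structural_design(des, rrisem:::base_terms())
    coef(lm(tr$slope ~ X))[["Xmemr"]] * sd(tr$memr) / sqrt(0.02)
  })
  expect_lt(abs(mean(bhats) - 0.028), 0.005)
})

test_that("truth_report echoes the planted standardized effects in table order", {
  rep1 <- truth_report(generator_config())
  expect_equal(nrow(rep1), 22)
  expect_equal(rep1$est[rep1$outcome == "slope" &
                          rep1$term == "memr:memb:female"], -0.069)
  expect_equal(rep1$est[rep1$outcome == "intercept" &
                          rep1$term == "memr:memb:female"], -0.190)
  rep0 <- truth_report(generator_config(planted = planted_truth(zero = TRUE)))
  expect_true(all(rep0$est == 0))
  # round-trip: large-n OLS on the true latents matches the report
  cfg <- generator_config(n_subjects = 200000, model_faithful = TRUE,
                          attrition = attrition_config(
                            base_dropout_hazard = 0, death_prob = 0),
                          seed = 55)
  co <- generate_cohort(cfg)
  tr <- co$truth; b <- co$baseline
  des <- list(memr = tr$memr, memb = tr$memb, memd = tr$memd,
              female = b$sex_female, apoe = b$apoe4_count,
              age_c = b$age_first_mri - 70)
  X <- rrisem:::structural_design(des, rrisem:::base_terms())
  sdX <- apply(X, 2, sd)
  bI <- coef(lm(tr$intercept ~ X))[-1] * sdX / sqrt(0.70)
  planted <- rep1$est[rep1$outcome == "intercept"]
  expect_lt(max(abs(unname(bI) - planted)), 0.01)
})

test_that("attrition is monotone, flag-consistent, and slope-linked", {
  cfg <- generator_config(n_subjects = 4000, seed = 3,
                          attrition = attrition_config(
                            base_dropout_hazard = 0, death_prob = 0))
  co <- generate_cohort(cfg)
  # no attrition: full window observed
  expect_true(all(co$truth$drop_after == 3))
  att <- attrition_config(base_dropout_hazard = 0.15, hazard_slope = -1.5,
                          death_prob = 0.01)
  co2 <- apply_attrition(co, att, seed = 9)
  # monotone: no gaps after dropout
  agg <- aggregate(T ~ id, co2$visits, max)
  expect_true(all(agg$T == co2$truth$drop_after[agg$id]))
  # negative slope loading: longer follow-up for faster decliners removed
  nv <- table(factor(co2$visits$id, levels = co2$baseline$id))
  expect_gt(cor(as.numeric(nv), co2$truth$slope), 0)
  # flags consistent: dropouts before the last visit are withdrawn or dead
  dropped <- co2$truth$drop_after < 3
  expect_true(all((co2$baseline$withdrawn | co2$baseline$deceased)[dropped]))
  # identity under zero hazards
  co3 <- apply_attrition(co, attrition_config(base_dropout_hazard = 0,
                                              death_prob = 0), seed = 9)
  expect_identical(co3$visits, co$visits)
})
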