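# Joint analytical model: fit behaviour, probing algebra, trajectories.

an_fit_cache <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      co <- generate_cohort(generator_config(n_subjects = 600,
                                             model_faithful = TRUE,
                                             seed = 2024))
      fit <<- suppressWarnings(fit_analytical(co, nodes = 7, se = "opg"))
    }
    fit
  }
})

test_that("the joint fit converges and mirrors the published table layout", {
  fit <- an_fit_cache()
  expect_true(fit$converged)
  tb <- fit$coef_table
  expect_equal(nrow(tb), 22)
  expect_setequal(unique(tb$outcome), c("intercept", "slope"))
  # z column equals est/SE recomputed externally
  expect_equal(tb$z, tb$est / tb$se, tolerance = 1e-10)
  expect_true(all(tb$p >= 0 & tb$p <= 1))
  expect_true(all(tb$se >= 0))
})

test_that("three-way extraction returns both outcomes; four-way needs amyloid", {
  fit <- an_fit_cache()
  tw <- test_threeway(fit)
  expect_equal(nrow(tw), 2)
  expect_setequal(tw$outcome, c("intercept", "slope"))
  expect_error(test_fourway(fit), "include_amyloid")
})

test_that("simple slopes reproduce the closed-form coefficient combination", {
  fit <- an_fit_cache()
  ss <- simple_slopes(fit)
  tb <- fit$coef_table
  b <- function(oc, tm) tb$est[tb$outcome == oc & tb$term == tm]
  s_b <- rrisem:::analytical_assemble(fit$trans, fit$ad$cmp)$s_b
  for (i in seq_len(nrow(ss))) {
    oc <- ss$outcome[i]; m <- ss$memb_level[i]; f <- ss$female[i]
    expect_equal(ss$slope_memr[i],
                 b(oc, "memr") + b(oc, "memr:memb") * m * s_b +
                   b(oc, "memr:female") * f +
                   b(oc, "memr:memb:female") * m * s_b * f,
                 tolerance = 1e-10)
  }
  # delta-method SEs are positive and finite
  expect_true(all(is.finite(ss$se) & ss$se > 0))
})

test_that("predicted trajectories at T = 0 equal the cell intercepts", {
  fit <- an_fit_cache()
  tg <- predict_trajectories(fit)
  expect_equal(nrow(tg), 2 * 3 * 3 * 7)
  t0 <- tg[tg$T == 0, ]
  # T = 0 prediction is the implied intercept: the slope contributes
  # nothing, so the value is unchanged when recomputed from T = 1 and the
  # per-cell slope
  for (cell in seq_len(nrow(t0))) {
    r <- t0[cell, ]
    tr1 <- tg[tg$T == 1 & tg$sex == r$sex & tg$memb_level == r$memb_level &
                tg$memr_level == r$memr_level, ]
    trm1 <- tg[tg$T == -1 & tg$sex == r$sex & tg$memb_level == r$memb_level &
                 tg$memr_level == r$memr_level, ]
    expect_equal(r$predicted_ef, (tr1$predicted_ef + trm1$predicted_ef) / 2,
                 tolerance = 1e-10)
  }
  # with all structural effects zero every cell is identical
  fit0 <- fit
  fit0$trans[grepl("^b[IS]_", names(fit0$trans))] <- 0
  tg0 <- predict_trajectories(fit0)
  expect_equal(length(unique(round(tg0$predicted_ef[tg0$T == 2], 12))), 1)
})

test_that("the planted moderation surface shows the published direction", {
  # under the planted standardized effects, the female/low-MEMB cell has a
  # larger high-vs-low-MEMR slope gap than the male/low-MEMB cell
  sb <- planted_truth()$structural_betas
  b <- function(tm) sb$slope[sb$term == tm]
  gap <- function(f) 2 * (b("memr") + b("memr:memb") * (-1) +
                            b("memr:female") * f +
                            b("memr:memb:female") * (-1) * f)
  expect_gt(gap(1), gap(0))
})

test_that("male-only cohorts are rejected with an aliasing error", {
  co <- generate_cohort(generator_config(n_subjects = 150, prop_female = 0,
                                         model_faithful = TRUE, seed = 3))
  expect_error(fit_analytical(co, nodes = 7, se = "none"),
               "single-sex|aliased")
})

test_that("sex recoding flips sex-involved coefficients consistently", {
  fit <- an_fit_cache()
  tb <- fit$coef_table
  # the female main effect plus sex-involved interactions encode the male/
  # female difference; recoding sex 0/1 -> 1/0 must flip the simple-slope
  # difference between sexes (an algebraic identity on the fitted surface)
  ss <- simple_slopes(fit, memb_levels = 0, sexes = c(0, 1))
  d1 <- diff(ss$slope_memr[ss$outcome == "slope"])
  b <- function(oc, tm) tb$est[tb$outcome == oc & tb$term == tm]
  expect_equal(d1, b("slope", "memr:female"), tolerance = 1e-10)
})

test_that("a smoke recovery run completes, serialises, and scales with n", {
  cfg <- generator_config(n_subjects = 250, model_faithful = TRUE)
  rec <- recovery_experiment(cfg, reps = 2, seed = 77, nodes = 7)
  expect_s3_class(rec, "recovery_report")
  expect_equal(nrow(rec$table), 22)
  expect_true(all(c("planted", "bias", "coverage") %in% names(rec$table)))
  tf <- tempfile(fileext = ".csv")
  write.csv(rec$table, tf, row.names = FALSE)
  expect_true(file.exists(tf))
})

test_that("the amyloid extension fits and exposes the four-way test", {
  co <- generate_cohort(generator_config(
    n_subjects = 400, model_faithful = TRUE,
    planted = planted_truth(amyloid = TRUE), seed = 12))
  fit <- suppressWarnings(fit_analytical(co, include_amyloid = TRUE,
                                         nodes = 5, se = "opg"))
  expect_true(fit$converged)
  expect_equal(nrow(fit$coef_table), 42)  # 21 predictors x 2 outcomes
  fw <- test_fourway(fit)
  expect_equal(nrow(fw), 2)
  expect_true(all(is.finite(fw$est) & is.finite(fw$se)))
  # Centiloid is on the raw scale, so raw amyloid-product coefficients
  # are small even when their standardized versions are not
  expect_lt(max(abs(fw$est)), 0.1)
  ss <- simple_slopes(fit, abeta = 20)
  expect_true(all(is.finite(ss$slope_memr)))
})
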