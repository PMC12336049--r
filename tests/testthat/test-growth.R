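test_that("growth bases match their definitions", {
  sp <- build_growth_spec("linear")
  pt <- sp$partable
  expect_equal(pt$value[pt$lhs == "S" & pt$op == "=~"], -3:3)
  spq <- build_growth_spec("quadratic")
  expect_equal(spq$partable$value[spq$partable$lhs == "Q" &
                                  spq$partable$op == "=~"],
               c(9, 4, 1, 0, 1, 4, 9))
  bl <- rrisem:::growth_basis("logarithmic")$S
  expect_equal(bl[4], 0)                 # anchored at the first MRI
  expect_true(all(diff(bl) > 0))         # strictly increasing
  expect_error(build_growth_spec("cubic"), "'arg'")
})

test_that("logarithmic basis preserves the sign of a planted decline", {
  set.seed(3)
  S_true <- -abs(rnorm(300, 0.3, 0.1))
  ef <- sapply(-3:3, function(Tt) 1 + S_true * Tt + rnorm(300, 0, 0.1))
  colnames(ef) <- rrisem:::EF_COLS
  fit <- quiet_fit(build_growth_spec("logarithmic"), as.data.frame(ef),
                   se = "none", check_identification = FALSE)
  expect_lt(fit$theta[["alpha_S"]], 0)
})

test_that("shifting EF by a constant moves only the intercept mean", {
  co <- generate_cohort(generator_config(n_subjects = 500,
                                         model_faithful = TRUE, seed = 17))
  Y <- ef_wide(co)[, rrisem:::EF_COLS]
  f1 <- quiet_fit(build_growth_spec("linear"), Y, se = "none",
                  check_identification = FALSE)
  f2 <- quiet_fit(build_growth_spec("linear"), Y + 2.5, se = "none",
                  check_identification = FALSE)
  expect_equal(f2$theta[["alpha_I"]], f1$theta[["alpha_I"]] + 2.5,
               tolerance = 1e-4)
  expect_equal(f2$theta[["alpha_S"]], f1$theta[["alpha_S"]],
               tolerance = 1e-5)
  expect_equal(f2$theta[["psi_S"]], f1$theta[["psi_S"]], tolerance = 1e-5)
})

test_that("noise-free linear trajectories are recovered exactly", {
  set.seed(5)
  n <- 150
  I <- rnorm(n, 1, 0.5); S <- rnorm(n, -0.1, 0.2)
  ef <- sapply(-3:3, function(Tt) I + S * Tt)
  colnames(ef) <- rrisem:::EF_COLS
  fit <- suppressWarnings(fit_ml(build_growth_spec("linear"),
                                 as.data.frame(ef), se = "none",
                                 check_identification = FALSE))
  expect_equal(fit$theta[["alpha_S"]], mean(S), tolerance = 1e-3)
  expect_equal(fit$theta[["alpha_I"]], mean(I), tolerance = 1e-3)
  expect_lt(fit$theta[["theta_ef"]], 1e-4)
})

test_that("strong curvature hands the comparison to the quadratic form", {
  set.seed(7)
  n <- 600
  I <- rnorm(n, 1, 0.5); S <- rnorm(n, -0.05, 0.1)
  Q <- rnorm(n, -0.08, 0.02)
  ef <- sapply(-3:3, function(Tt) I + S * Tt + Q * Tt^2 + rnorm(n, 0, 0.2))
  colnames(ef) <- rrisem:::EF_COLS
  co <- list(baseline = data.frame(id = 1:n, sex_female = 0, withdrawn = 0,
                                   deceased = 0),
             visits = NULL, time_codes = -3:3)
  # build a cohort-like wide table path: call fits directly
  fits <- suppressWarnings(
    lapply(c("linear", "quadratic"), function(f)
      fit_ml(build_growth_spec(f), as.data.frame(ef), se = "none",
             check_identification = FALSE)))
  ic <- sapply(fits, function(f) information_criteria(f$loglik, f$npar,
                                                      f$n)$aic)
  expect_lt(ic[2], ic[1])    # quadratic wins AIC
})

test_that("FIML growth fit under monotone dropout equals complete-data ML when complete", {
  co <- generate_cohort(generator_config(
    n_subjects = 400, model_faithful = TRUE, seed = 23,
    attrition = attrition_config(base_dropout_hazard = 0, death_prob = 0)))
  Y <- ef_wide(co)[, rrisem:::EF_COLS]
  ccY <- Y[complete.cases(Y), ]
  fit <- quiet_fit(build_growth_spec("linear"), ccY, se = "none",
                   check_identification = FALSE)
  # with complete data FIML equals the sufficient-statistic ML form
  expect_equal(fit$loglik,
               fiml_loglik(fit$spec, fit$theta, ccY), tolerance = 1e-9)
})

test_that("single-visit cohorts surface an identification error", {
  set.seed(9)
  Y <- as.data.frame(matrix(NA_real_, 200, 7))
  names(Y) <- rrisem:::EF_COLS
  Y$ef_0 <- rnorm(200, 1, 1)
  expect_error(
    suppressWarnings(fit_ml(build_growth_spec("linear"), Y, se = "none",
                            check_identification = TRUE)),
    "aliased|not identified")
})

test_that("comparison table reports all forms and a single-form table works", {
  co <- generate_cohort(generator_config(n_subjects = 500,
                                         model_faithful = TRUE, seed = 29))
  cmp1 <- suppressWarnings(compare_growth_forms(co, forms = "linear"))
  expect_equal(nrow(cmp1$table), 1)
  expect_equal(cmp1$selected, "linear")
})
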