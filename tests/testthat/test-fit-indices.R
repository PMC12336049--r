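test_that("chi-square, CFI/TLI, RMSEA, SRMR and ICs match their closed forms", {
  # chi2 arithmetic and clipping
  cs <- chi_square(-105, -100, 5, 10)
  expect_equal(cs$chi2, 10); expect_equal(cs$df, 5)
  expect_warning(cs0 <- chi_square(-99, -100, 5, 10), "clipped")
  expect_equal(cs0$chi2, 0)
  expect_error(chi_square(-100, -100, 12, 10), "df")
  # CFI/TLI worked case
  ct <- cfi_tli(10, 5, 110, 10)
  expect_equal(ct$cfi, 0.95, tolerance = 1e-12)
  expect_equal(ct$tli, 0.9, tolerance = 1e-12)
  expect_equal(cfi_tli(5, 5, 110, 10)$cfi, 1)
  expect_error(cfi_tli(10, 5, 110, 0), "baseline")
  # RMSEA point (n-1 denominator)
  rm <- rmsea(20, 10, 101)
  expect_equal(rm$rmsea, 0.1, tolerance = 1e-12)
  expect_equal(rmsea(8, 10, 101)$rmsea, 0)
  expect_lte(rm$lo, rm$hi)
  expect_equal(rmsea(20, 10, 100, n_convention = "n")$rmsea, 0.1,
               tolerance = 1e-12)
  # SRMR closed forms
  S <- diag(2); M <- diag(2)
  expect_equal(srmr(S, M), 0)
  M2 <- matrix(c(1, 0.25, 0.25, 1), 2)
  expect_equal(srmr(S, M2), sqrt(0.25^2 / 3), tolerance = 1e-12)
  # information criteria by hand
  ic <- information_criteria(-100, 3, 100)
  expect_equal(ic$aic, 206)
  expect_equal(ic$bic, 200 + 3 * log(100), tolerance = 1e-12)
  expect_equal(ic$abic, 200 + 3 * log(102 / 24), tolerance = 1e-12)
  expect_equal(information_criteria(0, 0, 50),
               list(aic = 0, bic = 0, abic = 0))
  # AIC < BIC whenever n >= 8
  for (n in c(8, 20, 1000)) {
    icn <- information_criteria(-10, 4, n)
    expect_lt(icn$aic, icn$bic)
  }
})

test_that("RMSEA CI endpoints invert the noncentral chi-square CDF", {
  rm <- rmsea(40, 15, 201)
  # the endpoints must satisfy the defining tail probabilities
  lam_lo <- rm$lo^2 * 15 * 200
  lam_hi <- rm$hi^2 * 15 * 200
  expect_equal(pchisq(40, 15, ncp = lam_lo), 0.95, tolerance = 1e-6)
  expect_equal(pchisq(40, 15, ncp = lam_hi), 0.05, tolerance = 1e-6)
  # Monte-Carlo: simulated noncentral chi-square mass at the endpoint
  set.seed(9)
  draws <- rchisq(2e5, df = 15, ncp = lam_hi)
  expect_lt(abs(mean(draws <= 40) - 0.05), 0.005)
  draws_lo <- rchisq(2e5, df = 15, ncp = lam_lo)
  expect_lt(abs(mean(draws_lo <= 40) - 0.95), 0.005)
})

test_that("chi-square is calibrated under the true model", {
  set.seed(17)
  reps <- 60
  chis <- numeric(reps)
  for (r in seq_len(reps)) {
    n <- 150
    f <- rnorm(n)
    Y <- data.frame(y1 = f + rnorm(n, 0, sqrt(0.3)),
                    y2 = 0.8 * f + rnorm(n, 0, sqrt(0.3)),
                    y3 = 0.6 * f + rnorm(n, 0, sqrt(0.3)),
                    y4 = 0.7 * f + rnorm(n, 0, sqrt(0.3)))
    sp <- one_factor_spec(loadings = c(1, 0.8, 0.6, 0.7), free = TRUE)
    fit <- suppressWarnings(quiet_fit(sp, Y, se = "none",
                                      check_identification = FALSE))
    chis[r] <- fit_stats(fit)$chi2_model
  }
  # 14 distinct moments, 12 free parameters -> df = 2
  df <- 2
  expect_equal(mean(chis), df, tolerance = 3 * sqrt(2 * df / reps) / df + 0.1)
})

test_that("fit battery on a growth fit behaves like a well-fitting model", {
  co <- generate_cohort(generator_config(n_subjects = 600,
                                         model_faithful = TRUE, seed = 13))
  fit <- quiet_fit(build_growth_spec("linear"), ef_wide(co)[, rrisem:::EF_COLS],
                   se = "none", check_identification = FALSE)
  fs <- fit_stats(fit)
  expect_gt(fs$cfi, 0.97)
  expect_lt(fs$rmsea, 0.05)
  expect_lt(fs$srmr, 0.08)
  expect_true(fs$rmsea_ci90[1] <= fs$rmsea_ci90[2])
  # AIC/BIC ranking invariance to a constant LL shift
  ic1 <- information_criteria(fit$loglik, fit$npar, fit$n)
  ic2 <- information_criteria(fit$loglik + 100, fit$npar + 1, fit$n)
  ic1b <- information_criteria(fit$loglik + 5, fit$npar, fit$n)
  ic2b <- information_criteria(fit$loglik + 105, fit$npar + 1, fit$n)
  expect_equal(ic1$bic - ic2$bic, ic1b$bic - ic2b$bic, tolerance = 1e-9)
})
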