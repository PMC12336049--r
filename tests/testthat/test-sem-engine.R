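# Core engine: implied moments, FIML, fitting, SEs, standardization,
# factor scores.

test_that("implied moments reproduce closed forms", {
  # single observed = single latent, loading 1, var 1, no error
  pt <- rbind(pr_row("f", "=~", "y1", FALSE, 1),
              pr_row("f", "~~", "f", FALSE, 1),
              pr_row("y1", "~~", "y1", FALSE, 0))
  sp <- model_spec("y1", "f", pt)
  im <- implied_moments(sp, setNames(numeric(0), character(0)))
  expect_equal(unname(im$sigma), matrix(1), tolerance = 1e-12)
  # two-indicator factor: lambda = (1,1), psi = 1, theta = 0.1
  sp2 <- one_factor_spec(loadings = c(1, 1), psi = 1, theta = c(0.1, 0.1))
  im2 <- implied_moments(sp2, setNames(numeric(0), character(0)))
  expect_equal(unname(im2$sigma), matrix(c(1.1, 1, 1, 1.1), 2),
               tolerance = 1e-12)
})

test_that("implied covariance of a recursive 6-variable spec matches simulation", {
  set.seed(1)
  n <- 200000
  f1 <- rnorm(n); f2 <- 0.5 * f1 + rnorm(n, 0, sqrt(0.75))
  Y <- cbind(y1 = f1 + rnorm(n, 0, 0.4), y2 = 0.7 * f1 + rnorm(n, 0, 0.4),
             y3 = 0.6 * f1 + rnorm(n, 0, 0.4), y4 = f2 + rnorm(n, 0, 0.4),
             y5 = 0.8 * f2 + rnorm(n, 0, 0.4),
             y6 = 0.5 * f2 + rnorm(n, 0, 0.4))
  pt <- rbind(
    pr_row(rep("f1", 3), "=~", c("y1", "y2", "y3"), FALSE, c(1, 0.7, 0.6)),
    pr_row(rep("f2", 3), "=~", c("y4", "y5", "y6"), FALSE, c(1, 0.8, 0.5)),
    pr_row("f2", "~", "f1", FALSE, 0.5),
    pr_row("f1", "~~", "f1", FALSE, 1),
    pr_row("f2", "~~", "f2", FALSE, 0.75),
    pr_row(paste0("y", 1:6), "~~", paste0("y", 1:6), FALSE, 0.16))
  sp <- model_spec(paste0("y", 1:6), c("f1", "f2"), pt)
  im <- implied_moments(sp, setNames(numeric(0), character(0)))
  expect_lt(max(abs(im$sigma - cov(Y) * (n - 1) / n)), 0.01)
})

test_that("non-recursive path matrix raises a singularity error", {
  pt <- rbind(pr_row("a", "~", "b", FALSE, 1),
              pr_row("b", "~", "a", FALSE, 1),
              pr_row(c("a", "b"), "~~", c("a", "b"), FALSE, 1))
  sp <- model_spec(c("a", "b"), character(), pt)
  expect_error(implied_moments(sp, setNames(numeric(0), character(0))),
               "singular|non-recursive")
})

test_that("casewise FIML equals full density when complete and the marginal when not", {
  sp <- bivariate_spec()
  th <- c("x ~1" = 0.3, "y ~1" = -0.2, "x ~~ x" = 1.5, "y ~~ y" = 0.8,
          "x ~~ y" = 0.6)
  rec <- c(x = 0.7, y = -1.1)
  mu <- c(0.3, -0.2)
  S <- matrix(c(1.5, 0.6, 0.6, 0.8), 2)
  full <- -log(2 * pi) - 0.5 * log(det(S)) -
    0.5 * drop(t(rec - mu) %*% solve(S) %*% (rec - mu))
  expect_equal(casewise_loglik(sp, th, rec), full, tolerance = 1e-12)
  # one variable missing -> univariate normal marginal
  expect_equal(casewise_loglik(sp, th, c(x = 0.7, y = NA)),
               dnorm(0.7, 0.3, sqrt(1.5), log = TRUE), tolerance = 1e-12)
  expect_warning(casewise_loglik(sp, th, c(x = NA, y = NA)), "empty")
})

test_that("marginalization matches the hand-derived density over random draws", {
  sp <- bivariate_spec()
  set.seed(42)
  for (i in 1:250) {
    mx <- rnorm(1); my <- rnorm(1)
    vx <- runif(1, 0.2, 3); vy <- runif(1, 0.2, 3)
    cxy <- runif(1, -0.9, 0.9) * sqrt(vx * vy)
    th <- c("x ~1" = mx, "y ~1" = my, "x ~~ x" = vx, "y ~~ y" = vy,
            "x ~~ y" = cxy)
    yv <- rnorm(1, 0, 2)
    expect_equal(casewise_loglik(sp, th, c(x = NA, y = yv)),
                 dnorm(yv, my, sqrt(vy), log = TRUE), tolerance = 1e-10)
  }
})

test_that("total FIML equals the sufficient-statistic complete-data form", {
  set.seed(7)
  n <- 120
  Y <- matrix(rnorm(3 * n), n, 3) %*% chol(matrix(c(1, .4, .2, .4, 1, .3,
                                                    .2, .3, 1), 3))
  colnames(Y) <- c("a", "b", "c")
  sp <- saturated_spec(c("a", "b", "c"))
  th <- spec_start_values(sp)
  th[paste(c("a", "b", "c"), "~1")] <- c(0.1, -0.2, 0.05)
  th[paste(c("a", "b", "c"), "~~", c("a", "b", "c"))] <- c(1.2, 0.9, 1.1)
  th[c("a ~~ b", "a ~~ c", "b ~~ c")] <- c(0.3, 0.1, 0.2)
  mu <- th[1:3]
  S <- matrix(c(1.2, .3, .1, .3, .9, .2, .1, .2, 1.1), 3)
  xbar <- colMeans(Y)
  Sm <- crossprod(sweep(Y, 2, xbar)) / n
  suff <- -(n / 2) * (3 * log(2 * pi) + determinant(S)$modulus[1] +
                        sum(solve(S) * Sm) +
                        drop(t(xbar - mu) %*% solve(S) %*% (xbar - mu)))
  expect_equal(fiml_loglik(sp, th, as.data.frame(Y)), as.numeric(suff),
               tolerance = 1e-8 * abs(suff))
  # invariance to subject and variable reordering
  perm <- sample(n)
  expect_equal(fiml_loglik(sp, th, as.data.frame(Y[perm, ])),
               fiml_loglik(sp, th, as.data.frame(Y)), tolerance = 1e-10)
  expect_equal(fiml_loglik(sp, th, as.data.frame(Y)[, c(3, 1, 2)]),
               fiml_loglik(sp, th, as.data.frame(Y)), tolerance = 1e-10)
})

test_that("saturated fit recovers sample moments (ML, denominator n)", {
  set.seed(3)
  Y <- as.data.frame(matrix(rnorm(3 * 150), 150, 3))
  names(Y) <- c("a", "b", "c")
  fit <- quiet_fit(saturated_spec(c("a", "b", "c")), Y, se = "none",
                   check_identification = FALSE)
  expect_true(fit$converged)
  S <- crossprod(sweep(as.matrix(Y), 2, colMeans(Y))) / nrow(Y)
  expect_equal(unname(fit$theta["a ~1"]), mean(Y$a), tolerance = 1e-5)
  expect_equal(unname(fit$theta["a ~~ a"]), S[1, 1], tolerance = 1e-4)
  expect_lt(abs(fit$theta[["a ~~ b"]] - S[1, 2]), 1e-4)
  expect_equal(fit$loglik, saturated_loglik(as.matrix(Y))$loglik,
               tolerance = 1e-8)
})

test_that("standard errors match the closed form for a known-variance mean", {
  set.seed(11)
  n <- 400
  Y <- data.frame(x = rnorm(n, 2, 1.5))
  pt <- rbind(pr_row("x", "~1", "", TRUE, NA),
              pr_row("x", "~~", "x", FALSE, 2.25))
  fit <- quiet_fit(model_spec("x", character(), pt), Y)
  expect_equal(unname(standard_errors(fit)["x ~1"]), 1.5 / sqrt(n),
               tolerance = 1e-3)
})

test_that("aliased duplicate parameters raise identification/unstable flags", {
  set.seed(5)
  Y <- data.frame(y = rnorm(100))
  # mean split into two perfectly aliased free parameters via two latents
  pt <- rbind(pr_row("y", "~", "m1", FALSE, 1),
              pr_row("y", "~", "m2", FALSE, 1),
              pr_row(c("m1", "m2"), "~1", "", TRUE, 0),
              pr_row(c("m1", "m2"), "~~", c("m1", "m2"), FALSE, 0),
              pr_row("y", "~~", "y", TRUE, NA))
  sp <- model_spec("y", c("m1", "m2"), pt)
  expect_error(quiet_fit(sp, Y, se = "none", check_identification = TRUE),
               "aliased|not identified")
  fit <- suppressWarnings(fit_ml(sp, Y, se = "observed",
                                 check_identification = FALSE))
  expect_true(fit$se_unstable)
})

test_that("one-factor estimates land within 3 SE of truth in most replicates", {
  set.seed(19)
  hits <- 0; reps <- 30
  for (r in seq_len(reps)) {
    n <- 2000
    f <- rnorm(n)
    Y <- data.frame(y1 = f + rnorm(n, 0, sqrt(0.3)),
                    y2 = 0.8 * f + rnorm(n, 0, sqrt(0.3)),
                    y3 = 0.6 * f + rnorm(n, 0, sqrt(0.3)))
    sp <- one_factor_spec(loadings = c(1, 0.8, 0.6), psi = 1,
                          theta = rep(0.3, 3), free = TRUE)
    fit <- quiet_fit(sp, Y, check_identification = FALSE)
    est <- fit$theta["f =~ y2"]
    se <- fit$se["f =~ y2"]
    if (abs(est - 0.8) <= 3 * se) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("standardization: closed form, identity and rescaling invariance", {
  set.seed(23)
  n <- 800
  x <- rnorm(n, 0, 2)
  y <- 0.2 * x + rnorm(n, 0, sqrt(1 - 0.2^2 * 4))
  pt <- rbind(pr_row("y", "~", "x", TRUE, NA),
              pr_row(c("x", "y"), "~~", c("x", "y"), TRUE, NA),
              pr_row(c("x", "y"), "~1", "", TRUE, NA))
  sp <- model_spec(c("x", "y"), character(), pt)
  fit <- quiet_fit(sp, data.frame(x = x, y = y), se = "none",
                   check_identification = FALSE)
  tb <- standardized_estimates(fit)
  brow <- tb$op == "~"
  # beta * SD(x)/SD(y_total), the outcome SD from the implied moments
  sdy <- sqrt(fit$theta[["y ~ x"]]^2 * fit$theta[["x ~~ x"]] +
                fit$theta[["y ~~ y"]])
  expect_equal(tb$std[brow],
               unname(fit$theta["y ~ x"] *
                        sqrt(fit$theta["x ~~ x"]) / sdy),
               tolerance = 1e-10)
  # with Var(x) = 4, total Var(y) = 1, beta = 0.2 -> standardized 0.4
  expect_lt(abs(tb$std[brow] - 0.4), 0.08)
  # rescale the predictor by 10, refit from the transformed optimum:
  # standardized estimates are invariant
  st10 <- fit$theta
  st10["y ~ x"] <- st10["y ~ x"] / 10
  st10["x ~~ x"] <- st10["x ~~ x"] * 100
  st10["x ~1"] <- st10["x ~1"] * 10
  fit10 <- quiet_fit(sp, data.frame(x = 10 * x, y = y), se = "none",
                     check_identification = FALSE, start = st10)
  tb10 <- standardized_estimates(fit10)
  expect_equal(tb10$std[brow], tb$std[brow], tolerance = 1e-4)
})

test_that("factor scores: noiseless limit, Bartlett unbiasedness, orthogonality", {
  set.seed(31)
  n <- 5000
  f1 <- rnorm(n); f2 <- rnorm(n)   # orthogonal in truth
  Y <- data.frame(y1 = f1 + rnorm(n, 0, sqrt(0.3)),
                  y2 = 0.8 * f1 + rnorm(n, 0, sqrt(0.3)),
                  y3 = f2 + rnorm(n, 0, sqrt(0.3)),
                  y4 = 0.7 * f2 + rnorm(n, 0, sqrt(0.3)))
  pt <- rbind(pr_row(rep("f1", 2), "=~", c("y1", "y2"), FALSE, c(1, 0.8)),
              pr_row(rep("f2", 2), "=~", c("y3", "y4"), FALSE, c(1, 0.7)),
              pr_row(c("f1", "f2"), "~~", c("f1", "f2"), FALSE, 1),
              pr_row(paste0("y", 1:4), "~~", paste0("y", 1:4), FALSE, 0.3))
  sp <- model_spec(paste0("y", 1:4), c("f1", "f2"), pt)
  th <- setNames(numeric(0), character(0))
  sb <- factor_scores(sp, th, Y, method = "bartlett")
  # conditionally unbiased: regression of scores on truth has slope ~ 1
  expect_equal(unname(coef(lm(sb[, "f1"] ~ f1))[2]), 1, tolerance = 0.03)
  expect_equal(unname(coef(lm(sb[, "f2"] ~ f2))[2]), 1, tolerance = 0.03)
  expect_lt(abs(cor(sb[, "f1"], sb[, "f2"]) - cor(f1, f2)), 0.05)
  sr <- factor_scores(sp, th, Y, method = "regression")
  # regression scores are shrunken relative to Bartlett
  expect_lt(var(sr[, "f1"]), var(sb[, "f1"]))
  # zero error variance: scores equal the indicator combination exactly
  pt0 <- pt; pt0$value[pt0$op == "~~" & pt0$lhs != pt0$rhs] <- NA
  pt0$value[pt0$op == "~~" & grepl("^y", pt0$lhs)] <- 1e-12
  sp0 <- model_spec(paste0("y", 1:4), c("f1", "f2"), pt0)
  Y0 <- data.frame(y1 = f1, y2 = 0.8 * f1, y3 = f2, y4 = 0.7 * f2)
  s0 <- factor_scores(sp0, th, Y0, method = "bartlett")
  expect_equal(unname(s0[, "f1"]), f1, tolerance = 1e-5)
})
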