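# Latent-interaction marginalisation: exact reductions, oracle
# equivalence and node-refinement convergence.

test_that("zero product coefficients reduce exactly to the linear likelihood", {
  dat <- simulate_interaction_toy(150, seed = 2)
  sp0 <- interaction_toy_spec(b_fz = 0)
  th <- setNames(numeric(0), character(0))
  m <- marginal_loglik_interaction(sp0, th, dat, nodes = 7)
  lin <- fiml_loglik(rrisem:::strip_products(sp0), th, dat)
  expect_equal(m$total, lin, tolerance = 1e-10 * abs(lin))
})

test_that("latent-by-binary product matches the exact two-group mixture", {
  dat <- simulate_interaction_toy(200, seed = 4)
  sp <- interaction_toy_spec()
  th <- setNames(numeric(0), character(0))
  m <- marginal_loglik_interaction(sp, th, dat, nodes = 15)
  exact <- 0
  for (zz in 0:1) {
    spz <- interaction_toy_spec(b_f = 0.5 + 0.6 * zz, b_fz = 0)
    exact <- exact + fiml_loglik(rrisem:::strip_products(spz), th,
                                 dat[dat$z == zz, ])
  }
  expect_equal(m$total, exact, tolerance = 1e-8 * abs(exact))
})

test_that("adaptive quadrature is node-converged at the default", {
  dat <- simulate_interaction_toy(200, seed = 6)
  sp <- interaction_toy_spec()
  th <- setNames(numeric(0), character(0))
  m15 <- marginal_loglik_interaction(sp, th, dat, nodes = 15)
  m31 <- marginal_loglik_interaction(sp, th, dat, nodes = 31)
  expect_lt(abs(m31$total - m15$total), 1e-6)
})

test_that("the joint-model quadrature agrees with its linear reduction and refinement", {
  co <- generate_cohort(generator_config(n_subjects = 150,
                                         model_faithful = TRUE, seed = 61))
  ad <- rrisem:::analytical_data(co)
  ptab <- rrisem:::analytical_partable(ad$terms, ad$covariates)
  tr <- rrisem:::analytical_start(co, ad, ptab)
  # with all product-term coefficients zero the model is linear: compare
  # against casewise FIML of the explicitly-built conditional-linear model
  tr0 <- tr
  tr0[grepl("^b[IS]_mem[rb]:", names(tr0))] <- 0
  obj9 <- rrisem:::make_analytical_objective(ad, nodes = 9)
  obj9$set_adaptation(tr0)
  ll9 <- obj9$loglik(tr0)$total
  # linear-model oracle: marginal covariance adds the latent contributions
  asm <- rrisem:::analytical_assemble(tr0, ad$cmp)
  n <- nrow(ad$Y)
  cw <- numeric(n)
  for (i in seq_len(n)) {
    yi <- ad$Y[i, ]; keep <- !is.na(yi)
    zi <- ad$Z[i, ]
    cx <- asm$cx0 + drop(asm$CXz %*% zi)
    cb <- asm$cb0 + drop(asm$CBz %*% zi)
    mu <- asm$a0 + drop(asm$A %*% zi)
    Sig <- asm$Sigma + tcrossprod(cx) + tcrossprod(cb)
    cw[i] <- rrisem:::dmvnorm_log(yi[keep], mu[keep],
                                  Sig[keep, keep, drop = FALSE])
  }
  expect_equal(ll9, sum(cw), tolerance = 1e-7 * abs(sum(cw)))
  # node refinement at the full (interacting) parameter value
  obj15 <- rrisem:::make_analytical_objective(ad, nodes = 15)
  obj31 <- rrisem:::make_analytical_objective(ad, nodes = 31)
  obj15$set_adaptation(tr); obj31$set_adaptation(tr)
  expect_lt(abs(obj31$loglik(tr)$total - obj15$loglik(tr)$total), 1e-4)
})

test_that("the analytic gradient of the joint objective matches differencing", {
  co <- generate_cohort(generator_config(n_subjects = 120,
                                         model_faithful = TRUE, seed = 71))
  ad <- rrisem:::analytical_data(co)
  ptab <- rrisem:::analytical_partable(ad$terms, ad$covariates)
  tr <- rrisem:::analytical_start(co, ad, ptab)
  objv <- rrisem:::make_analytical_objective(ad, nodes = 7)
  objv$set_adaptation(tr)
  g <- objv$gradient(tr)
  set.seed(1)
  for (k in sample(seq_along(tr), 8)) {
    h <- 1e-6 * max(1, abs(tr[k]))
    tp <- tr; tp[k] <- tr[k] + h
    tm <- tr; tm[k] <- tr[k] - h
    gn <- (objv$loglik(tp)$total - objv$loglik(tm)$total) / (2 * h)
    expect_equal(unname(g$grad[k]), gn,
                 tolerance = 1e-5 * max(1, abs(gn)))
  }
  sc <- objv$scores(tr)
  expect_equal(unname(colSums(sc$scores)), unname(g$grad),
               tolerance = 1e-8)
})
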