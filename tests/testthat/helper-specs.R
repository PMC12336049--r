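# Small spec builders reused across tests.

pr_row <- function(lhs, op, rhs, free, value = NA, label = "")
  data.frame(lhs = lhs, op = op, rhs = rhs, free = free, value = value,
             label = label, stringsAsFactors = FALSE)

# one-factor model with fixed or free parameters
one_factor_spec <- function(loadings = c(1, 0.8, 0.6), psi = 1,
                            theta = rep(0.3, length(loadings)),
                            free = FALSE) {
  p <- length(loadings)
  ind <- paste0("y", seq_len(p))
  pt <- rbind(
    pr_row(rep("f", p), "=~", ind, free = c(FALSE, rep(free, p - 1)),
           value = loadings),
    pr_row("f", "~~", "f", free = free, value = psi),
    pr_row(ind, "~~", ind, free = free, value = theta),
    pr_row(ind, "~1", "", free = free, value = 0))
  model_spec(ind, "f", pt)
}

# saturated mean/covariance spec over named columns
saturated_spec <- function(vars) {
  cmb <- utils::combn(vars, 2)
  pt <- rbind(pr_row(vars, "~1", "", TRUE, NA),
              pr_row(vars, "~~", vars, TRUE, NA),
              pr_row(cmb[1, ], "~~", cmb[2, ], TRUE, NA))
  model_spec(vars, character(), pt)
}

# bivariate normal with free means, variances, covariance
bivariate_spec <- function() saturated_spec(c("x", "y"))

# toy latent-interaction spec: f measured by y1/y2, outcome y3 with f,
# z and f:z effects (z is a fixed-x covariate)
interaction_toy_spec <- function(b_f = 0.5, b_z = 0.4, b_fz = 0.6,
                                 resid = 0.49, psi = 1) {
  pt <- rbind(
    pr_row("f", "=~", c("y1", "y2"), FALSE, c(1, 0.8)),
    pr_row("f", "~~", "f", FALSE, psi),
    pr_row(c("y1", "y2"), "~~", c("y1", "y2"), FALSE, 0.25),
    pr_row("y3", "~", "f", FALSE, b_f),
    pr_row("y3", "~", "z", FALSE, b_z),
    pr_row("y3", "~", "f:z", FALSE, b_fz),
    pr_row("y3", "~~", "y3", FALSE, resid),
    pr_row("y3", "~1", "", FALSE, 0.3))
  model_spec(c("y1", "y2", "y3", "z"), "f", pt, fixed_x = "z")
}

simulate_interaction_toy <- function(n, seed, b_f = 0.5, b_z = 0.4,
                                     b_fz = 0.6) {
  set.seed(seed)
  z <- rbinom(n, 1, 0.5)
  f <- rnorm(n)
  data.frame(y1 = f + rnorm(n, 0, 0.5),
             y2 = 0.8 * f + rnorm(n, 0, 0.5),
             y3 = 0.3 + b_f * f + b_z * z + b_fz * f * z + rnorm(n, 0, 0.7),
             z = z)
}

quiet_fit <- function(...) suppressWarnings(fit_ml(...))
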