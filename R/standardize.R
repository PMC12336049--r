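# Standardized estimates: each path coefficient is rescaled by
# SD(predictor)/SD(outcome) computed from model-implied variances
# (fixed-x covariates use their sample SDs). Binary covariates are
# standardized the same way (STDYX-style); an unstandardized-binary
# variant is available via `binary_std = FALSE`.

variable_sds <- function(fit, theta = fit$theta) {
  im <- implied_moments(fit$spec, theta)
  sds <- sqrt(pmax(diag(im$total), 0))
  names(sds) <- im$vars
  for (v in fit$spec$fixed_x)
    sds[v] <- sd(fit$data[[v]], na.rm = TRUE)
  sds
}

standardized_vector <- function(fit, theta, binary_std = TRUE) {
  spec <- fit$spec
  pt <- spec$partable
  est <- partable_estimates(spec, theta)
  sds <- variable_sds(fit, theta)
  binary_vars <- if (!binary_std) {
    vs <- spec$fixed_x[vapply(spec$fixed_x, function(v)
      all(na.omit(unique(fit$data[[v]])) %in% c(0, 1)), logical(1))]
    vs
  } else character()
  sd_of <- function(v) {
    if (v %in% binary_vars) return(1)
    s <- sds[v]
    if (!is.finite(s) || s <= 0)
      stop_schema("undefined standardization: variable '%s' has zero implied variance", v)
    s
  }
  out <- est
  for (i in seq_len(nrow(pt))) {
    op <- pt$op[i]; lhs <- pt$lhs[i]; rhs <- pt$rhs[i]
    if (op == "=~") {
      out[i] <- est[i] * sd_of(lhs) / sd_of(rhs)        # loading: latent -> indicator
    } else if (op == "~") {
      if (grepl(":", rhs, fixed = TRUE)) { out[i] <- NA_real_; next }
      out[i] <- est[i] * sd_of(rhs) / sd_of(lhs)
    } else if (op == "~~") {
      out[i] <- est[i] / (sd_of(lhs) * sd_of(rhs))
    } else if (op == "~1") {
      out[i] <- est[i] / sd_of(lhs)
    }
  }
  out
}

#' Standardized parameter estimates
#'
#' @param fit a converged [fit_ml()] result (linear spec).
#' @param binary_std standardize binary fixed-x covariates by their SD
#'   (default, STDYX-style) or leave them on the raw 0/1 scale.
#' @param se_delta also compute delta-method standard errors for the
#'   standardized estimates (requires a fit with a vcov).
#' @return the fit's coefficient table with `std` (and optionally
#'   `std_se`) columns added.
#' @export
standardized_estimates <- function(fit, binary_std = TRUE, se_delta = FALSE) {
  tb <- fit$coef_table
  tb$std <- standardized_vector(fit, fit$theta, binary_std = binary_std)
  if (se_delta && !is.null(fit$vcov)) {
    vlab <- variance_labels(fit$spec)
    fstd <- function(tr) {
      th <- trans_to_theta(setNames(tr, names(fit$theta_trans)), vlab)
      standardized_vector(fit, th, binary_std = binary_std)
    }
    J <- matrix(0, nrow(tb), length(fit$theta_trans))
    x0 <- fit$theta_trans
    f0 <- fstd(x0)
    for (j in seq_along(x0)) {
      h <- 1e-5 * max(1, abs(x0[j]))
      xp <- x0; xp[j] <- x0[j] + h
      xm <- x0; xm[j] <- x0[j] - h
      J[, j] <- (fstd(xp) - fstd(xm)) / (2 * h)
    }
    Jn <- nat_jacobian(x0, vlab)
    V_tr <- solve(Jn) %*% fit$vcov %*% t(solve(Jn))
    tb$std_se <- sqrt(pmax(rowSums((J %*% V_tr) * J), 0))
    tb$std_se[!tb$free] <- NA_real_
  }
  tb
}
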