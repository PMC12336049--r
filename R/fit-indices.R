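# Global fit battery: chi-square vs the saturated model, CFI/TLI against
# the independence baseline, RMSEA with a 90% CI by inversion of the
# noncentral chi-square CDF, SRMR, and AIC/BIC/aBIC.

#' Likelihood-ratio chi-square against the saturated model
#'
#' @param loglik_model,loglik_sat maximised log-likelihoods of the target
#'   and saturated models fitted on identical cases.
#' @param npar_model,npar_sat parameter counts.
#' @return list with `chi2` and `df`; negative chi-square is clipped to 0
#'   with a warning.
#' @export
chi_square <- function(loglik_model, loglik_sat, npar_model, npar_sat) {
  df <- npar_sat - npar_model
  if (df < 0)
    stop_schema("model has more parameters than the saturated model (df < 0)")
  chi2 <- 2 * (loglik_sat - loglik_model)
  if (chi2 < 0) {
    warning("negative chi-square clipped to 0")
    chi2 <- 0
  }
  list(chi2 = chi2, df = df)
}

#' Comparative fit index and Tucker-Lewis index
#'
#' Baseline is the independence model (free means and variances,
#' covariances zero). TLI is reported uncapped and may exceed 1.
#'
#' @param chi2_m,df_m model chi-square and df.
#' @param chi2_b,df_b baseline chi-square and df.
#' @export
cfi_tli <- function(chi2_m, df_m, chi2_b, df_b) {
  if (df_b == 0) stop_schema("undefined baseline: df_b = 0")
  num <- max(chi2_m - df_m, 0)
  den <- max(chi2_b - df_b, chi2_m - df_m, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  tli <- if (df_m == 0) NA_real_ else
    ((chi2_b / df_b) - (chi2_m / df_m)) / ((chi2_b / df_b) - 1)
  list(cfi = cfi, tli = tli)
}

#' Root mean square error of approximation with confidence interval
#'
#' Point estimate \eqn{\sqrt{\max(\chi^2 - df, 0) / (df \cdot (n-1))}}
#' (or denominator \eqn{df \cdot n} with `n_convention = "n"`); CI limits
#' by inverting the noncentral chi-square CDF in the noncentrality
#' parameter (bisection to 1e-8), with endpoints 0 when no root exists.
#'
#' @param chi2,df,n chi-square statistic, degrees of freedom, sample size.
#' @param conf confidence level (default 0.90).
#' @param n_convention denominator convention, `"n-1"` (default) or `"n"`.
#' @return list with `rmsea`, `lo`, `hi`.
#' @export
rmsea <- function(chi2, df, n, conf = 0.90, n_convention = c("n-1", "n")) {
  n_convention <- match.arg(n_convention)
  if (df <= 0) stop_schema("RMSEA undefined for df = 0")
  denom <- df * (if (n_convention == "n-1") n - 1 else n)
  point <- sqrt(max(chi2 - df, 0) / denom)
  a <- (1 - conf) / 2
  lo_l <- invert_ncp(chi2, df, 1 - a)
  hi_l <- invert_ncp(chi2, df, a)
  list(rmsea = point, lo = sqrt(max(lo_l, 0) / denom),
       hi = sqrt(max(hi_l, 0) / denom))
}

# Find lambda >= 0 with P(chisq_{df, lambda} <= chi2) = target (decreasing
# in lambda); 0 when no root.
invert_ncp <- function(chi2, df, target, tol = 1e-8) {
  f <- function(l) pchisq(chi2, df, ncp = l) - target
  if (f(0) <= 0) return(0)
  hi <- max(chi2, 1)
  while (f(hi) > 0 && hi < 1e8) hi <- hi * 2
  if (f(hi) > 0) return(hi)
  lo <- 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Standardised root mean square residual
#'
#' Root mean square of the standardized residuals over the unique variance
#' and covariance elements, standardizing by the sample SDs.
#'
#' @param sample_cov,implied_cov conformable covariance matrices.
#' @export
srmr <- function(sample_cov, implied_cov) {
  s <- sqrt(diag(sample_cov))
  if (any(s <= 0)) stop_schema("SRMR requires positive sample variances")
  D <- (sample_cov - implied_cov) / tcrossprod(s)
  sqrt(mean(D[upper.tri(D, diag = TRUE)]^2))
}

#' Information criteria
#'
#' AIC = -2LL + 2p; BIC = -2LL + p ln n; aBIC uses the sample-size
#' substitution (n + 2)/24.
#'
#' @param loglik maximised log-likelihood.
#' @param n_params number of free parameters.
#' @param n sample size.
#' @export
information_criteria <- function(loglik, n_params, n) {
  if (n <= 0) stop_schema("n must be positive")
  list(aic = -2 * loglik + 2 * n_params,
       bic = -2 * loglik + n_params * log(n),
       abic = -2 * loglik + n_params * log((n + 2) / 24))
}

#' Full fit-statistic battery for a fitted linear spec
#'
#' Fits the saturated and independence-baseline models on the same cases
#' and assembles chi-square, CFI, TLI, RMSEA (90% CI), SRMR, AIC, BIC and
#' aBIC.
#'
#' @param fit a [fit_ml()] result for a linear spec.
#' @param rmsea_n_convention passed to [rmsea()].
#' @return object of class `fit_stats` (a named list).
#' @export
fit_stats <- function(fit, rmsea_n_convention = "n-1") {
  if (fit$has_products)
    stop_schema("fit statistics are defined for linear specs")
  spec <- fit$spec
  yv <- setdiff(spec$observed, spec$fixed_x)
  Y <- as.matrix(fit$data[, yv, drop = FALSE])
  Z <- if (length(spec$fixed_x))
    as.matrix(fit$data[, spec$fixed_x, drop = FALSE]) else NULL
  sat <- saturated_loglik(Y, Z)
  base <- baseline_loglik(Y)
  cs <- chi_square(fit$loglik, sat$loglik, fit$npar, sat$npar)
  # baseline chi-square vs the same saturated model
  cb <- chi_square(base$loglik, sat$loglik, base$npar, sat$npar)
  ct <- cfi_tli(cs$chi2, cs$df, cb$chi2, cb$df)
  rm <- if (cs$df > 0)
    rmsea(cs$chi2, cs$df, fit$n, n_convention = rmsea_n_convention)
  else list(rmsea = 0, lo = 0, hi = 0)
  # SRMR from available-case sample moments vs implied
  Sobs <- stats_available_cov(Y)
  srmr_v <- srmr(Sobs, fit$implied$sigma[yv, yv, drop = FALSE])
  ic <- information_criteria(fit$loglik, fit$npar, fit$n)
  structure(list(chi2_model = cs$chi2, df_model = cs$df,
                 chi2_baseline = cb$chi2, df_baseline = cb$df,
                 cfi = ct$cfi, tli = ct$tli,
                 rmsea = rm$rmsea, rmsea_ci90 = c(rm$lo, rm$hi),
                 srmr = srmr_v, aic = ic$aic, bic = ic$bic, abic = ic$abic,
                 n = fit$n, n_params = fit$npar),
            class = "fit_stats")
}

#' @export
print.fit_stats <- function(x, ...) {
  cat(sprintf("chi2(%d) = %.3f;  CFI = %.3f; TLI = %.3f\n",
              x$df_model, x$chi2_model, x$cfi, x$tli))
  cat(sprintf("RMSEA = %.3f [%.3f, %.3f];  SRMR = %.3f\n",
              x$rmsea, x$rmsea_ci90[1], x$rmsea_ci90[2], x$srmr))
  cat(sprintf("AIC = %.3f; BIC = %.3f; aBIC = %.3f  (n = %d, p = %d)\n",
              x$aic, x$bic, x$abic, x$n, x$n_params))
  invisible(x)
}

# One-row data.frame in reporting order.
fit_stats_row <- function(fs) {
  data.frame(cfi = fs$cfi, tli = fs$tli, rmsea = fs$rmsea,
             rmsea_lo = fs$rmsea_ci90[1], rmsea_hi = fs$rmsea_ci90[2],
             srmr = fs$srmr, aic = fs$aic, bic = fs$bic, abic = fs$abic)
}
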