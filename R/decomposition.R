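# Stage 1: decomposition of the episodic-memory composite into orthogonal
# brain (MEMB), demographic (MEMD) and residual-reserve (MEMR) components
# under fixed measurement-error constraints.
#
# The three ICV-adjusted brain volumes are standardized in-stage and each
# measures a single-indicator latent brain factor with error variance
# fixed at 0.10 (10% unreliability on the unit scale). Memory is regressed
# on the three brain latents (freely estimated weights, so MEMB is their
# fitted linear combination), on the observed demographic/methodological
# covariates (MEMD is their fitted combination), and on a residual latent
# MEMR with free variance; the memory measurement-error variance is fixed
# at 0.1365 on the composite scale. All three components are mutually
# orthogonal by construction.

DEFAULT_DEMO_COVARIATES <- c("education_years", "n_prior_assessments",
                             "prior_interval_months", "n_prior_x_interval",
                             "withdrawn", "deceased")

INDICATOR_RAW <- c(ind_gm = "gm_vol", ind_hippo = "hippo_vol",
                   ind_wmh = "wmh_vol")

#' Assemble the baseline analysis table
#'
#' Standardizes the brain indicators (sample z-scores) and builds the
#' demographic covariate columns, including the prior-assessments-by-
#' interval product term.
#'
#' @param cohort a `cohort`.
#' @param covariates demographic covariate columns to carry.
#' @return list with `data` (data.frame) and `scaling` (indicator means
#'   and SDs used for the z-transform).
#' @keywords internal
decomposition_data <- function(cohort, covariates = DEFAULT_DEMO_COVARIATES) {
  b <- cohort$baseline
  b$n_prior_x_interval <- b$n_prior_assessments * b$prior_interval_months
  miss <- setdiff(covariates, names(b))
  if (length(miss))
    stop_schema("cohort baseline lacks covariate column(s): %s",
                paste(miss, collapse = ", "))
  sc <- lapply(INDICATOR_RAW, function(cn) {
    x <- b[[cn]]
    c(mean = mean(x, na.rm = TRUE), sd = sd(x, na.rm = TRUE))
  })
  d <- data.frame(id = b$id)
  for (nm in names(INDICATOR_RAW))
    d[[nm]] <- (b[[INDICATOR_RAW[nm]]] - sc[[nm]]["mean"]) / sc[[nm]]["sd"]
  d$mem <- b$mem_composite
  for (cv in covariates) d[[cv]] <- b[[cv]]
  list(data = d, scaling = sc, covariates = covariates)
}

#' Build the memory-decomposition model spec
#'
#' @param covariates demographic regressors of memory (default: education
#'   plus the methodological set - prior assessments, interval, their
#'   product, withdrawn, deceased). An empty vector drops MEMD.
#' @param mem_error_var fixed memory measurement-error variance.
#' @param indicator_error_var fixed indicator error variance on the
#'   standardized scale.
#' @return a [model_spec()] implementing the constrained decomposition.
#' @export
build_decomposition_spec <- function(covariates = DEFAULT_DEMO_COVARIATES,
                                     mem_error_var = 0.1365,
                                     indicator_error_var = 0.10) {
  ind <- names(INDICATOR_RAW)
  lat <- c("B_gm", "B_hippo", "B_wmh", "MEMR")
  pr <- function(lhs, op, rhs, free, value = NA, label = "")
    data.frame(lhs = lhs, op = op, rhs = rhs, free = free, value = value,
               label = label, stringsAsFactors = FALSE)
  pt <- rbind(
    pr(lat[1:3], "=~", ind, FALSE, 1),
    pr(ind, "~~", ind, FALSE, indicator_error_var),
    pr(ind, "~1", "", TRUE, 0),
    pr(lat[1:3], "~~", lat[1:3], TRUE, 0.9,
       label = paste0("psi_", c("gm", "hippo", "wmh"))),
    pr(c("B_gm", "B_gm", "B_hippo"), "~~", c("B_hippo", "B_wmh", "B_wmh"),
       TRUE, 0.3),
    pr("mem", "~", lat[1:3], TRUE, 0.2,
       label = paste0("w_", c("gm", "hippo", "wmh"))),
    pr("mem", "~", "MEMR", FALSE, 1),
    pr("MEMR", "~~", "MEMR", TRUE, 0.3, label = "psi_memr"),
    pr("mem", "~~", "mem", FALSE, mem_error_var),
    pr("mem", "~1", "", TRUE, 0))
  if (length(covariates))
    pt <- rbind(pt, pr("mem", "~", covariates, TRUE, 0,
                       label = paste0("d_", covariates)))
  model_spec(observed = c(ind, "mem", covariates), latents = lat,
             partable = pt, fixed_x = covariates)
}

#' Decompose episodic memory into MEMB, MEMD and MEMR
#'
#' Fits the constrained decomposition by FIML and returns variance
#' components plus per-subject component scores. The MEMB score is the
#' regression (posterior-mean) combination of the brain latents given the
#' indicators alone, which makes the residual MEMR score uncorrelated
#' with it in the population; the MEMR score is the memory residual
#' (Bartlett-style, conditionally unbiased up to brain-score shrinkage).
#'
#' @param cohort a `cohort`.
#' @param spec optional [build_decomposition_spec()] result.
#' @param covariates demographic regressors (used when `spec` is NULL).
#' @param se standard-error method passed to [fit_ml()].
#' @param control optimiser control passed to [fit_ml()].
#' @return object of class `decomposition` with elements `fit`,
#'   `variances`, `weights`, `scores` (id, memb, memd, memr).
#' @export
decompose <- function(cohort, spec = NULL,
                      covariates = DEFAULT_DEMO_COVARIATES,
                      se = "observed", control = list()) {
  dd <- decomposition_data(cohort, covariates)
  if (is.null(spec)) spec <- build_decomposition_spec(covariates)
  fit <- fit_ml(spec, dd$data, se = se, control = control,
                check_identification = FALSE)
  if (!fit$converged)
    warning("decomposition fit flagged non-converged (rel grad max-norm ",
            format(fit$grad_norm, digits = 3), ")")
  th <- fit$theta
  w <- th[c("w_gm", "w_hippo", "w_wmh")]
  Psi <- matrix(0, 3, 3)
  diag(Psi) <- th[c("psi_gm", "psi_hippo", "psi_wmh")]
  Psi[1, 2] <- Psi[2, 1] <- th["B_gm ~~ B_hippo"]
  Psi[1, 3] <- Psi[3, 1] <- th["B_gm ~~ B_wmh"]
  Psi[2, 3] <- Psi[3, 2] <- th["B_hippo ~~ B_wmh"]
  dvec <- if (length(covariates)) th[paste0("d_", covariates)] else numeric(0)
  psi_memr <- unname(th["psi_memr"])
  if (psi_memr < 1e-3)
    warning("free MEMR variance at/near the zero boundary")

  memb_var <- drop(t(w) %*% Psi %*% w)
  Zc <- if (length(covariates))
    as.matrix(dd$data[, covariates, drop = FALSE]) else NULL
  memd_lin <- if (length(covariates)) drop(Zc %*% dvec) else rep(0, nrow(dd$data))
  nd <- sum(!is.na(memd_lin))
  memd_var <- if (length(covariates))
    var(memd_lin, na.rm = TRUE) * (nd - 1) / nd else 0
  err_var <- fit$spec$partable$value[fit$spec$partable$lhs == "mem" &
                                       fit$spec$partable$op == "~~"]
  variances <- c(memb = memb_var, memd = memd_var, memr = psi_memr,
                 error = err_var)

  scores <- decomposition_scores(dd, w, Psi, dvec, th, memd_lin)
  structure(list(fit = fit, variances = variances,
                 weights = list(brain = w, demographic = dvec),
                 scores = scores, scaling = dd$scaling,
                 covariates = covariates), class = "decomposition")
}

decomposition_scores <- function(dd, w, Psi, dvec, th, memd_lin) {
  ind <- as.matrix(dd$data[, names(INDICATOR_RAW)])
  nu_ind <- th[paste(names(INDICATOR_RAW), "~1")]
  R <- sweep(ind, 2, nu_ind)
  Theta <- diag(0.10, 3)
  # posterior mean of the brain latents given the indicators alone
  W <- Psi %*% solve(Psi + Theta)
  Bhat <- matrix(NA_real_, nrow(R), 3)
  cc <- complete.cases(R)
  Bhat[cc, ] <- R[cc, , drop = FALSE] %*% t(W)
  if (any(!cc)) {        # per-pattern posterior for partially observed rows
    for (i in which(!cc)) {
      j <- which(!is.na(R[i, ]))
      if (!length(j)) next
      Wj <- Psi[, j, drop = FALSE] %*%
        solve(Psi[j, j, drop = FALSE] + Theta[j, j, drop = FALSE])
      Bhat[i, ] <- drop(Wj %*% R[i, j])
    }
  }
  memb <- drop(Bhat %*% w)
  memd <- memd_lin - mean(memd_lin, na.rm = TRUE)
  memr <- dd$data$mem - unname(th["mem ~1"]) - memd_lin - memb
  data.frame(id = dd$data$id, memb = memb, memd = memd, memr = memr)
}

#' Variance-component table of a decomposition
#'
#' @param result a [decompose()] result.
#' @return data.frame with component variances and shares of the total
#'   model-implied memory variance (shares sum to 1).
#' @export
variance_table <- function(result) {
  v <- result$variances
  data.frame(component = names(v), variance = unname(v),
             share = unname(v) / sum(v))
}

#' @export
print.decomposition <- function(x, ...) {
  cat("memory decomposition (fixed errors: indicators 0.10, memory",
      format(x$variances["error"]), ")\n")
  print(variance_table(x), digits = 3, row.names = FALSE)
  cat("converged:", x$fit$converged, "\n")
  invisible(x)
}
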