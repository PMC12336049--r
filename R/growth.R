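# Stage 2: latent growth curve models of executive function over up to
# seven 18-month visits (T = -3..+3, anchored at the first MRI), and the
# growth-form comparison (linear, quadratic, logarithmic).

EF_COLS <- c("ef_m3", "ef_m2", "ef_m1", "ef_0", "ef_p1", "ef_p2", "ef_p3")

#' Wide executive-function matrix from a cohort
#'
#' @param cohort a `cohort`.
#' @return data.frame with one row per subject and one column per visit
#'   offset (`ef_m3` .. `ef_p3`), `NA` where unobserved.
#' @export
ef_wide <- function(cohort) {
  b <- cohort$baseline
  v <- cohort$visits
  out <- data.frame(id = b$id)
  for (k in seq_along(cohort$time_codes)) {
    Tk <- cohort$time_codes[k]
    m <- v[v$T == Tk, ]
    out[[EF_COLS[k]]] <- m$ef[match(b$id, m$id)]
  }
  out
}

growth_basis <- function(form, time_codes = -3:3) {
  switch(form,
         linear = list(S = time_codes),
         quadratic = list(S = time_codes, Q = time_codes^2),
         logarithmic = list(S = sign(time_codes) * log(1 + abs(time_codes))),
         stop_schema("unknown growth form '%s'", form))
}

#' Build a latent growth curve model spec
#'
#' The intercept basis is all ones; the linear basis equals the visit
#' offset T; the quadratic form adds T^2; the logarithmic basis is
#' sign(T) * ln(1 + |T|), which is strictly increasing and zero at T = 0
#' so the intercept keeps its meaning (expected EF at the first MRI) with
#' pre-baseline visits present.
#'
#' @param form `"linear"`, `"quadratic"` or `"logarithmic"`.
#' @param equal_residuals constrain the per-visit residual variances
#'   equal (default) or leave them free.
#' @param time_codes visit offsets (default -3..3).
#' @return a [model_spec()].
#' @export
build_growth_spec <- function(form = c("linear", "quadratic", "logarithmic"),
                              equal_residuals = TRUE, time_codes = -3:3) {
  form <- match.arg(form)
  basis <- growth_basis(form, time_codes)
  lat <- c("I", names(basis))
  pr <- function(lhs, op, rhs, free, value = NA, label = "")
    data.frame(lhs = lhs, op = op, rhs = rhs, free = free, value = value,
               label = label, stringsAsFactors = FALSE)
  pt <- pr("I", "=~", EF_COLS, FALSE, 1)
  for (nm in names(basis))
    pt <- rbind(pt, pr(nm, "=~", EF_COLS, FALSE, basis[[nm]]))
  pt <- rbind(pt,
              pr(EF_COLS, "~1", "", FALSE, 0),
              pr(lat, "~1", "", TRUE, 0, label = paste0("alpha_", lat)),
              pr(lat, "~~", lat, TRUE, 0.3, label = paste0("psi_", lat)))
  cmb <- utils::combn(lat, 2)
  pt <- rbind(pt, pr(cmb[1, ], "~~", cmb[2, ], TRUE, 0))
  pt <- rbind(pt, pr(EF_COLS, "~~", EF_COLS, TRUE, 0.1,
                     label = if (equal_residuals) "theta_ef"
                     else paste0("theta_", EF_COLS)))
  model_spec(observed = EF_COLS, latents = lat, partable = pt)
}

#' Compare growth functional forms
#'
#' Fits each requested form by FIML on identical cases, computes the full
#' fit battery, and selects a form by the parsimony rule: when every
#' converged form fits adequately (CFI >= 0.95, RMSEA <= 0.06,
#' SRMR <= 0.08), prefer the fewest parameters, breaking ties by BIC;
#' otherwise prefer the lowest BIC.
#'
#' @param cohort a `cohort`.
#' @param forms character vector of at least two forms (or one, for a
#'   single-row comparison table).
#' @param equal_residuals passed to [build_growth_spec()].
#' @param se passed to [fit_ml()].
#' @return object of class `growth_comparison`: `$table` (one row per
#'   form: fit battery + AIC/BIC/aBIC), `$fits`, `$selected`,
#'   `$rationale`.
#' @export
compare_growth_forms <- function(cohort,
                                 forms = c("linear", "quadratic",
                                           "logarithmic"),
                                 equal_residuals = TRUE, se = "none") {
  Y <- ef_wide(cohort)[, EF_COLS]
  fits <- list(); stats <- list()
  for (f in forms) {
    spec <- build_growth_spec(f, equal_residuals = equal_residuals)
    fit <- fit_ml(spec, Y, se = se)
    fits[[f]] <- fit
    stats[[f]] <- fit_stats(fit)
  }
  conv <- vapply(fits, function(f) f$converged, logical(1))
  if (!any(conv)) stop_schema("no growth form converged")
  tab <- do.call(rbind, lapply(forms, function(f) {
    cbind(data.frame(form = f, converged = conv[[f]],
                     n_params = fits[[f]]$npar,
                     loglik = fits[[f]]$loglik),
          fit_stats_row(stats[[f]]))
  }))
  cand <- tab[tab$converged, ]
  adequate <- cand$cfi >= 0.95 & cand$rmsea <= 0.06 & cand$srmr <= 0.08
  if (all(adequate)) {
    k <- order(cand$n_params, cand$bic)[1]
    rationale <- "all converged forms adequate; fewest parameters (ties by BIC)"
  } else {
    k <- which.min(cand$bic)
    rationale <- "not all forms adequate; lowest BIC"
  }
  structure(list(table = tab, fits = fits, selected = cand$form[k],
                 rationale = rationale), class = "growth_comparison")
}

#' @export
print.growth_comparison <- function(x, ...) {
  print(x$table, digits = 4, row.names = FALSE)
  cat("selected:", x$selected, "(", x$rationale, ")\n")
  invisible(x)
}
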