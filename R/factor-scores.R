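#' Per-subject latent factor scores
#'
#' Computes factor scores for a converged linear spec. Regression scores
#' are the conditional means of the latents given the observed data
#' (shrunken towards zero); Bartlett scores weight by the inverse residual
#' covariance and are conditionally unbiased for the true latents.
#' Missing observed values are handled per missing-data pattern.
#'
#' @param spec a linear [model_spec()].
#' @param theta named free-parameter vector (e.g. a fit's `$theta`).
#' @param data data.frame with the observed variables.
#' @param method `"regression"` or `"bartlett"`.
#' @return matrix (subjects x latents) of scores.
#' @export
factor_scores <- function(spec, theta, data,
                          method = c("regression", "bartlett")) {
  method <- match.arg(method)
  if (n_product_terms(spec) > 0)
    stop_schema("factor scores require a linear spec")
  im <- implied_moments(spec, theta)
  ram <- ram_matrices(spec, theta)
  fx <- spec$fixed_x
  yv <- im$yvars
  lat <- spec$latents
  IA <- solve_IA(ram$A)
  L <- IA[yv, lat, drop = FALSE]            # total-effect loadings
  Psi <- im$total[lat, lat, drop = FALSE]
  Y <- as.matrix(data[, yv, drop = FALSE])
  n <- nrow(Y)
  mu_mat <- matrix(im$mu, n, length(yv), byrow = TRUE)
  if (!is.null(im$gamma))
    mu_mat <- mu_mat + as.matrix(data[, fx, drop = FALSE]) %*% t(im$gamma)
  scores <- matrix(NA_real_, n, length(lat), dimnames = list(NULL, lat))
  obs <- !is.na(Y)
  key <- apply(obs, 1L, function(r) paste(which(r), collapse = ","))
  for (k in unique(key)) {
    rows <- which(key == k)
    j <- which(obs[rows[1L], ])
    if (!length(j)) next
    R <- Y[rows, j, drop = FALSE] - mu_mat[rows, j, drop = FALSE]
    if (method == "regression") {
      Wt <- im$total[lat, yv[j], drop = FALSE] %*%
        solve(im$sigma[j, j, drop = FALSE])
    } else {
      Lj <- L[j, , drop = FALSE]
      Th <- im$sigma[j, j, drop = FALSE] - Lj %*% Psi %*% t(Lj)
      Thi <- pseudo_solve(symm(Th))$inv
      M <- symm(t(Lj) %*% Thi %*% Lj)
      Wt <- pseudo_solve(M)$inv %*% t(Lj) %*% Thi
    }
    scores[rows, ] <- R %*% t(Wt)
  }
  scores
}
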