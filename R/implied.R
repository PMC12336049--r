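# Model-implied moments via the reticular-action (RAM) representation:
# v = A v + u, with u ~ N(M, S) over the stacked (observed, latent) vector.
# mu = F (I - A)^{-1} M,  Sigma = F (I - A)^{-1} S (I - A)^{-T} F'.

ram_matrices <- function(spec, theta, exclude_products = TRUE) {
  vars <- c(spec$observed, spec$latents)
  nv <- length(vars)
  A <- matrix(0, nv, nv, dimnames = list(vars, vars))
  S <- matrix(0, nv, nv, dimnames = list(vars, vars))
  M <- setNames(numeric(nv), vars)
  est <- partable_estimates(spec, theta)
  pt <- spec$partable
  for (i in seq_len(nrow(pt))) {
    op <- pt$op[i]; lhs <- pt$lhs[i]; rhs <- pt$rhs[i]; v <- est[i]
    if (op == "=~") {
      A[rhs, lhs] <- v
    } else if (op == "~") {
      if (grepl(":", rhs, fixed = TRUE)) {
        if (!exclude_products)
          stop_schema("product term '%s' has no linear implied-moment map", rhs)
        next
      }
      A[lhs, rhs] <- v
    } else if (op == "~~") {
      S[lhs, rhs] <- v; S[rhs, lhs] <- v
    } else if (op == "~1") {
      M[lhs] <- v
    } else stop_schema("unknown partable op '%s'", op)
  }
  list(A = A, S = S, M = M, vars = vars)
}

solve_IA <- function(A) {
  IA <- diag(nrow(A)) - A
  out <- tryCatch(solve(IA), error = function(e) NULL)
  if (is.null(out))
    stop_schema("(I - B) is singular: the model is non-recursive or ill-posed")
  dimnames(out) <- dimnames(A)
  out
}

#' Model-implied mean and covariance of the observed variables
#'
#' Computes the linear-part implied moments
#' \eqn{\mu = F(I-A)^{-1}M} and \eqn{\Sigma = F(I-A)^{-1}S(I-A)^{-T}F'}.
#' Product terms (latent interactions) are excluded from this linear map.
#' For specs with `fixed_x` regressors the conditional moments are returned:
#' a base mean `mu`, a coefficient matrix `gamma` (columns = fixed-x
#' variables) so that the subject-level mean is `mu + gamma %*% x`, and the
#' conditional covariance `sigma`.
#'
#' @param spec a [model_spec()].
#' @param theta named numeric vector of free-parameter values.
#' @return list with `mu`, `sigma`, `gamma` (NULL when no fixed-x), `latent`
#'   (total covariance over all variables, for scores/standardization).
#' @export
implied_moments <- function(spec, theta) {
  ram <- ram_matrices(spec, theta)
  fx <- spec$fixed_x
  y <- setdiff(spec$observed, fx)
  # condition on fixed-x: zero their dispersion and mean, keep paths
  ram$S[fx, ] <- 0; ram$S[, fx] <- 0; ram$M[fx] <- 0
  IA <- solve_IA(ram$A)
  total <- symm(IA %*% ram$S %*% t(IA))
  mu_all <- drop(IA %*% ram$M)
  gamma <- if (length(fx)) IA[y, fx, drop = FALSE] else NULL
  list(mu = mu_all[y], sigma = total[y, y, drop = FALSE], gamma = gamma,
       total = total, vars = ram$vars, yvars = y)
}
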