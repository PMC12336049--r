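# Marginal likelihood for specs with latent product terms.
#
# Conditional on the interacting latent, a model whose products each
# involve at most one other (linear) variable is Gaussian, so the
# marginal likelihood is a one-dimensional integral evaluated with
# adaptive Gauss-Hermite quadrature: per subject, the integrand is
# recentred at its mode with a curvature-matched scale, which integrates
# exactly-Gaussian integrands exactly and makes node-refinement converge
# fast. When every product coefficient is zero the model is linear and
# the quadrature reduces algebraically to the casewise FIML likelihood.

product_rows <- function(spec) which(grepl(":", spec$partable$rhs, fixed = TRUE))

# The integrated latent: must appear in every product that contains more
# than one latent token, be exogenous (no incoming paths) and orthogonal
# to the other latents.
integration_latent <- function(spec) {
  pt <- spec$partable
  rows <- product_rows(spec)
  toks <- lapply(pt$rhs[rows], function(r) strsplit(r, ":", fixed = TRUE)[[1]])
  lat_toks <- lapply(toks, intersect, spec$latents)
  cand <- Reduce(intersect, lat_toks[lengths(lat_toks) > 0])
  cand <- cand[vapply(cand, function(xi) {
    all(vapply(lat_toks, function(l) length(setdiff(l, xi)) <= 1, logical(1)))
  }, logical(1))]
  if (!length(cand))
    stop_schema(paste("no single latent renders all products conditionally",
                      "linear; this general path integrates one latent",
                      "(the joint analytical model uses its own",
                      "two-dimensional marginalisation)"))
  xi <- cand[1L]
  # exogeneity: no incoming regressions/loadings, no covariances
  into <- pt$op %in% c("~", "=~") & ((pt$lhs == xi & pt$op == "~") |
                                       (pt$op == "=~" & pt$lhs == xi))
  covs <- pt$op == "~~" & (pt$lhs == xi | pt$rhs == xi) & pt$lhs != pt$rhs
  if (any(covs))
    stop_schema("integrated latent '%s' must be orthogonal to other variables", xi)
  xi
}

#' Marginal log-likelihood under latent interactions
#'
#' Integrates the conditional-normal likelihood over the interacting
#' latent with adaptive Gauss-Hermite quadrature (per-subject mode and
#' curvature recentring). Reduces exactly to the linear FIML likelihood
#' when all product coefficients are zero.
#'
#' @param spec a [model_spec()] with product terms, each involving the
#'   integrated latent and at most one other linear variable.
#' @param theta named free-parameter vector.
#' @param data data.frame of observed variables.
#' @param nodes number of quadrature nodes (>= 3).
#' @param adaptive recentre nodes per subject (default); otherwise a
#'   fixed prior-scaled grid is used.
#' @return list with `total` and per-subject `casewise` log-likelihoods.
#' @export
marginal_loglik_interaction <- function(spec, theta, data, nodes = 15L,
                                        adaptive = TRUE) {
  if (nodes < 3) stop_schema("nodes must be >= 3")
  est <- partable_estimates(spec, theta)
  rows <- product_rows(spec)
  if (!length(rows))
    stop_schema("spec has no product terms; use fiml_loglik()")
  if (all(est[rows] == 0)) {
    cw <- casewise_loglik_matrix(strip_products(spec), theta, data)
    return(list(total = sum(cw), casewise = cw))
  }
  xi <- integration_latent(spec)
  psi_row <- spec$partable$op == "~~" & spec$partable$lhs == xi &
    spec$partable$rhs == xi
  psi_xi <- est[psi_row][1]
  if (!is.finite(psi_xi) || psi_xi <= 0)
    stop_schema("integrated latent '%s' needs a positive variance", xi)

  cond <- conditional_moments_builder(spec, theta, xi)
  yv <- cond$yvars
  Y <- as.matrix(data[, yv, drop = FALSE])
  Z <- if (length(spec$fixed_x))
    as.matrix(data[, spec$fixed_x, drop = FALSE]) else NULL
  gh <- gh_probabilist(nodes)
  n <- nrow(Y)
  cw <- numeric(n)
  for (i in seq_len(n)) {
    yi <- Y[i, ]
    keep <- !is.na(yi)
    if (!any(keep)) { warning("empty observed subvector"); next }
    zi <- if (is.null(Z)) NULL else Z[i, ]
    h <- function(x) {
      cm <- cond$at(x, zi)
      drop(dmvnorm_log(yi[keep], cm$mu[keep],
                       cm$sigma[keep, keep, drop = FALSE])) +
        dnorm(x, 0, sqrt(psi_xi), log = TRUE)
    }
    if (adaptive) {
      opt <- optimize(function(x) -h(x), lower = -8 * sqrt(psi_xi),
                      upper = 8 * sqrt(psi_xi), tol = 1e-10)
      m <- opt$minimum
      d <- 1e-4 * sqrt(psi_xi)
      h2 <- (h(m + d) - 2 * h(m) + h(m - d)) / d^2
      s <- if (h2 < 0) 1 / sqrt(-h2) else sqrt(psi_xi)
    } else {
      m <- 0; s <- sqrt(psi_xi)
    }
    xk <- m + s * gh$x
    hk <- vapply(xk, h, numeric(1))
    # importance form: integral e^h dx = s * sum w_k e^{h_k} / phi(t_k)
    cw[i] <- logsumexp(hk - dnorm(gh$x, log = TRUE) + log(gh$w)) + log(s)
  }
  if (!all(is.finite(cw)))
    stop_schema("integration failure (non-finite weights) for subject(s): %s",
                paste(head(which(!is.finite(cw)), 5), collapse = ", "))
  list(total = sum(cw), casewise = cw)
}

strip_products <- function(spec) {
  rows <- product_rows(spec)
  pt <- if (length(rows)) spec$partable[-rows, , drop = FALSE]
  else spec$partable
  model_spec(spec$observed, spec$latents, pt, spec$fixed_x)
}

# Per-subject casewise FIML log-likelihoods for a linear spec.
casewise_loglik_matrix <- function(spec, theta, data) {
  im <- implied_moments(spec, theta)
  yv <- im$yvars
  Y <- as.matrix(data[, yv, drop = FALSE])
  n <- nrow(Y)
  mu_mat <- matrix(im$mu, n, length(yv), byrow = TRUE)
  if (!is.null(im$gamma))
    mu_mat <- mu_mat +
      as.matrix(data[, spec$fixed_x, drop = FALSE]) %*% t(im$gamma)
  cw <- numeric(n)
  obs <- !is.na(Y)
  key <- apply(obs, 1L, function(r) paste(which(r), collapse = ","))
  for (k in unique(key)) {
    idx <- which(key == k)
    j <- which(obs[idx[1L], ])
    if (!length(j)) { warning("empty observed subvector"); next }
    R <- Y[idx, j, drop = FALSE] - mu_mat[idx, j, drop = FALSE]
    S <- im$sigma[j, j, drop = FALSE]
    L <- chol(S)
    zq <- forwardsolve(t(L), t(R))
    cw[idx] <- -0.5 * length(j) * log(2 * pi) - sum(log(diag(L))) -
      0.5 * colSums(zq^2)
  }
  cw
}

# Conditional moments of the observed vector given the integrated latent
# equal to x (and, for subject-dependent product members, covariates z).
conditional_moments_builder <- function(spec, theta, xi) {
  est <- partable_estimates(spec, theta)
  pt <- spec$partable
  base <- ram_matrices(spec, theta)
  fx <- spec$fixed_x
  yv <- setdiff(spec$observed, fx)
  # condition: xi becomes a constant -> drop its variance, set mean to x
  base$S[xi, ] <- 0; base$S[, xi] <- 0
  base$S[fx, ] <- 0; base$S[, fx] <- 0; base$M[fx] <- 0
  rows <- product_rows(spec)
  list(
    yvars = yv,
    at = function(x, z = NULL) {
      A <- base$A; M <- base$M
      M[xi] <- x
      for (r in rows) {
        toks <- strsplit(pt$rhs[r], ":", fixed = TRUE)[[1]]
        beta <- est[r]
        lin <- setdiff(toks, c(xi, fx))
        fixv <- prod(vapply(toks[toks != xi & toks %in% fx],
                            function(v) z[[v]], numeric(1)),
                     if (xi %in% toks) x else 1)
        if (length(lin) == 0) {
          M[pt$lhs[r]] <- M[pt$lhs[r]] + beta * fixv
        } else if (length(lin) == 1) {
          A[pt$lhs[r], lin] <- A[pt$lhs[r], lin] + beta * fixv
        } else stop_schema("product '%s' has more than one linear member",
                           pt$rhs[r])
      }
      IA <- solve_IA(A)
      mu_all <- drop(IA %*% M)
      if (!is.null(z) && length(fx))
        mu_all <- mu_all + drop(IA[, fx, drop = FALSE] %*% unlist(z[fx]))
      Sg <- symm(IA %*% base$S %*% t(IA))
      list(mu = mu_all[yv], sigma = Sg[yv, yv, drop = FALSE])
    })
}
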