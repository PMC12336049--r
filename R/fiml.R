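# Full-information maximum likelihood for multivariate-normal models under
# arbitrary missingness. Likelihoods are accumulated per missing-data
# pattern from sufficient statistics, so each evaluation is O(1) in n.

# Group rows of Y by missing-data pattern and precompute per-pattern moments
# of (observed y block, fixed-x covariates z).
pattern_stats <- function(Y, Z = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    if (anyNA(Z))
      stop_schema("fixed-x covariates must be complete")
  }
  obs <- !is.na(Y)
  key <- apply(obs, 1L, function(r) paste(which(r), collapse = ","))
  out <- list()
  for (k in unique(key)) {
    rows <- which(key == k)
    cols <- which(obs[rows[1L], ])
    if (!length(cols)) {
      warning("record with no observed variables contributes 0 to the likelihood")
      next
    }
    Yg <- Y[rows, cols, drop = FALSE]
    ng <- length(rows)
    ybar <- colMeans(Yg)
    Yc <- sweep(Yg, 2L, ybar)
    Syy <- crossprod(Yc) / ng
    if (!is.null(Z)) {
      Zg <- Z[rows, , drop = FALSE]
      zbar <- colMeans(Zg)
      Zc <- sweep(Zg, 2L, zbar)
      Syz <- crossprod(Yc, Zc) / ng
      Szz <- crossprod(Zc) / ng
    } else zbar <- Syz <- Szz <- NULL
    out[[length(out) + 1L]] <- list(cols = cols, rows = rows, n = ng,
                                    ybar = ybar, Syy = Syy,
                                    zbar = zbar, Syz = Syz, Szz = Szz)
  }
  structure(list(patterns = out, n = n, p = ncol(Y),
                 ynames = colnames(Y)), class = "fiml_stats")
}

# Total FIML log-likelihood from pattern sufficient statistics.
# mu0: base mean (p), sigma: covariance (p x p), gamma: p x q or NULL.
fiml_loglik_stats <- function(mu0, sigma, gamma, stats) {
  tryCatch(fiml_loglik_stats_core(mu0, sigma, gamma, stats),
           error = function(e) -Inf)
}

fiml_loglik_stats_core <- function(mu0, sigma, gamma, stats) {
  ll <- 0
  for (pat in stats$patterns) {
    j <- pat$cols
    S <- sigma[j, j, drop = FALSE]
    L <- chol(S)
    if (is.null(gamma)) {
      rbar <- pat$ybar - mu0[j]
      Sr <- pat$Syy
    } else {
      W <- gamma[j, , drop = FALSE]
      rbar <- pat$ybar - drop(W %*% pat$zbar) - mu0[j]
      Sr <- pat$Syy - pat$Syz %*% t(W) - W %*% t(pat$Syz) +
        W %*% pat$Szz %*% t(W)
    }
    P <- chol2inv(L)
    q <- sum(P * Sr) + drop(crossprod(rbar, P %*% rbar))
    ll <- ll - 0.5 * pat$n *
      (length(j) * log(2 * pi) + 2 * sum(log(diag(L))) + q)
  }
  ll
}

#' Casewise FIML log-likelihood of one record
#'
#' The multivariate-normal log-density of a subject's observed subvector
#' under the sub-selected model-implied moments; this is the per-case
#' building block of full-information maximum likelihood. Values for the
#' spec's `fixed_x` covariates (if any) must be supplied and complete.
#'
#' @param spec a [model_spec()] without product terms.
#' @param theta named free-parameter vector.
#' @param record named numeric vector; `NA` entries (or omitted observed
#'   variables) are treated as missing.
#' @return log-likelihood contribution (0, with a warning, if nothing is
#'   observed).
#' @export
casewise_loglik <- function(spec, theta, record) {
  im <- implied_moments(spec, theta)
  record <- unlist(record)
  mu <- im$mu
  if (!is.null(im$gamma)) {
    z <- record[spec$fixed_x]
    if (anyNA(z)) stop_schema("fixed-x covariates must be complete")
    mu <- mu + drop(im$gamma %*% z)
  }
  y <- record[im$yvars]
  keep <- !is.na(y)
  if (!any(keep)) {
    warning("empty observed subvector; contributes 0")
    return(0)
  }
  drop(dmvnorm_log(y[keep], mu[keep],
                   im$sigma[keep, keep, drop = FALSE]))
}

#' Total FIML log-likelihood of a dataset
#'
#' @param spec a [model_spec()] without product terms.
#' @param theta named free-parameter vector.
#' @param data data.frame or matrix holding the spec's observed variables
#'   (missing values as `NA`); fixed-x columns must be complete.
#' @param stats optional precomputed [pattern_stats()] (internal reuse).
#' @export
fiml_loglik <- function(spec, theta, data, stats = NULL) {
  im <- implied_moments(spec, theta)
  if (is.null(stats)) stats <- spec_pattern_stats(spec, data)
  fiml_loglik_stats(im$mu, im$sigma, im$gamma, stats)
}

spec_pattern_stats <- function(spec, data) {
  y <- setdiff(spec$observed, spec$fixed_x)
  miss <- setdiff(spec$observed, colnames(data))
  if (length(miss))
    stop_schema("data is missing observed columns: %s", paste(miss, collapse = ", "))
  Y <- as.matrix(data[, y, drop = FALSE])
  Z <- if (length(spec$fixed_x)) as.matrix(data[, spec$fixed_x, drop = FALSE]) else NULL
  pattern_stats(Y, Z)
}

# Saturated (H1) model: unrestricted mean, covariance and, when covariates
# are present, unrestricted regression of every y on the covariates.
# Closed form with complete data, quasi-Newton over pattern statistics
# otherwise. Returns loglik and parameter count.
saturated_loglik <- function(Y, Z = NULL) {
  Y <- as.matrix(Y)
  p <- ncol(Y)
  q <- if (is.null(Z)) 0L else ncol(Z)
  npar <- p + p * q + p * (p + 1) / 2
  if (!anyNA(Y)) {
    n <- nrow(Y)
    if (is.null(Z)) {
      mu <- colMeans(Y)
      S <- crossprod(sweep(Y, 2L, mu)) / n
      ll <- -0.5 * n * (p * log(2 * pi) + determinant(S)$modulus[1] + p)
    } else {
      X <- cbind(1, Z)
      B <- solve(crossprod(X), crossprod(X, Y))
      R <- Y - X %*% B
      S <- crossprod(R) / n
      ll <- -0.5 * n * (p * log(2 * pi) + determinant(S)$modulus[1] + p)
    }
    return(list(loglik = as.numeric(ll), npar = npar))
  }
  stats <- pattern_stats(Y, Z)
  # start at available-case moments
  mu0 <- colMeans(Y, na.rm = TRUE)
  S0 <- stats_available_cov(Y)
  G0 <- matrix(0, p, q)
  L0 <- t(chol(S0))
  pack <- c(mu0, as.vector(G0), log(diag(L0)), L0[lower.tri(L0)])
  unpack <- function(th) {
    mu <- th[1:p]
    G <- if (q) matrix(th[p + seq_len(p * q)], p, q) else NULL
    rest <- th[(p + p * q + 1):length(th)]
    L <- matrix(0, p, p)
    diag(L) <- exp(rest[1:p])
    L[lower.tri(L)] <- rest[-(1:p)]
    list(mu = mu, gamma = G, sigma = L %*% t(L))
  }
  obj <- function(th) {
    u <- unpack(th)
    -fiml_loglik_stats(u$mu, u$sigma, u$gamma, stats)
  }
  opt <- nlminb(pack, obj, control = list(iter.max = 2000, eval.max = 4000,
                                          rel.tol = 1e-12))
  list(loglik = -opt$objective, npar = npar)
}

stats_available_cov <- function(Y) {
  S <- cov(Y, use = "pairwise.complete.obs")
  S[is.na(S)] <- 0
  ev <- eigen(symm(S), symmetric = TRUE)
  lam <- pmax(ev$values, 1e-6 * max(ev$values, 1))
  symm(ev$vectors %*% (lam * t(ev$vectors)))
}

# Independence (baseline) model: free means and variances, covariances zero.
# Under missingness the columns factorise, so per-column univariate ML.
baseline_loglik <- function(Y) {
  Y <- as.matrix(Y)
  ll <- 0
  for (j in seq_len(ncol(Y))) {
    yj <- Y[, j]
    yj <- yj[!is.na(yj)]
    m <- mean(yj); v <- mean((yj - m)^2)
    ll <- ll + sum(dnorm(yj, m, sqrt(v), log = TRUE))
  }
  list(loglik = ll, npar = 2L * ncol(Y))
}
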