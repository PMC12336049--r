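# Maximum-likelihood fitting of model specs. Variance parameters are
# optimised on a log scale; covariance/structural parameters are
# unconstrained. Non-positive-definite implied covariances are handled by a
# large finite barrier, so the optimiser backs away rather than failing.

PD_PENALTY <- 1e10

variance_labels <- function(spec) {
  pt <- spec$partable
  unique(pt$label[pt$free & pt$op == "~~" & pt$lhs == pt$rhs])
}

theta_to_trans <- function(theta, vlab) {
  th <- theta
  v <- intersect(names(th), vlab)
  th[v] <- log(pmax(th[v], 1e-8))
  th
}

trans_to_theta <- function(trans, vlab) {
  th <- trans
  v <- intersect(names(th), vlab)
  th[v] <- exp(th[v])
  th
}

num_grad <- function(f, x, h = 1e-5) {
  g <- numeric(length(x))
  for (j in seq_along(x)) {
    hj <- h * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + hj
    xm <- x; xm[j] <- x[j] - hj
    g[j] <- (f(xp) - f(xm)) / (2 * hj)
  }
  g
}

num_hess <- function(f, x, h = 1e-4) {
  q <- length(x)
  H <- matrix(0, q, q)
  for (j in seq_len(q)) {
    hj <- h * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + hj
    xm <- x; xm[j] <- x[j] - hj
    H[, j] <- (num_grad(f, xp, h) - num_grad(f, xm, h)) / (2 * hj)
  }
  symm(H)
}

pseudo_solve <- function(H, tol = 1e-10) {
  ev <- eigen(symm(H), symmetric = TRUE)
  scale_ <- max(abs(ev$values))
  if (scale_ == 0)
    return(list(inv = H * 0, pd = FALSE, null_vectors = ev$vectors))
  pos <- ev$values > tol * scale_
  V <- ev$vectors[, pos, drop = FALSE]
  list(inv = V %*% (t(V) / ev$values[pos]), pd = all(pos),
       null_vectors = ev$vectors[, !pos, drop = FALSE])
}

#' Fit a model spec by (full-information) maximum likelihood
#'
#' Maximises the FIML log-likelihood with a quasi-Newton optimiser.
#' Specs containing latent product terms are marginalised over the
#' interacting latents with Gauss-Hermite quadrature (see
#' [marginal_loglik_interaction()]); linear specs use closed-form implied
#' moments with per-pattern sufficient statistics.
#'
#' @param spec a [model_spec()].
#' @param data data.frame with the observed variables.
#' @param start optional named starting values (natural scale); defaults to
#'   the partable's `value` column with data-driven fallbacks.
#' @param se `"observed"` (inverse observed information, default) or
#'   `"none"`.
#' @param nodes quadrature nodes per interacting latent (product specs).
#' @param check_identification check the information-matrix rank at the
#'   optimum and fail with the aliased labels when deficient.
#' @param control optimiser control: `rel_tol` (relative log-likelihood
#'   change, default 1e-10), `grad_tol` (relative gradient max-norm defining
#'   the convergence flag, default 1e-5), `iter_max`.
#' @return object of class `sem_fit` with estimates, standard errors,
#'   z = est/SE, two-sided p-values, log-likelihood and convergence
#'   metadata.
#' @export
fit_ml <- function(spec, data, start = NULL, se = c("observed", "none"),
                   nodes = 15L, check_identification = TRUE,
                   control = list()) {
  se <- match.arg(se)
  ctrl <- modifyList(list(rel_tol = 1e-10, grad_tol = 1e-5, iter_max = 500L),
                     control)
  has_products <- n_product_terms(spec) > 0
  vlab <- variance_labels(spec)
  th0 <- default_start_values(spec, data, start)
  stats <- if (!has_products) spec_pattern_stats(spec, data) else NULL

  loglik_fun <- if (!has_products) {
    compile_linear_loglik(spec, stats)
  } else {
    function(theta) marginal_loglik_interaction(spec, theta, data,
                                                nodes = nodes)$total
  }
  tr0 <- theta_to_trans(th0, vlab)
  obj <- function(tr) {
    th <- trans_to_theta(setNames(tr, names(tr0)), vlab)
    ll <- loglik_fun(th)
    if (!is.finite(ll)) return(PD_PENALTY)
    -ll
  }

  lower <- rep(-Inf, length(tr0))
  lower[names(tr0) %in% vlab] <- -18   # variance floor exp(-18) on log scale
  opt <- nlminb(tr0, obj, lower = lower,
                control = list(iter.max = ctrl$iter_max,
                               eval.max = 4L * ctrl$iter_max,
                               rel.tol = ctrl$rel_tol))
  tr_hat <- setNames(opt$par, names(tr0))
  ll_hat <- -opt$objective
  g <- num_grad(obj, tr_hat)
  grad_norm <- max(abs(g)) / max(1, abs(ll_hat))
  if (grad_norm >= ctrl$grad_tol) {       # polish with BFGS if PORT stalled
    opt2 <- optim(tr_hat, obj, method = "BFGS",
                  control = list(maxit = 300, reltol = 1e-14))
    if (opt2$value <= -ll_hat + 1e-10) {
      tr_hat <- setNames(opt2$par, names(tr0))
      ll_hat <- -opt2$value
      g <- num_grad(obj, tr_hat)
      grad_norm <- max(abs(g)) / max(1, abs(ll_hat))
    }
  }
  th_hat <- trans_to_theta(tr_hat, vlab)
  converged <- grad_norm < ctrl$grad_tol

  vcov_nat <- se_vec <- NULL
  unstable <- FALSE
  if (se == "observed" || check_identification) {
    H <- num_hess(obj, tr_hat)
    ps <- pseudo_solve(H, tol = 1e-9)
    if (!ps$pd && check_identification) {
      load <- rowSums(abs(ps$null_vectors))
      bad <- names(tr_hat)[load > 0.3 * max(load)]
      # a variance estimated at (near) zero gives a flat log-scale
      # direction: a boundary solution, not aliasing
      boundary <- bad[bad %in% vlab & exp(tr_hat[bad]) < 1e-5]
      bad <- setdiff(bad, boundary)
      if (length(bad))
        stop_schema("model not identified (information matrix rank-deficient); aliased parameters: %s",
                    paste(bad, collapse = ", "))
      if (length(boundary))
        warning("variance parameter(s) at the zero boundary: ",
                paste(boundary, collapse = ", "))
    }
  }
  if (se == "observed") {
    if (!ps$pd) {
      warning("observed information not positive definite; ",
              "pseudo-inverse standard errors flagged as unstable")
      unstable <- TRUE
    }
    V_tr <- ps$inv
    J <- nat_jacobian(tr_hat, vlab)
    vcov_nat <- symm(J %*% V_tr %*% t(J))
    dimnames(vcov_nat) <- list(names(th_hat), names(th_hat))
    se_vec <- sqrt(pmax(diag(vcov_nat), 0))
  }

  fit <- structure(list(
    spec = spec, theta = th_hat, theta_trans = tr_hat,
    loglik = ll_hat, npar = length(th_hat),
    n = if (!is.null(stats)) stats$n else nrow(data),
    converged = converged, grad_norm = grad_norm,
    vcov = vcov_nat, se = se_vec, se_unstable = unstable,
    implied = if (!has_products) implied_moments(spec, th_hat) else NULL,
    data = data, stats = stats, has_products = has_products,
    nodes = nodes, control = ctrl), class = "sem_fit")
  fit$coef_table <- coef_table(fit)
  fit
}

# Jacobian of natural = h(transformed): diagonal (exp for log-variances).
nat_jacobian <- function(tr, vlab) {
  d <- rep(1, length(tr))
  v <- names(tr) %in% vlab
  d[v] <- exp(tr[v])
  diag(d, length(tr))
}

default_start_values <- function(spec, data, start = NULL) {
  th <- spec_start_values(spec)
  pt <- spec$partable
  for (lab in names(th)) {
    rows <- which(pt$free & pt$label == lab)
    r <- rows[1L]
    if (!is.na(pt$value[r]) && pt$value[r] != 0) { th[lab] <- pt$value[r]; next }
    if (pt$op[r] == "~~" && pt$lhs[r] == pt$rhs[r]) {
      v <- if (pt$lhs[r] %in% colnames(data))
        var(data[[pt$lhs[r]]], na.rm = TRUE) else 1
      th[lab] <- max(0.5 * v, 0.05)
    } else if (pt$op[r] == "~1") {
      th[lab] <- if (pt$lhs[r] %in% colnames(data))
        mean(data[[pt$lhs[r]]], na.rm = TRUE) else 0
    } else if (pt$op[r] == "=~") {
      th[lab] <- 1
    } else th[lab] <- if (th[lab] != 0) th[lab] else 0
  }
  if (!is.null(start)) th[names(start)] <- start
  # variances must start strictly positive
  vl <- variance_labels(spec)
  th[vl] <- pmax(th[vl], 1e-3)
  th
}

coef_table <- function(fit) {
  pt <- fit$spec$partable
  est <- partable_estimates(fit$spec, fit$theta)
  out <- data.frame(lhs = pt$lhs, op = pt$op, rhs = pt$rhs,
                    label = pt$label, free = pt$free, est = est,
                    stringsAsFactors = FALSE)
  out$se <- out$z <- out$p <- NA_real_
  if (!is.null(fit$se)) {
    idx <- out$free
    out$se[idx] <- fit$se[out$label[idx]]
    out$z[idx] <- out$est[idx] / out$se[idx]
    out$p[idx] <- 2 * pnorm(-abs(out$z[idx]))
  }
  out
}

#' Standard errors from the inverse observed information
#'
#' @param fit a converged [fit_ml()] result.
#' @return named numeric vector of standard errors (natural scale).
#' @export
standard_errors <- function(fit) {
  if (is.null(fit$se))
    stop_schema("fit was run with se = 'none'; refit with se = 'observed'")
  fit$se
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("sem_fit:", x$npar, "free parameters, n =", x$n, "\n")
  cat("logLik:", format(x$loglik, digits = 10),
      " converged:", x$converged,
      " (rel grad max-norm ", format(x$grad_norm, digits = 3), ")\n", sep = "")
  if (isTRUE(x$se_unstable)) cat("NOTE: standard errors flagged unstable\n")
  tb <- x$coef_table
  tb <- tb[tb$free, c("lhs", "op", "rhs", "est", "se", "z", "p")]
  print(utils::head(tb, 30), digits = 3, row.names = FALSE)
  if (nrow(tb) > 30) cat("... (", nrow(tb) - 30, " more rows)\n", sep = "")
  invisible(x)
}

#' @export
logLik.sem_fit <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$n,
            class = "logLik")
}

#' @export
coef.sem_fit <- function(object, ...) object$theta

#' @export
vcov.sem_fit <- function(object, ...) object$vcov

# Compile a linear spec to an integer-indexed likelihood evaluator: the
# generic partable walk (string indexing, per-row dispatch) dominates the
# per-evaluation cost of small models, so Monte-Carlo loops use this
# closure instead. Produces identical values to fiml_loglik().
compile_linear_loglik <- function(spec, stats) {
  pt <- spec$partable
  vars <- c(spec$observed, spec$latents)
  nv <- length(vars)
  vi <- setNames(seq_len(nv), vars)
  fx <- spec$fixed_x
  yv <- setdiff(spec$observed, fx)
  yi <- unname(vi[yv]); fxi <- unname(vi[fx])
  base <- pt$value
  base[is.na(base)] <- 0
  free_rows <- which(pt$free)
  free_lab <- pt$label[free_rows]

  opA <- pt$op %in% c("=~", "~") & !grepl(":", pt$rhs, fixed = TRUE)
  a_rows <- which(opA)
  a_i <- ifelse(pt$op[a_rows] == "=~", vi[pt$rhs[a_rows]],
                vi[pt$lhs[a_rows]])
  a_j <- ifelse(pt$op[a_rows] == "=~", vi[pt$lhs[a_rows]],
                vi[pt$rhs[a_rows]])
  s_rows <- which(pt$op == "~~")
  s_i <- unname(vi[pt$lhs[s_rows]]); s_j <- unname(vi[pt$rhs[s_rows]])
  keepS <- !(s_i %in% fxi | s_j %in% fxi)
  s_rows <- s_rows[keepS]; s_i <- s_i[keepS]; s_j <- s_j[keepS]
  m_rows <- which(pt$op == "~1")
  m_i <- unname(vi[pt$lhs[m_rows]])
  keepM <- !(m_i %in% fxi)
  m_rows <- m_rows[keepM]; m_i <- m_i[keepM]
  iA <- cbind(a_i, a_j)
  iS <- rbind(cbind(s_i, s_j), cbind(s_j, s_i))
  vS <- c(s_rows, s_rows)
  I_nv <- diag(nv)

  function(theta) {
    est <- base
    est[free_rows] <- theta[free_lab]
    A <- matrix(0, nv, nv); S <- matrix(0, nv, nv); M <- numeric(nv)
    A[iA] <- est[a_rows]
    S[iS] <- est[vS]
    M[m_i] <- est[m_rows]
    IA <- tryCatch(solve(I_nv - A), error = function(e) NULL)
    if (is.null(IA)) return(-Inf)
    total <- IA %*% S %*% t(IA)
    mu_all <- drop(IA %*% M)
    gamma <- if (length(fxi)) IA[yi, fxi, drop = FALSE] else NULL
    fiml_loglik_stats(mu_all[yi], symm(total[yi, yi, drop = FALSE]),
                      gamma, stats)
  }
}
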