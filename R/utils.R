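#' @keywords internal
"_PACKAGE"

#' @importFrom stats dnorm pnorm qnorm rnorm runif rbinom rgamma rnbinom
#'   pchisq qchisq rchisq var sd cov cor optim nlminb uniroot complete.cases
#'   setNames aggregate pt t.test chisq.test na.omit quantile coef
#' @importFrom utils read.csv write.csv modifyList head
NULL

# Row-wise log-sum-exp of a matrix (numerically stable).
logsumexp_rows <- function(M) {
  mx <- apply(M, 1L, max)
  mx + log(rowSums(exp(M - mx)))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Multivariate normal log-density via Cholesky; x may be a matrix (rows = obs).
dmvnorm_log <- function(x, mean, sigma) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  p <- ncol(x)
  L <- chol(sigma)
  z <- forwardsolve(t(L), t(x) - mean)
  -0.5 * p * log(2 * pi) - sum(log(diag(L))) - 0.5 * colSums(z^2)
}

# Gauss-Hermite nodes/weights in "probabilist" form for N(0, 1):
# integral f(x) phi(x) dx ~ sum w_i f(x_i).
gh_probabilist <- function(n) {
  gh <- pracma::gaussHermite(n)
  list(x = gh$x * sqrt(2), w = gh$w / sqrt(pi))
}

# Symmetrise a nearly-symmetric matrix.
symm <- function(A) (A + t(A)) / 2

# Cheap stable hash of an R object (config provenance), no external deps.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_schema <- function(...) stop(sprintf(...), call. = FALSE)
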