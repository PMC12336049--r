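#' Declarative SEM model specification
#'
#' A `model_spec` is a constrained-SEM description: observed and latent
#' variables, plus a parameter table with one row per loading, regression,
#' (co)variance or mean entry. Entries are either fixed (explicit value) or
#' free (optionally sharing a label to impose equality constraints).
#' Regressions may include product terms of two or three variables written
#' `"a:b"` or `"a:b:c"`; the spec without product rows implies a proper
#' multivariate-normal model.
#'
#' @param observed character vector of observed variable names.
#' @param latents character vector of latent variable names (may be empty).
#' @param partable data.frame with columns `lhs`, `op`, `rhs`, `free`,
#'   `value`, and optionally `label`. `op` is one of `"=~"` (latent `lhs`
#'   measured by indicator `rhs`), `"~"` (`lhs` regressed on `rhs`), `"~~"`
#'   ((co)variance between `lhs` and `rhs`), `"~1"` (mean/intercept of
#'   `lhs`). For free rows `value` is used as the starting value.
#' @param fixed_x character vector of observed variables treated as fixed
#'   exogenous regressors (the likelihood conditions on them).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(observed, latents = character(), partable,
                       fixed_x = character()) {
  stopifnot(is.data.frame(partable))
  req <- c("lhs", "op", "rhs", "free", "value")
  if (!all(req %in% names(partable)))
    stop_schema("partable must have columns: %s", paste(req, collapse = ", "))
  if (is.null(partable$label)) partable$label <- ""
  partable$label <- as.character(partable$label)
  partable$lhs <- as.character(partable$lhs)
  partable$rhs <- as.character(partable$rhs)
  partable$op <- as.character(partable$op)
  partable$free <- as.logical(partable$free)
  partable$value <- as.numeric(partable$value)

  if (anyDuplicated(c(observed, latents)))
    stop_schema("observed and latent variable names must be unique")
  vars <- c(observed, latents)
  refd <- unlist(strsplit(c(partable$lhs, partable$rhs[partable$op != "~1"]),
                          ":", fixed = TRUE))
  unknown <- setdiff(refd, c(vars, ""))
  if (length(unknown))
    stop_schema("partable references undeclared variables: %s",
                paste(unique(unknown), collapse = ", "))
  bad_fx <- setdiff(fixed_x, observed)
  if (length(bad_fx))
    stop_schema("fixed_x variables not observed: %s", paste(bad_fx, collapse = ", "))

  # auto-label free rows; equality constraints come from shared labels
  auto <- partable$label == ""
  partable$label[auto] <- trimws(paste(partable$lhs[auto], partable$op[auto],
                                       partable$rhs[auto]))
  fixed_rows <- !partable$free
  if (any(is.na(partable$value[fixed_rows])))
    stop_schema("fixed partable entries must carry explicit values")
  # free labels must not collide with different row meanings unless equality
  free_labels <- unique(partable$label[partable$free])

  spec <- structure(list(observed = observed, latents = latents,
                         partable = partable, fixed_x = fixed_x,
                         free_labels = free_labels),
                    class = "model_spec")
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  pt <- spec$partable
  prods <- grepl(":", pt$rhs, fixed = TRUE)
  if (any(prods & pt$op != "~"))
    stop_schema("product terms are only allowed on the rhs of regressions")
  for (r in pt$rhs[prods]) {
    mem <- strsplit(r, ":", fixed = TRUE)[[1]]
    if (length(mem) < 2L || length(mem) > 4L)
      stop_schema("product term '%s' must have 2-4 members", r)
  }
  invisible(spec)
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", length(x$observed), "observed,",
      length(x$latents), "latent;",
      sum(x$partable$free), "free rows (",
      length(x$free_labels), "free parameters ),",
      sum(!x$partable$free), "fixed rows\n")
  if (length(x$fixed_x)) cat("fixed-x:", paste(x$fixed_x, collapse = ", "), "\n")
  if (n_product_terms(x) > 0)
    cat("product terms:", n_product_terms(x), "\n")
  invisible(x)
}

n_product_terms <- function(spec)
  sum(grepl(":", spec$partable$rhs, fixed = TRUE))

#' Free parameters of a model spec
#'
#' @param spec a `model_spec`.
#' @return named numeric vector of starting values, one per free label.
#' @export
spec_start_values <- function(spec) {
  pt <- spec$partable
  fr <- pt[pt$free, , drop = FALSE]
  vals <- fr$value[!duplicated(fr$label)]
  names(vals) <- fr$label[!duplicated(fr$label)]
  vals[is.na(vals)] <- 0
  vals
}

# Fill a partable's `est` column from a named theta vector (free rows) and
# fixed values; returns the numeric vector of row estimates.
partable_estimates <- function(spec, theta) {
  pt <- spec$partable
  est <- pt$value
  idx <- pt$free
  miss <- setdiff(unique(pt$label[idx]), names(theta))
  if (length(miss))
    stop_schema("theta is missing parameters: %s", paste(miss, collapse = ", "))
  est[idx] <- theta[pt$label[idx]]
  est
}

#' Serialize a model spec to JSON
#'
#' @param spec a `model_spec`.
#' @param path optional file path; if omitted the JSON string is returned.
#' @export
spec_to_json <- function(spec, path = NULL) {
  doc <- list(observed = spec$observed, latents = spec$latents,
              fixed_x = spec$fixed_x, partable = spec$partable)
  js <- jsonlite::toJSON(doc, dataframe = "columns", auto_unbox = FALSE,
                         digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    invisible(path)
  } else js
}

#' Read a model spec from JSON
#'
#' @param x JSON string or file path produced by [spec_to_json()].
#' @export
spec_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x)
  pt <- as.data.frame(doc$partable, stringsAsFactors = FALSE)
  model_spec(observed = as.character(doc$observed),
             latents = as.character(doc$latents),
             partable = pt,
             fixed_x = as.character(doc$fixed_x))
}
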