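# Cohort I/O and Table-1-style descriptives.
#
# CSV dialect: header row, UTF-8, "." decimal separator, missing values
# encoded as empty fields. Doubles round-trip at 15 significant digits.

BASELINE_COLS <- c("id", "sex_female", "age_first_mri", "apoe4_count",
                   "education_years", "n_prior_assessments",
                   "prior_interval_months", "withdrawn", "deceased",
                   "gm_vol", "hippo_vol", "wmh_vol", "mem_composite",
                   "centiloid")
VISIT_COLS <- c("id", "T", "months_from_first_mri", "ef")

#' Write a cohort to baseline/visits CSV files
#'
#' Writes `baseline.csv` (one row per subject), `visits.csv` (long
#' executive-function table) and a JSON column dictionary sidecar.
#'
#' @param cohort a `cohort` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bp <- file.path(dir, "baseline.csv")
  vp <- file.path(dir, "visits.csv")
  write.csv(format_df15(cohort$baseline[, BASELINE_COLS]), bp,
            row.names = FALSE, na = "", quote = FALSE)
  write.csv(format_df15(cohort$visits[, VISIT_COLS]), vp,
            row.names = FALSE, na = "", quote = FALSE)
  dict <- list(
    baseline = list(
      id = "unique subject identifier",
      sex_female = "sex (1 = female, 0 = male)",
      age_first_mri = "age in years at first MRI",
      apoe4_count = "number of APOE e4 alleles (0/1/2)",
      education_years = "years of education",
      n_prior_assessments = "cognitive assessments before first MRI",
      prior_interval_months = "months containing those prior assessments",
      withdrawn = "withdrew during follow-up (0/1)",
      deceased = "died during follow-up (0/1)",
      gm_vol = "ICV-adjusted grey-matter volume",
      hippo_vol = "ICV-adjusted hippocampal volume",
      wmh_vol = "ICV-adjusted white-matter-hyperintensity volume",
      mem_composite = "episodic-memory composite at first MRI",
      centiloid = "PET amyloid burden, Centiloid scale"),
    visits = list(
      id = "subject identifier",
      T = "visit offset from first MRI, T in -3..3",
      months_from_first_mri = "18 * T",
      ef = "executive-function composite"))
  jsonlite::write_json(dict, file.path(dir, "dictionary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(baseline = bp, visits = vp))
}

format_df15 <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]]))
      df[[j]] <- ifelse(is.na(df[[j]]), NA,
                        formatC(df[[j]], digits = 15, format = "g"))
  df
}

#' Read and validate a cohort from CSV files
#'
#' @param baseline_path,visits_path paths written by [write_cohort()] (or
#'   equivalent tables).
#' @return a validated `cohort` object.
#' @export
read_cohort <- function(baseline_path, visits_path) {
  for (p in c(baseline_path, visits_path))
    if (!file.exists(p)) stop_schema("file not found: %s", p)
  b <- read.csv(baseline_path, na.strings = "")
  v <- read.csv(visits_path, na.strings = "")
  miss_b <- setdiff(BASELINE_COLS, names(b))
  if (length(miss_b))
    stop_schema("baseline table is missing column(s): %s",
                paste(miss_b, collapse = ", "))
  miss_v <- setdiff(VISIT_COLS, names(v))
  if (length(miss_v))
    stop_schema("visits table is missing column(s): %s",
                paste(miss_v, collapse = ", "))
  new_cohort(b[, BASELINE_COLS], v[, VISIT_COLS])
}

#' Sex-stratified descriptive statistics
#'
#' Table-1-style summary: overall and sex-stratified means/SDs (or
#' proportions), two-sample t (continuous) or chi-square (categorical)
#' p-values, and standardized mean differences
#' SMD = |m_f - m_m| / pooled SD with the unweighted pooled SD
#' \eqn{\sqrt{(s_m^2 + s_f^2)/2}}.
#'
#' @param cohort a `cohort` object.
#' @return data.frame of class `cohort_descriptives`.
#' @export
descriptives <- function(cohort) {
  b <- cohort$baseline
  if (nrow(b) == 0) stop_schema("empty cohort")
  ef0 <- cohort$visits$ef[cohort$visits$T == 0]
  ef0 <- ef0[match(b$id, cohort$visits$id[cohort$visits$T == 0])]
  vars <- list(
    age_first_mri = list(x = b$age_first_mri, type = "cont"),
    education_years = list(x = b$education_years, type = "cont"),
    apoe4_count = list(x = b$apoe4_count, type = "cat"),
    n_prior_assessments = list(x = b$n_prior_assessments, type = "cont"),
    prior_interval_months = list(x = b$prior_interval_months, type = "cont"),
    gm_vol = list(x = b$gm_vol, type = "cont"),
    hippo_vol = list(x = b$hippo_vol, type = "cont"),
    wmh_vol = list(x = b$wmh_vol, type = "cont"),
    withdrawn = list(x = b$withdrawn, type = "cat"),
    deceased = list(x = b$deceased, type = "cat"),
    mem_composite = list(x = b$mem_composite, type = "cont"),
    ef_at_first_mri = list(x = ef0, type = "cont"),
    centiloid = list(x = b$centiloid, type = "cont"))
  f <- b$sex_female
  both_sexes <- length(unique(f)) == 2
  if (!both_sexes)
    warning("single-sex cohort: stratified columns suppressed")
  rows <- lapply(names(vars), function(nm) {
    x <- vars[[nm]]$x; tp <- vars[[nm]]$type
    out <- data.frame(variable = nm, type = tp,
                      overall_mean = mean(x, na.rm = TRUE),
                      overall_sd = sd(x, na.rm = TRUE),
                      male_mean = NA_real_, male_sd = NA_real_,
                      female_mean = NA_real_, female_sd = NA_real_,
                      p = NA_real_, smd = NA_real_)
    if (!both_sexes) return(out)
    xm <- x[f == 0]; xf <- x[f == 1]
    out$male_mean <- mean(xm, na.rm = TRUE)
    out$male_sd <- sd(xm, na.rm = TRUE)
    out$female_mean <- mean(xf, na.rm = TRUE)
    out$female_sd <- sd(xf, na.rm = TRUE)
    out$smd <- smd_pooled(xm, xf)
    out$p <- tryCatch({
      if (tp == "cont") t.test(xm, xf)$p.value
      else suppressWarnings(chisq.test(table(x, f))$p.value)
    }, error = function(e) NA_real_)
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_descriptives", "data.frame")
  out
}

smd_pooled <- function(a, bb) {
  pooled <- sqrt((var(a, na.rm = TRUE) + var(bb, na.rm = TRUE)) / 2)
  if (!is.finite(pooled) || pooled == 0) return(0)
  abs(mean(bb, na.rm = TRUE) - mean(a, na.rm = TRUE)) / pooled
}

#' Analysis configuration
#'
#' @param time_unit `"visit"` (one 18-month interval, default) or
#'   `"month"`.
#' @param age_center years at which age is centred (default 70).
#' @param growth_forms growth functions to compare.
#' @param quadrature_nodes Gauss-Hermite nodes per interacting latent.
#' @param rel_tol,grad_tol optimiser tolerances.
#' @param include_amyloid extend the structural model with Centiloid.
#' @param seed integer seed for every stochastic stage.
#' @export
analysis_config <- function(time_unit = c("visit", "month"), age_center = 70,
                            growth_forms = c("linear", "quadratic",
                                             "logarithmic"),
                            quadrature_nodes = 15L, rel_tol = 1e-8,
                            grad_tol = 1e-5, include_amyloid = FALSE,
                            seed = 1L) {
  time_unit <- match.arg(time_unit)
  growth_forms <- match.arg(growth_forms, several.ok = TRUE)
  if (quadrature_nodes < 3) stop_schema("quadrature_nodes must be >= 3")
  if (rel_tol <= 0 || grad_tol <= 0) stop_schema("tolerances must be > 0")
  structure(list(time_unit = time_unit, age_center = age_center,
                 growth_forms = growth_forms,
                 quadrature_nodes = as.integer(quadrature_nodes),
                 rel_tol = rel_tol, grad_tol = grad_tol,
                 include_amyloid = include_amyloid, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop_schema("config file not found: %s", path)
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path)
  do.call(analysis_config, vals)
}
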