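# Synthetic-cohort generator with planted truth.
#
# The generator draws cohorts with the exact statistical structure the
# downstream analysis assumes: an episodic-memory composite built from an
# orthogonal brain component (MEMB, a weighted combination of three latent
# brain factors measured by ICV-adjusted volumes with 10% unreliability),
# a demographic component (MEMD, a linear combination of observed
# covariates), a residual reserve component (MEMR) and fixed measurement
# error; executive function follows a linear latent growth curve over
# 18-month visits T = -3..+3 whose intercept and slope are driven by
# planted standardized structural effects; attrition is informative
# (dropout hazard loads on the intercept/slope deviations).

TERM_LABELS <- c(
  memr = "MEMR", memb = "MEMB", memd = "MEMD", female = "Female sex",
  apoe = "APOE e4 carrier", age_c = "Age at first MRI (centred at 70 years)",
  abeta = "Abeta",
  "female:apoe" = "Female x APOE e4 carrier",
  "memr:memb" = "MEMR x MEMB", "memr:female" = "MEMR x Female sex",
  "memb:female" = "MEMB x Female sex",
  "memr:abeta" = "MEMR x Abeta", "memb:abeta" = "MEMB x Abeta",
  "female:abeta" = "Female sex x Abeta",
  "abeta:apoe" = "Abeta x APOE e4 carrier",
  "memr:memb:female" = "MEMR x MEMB x Female sex",
  "memr:memb:abeta" = "MEMR x MEMB x Abeta",
  "memr:female:abeta" = "MEMR x Female sex x Abeta",
  "memb:female:abeta" = "MEMB x Female sex x Abeta",
  "female:abeta:apoe" = "Female sex x Abeta x APOE e4 carrier",
  "memr:memb:female:abeta" = "MEMR x MEMB x Female sex x Abeta")

base_terms <- function() c("memr", "memb", "memd", "female", "apoe", "age_c",
                           "female:apoe", "memr:memb", "memr:female",
                           "memb:female", "memr:memb:female")

amyloid_terms <- function() c("memr", "memb", "memd", "female", "abeta",
                              "apoe", "age_c", "memr:memb", "memr:female",
                              "memr:abeta", "memb:female", "memb:abeta",
                              "female:abeta", "female:apoe", "abeta:apoe",
                              "memr:memb:female", "memr:memb:abeta",
                              "memr:female:abeta", "memb:female:abeta",
                              "female:abeta:apoe", "memr:memb:female:abeta")

#' Planted structural truth for the synthetic cohort
#'
#' Standardized structural coefficients (executive-function intercept and
#' slope regressed on the memory components, sex, covariates and their
#' products), latent variances, the fixed measurement-error constraints,
#' and the executive-function growth parameters. Defaults reproduce the
#' coefficient structure the analysis is designed to recover.
#'
#' @param amyloid plant the extended coefficient set including Centiloid
#'   amyloid burden and all its interactions.
#' @param zero plant all structural effects at 0 (null configuration).
#' @param null_interactions keep the main effects but plant every
#'   interaction effect at 0 (type-I-error configuration).
#' @param ... named overrides of any field.
#' @return object of class `planted_truth`.
#' @export
planted_truth <- function(amyloid = FALSE, zero = FALSE,
                          null_interactions = FALSE, ...) {
  if (!amyloid) {
    terms <- base_terms()
    bi <- c(0.413, 0.628, 0.268, 0.016, 0.040, -0.008,
            0.033, -0.110, -0.047, -0.039, -0.190)
    bs <- c(0.028, 0.123, 0.025, 0.000, -0.044, 0.002,
            0.012, 0.007, 0.009, -0.004, -0.069)
  } else {
    terms <- amyloid_terms()
    bi <- c(0.409, 0.568, 0.264, -0.008, 0.000, -0.117, -0.009,
            -0.107, -0.075, 0.001, 0.052, 0.003, -0.001, 0.121, 0.004,
            -0.142, 0.001, 0.001, -0.003, -0.002, -0.001)
    bs <- c(-0.005, 0.066, 0.021, -0.013, 0.000, -0.030, 0.002,
            0.047, 0.035, 0.000, 0.037, 0.001, 0.000, 0.019, 0.000,
            -0.105, 0.000, 0.000, -0.001, 0.000, 0.000)
  }
  if (zero) bi <- bs <- rep(0, length(terms))
  if (null_interactions) {
    inter <- grepl(":", terms, fixed = TRUE)
    bi[inter] <- 0; bs[inter] <- 0
  }
  structural_betas <- data.frame(term = terms, intercept = bi, slope = bs,
                                 stringsAsFactors = FALSE)
  tr <- list(
    brain_reliability = 0.90,
    mem_error_var = 0.1365,
    memr_var = 0.30,
    memb_var = 0.25,
    brain_corr = matrix(c(1, 0.55, -0.35,
                          0.55, 1, -0.30,
                          -0.35, -0.30, 1), 3, 3),
    brain_weight_dir = c(0.5, 0.6, -0.3),
    demo_weights = c(edu_years = 0.098, n_prior = 0.030,
                     prior_interval = 0.004, n_prior_x_interval = -8e-4,
                     withdrawn = -0.15, deceased = -0.30),
    structural_betas = structural_betas,
    ef_intercept_var = 0.70,
    ef_slope_var = 0.02,
    ef_resid_corr = -0.20,
    ef_residual_var_per_visit = 0.057,
    ef_intercept_mean = 0.82,
    ef_slope_mean = -0.02,
    mem_mean = 0.50,
    memr_sex_shift = 0.33)
  tr <- modifyList(tr, list(...))
  class(tr) <- "planted_truth"
  validate_truth(tr)
  tr
}

validate_truth <- function(tr) {
  stopifnot(tr$mem_error_var > 0, tr$memr_var > 0, tr$memb_var > 0,
            tr$ef_residual_var_per_visit > 0, tr$ef_intercept_var > 0,
            tr$ef_slope_var > 0, abs(tr$ef_resid_corr) < 1)
  ev <- eigen(tr$brain_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop_schema("brain correlation matrix is not positive definite")
  invisible(tr)
}

#' Attrition configuration
#'
#' Per-visit post-baseline dropout with hazard loadings on the subject's
#' executive-function intercept/slope deviations (standardized), plus a
#' per-visit death hazard with a male multiplier.
#'
#' @param base_dropout_hazard per-visit withdrawal probability at average
#'   standing.
#' @param hazard_intercept,hazard_slope logit-scale loadings on the
#'   standardized intercept and slope deviations.
#' @param death_prob per-visit death probability (females).
#' @param male_death_multiplier hazard multiplier for males.
#' @param intermittent_prob probability that an in-window visit is missed
#'   without dropout (default 0: monotone missingness).
#' @export
attrition_config <- function(base_dropout_hazard = 0.11,
                             hazard_intercept = -0.25,
                             hazard_slope = -0.50,
                             death_prob = 0.012,
                             male_death_multiplier = 2.4,
                             intermittent_prob = 0) {
  stopifnot(base_dropout_hazard >= 0, base_dropout_hazard < 1,
            death_prob >= 0, death_prob < 1, male_death_multiplier > 0,
            intermittent_prob >= 0, intermittent_prob < 1)
  structure(list(base_dropout_hazard = base_dropout_hazard,
                 hazard_intercept = hazard_intercept,
                 hazard_slope = hazard_slope,
                 death_prob = death_prob,
                 male_death_multiplier = male_death_multiplier,
                 intermittent_prob = intermittent_prob),
            class = "attrition_config")
}

#' Synthetic-cohort generator configuration
#'
#' Defaults emulate the reference cohort's baseline marginals (n = 997;
#' 55.4% female; APOE e4 counts 65.1/29.2/5.7%; age 72.79 (6.60); sex-
#' specific education 13.33 (3.18) male / 12.63 (2.95) female; grey-matter
#' 454.17 (25.32), hippocampal 5.70 (0.72) and right-skewed WMH 9.36
#' (13.41) volumes; Centiloid 28.78 (42.83)) together with the planted
#' structural truth and informative attrition.
#'
#' `model_faithful = TRUE` zeroes the realism features that sit outside
#' the estimation model family (female MEMR advantage, lognormal WMH
#' marginal): parameter-recovery experiments are parametric-bootstrap
#' studies and must generate from the fitted model family.
#'
#' @param n_subjects cohort size.
#' @param prop_female fraction female.
#' @param apoe_probs probabilities of 0/1/2 e4 alleles (sum 1).
#' @param age_mean,age_sd years at first MRI.
#' @param edu_mean_male,edu_sd_male,edu_mean_female,edu_sd_female years.
#' @param indicator_means,indicator_sds named (gm, hippo, wmh) raw-scale
#'   affine back-transform of the standardized indicators.
#' @param wmh_lognormal give WMH a right-skewed (lognormal) marginal.
#' @param centiloid_mean,centiloid_sd,centiloid_missing Centiloid scale.
#' @param planted a [planted_truth()].
#' @param attrition an [attrition_config()].
#' @param model_faithful zero the model-external realism features.
#' @param seed integer RNG seed.
#' @export
generator_config <- function(n_subjects = 997,
                             prop_female = 552 / 997,
                             apoe_probs = c(649, 291, 57) / 997,
                             age_mean = 72.79, age_sd = 6.60,
                             edu_mean_male = 13.33, edu_sd_male = 3.18,
                             edu_mean_female = 12.63, edu_sd_female = 2.95,
                             indicator_means = c(gm = 454.17, hippo = 5.70,
                                                 wmh = 9.36),
                             indicator_sds = c(gm = 25.32, hippo = 0.72,
                                               wmh = 13.41),
                             wmh_lognormal = TRUE,
                             centiloid_mean = 28.78, centiloid_sd = 42.83,
                             centiloid_missing = 0,
                             planted = planted_truth(),
                             attrition = attrition_config(),
                             model_faithful = FALSE,
                             seed = 1L) {
  if (model_faithful) {
    planted$memr_sex_shift <- 0
    wmh_lognormal <- FALSE
    # non-informative dropout: hazard loadings on the growth deviations
    # would make the withdrawn/deceased MEMD regressors endogenous
    attrition$hazard_intercept <- 0
    attrition$hazard_slope <- 0
  }
  cfg <- list(n_subjects = as.integer(n_subjects), prop_female = prop_female,
              apoe_probs = apoe_probs, age_mean = age_mean, age_sd = age_sd,
              edu_mean_male = edu_mean_male, edu_sd_male = edu_sd_male,
              edu_mean_female = edu_mean_female, edu_sd_female = edu_sd_female,
              indicator_means = indicator_means, indicator_sds = indicator_sds,
              wmh_lognormal = wmh_lognormal,
              centiloid_mean = centiloid_mean, centiloid_sd = centiloid_sd,
              centiloid_missing = centiloid_missing,
              planted = planted, attrition = attrition, seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$n_subjects < 1) stop_schema("n_subjects must be >= 1")
  if (abs(sum(cfg$apoe_probs) - 1) > 1e-12)
    stop_schema("apoe_probs must sum to 1")
  if (any(cfg$apoe_probs < 0)) stop_schema("apoe_probs must be non-negative")
  if (cfg$prop_female < 0 || cfg$prop_female > 1)
    stop_schema("prop_female must lie in [0, 1]")
  sds <- c(cfg$age_sd, cfg$edu_sd_male, cfg$edu_sd_female,
           cfg$indicator_sds, cfg$centiloid_sd)
  if (any(sds <= 0)) stop_schema("all sds must be > 0")
  validate_truth(cfg$planted)
  invisible(cfg)
}

# ---- planted-coefficient machinery -------------------------------------

# Evaluate structural design columns from base variables.
structural_design <- function(base, terms) {
  out <- sapply(terms, function(tm) {
    toks <- strsplit(tm, ":", fixed = TRUE)[[1]]
    Reduce(`*`, lapply(toks, function(t) base[[t]]))
  })
  colnames(out) <- terms
  out
}

moment_cache <- new.env(parent = emptyenv())

# Population covariance matrix of the structural predictors, by large-n
# Monte Carlo under the config (isolated RNG; memoised per config).
predictor_moments <- function(cfg, terms, n_mc = 200000L) {
  key <- paste(config_hash(cfg[setdiff(names(cfg), c("n_subjects", "seed"))]),
               paste(terms, collapse = "|"))
  if (!is.null(moment_cache[[key]])) return(moment_cache[[key]])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(104729L)
  base <- draw_base_variables(cfg, n_mc, for_moments = TRUE)
  X <- structural_design(base, terms)
  mom <- list(mean = colMeans(X), cov = cov(X),
              sds = apply(X, 2, sd),
              memd_mean = mean(base$memd), memd_sd = sd(base$memd))
  moment_cache[[key]] <- mom
  mom
}

# Draw the exogenous base variables and latent components (no EF yet).
# In `for_moments` mode (the large-n moment run) the growth deviations are
# drawn standardized, since only the predictor moments are needed.
draw_base_variables <- function(cfg, n, for_moments = FALSE) {
  tr <- cfg$planted
  female <- rbinom(n, 1, cfg$prop_female)
  apoe <- sample(0:2, n, replace = TRUE, prob = cfg$apoe_probs)
  age <- rnorm(n, cfg$age_mean, cfg$age_sd)
  edu <- ifelse(female == 1,
                rnorm(n, cfg$edu_mean_female, cfg$edu_sd_female),
                rnorm(n, cfg$edu_mean_male, cfg$edu_sd_male))
  # prior-assessment exposure: counts with mean 2.34, sd 1.62 (capped),
  # and the months containing them (right-skewed)
  n_prior <- pmin(rnbinom(n, size = 19.5, mu = 2.34), 6L)
  interval <- ifelse(n_prior > 0,
                     rgamma(n, shape = 0.64, scale = 38.2), 0)
  # Centiloid: shifted gamma reproducing mean/SD with right skew
  cl_mu <- cfg$centiloid_mean + 10
  cl_shape <- cl_mu^2 / cfg$centiloid_sd^2
  centiloid <- -10 + rgamma(n, shape = cl_shape,
                            scale = cfg$centiloid_sd^2 / cl_mu)
  # latent brain factors (standardized indicator scale, reliability var)
  Rb <- tr$brain_corr * tr$brain_reliability
  B <- matrix(rnorm(3 * n), n, 3) %*% chol(Rb)
  w <- planted_brain_weights(tr)
  memb <- drop(B %*% w)
  memr0 <- rnorm(n, 0, sqrt(tr$memr_var))
  memr <- memr0 + tr$memr_sex_shift * female

  # growth deviations: the attrition flags (needed before MEMD) load on them
  if (for_moments) {
    zI <- zS <- 1; zIS <- tr$ef_resid_corr
  } else {
    zI <- tr$ef_intercept_var * (1 - planted_r2(cfg, "intercept"))
    zS <- tr$ef_slope_var * (1 - planted_r2(cfg, "slope"))
    if (zI <= 0 || zS <= 0)
      stop_schema("planted structural effects imply non-positive residual variance")
    zIS <- tr$ef_resid_corr * sqrt(zI * zS)
  }
  Zmat <- matrix(rnorm(2 * n), n, 2) %*% chol(matrix(c(zI, zIS, zIS, zS), 2))
  zeta_i <- Zmat[, 1]; zeta_s <- Zmat[, 2]

  base <- list(female = female, apoe = apoe, age = age, age_c = age - 70,
               edu_years = edu, n_prior = n_prior, prior_interval = interval,
               n_prior_x_interval = n_prior * interval,
               centiloid = centiloid, abeta = centiloid,
               B = B, memb = memb, memr = memr, memr0 = memr0,
               zeta_i = zeta_i, zeta_s = zeta_s,
               sd_zeta = c(sqrt(zI), sqrt(zS)), zIS = zIS)
  if (for_moments) {
    att <- simulate_attrition_flags(cfg$attrition, female, zeta_i, zeta_s,
                                    sd_i = sqrt(zI), sd_s = sqrt(zS))
    base$withdrawn <- att$withdrawn
    base$deceased <- att$deceased
    base$memd <- planted_memd(cfg, base)
  }
  base
}

planted_brain_weights <- function(tr) {
  Rb <- tr$brain_corr * tr$brain_reliability
  dir <- tr$brain_weight_dir
  dir * sqrt(tr$memb_var / drop(t(dir) %*% Rb %*% dir))
}

# MEMD: planted linear combination of the demographic/methodological
# covariates. Nominal population centres only shift the intercept (the
# slopes are what the estimator recovers), so they are held fixed.
planted_memd <- function(cfg, base) {
  d <- cfg$planted$demo_weights
  centres <- c(edu_years = cfg$edu_mean_male * (1 - cfg$prop_female) +
                 cfg$edu_mean_female * cfg$prop_female,
               n_prior = 2.34, prior_interval = 21.7,
               n_prior_x_interval = 57.0, withdrawn = 0.25, deceased = 0.05)
  drop(d["edu_years"] * (base$edu_years - centres["edu_years"]) +
         d["n_prior"] * (base$n_prior - centres["n_prior"]) +
         d["prior_interval"] * (base$prior_interval - centres["prior_interval"]) +
         d["n_prior_x_interval"] * (base$n_prior_x_interval - centres["n_prior_x_interval"]) +
         d["withdrawn"] * (base$withdrawn - centres["withdrawn"]) +
         d["deceased"] * (base$deceased - centres["deceased"]))
}

# R-squared of the planted standardized structural model for one outcome.
planted_r2 <- function(cfg, outcome = c("intercept", "slope")) {
  outcome <- match.arg(outcome)
  sb <- cfg$planted$structural_betas
  mom <- predictor_moments(cfg, sb$term)
  ok <- mom$sds > 1e-10          # constant predictors contribute nothing
  if (!any(ok)) return(0)
  R <- cov2cor(mom$cov[ok, ok, drop = FALSE])
  beta <- sb[[outcome]][ok]
  drop(t(beta) %*% R %*% beta)
}

# Raw-scale structural coefficients from the planted standardized ones.
planted_raw_betas <- function(cfg, outcome = c("intercept", "slope")) {
  outcome <- match.arg(outcome)
  sb <- cfg$planted$structural_betas
  mom <- predictor_moments(cfg, sb$term)
  sd_out <- sqrt(if (outcome == "intercept") cfg$planted$ef_intercept_var
                 else cfg$planted$ef_slope_var)
  raw <- ifelse(mom$sds > 1e-10, sb[[outcome]] * sd_out / mom$sds, 0)
  setNames(raw, sb$term)
}

simulate_attrition_flags <- function(att, female, zeta_i, zeta_s,
                                     sd_i, sd_s, n_post = 3L) {
  n <- length(female)
  lin <- qlogis(max(att$base_dropout_hazard, 1e-12)) +
    att$hazard_intercept * zeta_i / sd_i +
    att$hazard_slope * zeta_s / sd_s
  p_drop <- if (att$base_dropout_hazard == 0) rep(0, n) else plogis(lin)
  p_death <- att$death_prob *
    ifelse(female == 1, 1, att$male_death_multiplier)
  p_death <- pmin(p_death, 1)
  drop_after <- rep(n_post, n)     # last post-baseline visit observed
  withdrawn <- deceased <- integer(n)
  alive <- rep(TRUE, n)
  for (t in seq_len(n_post)) {
    dies <- alive & (runif(n) < p_death)
    deceased[dies] <- 1L
    drop_after[dies] <- pmin(drop_after[dies], t - 1L)
    alive[dies] <- FALSE
    drops <- alive & withdrawn == 0L & (runif(n) < p_drop)
    withdrawn[drops] <- 1L
    drop_after[drops] <- pmin(drop_after[drops], t - 1L)
    alive[drops] <- FALSE
  }
  list(withdrawn = withdrawn, deceased = deceased, drop_after = drop_after)
}

# ---- cohort generation --------------------------------------------------

#' Generate a synthetic cohort with planted truth
#'
#' @param config a [generator_config()].
#' @return object of class `cohort`: `$baseline` (one row per subject),
#'   `$visits` (long executive-function table with columns `id`, `T`,
#'   `months_from_first_mri`, `ef`), `$time_codes`, and a `$truth`
#'   attribute carrying the per-subject latent values and the planted
#'   configuration for recovery comparisons.
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  tr <- config$planted
  # fail early on non-positive-definite implied structures
  if (planted_r2(config, "intercept") >= 1 || planted_r2(config, "slope") >= 1)
    stop_schema("planted structural betas imply R-squared >= 1 (non-PD)")
  set.seed(config$seed)
  n <- config$n_subjects
  base <- draw_base_variables(config, n)
  att <- simulate_attrition_flags(config$attrition, base$female,
                                  base$zeta_i, base$zeta_s,
                                  sd_i = base$sd_zeta[1], sd_s = base$sd_zeta[2])
  base$withdrawn <- att$withdrawn
  base$deceased <- att$deceased
  base$memd <- planted_memd(config, base)

  sb <- tr$structural_betas
  X <- structural_design(base, sb$term)
  mom <- predictor_moments(config, sb$term)
  Xc <- sweep(X, 2, mom$mean)   # products formed from centred components
  bI <- planted_raw_betas(config, "intercept")
  bS <- planted_raw_betas(config, "slope")
  I <- tr$ef_intercept_mean + drop(Xc %*% bI) + base$zeta_i
  S <- tr$ef_slope_mean + drop(Xc %*% bS) + base$zeta_s

  mem_nu <- tr$mem_mean - tr$memr_sex_shift * config$prop_female
  mem <- mem_nu + base$memb + base$memd + base$memr +
    rnorm(n, 0, sqrt(tr$mem_error_var))

  # indicators: standardized latent + error, then raw-scale back-transform
  err_sd <- sqrt(1 - tr$brain_reliability)
  ind_std <- base$B + matrix(rnorm(3 * n, 0, err_sd), n, 3)
  gm <- config$indicator_means["gm"] + config$indicator_sds["gm"] * ind_std[, 1]
  hippo <- config$indicator_means["hippo"] + config$indicator_sds["hippo"] * ind_std[, 2]
  if (config$wmh_lognormal) {
    # monotone lognormal transform of the standardized score, rescaled to
    # the target mean/SD (right skew: SD exceeds the mean)
    cv <- config$indicator_sds["wmh"] / config$indicator_means["wmh"]
    slog <- sqrt(log(1 + cv^2))
    raw <- exp(slog * ind_std[, 3])
    wmh <- config$indicator_means["wmh"] * raw / exp(slog^2 / 2)
  } else {
    wmh <- config$indicator_means["wmh"] + config$indicator_sds["wmh"] * ind_std[, 3]
  }

  centiloid <- base$centiloid
  if (config$centiloid_missing > 0)
    centiloid[runif(n) < config$centiloid_missing] <- NA_real_

  start_T <- -pmin(base$n_prior, 3L)
  baseline <- data.frame(
    id = seq_len(n), sex_female = base$female, age_first_mri = base$age,
    apoe4_count = base$apoe, education_years = base$edu_years,
    n_prior_assessments = base$n_prior,
    prior_interval_months = base$prior_interval,
    withdrawn = base$withdrawn, deceased = base$deceased,
    gm_vol = gm, hippo_vol = hippo, wmh_vol = wmh,
    mem_composite = mem, centiloid = centiloid)

  sig_e <- sqrt(tr$ef_residual_var_per_visit)
  lens <- att$drop_after - start_T + 1L
  ids <- rep.int(seq_len(n), lens)
  Ts <- sequence(lens, from = start_T, by = 1L)
  visits <- data.frame(id = ids, T = Ts, months_from_first_mri = 18 * Ts,
                       ef = I[ids] + S[ids] * Ts +
                         rnorm(length(Ts), 0, sig_e))
  if (config$attrition$intermittent_prob > 0) {
    keep <- visits$T == 0 |
      runif(nrow(visits)) >= config$attrition$intermittent_prob
    visits <- visits[keep, ]
  }

  truth <- list(memr = base$memr, memb = base$memb, memd = base$memd,
                brain = base$B, intercept = I, slope = S,
                zeta_i = base$zeta_i, zeta_s = base$zeta_s,
                sd_zeta = base$sd_zeta,
                drop_after = att$drop_after, start_T = start_T,
                raw_betas = list(intercept = bI, slope = bS),
                config = config)
  new_cohort(baseline, visits, truth = truth)
}

new_cohort <- function(baseline, visits, truth = NULL) {
  obj <- structure(list(baseline = baseline, visits = visits,
                        time_codes = -3:3, truth = truth),
                   class = "cohort")
  validate_cohort(obj)
  obj
}

validate_cohort <- function(x) {
  b <- x$baseline; v <- x$visits
  if (anyDuplicated(b$id))
    stop_schema("duplicate subject ids: %s",
                paste(unique(b$id[duplicated(b$id)]), collapse = ", "))
  bad_T <- !(v$T %in% x$time_codes)
  if (any(bad_T))
    stop_schema("visit offsets outside the allowed set (-3..3): rows %s",
                paste(head(which(bad_T), 5), collapse = ", "))
  bad_apoe <- !(b$apoe4_count %in% 0:2)
  if (any(bad_apoe))
    stop_schema("apoe4_count outside {0,1,2} for subject(s): %s",
                paste(head(b$id[bad_apoe], 5), collapse = ", "))
  bad_sex <- !(b$sex_female %in% 0:1)
  if (any(bad_sex))
    stop_schema("sex_female outside {0,1} for subject(s): %s",
                paste(head(b$id[bad_sex], 5), collapse = ", "))
  orphan <- setdiff(v$id, b$id)
  if (length(orphan))
    stop_schema("visits reference unknown subject ids: %s",
                paste(head(orphan, 5), collapse = ", "))
  no_ef <- setdiff(b$id, v$id[!is.na(v$ef)])
  if (length(no_ef))
    stop_schema("subjects without any EF observation: %s",
                paste(head(no_ef, 5), collapse = ", "))
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort:", nrow(x$baseline), "subjects,", nrow(x$visits),
      "EF observations over T in {-3..3} (18-month visits)\n")
  cat(sprintf("  female: %.1f%%; withdrawn: %.1f%%; deceased: %.1f%%\n",
              100 * mean(x$baseline$sex_female),
              100 * mean(x$baseline$withdrawn),
              100 * mean(x$baseline$deceased)))
  if (!is.null(x$truth)) cat("  planted truth attached\n")
  invisible(x)
}

#' Apply informative attrition to a complete-grid cohort
#'
#' Deletes EF observations after a simulated dropout visit, with monotone
#' missingness, and sets the withdrawn/deceased flags consistently. The
#' dropout hazard loads on the subject's intercept/slope deviations, so
#' subjects who decline faster leave earlier when the slope loading is
#' negative. Requires a generator-produced cohort (the planted deviations
#' travel with it).
#'
#' @param cohort a [generate_cohort()] result with complete EF grids.
#' @param attrition an [attrition_config()].
#' @param seed RNG seed.
#' @export
apply_attrition <- function(cohort, attrition, seed = 1L) {
  if (is.null(cohort$truth))
    stop_schema("apply_attrition needs a generator-produced cohort with truth attached")
  set.seed(seed)
  tru <- cohort$truth
  att <- simulate_attrition_flags(attrition, cohort$baseline$sex_female,
                                  tru$zeta_i, tru$zeta_s,
                                  sd_i = tru$sd_zeta[1], sd_s = tru$sd_zeta[2])
  b <- cohort$baseline
  b$withdrawn <- att$withdrawn
  b$deceased <- att$deceased
  v <- cohort$visits
  keep <- v$T <= att$drop_after[match(v$id, b$id)]
  v <- v[keep, , drop = FALSE]
  tru$drop_after <- att$drop_after
  new_cohort(b, v, truth = tru)
}

#' Echo the planted standardized truth in reporting order
#'
#' @param config a [generator_config()].
#' @return data.frame with one row per structural term and outcome,
#'   in the canonical coefficient-table row order.
#' @export
truth_report <- function(config) {
  sb <- config$planted$structural_betas
  out <- rbind(
    data.frame(outcome = "intercept", term = sb$term,
               label = TERM_LABELS[sb$term], est = sb$intercept),
    data.frame(outcome = "slope", term = sb$term,
               label = TERM_LABELS[sb$term], est = sb$slope))
  rownames(out) <- NULL
  out
}
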