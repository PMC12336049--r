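# Stage 3: the joint analytical model. Executive-function intercept and
# slope are regressed on the residual reserve index (MEMR), brain
# integrity (MEMB), the demographic component (MEMD), sex, covariates and
# all their 2-/3-way products (optionally the Centiloid four-way
# extension), with the memory decomposition and the linear growth curve
# estimated simultaneously by maximum likelihood.
#
# Estimation: conditional on the two interacting latents (MEMR, MEMB)
# the model is linear Gaussian with a covariance that does not depend on
# the conditioning point, so the marginal likelihood is evaluated on a
# shared prior-scaled two-dimensional Gauss-Hermite grid with all
# subjects vectorised per missing-data pattern, and the exact gradient of
# the discretised likelihood is assembled from posterior node moments.

AN_P <- 11L  # ind_gm, ind_hippo, ind_wmh, mem, ef_m3..ef_p3
AN_IND <- 1:3; AN_MEM <- 4L; AN_EF <- 5:11

term_tokens <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

term_obs_part <- function(term) {
  toks <- setdiff(term_tokens(term), c("memr", "memb"))
  if (!length(toks)) "" else paste(toks, collapse = ":")
}

term_latents <- function(term) intersect(term_tokens(term), c("memr", "memb"))

# observed covariate columns the structural design needs
analytical_zcols <- function(terms, covariates) {
  obs <- setdiff(unique(vapply(terms, term_obs_part, character(1))), "")
  obs <- setdiff(obs, "memd")
  c(covariates, obs)
}

#' Build the joint analytical model spec
#'
#' Returns the declarative spec of the Fig.-2-style joint model:
#' decomposition + linear growth + structural regressions of the EF
#' intercept and slope on MEMR, MEMB, MEMD, female sex, APOE e4 count,
#' centred age, the sex-by-APOE control, and all latent products
#' (MEMR x MEMB and the triple/quadruple products with the observed
#' moderators). With `include_amyloid = TRUE` the Centiloid main effect
#' and every amyloid interaction up to MEMR x MEMB x sex x Abeta is
#' added (21 structural predictors per outcome instead of 11).
#'
#' @param include_amyloid extend with the Centiloid terms.
#' @param covariates demographic regressors of memory.
#' @return a [model_spec()] (the serialisable declaration; fitting goes
#'   through [fit_analytical()], which implements its likelihood).
#' @export
build_analytical_spec <- function(include_amyloid = FALSE,
                                  covariates = DEFAULT_DEMO_COVARIATES) {
  terms <- if (include_amyloid) amyloid_terms() else base_terms()
  ind <- names(INDICATOR_RAW)
  lat <- c("B_gm", "B_hippo", "B_wmh", "MEMB", "MEMR", "I", "S")
  zc <- analytical_zcols(terms, covariates)
  zbase <- unique(unlist(strsplit(setdiff(zc, covariates), ":", fixed = TRUE)))
  obs <- c(ind, "mem", EF_COLS, covariates, zbase)
  pr <- function(lhs, op, rhs, free, value = NA, label = "")
    data.frame(lhs = lhs, op = op, rhs = rhs, free = free, value = value,
               label = label, stringsAsFactors = FALSE)
  pt <- rbind(
    pr(c("B_gm", "B_hippo", "B_wmh"), "=~", ind, FALSE, 1),
    pr(ind, "~~", ind, FALSE, 0.10),
    pr(ind, "~1", "", TRUE, 0),
    pr(c("B_gm", "B_hippo", "B_wmh"), "~~", c("B_gm", "B_hippo", "B_wmh"),
       TRUE, 0.9, label = paste0("psi_", c("gm", "hippo", "wmh"))),
    pr(c("B_gm", "B_gm", "B_hippo"), "~~", c("B_hippo", "B_wmh", "B_wmh"),
       TRUE, 0.3),
    pr("MEMB", "~", c("B_gm", "B_hippo", "B_wmh"), TRUE, 0.2,
       label = paste0("w_", c("gm", "hippo", "wmh"))),
    pr("mem", "~", "MEMB", FALSE, 1),
    pr("mem", "~", "MEMR", FALSE, 1),
    pr("MEMR", "~~", "MEMR", TRUE, 0.3, label = "psi_memr"),
    pr("mem", "~~", "mem", FALSE, 0.1365),
    pr("mem", "~1", "", TRUE, 0),
    pr("mem", "~", covariates, TRUE, 0, label = paste0("d_", covariates)),
    pr("I", "=~", EF_COLS, FALSE, 1),
    pr("S", "=~", EF_COLS, FALSE, -3:3),
    pr(EF_COLS, "~1", "", FALSE, 0),
    pr(EF_COLS, "~~", EF_COLS, TRUE, 0.1, label = "theta_ef"),
    pr(c("I", "S"), "~1", "", TRUE, 0, label = c("alpha_I", "alpha_S")),
    pr(c("I", "S"), "~~", c("I", "S"), TRUE, 0.2,
       label = c("zeta_I", "zeta_S")),
    pr("I", "~~", "S", TRUE, 0, label = "zeta_IS"))
  spec_term_rhs <- function(term) {
    toks <- term_tokens(term)
    toks <- ifelse(toks == "memr", "MEMR", ifelse(toks == "memb", "MEMB", toks))
    paste(toks, collapse = ":")
  }
  for (outc in c("I", "S")) {
    pre <- if (outc == "I") "bI_" else "bS_"
    for (tm in terms) {
      # MEMD (the fitted demographic combination) is carried declaratively
      # as a computed score column; fitting treats it as d'z throughout
      rhs <- if (tm == "memd") "memd_score" else spec_term_rhs(tm)
      pt <- rbind(pt, pr(outc, "~", rhs, TRUE, 0, label = paste0(pre, tm)))
    }
  }
  obs <- c(obs, "memd_score")
  spec <- model_spec(observed = unique(obs), latents = lat, partable = pt,
                     fixed_x = unique(c(covariates, zbase, "memd_score")))
  attr(spec, "analytical") <- list(terms = terms, covariates = covariates,
                                   include_amyloid = include_amyloid)
  spec
}

# ---- data preparation ---------------------------------------------------

analytical_data <- function(cohort, covariates = DEFAULT_DEMO_COVARIATES,
                            include_amyloid = FALSE, age_center = 70) {
  dd <- decomposition_data(cohort, covariates)
  wide <- ef_wide(cohort)
  b <- cohort$baseline
  Y <- as.matrix(cbind(dd$data[, names(INDICATOR_RAW)], mem = dd$data$mem,
                       wide[, EF_COLS]))
  zb <- data.frame(female = b$sex_female, apoe = b$apoe4_count,
                   age_c = b$age_first_mri - age_center)
  if (include_amyloid) zb$abeta <- b$centiloid
  terms <- if (include_amyloid) amyloid_terms() else base_terms()
  zc <- analytical_zcols(terms, covariates)
  Zfull <- cbind(dd$data[, covariates, drop = FALSE], zb)
  for (cn in setdiff(zc, names(Zfull))) {
    toks <- strsplit(cn, ":", fixed = TRUE)[[1]]
    Zfull[[cn]] <- Reduce(`*`, lapply(toks, function(t) Zfull[[t]]))
  }
  Z <- as.matrix(Zfull[, zc, drop = FALSE])
  if (anyNA(Z)) {
    bad <- b$id[!complete.cases(Z)]
    stop_schema("missing baseline covariate values for subject(s): %s",
                paste(head(bad, 5), collapse = ", "))
  }
  list(Y = Y, Z = Z, zcols = zc, base = Zfull, terms = terms,
       covariates = covariates, scaling = dd$scaling, id = b$id,
       cmp = analytical_compile(terms, covariates, zc))
}

# ---- parameter table ----------------------------------------------------

analytical_partable <- function(terms, covariates) {
  nm <- c("nu_gm", "nu_hippo", "nu_wmh",
          "lb1", "b21", "lb2", "b31", "b32", "lb3",
          "w_gm", "w_hippo", "w_wmh", "nu_mem",
          paste0("d_", covariates), "ls_r",
          "alpha_I", "alpha_S", "lzi", "zis", "lzs", "lte",
          paste0("bI_", terms), paste0("bS_", terms))
  log_par <- nm %in% c("lb1", "lb2", "lb3", "ls_r", "lzi", "lzs", "lte")
  data.frame(name = nm, log = log_par, stringsAsFactors = FALSE)
}

# Compile term metadata and parameter positions to integer indexing so
# the assembly (called ~100x per analytic gradient for its finite-
# difference Jacobian) stays cheap.
analytical_compile <- function(terms, covariates, zcols) {
  ptab <- analytical_partable(terms, covariates)
  pos <- setNames(seq_len(nrow(ptab)), ptab$name)
  k <- length(terms)
  lat_class <- integer(k); obs_col <- integer(k); is_memd <- logical(k)
  for (i in seq_len(k)) {
    lats <- term_latents(terms[i])
    lat_class[i] <- if (length(lats) == 2) 3L
    else if (identical(lats, "memr")) 1L
    else if (identical(lats, "memb")) 2L else 0L
    op <- term_obs_part(terms[i])
    is_memd[i] <- identical(op, "memd")
    obs_col[i] <- if (op == "" || is_memd[i]) 0L else match(op, zcols)
  }
  list(terms = terms, covariates = covariates, zcols = zcols, k = k,
       ptab = ptab, q = length(zcols),
       i_nu = unname(pos[c("nu_gm", "nu_hippo", "nu_wmh")]),
       i_ch = unname(pos[c("lb1", "b21", "lb2", "b31", "b32", "lb3")]),
       i_w = unname(pos[c("w_gm", "w_hippo", "w_wmh")]),
       i_numem = unname(pos["nu_mem"]),
       i_d = unname(pos[paste0("d_", covariates)]),
       i_dcol = match(covariates, zcols),
       i_lsr = unname(pos["ls_r"]),
       i_aI = unname(pos["alpha_I"]), i_aS = unname(pos["alpha_S"]),
       i_lzi = unname(pos["lzi"]), i_zis = unname(pos["zis"]),
       i_lzs = unname(pos["lzs"]), i_lte = unname(pos["lte"]),
       i_bI = unname(pos[paste0("bI_", terms)]),
       i_bS = unname(pos[paste0("bS_", terms)]),
       lat_class = lat_class, obs_col = obs_col, is_memd = is_memd,
       Tt = -3:3)
}

analytical_assemble <- function(tr, cmp) {
  tr <- as.numeric(tr)
  ch <- tr[cmp$i_ch]
  L <- matrix(0, 3, 3)
  diag(L) <- exp(ch[c(1, 3, 6)])
  L[2, 1] <- ch[2]; L[3, 1] <- ch[4]; L[3, 2] <- ch[5]
  Psi_B <- L %*% t(L)
  w <- tr[cmp$i_w]
  Pw <- drop(Psi_B %*% w)
  psi_b <- max(sum(w * Pw), 1e-12)
  s_b <- sqrt(psi_b)
  h <- Pw / psi_b
  s_r <- exp(tr[cmp$i_lsr])
  lz1 <- exp(tr[cmp$i_lzi]); z21 <- tr[cmp$i_zis]; lz2 <- exp(tr[cmp$i_lzs])
  Psi_z <- matrix(c(lz1^2, lz1 * z21, lz1 * z21, z21^2 + lz2^2), 2, 2)
  s_e2 <- exp(2 * tr[cmp$i_lte])
  Tt <- cmp$Tt

  Sigma <- matrix(0, AN_P, AN_P)
  Sigma[AN_IND, AN_IND] <- Psi_B - tcrossprod(Pw) / psi_b + diag(0.10, 3)
  Sigma[AN_MEM, AN_MEM] <- 0.1365
  Sigma[AN_EF, AN_EF] <- Psi_z[1, 1] + outer(Tt, Tt) * Psi_z[2, 2] +
    Psi_z[1, 2] * (outer(Tt, rep(1, 7)) + outer(rep(1, 7), Tt)) +
    diag(s_e2, 7)

  q <- cmp$q
  a0 <- numeric(AN_P)
  A <- matrix(0, AN_P, q)
  cx0 <- cb0 <- cxb0 <- numeric(AN_P)
  CXz <- CBz <- CXBz <- matrix(0, AN_P, q)

  a0[AN_IND] <- tr[cmp$i_nu]
  a0[AN_MEM] <- tr[cmp$i_numem]
  a0[AN_EF] <- tr[cmp$i_aI] + Tt * tr[cmp$i_aS]
  d <- tr[cmp$i_d]
  A[AN_MEM, cmp$i_dcol] <- d
  cx0[AN_MEM] <- s_r
  cb0[AN_MEM] <- s_b
  cb0[AN_IND] <- h * s_b

  bI <- tr[cmp$i_bI]; bS <- tr[cmp$i_bS]
  for (i in seq_len(cmp$k)) {
    cf <- bI[i] + Tt * bS[i]
    lc <- cmp$lat_class[i]; oc <- cmp$obs_col[i]
    if (cmp$is_memd[i]) {
      A[AN_EF, cmp$i_dcol] <- A[AN_EF, cmp$i_dcol] + outer(cf, d)
    } else if (lc == 0L) {
      A[AN_EF, oc] <- A[AN_EF, oc] + cf
    } else if (lc == 1L) {
      if (oc == 0L) cx0[AN_EF] <- cx0[AN_EF] + s_r * cf
      else CXz[AN_EF, oc] <- CXz[AN_EF, oc] + s_r * cf
    } else if (lc == 2L) {
      if (oc == 0L) cb0[AN_EF] <- cb0[AN_EF] + s_b * cf
      else CBz[AN_EF, oc] <- CBz[AN_EF, oc] + s_b * cf
    } else {
      if (oc == 0L) cxb0[AN_EF] <- cxb0[AN_EF] + s_r * s_b * cf
      else CXBz[AN_EF, oc] <- CXBz[AN_EF, oc] + s_r * s_b * cf
    }
  }
  list(a0 = a0, A = A, cx0 = cx0, CXz = CXz, cb0 = cb0, CBz = CBz,
       cxb0 = cxb0, CXBz = CXBz, Sigma = Sigma,
       s_r = s_r, s_b = s_b, Psi_B = Psi_B, w = w, Psi_z = Psi_z,
       s_e2 = s_e2)
}

# ---- likelihood & gradient ----------------------------------------------

# ---- likelihood & gradient ----------------------------------------------
#
# The marginal likelihood integrates over the standardized interacting
# latents u = (u1, u2) with per-subject adaptive Gauss-Hermite
# quadrature. Node locations u_ik = m_i + s_i v_k use proposal means and
# scales from the Gaussian posterior of u under the linear part of the
# model, computed once at a reference parameter value and then held
# fixed, so the discretised likelihood stays a smooth function of theta
# and its analytic gradient (via posterior node moments and the
# finite-differenced assembly Jacobian) is exact. Because the conditional
# covariance does not depend on the conditioning point, the exponent at
# every node is a polynomial in (v1, v2) of degree (2, 2), and all
# subjects in a missing-data pattern are evaluated with a single matrix
# product against the shared 9-term node basis.

make_analytical_objective <- function(ad, nodes = 15L) {
  Y <- ad$Y; Z <- ad$Z
  terms <- ad$terms; covariates <- ad$covariates; zcols <- ad$zcols
  cmp <- ad$cmp
  n <- nrow(Y); q <- ncol(Z)
  gh <- gh_probabilist(nodes)
  v1 <- rep(gh$x, times = nodes); v2 <- rep(gh$x, each = nodes)
  lw0 <- rep(log(gh$w), times = nodes) + rep(log(gh$w), each = nodes)
  keepg <- lw0 > max(lw0) - 46
  v1 <- v1[keepg]; v2 <- v2[keepg]; lw0 <- lw0[keepg]
  G <- length(v1)
  # importance weights against the proposal density
  lw <- lw0 - dnorm(v1, log = TRUE) - dnorm(v2, log = TRUE)
  # shared node basis: exponent is a degree-(2,2) polynomial in (v1, v2)
  Vbasis <- cbind(1, v1, v1^2, v2, v1 * v2, v1^2 * v2,
                  v2^2, v1 * v2^2, v1^2 * v2^2)
  Gmom_v <- cbind(v1, v2, v1^2, v2^2, v1 * v2, v1^2 * v2, v1 * v2^2,
                  v1^2 * v2^2)
  obs <- !is.na(Y)
  key <- apply(obs, 1L, function(r) paste(which(r), collapse = ","))
  pats <- lapply(unique(key), function(k) {
    idx <- which(key == k)
    list(idx = idx, j = which(obs[idx[1L], ]))
  })

  # adaptation state: proposal means/scales per subject (fixed wrt theta)
  adapt <- new.env(parent = emptyenv())
  adapt$m1 <- adapt$m2 <- rep(0, n)
  adapt$s1 <- adapt$s2 <- rep(1, n)

  # map the 10 u-monomial coefficients to the 9 shared v-basis columns
  # (a = m1, b = s1, c = m2, d = s2 per subject)
  expand_coef <- function(Coef, a, b, c, d) {
    k4 <- Coef[, 4] + Coef[, 8]   # u1*u2 enters twice
    CV <- matrix(0, nrow(Coef), 9L)
    CV[, 1] <- Coef[, 1] + Coef[, 2] * a + Coef[, 3] * c + k4 * a * c +
      Coef[, 5] * a^2 + Coef[, 6] * c^2 + Coef[, 9] * a^2 * c +
      Coef[, 10] * a * c^2 + Coef[, 7] * a^2 * c^2
    CV[, 2] <- Coef[, 2] * b + k4 * c * b + Coef[, 5] * 2 * a * b +
      Coef[, 9] * 2 * a * b * c + Coef[, 10] * b * c^2 +
      Coef[, 7] * 2 * a * b * c^2
    CV[, 3] <- Coef[, 5] * b^2 + Coef[, 9] * b^2 * c +
      Coef[, 7] * b^2 * c^2
    CV[, 4] <- Coef[, 3] * d + k4 * a * d + Coef[, 6] * 2 * c * d +
      Coef[, 9] * a^2 * d + Coef[, 10] * 2 * a * c * d +
      Coef[, 7] * a^2 * 2 * c * d
    CV[, 5] <- k4 * b * d + Coef[, 9] * 2 * a * b * d +
      Coef[, 10] * 2 * b * c * d + Coef[, 7] * 4 * a * b * c * d
    CV[, 6] <- Coef[, 9] * b^2 * d + Coef[, 7] * 2 * b^2 * c * d
    CV[, 7] <- Coef[, 6] * d^2 + Coef[, 10] * a * d^2 +
      Coef[, 7] * a^2 * d^2
    CV[, 8] <- Coef[, 10] * b * d^2 + Coef[, 7] * 2 * a * b * d^2
    CV[, 9] <- Coef[, 7] * b^2 * d^2
    CV
  }

  # posterior moments of (u1, u2, u1*u2) from posterior v-moments
  u_moments <- function(Vm, a, b, c, d) {
    Ev1 <- Vm[, 1]; Ev2 <- Vm[, 2]; Ev11 <- Vm[, 3]; Ev22 <- Vm[, 4]
    Ev12 <- Vm[, 5]; Ev112 <- Vm[, 6]; Ev122 <- Vm[, 7]; Ev1122 <- Vm[, 8]
    m1 <- a + b * Ev1
    m2 <- c + d * Ev2
    M11 <- a^2 + 2 * a * b * Ev1 + b^2 * Ev11
    M22 <- c^2 + 2 * c * d * Ev2 + d^2 * Ev22
    m3 <- a * c + a * d * Ev2 + b * c * Ev1 + b * d * Ev12
    M13 <- a^2 * c + a^2 * d * Ev2 + 2 * a * b * c * Ev1 +
      2 * a * b * d * Ev12 + b^2 * c * Ev11 + b^2 * d * Ev112
    M23 <- a * c^2 + 2 * a * c * d * Ev2 + a * d^2 * Ev22 +
      b * c^2 * Ev1 + 2 * b * c * d * Ev12 + b * d^2 * Ev122
    M33 <- a^2 * c^2 + 2 * a^2 * c * d * Ev2 + a^2 * d^2 * Ev22 +
      2 * a * b * c^2 * Ev1 + 4 * a * b * c * d * Ev12 +
      2 * a * b * d^2 * Ev122 + b^2 * c^2 * Ev11 +
      2 * b^2 * c * d * Ev112 + b^2 * d^2 * Ev1122
    list(m1 = m1, m2 = m2, m3 = m3, M11 = M11, M22 = M22, M33 = M33,
         M12 = m3, M13 = M13, M23 = M23)
  }

  pattern_blocks <- function(asm, pat) {
    j <- pat$j; idx <- pat$idx
    Zg <- Z[idx, , drop = FALSE]
    R <- Y[idx, j, drop = FALSE] -
      matrix(asm$a0[j], length(idx), length(j), byrow = TRUE) -
      Zg %*% t(asm$A[j, , drop = FALSE])
    Cx <- matrix(asm$cx0[j], length(idx), length(j), byrow = TRUE) +
      Zg %*% t(asm$CXz[j, , drop = FALSE])
    Cb <- matrix(asm$cb0[j], length(idx), length(j), byrow = TRUE) +
      Zg %*% t(asm$CBz[j, , drop = FALSE])
    Cq <- matrix(asm$cxb0[j], length(idx), length(j), byrow = TRUE) +
      Zg %*% t(asm$CXBz[j, , drop = FALSE])
    list(R = R, Cx = Cx, Cb = Cb, Cq = Cq, Zg = Zg)
  }

  core <- function(asm, want = c("ll", "grad", "scores")) {
    want <- match.arg(want)
    cw <- numeric(n)
    pat_cache <- vector("list", length(pats))
    for (pp in seq_along(pats)) {
      pat <- pats[[pp]]
      j <- pat$j; idx <- pat$idx
      Sj <- asm$Sigma[j, j, drop = FALSE]
      Lc <- tryCatch(chol(Sj), error = function(e) NULL)
      if (is.null(Lc)) return(NULL)
      P <- chol2inv(Lc)
      logdet <- 2 * sum(log(diag(Lc)))
      bl <- pattern_blocks(asm, pat)
      R <- bl$R; Cx <- bl$Cx; Cb <- bl$Cb; Cq <- bl$Cq
      RP <- R %*% P; CxP <- Cx %*% P; CbP <- Cb %*% P; CqP <- Cq %*% P
      Coef <- cbind(rowSums(RP * R), -2 * rowSums(CxP * R),
                    -2 * rowSums(CbP * R), -2 * rowSums(CqP * R),
                    rowSums(CxP * Cx) + 1, rowSums(CbP * Cb) + 1,
                    rowSums(CqP * Cq),
                    2 * rowSums(CxP * Cb), 2 * rowSums(CxP * Cq),
                    2 * rowSums(CbP * Cq))
      a <- adapt$m1[idx]; b <- adapt$s1[idx]
      cc <- adapt$m2[idx]; d <- adapt$s2[idx]
      CV <- expand_coef(Coef, a, b, cc, d)
      Q <- CV %*% t(Vbasis)
      LLm <- sweep(-0.5 * Q, 2L, lw, `+`) + (log(b) + log(d) - log(2 * pi)) -
        0.5 * (length(j) * log(2 * pi) + logdet)
      cwi <- logsumexp_rows(LLm)
      cw[idx] <- cwi
      if (want != "ll")
        pat_cache[[pp]] <- c(bl, list(P = P, LLm = LLm, cwi = cwi,
                                      a = a, b = b, cc = cc, d = d))
    }
    if (want == "ll") return(list(total = sum(cw), casewise = cw))

    if (want == "scores") {
      D <- 4L * AN_P + 4L * AN_P * q + AN_P * AN_P
      off_A <- AN_P; off_cx0 <- off_A + AN_P * q
      off_CXz <- off_cx0 + AN_P; off_cb0 <- off_CXz + AN_P * q
      off_CBz <- off_cb0 + AN_P; off_cxb0 <- off_CBz + AN_P * q
      off_CXBz <- off_cxb0 + AN_P; off_Sig <- off_CXBz + AN_P * q
      M <- matrix(0, n, D)
    }
    g_a0 <- numeric(AN_P); g_A <- matrix(0, AN_P, q)
    g_cx0 <- g_cb0 <- g_cxb0 <- numeric(AN_P)
    g_CXz <- g_CBz <- g_CXBz <- matrix(0, AN_P, q)
    g_Sig <- matrix(0, AN_P, AN_P)
    for (pp in seq_along(pats)) {
      pat <- pats[[pp]]; pc <- pat_cache[[pp]]
      j <- pat$j; idx <- pat$idx
      pj <- length(j)
      Pi <- exp(pc$LLm - pc$cwi)
      Vm <- Pi %*% Gmom_v
      um <- u_moments(Vm, pc$a, pc$b, pc$cc, pc$d)
      m1 <- um$m1; m2 <- um$m2; m3 <- um$m3
      M11 <- um$M11; M22 <- um$M22; M33 <- um$M33
      M12 <- um$M12; M13 <- um$M13; M23 <- um$M23
      R <- pc$R; Cx <- pc$Cx; Cb <- pc$Cb; Cq <- pc$Cq; P <- pc$P
      V0 <- R - Cx * m1 - Cb * m2 - Cq * m3
      V1 <- R * m1 - Cx * M11 - Cb * M12 - Cq * M13
      V2 <- R * m2 - Cx * M12 - Cb * M22 - Cq * M23
      V3 <- R * m3 - Cx * M13 - Cb * M23 - Cq * M33
      Zg <- pc$Zg
      if (want == "grad") {
        g_a0[j] <- g_a0[j] + drop(colSums(V0) %*% P)
        g_cx0[j] <- g_cx0[j] + drop(colSums(V1) %*% P)
        g_cb0[j] <- g_cb0[j] + drop(colSums(V2) %*% P)
        g_cxb0[j] <- g_cxb0[j] + drop(colSums(V3) %*% P)
        g_A[j, ] <- g_A[j, ] + P %*% crossprod(V0, Zg)
        g_CXz[j, ] <- g_CXz[j, ] + P %*% crossprod(V1, Zg)
        g_CBz[j, ] <- g_CBz[j, ] + P %*% crossprod(V2, Zg)
        g_CXBz[j, ] <- g_CXBz[j, ] + P %*% crossprod(V3, Zg)
        EE <- crossprod(R, V0) - crossprod(Cx, V1) - crossprod(Cb, V2) -
          crossprod(Cq, V3)
        EE <- (EE + t(EE)) / 2
        SS <- P %*% EE %*% P
        g_Sig[j, j] <- g_Sig[j, j] + 0.5 * (SS - length(idx) * P)
      } else {
        V0P <- V0 %*% P; V1P <- V1 %*% P; V2P <- V2 %*% P; V3P <- V3 %*% P
        M[idx, j] <- V0P
        M[idx, off_cx0 + j] <- V1P
        M[idx, off_cb0 + j] <- V2P
        M[idx, off_cxb0 + j] <- V3P
        ai <- rep(seq_len(pj), q); bi <- rep(seq_len(q), each = pj)
        colz <- rep((seq_len(q) - 1L) * AN_P, each = pj) + rep(j, q)
        M[idx, off_A + colz] <- V0P[, ai] * Zg[, bi]
        M[idx, off_CXz + colz] <- V1P[, ai] * Zg[, bi]
        M[idx, off_CBz + colz] <- V2P[, ai] * Zg[, bi]
        M[idx, off_CXBz + colz] <- V3P[, ai] * Zg[, bi]
        W0 <- Cx * m1 + Cb * m2 + Cq * m3
        W1 <- Cx * M11 + Cb * M12 + Cq * M13
        W2 <- Cx * M12 + Cb * M22 + Cq * M23
        W3 <- Cx * M13 + Cb * M23 + Cq * M33
        aj <- rep(seq_len(pj), pj); bj <- rep(seq_len(pj), each = pj)
        Evec <- R[, aj] * (R - W0)[, bj] - W0[, aj] * R[, bj] +
          Cx[, aj] * W1[, bj] + Cb[, aj] * W2[, bj] + Cq[, aj] * W3[, bj]
        SSvec <- Evec %*% kronecker(P, P)
        colS <- rep((j - 1L) * AN_P, each = pj) + rep(j, pj)
        M[idx, off_Sig + colS] <- 0.5 * sweep(SSvec, 2L, as.vector(P))
      }
    }
    if (want == "scores")
      return(list(total = sum(cw), casewise = cw, M = M))
    list(total = sum(cw), casewise = cw,
         g = list(a0 = g_a0, A = g_A, cx0 = g_cx0, CXz = g_CXz,
                  cb0 = g_cb0, CBz = g_CBz, cxb0 = g_cxb0, CXBz = g_CXBz,
                  Sigma = g_Sig))
  }

  flatten_asm <- function(asm)
    c(asm$a0, asm$A, asm$cx0, asm$CXz, asm$cb0, asm$CBz, asm$cxb0,
      asm$CXBz, asm$Sigma)

  # Jacobian of the assembly map: mean-structure parameters (means,
  # covariate and structural coefficients) have closed-form columns; the
  # covariance-side parameters (Cholesky factors, latent scales) are
  # finite-differenced.
  D_flat <- 4L * AN_P + 4L * AN_P * q + AN_P * AN_P
  off <- list(a0 = 0L, A = AN_P, cx0 = AN_P + AN_P * q,
              CXz = 2L * AN_P + AN_P * q, cb0 = 2L * AN_P + 2L * AN_P * q,
              CBz = 3L * AN_P + 2L * AN_P * q,
              cxb0 = 3L * AN_P + 3L * AN_P * q,
              CXBz = 4L * AN_P + 3L * AN_P * q,
              Sigma = 4L * AN_P + 4L * AN_P * q)
  fd_params <- c(cmp$i_ch, cmp$i_w, cmp$i_lsr, cmp$i_lzi, cmp$i_zis,
                 cmp$i_lzs, cmp$i_lte)
  Acol <- function(col) off$A + (col - 1L) * AN_P   # base offset of A col

  assembly_jacobian <- function(tr) {
    tr <- as.numeric(tr)
    J <- matrix(0, D_flat, length(tr))
    for (k in fd_params) {
      hstep <- 1e-6 * max(1, abs(tr[k]))
      tp <- tr; tp[k] <- tr[k] + hstep
      tm <- tr; tm[k] <- tr[k] - hstep
      J[, k] <- (flatten_asm(analytical_assemble(tp, cmp)) -
                   flatten_asm(analytical_assemble(tm, cmp))) / (2 * hstep)
    }
    asm <- analytical_assemble(tr, cmp)
    s_r <- asm$s_r; s_b <- asm$s_b
    d <- tr[cmp$i_d]
    Tt <- cmp$Tt
    J[off$a0 + AN_IND, cmp$i_nu] <- diag(3)
    J[off$a0 + AN_MEM, cmp$i_numem] <- 1
    J[off$a0 + AN_EF, cmp$i_aI] <- 1
    J[off$a0 + AN_EF, cmp$i_aS] <- Tt
    bI <- tr[cmp$i_bI]; bS <- tr[cmp$i_bS]
    # covariate weights: the memory row plus every memd-carrying EF row
    imemd <- which(cmp$is_memd)
    cf_memd <- if (length(imemd))
      bI[imemd] + Tt * bS[imemd] else rep(0, 7)
    for (jc in seq_along(cmp$i_d)) {
      col0 <- Acol(cmp$i_dcol[jc])
      J[col0 + AN_MEM, cmp$i_d[jc]] <- 1
      if (length(imemd)) {
        J[col0 + AN_EF, cmp$i_d[jc]] <- cf_memd
        # ...and d enters the memd structural term itself
      }
    }
    for (i in seq_len(cmp$k)) {
      for (which_b in 1:2) {
        pk <- if (which_b == 1) cmp$i_bI[i] else cmp$i_bS[i]
        cfd <- if (which_b == 1) rep(1, 7) else Tt
        lc <- cmp$lat_class[i]; oc <- cmp$obs_col[i]
        if (cmp$is_memd[i]) {
          for (jc in seq_along(cmp$i_d))
            J[Acol(cmp$i_dcol[jc]) + AN_EF, pk] <- cfd * d[jc]
        } else if (lc == 0L) {
          J[Acol(oc) + AN_EF, pk] <- cfd
        } else if (lc == 1L) {
          tgt <- if (oc == 0L) off$cx0 + AN_EF else off$CXz + Acol(oc) -
            off$A + AN_EF
          J[tgt, pk] <- s_r * cfd
        } else if (lc == 2L) {
          tgt <- if (oc == 0L) off$cb0 + AN_EF else off$CBz + Acol(oc) -
            off$A + AN_EF
          J[tgt, pk] <- s_b * cfd
        } else {
          tgt <- if (oc == 0L) off$cxb0 + AN_EF else off$CXBz + Acol(oc) -
            off$A + AN_EF
          J[tgt, pk] <- s_r * s_b * cfd
        }
      }
    }
    J
  }

  # Gaussian posterior of u under the linear part of the model at `tr`;
  # sets the proposal means/scales used by all subsequent evaluations.
  set_adaptation <- function(tr) {
    asm <- analytical_assemble(tr, cmp)
    for (pat in pats) {
      j <- pat$j; idx <- pat$idx
      bl <- pattern_blocks(asm, pat)
      ckey <- do.call(paste, as.data.frame(round(cbind(bl$Cx, bl$Cb), 10)))
      for (kk in unique(ckey)) {
        rows <- which(ckey == kk)
        cx <- bl$Cx[rows[1L], ]; cb <- bl$Cb[rows[1L], ]
        Stot <- asm$Sigma[j, j, drop = FALSE] + tcrossprod(cx) +
          tcrossprod(cb)
        Cuy <- rbind(cx, cb)
        Muy <- Cuy %*% solve(Stot)
        Vpost <- diag(2) - Muy %*% t(Cuy)
        s <- sqrt(pmin(pmax(diag(Vpost), 2.5e-3), 1))
        mm <- bl$R[rows, , drop = FALSE] %*% t(Muy)
        adapt$m1[idx[rows]] <- pmax(pmin(mm[, 1], 6), -6)
        adapt$m2[idx[rows]] <- pmax(pmin(mm[, 2], 6), -6)
        adapt$s1[idx[rows]] <- s[1]
        adapt$s2[idx[rows]] <- s[2]
      }
    }
    invisible(NULL)
  }

  loglik <- function(tr) {
    asm <- analytical_assemble(tr, cmp)
    core(asm, "ll")
  }
  gradient <- function(tr) {
    asm <- analytical_assemble(tr, cmp)
    out <- core(asm, "grad")
    if (is.null(out)) return(NULL)
    gl <- out$g
    gflat <- c(gl$a0, gl$A, gl$cx0, gl$CXz, gl$cb0, gl$CBz, gl$cxb0,
               gl$CXBz, gl$Sigma)
    gr <- drop(crossprod(assembly_jacobian(tr), gflat))
    names(gr) <- names(tr)
    list(total = out$total, grad = gr, casewise = out$casewise)
  }
  # per-subject score matrix (n x npar) for the outer-product (scores)
  # information estimate
  scores <- function(tr) {
    asm <- analytical_assemble(tr, cmp)
    out <- core(asm, "scores")
    if (is.null(out)) return(NULL)
    SC <- out$M %*% assembly_jacobian(tr)
    colnames(SC) <- names(tr)
    list(total = out$total, scores = SC, casewise = out$casewise)
  }
  list(loglik = loglik, gradient = gradient, scores = scores,
       set_adaptation = set_adaptation, n = n, G = G, cmp = cmp)
}


# ---- starting values ----------------------------------------------------
#
# Closed-form method-of-moments starts: the brain covariance from the
# indicator sample moments minus the fixed error, the memory weights from
# the OLS of memory on covariates and indicators (corrected for indicator
# unreliability), growth parameters from per-subject least squares, and
# structural coefficients from the two-stage factor-score regression
# (known to be attenuated; used only to start the joint optimiser).
analytical_start <- function(cohort, ad, ptab) {
  Y <- ad$Y; Z <- ad$Z
  ind <- Y[, AN_IND, drop = FALSE]
  mem <- Y[, AN_MEM]
  EF <- Y[, AN_EF, drop = FALSE]
  covn <- ad$covariates
  tr <- setNames(numeric(nrow(ptab)), ptab$name)

  nu_ind <- colMeans(ind, na.rm = TRUE)
  cc <- complete.cases(ind)
  Psi_B <- cov(ind[cc, , drop = FALSE]) * (sum(cc) - 1) / sum(cc) -
    diag(0.10, 3)
  ev <- eigen(symm(Psi_B), symmetric = TRUE)
  Psi_B <- symm(ev$vectors %*% (pmax(ev$values, 0.05) * t(ev$vectors)))
  L <- t(chol(Psi_B))
  tr[c("nu_gm", "nu_hippo", "nu_wmh")] <- nu_ind
  tr["lb1"] <- log(L[1, 1]); tr["b21"] <- L[2, 1]; tr["lb2"] <- log(L[2, 2])
  tr["b31"] <- L[3, 1]; tr["b32"] <- L[3, 2]; tr["lb3"] <- log(L[3, 3])

  Zd <- as.matrix(ad$base[, covn, drop = FALSE])
  X <- cbind(1, Zd, ind)
  okm <- complete.cases(X) & !is.na(mem)
  cf <- tryCatch(qr.coef(qr(X[okm, , drop = FALSE]), mem[okm]),
                 error = function(e) rep(0, ncol(X)))
  cf[is.na(cf)] <- 0
  d <- cf[1 + seq_along(covn)]
  g <- cf[(length(cf) - 2):length(cf)]
  w <- drop(solve(Psi_B, (Psi_B + diag(0.10, 3)) %*% g))
  if (max(abs(w)) < 1e-6) w <- c(0.2, 0.2, 0.2)
  resid_m <- mem[okm] - drop(X[okm, ] %*% cf)
  psi_r <- drop(mean(resid_m^2) - 0.1365 -
                  t(w) %*% Psi_B %*% w +
                  t(g) %*% (Psi_B + diag(0.10, 3)) %*% g)
  psi_r <- min(max(psi_r, 0.05), 3)
  tr[c("w_gm", "w_hippo", "w_wmh")] <- w
  tr["nu_mem"] <- cf[1]
  tr[paste0("d_", covn)] <- d
  tr["ls_r"] <- 0.5 * log(psi_r)

  # per-subject least-squares growth summaries
  Tt <- -3:3
  Obs <- !is.na(EF)
  EF0 <- ifelse(Obs, EF, 0)
  nT <- rowSums(Obs)
  sT <- drop(Obs %*% Tt); sT2 <- drop(Obs %*% Tt^2)
  sy <- rowSums(EF0); sTy <- drop(EF0 %*% Tt)
  den <- nT * sT2 - sT^2
  S_i <- ifelse(den > 1e-8, (nT * sTy - sT * sy) / pmax(den, 1e-8), NA)
  I_i <- ifelse(nT > 0, (sy - ifelse(is.na(S_i), 0, S_i) * sT) / nT, NA)
  fitted <- outer(ifelse(is.na(I_i), 0, I_i), rep(1, 7)) +
    outer(ifelse(is.na(S_i), 0, S_i), Tt)
  rss <- rowSums(((EF - fitted)^2) * Obs, na.rm = TRUE)
  dfres <- pmax(nT - 2, 0)
  theta_ef <- sum(rss[dfres > 0]) / max(sum(dfres), 1)
  tr["lte"] <- 0.5 * log(min(max(theta_ef, 0.02), 2))
  tr["alpha_I"] <- mean(I_i, na.rm = TRUE)
  tr["alpha_S"] <- mean(S_i, na.rm = TRUE)

  # two-stage structural starts from component scores
  W <- Psi_B %*% solve(Psi_B + diag(0.10, 3))
  Bhat <- sweep(ind, 2, nu_ind)
  Bhat[!complete.cases(Bhat), ] <- 0
  Bhat <- Bhat %*% t(W)
  memb_sc <- drop(Bhat %*% w)
  memd_sc <- drop(Zd %*% d)
  memr_sc <- mem - cf[1] - memd_sc - memb_sc
  memr_sc[is.na(memr_sc)] <- 0
  s_b0 <- sqrt(max(drop(t(w) %*% Psi_B %*% w), 1e-6))
  des <- list(memr = memr_sc / max(sd(memr_sc), 1e-8) * sqrt(psi_r),
              memb = memb_sc / max(sd(memb_sc), 1e-8) * s_b0,
              memd = memd_sc - mean(memd_sc))
  for (cn in setdiff(names(ad$base), names(des))) des[[cn]] <- ad$base[[cn]]
  Xs <- structural_design(des, ad$terms)
  okI <- complete.cases(Xs) & !is.na(I_i)
  okS <- complete.cases(Xs) & !is.na(S_i)
  bI0 <- tryCatch(qr.coef(qr(cbind(1, Xs[okI, , drop = FALSE])), I_i[okI]),
                  error = function(e) rep(0, ncol(Xs) + 1))
  bS0 <- tryCatch(qr.coef(qr(cbind(1, Xs[okS, , drop = FALSE])), S_i[okS]),
                  error = function(e) rep(0, ncol(Xs) + 1))
  bI0[is.na(bI0)] <- 0; bS0[is.na(bS0)] <- 0
  tr[paste0("bI_", ad$terms)] <- bI0[-1]
  tr[paste0("bS_", ad$terms)] <- bS0[-1]
  rI <- I_i[okI] - drop(cbind(1, Xs[okI, , drop = FALSE]) %*% bI0)
  rS <- S_i[okS] - drop(cbind(1, Xs[okS, , drop = FALSE]) %*% bS0)
  zi <- min(max(var(rI) * 0.7, 0.02), 3)
  zs <- min(max(var(rS, na.rm = TRUE) * 0.5, 5e-4), 1)
  tr["lzi"] <- 0.5 * log(zi)
  tr["zis"] <- 0
  tr["lzs"] <- 0.5 * log(zs)
  tr
}
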