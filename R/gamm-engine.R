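# Internal penalized-spline mixed-model engine.
#
# Model (per response y, one row per scan):
#   y = X beta + Z_f b_f + Z_d b_d + a_subject + e
# where Z_f/Z_d are natural-parameterized penalized smooth bases (age smooth
# and sex-specific deviation smooth), b_j ~ N(0, tau_j I), subject intercepts
# a ~ N(0, tau_a I), e ~ N(0, sigma^2 I).  Writing gamma_j = tau_j / sigma^2
# (so the smoothing parameter is lambda_j = 1/gamma_j), the marginal
# covariance is sigma^2 (D + B Gamma B') with D block-diagonal over subjects
# (I + gamma_a J).  All likelihood quantities are computed from per-subject
# sufficient statistics via Woodbury identities, so a likelihood evaluation or
# a bootstrap refit costs O(S P^2), never O(n^2).

sg_design <- function(df, with_sex = TRUE, K = 10, K_sex = 5,
                      include_icv = TRUE, basis = NULL, age_range = NULL,
                      icv_ref = NULL) {
  need <- c("subject_id", "age_days", "sex", "site")
  if (include_icv) need <- c(need, "icv")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  t <- as.numeric(df$age_days)
  if (is.null(age_range)) {
    # extend to the full study span when the data sit inside it, so curves
    # can be evaluated at term birth (day 0) and the 27-month ceiling
    age_range <- if (min(t) >= 0 && max(t) <= 810) c(0, 810) else range(t)
  }
  if (is.null(basis)) basis <- build_spline_basis(t, K, range = age_range)
  n <- nrow(df)

  smooth_parts <- function(bas) {
    B <- eval_basis(bas, t)
    cm <- colMeans(B)
    qr_c <- qr(matrix(cm, ncol = 1))
    Zc <- qr.Q(qr_c, complete = TRUE)[, -1, drop = FALSE]   # K x (K-1)
    St <- crossprod(Zc, bas$S %*% Zc)
    eg <- eigen(St, symmetric = TRUE)
    pos <- eg$values > max(eg$values) * 1e-8
    Tr_rand <- Zc %*% eg$vectors[, pos, drop = FALSE] %*%
      diag(1 / sqrt(eg$values[pos]), sum(pos))
    Tr_null <- Zc %*% eg$vectors[, !pos, drop = FALSE]
    list(basis = bas, Tr_rand = Tr_rand, Tr_null = Tr_null)
  }

  sf <- smooth_parts(basis)
  Xnull_f <- eval_basis(basis, t) %*% sf$Tr_null
  Zf <- eval_basis(basis, t) %*% sf$Tr_rand

  site <- factor(df$site)
  site_freq <- table(site) / n
  dropped_site <- FALSE
  if (nlevels(site) > 1) {
    Xsite <- model.matrix(~site)[, -1, drop = FALSE]
  } else {
    Xsite <- matrix(nrow = n, ncol = 0)
    dropped_site <- TRUE
    message("single site level; site effect dropped from the model")
  }

  icv_center <- icv_scale <- NA_real_
  if (include_icv) {
    icv <- as.numeric(df$icv)
    icv_center <- mean(icv); icv_scale <- sd(icv)
    if (!is.finite(icv_scale) || icv_scale == 0) icv_scale <- 1
    Xicv <- matrix((icv - icv_center) / icv_scale, ncol = 1,
                   dimnames = list(NULL, "icv"))
  } else {
    Xicv <- matrix(nrow = n, ncol = 0)
  }

  sd_parts <- NULL
  Xsex <- Xnull_d <- matrix(nrow = n, ncol = 0)
  Zd <- matrix(nrow = n, ncol = 0)
  male_frac <- mean(df$sex == "male")
  if (with_sex) {
    if (length(unique(df$sex)) < 2)
      stop("'with_sex = TRUE' requires both sexes in the data")
    g <- as.numeric(df$sex == "male")
    bas_d <- build_spline_basis(t, K_sex, range = basis$range)
    sd_parts <- smooth_parts(bas_d)
    Xsex <- matrix(g, ncol = 1, dimnames = list(NULL, "sexmale"))
    Xnull_d <- g * (eval_basis(bas_d, t) %*% sd_parts$Tr_null)
    Zd <- g * (eval_basis(bas_d, t) %*% sd_parts$Tr_rand)
  }

  X <- cbind("(Intercept)" = 1, Xsite, Xicv, Xsex, f_null = Xnull_f,
             if (ncol(Xnull_d)) structure(Xnull_d, dimnames = list(NULL, "d_null")))
  Z <- cbind(Zf, Zd)
  pen_group <- c(rep(1L, ncol(Zf)), rep(2L, ncol(Zd)))

  list(
    X = X, Z = Z, pen_group = pen_group,
    subject = factor(df$subject_id), t = t,
    basis = basis, f_parts = sf, d_parts = sd_parts,
    with_sex = with_sex, include_icv = include_icv,
    site_levels = levels(site), site_freq = as.numeric(site_freq),
    dropped_site = dropped_site,
    icv_center = icv_center, icv_scale = icv_scale, icv_ref = icv_ref,
    male_frac = male_frac,
    p = ncol(X), q = ncol(Z), n = n
  )
}

# cohort-mean ICV trajectory at age t (and its slope, per day), taken from a
# sex-free spline mixed-model fit of ICV on age (the package's own engine)
sg_icvbar <- function(design, t, deriv = FALSE) {
  ref <- design$icv_ref
  if (is.null(ref)) return(rep(0, length(t)))
  R <- sg_pred_rows(ref$design, t, "pooled", deriv = deriv)
  as.vector(R %*% ref$theta_pop)
}

# rows mapping the population coefficient vector (beta, b_f, b_d) to curve
# values (or derivatives) at ages t for a sex stratum
sg_pred_rows <- function(design, t, stratum = "pooled", deriv = FALSE) {
  t <- as.numeric(t)
  w_male <- switch(stratum,
    male = 1, female = 0, pooled = design$male_frac,
    stop("unknown stratum '", stratum, "'"))
  nt <- length(t)
  d <- as.integer(deriv)
  Bf <- eval_basis(design$basis, t, deriv = d)
  parts <- list()
  parts$int <- matrix(if (deriv) 0 else 1, nt, 1)
  if (length(design$site_levels) > 1) {
    sw <- if (deriv) rep(0, length(design$site_levels) - 1) else
      design$site_freq[-1]
    parts$site <- matrix(rep(sw, each = nt), nt)
  }
  if (design$include_icv) {
    icv <- if (deriv) sg_icvbar(design, t, deriv = TRUE) / design$icv_scale
           else (sg_icvbar(design, t) - design$icv_center) / design$icv_scale
    parts$icv <- matrix(icv, ncol = 1)
  }
  if (design$with_sex) parts$sex <- matrix(if (deriv) 0 else w_male, nt, 1)
  parts$f_null <- Bf %*% design$f_parts$Tr_null
  if (design$with_sex) {
    Bd <- eval_basis(design$d_parts$basis, t, deriv = d)
    parts$d_null <- w_male * (Bd %*% design$d_parts$Tr_null)
  }
  parts$f_rand <- Bf %*% design$f_parts$Tr_rand
  if (design$with_sex) {
    Bd <- eval_basis(design$d_parts$basis, t, deriv = d)
    parts$d_rand <- w_male * (Bd %*% design$d_parts$Tr_rand)
  }
  do.call(cbind, parts)
}

# per-subject sufficient statistics; Y may be a matrix (columns = responses)
sg_suffstats <- function(design, Y) {
  Y <- as.matrix(Y)
  U <- cbind(design$X, design$Z)
  P <- ncol(U)
  subj <- design$subject
  S <- nlevels(subj)
  idx <- split(seq_len(design$n), subj)
  n_s <- lengths(idx)
  Gflat <- matrix(0, P * P, S)
  Umat <- matrix(0, P, S)
  m <- ncol(Y)
  H <- array(0, c(P, S, m))
  Y1 <- matrix(0, S, m)
  YY <- matrix(0, S, m)
  for (s in seq_len(S)) {
    rows <- idx[[s]]
    Us <- U[rows, , drop = FALSE]
    Gflat[, s] <- as.vector(crossprod(Us))
    Umat[, s] <- colSums(Us)
    ys <- Y[rows, , drop = FALSE]
    H[, s, ] <- crossprod(Us, ys)
    Y1[s, ] <- colSums(ys)
    YY[s, ] <- colSums(ys^2)
  }
  list(Gflat = Gflat, Umat = Umat, H = H, Y1 = Y1, YY = YY,
       n_s = as.numeric(n_s), S = S, P = P, p = design$p, q = design$q,
       pen_group = design$pen_group, n = design$n,
       subjects = levels(subj))
}

# assemble GLS blocks A = U' D^{-1} U, b = U' D^{-1} y, yDy, with subject
# resampling weights w (default all-ones)
sg_assemble <- function(ss, gamma_a, resp = 1L, w = NULL) {
  if (is.null(w)) w <- rep(1, ss$S)
  cs <- gamma_a / (1 + ss$n_s * gamma_a)
  wc <- w * cs
  A <- matrix(ss$Gflat %*% w, ss$P, ss$P) -
    ss$Umat %*% (t(ss$Umat) * wc)
  b <- as.vector(matrix(ss$H[, , resp], ss$P, ss$S) %*% w) -
    as.vector(ss$Umat %*% (wc * ss$Y1[, resp]))
  yDy <- sum(w * ss$YY[, resp]) - sum(wc * ss$Y1[, resp]^2)
  list(A = A, b = b, yDy = yDy,
       logdetD = sum(w * log1p(ss$n_s * gamma_a)),
       n = sum(w * ss$n_s))
}

# profile negative log-likelihood in psi = log(gamma) for the free groups.
# gammas: named vector c(f=, sex=, subject=) with NA for free entries filled
# from psi in order.
sg_gamma_vec <- function(psi, template) {
  out <- template
  out[is.na(template)] <- exp(psi)
  out
}

sg_profile <- function(gammas, ss, resp = 1L, method = "ML", w = NULL,
                       want_fit = FALSE) {
  asm <- sg_assemble(ss, gammas[["subject"]], resp, w)
  p <- ss$p; q <- ss$q; P <- ss$P
  fi <- seq_len(p); bi <- p + seq_len(q)
  gvec <- ifelse(ss$pen_group == 1L, gammas[["f"]], gammas[["sex"]])
  A <- asm$A
  if (q > 0) {
    Kmat <- A[bi, bi, drop = FALSE] + diag(1 / gvec, q)
    cK <- tryCatch(chol(Kmat), error = function(e) NULL)
    if (is.null(cK)) return(list(nll = 1e10))
    ABX <- A[bi, fi, drop = FALSE]
    KiABX <- backsolve(cK, forwardsolve(t(cK), ABX))
    Kib <- backsolve(cK, forwardsolve(t(cK), asm$b[bi]))
    XVX <- A[fi, fi, drop = FALSE] - crossprod(ABX, KiABX)
    XVy <- asm$b[fi] - crossprod(ABX, Kib)
    yVy <- asm$yDy - sum(asm$b[bi] * Kib)
    logdetK <- 2 * sum(log(diag(cK))) + sum(log(gvec))
  } else {
    XVX <- A[fi, fi, drop = FALSE]
    XVy <- asm$b[fi]
    yVy <- asm$yDy
    logdetK <- 0
  }
  cX <- tryCatch(chol(XVX), error = function(e) NULL)
  if (is.null(cX)) return(list(nll = 1e10))
  beta <- backsolve(cX, forwardsolve(t(cX), XVy))
  rss <- max(yVy - sum(XVy * beta), 1e-12)
  n <- asm$n
  logdetV <- asm$logdetD + logdetK
  if (method == "REML") {
    s2 <- rss / (n - p)
    nll <- 0.5 * ((n - p) * log(2 * pi * s2) + (n - p) + logdetV +
                    2 * sum(log(diag(cX))))
  } else {
    s2 <- rss / n
    nll <- 0.5 * (n * log(2 * pi * s2) + n + logdetV)
  }
  out <- list(nll = nll, sigma2 = s2, beta = as.vector(beta))
  if (want_fit && q > 0) {
    resid_b <- asm$b[bi] - A[bi, fi, drop = FALSE] %*% beta
    out$bhat <- as.vector(backsolve(cK, forwardsolve(t(cK), resid_b)))
  } else if (want_fit) {
    out$bhat <- numeric(0)
  }
  out
}

sg_optimize <- function(ss, resp = 1L, method = "ML", with_sex = TRUE,
                        fixed = list(), w = NULL, warm_start = NULL) {
  template <- c(f = NA_real_, sex = if (with_sex) NA_real_ else 0,
                subject = NA_real_)
  if (!is.null(fixed$lambda)) template[["f"]] <- 1 / fixed$lambda
  if (!is.null(fixed$lambda_sex) && with_sex)
    template[["sex"]] <- 1 / fixed$lambda_sex
  if (!is.null(fixed$gamma_subject)) template[["subject"]] <- fixed$gamma_subject
  nfree <- sum(is.na(template))
  obj <- function(psi) sg_profile(sg_gamma_vec(psi, template), ss, resp,
                                  method, w)$nll
  if (nfree == 0) {
    best <- list(par = numeric(0), value = obj(numeric(0)), convergence = 0L)
    starts_val <- best$value
  } else {
    starts <- if (is.null(warm_start)) {
      list(rep(0, nfree), rep(3, nfree), rep(-3, nfree))
    } else {
      list(pmin(pmax(warm_start, -18), 18))
    }
    fits <- lapply(starts, function(s0) {
      tryCatch(
        optim(s0, obj, method = "L-BFGS-B", lower = -18, upper = 18,
              control = list(factr = 1e7, maxit = 200)),
        error = function(e) list(par = s0, value = obj(s0), convergence = 52L)
      )
    })
    vals <- vapply(fits, `[[`, 0, "value")
    best <- fits[[which.min(vals)]]
    starts_val <- vapply(starts, obj, 0)
  }
  gammas <- sg_gamma_vec(best$par, template)
  fit <- sg_profile(gammas, ss, resp, method, w, want_fit = TRUE)
  list(gammas = gammas, nll = best$value, fit = fit,
       convergence = best$convergence, start_values = starts_val)
}

# penalized-GLS refit at fixed variance ratios (used by the bootstrap):
# returns the population coefficient vector (beta, b_f, b_d)
sg_refit_theta <- function(ss, gammas, resp = 1L, w = NULL) {
  asm <- sg_assemble(ss, gammas[["subject"]], resp, w)
  q <- ss$q
  A <- asm$A
  if (q > 0) {
    gvec <- ifelse(ss$pen_group == 1L, gammas[["f"]], gammas[["sex"]])
    bi <- ss$p + seq_len(q)
    A[bi, bi] <- A[bi, bi] + diag(1 / gvec, q)
  }
  cA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(cA)) return(NULL)
  as.vector(backsolve(cA, forwardsolve(t(cA), asm$b)))
}
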