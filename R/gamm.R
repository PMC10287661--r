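#' Fit a penalized-spline growth-trajectory mixed model
#'
#' Fits the growth model
#' \deqn{y_i(t) = s_i + \beta_T T_i(t) + f(t) + \Delta(t) g_i + \alpha_i + e_i(t)}
#' where `s_i` is a fixed site effect, `T_i(t)` the per-scan intracranial
#' volume (ICV) covariate, `f(t)` a penalized cubic-spline smooth of age,
#' `\Delta(t)` an optional penalized sex-deviation smooth (male relative to
#' female), `\alpha_i` a subject random intercept and `e_i(t)` Gaussian noise.
#' Smooths carry sum-to-zero constraints for identifiability; their penalties
#' are treated as Gaussian precisions so that the smoothing parameters and
#' variance components are selected jointly by maximizing the marginal
#' likelihood (ML, the default) or its restricted variant (REML).
#'
#' @param records data.frame of scan records (one row per scan) with columns
#'   `subject_id`, `age_days`, `sex`, `site`, `icv` and the response.
#' @param response name of the response column (e.g. `"thalamus_L"`), or a
#'   numeric vector of length `nrow(records)`.
#' @param with_sex include the sex main effect and deviation smooth
#'   (`FALSE` drops them, the sex-free model used for vertex-wise fits).
#' @param K,K_sex basis dimensions of the age smooth and sex-deviation smooth.
#' @param method `"ML"` (default) or `"REML"` smoothness selection.
#' @param include_icv include the ICV covariate.
#' @param fixed optional list pinning variance parameters instead of
#'   optimizing them: `lambda` (age-smooth smoothing parameter),
#'   `lambda_sex`, `gamma_subject` (subject-intercept variance ratio
#'   \eqn{\tau_\alpha/\sigma^2}).
#' @param compute_cov compute the coefficient covariance needed for
#'   confidence bands (skippable for speed in mass per-vertex fits).
#' @param age_range boundary span for the spline basis; defaults to
#'   `c(0, 810)` days when the data lie inside it, else the observed range.
#' @param icv_ref optional precomputed ICV reference fit (a sex-free
#'   `gamm_fit` of ICV on age) reused across models of the same cohort;
#'   fitted internally when `NULL`. Population curves are evaluated at this
#'   cohort-mean ICV trajectory.
#' @return an object of class `gamm_fit`.
#' @seealso [predict_curve()], [derivative_curve()], [normalized_curve()],
#'   [stratified_bootstrap()]
#' @export
fit_gamm <- function(records, response, with_sex = TRUE, K = 10, K_sex = 5,
                     method = c("ML", "REML"), include_icv = TRUE,
                     fixed = list(), compute_cov = TRUE, age_range = NULL,
                     icv_ref = NULL) {
  method <- match.arg(method)
  if (include_icv && is.null(icv_ref)) {
    icv_ref <- fit_gamm(records, as.numeric(records$icv), with_sex = FALSE,
                        K = min(K, 8), include_icv = FALSE, method = method,
                        compute_cov = FALSE, age_range = age_range)
  }
  if (is.character(response)) {
    if (!response %in% names(records))
      stop(sprintf("response column '%s' not found", response))
    y <- as.numeric(records[[response]])
    resp_name <- response
  } else {
    y <- as.numeric(response)
    if (length(y) != nrow(records))
      stop("numeric response must have one value per record")
    resp_name <- "response"
  }
  if (anyNA(y)) stop("response contains missing values")
  n <- nrow(records)
  if (n < 20) warning("fewer than 20 scans; trajectory estimates will be unstable")
  nrep <- sum(table(records$subject_id) >= 2)
  if (nrep < 2)
    warning("fewer than 2 subjects with repeated scans; the subject-intercept variance is weakly identified")

  design <- sg_design(records, with_sex = with_sex, K = K, K_sex = K_sex,
                      include_icv = include_icv, age_range = age_range,
                      icv_ref = icv_ref)
  ss <- sg_suffstats(design, y)
  opt <- sg_optimize(ss, method = method, with_sex = with_sex, fixed = fixed)
  if (opt$nll >= 1e10) {
    stop("trajectory fit failed to converge from all starts; final objective not finite")
  }
  theta_pop <- c(opt$fit$beta, opt$fit$bhat)

  subj <- design$subject
  Vpop <- NULL; theta_all <- NULL; fitted_vals <- NULL; blups <- NULL
  neq_resid <- NA_real_
  if (compute_cov) {
    Msub <- model.matrix(~ 0 + subj)
    W <- cbind(design$X, design$Z, Msub)
    gvec <- ifelse(design$pen_group == 1L, opt$gammas[["f"]], opt$gammas[["sex"]])
    saug <- c(rep(0, design$p), 1 / gvec,
              rep(1 / opt$gammas[["subject"]], nlevels(subj)))
    Pm <- crossprod(W) + diag(saug, length(saug))
    cP <- chol(Pm)
    Wy <- crossprod(W, y)
    theta_all <- as.vector(backsolve(cP, forwardsolve(t(cP), Wy)))
    neq_resid <- max(abs(Pm %*% theta_all - Wy)) / max(abs(Wy))
    Vall <- opt$fit$sigma2 * chol2inv(cP)
    npop <- design$p + design$q
    Vpop <- Vall[seq_len(npop), seq_len(npop), drop = FALSE]
    fitted_vals <- as.vector(W %*% theta_all)
    blups <- setNames(theta_all[npop + seq_len(nlevels(subj))], levels(subj))
    theta_pop <- theta_all[seq_len(npop)]
  }

  subj_tab <- data.frame(
    subject_id = levels(subj),
    site = records$site[!duplicated(records$subject_id)][
      match(levels(subj), unique(records$subject_id))],
    sex = records$sex[!duplicated(records$subject_id)][
      match(levels(subj), unique(records$subject_id))],
    n_scans = as.integer(table(subj)),
    stringsAsFactors = FALSE
  )

  structure(list(
    design = design, ss = ss, response = resp_name, y = y,
    theta_pop = theta_pop, Vpop = Vpop, blups = blups,
    sigma2 = opt$fit$sigma2, gammas = opt$gammas,
    lambda = c(f = 1 / opt$gammas[["f"]],
               sex = if (with_sex) 1 / opt$gammas[["sex"]] else NA_real_),
    var_subject = opt$gammas[["subject"]] * opt$fit$sigma2,
    logLik = -opt$nll, method = method,
    convergence = opt$convergence, start_values = opt$start_values,
    neq_resid = neq_resid,
    fitted = fitted_vals, subjects = subj_tab, n = n
  ), class = "gamm_fit")
}

#' @export
print.gamm_fit <- function(x, ...) {
  cat(sprintf("Penalized-spline growth model (%s): response '%s'\n",
              x$method, x$response))
  cat(sprintf("  %d scans, %d subjects; K = %d%s\n", x$n,
              nrow(x$subjects), x$design$basis$K,
              if (x$design$with_sex)
                sprintf(" (+ sex smooth K = %d)", x$design$d_parts$basis$K) else ""))
  cat(sprintf("  sigma^2 = %.4g, subject-intercept var = %.4g, lambda_f = %.4g\n",
              x$sigma2, x$var_subject, x$lambda[["f"]]))
  cat(sprintf("  log marginal likelihood = %.4f\n", x$logLik))
  invisible(x)
}

sg_check_span <- function(model, grid) {
  rng <- model$design$basis$range
  if (any(grid < rng[1] - 1e-8 | grid > rng[2] + 1e-8))
    stop(sprintf("grid extends beyond the fitted age span [%g, %g]",
                 rng[1], rng[2]))
}

sg_curve_df <- function(grid, est, se, stratum, units) {
  out <- data.frame(age_days = grid, estimate = est,
                    lower = est - 1.96 * se, upper = est + 1.96 * se,
                    stratum = stratum, stringsAsFactors = FALSE)
  attr(out, "units") <- units
  class(out) <- c("fitted_curve", "data.frame")
  out
}

#' Population-level fitted trajectory with 95% confidence band
#'
#' Predicts the population curve at the reference covariate profile: site
#' coefficients averaged with observed site frequencies, ICV fixed at the
#' cohort mean ICV-vs-age curve (binned means, linearly interpolated), and the
#' requested sex stratum (`"pooled"` averages sexes with their observed
#' frequencies). The band is the pointwise \eqn{\pm 1.96} SE from the
#' coefficient covariance.
#'
#' @param model a [fit_gamm()] fit (with `compute_cov = TRUE` for bands).
#' @param grid ages (days) inside the fitted span.
#' @param stratum `"pooled"`, `"male"` or `"female"`.
#' @return a `fitted_curve` data.frame: `age_days`, `estimate`, `lower`,
#'   `upper`, `stratum`.
#' @export
predict_curve <- function(model, grid, stratum = "pooled") {
  stopifnot(inherits(model, "gamm_fit"))
  sg_check_span(model, grid)
  R <- sg_pred_rows(model$design, grid, stratum)
  est <- as.vector(R %*% model$theta_pop)
  se <- if (!is.null(model$Vpop)) sqrt(rowSums((R %*% model$Vpop) * R)) else rep(NA_real_, length(grid))
  sg_curve_df(grid, est, se, stratum, "response")
}

#' Growth-rate curve: analytic first derivative of the fitted trajectory
#'
#' The derivative of the population curve with respect to age, scaled to
#' response units per month (30 days/month). It is the exact derivative of
#' [predict_curve()]: spline basis derivatives times the fitted coefficients,
#' plus the (piecewise-constant) slope of the cohort mean ICV curve times the
#' ICV coefficient.
#'
#' @inheritParams predict_curve
#' @return a `fitted_curve` data.frame in response units per month.
#' @export
derivative_curve <- function(model, grid, stratum = "pooled") {
  stopifnot(inherits(model, "gamm_fit"))
  sg_check_span(model, grid)
  R <- sg_pred_rows(model$design, grid, stratum, deriv = TRUE) * 30
  est <- as.vector(R %*% model$theta_pop)
  se <- if (!is.null(model$Vpop)) sqrt(rowSums((R %*% model$Vpop) * R)) else rep(NA_real_, length(grid))
  sg_curve_df(grid, est, se, stratum, "response per month")
}

#' Normalized trajectory relative to the volume at term birth
#'
#' `Y(t) / Y(0)` using the model's population prediction at age 0; confidence
#' bounds are scaled by the same `Y(0)`.
#'
#' @inheritParams predict_curve
#' @return a unitless `fitted_curve`; the value at age 0 is exactly 1.
#' @export
normalized_curve <- function(model, grid, stratum = "pooled") {
  stopifnot(inherits(model, "gamm_fit"))
  t0 <- model$design$basis$range[1]
  sg_check_span(model, c(grid, 0))
  y0 <- predict_curve(model, 0, stratum)$estimate
  if (y0 <= 0) stop("population prediction at age 0 is nonpositive; cannot normalize")
  pc <- predict_curve(model, grid, stratum)
  out <- sg_curve_df(grid, pc$estimate / y0, (pc$upper - pc$estimate) / 1.96 / y0,
                     stratum, "ratio to birth volume")
  out
}

#' Record-level predictions from a fitted trajectory model
#'
#' Predicts at the observed covariates of `newdata` (site, ICV, sex, age),
#' adding each subject's estimated random intercept when the subject was in
#' the training data. Predicting on the training records reproduces the
#' fitted values.
#'
#' @param object a `gamm_fit`.
#' @param newdata scan records; defaults to fitted values on training data.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.gamm_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  d <- object$design
  t <- as.numeric(newdata$age_days)
  sg_check_span(object, t)
  nt <- length(t)
  Bf <- eval_basis(d$basis, t)
  parts <- list(int = matrix(1, nt, 1))
  if (length(d$site_levels) > 1) {
    site <- factor(newdata$site, levels = d$site_levels)
    if (anyNA(site)) stop("unknown site level in 'newdata'")
    parts$site <- model.matrix(~site)[, -1, drop = FALSE]
  }
  if (d$include_icv)
    parts$icv <- matrix((as.numeric(newdata$icv) - d$icv_center) / d$icv_scale)
  if (d$with_sex) {
    g <- as.numeric(newdata$sex == "male")
    parts$sex <- matrix(g)
  }
  parts$f_null <- Bf %*% d$f_parts$Tr_null
  if (d$with_sex) {
    Bd <- eval_basis(d$d_parts$basis, t)
    parts$d_null <- g * (Bd %*% d$d_parts$Tr_null)
  }
  parts$f_rand <- Bf %*% d$f_parts$Tr_rand
  if (d$with_sex) parts$d_rand <- g * (Bd %*% d$d_parts$Tr_rand)
  R <- do.call(cbind, parts)
  out <- as.vector(R %*% object$theta_pop)
  if (!is.null(object$blups)) {
    bl <- object$blups[as.character(newdata$subject_id)]
    bl[is.na(bl)] <- 0
    out <- out + as.vector(bl)
  }
  out
}

#' Export a fitted model to a JSON-serializable list
#' @param model a `gamm_fit`.
#' @return list of coefficients, knots, variance components and fit metadata.
#' @export
gamm_to_list <- function(model) {
  stopifnot(inherits(model, "gamm_fit"))
  list(
    response = model$response, method = model$method, n = model$n,
    K = model$design$basis$K, knots = model$design$basis$knots,
    with_sex = model$design$with_sex,
    theta_pop = model$theta_pop, sigma2 = model$sigma2,
    var_subject = model$var_subject, lambda = as.list(model$lambda),
    logLik = model$logLik, convergence = model$convergence
  )
}
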