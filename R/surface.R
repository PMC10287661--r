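#' Fit per-vertex local-area growth trajectories
#'
#' Computes the local surface area of every vertex of every scan (barycentric
#' one-ring/3 allocation) and fits the sex-free growth model (site effect +
#' ICV covariate + penalized age smooth + subject random intercept) to each
#' vertex's area series. All vertices share one spline basis and design;
#' smoothing and variance parameters are selected per vertex. Vertices whose
#' optimizer fails are masked and excluded from all downstream maps.
#'
#' @param series a `mesh_series` of corresponded meshes.
#' @param records cohort scan records supplying site, sex and ICV; matched to
#'   scans by `(subject_id, age_days)`.
#' @param K spline basis dimension.
#' @param include_icv adjust for ICV (the default, as in the volumetric model).
#' @param method `"ML"` or `"REML"` smoothness selection.
#' @return object of class `vertex_gamm`.
#' @export
fit_vertex_trajectories <- function(series, records, K = 10,
                                    include_icv = TRUE, method = "ML") {
  stopifnot(inherits(series, "mesh_series"))
  if (length(series$coords) < 20)
    stop("need at least 20 scans to fit vertex trajectories")
  j <- match(paste(series$meta$subject_id, series$meta$age_days),
             paste(records$subject_id, records$age_days))
  if (anyNA(j)) stop("mesh scans missing from the cohort table")
  df <- records[j, , drop = FALSE]
  A <- t(vapply(series$coords,
                function(xyz) vertex_local_area(xyz, series$faces),
                numeric(nrow(series$coords[[1]]))))
  V <- ncol(A)
  icv_ref <- if (include_icv) {
    fit_gamm(df, as.numeric(df$icv), with_sex = FALSE, K = min(K, 8),
             include_icv = FALSE, method = method, compute_cov = FALSE)
  } else NULL
  design <- sg_design(df, with_sex = FALSE, K = K, include_icv = include_icv,
                      icv_ref = icv_ref)
  ss <- sg_suffstats(design, A)
  npop <- design$p + design$q
  Theta <- matrix(NA_real_, npop, V)
  Gamma <- matrix(NA_real_, 2, V, dimnames = list(c("f", "subject"), NULL))
  sigma2 <- rep(NA_real_, V)
  masked <- logical(V)
  for (v in seq_len(V)) {
    op <- tryCatch(sg_optimize(ss, resp = v, method = method, with_sex = FALSE),
                   error = function(e) NULL)
    if (is.null(op) || op$nll >= 1e10 ||
        !all(is.finite(c(op$fit$beta, op$fit$bhat)))) {
      masked[v] <- TRUE
      message(sprintf("vertex %d failed to converge; masked", v))
      next
    }
    Theta[, v] <- c(op$fit$beta, op$fit$bhat)
    Gamma[, v] <- op$gammas[c("f", "subject")]
    sigma2[v] <- op$fit$sigma2
  }
  subj <- design$subject
  subjects <- data.frame(
    subject_id = levels(subj),
    site = df$site[!duplicated(df$subject_id)][
      match(levels(subj), unique(df$subject_id))],
    n_scans = as.integer(table(subj)), stringsAsFactors = FALSE)
  structure(list(design = design, ss = ss, Theta = Theta, Gamma = Gamma,
                 sigma2 = sigma2, masked = masked, V = V, method = method,
                 subjects = subjects, areas = A, faces = series$faces),
            class = "vertex_gamm")
}

#' @export
print.vertex_gamm <- function(x, ...) {
  cat(sprintf("Vertex-wise growth trajectories: %d vertices (%d masked), %d scans\n",
              x$V, sum(x$masked), x$design$n))
  invisible(x)
}

sg_vertex_rates <- function(vfit, theta, month) {
  t <- month * 30
  Rv <- sg_pred_rows(vfit$design, t, "pooled")
  Rd <- sg_pred_rows(vfit$design, t, "pooled", deriv = TRUE) * 30
  a <- as.vector(Rv %*% theta)
  da <- as.vector(Rd %*% theta)
  rate <- da / a
  rate[!is.finite(rate) | a <= 0] <- NA_real_
  rate
}

#' Monthly surface-area expansion-rate map
#'
#' Relative expansion rate `(dA/dt)/A(t)` per month (30 days) at each vertex,
#' from the analytic derivative of the fitted area trajectory. Vertices with
#' nonpositive fitted area, and masked vertices, are `NA`.
#'
#' @param vfit a `vertex_gamm`.
#' @param month evaluation age in months (within the fitted span).
#' @param relative if `FALSE`, return the absolute rate `dA/dt` (mm^2/month).
#' @return numeric vector of per-vertex rates with attribute `month`.
#' @export
expansion_rate_map <- function(vfit, month, relative = TRUE) {
  stopifnot(inherits(vfit, "vertex_gamm"))
  t <- month * 30
  sg_check_span(list(design = vfit$design), t)
  Rv <- sg_pred_rows(vfit$design, t, "pooled")
  Rd <- sg_pred_rows(vfit$design, t, "pooled", deriv = TRUE) * 30
  a <- as.vector(Rv %*% vfit$Theta)
  da <- as.vector(Rd %*% vfit$Theta)
  out <- if (relative) da / a else da
  out[vfit$masked | !is.finite(out) | (relative & a <= 0)] <- NA_real_
  attr(out, "month") <- month
  out
}

#' Bootstrap replicate expansion-rate maps
#'
#' Stratified subject bootstrap (site x scans-category strata by default) of
#' the per-vertex expansion rates at one month, refitting every vertex per
#' replicate with its smoothing and variance parameters held at the point
#' estimates.
#'
#' @param vfit a `vertex_gamm`.
#' @param month age in months.
#' @param B number of replicates.
#' @param seed integer seed.
#' @param strata as in [stratified_bootstrap()].
#' @param relative relative (fraction/month) or absolute rates.
#' @return matrix, B rows x V vertices, of replicate rates.
#' @export
bootstrap_expansion_rates <- function(vfit, month, B = 200, seed = 1L,
                                      strata = NULL, relative = TRUE) {
  stopifnot(inherits(vfit, "vertex_gamm"))
  W <- sg_boot_weights(vfit$subjects, B, strata, seed)
  t <- month * 30
  Rv <- sg_pred_rows(vfit$design, t, "pooled")
  Rd <- sg_pred_rows(vfit$design, t, "pooled", deriv = TRUE) * 30
  out <- matrix(NA_real_, B, vfit$V)
  for (b in seq_len(B)) {
    w <- W[, b]
    for (v in seq_len(vfit$V)) {
      if (vfit$masked[v]) next
      th <- sg_refit_theta(vfit$ss,
                           c(f = unname(vfit$Gamma["f", v]), sex = 0,
                             subject = unname(vfit$Gamma["subject", v])),
                           resp = v, w = w)
      if (is.null(th)) next
      a <- sum(Rv * th); da <- sum(Rd * th)
      out[b, v] <- if (relative) { if (a > 0) da / a else NA_real_ } else da
    }
  }
  out
}

#' Detect statistically significant high- and low-growth regions
#'
#' Candidates are the top and bottom `q` fraction of vertices by expansion
#' rate (quantile by rank with stable tie-breaking by vertex index, so
#' exactly `ceiling(q*V)` vertices qualify on each side). For each candidate,
#' the bootstrap replicates of its rate are compared against the cross-vertex
#' median of the point rates: `t = (mean(replicates) - median) /
#' sd(replicates)` with `B - 1` degrees of freedom (the bootstrap SD
#' estimates the sampling SD of the vertex rate). Two-sided p-values are
#' Benjamini-Hochberg adjusted across the tested candidates; significant
#' candidates above/below the median are labelled `high`/`low`.
#'
#' @param rates point expansion rates (from [expansion_rate_map()]).
#' @param replicate_rates B x V matrix (from [bootstrap_expansion_rates()]).
#' @param q candidate fraction per tail (default 0.20).
#' @param alpha FDR level.
#' @return data.frame: `vertex`, `rate`, `candidate`, `t`, `p`, `q_bh`,
#'   `label` (`"high"`, `"low"` or `"none"`).
#' @export
detect_growth_regions <- function(rates, replicate_rates, q = 0.20,
                                  alpha = 0.05) {
  replicate_rates <- as.matrix(replicate_rates)
  V <- length(rates)
  if (ncol(replicate_rates) != V)
    stop("'replicate_rates' must have one column per vertex")
  if (nrow(replicate_rates) < 100)
    warning("fewer than 100 replicate maps; detection p-values will be unstable")
  valid <- which(!is.na(rates))
  out <- data.frame(vertex = seq_len(V), rate = rates, candidate = FALSE,
                    t = NA_real_, p = NA_real_, q_bh = NA_real_,
                    label = "none", stringsAsFactors = FALSE)
  if (!length(valid)) return(out)
  med <- median(rates[valid])
  if (diff(range(rates[valid])) < .Machine$double.eps * max(1, abs(med))) {
    return(out)   # all rates identical: no candidates
  }
  nq <- ceiling(q * length(valid))
  ord <- valid[order(rates[valid], valid)]   # ascending, ties by vertex index
  bottom <- ord[seq_len(nq)]
  top <- ord[seq.int(length(ord) - nq + 1L, length(ord))]
  cand <- union(bottom, top)
  out$candidate[cand] <- TRUE
  B <- nrow(replicate_rates)
  tstat <- vapply(cand, function(v) {
    rv <- replicate_rates[, v]
    rv <- rv[is.finite(rv)]
    if (length(rv) < 2 || sd(rv) == 0) return(NA_real_)
    (mean(rv) - med) / sd(rv)
  }, 0)
  p <- 2 * pt(-abs(tstat), df = B - 1)
  qv <- p.adjust(p, method = "BH")
  out$t[cand] <- tstat
  out$p[cand] <- p
  out$q_bh[cand] <- qv
  sig <- cand[!is.na(qv) & qv < alpha]
  out$label[sig] <- ifelse(rates[sig] > med, "high", "low")
  out
}

#' Dice overlap between two vertex index sets
#' @param a,b integer vertex index vectors.
#' @return `2|a n b| / (|a| + |b|)`; 1 for identical non-empty sets.
#' @export
dice_overlap <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}
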