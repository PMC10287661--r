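#' Age intervals for growth-rate tables
#'
#' The nine age ranges over which interval growth rates are tabulated
#' (months; 1 month = 30 days): 0-3, 3-6, 6-9, 9-12, 12-18, 18-24, 0-6,
#' 0-12 and 0-24.
#'
#' @return data.frame with columns `t1`, `t2` (months) and `label`.
#' @export
growth_intervals <- function() {
  t1 <- c(0, 3, 6, 9, 12, 18, 0, 0, 0)
  t2 <- c(3, 6, 9, 12, 18, 24, 6, 12, 24)
  data.frame(t1 = t1, t2 = t2, label = sprintf("%dM-%dM", t1, t2))
}

sg_interp <- function(curve, days) {
  if (any(days < min(curve$age_days) - 1e-8 | days > max(curve$age_days) + 1e-8))
    stop("interval endpoint outside the curve grid")
  approx(curve$age_days, curve$estimate, xout = days, rule = 1)$y
}

#' Interval growth rate of a fitted curve
#'
#' The fractional change of the population curve between two ages:
#' `(Y(t2) - Y(t1)) / Y(t1)`, with endpoints in months (30 days/month) and
#' linear interpolation between grid points.
#'
#' @param curve a `fitted_curve` (from [predict_curve()]).
#' @param t1,t2 interval endpoints in months, `0 <= t1 < t2 <= 27`.
#' @return the growth rate as a fraction (0.20 means +20%).
#' @export
interval_growth_rate <- function(curve, t1, t2) {
  if (!(t1 >= 0 && t1 < t2 && t2 <= 27)) stop("need 0 <= t1 < t2 <= 27 months")
  y <- sg_interp(curve, c(t1, t2) * 30)
  if (y[1] <= 0) stop("curve value at t1 is nonpositive; growth rate undefined")
  (y[2] - y[1]) / y[1]
}

# subject resampling weights: S x B matrix of counts, resampling subjects
# with replacement within strata so each stratum keeps its subject count
sg_boot_weights <- function(subjects, B, strata = NULL, seed = 1L) {
  S <- nrow(subjects)
  if (is.null(strata)) {
    cat3 <- pmin(subjects$n_scans, 3L)
    strata <- interaction(subjects$site, factor(cat3, levels = 1:3,
                                                labels = c("1", "2", "3+")),
                          drop = TRUE)
  } else if (is.character(strata) && all(strata %in% names(subjects))) {
    strata <- interaction(subjects[strata], drop = TRUE)
  } else {
    strata <- factor(strata)
    if (length(strata) != S) stop("'strata' must have one level per subject")
  }
  idx <- split(seq_len(S), strata)
  sg_with_seed(seed, {
    W <- matrix(0L, S, B)
    for (b in seq_len(B)) {
      for (g in idx) {
        drawn <- g[sample.int(length(g), length(g), replace = TRUE)]
        tb <- tabulate(drawn, nbins = S)
        W[, b] <- W[, b] + tb
      }
    }
    W
  })
}

#' Stratified bootstrap of a fitted growth trajectory
#'
#' Resamples whole subjects with replacement (all scans of a drawn subject
#' move together) within design strata — by default site crossed with the
#' number-of-scans category \{1, 2, 3+\}, preserving both design margins —
#' and refits the model to each replicate. By default the smoothing
#' parameters and variance ratios are held at their point estimates
#' (a fast penalized-GLS refit); `refit_lambda = TRUE` re-optimizes them per
#' replicate.
#'
#' @param model a `gamm_fit`.
#' @param B number of replicates (at least 100 recommended for inference;
#'   a warning is issued below 500).
#' @param seed integer seed; replicates are deterministic given the seed.
#' @param strata `NULL` for the default site x scans-category stratification,
#'   a character vector of column names of the subject table (`site`, `sex`,
#'   `n_scans`), or a factor with one level per subject.
#' @param refit_lambda re-select smoothing/variance parameters per replicate.
#' @return object of class `gamm_boot`: population-coefficient replicates
#'   (`Theta`, columns = replicates), the model reference, and bookkeeping.
#' @export
stratified_bootstrap <- function(model, B = 1000, seed = 1L, strata = NULL,
                                 refit_lambda = FALSE) {
  stopifnot(inherits(model, "gamm_fit"))
  if (B < 2) stop("'B' must be at least 2")
  if (B < 500) warning(sprintf("B = %d bootstrap replicates; below 500 the SD estimate may be unstable", B))
  W <- sg_boot_weights(model$subjects, B, strata, seed)
  npop <- model$design$p + model$design$q
  Theta <- matrix(NA_real_, npop, B)
  failed <- 0L
  for (b in seq_len(B)) {
    w <- W[, b]
    th <- if (refit_lambda) {
      # warm-start each replicate's smoothing/variance search at the point
      # estimate; replicates rarely move far
      ws <- log(unname(c(model$gammas[["f"]],
                         if (model$design$with_sex) model$gammas[["sex"]],
                         model$gammas[["subject"]])))
      op <- tryCatch(sg_optimize(model$ss, method = model$method,
                                 with_sex = model$design$with_sex, w = w,
                                 warm_start = ws),
                     error = function(e) NULL)
      if (is.null(op) || op$nll >= 1e10) NULL else c(op$fit$beta, op$fit$bhat)
    } else {
      sg_refit_theta(model$ss, model$gammas, w = w)
    }
    if (is.null(th)) failed <- failed + 1L else Theta[, b] <- th
  }
  if (failed > 0) {
    message(sprintf("%d of %d bootstrap replicates failed to fit and were dropped", failed, B))
    if (failed > 0.05 * B) stop("more than 5% of bootstrap replicates failed to fit")
    Theta <- Theta[, colSums(is.na(Theta)) == 0, drop = FALSE]
  }
  structure(list(Theta = Theta, B = ncol(Theta), seed = seed,
                 refit_lambda = refit_lambda, model = model),
            class = "gamm_boot")
}

#' Replicate population curves from a bootstrap
#'
#' @param boot a `gamm_boot`.
#' @param grid ages in days.
#' @param stratum sex stratum as in [predict_curve()].
#' @param deriv evaluate derivatives (per month) instead of values.
#' @return matrix, `length(grid)` rows x B replicate columns.
#' @export
bootstrap_curves <- function(boot, grid, stratum = "pooled", deriv = FALSE) {
  stopifnot(inherits(boot, "gamm_boot"))
  sg_check_span(boot$model, grid)
  R <- sg_pred_rows(boot$model$design, grid, stratum, deriv = deriv)
  if (deriv) R <- R * 30
  R %*% boot$Theta
}

#' Z-tests of growth against zero with Bonferroni control
#'
#' For each cell, the bootstrap SD of the replicate statistics estimates the
#' sampling SD of the point statistic; `Z = |point| / SD(replicates)`, the
#' two-sided p-value comes from the standard normal, and the Bonferroni
#' adjustment multiplies by the number `m` of simultaneous tests.
#'
#' @param point numeric vector of point statistics (one per cell).
#' @param replicates matrix of replicate statistics, cells in rows.
#' @param m number of simultaneous tests (defaults to `length(point)`).
#' @param alpha significance level for the `significant` flag.
#' @return data.frame: `point`, `boot_sd`, `z`, `p`, `p_adj`, `significant`.
#' @export
growth_significance <- function(point, replicates, m = length(point),
                                alpha = 0.05) {
  replicates <- as.matrix(replicates)
  if (length(point) != nrow(replicates))
    stop("'replicates' must have one row per point statistic")
  if (ncol(replicates) < 2) stop("need at least 2 replicates per cell")
  bsd <- apply(replicates, 1, sd)
  z <- ifelse(bsd > 0, abs(point) / bsd, ifelse(point == 0, 0, Inf))
  if (any(bsd == 0 & point != 0))
    warning("zero bootstrap SD with nonzero statistic; p reported as 0")
  p <- 2 * pnorm(-z)
  p_adj <- pmin(1, m * p)
  data.frame(point = point, boot_sd = bsd, z = z, p = p, p_adj = p_adj,
             significant = p_adj < alpha)
}

#' Interval growth-rate table with bootstrap Z-tests
#'
#' The per-structure machinery behind the growth-rate tables: for each age
#' interval and sex stratum, the population growth rate
#' `(Y(t2) - Y(t1))/Y(t1)`, the bootstrap SD of the volume change
#' `Y(t2) - Y(t1)`, the Z-statistic `|Y(t2) - Y(t1)| / SD[Y(t2) - Y(t1)]`,
#' its two-sided normal p-value, and the Bonferroni-adjusted p-value over
#' `m` simultaneous tests.
#'
#' @param model a `gamm_fit`.
#' @param boot a matching `gamm_boot`.
#' @param intervals data.frame with `t1`, `t2` in months
#'   (default [growth_intervals()]).
#' @param sexes strata to tabulate; default `c("male", "female")` for a
#'   sex-aware model, else `"pooled"`.
#' @param m Bonferroni count; by default the number of intervals, and in a
#'   multi-structure table the caller passes structures x intervals.
#' @param alpha significance level.
#' @return data.frame: `interval`, `sex`, `rate`, `boot_sd_diff`, `z`, `p`,
#'   `p_adj`, `significant`.
#' @export
growth_table <- function(model, boot, intervals = growth_intervals(),
                         sexes = NULL, m = NULL, alpha = 0.05) {
  stopifnot(inherits(model, "gamm_fit"), inherits(boot, "gamm_boot"))
  if (is.null(sexes)) {
    sexes <- if (model$design$with_sex) c("male", "female") else "pooled"
  }
  if (is.null(m)) m <- nrow(intervals)
  days <- sort(unique(c(intervals$t1, intervals$t2) * 30))
  out <- list()
  for (sx in sexes) {
    pc <- predict_curve(model, days, sx)
    reps <- bootstrap_curves(boot, days, sx)
    i1 <- match(intervals$t1 * 30, days); i2 <- match(intervals$t2 * 30, days)
    y1 <- pc$estimate[i1]; y2 <- pc$estimate[i2]
    if (any(y1 <= 0)) stop("curve value at an interval start is nonpositive")
    diff_point <- y2 - y1
    diff_reps <- reps[i2, , drop = FALSE] - reps[i1, , drop = FALSE]
    gs <- growth_significance(diff_point, diff_reps, m = m, alpha = alpha)
    out[[sx]] <- data.frame(
      interval = sprintf("%gM-%gM", intervals$t1, intervals$t2),
      t1 = intervals$t1, t2 = intervals$t2, sex = sx,
      rate = diff_point / y1, boot_sd_diff = gs$boot_sd,
      z = gs$z, p = gs$p, p_adj = gs$p_adj, significant = gs$significant,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reshape a combined growth table to the classic wide layout
#'
#' Rows are age intervals; columns are structure-by-sex growth rates in
#' percent, with `*` marking cells significant after Bonferroni correction —
#' the layout of the printed growth-rate tables.
#'
#' @param long a combined long table (rows from [growth_table()] with a
#'   `structure` column).
#' @return data.frame, one row per interval.
#' @export
growth_table_wide <- function(long) {
  stopifnot(all(c("structure", "interval", "sex", "rate") %in% names(long)))
  iv <- unique(long$interval)
  out <- data.frame(interval = iv, stringsAsFactors = FALSE)
  for (st in unique(long$structure)) {
    for (sx in unique(long$sex)) {
      sel <- long$structure == st & long$sex == sx
      cell <- sprintf("%.1f%s", 100 * long$rate[sel],
                      ifelse(long$significant[sel], "*", ""))
      out[[paste(st, sx, sep = ".")]] <- cell[match(iv, long$interval[sel])]
    }
  }
  out
}

#' Pointwise bootstrap test of the sex effect
#'
#' Tests, at each grid age, whether the fitted male-minus-female population
#' difference (sex main effect plus deviation smooth) differs from zero,
#' using the bootstrap SD of the replicate differences.
#'
#' @param model a `gamm_fit` fitted with `with_sex = TRUE`.
#' @param boot a matching `gamm_boot`.
#' @param grid ages in days.
#' @param alpha significance level.
#' @return data.frame: `age_days`, `difference`, `boot_sd`, `z`, `p`,
#'   `significant`.
#' @export
sex_effect_test <- function(model, boot, grid, alpha = 0.05) {
  stopifnot(inherits(model, "gamm_fit"))
  if (!model$design$with_sex) stop("model was fitted without a sex term")
  if (is.null(boot)) stop("bootstrap replicates are required")
  dm <- predict_curve(model, grid, "male")$estimate -
    predict_curve(model, grid, "female")$estimate
  reps <- bootstrap_curves(boot, grid, "male") -
    bootstrap_curves(boot, grid, "female")
  gs <- growth_significance(dm, reps, m = 1, alpha = alpha)
  data.frame(age_days = grid, difference = dm, boot_sd = gs$boot_sd,
             z = gs$z, p = gs$p, significant = gs$p < alpha)
}

#' Asymmetry-index trajectory
#'
#' `AI(t) = (L(t) - R(t)) / ((L(t) + R(t))/2)`; positive values indicate
#' leftward asymmetry.
#'
#' @param left,right `fitted_curve`s of the left and right hemisphere on a
#'   common age grid.
#' @return data.frame `age_days`, `ai`.
#' @export
asymmetry_index <- function(left, right) {
  if (!isTRUE(all.equal(left$age_days, right$age_days)))
    stop("left and right curves must share one age grid")
  denom <- (left$estimate + right$estimate) / 2
  if (any(denom <= 0)) stop("L + R must be positive to form the asymmetry index")
  data.frame(age_days = left$age_days,
             ai = (left$estimate - right$estimate) / denom)
}
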