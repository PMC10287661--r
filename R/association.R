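#' Log volume-to-ICV ratio
#'
#' `log(volume / icv)`, the relative-volume predictor used in the
#' brain-behavior association models.
#'
#' @param volume structure volume (mm^3), positive.
#' @param icv intracranial volume (mm^3), positive.
#' @return unitless log ratio.
#' @export
log_volume_ratio <- function(volume, icv) {
  if (any(volume <= 0) || any(icv <= 0))
    stop("'volume' and 'icv' must be positive")
  log(volume / icv)
}

#' Benjamini-Hochberg FDR adjustment, optionally within groups
#'
#' Standard step-up BH q-values; when `group` is supplied the adjustment is
#' applied separately within each group (e.g. within each Mullen score
#' across structures).
#'
#' @param p p-values in \[0, 1\].
#' @param group optional grouping vector of the same length.
#' @return q-values, same length and order as `p`.
#' @export
fdr_adjust <- function(p, group = NULL) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  if (is.null(group)) return(p.adjust(p, method = "BH"))
  if (length(group) != length(p)) stop("'group' must match 'p' in length")
  q <- rep(NA_real_, length(p))
  for (g in unique(group)) {
    i <- which(group == g)
    q[i] <- p.adjust(p[i], method = "BH")
  }
  q
}

# standardize to mean 0, variance 1 (constant columns left at 0)
sg_std <- function(x) {
  x <- as.numeric(x)
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(x * 0)
  (x - mean(x)) / s
}

# assemble the standardized covariate frame for the association models
sg_assoc_frame <- function(records, score, predictors = NULL) {
  col <- paste0("mullen_", score)
  if (!col %in% names(records))
    stop(sprintf("score column '%s' not found", col))
  keep <- !is.na(records[[col]])
  d <- records[keep, , drop = FALSE]
  if (nrow(d) < 30)
    stop(sprintf("need at least 30 score observations, got %d", nrow(d)))
  out <- data.frame(
    y = d[[col]],
    age = sg_std(d$age_days),
    sex = sg_std(as.numeric(d$sex == "male")),
    site = sg_std(as.numeric(factor(d$site)) - 1),
    income = sg_std(d$income),
    edu = sg_std(d$maternal_education),
    icv = sg_std(d$icv),
    subject_id = d$subject_id,
    stringsAsFactors = FALSE
  )
  for (s in predictors) {
    v <- d[[paste0(s, "_L")]] + d[[paste0(s, "_R")]]
    out[[paste0("ratio_", s)]] <- sg_std(log_volume_ratio(v, d$icv))
  }
  out
}

sg_covariates <- c("age", "sex", "site", "income", "edu", "icv")

# random-intercept LMM with Satterthwaite tests; falls back to OLS with
# d.f. = n - p when the random-effect variance is singular
sg_lmm <- function(formula, data, reml = TRUE) {
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(formula, data = data, REML = reml,
                     control = lme4::lmerControl(check.conv.singular =
                       lme4::.makeCC(action = "ignore", tol = 1e-4))))),
    error = function(e) NULL)
  if (is.null(fit)) {
    # e.g. one observation per subject: the intercept variance is not
    # identifiable at all
    warning("singular random-intercept variance; falling back to OLS with d.f. = n - p")
    return(list(fit = lm(lme4::nobars(formula), data = data), singular = TRUE))
  }
  if (lme4::isSingular(fit, tol = 1e-4)) {
    warning("singular random-intercept variance; falling back to OLS with d.f. = n - p")
    fixed <- lme4::nobars(formula)
    return(list(fit = lm(fixed, data = data), singular = TRUE))
  }
  list(fit = fit, singular = FALSE)
}

#' Mixed-model association between a structure's relative volume and a score
#'
#' Fits the random-intercept linear mixed model
#' `score ~ age + sex + site + income + edu + ICV + log(volume/ICV) + (1 | subject)`
#' with every covariate and the predictor standardized to mean zero and unit
#' variance, and tests the predictor coefficient with Satterthwaite's
#' approximate t-test. If the random-intercept variance is estimated as
#' singular the model falls back to ordinary least squares with `n - p`
#' degrees of freedom (with a warning).
#'
#' @param records scan records with Mullen scores (see [generate_mullen()]
#'   or [read_cohort()]).
#' @param score one of `"GM"`, `"FM"`, `"VR"`, `"RL"`, `"EL"`, `"ELC"`.
#' @param structure one of the six structure names; the predictor is the
#'   standardized bilateral `log((L + R)/ICV)`.
#' @param reml fit by REML (default) or ML.
#' @return data.frame (one row): `score`, `structure`, `beta` (standardized
#'   coefficient), `se`, `df` (Satterthwaite), `t`, `p`, `singular`.
#' @export
fit_association_lmm <- function(records, score, structure, reml = TRUE) {
  d <- sg_assoc_frame(records, score, predictors = structure)
  pred <- paste0("ratio_", structure)
  f <- as.formula(paste("y ~", paste(sg_covariates, collapse = " + "), "+",
                        pred, "+ (1 | subject_id)"))
  m <- sg_lmm(f, d, reml = reml)
  if (m$singular) {
    sm <- summary(m$fit)$coefficients
    row <- sm[pred, ]
    df <- m$fit$df.residual
    out <- data.frame(score = score, structure = structure,
                      beta = row[["Estimate"]], se = row[["Std. Error"]],
                      df = df, t = row[["t value"]],
                      p = row[["Pr(>|t|)"]], singular = TRUE,
                      stringsAsFactors = FALSE)
  } else {
    sm <- summary(m$fit)$coefficients
    row <- sm[pred, ]
    out <- data.frame(score = score, structure = structure,
                      beta = row[["Estimate"]], se = row[["Std. Error"]],
                      df = row[["df"]], t = row[["t value"]],
                      p = row[["Pr(>|t|)"]], singular = FALSE,
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Association table across structures and scores with FDR control
#'
#' Runs [fit_association_lmm()] for every requested structure-score pair and
#' adds Benjamini-Hochberg q-values, by default grouped within each score
#' across the six structures (`fdr_grouping = "score"`); `"all"` pools every
#' test into one family.
#'
#' @param records scan records with Mullen scores.
#' @param scores,structures character vectors of scores and structures.
#' @param fdr_grouping `"score"` or `"all"`.
#' @param reml fit by REML (default) or ML.
#' @param alpha significance level for the flag.
#' @return data.frame with one row per score x structure: `beta`, `p`, `q`,
#'   `significant`.
#' @export
association_table <- function(records, scores = SG_SCORES,
                              structures = SG_STRUCTURES,
                              fdr_grouping = c("score", "all"),
                              reml = TRUE, alpha = 0.05) {
  fdr_grouping <- match.arg(fdr_grouping)
  res <- do.call(rbind, lapply(scores, function(sc) {
    do.call(rbind, lapply(structures, function(st) {
      fit_association_lmm(records, sc, st, reml = reml)
    }))
  }))
  res$q <- fdr_adjust(res$p,
                      group = if (fdr_grouping == "score") res$score else NULL)
  res$significant <- res$q < alpha
  res
}

#' Nested-model ANOVA F comparison
#'
#' Tests whether adding the log volume ratios of the given structures to the
#' covariates-only null model improves the fit of the score, via the joint
#' F-test (Satterthwaite denominator degrees of freedom) of the added
#' coefficients in the ML-fitted full mixed model. With no added predictors
#' the test is degenerate: `F = 0`, `p = 1`.
#'
#' @param records scan records with Mullen scores.
#' @param score the Mullen score.
#' @param structures structures whose log ratios enter the full model.
#' @return data.frame: `score`, `predictors`, `F`, `df1`, `df2`, `p_F`.
#' @export
compare_models <- function(records, score, structures) {
  if (!length(structures)) {
    return(data.frame(score = score, predictors = "", F = 0, df1 = 0,
                      df2 = NA_real_, p_F = 1, stringsAsFactors = FALSE))
  }
  d <- sg_assoc_frame(records, score, predictors = structures)
  preds <- paste0("ratio_", structures)
  f <- as.formula(paste("y ~", paste(c(sg_covariates, preds), collapse = " + "),
                        "+ (1 | subject_id)"))
  m <- sg_lmm(f, d, reml = FALSE)
  if (m$singular) {
    f0 <- as.formula(paste("y ~", paste(sg_covariates, collapse = " + ")))
    a <- anova(lm(f0, data = d), m$fit)
    out <- data.frame(score = score, predictors = paste(structures, collapse = "+"),
                      F = a$F[2], df1 = a$Df[2], df2 = a$Res.Df[2],
                      p_F = a$`Pr(>F)`[2], stringsAsFactors = FALSE)
  } else {
    cf <- names(lme4::fixef(m$fit))
    L <- matrix(0, length(preds), length(cf))
    L[cbind(seq_along(preds), match(preds, cf))] <- 1
    ct <- lmerTest::contest(m$fit, L, joint = TRUE)
    out <- data.frame(score = score, predictors = paste(structures, collapse = "+"),
                      F = ct$`F value`, df1 = ct$NumDF, df2 = ct$DenDF,
                      p_F = ct$`Pr(>F)`, stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Vertex-wise association between local area and a score
#'
#' Fits, at every vertex, the mixed model `score ~ age + sex + site + income +
#' edu + ICV + area_v + (1 | subject)` with standardized covariates and
#' standardized vertex area, joining behavioral visits to mesh scans by
#' nearest age within a tolerance window. p-values are BH-adjusted across the
#' vertices of the structure.
#'
#' @param records scan records with Mullen scores (the behavioral visits).
#' @param vfit a `vertex_gamm` (supplies per-scan vertex areas and metadata).
#' @param score the Mullen score.
#' @param window maximum |score age - scan age| in days for the join
#'   (default 45).
#' @param alpha FDR level.
#' @param random_intercept include the by-subject random intercept (default);
#'   `FALSE` reproduces the fixed-effects-only form.
#' @return data.frame per vertex: `beta`, `t`, `df`, `p`, `q`, `significant`.
#' @export
vertex_association <- function(records, vfit, score, window = 45,
                               alpha = 0.05, random_intercept = TRUE) {
  stopifnot(inherits(vfit, "vertex_gamm"))
  col <- paste0("mullen_", score)
  if (!col %in% names(records)) stop(sprintf("score column '%s' not found", col))
  beh <- records[!is.na(records[[col]]), , drop = FALSE]
  mesh_meta <- vfit$design  # scans underlying the vertex fit
  scan_sub <- as.character(vfit$design$subject)
  scan_age <- vfit$design$t
  # nearest mesh scan of the same subject within the window
  j <- vapply(seq_len(nrow(beh)), function(i) {
    k <- which(scan_sub == beh$subject_id[i])
    if (!length(k)) return(NA_integer_)
    dk <- abs(scan_age[k] - beh$age_days[i])
    if (min(dk) > window) return(NA_integer_)
    k[which.min(dk)]
  }, 1L)
  drop <- is.na(j)
  if (any(drop))
    message(sprintf("%d behavioral visit(s) without a mesh scan within %d days dropped",
                    sum(drop), window))
  beh <- beh[!drop, , drop = FALSE]; j <- j[!drop]
  d0 <- sg_assoc_frame(beh, score)
  re <- if (random_intercept) "+ (1 | subject_id)" else ""
  out <- data.frame(vertex = seq_len(vfit$V), beta = NA_real_, t = NA_real_,
                    df = NA_real_, p = NA_real_)
  for (v in seq_len(vfit$V)) {
    if (vfit$masked[v]) next
    d0$area <- sg_std(vfit$areas[j, v])
    f <- as.formula(paste("y ~", paste(sg_covariates, collapse = " + "),
                          "+ area", re))
    row <- if (random_intercept) {
      m <- withCallingHandlers(sg_lmm(f, d0), warning = function(w)
        invokeRestart("muffleWarning"))
      sm <- summary(m$fit)$coefficients["area", ]
      if (m$singular) c(sm[["Estimate"]], sm[["t value"]],
                        m$fit$df.residual, sm[["Pr(>|t|)"]])
      else c(sm[["Estimate"]], sm[["t value"]], sm[["df"]], sm[["Pr(>|t|)"]])
    } else {
      sm <- summary(lm(f, data = d0))$coefficients["area", ]
      c(sm[["Estimate"]], sm[["t value"]], nrow(d0) - 8, sm[["Pr(>|t|)"]])
    }
    out[v, c("beta", "t", "df", "p")] <- row
  }
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- fdr_adjust(out$p[ok])
  out$significant <- !is.na(out$q) & out$q < alpha
  out
}
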