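#' @importFrom stats rnorm runif quantile median sd var coef pnorm pt qnorm
#'   setNames aggregate approx approxfun fitted lm anova as.formula complete.cases
#'   p.adjust optim model.matrix resid predict
NULL

SG_STRUCTURES <- c("thalamus", "caudate", "putamen", "pallidum", "hippocampus", "amygdala")
SG_HEMIS <- c("L", "R")
SG_SCORES <- c("GM", "FM", "VR", "RL", "EL", "ELC")

sg_volume_cols <- function() {
  as.vector(outer(SG_STRUCTURES, SG_HEMIS, paste, sep = "_"))
}

#' Configuration for the synthetic longitudinal cohort
#'
#' Encodes the sampling design being emulated: ages 0--810 days (0--27 months
#' at 30 days/month), unbalanced longitudinal follow-up with ~55% singleton
#' subjects, two acquisition sites and two sexes, subject random intercepts and
#' Gaussian measurement noise. `noise_sd` and `random_intercept_sd` are
#' expressed as fractions of each structure's volume at birth, so that noise is
#' comparable across structures whose volumes span an order of magnitude.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param age_range allowed scan ages in days, within \[0, 810\].
#' @param scans_per_subject named probability vector over scan counts per
#'   subject (names are integer counts).
#' @param site_probabilities named probability vector over sites.
#' @param sex_probabilities named probability vector over `female`/`male`.
#' @param noise_sd residual SD as a fraction of birth volume (>= 0).
#' @param random_intercept_sd subject-intercept SD as a fraction of birth volume.
#' @param icv_subject_sd SD of the subject-level multiplicative ICV scale.
#' @param icv_noise_sd per-scan ICV noise as a fraction of birth ICV.
#' @param seed integer seed making generation deterministic.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 231,
                          age_range = c(0, 810),
                          scans_per_subject = c("1" = 0.55, "2" = 0.33, "3" = 0.12),
                          site_probabilities = c(S1 = 0.5, S2 = 0.5),
                          sex_probabilities = c(female = 0.545, male = 0.455),
                          noise_sd = 0.025,
                          random_intercept_sd = 0.04,
                          icv_subject_sd = 0.05,
                          icv_noise_sd = 0.01,
                          seed = 1L) {
  chk_prob <- function(p, nm) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop(sprintf("'%s' must be nonnegative and sum to 1", nm))
  }
  if (n_subjects < 1) stop("'n_subjects' must be at least 1")
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative")
  if (random_intercept_sd < 0) stop("'random_intercept_sd' must be nonnegative")
  if (age_range[1] < 0 || age_range[2] > 810 || age_range[1] >= age_range[2])
    stop("'age_range' must be an increasing interval within [0, 810]")
  chk_prob(scans_per_subject, "scans_per_subject")
  chk_prob(site_probabilities, "site_probabilities")
  chk_prob(sex_probabilities, "sex_probabilities")
  if (is.null(names(scans_per_subject)) || anyNA(as.integer(names(scans_per_subject))))
    stop("'scans_per_subject' must be named by integer scan counts")
  structure(list(
    n_subjects = as.integer(n_subjects), age_range = age_range,
    scans_per_subject = scans_per_subject,
    site_probabilities = site_probabilities,
    sex_probabilities = sex_probabilities,
    noise_sd = noise_sd, random_intercept_sd = random_intercept_sd,
    icv_subject_sd = icv_subject_sd, icv_noise_sd = icv_noise_sd,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Ground-truth growth curves for the synthetic cohort
#'
#' Five structures follow a log-saturating curve `a * (1 + G * log(1 + t/c) /
#' log(1 + 810/c))` (rapid early growth that slows at a structure-specific
#' timescale `c`); the amygdala analog grows linearly, mirroring its
#' approximately linear volumetric increase during infancy. `G` is the total
#' fractional growth over 0--810 days. Sex offsets grow linearly from zero at
#' birth (males larger); the caudate and amygdala analogs carry no sex effect.
#' Behavioral effects are standardized coefficients of each structure's
#' bilateral log volume-to-ICV ratio on each Mullen score.
#'
#' @param flat if `TRUE`, all growth and sex/site effects are zeroed (volumes
#'   constant at birth values) — the null cohort used for calibration studies.
#' @param behavior_effects optional 6 x 6 matrix (structures x scores)
#'   overriding the planted standardized behavioral coefficients.
#' @return object of class `growth_truth`.
#' @export
default_growth_truth <- function(flat = FALSE, behavior_effects = NULL) {
  st <- expand.grid(structure = SG_STRUCTURES, hemi = SG_HEMIS,
                    stringsAsFactors = FALSE)
  base_a <- c(thalamus = 3400, caudate = 1600, putamen = 1900,
              pallidum = 520, hippocampus = 1400, amygdala = 550)
  growth_L <- c(thalamus = 0.45, caudate = 1.07, putamen = 1.16,
                pallidum = 0.95, hippocampus = 0.64, amygdala = 0.53)
  growth_R <- c(thalamus = 0.39, caudate = 1.07, putamen = 1.11,
                pallidum = 1.06, hippocampus = 0.71, amygdala = 0.52)
  tscale <- c(thalamus = 60, caudate = 150, putamen = 140,
              pallidum = 60, hippocampus = 200, amygdala = NA)
  sexd <- c(thalamus = 0.05, caudate = 0, putamen = 0.05,
            pallidum = 0.05, hippocampus = 0.05, amygdala = 0)
  st$family <- ifelse(st$structure == "amygdala", "linear", "logsat")
  st$a <- base_a[st$structure] * ifelse(st$hemi == "R", 0.97, 1)
  st$G <- ifelse(st$hemi == "L", growth_L[st$structure], growth_R[st$structure])
  st$c <- tscale[st$structure]
  st$sex_delta <- sexd[st$structure]
  st$site_offset <- 0.01   # site 2 minus site 1, fraction of birth volume
  icv <- list(a = 450000, G = 1.4, c = 150)
  st$icv_beta <- 0.5 * st$a / icv$a
  if (flat) {
    st$G <- 0; st$sex_delta <- 0; st$site_offset <- 0; st$icv_beta <- 0
    icv$G <- 0
  }
  if (is.null(behavior_effects)) {
    behavior_effects <- matrix(0, 6, 6, dimnames = list(SG_STRUCTURES, SG_SCORES))
    behavior_effects["thalamus", "RL"] <- 4
    behavior_effects["thalamus", "EL"] <- 3
    behavior_effects["caudate", "FM"] <- 2
    behavior_effects["putamen", "FM"] <- 2
    behavior_effects["thalamus", "ELC"] <- 2
  } else {
    behavior_effects <- as.matrix(behavior_effects)
    if (!all(dim(behavior_effects) == c(6, 6)))
      stop("'behavior_effects' must be a 6 x 6 structures-by-scores matrix")
    dimnames(behavior_effects) <- list(SG_STRUCTURES, SG_SCORES)
  }
  structure(list(structures = st, icv = icv, behavior = behavior_effects),
            class = "growth_truth")
}

# population truth curve (no site/sex/ICV/subject terms)
sg_truth_base <- function(row, t) {
  if (row$family == "linear") {
    row$a * (1 + row$G * t / 810)
  } else {
    row$a * (1 + row$G * log(1 + t / row$c) / log(1 + 810 / row$c))
  }
}

sg_truth_base_deriv <- function(row, t) {
  if (row$family == "linear") {
    rep(row$a * row$G / 810, length(t))
  } else {
    row$a * row$G / log(1 + 810 / row$c) / (row$c + t)
  }
}

sg_truth_row <- function(truth, response) {
  st <- truth$structures
  key <- paste(st$structure, st$hemi, sep = "_")
  i <- match(response, key)
  if (is.na(i)) stop(sprintf("unknown structure '%s'", response))
  st[i, , drop = FALSE]
}

#' Evaluate the ground-truth volume for given covariates
#'
#' The noiseless generating value: base curve plus site offset, sex offset
#' (linear-in-age male excess) and the ICV deviation term.
#'
#' @param truth a `growth_truth`.
#' @param response structure-hemisphere name, e.g. `"thalamus_L"`.
#' @param t age(s) in days.
#' @param sex `"female"` or `"male"`.
#' @param site site index (1 = reference) or site name position.
#' @param icv_dev deviation of the subject's ICV from the population ICV curve
#'   at age `t` (mm^3).
#' @return numeric vector of volumes (mm^3).
#' @export
truth_volume <- function(truth, response, t, sex = "female", site = 1L,
                         icv_dev = 0) {
  row <- sg_truth_row(truth, response)
  base <- sg_truth_base(row, t)
  base +
    row$site_offset * row$a * (as.integer(site) - 1L) +
    row$sex_delta * row$a * (t / 810) * (sex == "male") +
    row$icv_beta * icv_dev
}

#' Ground-truth population ICV curve
#' @param truth a `growth_truth`.
#' @param t age(s) in days.
#' @return ICV in mm^3.
#' @export
truth_icv <- function(truth, t) {
  ic <- truth$icv
  ic$a * (1 + ic$G * log(1 + t / ic$c) / log(1 + 810 / ic$c))
}

# run expr with a private RNG stream, restoring the caller's stream after
sg_with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic longitudinal cohort with known ground truth
#'
#' Draws subjects (sex, site, number of scans), per-subject scan ages without
#' replacement (a mixture putting ~60% of visits in the 3--15 month window,
#' emulating the denser mid-infancy sampling of longitudinal infant studies),
#' subject random intercepts and per-scan ICV, then builds per-structure
#' volumes as truth curve + site offset + sex offset + ICV term + subject
#' intercept + Gaussian noise.
#'
#' @param config a [cohort_config()].
#' @param truth a `growth_truth`; defaults to [default_growth_truth()].
#' @return list with `records` (data.frame, one row per scan) and `truth`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            truth = default_growth_truth()) {
  stopifnot(inherits(config, "cohort_config"), inherits(truth, "growth_truth"))
  sg_with_seed(config$seed, {
    n <- config$n_subjects
    ids <- sprintf("S%04d", seq_len(n))
    sex <- sample(names(config$sex_probabilities), n, replace = TRUE,
                  prob = config$sex_probabilities)
    site <- sample(names(config$site_probabilities), n, replace = TRUE,
                   prob = config$site_probabilities)
    nsc <- as.integer(sample(names(config$scans_per_subject), n, replace = TRUE,
                             prob = config$scans_per_subject))
    lo <- config$age_range[1]; hi <- config$age_range[2]
    mid_lo <- max(lo, 90); mid_hi <- min(hi, 450)
    early_hi <- min(hi, 90)
    draw_ages <- function(k) {
      # visit-age mixture: dense 3-15 month window, an early-infancy
      # component (monthly year-1 visits start near birth), and a uniform
      # spread over the full span
      ages <- integer(0)
      while (length(ages) < k) {
        need <- k - length(ages)
        u <- runif(need)
        a <- ifelse(u < 0.5, floor(runif(need, mid_lo, mid_hi + 1)),
             ifelse(u < 0.65, floor(runif(need, lo, early_hi + 1)),
                    floor(runif(need, lo, hi + 1))))
        ages <- unique(c(ages, pmin(as.integer(a), hi)))
      }
      sort(ages[seq_len(k)])
    }
    ages <- lapply(nsc, draw_ages)
    kappa <- rnorm(n, 0, config$icv_subject_sd)
    st <- truth$structures
    keys <- paste(st$structure, st$hemi, sep = "_")
    alpha <- matrix(rnorm(n * nrow(st), 0,
                          rep(config$random_intercept_sd * st$a, each = n)),
                    n, nrow(st), dimnames = list(NULL, keys))
    income <- sample(1:5, n, replace = TRUE)
    edu <- sample(0:1, n, replace = TRUE)

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      t <- ages[[i]]
      m <- length(t)
      icv_pop <- truth_icv(truth, t)
      icv <- icv_pop * (1 + kappa[i]) +
        rnorm(m, 0, config$icv_noise_sd * truth$icv$a)
      vols <- matrix(NA_real_, m, nrow(st), dimnames = list(NULL, keys))
      for (j in seq_len(nrow(st))) {
        row <- st[j, , drop = FALSE]
        mu <- truth_volume(truth, keys[j], t, sex = sex[i],
                           site = match(site[i], names(config$site_probabilities)),
                           icv_dev = icv - icv_pop)
        vols[, j] <- mu + alpha[i, j] + rnorm(m, 0, config$noise_sd * row$a)
      }
      rows[[i]] <- data.frame(subject_id = ids[i], age_days = t,
                              sex = sex[i], site = site[i], icv = icv,
                              income = income[i], maternal_education = edu[i],
                              vols, stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, rows)
    rownames(records) <- NULL
    if (any(records[, keys] <= 0)) {
      stop("generated nonpositive volumes; reduce 'noise_sd' or 'random_intercept_sd'")
    }
    list(records = records, truth = truth)
  })
}

#' Fill Mullen early-learning scores on scan records
#'
#' Each of the six scores (t-score scale, mean 50, SD 10) is generated as
#' 50 + household-covariate effects + planted standardized effects times the
#' standardized bilateral log volume-to-ICV ratios + a subject intercept +
#' Gaussian noise. Planted coefficients are per-SD-of-predictor score points,
#' the scale on which association models report standardized coefficients.
#'
#' @param records scan records from [generate_cohort()].
#' @param truth the matching `growth_truth` (its `behavior` matrix is used).
#' @param seed integer seed.
#' @param noise_sd residual SD in score points (default 8).
#' @param intercept_sd subject-intercept SD in score points (default 4).
#' @return `records` with columns `mullen_GM`, ..., `mullen_ELC` appended.
#' @export
generate_mullen <- function(records, truth, seed = 1L, noise_sd = 8,
                            intercept_sd = 4) {
  stopifnot(inherits(truth, "growth_truth"))
  keys <- sg_volume_cols()
  miss <- !stats::complete.cases(records[, c(keys, "icv")])
  if (any(miss)) {
    warning(sprintf("%d record(s) with missing volumes skipped", sum(miss)))
  }
  sg_with_seed(seed, {
    ok <- which(!miss)
    z <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
    ratios <- sapply(SG_STRUCTURES, function(s) {
      v <- records[ok, paste0(s, "_L")] + records[ok, paste0(s, "_R")]
      z(log(v / records$icv[ok]))
    })
    zinc <- z(records$income[ok]); zedu <- z(records$maternal_education[ok])
    subj <- records$subject_id[ok]
    usub <- unique(subj)
    b0 <- setNames(rnorm(length(usub), 0, intercept_sd), usub)
    for (sc in SG_SCORES) {
      y <- 50 + 1.0 * zinc + 0.5 * zedu +
        as.vector(ratios %*% truth$behavior[, sc]) +
        b0[subj] + rnorm(length(ok), 0, noise_sd)
      col <- paste0("mullen_", sc)
      records[[col]] <- NA_real_
      records[[col]][ok] <- y
    }
    records
  })
}
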