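# shared fixtures and oracles, built in code at test time

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
quiet_messages <- function(expr) suppressMessages(expr)

# a fitted_curve-shaped frame from explicit values
make_curve <- function(age_days, estimate) {
  out <- data.frame(age_days = age_days, estimate = estimate,
                    lower = estimate, upper = estimate, stratum = "pooled")
  class(out) <- c("fitted_curve", "data.frame")
  out
}

# population truth curve matching predict_curve's reference profile
# (female/male pooled by observed frequency, site offsets frequency-weighted,
# ICV at its population curve so the ICV deviation term vanishes)
truth_pooled_curve <- function(truth, model, response, grid) {
  st <- truth$structures
  key <- paste(st$structure, st$hemi, sep = "_")
  row <- st[match(response, key), ]
  base <- if (row$family == "linear") {
    row$a * (1 + row$G * grid / 810)
  } else {
    row$a * (1 + row$G * log(1 + grid / row$c) / log(1 + 810 / row$c))
  }
  male_w <- model$design$male_frac
  site_w <- if (length(model$design$site_freq) > 1) model$design$site_freq[2] else 0
  base + male_w * row$sex_delta * row$a * (grid / 810) +
    site_w * row$site_offset * row$a
}

# independent Cox-de Boor recursion (order m B-spline, 0/0 = 0 convention)
coxdeboor <- function(t, knots, i, m) {
  if (m == 1) {
    hi <- knots[i + 1]
    if ((t >= knots[i] && t < hi) || (t == hi && hi == max(knots))) 1 else 0
  } else {
    d1 <- knots[i + m - 1] - knots[i]
    d2 <- knots[i + m] - knots[i + 1]
    a <- if (d1 > 0) (t - knots[i]) / d1 * coxdeboor(t, knots, i, m - 1) else 0
    b <- if (d2 > 0) (knots[i + m] - t) / d2 * coxdeboor(t, knots, i + 1, m - 1) else 0
    a + b
  }
}

# independent step-up BH implementation (sort, running minimum from the top)
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

tmpdir <- function() {
  d <- tempfile("growmap")
  dir.create(d)
  d
}

small_cohort <- function(seed, n = 60, ...) {
  generate_cohort(cohort_config(n_subjects = n, seed = seed, ...))
}
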