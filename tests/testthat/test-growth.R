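test_that("interval growth rates follow the defining arithmetic", {
  cv <- make_curve(c(0, 90), c(100, 120))
  expect_equal(interval_growth_rate(cv, 0, 3), 0.20)
  cv2 <- make_curve(c(0, 90), c(100, 100))
  expect_equal(interval_growth_rate(cv2, 0, 3), 0)
  expect_error(interval_growth_rate(cv, 3, 3), "t1 < t2")
  expect_error(interval_growth_rate(make_curve(c(0, 90), c(-1, 5)), 0, 3),
               "nonpositive")
  # exponential truth: rate over [t1, t2] is exp(r (t2 - t1)) - 1
  r <- 0.002
  tt <- seq(0, 810, by = 30)
  cve <- make_curve(tt, 100 * exp(r * tt))
  expect_equal(interval_growth_rate(cve, 6, 12), exp(r * 180) - 1,
               tolerance = 1e-12)
})

test_that("rates chain multiplicatively on a common fitted curve", {
  g <- small_cohort(51, n = 80)
  m <- quiet(fit_gamm(g$records, "hippocampus_R"))
  pc <- predict_curve(m, seq(0, 810, by = 10), "female")
  r03 <- interval_growth_rate(pc, 0, 3)
  r36 <- interval_growth_rate(pc, 3, 6)
  r06 <- interval_growth_rate(pc, 0, 6)
  expect_lt(abs((1 + r03) * (1 + r36) - 1 - r06), 1e-10)
})

test_that("bootstrap replicates are deterministic and order-invariant", {
  g <- small_cohort(52, n = 60)
  m <- quiet(fit_gamm(g$records, "thalamus_R"))
  b1 <- quiet(stratified_bootstrap(m, B = 12, seed = 4))
  b2 <- quiet(stratified_bootstrap(m, B = 12, seed = 4))
  expect_identical(b1$Theta, b2$Theta)
  grid <- seq(0, 810, by = 90)
  reps <- bootstrap_curves(b1, grid, "male")
  sd1 <- apply(reps, 1, sd)
  sd2 <- apply(reps[, sample(ncol(reps))], 1, sd)
  expect_equal(sd1, sd2)
  expect_warning(stratified_bootstrap(m, B = 10, seed = 1), "below 500")
})

test_that("bootstrap SD vanishes as the noise does", {
  g <- generate_cohort(cohort_config(n_subjects = 60, seed = 53,
                                     noise_sd = 1e-6,
                                     random_intercept_sd = 1e-6,
                                     icv_subject_sd = 1e-6, icv_noise_sd = 0))
  m <- quiet(fit_gamm(g$records, "caudate_R"))
  bt <- quiet(stratified_bootstrap(m, B = 60, seed = 2))
  gt <- growth_table(m, bt)
  rate_sd <- gt$boot_sd_diff / 1600   # relative to the structure scale
  expect_lt(max(rate_sd), 1e-4)
})

test_that("bootstrap SD scales roughly as 1/sqrt(n_subjects)", {
  sd_at <- function(n, seeds) {
    mean(sapply(seeds, function(s) {
      g <- small_cohort(s, n = n)
      m <- quiet(fit_gamm(g$records, "thalamus_L", with_sex = FALSE))
      bt <- quiet(stratified_bootstrap(m, B = 120, seed = s))
      sd(bootstrap_curves(bt, 360)[1, ])
    }))
  }
  s1 <- sd_at(60, 61:68)
  s2 <- sd_at(240, 71:78)
  slope <- log(s2 / s1) / log(240 / 60)
  expect_gt(slope, -0.65)
  expect_lt(slope, -0.35)
})

test_that("growth_significance applies the Bonferroni contract", {
  set.seed(54)
  point <- c(0, 1, 5, -3)
  reps <- matrix(rnorm(4 * 200, sd = 1.5), 4, 200)
  gs <- growth_significance(point, reps, m = 9)
  expect_equal(gs$z[1], 0)
  expect_equal(gs$p[1], 1)
  expect_true(all(gs$p_adj >= gs$p))
  expect_true(all(gs$p_adj <= 1))
  expect_true(all(gs$significant == (gs$p_adj < 0.05)))
  # flagged set is a subset of the unadjusted flag set
  expect_true(all(which(gs$p_adj < 0.05) %in% which(gs$p < 0.05)))
  expect_warning(growth_significance(c(1, 0), matrix(0, 2, 5)), "zero bootstrap SD")
})

test_that("growth tables carry one row per interval and sex", {
  g <- small_cohort(55, n = 80)
  m <- quiet(fit_gamm(g$records, "putamen_L"))
  bt <- quiet(stratified_bootstrap(m, B = 80, seed = 5))
  gt <- growth_table(m, bt, m = 54)
  expect_equal(nrow(gt), 2 * nrow(growth_intervals()))
  expect_setequal(unique(gt$sex), c("male", "female"))
  expect_true(all(gt$p_adj >= gt$p))
  # strong true growth in the first interval is detected
  expect_true(all(gt$significant[gt$interval == "0M-24M"]))
})

test_that("sex difference test reproduces the curve algebra", {
  g <- small_cohort(56, n = 80)
  m <- quiet(fit_gamm(g$records, "pallidum_R"))
  bt <- quiet(stratified_bootstrap(m, B = 80, seed = 6))
  grid <- seq(90, 810, by = 180)
  st <- sex_effect_test(m, bt, grid)
  expect_equal(st$difference,
               predict_curve(m, grid, "male")$estimate -
                 predict_curve(m, grid, "female")$estimate,
               tolerance = 1e-12)
  expect_error(sex_effect_test(m, NULL, grid), "required")
  m0 <- quiet(fit_gamm(g$records, "pallidum_R", with_sex = FALSE))
  expect_error(sex_effect_test(m0, bt, grid), "without a sex term")
})

test_that("asymmetry index is antisymmetric and exact on known values", {
  l <- make_curve(c(0, 100), c(110, 110))
  r <- make_curve(c(0, 100), c(90, 90))
  expect_equal(asymmetry_index(l, r)$ai, c(0.2, 0.2))
  expect_equal(asymmetry_index(r, l)$ai, -asymmetry_index(l, r)$ai)
  expect_equal(asymmetry_index(l, l)$ai, c(0, 0))
  expect_error(asymmetry_index(l, make_curve(c(0, 50), c(90, 90))),
               "share one age grid")
  expect_error(asymmetry_index(make_curve(0, -2), make_curve(0, 1)),
               "positive")
})
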