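test_that("log volume ratio follows its defining identities", {
  expect_equal(log_volume_ratio(5, 5), 0)
  expect_equal(log_volume_ratio(exp(-1), 1), -1)
  expect_equal(log_volume_ratio(2, 1) - log_volume_ratio(1, 1), log(2))
  expect_error(log_volume_ratio(-1, 5), "positive")
  expect_error(log_volume_ratio(1, 0), "positive")
})

test_that("BH q-values reproduce an independent step-up implementation", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.37), 0.37)
  expect_equal(fdr_adjust(rep(1, 6)), rep(1, 6))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(91)
  for (i in 1:1000) {
    p <- runif(sample(1:20, 1))
    expect_equal(fdr_adjust(p), bh_stepup(p), tolerance = 1e-12)
  }
  # grouped adjustment is independent across groups
  p <- c(0.01, 0.04, 0.01, 0.04)
  g <- c("a", "a", "b", "b")
  expect_equal(fdr_adjust(p, g), c(fdr_adjust(p[1:2]), fdr_adjust(p[3:4])))
})

test_that("no-repeats singular fits fall back to OLS with d.f. = n - p", {
  g <- small_cohort(92, n = 120)
  r <- g$records[!duplicated(g$records$subject_id), ]   # one scan each
  r <- generate_mullen(r, g$truth, seed = 1, intercept_sd = 0)
  expect_warning(a <- fit_association_lmm(r, "FM", "caudate"),
                 "singular")
  d <- growmap:::sg_assoc_frame(r, "FM", "caudate")
  ols <- summary(lm(y ~ age + sex + site + income + edu + icv + ratio_caudate,
                    data = d))$coefficients["ratio_caudate", ]
  expect_equal(a$t, ols[["t value"]], tolerance = 1e-6)
  expect_equal(a$beta, ols[["Estimate"]], tolerance = 1e-6)
  expect_equal(a$df, nrow(d) - 8)
  expect_true(a$singular)
})

test_that("Satterthwaite d.f. are positive and bounded by n - p", {
  g <- small_cohort(93, n = 80)
  r <- generate_mullen(g$records, g$truth, seed = 2)
  a <- quiet(fit_association_lmm(r, "RL", "thalamus"))
  expect_gt(a$df, 0)
  expect_lte(a$df, nrow(r) - 8 + 1e-9)
  expect_gt(a$p, 0)
})

test_that("standardized coefficients are invariant to predictor units", {
  g <- small_cohort(94, n = 100)
  r <- generate_mullen(g$records, g$truth, seed = 3)
  a1 <- quiet(fit_association_lmm(r, "RL", "thalamus"))
  r2 <- r
  r2$thalamus_L <- r2$thalamus_L * 1000   # mm^3 -> different unit
  r2$thalamus_R <- r2$thalamus_R * 1000
  a2 <- quiet(fit_association_lmm(r2, "RL", "thalamus"))
  expect_equal(a1$beta, a2$beta, tolerance = 1e-6)
  expect_equal(a1$p, a2$p, tolerance = 1e-6)
})

test_that("the association table groups FDR within scores by default", {
  g <- small_cohort(95, n = 250)
  r <- generate_mullen(g$records, g$truth, seed = 4, noise_sd = 4)
  at <- quiet(association_table(r, scores = c("RL", "GM"),
                                structures = c("thalamus", "pallidum",
                                               "amygdala")))
  expect_equal(nrow(at), 6)
  for (sc in c("RL", "GM")) {
    i <- at$score == sc
    expect_equal(at$q[i], fdr_adjust(at$p[i]))
  }
  expect_true(all(at$q >= at$p - 1e-12))
  # the planted thalamus-RL effect is the clearest signal
  expect_true(at$significant[at$score == "RL" & at$structure == "thalamus"])
})

test_that("nested-model F comparison behaves at its edges", {
  g <- small_cohort(96, n = 120)
  r <- generate_mullen(g$records, g$truth, seed = 5, noise_sd = 4)
  cm0 <- compare_models(r, "FM", character(0))
  expect_equal(cm0$F, 0)
  expect_equal(cm0$p_F, 1)
  cm <- quiet(compare_models(r, "FM", c("caudate", "putamen")))
  expect_lt(cm$p_F, 0.05)
  expect_gt(cm$F, 0)
  expect_equal(cm$df1, 2)
})

test_that("a pure-noise added predictor yields uniform F-test p-values", {
  g <- small_cohort(97, n = 60)
  tr0 <- default_growth_truth(behavior_effects = matrix(0, 6, 6))
  ps <- vapply(1:30, function(i) {
    r <- generate_mullen(g$records, tr0, seed = 100 + i)
    quiet(compare_models(r, "VR", "hippocampus"))$p_F
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("vertex association recovers a geometry-linked score", {
  g <- small_cohort(98, n = 100)
  gm <- generate_meshes(g$records, n_vertices = 42, seed = 99,
                        noise_sd = 0.04)
  vf <- quiet(fit_vertex_trajectories(gm$series, g$records))
  tr <- gm$mesh_truth
  r <- generate_mullen(g$records, g$truth, seed = 6)
  # plant a score on the patch-specific geometry: the patch mean area with
  # the global size and growth components regressed out, so only patch
  # vertices carry the signal
  patch_area <- rowMeans(vf$areas[, tr$high, drop = FALSE])
  patch_local <- resid(lm(patch_area ~ rowMeans(vf$areas) + r$age_days + r$icv))
  z <- patch_local / sd(patch_local)
  set.seed(7)
  r$mullen_GM <- 50 + 3 * z + rnorm(nrow(r), 0, 1)
  va <- quiet(vertex_association(r, vf, "GM"))
  sig <- which(va$significant)
  expect_gt(length(sig), 0)
  # mask confined to the patch plus its immediate neighborhood
  halo <- unique(as.vector(vf$faces[rowSums(matrix(vf$faces %in% tr$high,
                                                   ncol = 3)) > 0, ]))
  expect_true(all(sig %in% halo))
  expect_gt(dice_overlap(sig, tr$high), 0.6)
  # null: a score independent of geometry flags at most a small fraction
  r$mullen_VR <- rnorm(nrow(r), 50, 10)
  va0 <- quiet(vertex_association(r, vf, "VR"))
  expect_lte(mean(va0$significant, na.rm = TRUE), 0.05)
})
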