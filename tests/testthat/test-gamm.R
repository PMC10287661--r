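test_that("zero-noise data from a realizable spline are recovered to 1e-6", {
  # truth is itself a K-dimensional spline, single site, no ICV, no sex,
  # no subject intercepts: the fit must interpolate
  set.seed(1)
  n_sub <- 40
  ages <- sort(sample(0:810, 120, replace = FALSE))
  b <- build_spline_basis(ages, K = 8, range = c(0, 810))
  coefs <- c(3, 3.2, 3.8, 4.4, 4.6, 4.9, 5.0, 5.1) * 1000
  df <- data.frame(subject_id = rep(sprintf("S%02d", 1:n_sub), length.out = 120),
                   age_days = ages, sex = "female", site = "A")
  df$y <- as.vector(eval_basis(b, ages) %*% coefs)
  m <- quiet(fit_gamm(df, "y", with_sex = FALSE, include_icv = FALSE, K = 8))
  grid <- seq(0, 810, by = 5)
  truth <- as.vector(eval_basis(b, grid) %*% coefs)
  est <- predict_curve(m, grid)$estimate
  expect_lt(max(abs(est - truth)) / max(abs(truth)), 1e-6)
})

test_that("the smooth degenerates to the straight-line fit as lambda grows", {
  set.seed(2)
  n <- 150
  df <- data.frame(subject_id = sprintf("S%03d", 1:n),
                   age_days = sort(sample(0:810, n)),
                   sex = "female", site = "A")
  df$y <- 3000 + 2 * df$age_days + rnorm(n, 0, 50)
  m <- quiet(fit_gamm(df, "y", with_sex = FALSE, include_icv = FALSE,
                      fixed = list(lambda = 1e14, gamma_subject = 1e-10)))
  ols <- lm(y ~ age_days, data = df)
  grid <- seq(0, 810, by = 30)
  expect_equal(predict_curve(m, grid)$estimate,
               unname(predict(ols, data.frame(age_days = grid))),
               tolerance = 1e-6)
})

test_that("engine likelihood matches a dense-matrix implementation", {
  # independent oracle: build V = sigma^2 (I + g_a ZZ' + sum g_j B_j B_j')
  # explicitly and profile beta and sigma^2 by brute force
  g <- small_cohort(5, n = 50)
  r <- g$records
  m <- quiet(fit_gamm(r, "caudate_L", with_sex = TRUE))
  d <- m$design
  X <- d$X; Z <- d$Z; y <- m$y
  Msub <- model.matrix(~ 0 + d$subject)
  dense_nll <- function(gf, gs, ga, method = "ML") {
    V0 <- diag(d$n) + ga * tcrossprod(Msub) +
      tcrossprod(Z %*% diag(sqrt(ifelse(d$pen_group == 1, gf, gs))))
    ci <- chol(V0)
    Xi <- backsolve(ci, forwardsolve(t(ci), X))
    yi <- backsolve(ci, forwardsolve(t(ci), y))
    XVX <- crossprod(X, Xi); XVy <- crossprod(X, yi)
    beta <- solve(XVX, XVy)
    rss <- sum(y * yi) - sum(XVy * beta)
    n <- d$n; p <- ncol(X)
    ld <- 2 * sum(log(diag(ci)))
    if (method == "ML") {
      s2 <- rss / n
      0.5 * (n * log(2 * pi * s2) + n + ld)
    } else {
      s2 <- rss / (n - p)
      0.5 * ((n - p) * log(2 * pi * s2) + (n - p) + ld +
               determinant(XVX, logarithm = TRUE)$modulus)
    }
  }
  for (psi in list(c(0, 0, 0), c(2, -1, 1), c(-3, 2, -2))) {
    gam <- exp(psi)
    ours_ml <- growmap:::sg_profile(c(f = gam[1], sex = gam[2], subject = gam[3]),
                                    m$ss, method = "ML")$nll
    ours_reml <- growmap:::sg_profile(c(f = gam[1], sex = gam[2], subject = gam[3]),
                                      m$ss, method = "REML")$nll
    expect_equal(ours_ml, dense_nll(gam[1], gam[2], gam[3], "ML"),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(ours_reml, dense_nll(gam[1], gam[2], gam[3], "REML"),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("penalized normal equations are satisfied at the optimum", {
  g <- small_cohort(6, n = 50)
  m <- quiet(fit_gamm(g$records, "putamen_R"))
  expect_lt(m$neq_resid, 1e-8)
  # accepted optimum is no worse than any optimizer start
  expect_true(all(-m$logLik <= m$start_values + 1e-6))
})

test_that("record-level prediction reproduces fitted values", {
  g <- small_cohort(7, n = 40)
  m <- quiet(fit_gamm(g$records, "hippocampus_L"))
  expect_equal(predict(m, g$records), m$fitted, tolerance = 1e-10)
})

test_that("male and female curves differ exactly by the fitted sex terms", {
  g <- small_cohort(8, n = 60)
  m <- quiet(fit_gamm(g$records, "thalamus_L"))
  grid <- seq(0, 810, by = 90)
  diff <- predict_curve(m, grid, "male")$estimate -
    predict_curve(m, grid, "female")$estimate
  Rm <- growmap:::sg_pred_rows(m$design, grid, "male")
  Rf <- growmap:::sg_pred_rows(m$design, grid, "female")
  expect_equal(diff, as.vector((Rm - Rf) %*% m$theta_pop), tolerance = 1e-12)
  # the difference is exactly sex main effect + deviation smooth: it carries
  # no contribution from site, ICV or the shared age smooth columns
  shared <- !grepl("sex|d_null|d_rand",
                   c(colnames(m$design$X), rep("f_rand", m$design$q)))
  expect_true(all(abs(Rm - Rf)[, which(shared[seq_len(m$design$p)])] == 0))
})

test_that("derivatives are exact: constants, straight lines, finite differences", {
  set.seed(9)
  n <- 80
  df <- data.frame(subject_id = sprintf("S%03d", rep(1:40, each = 2)),
                   age_days = sample(0:810, n), sex = "female", site = "A")
  df$y <- rep(500, n)
  m0 <- quiet(fit_gamm(df, "y", with_sex = FALSE, include_icv = FALSE))
  grid <- seq(10, 800, by = 30)
  expect_lt(max(abs(derivative_curve(m0, grid)$estimate)), 1e-8 * 500)
  df$y <- 100 + 1.7 * df$age_days
  m1 <- quiet(fit_gamm(df, "y", with_sex = FALSE, include_icv = FALSE))
  expect_equal(derivative_curve(m1, grid)$estimate, rep(30 * 1.7, length(grid)),
               tolerance = 1e-6)
  # finite-difference oracle on a real fit
  g <- small_cohort(10, n = 60)
  m <- quiet(fit_gamm(g$records, "pallidum_L"))
  tt <- c(100.55, 301.2, 502.4, 688.9)
  h <- 0.1
  fd <- (predict_curve(m, tt + h, "male")$estimate -
           predict_curve(m, tt - h, "male")$estimate) / (2 * h) * 30
  an <- derivative_curve(m, tt, "male")$estimate
  expect_lt(max(abs(an - fd)) / max(abs(an)), 1e-4)
})

test_that("normalized curves are anchored at 1 and track known total growth", {
  g <- small_cohort(12, n = 150)
  m <- quiet(fit_gamm(g$records, "caudate_L"))
  grid <- seq(0, 810, by = 30)
  nc <- normalized_curve(m, grid)
  expect_equal(nc$estimate[1], 1, tolerance = 1e-12)
  expect_true(all(diff(predict_curve(m, grid)$estimate) > 0) ==
                all(nc$estimate[-1] >= 1))
  # caudate truth roughly doubles by 810 days (G = 1.07)
  expect_equal(nc$estimate[length(grid)], 2.07, tolerance = 0.12)
})

test_that("confidence bands are ordered and shrink with sample size", {
  g_small <- small_cohort(13, n = 50)
  g_big <- small_cohort(14, n = 200)
  grid <- seq(30, 780, by = 150)
  w <- sapply(list(g_small, g_big), function(g) {
    m <- quiet(fit_gamm(g$records, "thalamus_L"))
    pc <- predict_curve(m, grid)
    expect_true(all(pc$lower <= pc$estimate & pc$estimate <= pc$upper))
    mean(pc$upper - pc$lower)
  })
  expect_lt(w[2], w[1])
})

test_that("fit agrees with an independent penalized-GAMM implementation", {
  skip_if_not_installed("mgcv")
  g <- small_cohort(15, n = 120)
  r <- g$records
  m <- quiet(fit_gamm(r, "putamen_L", with_sex = FALSE))
  r$subject <- factor(r$subject_id)
  r$site_f <- factor(r$site)
  gm <- mgcv::gam(putamen_L ~ site_f + icv + s(age_days, bs = "ps", k = 10) +
                    s(subject, bs = "re"), data = r, method = "ML")
  noise_abs <- 0.025 * 1900
  expect_lt(sqrt(mean((m$fitted - fitted(gm))^2)), 0.5 * noise_abs)
  # variance components agree in order of magnitude
  expect_equal(log(m$sigma2), log(gm$sig2), tolerance = 0.5)
})

test_that("degenerate designs are handled as documented", {
  g <- small_cohort(16, n = 40)
  r <- g$records
  r$site <- "S1"
  expect_message(m <- suppressWarnings(fit_gamm(r, "thalamus_L")),
                 "site effect dropped")
  expect_error(predict_curve(m, 900), "beyond the fitted age span")
  w <- capture_warnings(quiet_messages(fit_gamm(g$records[1:12, ], "thalamus_L",
                                                with_sex = FALSE, K = 5)))
  expect_true(any(grepl("fewer than 20 scans", w)))
  r3 <- g$records
  r3$sex <- "female"
  expect_error(fit_gamm(r3, "thalamus_L", with_sex = TRUE), "both sexes")
})
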