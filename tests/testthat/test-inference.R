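test_that("Bonferroni thresholds divide the level by the comparison count", {
  expect_equal(bonferroni_threshold(0.05, 15), 0.05 / 15)
  expect_equal(signif(bonferroni_threshold(0.05, 15), 1), 0.003)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 10), 0.001)
  expect_error(bonferroni_threshold(0, 15), "alpha")
  expect_error(bonferroni_threshold(1, 15), "alpha")
  expect_error(bonferroni_threshold(0.05, 0), "m")
})

make_six_bands <- function(n = 400) {
  t <- seq(0, 1, length.out = n)
  base <- sin(2 * pi * 1.3 * t) + 0.1 * cos(2 * pi * 5 * t)
  list(beta_l = base, beta_h = 0.8 * base + 0.01 * sin(7 * t),
       gamma_l = cos(2 * pi * 2.1 * t), gamma_h = -base,
       Gamma_l = -0.9 * base + 0.02 * t, Gamma_h = 2 - base)
}

test_that("interval correlation grids obey the Pearson contracts", {
  tc <- make_six_bands()
  g <- interval_correlations(tc, boundaries = c(100, 200, 300), "ISP1")
  expect_equal(diag(g$r), rep(1, 6), ignore_attr = TRUE)
  expect_equal(g$r, t(g$r))
  expect_equal(g$m, 15)
  expect_equal(g$alpha_critical, 0.05 / 15)
  expect_equal(g$r["beta_l", "gamma_h"], -1)       # exact anti-correlation
  expect_equal(g$r["beta_l", "Gamma_h"], -1)       # affine shift is immaterial
  expect_true(all(g$p >= 0 & g$p <= 1))
  expect_false(any(diag(g$mask)))
  expect_equal(g$n, 100)
})

test_that("correlation grids are invariant to common affine rescaling", {
  tc <- make_six_bands()
  g1 <- interval_correlations(tc, c(100, 200, 300), "vowel")
  tc2 <- lapply(tc, function(x) 3.7 * x - 1.2)
  g2 <- interval_correlations(tc2, c(100, 200, 300), "vowel")
  expect_equal(g1$r, g2$r, tolerance = 1e-12)
  expect_equal(g1$p, g2$p, tolerance = 1e-9)
})

test_that("zero-variance bands make interval correlations error", {
  tc <- make_six_bands()
  tc$gamma_l <- rep(1, length(tc$beta_l))
  expect_error(interval_correlations(tc, c(100, 200, 300), "ISP1"),
               "zero variance")
})

test_that("CV-centred correlations use the stated window and recover signs", {
  n <- 600
  boundaries <- c(200, 300, 450)
  t <- seq_len(n) / n
  up <- t + 0.001 * sin(40 * t)
  down <- 1 - t + 0.001 * cos(40 * t)
  tc <- list(beta_l = down, beta_h = down * 0.9, gamma_l = up,
             gamma_h = up * 1.1, Gamma_l = up + 0.2, Gamma_h = up * 0.8)
  g <- cv_centered_correlations(tc, boundaries, width = 100)
  expect_equal(unname(g$window), c(300 - 50, 300 + 50))
  expect_lt(g$r["beta_l", "Gamma_l"], 0) # opposite monotone trends
  expect_gt(g$r["Gamma_l", "Gamma_h"], 0) # common rising trend
  expect_error(cv_centered_correlations(tc, c(10, 30, 60), width = 100),
               "outside")
  tc$beta_l <- rep(1, n)
  expect_error(cv_centered_correlations(tc, boundaries, width = 100),
               "zero variance")
})

test_that("local extrema are strict interior turning points per interval", {
  n <- 400
  b <- c(100, 200, 300)
  x <- numeric(n)
  x[1:100] <- -(1:100 - 50)^2            # one parabola bump in ISP1
  x[101:200] <- seq(0, 1, length.out = 100)  # monotone consonant
  x[201:300] <- sin(2 * pi * (1:100) / 100)  # one full sine period in vowel
  x[301:400] <- 0
  ex <- local_extrema(x, b)
  isp1 <- ex[ex$interval == "ISP1", ]
  expect_equal(nrow(isp1), 1)
  expect_equal(isp1$type, "max")
  expect_equal(isp1$index, 50)
  expect_equal(nrow(ex[ex$interval == "consonant", ]), 0)
  vow <- ex[ex$interval == "vowel", ]
  expect_setequal(vow$type, c("max", "min"))
  expect_equal(nrow(vow), 2)
  expect_equal(nrow(ex[ex$interval == "ISP2", ]), 0) # flat: no strict extrema
})

test_that("Gaussian wavelet maps behave like zero-mean matched filters", {
  n <- 800
  x0 <- rep(2.5, n)
  w <- gaussian_wavelet_map(x0, sigma = 1:20)
  expect_lt(max(abs(w$coef), na.rm = TRUE), 1e-9)

  sigma0 <- 8
  t0 <- 400
  x <- exp(-((seq_len(n) - t0)^2) / (2 * sigma0^2))
  w <- gaussian_wavelet_map(x, sigma = 1:20)
  peak <- which(w$coef == max(w$coef, na.rm = TRUE), arr.ind = TRUE)
  expect_lt(abs(peak[1, "col"] - t0), 3)
  # independent grid-search oracle: direct inner products of the zero-mean,
  # unit-energy templates with the bump, centred at t0
  direct <- vapply(w$sigma, function(s) {
    h <- ceiling(4 * s)
    g <- exp(-((-h):h)^2 / (2 * s^2))
    g <- g - mean(g)
    g <- g / sqrt(sum(g^2))
    sum(g * x[(t0 - h):(t0 + h)])
  }, 0)
  expect_equal(w$sigma[peak[1, "row"]], w$sigma[which.max(direct)])
  expect_equal(w$coef[, t0], direct, tolerance = 1e-10, ignore_attr = TRUE)

  wneg <- gaussian_wavelet_map(-x, sigma = 1:20)
  expect_equal(wneg$coef, -w$coef)
  expect_error(gaussian_wavelet_map(rnorm(50), sigma = 1:42), "support")
})

test_that("change points find exact steps and ignore constants", {
  x <- c(rep(0, 40), rep(1, 60))
  expect_equal(as.integer(detect_change_points(x)), 40L)
  expect_length(detect_change_points(rep(2, 100)), 0)
  two <- c(rep(0, 50), rep(3, 50), rep(-1, 40))
  expect_equal(as.integer(detect_change_points(two)), c(50L, 100L))
  # too short for two segments: no change points
  expect_length(detect_change_points(rnorm(15), min_seglen = 10), 0)
})

test_that("detected change points respect the minimum segment length", {
  set.seed(7)
  for (i in 1:10) {
    n <- sample(60:200, 1)
    x <- rnorm(n) + rep(rnorm(4, sd = 3), length.out = n, each = ceiling(n / 4))
    cps <- detect_change_points(x, min_seglen = 10)
    edges <- c(0, cps, n)
    expect_true(all(diff(edges) >= 10))
    expect_true(all(diff(cps) > 0))
  }
})

test_that("PELT matches the exhaustive dynamic-programming optimum", {
  set.seed(123)
  for (i in 1:25) {
    n <- sample(25:60, 1)
    k <- sample(0:2, 1)
    means <- rnorm(k + 1, sd = 2)
    x <- rnorm(n) + rep(means, length.out = n, each = ceiling(n / (k + 1)))
    got <- detect_change_points(x, min_seglen = 5)
    want <- dp_segment_oracle(x, min_seglen = 5)
    expect_equal(as.integer(got), as.integer(want$cps))
    expect_equal(attr(got, "cost"), want$cost, tolerance = 1e-9)
  }
})

test_that("ERD onset is the right edge of the maximal pre-onset interval", {
  x <- c(rep(5, 120), seq(5, 0, length.out = 200), rep(0, 80))
  cps <- detect_change_points(x, noise_sd = 0.15)
  est <- erd_onset(x, cps, onset_idx = 300)
  expect_lt(abs(est - 120), 25)
  expect_true(is.na(erd_onset(x, integer(0), onset_idx = 300)))
})

sim_interval_data <- function(means, n_sessions = 31, tau = 0.5, sd = 1) {
  k <- length(means)
  b <- rnorm(n_sessions, sd = tau)
  data.frame(
    session = rep(seq_len(n_sessions), each = k),
    interval = rep(paste0("I", seq_len(k)), times = n_sessions),
    power = rep(means, times = n_sessions) + rep(b, each = k) +
      rnorm(n_sessions * k, sd = sd)
  )
}

test_that("the interval LME detects a strong effect and recovers its means", {
  set.seed(202)
  truth <- c(0, 0, 1, 1, 0)
  d <- sim_interval_data(truth)
  fit <- interval_lme_lrt(d)
  expect_equal(fit$df, 4) # K - 1
  expect_lt(fit$p, 0.001)
  se_mean <- sqrt((0.5^2 + 1) / 31)
  expect_true(all(abs(fit$interval_means - truth) < 3 * se_mean))
  expect_false(fit$singular)
})

test_that("singular random-effect fits are flagged rather than dropped", {
  set.seed(9)
  d <- sim_interval_data(c(0, 2, 0), tau = 0) # no session heterogeneity
  fit <- interval_lme_lrt(d)
  expect_true(fit$singular)
  expect_equal(fit$df, 2)
  expect_lt(fit$p, 0.001)
  expect_error(interval_lme_lrt(data.frame(session = 1:4,
                                           interval = "I1", power = rnorm(4))),
               ">= 2 intervals")
})

test_that("Tukey tables cover all pairs with valid adjusted p-values", {
  set.seed(31)
  d <- sim_interval_data(c(0, 0.2, 1.5, 0.1))
  fit <- interval_lme_lrt(d)
  tk <- tukey_pairwise(fit, bonferroni_families = 6)
  expect_equal(nrow(tk), choose(4, 2))
  expect_true(all(tk$p_tukey >= 0 & tk$p_tukey <= 1))
  expect_true(all(tk$p_bonferroni >= 0 & tk$p_bonferroni <= 1))
  expect_equal(tk$p_bonferroni, pmin(1, tk$p_tukey * 6))
})

test_that("with two intervals the Tukey decision agrees with the LRT", {
  set.seed(55)
  strong <- sim_interval_data(c(0, 2))
  fit <- interval_lme_lrt(strong)
  tk <- tukey_pairwise(fit)
  expect_lt(fit$p, 0.05)
  expect_lt(tk$p_tukey, 0.05)
  null <- sim_interval_data(c(0.3, 0.3))
  fit0 <- interval_lme_lrt(null)
  tk0 <- tukey_pairwise(fit0)
  expect_gt(fit0$p, 0.05)
  expect_gt(tk0$p_tukey, 0.05)
})
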