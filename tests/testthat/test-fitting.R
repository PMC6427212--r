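test_that("m-infinity normalization rescales, interpolates, is idempotent", {
  pr <- release_profile(c(1, 2, 4, 6, 8), c(0.1, 0.2, 0.35, 0.5, 0.55),
                        sd = rep(0.01, 5))
  nrm <- normalize_to_minf(pr, t_ref = 6)
  expect_equal(nrm$release, pr$release / 0.5)
  expect_equal(nrm$sd, pr$sd / 0.5)
  expect_equal(nrm$release[4], 1)
  expect_identical(normalize_to_minf(nrm, 6)$release, nrm$release)

  # t_ref between sample points: divisor from linear interpolation
  pr2 <- release_profile(c(5, 7), c(0.4, 0.6))
  nrm2 <- normalize_to_minf(pr2, t_ref = 6) # divisor 0.5
  expect_equal(nrm2$release, c(0.8, 1.2))

  expect_error(normalize_to_minf(release_profile(c(1, 2), c(0, 0)), 2),
               "zero")
  expect_error(normalize_to_minf(pr2, 20), "outside")
})

test_that("window selection filters by time and release cap", {
  t <- c(0.5, 1, 2, 3, 4, 5, 6, 8, 12, 24)
  pr <- release_profile(t, pmin(0.9, higuchi(t, 0.3)))
  w <- select_window(pr, t_min = 2, t_max = 7)
  expect_equal(w$time_h, c(2, 3, 4, 5, 6))
  capd <- select_window(pr, cap = 0.6)
  expect_true(all(capd$release <= 0.6))
  expect_gt(nrow(pr), nrow(capd))
  # cap above the data is a no-op
  expect_equal(nrow(select_window(pr, cap = 2)), nrow(pr))
  expect_error(select_window(pr, t_min = 30), "empty window")

  # normalization commutes with windowing
  a <- select_window(normalize_to_minf(pr, 6), t_max = 6)
  b <- normalize_to_minf(select_window(pr, t_max = 6), 6)
  expect_equal(a$release, b$release)
})

test_that("weighted SS is the weighted sum of squared deviations", {
  expect_equal(weighted_ss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(weighted_ss(c(1, 2), c(0, 0)), 5)
  expect_equal(weighted_ss(c(1, 2), c(0, 0), c(2, 1)), 6)
  expect_error(weighted_ss(1:3, 1:2), "length")
})

test_that("closed-form weighted regression matches the normal equations", {
  x <- c(1, 2, 3, 4)
  lf <- fit_linear(x, 3 * x + 1)
  expect_equal(lf$slope, 3, tolerance = 1e-12)
  expect_equal(lf$intercept, 1, tolerance = 1e-12)
  expect_equal(lf$ss, 0, tolerance = 1e-20)
  expect_equal(as.numeric(lf$r2), 1)

  # constant y: slope 0, r2 degenerate -> 0 with flag
  lfc <- fit_linear(x, rep(2, 4))
  expect_equal(lfc$slope, 0)
  expect_equal(as.numeric(lfc$r2), 0)
  expect_true(attr(lfc$r2, "degenerate"))
  expect_error(fit_linear(rep(1, 4), 1:4), "degenerate x")

  # seeded noisy fixture against an independent oracle (lm with weights)
  withr::local_seed(42)
  xx <- runif(12, 0, 5)
  yy <- 1.5 + 0.8 * xx + rnorm(12, 0, 0.3)
  ww <- runif(12, 0.5, 2)
  lf2 <- fit_linear(xx, yy, ww)
  or <- lm(yy ~ xx, weights = ww)
  expect_equal(lf2$slope, unname(coef(or)[2]), tolerance = 1e-10)
  expect_equal(lf2$intercept, unname(coef(or)[1]), tolerance = 1e-10)
  expect_equal(lf2$se_slope, summary(or)$coefficients[2, 2], tolerance = 1e-10)
  expect_equal(lf2$ss, sum(ww * or$residuals^2), tolerance = 1e-10)
})

test_that("r-squared matches its definition and flags zero variance", {
  expect_equal(as.numeric(r_squared(c(1, 2, 3), c(1, 2, 3))), 1)
  obs <- c(1, 2, 3, 4)
  expect_equal(as.numeric(r_squared(obs, rep(mean(obs), 4))), 0)
  expect_equal(as.numeric(r_squared(c(1, 2, 3), c(1, 2, 4))), 0.5)
  expect_warning(rd <- r_squared(c(2, 2, 2), c(1, 2, 3)), "degenerate")
  expect_true(attr(rd, "degenerate"))
})

test_that("every model recovers its own noiseless parameters exactly", {
  for (m in kinetic_models()) {
    pr <- noiseless_profile(m, recovery_params[[m]])
    for (meth in c("nonlinear", "linearized")) {
      f <- fit_release(pr, m, method = meth)
      expect_equal(unname(f$params),
                   unname(unlist(recovery_params[[m]])[names(f$params)]),
                   tolerance = 1e-8, info = paste(m, meth))
      expect_lt(f$ss, 1e-16 * f$n)
    }
  }
})

test_that("noiseless recovery survives a generating lag under grid search", {
  pr <- noiseless_profile("higuchi", list(alpha = 0.35),
                          schedule = c(0.5, 1, 2, 3, 4, 5, 6, 8), t_lag = 1)
  f <- fit_release(pr, "higuchi", lag = "grid")
  expect_equal(f$lag_used, 1, tolerance = 1e-9)
  expect_equal(f$params[["alpha"]], 0.35, tolerance = 1e-6)
})

test_that("direct minimization is never worse than the back-mapped line", {
  withr::local_seed(7)
  for (m in c("higuchi", "power_law", "weibull", "noyes_whitney")) {
    pr <- simulate_release(m, recovery_params[[m]], schedule = sched8,
                           noise_sd = 0.02, plateau_after = Inf)
    fn <- fit_release(pr, m, method = "nonlinear")
    fl <- fit_release(pr, m, method = "linearized")
    # compare on the union of points the nonlinear fit uses
    ss_lin <- weighted_ss(fn$fitted$observed,
                          eval_model_public(m, fl$params, fn$fitted$time_h))
    expect_true(fn$ss <= ss_lin * (1 + 1e-8), info = m)
  }
})

test_that("parameter recovery is unbiased at realistic noise", {
  # 500 seeded replicates at sd 0.01 on the 8-point 0.5-6 h schedule:
  # per-parameter bias under 5% of truth
  n_rep <- 500
  for (m in kinetic_models()) {
    truth <- unlist(recovery_params[[m]])
    est <- matrix(NA_real_, n_rep, length(truth),
                  dimnames = list(NULL, names(truth)))
    for (i in seq_len(n_rep)) {
      pr <- simulate_release(m, recovery_params[[m]], schedule = sched8,
                             noise_sd = 0.01, n_reps = 3,
                             plateau_after = Inf, seed = 5000 + i)
      est[i, ] <- fit_release(pr, m)$params[names(truth)]
    }
    bias <- colMeans(est) - truth
    expect_true(all(abs(bias) < 0.05 * abs(truth)),
                info = paste(m, paste(round(bias, 4), collapse = ",")))
  }
})

test_that("percent-scaled data is rejected for fraction-valued models", {
  pr <- release_profile(c(1, 2, 3, 4), c(10, 20, 30, 40))
  expect_error(fit_release(pr, "higuchi"), "percent")
})

test_that("inverse-variance weighting uses the sd column", {
  pr <- simulate_release("higuchi", list(alpha = 0.3), noise_sd = 0.01,
                         seed = 11, plateau_after = Inf)
  f <- fit_release(pr, "higuchi", weights = "1/sd2")
  expect_equal(f$fitted$weight, 1 / pr$sd^2)
  pr_nosd <- release_profile(pr$time_h, pr$release)
  expect_error(fit_release(pr_nosd, "higuchi", weights = "1/sd2"), "sd")
})
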