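test_that("AIC and Schwarz criteria match hand computations", {
  expect_equal(aic_ss(10, 1, 2), 4)
  expect_equal(aic_ss(5, exp(2), 1), 12)
  # unit parameter penalty is exactly 2
  expect_equal(aic_ss(7, 0.3, 3) - aic_ss(7, 0.3, 2), 2)

  expect_equal(schwarz_ss(10, 1, 3), 6.907755279, tolerance = 1e-9)
  expect_equal(schwarz_ss(3, 1, 0), 0)
  expect_error(schwarz_ss(exp(1), 1, 1), "integer")

  # SC - AIC = p (ln N - 2): SC harsher iff N > e^2
  for (N in c(5, 7, 8, 20)) {
    d <- schwarz_ss(N, 2.5, 2) - aic_ss(N, 2.5, 2)
    expect_equal(d, 2 * (log(N) - 2))
    expect_equal(d > 0, N > exp(2))
  }

  # perfect fit: -Inf sentinel with flag
  a0 <- aic_ss(10, 0, 2)
  expect_identical(as.numeric(a0), -Inf)
  expect_true(attr(a0, "perfect_fit"))
})

test_that("Imbimbo criterion matches the worked value and its structure", {
  # t(8, two-sided 95%) = 2.306004; sqrt(4 * (1/8 - 1/10)) = sqrt(0.1)
  expect_equal(imbimbo(N = 10, SS = 4, p = 2, mean_fitted = 50),
               2.306004 * sqrt(0.1) / 50, tolerance = 1e-6)
  expect_equal(imbimbo(N = 10, SS = 0, p = 2, mean_fitted = 50), 0)
  # doubling the mean fitted value halves I_p
  expect_equal(imbimbo(N = 10, SS = 4, p = 2, mean_fitted = 100),
               imbimbo(N = 10, SS = 4, p = 2, mean_fitted = 50) / 2)
  expect_error(imbimbo(N = 10, SS = 4, p = 2, mean_fitted = 0), "positive")
  expect_error(imbimbo(N = 2, SS = 1, p = 2, mean_fitted = 1), "N > p")
  # depends on SS and the mean only, not on which point contributed what
  expect_equal(imbimbo(N = 6, SS = 1.3, p = 1, mean_fitted = 2),
               imbimbo(N = 6, SS = 1.3, p = 1, mean_fitted = 2))
})

test_that("nested F-test reproduces the arithmetic and p-value oracle", {
  # build two release_fit objects with controlled SS via noiseless data
  t <- c(0.5, 1, 2, 3, 4, 5, 5.5, 6, 7, 8, 10, 12)
  pr <- release_profile(t, higuchi(t, 0.25))
  fq <- fit_release(pr, "higuchi")
  fp <- fit_release(pr, "power_law")
  res <- suppressWarnings(f_nested(fq, fp))
  # noiseless data from the simple model: F numerically 0
  expect_lt(res$statistic, 1e-6)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 10)

  # arithmetic example: SS_q=10, SS_p=5, N=12, q=1, p=2 -> F=10, df=(1,10)
  fq2 <- fq; fq2$ss <- 10
  fp2 <- fp; fp2$ss <- 5
  res2 <- f_nested(fq2, fp2)
  expect_equal(res2$statistic, 10)
  # upper-tail p from the incomplete-beta representation of the F CDF
  expect_equal(res2$p_value, 0.01011955974, tolerance = 1e-6)

  # no improvement: F = 0, p = 1
  fp3 <- fp; fp3$ss <- fq2$ss
  res3 <- f_nested(fq2, fp3)
  expect_equal(res3$statistic, 0)
  expect_equal(res3$p_value, 1)

  # SS_q < SS_p violates the nesting expectation: floored and flagged
  fq4 <- fq; fq4$ss <- 1
  fp4 <- fp; fp4$ss <- 2
  expect_warning(res4 <- f_nested(fq4, fp4), "floored")
  expect_equal(res4$statistic, 0)
  expect_true(res4$floored)

  # unregistered pair rejected
  fz <- fit_release(pr, "zero_order")
  expect_error(f_nested(fz, fp), "not registered")
  # equal parameter counts: extra-sum-of-squares df is zero
  fpl <- fit_release(pr, "power_law")
  fwb <- fit_release(pr, "weibull")
  expect_error(f_nested(fpl, fwb), "same number of parameters")
})

test_that("registered exact nestings are true degenerations", {
  withr::local_seed(99)
  reg <- nested_pairs()
  exact <- reg[!reg$approximate, ]
  constrain <- list(
    "zero_order_origin.power_law" = function(par) c(alpha = par[["k"]], beta = 1),
    "higuchi.power_law" = function(par) c(alpha = par[["alpha"]], beta = 0.5),
    "noyes_whitney.weibull" = function(par) c(alpha = par[["k"]], beta = 1)
  )
  simple_eval <- list(
    zero_order_origin = function(par, t) zero_order(t, 0, par[["k"]]),
    higuchi = function(par, t) higuchi(t, par[["alpha"]]),
    noyes_whitney = function(par, t) noyes_whitney(t, par[["k"]])
  )
  complex_eval <- list(
    power_law = function(par, t) power_law(t, par[["alpha"]], par[["beta"]]),
    weibull = function(par, t) weibull_release(t, par[["alpha"]], par[["beta"]])
  )
  for (i in seq_len(nrow(exact))) {
    s <- exact$simple[i]; cx <- exact$complex[i]
    for (rep in 1:20) {
      par_s <- c(k = runif(1, 0.05, 1), alpha = runif(1, 0.05, 1))
      tt <- runif(1, 0, 10)
      par_c <- constrain[[paste(s, cx, sep = ".")]](par_s)
      expect_equal(complex_eval[[cx]](par_c, tt),
                   simple_eval[[s]](par_s, tt),
                   tolerance = 1e-12, info = paste(s, cx))
    }
  }
})

test_that("ranking is dominance-consistent and surfaces ties", {
  t <- c(0.5, 1, 2, 3, 4, 5, 5.5, 6, 7, 8)
  pr <- release_profile(t, higuchi(t, 0.25))
  f1 <- fit_release(pr, "higuchi")
  f2 <- fit_release(pr, "noyes_whitney")
  # same p: ordering under every criterion follows SS alone
  f1$ss <- 1; f2$ss <- exp(1)
  f1$fitted$fitted <- f1$fitted$observed # keep means comparable
  f2$fitted$fitted <- f2$fitted$observed
  rep12 <- rank_models(list(f1, f2))
  expect_equal(rep12$table$rank_aic, c(1L, 2L))
  expect_equal(rep12$table$rank_sc, c(1L, 2L))
  expect_equal(rep12$table$rank_imbimbo, c(1L, 2L))
  expect_equal(rep12$consensus, "higuchi")
  expect_false(rep12$disagreement)

  # identical SS and p: explicit tie
  f2$ss <- 1
  rep_tie <- rank_models(list(f1, f2))
  expect_true(rep_tie$tied)
  expect_equal(rep_tie$table$rank_aic, c(1L, 1L))

  # fits on different windows are incomparable
  f3 <- fit_release(select_window(pr, t_max = 5), "noyes_whitney")
  expect_error(rank_models(list(f1, f3)), "not comparable")
})

test_that("selection report accessors and writer emit the comparison table", {
  pan <- simulate_panel(seed = 21, noise_sd = 0.005)
  nrm <- normalize_to_minf(pan[[1]], 6)
  fits <- lapply(kinetic_models(), function(m) fit_release(nrm, m, t_max = 6))
  report <- suppressWarnings(rank_models(fits))
  expect_s3_class(tidy(report), "tbl_df")
  expect_true(setequal(tidy(report)$model, kinetic_models()))
  expect_true(all(c("consensus", "disagreement") %in% names(glance(report))))
  # ranking is a permutation
  expect_setequal(report$table$rank_aic, rank(report$table$aic, ties.method = "min"))

  dir <- withr::local_tempdir()
  tab <- write_selection_report(report, file.path(dir, "cmp"))
  expect_true(file.exists(file.path(dir, "cmp.csv")))
  expect_true(file.exists(file.path(dir, "cmp.json")))
  reread <- readr::read_csv(file.path(dir, "cmp.csv"), show_col_types = FALSE)
  expect_equal(names(reread),
               c("Model", "AIC", "SC", "Imbimbo", "F", "F_pvalue"))
  expect_equal(reread$AIC, report$table$aic)
})
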