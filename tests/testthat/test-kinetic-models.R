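test_that("closed-form release laws match hand-evaluated values", {
  # zero order
  expect_equal(zero_order(0, a = 0, k = 5), 0)
  expect_equal(zero_order(4, a = 2, k = 5), 22)
  expect_equal(zero_order(3, a = 0, k = 5, t_lag = 1), 10)
  expect_error(zero_order(-1, k = 5), "negative")

  # first order: half-life identity and exponential oracle
  expect_equal(noyes_whitney(1, k = log(2)), 0.5)
  expect_equal(noyes_whitney(0, k = 0.3), 0)
  expect_equal(noyes_whitney(2, k = 0.3), 0.4511883639, tolerance = 1e-9)

  # Weibull: zero case and exponential-series oracle (4^0.75 = 2.828427)
  expect_equal(weibull_release(0, alpha = 0.3, beta = 1.2), 0)
  expect_equal(weibull_release(4, alpha = 0.1, beta = 0.75), 0.2463616836,
               tolerance = 1e-9)

  # power law: arithmetic, unit-time identity, square-root identity
  expect_equal(power_law(4, alpha = 0.2, beta = 0.5), 0.4)
  for (b in c(0.3, 0.5, 1.1)) expect_equal(power_law(1, 0.27, b), 0.27)
  t <- c(0.25, 1, 2.25, 9)
  expect_equal(power_law(t, 0.2, 0.5), higuchi(t, 0.2))
})

test_that("lag convention shifts every model uniformly", {
  t <- c(0, 0.5, 1, 2, 4)
  for (m in kinetic_models()) {
    par <- unlist(recovery_params[[m]])
    shifted <- eval_model_public(m, par, t, t_lag = 1)
    base <- eval_model_public(m, par, pmax(t - 1, 0), t_lag = 0)
    expect_equal(shifted, base, info = m)
  }
})

test_that("fraction-valued models start at zero and are non-decreasing", {
  t <- seq(0, 24, by = 0.25)
  cases <- list(
    list(m = "noyes_whitney", par = c(k = 0.4)),
    list(m = "higuchi", par = c(alpha = 0.3)),
    list(m = "power_law", par = c(alpha = 0.25, beta = 0.7)),
    list(m = "weibull", par = c(alpha = 0.2, beta = 1.4))
  )
  for (lag in c(0, 1.5)) {
    for (cs in cases) {
      r <- eval_model_public(cs$m, cs$par, t, lag)
      expect_equal(r[t <= lag], rep(0, sum(t <= lag)), info = cs$m)
      expect_true(all(diff(r) >= 0), info = cs$m)
    }
  }
})

test_that("Weibull degenerates to the power law with a Taylor-bounded gap", {
  for (alpha in c(0.001, 0.005, 0.01)) {
    for (beta in c(0.5, 0.8, 1)) {
      t <- seq(0.1, 1, by = 0.1)
      x <- alpha * t^beta
      keep <- x <= 0.01
      gap <- abs(weibull_release(t, alpha, beta) - power_law(t, alpha, beta))
      expect_true(all(gap[keep] <= x[keep]^2 / 2))
    }
  }
  # the small-argument case quoted with the coarser alpha^2 bound
  expect_lt(abs(weibull_release(1, 0.01, 0.8) - power_law(1, 0.01, 0.8)),
            0.01^2)
})

test_that("linearize maps points to the model's straight-line coordinates", {
  pr <- release_profile(c(1, 2, 4), c(0.5, 0.7, 0.9))
  nw <- linearize(pr, "noyes_whitney")
  expect_equal(nw$x[1], 1)
  expect_equal(nw$y[1], 0.6931472, tolerance = 1e-6)

  # r = 1 is outside the Weibull transform domain and gets dropped
  pr2 <- release_profile(c(1, 2, 4), c(0.5, 0.8, 1.0))
  expect_message(wb <- linearize(pr2, "weibull", quiet = FALSE), "dropped")
  expect_equal(nrow(wb), 2)
  expect_equal(attr(wb, "dropped"), 1)

  # noiseless power-law data is exactly collinear after the transform
  t <- c(0.5, 1, 2, 4, 8)
  pr3 <- release_profile(t, power_law(t, 0.2, 0.7))
  pl <- linearize(pr3, "power_law")
  slopes <- diff(pl$y) / diff(pl$x)
  expect_equal(slopes, rep(0.7, length(slopes)), tolerance = 1e-12)
})

test_that("linearize-then-backmap reproduces noiseless data to 1e-12", {
  t <- c(0.5, 1, 2, 3, 4, 5, 6)
  gens <- list(
    power_law = list(par = c(alpha = 0.3, beta = 0.6),
                     back = function(lf) c(exp(lf$intercept), lf$slope),
                     eval = function(p, t) power_law(t, p[1], p[2])),
    weibull = list(par = c(alpha = 0.2, beta = 0.8),
                   back = function(lf) c(exp(lf$intercept), lf$slope),
                   eval = function(p, t) weibull_release(t, p[1], p[2])),
    noyes_whitney = list(par = c(k = 0.4),
                         back = function(lf) lf$slope,
                         eval = function(p, t) noyes_whitney(t, p[1]))
  )
  for (nm in names(gens)) {
    g <- gens[[nm]]
    r <- g$eval(g$par, t)
    lin <- linearize(release_profile(t, r), nm)
    lf <- fit_linear(lin$x, lin$y,
                     intercept = nm != "noyes_whitney")
    p_hat <- g$back(lf)
    expect_equal(g$eval(p_hat, t), r, tolerance = 1e-12, info = nm)
  }
})

test_that("transport-mechanism classification uses the printed thresholds", {
  expect_equal(as.character(classify_transport(0.5)), "fickian")
  expect_equal(as.character(classify_transport(0.75)), "fickian") # inclusive
  expect_equal(as.character(classify_transport(0.9)), "combined")
  expect_equal(as.character(classify_transport(1.3)), "complex")
  b1 <- classify_transport(1)
  expect_equal(as.character(b1), "complex")
  expect_true(attr(b1, "boundary")) # beta = 1 is a flagged boundary call
  expect_error(classify_transport(0), "beta > 0")
})
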