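# Weighted least-squares fitting of release models, in linearized and
# direct nonlinear form. The reported SS is always computed in the
# untransformed release space so that information criteria are comparable
# across models fitted through different transforms.

#' Weighted sum of squared deviations
#'
#' `SS = sum(w_i * (y_obs_i - y_calc_i)^2)`, the objective every fit
#' minimizes and the quantity the information criteria consume.
#'
#' @param observed,calculated Numeric vectors of equal length.
#' @param weights Non-negative weights, default 1 for every point.
#' @return The weighted sum of squares (scalar, `>= 0`).
#' @export
weighted_ss <- function(observed, calculated, weights = NULL) {
  if (length(observed) != length(calculated)) {
    abort("observed and calculated must have the same length")
  }
  if (is.null(weights)) weights <- rep(1, length(observed))
  if (length(weights) != length(observed)) {
    abort("weights must match the data length")
  }
  stopifnot(all(weights >= 0), any(weights > 0))
  sum(weights * (observed - calculated)^2)
}

#' Coefficient of determination
#'
#' `r^2 = 1 - SS_res / SS_tot` about the observed mean. Zero-variance
#' (degenerate) observations yield `r^2 = 0` with attribute
#' `degenerate = TRUE` and a warning, rather than an error, since windowed
#' sub-profiles can be near-flat.
#'
#' @param observed,calculated Numeric vectors (`>= 2` points).
#' @return `r^2` with a logical `"degenerate"` attribute.
#' @export
r_squared <- function(observed, calculated) {
  if (length(observed) < 2) abort("need at least 2 points for r^2")
  ss_res <- sum((observed - calculated)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    warn("zero total variance: r^2 reported as 0 (degenerate)")
    return(structure(0, degenerate = TRUE))
  }
  structure(1 - ss_res / ss_tot, degenerate = FALSE)
}

#' Weighted linear regression in closed form
#'
#' Ordinary weighted least squares by the normal equations, returning the
#' coefficient standard errors needed for slope-parallelism testing.
#'
#' @param x,y Numeric vectors (`>= 3` points); `x` must not be constant
#'   when an intercept is fitted.
#' @param weights Non-negative weights, default 1.
#' @param intercept Fit an intercept (`TRUE`) or a through-origin line.
#' @return A list of class `linear_fit` with elements `slope`, `intercept`,
#'   `se_slope`, `se_intercept`, `ss` (weighted residual SS), `sigma2`
#'   (residual variance), `r2`, `df`, `n`, `fitted`, `residuals`.
#' @export
fit_linear <- function(x, y, weights = NULL, intercept = TRUE) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) abort("need at least 3 points for a linear fit")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), any(weights > 0))
  if (intercept && diff(range(x)) == 0) {
    abort("degenerate x: all abscissae equal")
  }
  X <- if (intercept) cbind(`(Intercept)` = 1, x = x) else cbind(x = x)
  XtW <- t(X * weights)
  xtwx <- XtW %*% X
  beta <- drop(solve(xtwx, XtW %*% y))
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  ss <- sum(weights * resid^2)
  df <- n - ncol(X)
  sigma2 <- if (df > 0) ss / df else NA_real_
  covb <- if (df > 0) sigma2 * solve(xtwx) else xtwx * NA_real_
  wmean <- sum(weights * y) / sum(weights)
  ss_tot <- sum(weights * (y - wmean)^2)
  degenerate <- ss_tot == 0
  r2 <- if (degenerate) 0 else 1 - ss / ss_tot
  if (intercept) {
    out <- list(slope = beta[["x"]], intercept = beta[["(Intercept)"]],
                se_slope = sqrt(covb["x", "x"]),
                se_intercept = sqrt(covb["(Intercept)", "(Intercept)"]))
  } else {
    out <- list(slope = beta[["x"]], intercept = 0,
                se_slope = sqrt(covb["x", "x"]), se_intercept = NA_real_)
  }
  structure(
    c(out, list(ss = ss, sigma2 = sigma2, r2 = structure(r2, degenerate = degenerate),
                df = df, n = n, fitted = fitted, residuals = resid,
                has_intercept = intercept)),
    class = "linear_fit"
  )
}

#' @export
print.linear_fit <- function(x, ...) {
  cat("<linear_fit> slope = ", format(x$slope), " (SE ", format(x$se_slope),
      "), intercept = ", format(x$intercept),
      ", r2 = ", format(as.numeric(x$r2)), ", df = ", x$df, "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Linearized parameter estimates (also the start point of the nonlinear fit)

linearized_estimate <- function(model, t, r, weights, t_lag = 0) {
  te <- pmax(t - t_lag, 0)
  m <- get_model(model)
  p <- length(m$pars)
  est <- switch(model,
    zero_order = {
      lf <- fit_linear(te, r, weights)
      list(par = c(a = lf$intercept, k = max(lf$slope, 0)), keep = rep(TRUE, length(t)), lf = lf)
    },
    zero_order_origin = {
      lf <- fit_linear(te, r, weights, intercept = FALSE)
      list(par = c(k = max(lf$slope, 0)), keep = rep(TRUE, length(t)), lf = lf)
    },
    noyes_whitney = {
      keep <- r > 0 & r < 1
      check_transform_points(keep, p, model)
      lf <- fit_linear(te[keep], -log(1 - r[keep]), weights[keep], intercept = FALSE)
      list(par = c(k = max(lf$slope, 0)), keep = keep, lf = lf)
    },
    higuchi = {
      lf <- fit_linear(sqrt(te), r, weights, intercept = FALSE)
      list(par = c(alpha = max(lf$slope, 0)), keep = rep(TRUE, length(t)), lf = lf)
    },
    power_law = {
      keep <- r > 0 & te > 0
      check_transform_points(keep, p, model)
      lf <- fit_linear(log(te[keep]), log(r[keep]), weights[keep])
      list(par = c(alpha = exp(lf$intercept), beta = max(lf$slope, 1e-6)),
           keep = keep, lf = lf)
    },
    weibull = {
      keep <- r > 0 & r < 1 & te > 0
      check_transform_points(keep, p, model)
      lf <- fit_linear(log(te[keep]), log(-log(1 - r[keep])), weights[keep])
      list(par = c(alpha = exp(lf$intercept), beta = max(lf$slope, 1e-6)),
           keep = keep, lf = lf)
    },
    abort(paste0("model '", model, "' has no linearized estimator"))
  )
  est$dropped <- sum(!est$keep)
  est
}

check_transform_points <- function(keep, p, model) {
  if (sum(keep) < p + 2) {
    abort(paste0("insufficient points (", sum(keep),
                 ") inside the '", model, "' transform domain"))
  }
}

# ---------------------------------------------------------------------------

#' Fit a release model to a profile
#'
#' Fits one of the registered kinetic models by weighted least squares.
#' `method = "linearized"` regresses in the model's linear coordinates (see
#' [linearize()]) and back-maps the coefficients; `method = "nonlinear"`
#' (default) minimizes the weighted SS directly in the untransformed release
#' space by bounded Levenberg-Marquardt, started from the linearized
#' estimate; `method = "both"` does both and flags parameter disagreement
#' greater than 5%. In every case the reported `ss`, `r2` and fitted values
#' are computed in the untransformed space, so AIC/SC/Imbimbo values are
#' comparable across models.
#'
#' Points at `t = 0` are kept for the nonlinear fit but excluded from
#' log-transformed coordinates; transform-domain exclusions are counted in
#' `dropped`.
#'
#' @param profile A [release_profile()] (fractions, not percent).
#' @param model One of [kinetic_models()].
#' @param method `"nonlinear"`, `"linearized"`, or `"both"`.
#' @param t_min,t_max,cap Optional fitting window, applied via
#'   [select_window()].
#' @param lag `"none"` (default), `"fixed"` (use `t_lag`), or `"grid"`
#'   (scan `t_lag` in 0.1 h steps over the sampling range, minimizing SS;
#'   ties broken toward smaller lag).
#' @param t_lag Lag time in hours for `lag = "fixed"`.
#' @param weights `NULL` for unit weights, the string `"1/sd2"` for
#'   inverse-variance weights from the profile's `sd` column, or a numeric
#'   vector.
#' @param quiet Suppress messages about dropped points.
#' @return An object of class `release_fit`; see [tidy.release_fit()],
#'   [glance.release_fit()], [augment.release_fit()], and
#'   [autoplot.release_fit()].
#' @examples
#' pr <- release_profile(c(0.5, 1, 2, 3, 4, 5, 6), higuchi(c(0.5, 1, 2, 3, 4, 5, 6), 0.35))
#' fit_release(pr, "higuchi")
#' @export
fit_release <- function(profile, model,
                        method = c("nonlinear", "linearized", "both"),
                        t_min = -Inf, t_max = Inf, cap = NULL,
                        lag = c("none", "fixed", "grid"), t_lag = 0,
                        weights = NULL, quiet = TRUE) {
  method <- match.arg(method)
  lag <- match.arg(lag)
  m <- get_model(model)
  p <- length(m$pars)
  if (m$fraction_valued && max(profile$release) > 1.5) {
    abort("release values look like percent; fraction-valued models need fractions in [0, 1]")
  }
  win <- select_window(profile, t_min = t_min, t_max = t_max, cap = cap)
  if (nrow(win) < p + 2) {
    abort(paste0("insufficient points in window (", nrow(win),
                 ") for model '", model, "' with ", p, " parameter(s)"))
  }
  w <- resolve_weights(weights, win)

  if (lag == "none") t_lag <- 0
  if (lag == "grid") {
    cand <- seq(0, max(win$time_h), by = 0.1)
    cand <- cand[vapply(cand, function(l) sum(win$time_h > l) >= p + 2, logical(1))]
    fits <- lapply(cand, function(l) {
      tryCatch(fit_release_at(win, model, method, l, w, quiet = TRUE),
               error = function(e) NULL)
    })
    ok <- !vapply(fits, is.null, logical(1))
    if (!any(ok)) abort("lag grid search failed at every candidate lag")
    ss <- vapply(fits[ok], function(f) f$ss, numeric(1))
    best <- which(ok)[which.min(ss)] # which.min takes the first, i.e. smallest lag, on ties
    fit <- fits[[best]]
  } else {
    fit <- fit_release_at(win, model, method, t_lag, w, quiet = quiet)
  }
  fit$window_used <- attr(win, "window")
  fit$lag_mode <- lag
  fit$formulation <- attr(profile, "formulation")
  fit$normalized <- is_normalized(profile)
  fit
}

resolve_weights <- function(weights, win) {
  if (is.null(weights)) return(rep(1, nrow(win)))
  if (identical(weights, "1/sd2")) {
    if (!"sd" %in% names(win)) abort("weights = \"1/sd2\" needs an sd column")
    sd <- win$sd
    if (any(!is.finite(sd)) || any(sd <= 0)) {
      abort("weights = \"1/sd2\" needs finite positive sd at every point")
    }
    return(1 / sd^2)
  }
  stopifnot(is.numeric(weights), length(weights) == nrow(win))
  weights
}

fit_release_at <- function(win, model, method, t_lag, w, quiet = TRUE) {
  m <- get_model(model)
  p <- length(m$pars)
  t <- win$time_h
  r <- win$release

  est <- linearized_estimate(model, t, r, w, t_lag)
  if (!quiet && est$dropped > 0) {
    inform(paste0(est$dropped, " point(s) outside the '", model,
                  "' transform domain dropped from the linearized fit"))
  }

  lin_par <- est$par
  result_for <- function(par, keep, dropped, converged = TRUE, niter = 0L) {
    fitted <- eval_model(model, par, t[keep], t_lag)
    ss <- weighted_ss(r[keep], fitted, w[keep])
    n <- sum(keep)
    r2 <- suppressWarnings(r_squared(r[keep], fitted))
    structure(list(
      model = model, method = method,
      params = par, params_linearized = lin_par,
      ss = ss, n = n, p = p, df = n - p, r2 = as.numeric(r2),
      r2_degenerate = isTRUE(attr(r2, "degenerate")),
      fitted = tibble::tibble(time_h = t[keep], observed = r[keep],
                              fitted = fitted, weight = w[keep]),
      linear = est$lf, t_lag = t_lag, lag_used = t_lag,
      dropped = dropped, converged = converged, iterations = niter,
      disagreement = FALSE
    ), class = "release_fit")
  }

  if (method == "linearized") {
    return(result_for(lin_par, est$keep, est$dropped))
  }

  # direct nonlinear minimization of the untransformed weighted SS
  start <- pmax(lin_par, m$lower + 1e-8)
  start[!is.finite(start)] <- 0.1
  resid_fn <- function(par) {
    par <- setNames(par, m$pars)
    sqrt(w) * (r - eval_model(model, par, t, t_lag))
  }
  nls <- minpack.lm::nls.lm(
    par = start, lower = m$lower, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12, gtol = 0)
  )
  if (nls$info == 0 || nls$info == 9) {
    abort(paste0("nonlinear fit for '", model, "' did not converge (info = ",
                 nls$info, "); start = ",
                 paste(names(start), round(start, 4), sep = "=", collapse = ", "),
                 ", iterations = ", nls$niter))
  }
  par_nl <- setNames(nls$par, m$pars)
  out <- result_for(par_nl, rep(TRUE, length(t)), 0L,
                    converged = TRUE, niter = nls$niter)
  if (method == "both") {
    rel <- abs(par_nl - lin_par) / pmax(abs(par_nl), .Machine$double.eps)
    out$disagreement <- any(rel > 0.05)
    if (out$disagreement && !quiet) {
      inform(paste0("linearized and nonlinear '", model,
                    "' estimates disagree by more than 5%"))
    }
  }
  out
}

# ---------------------------------------------------------------------------
# broom-style accessors

#' @export
print.release_fit <- function(x, ...) {
  cat("<release_fit> model '", x$model, "' (", x$method, ")\n", sep = "")
  cat("  params: ", paste(names(x$params), signif(x$params, 6), sep = " = ",
                          collapse = ", "), "\n", sep = "")
  cat("  SS = ", format(x$ss), ", N = ", x$n, ", p = ", x$p,
      ", df = ", x$df, ", r2 = ", round(x$r2, 4), "\n", sep = "")
  if (x$t_lag > 0) cat("  t_lag = ", x$t_lag, " h\n", sep = "")
  if (x$dropped > 0) cat("  dropped points: ", x$dropped, "\n", sep = "")
  invisible(x)
}

#' Tidy a release fit
#'
#' @param x A `release_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, and (when a
#'   linearized co-estimate exists) `estimate_linearized`.
#' @method tidy release_fit
#' @export
tidy.release_fit <- function(x, ...) {
  out <- tibble::tibble(term = names(x$params), estimate = unname(x$params))
  if (!is.null(x$params_linearized) &&
      setequal(names(x$params_linearized), names(x$params))) {
    out$estimate_linearized <- unname(x$params_linearized[out$term])
  }
  out
}

#' One-row summary of a release fit
#'
#' @param x A `release_fit`.
#' @param ... Unused.
#' @return A tibble with `model`, `method`, `ss`, `n`, `p`, `df`, `r2`,
#'   `t_lag`, `dropped`, `converged`.
#' @method glance release_fit
#' @export
glance.release_fit <- function(x, ...) {
  tibble::tibble(model = x$model, method = x$method, ss = x$ss, n = x$n,
                 p = x$p, df = x$df, r2 = x$r2, t_lag = x$t_lag,
                 dropped = x$dropped, converged = x$converged)
}

#' Per-point fitted values and residuals
#'
#' @param x A `release_fit`.
#' @param ... Unused.
#' @return A tibble with `time_h`, `observed`, `fitted`, `resid`, `weight`.
#' @method augment release_fit
#' @export
augment.release_fit <- function(x, ...) {
  dplyr::mutate(x$fitted, resid = .data$observed - .data$fitted,
                .after = "fitted")
}

#' Plot a release fit
#'
#' Observed points with the fitted release curve evaluated on a fine grid.
#'
#' @param object A `release_fit`.
#' @param ... Unused.
#' @method autoplot release_fit
#' @export
autoplot.release_fit <- function(object, ...) {
  dat <- object$fitted
  grid <- seq(min(dat$time_h), max(dat$time_h), length.out = 200)
  curve <- tibble::tibble(
    time_h = grid,
    fitted = eval_model(object$model, object$params, grid, object$t_lag)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$fitted),
                       colour = "steelblue") +
    ggplot2::labs(x = "time (h)", y = "cumulative release",
                  title = paste0(object$model,
                                 " (SS = ", signif(object$ss, 3),
                                 ", r2 = ", round(object$r2, 3), ")"))
}
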