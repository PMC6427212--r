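# Closed-form release laws. Internal convention: cumulative release is a
# fraction in [0, 1]; percent is an I/O convention handled at the table edge.
# Lag time enters every law through the effective time max(t - t_lag, 0).

t_eff <- function(t, t_lag = 0) {
  stopifnot(t_lag >= 0)
  if (any(t < 0)) abort("negative times are not allowed")
  pmax(t - t_lag, 0)
}

#' Zero-order release
#'
#' Constant-rate release, `R(t) = a + k * max(t - t_lag, 0)`. The intercept
#' `a` is a free empirical parameter (burst or assay offset); no mechanistic
#' meaning is attached to it.
#'
#' @param t Time in hours (vector, `>= 0`).
#' @param a Intercept, same units as the release values.
#' @param k Release rate per hour (`>= 0`).
#' @param t_lag Lag time in hours (`>= 0`), applied as
#'   `t_eff = max(t - t_lag, 0)`.
#' @return Numeric vector of cumulative release.
#' @examples
#' zero_order(c(0, 2, 4), a = 2, k = 5)
#' @export
zero_order <- function(t, a = 0, k, t_lag = 0) {
  stopifnot(k >= 0)
  a + k * t_eff(t, t_lag)
}

#' First-order (Noyes-Whitney) release
#'
#' Boundary-layer dissolution kinetics, `r(t) = 1 - exp(-k * t_eff)`, the
#' solution of `-ln(1 - r) = k t`. Values lie in `[0, 1)`.
#'
#' @inheritParams zero_order
#' @param k First-order rate constant (1/h, `>= 0`).
#' @return Released fraction in `[0, 1)`.
#' @examples
#' noyes_whitney(1, k = log(2)) # half the payload after one half-life
#' @export
noyes_whitney <- function(t, k, t_lag = 0) {
  stopifnot(k >= 0)
  1 - exp(-k * t_eff(t, t_lag))
}

#' Weibull release model
#'
#' Empirical sigmoidal release, `r(t) = 1 - exp(-alpha * t_eff^beta)`.
#' The shape exponent `beta` carries the transport-mechanism classification
#' (see [classify_transport()]); for small `alpha * t^beta` the model
#' degenerates to the power law `alpha * t^beta`.
#'
#' @inheritParams zero_order
#' @param alpha Scale constant (`>= 0`), units 1/h^beta.
#' @param beta Shape exponent (`> 0`), dimensionless.
#' @return Released fraction in `[0, 1)`.
#' @examples
#' weibull_release(4, alpha = 0.1, beta = 0.75)
#' @export
weibull_release <- function(t, alpha, beta, t_lag = 0) {
  stopifnot(alpha >= 0, beta > 0)
  1 - exp(-alpha * t_eff(t, t_lag)^beta)
}

#' Power-law (Siepmann-Peppas) release
#'
#' `r(t) = alpha * t_eff^beta`, the generalization of the Higuchi law;
#' `beta = 0.5` reproduces a square-root law exactly.
#'
#' @inheritParams weibull_release
#' @return Released fraction (unbounded above; callers window the data).
#' @examples
#' power_law(4, alpha = 0.2, beta = 0.5)
#' @export
power_law <- function(t, alpha, beta, t_lag = 0) {
  stopifnot(alpha >= 0, beta > 0)
  alpha * t_eff(t, t_lag)^beta
}

#' Higuchi square-root release
#'
#' `r(t) = alpha * sqrt(t_eff)`: the power law with `beta` fixed at 0.5,
#' in the parameterization used for matrix diffusion under pseudo
#' steady-state. Valid for roughly the first 60% of release.
#'
#' @inheritParams weibull_release
#' @param alpha Square-root rate constant (1/sqrt(h), `>= 0`).
#' @examples
#' higuchi(4, alpha = 0.2)
#' @export
higuchi <- function(t, alpha, t_lag = 0) {
  stopifnot(alpha >= 0)
  alpha * sqrt(t_eff(t, t_lag))
}

# ---------------------------------------------------------------------------
# Model registry: one row per fittable model. Evaluators take a named numeric
# parameter vector plus t and t_lag so the fitting layer is model-agnostic.

model_registry <- function() {
  list(
    zero_order = list(
      pars  = c("a", "k"),
      lower = c(a = -Inf, k = 0),
      fn    = function(par, t, t_lag = 0) zero_order(t, par[["a"]], par[["k"]], t_lag),
      fraction_valued = FALSE
    ),
    zero_order_origin = list(
      pars  = "k",
      lower = c(k = 0),
      fn    = function(par, t, t_lag = 0) zero_order(t, 0, par[["k"]], t_lag),
      fraction_valued = FALSE
    ),
    noyes_whitney = list(
      pars  = "k",
      lower = c(k = 0),
      fn    = function(par, t, t_lag = 0) noyes_whitney(t, par[["k"]], t_lag),
      fraction_valued = TRUE
    ),
    higuchi = list(
      pars  = "alpha",
      lower = c(alpha = 0),
      fn    = function(par, t, t_lag = 0) higuchi(t, par[["alpha"]], t_lag),
      fraction_valued = TRUE
    ),
    power_law = list(
      pars  = c("alpha", "beta"),
      lower = c(alpha = 0, beta = 1e-6),
      fn    = function(par, t, t_lag = 0) power_law(t, par[["alpha"]], par[["beta"]], t_lag),
      fraction_valued = TRUE
    ),
    weibull = list(
      pars  = c("alpha", "beta"),
      lower = c(alpha = 0, beta = 1e-6),
      fn    = function(par, t, t_lag = 0) weibull_release(t, par[["alpha"]], par[["beta"]], t_lag),
      fraction_valued = TRUE
    )
  )
}

#' Names of the fittable release models
#'
#' @param fitting_set If `TRUE` (default) return the five models of the
#'   standard comparison panel; otherwise every registered model, including
#'   the through-origin zero-order variant used in the nesting registry.
#' @return Character vector of model names.
#' @export
kinetic_models <- function(fitting_set = TRUE) {
  nms <- names(model_registry())
  if (fitting_set) setdiff(nms, "zero_order_origin") else nms
}

get_model <- function(model) {
  reg <- model_registry()
  if (!model %in% names(reg)) {
    abort(paste0("unknown model '", model, "'; registered models: ",
                 paste(names(reg), collapse = ", ")))
  }
  reg[[model]]
}

eval_model <- function(model, par, t, t_lag = 0) {
  m <- get_model(model)
  missing <- setdiff(m$pars, names(par))
  if (length(missing)) {
    abort(paste0("model '", model, "' needs parameter(s): ",
                 paste(missing, collapse = ", ")))
  }
  m$fn(par, t, t_lag)
}

# ---------------------------------------------------------------------------
# Linearizing transforms

#' Linearize a release profile under a model's transform
#'
#' Maps `(t, r)` points to the coordinates in which the model is a straight
#' line: Noyes-Whitney `(t, -ln(1 - r))`, Weibull `(ln t, ln(-ln(1 - r)))`,
#' power law `(ln t, ln r)`, Higuchi `(sqrt(t), r)`, zero order `(t, r)`.
#' Points outside the transform domain (`r <= 0` or `r >= 1` for log
#' transforms, `t = 0` for `ln t`) are dropped; the count of dropped points
#' is attached as attribute `"dropped"` and reported via a message.
#'
#' @param profile A release profile (see [release_profile()]) or any data
#'   frame with columns `time_h` and `release`.
#' @param model Model name, one of [kinetic_models()].
#' @param quiet Suppress the dropped-point message.
#' @return A tibble with columns `time_h`, `x`, `y` and attribute `dropped`.
#' @export
linearize <- function(profile, model, quiet = FALSE) {
  stopifnot(is.data.frame(profile), all(c("time_h", "release") %in% names(profile)))
  t <- profile$time_h
  r <- profile$release
  keep <- rep(TRUE, length(t))
  trans <- switch(model,
    zero_order = ,
    zero_order_origin = list(x = t, y = r),
    noyes_whitney = {
      keep <- r > 0 & r < 1
      list(x = t, y = -log(1 - r))
    },
    weibull = {
      keep <- r > 0 & r < 1 & t > 0
      list(x = log(t), y = log(-log(1 - r)))
    },
    power_law = {
      keep <- r > 0 & t > 0
      list(x = log(t), y = log(r))
    },
    higuchi = list(x = sqrt(t), y = r),
    abort(paste0("no linearizing transform registered for model '", model, "'"))
  )
  dropped <- sum(!keep)
  if (dropped > 0 && !quiet) {
    inform(paste0(dropped, " point(s) outside the '", model,
                  "' transform domain dropped"))
  }
  out <- tibble::tibble(time_h = t[keep], x = trans$x[keep], y = trans$y[keep])
  attr(out, "dropped") <- dropped
  out
}

#' Classify the release-transport mechanism from the Weibull exponent
#'
#' Thresholds on the shape exponent: `beta <= 0.75` Fickian diffusion
#' (fractal or Euclidean), `0.75 < beta < 1` combined diffusion and
#' swelling-controlled transport, `beta >= 1` complex mechanism. The
#' `beta = 1` boundary is assigned to `"complex"` and flagged through the
#' `"boundary"` attribute, since only values strictly over 1 are
#' unambiguously complex.
#'
#' @param beta Weibull/power-law shape exponent(s), `> 0`.
#' @return Character vector of labels (`"fickian"`, `"combined"`,
#'   `"complex"`) with a logical `"boundary"` attribute marking `beta == 1`.
#' @examples
#' classify_transport(c(0.5, 0.75, 0.9, 1, 1.3))
#' @export
classify_transport <- function(beta) {
  stopifnot(all(beta > 0))
  lab <- ifelse(beta <= 0.75, "fickian", ifelse(beta < 1, "combined", "complex"))
  structure(lab, boundary = beta == 1)
}
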