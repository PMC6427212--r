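# Diffusion-theoretic laws: film model, Higuchi matrix law, and the
# error-function solution of Fick's second law for an infinite reservoir
# releasing into a semi-infinite medium.

#' Film-model rate constant
#'
#' First-order rate constant for transport across a stagnant boundary layer,
#' `k = A * D / delta`.
#'
#' @param A Interface area (length^2, `> 0`).
#' @param D Diffusion coefficient (length^2/h, `> 0`).
#' @param delta Stationary-layer thickness (length, `> 0`).
#' @return Rate constant.
#' @export
film_rate_constant <- function(A, D, delta) {
  stopifnot(A > 0, D > 0)
  if (any(delta <= 0)) abort("stationary-layer thickness delta must be > 0")
  A * D / delta
}

#' Higuchi amount released from a planar matrix
#'
#' `m(t) = sqrt(D * Cs * (2 * C0 - Cs) * t)` per unit area, for diffusion
#' out of a matrix with initial loading `C0` above the drug solubility `Cs`,
#' under pseudo steady-state and perfect sink. The induced square-root rate
#' constant is `alpha = sqrt(D * Cs * (2 * C0 - Cs))`.
#'
#' @param t Time in hours (`>= 0`).
#' @param D Diffusion coefficient.
#' @param Cs Drug solubility in the matrix.
#' @param C0 Initial drug concentration in the matrix; requires
#'   `2 * C0 - Cs > 0`.
#' @return Amount released per unit area.
#' @export
higuchi_amount <- function(t, D, Cs, C0) {
  stopifnot(D > 0, Cs >= 0, C0 >= 0)
  if (2 * C0 - Cs <= 0) abort("nonphysical concentrations: need 2*C0 - Cs > 0")
  if (any(t < 0)) abort("negative times are not allowed")
  sqrt(D * Cs * (2 * C0 - Cs)) * sqrt(t)
}

#' Concentration profile ahead of an infinite reservoir
#'
#' Solution of Fick's second law in a semi-infinite medium with the
#' interface held at concentration `cs`:
#' `c(y, t) = cs * (1 - erf(y / sqrt(4 D t)))`, with the standard error
#' function `erf(z) = (2/sqrt(pi)) * integral_0^z exp(-x^2) dx`. At `t = 0`
#' the profile is the sharp front `c = cs` at `y = 0` and `0` beyond.
#'
#' @param y Distance from the interface (`>= 0`).
#' @param t Time (`>= 0`).
#' @param D Diffusion coefficient (`> 0`).
#' @param cs Interface (reservoir) concentration (`>= 0`).
#' @return Concentration at `(y, t)`; vectorized over `y` and `t`.
#' @export
erf_profile <- function(y, t, D, cs) {
  stopifnot(D > 0, cs >= 0)
  if (any(y < 0)) abort("distance y must be >= 0")
  if (any(t < 0)) abort("negative times are not allowed")
  n <- max(length(y), length(t))
  y <- rep_len(y, n)
  t <- rep_len(t, n)
  out <- numeric(n)
  pos <- t > 0
  out[pos] <- cs * (1 - erf(y[pos] / sqrt(4 * D * t[pos])))
  out[!pos] <- ifelse(y[!pos] == 0, cs, 0)
  out
}

# standard error function via the Gaussian CDF
erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1

#' Reservoir square-root release law
#'
#' Amount released by time `t` from an infinite reservoir into a
#' semi-infinite medium, obtained by integrating the interface flux
#' `-D dc/dy` at `y = 0` of [erf_profile()]:
#' `m(t) = (2/sqrt(pi)) * A * cs * sqrt(D * t)`.
#'
#' @inheritParams erf_profile
#' @param A Interface area (`> 0`).
#' @return Cumulative amount released.
#' @export
reservoir_sqrt_amount <- function(t, D, cs, A) {
  stopifnot(D > 0, cs >= 0, A > 0)
  if (any(t < 0)) abort("negative times are not allowed")
  (2 / sqrt(pi)) * A * cs * sqrt(D * t)
}

#' Residual of the erf profile under Fick's second law
#'
#' Evaluates `dc/dt - D d2c/dy2` for [erf_profile()] by second-order central
#' finite differences on a rectangular grid strictly inside the domain
#' (`t > 0`), returning the maximum absolute residual over interior nodes.
#' For the analytic solution the residual converges to zero at second order
#' in the grid spacings; evaluating with a deliberately wrong `D` leaves a
#' residual bounded away from zero wherever the profile has curvature.
#'
#' @param D Diffusion coefficient used in the operator (may deliberately
#'   differ from `D_profile`).
#' @param cs Interface concentration.
#' @param y_grid,t_grid Strictly increasing grids with at least 3 points
#'   each; `t_grid` must be strictly positive.
#' @param D_profile Diffusion coefficient used to generate the profile
#'   (defaults to `D`).
#' @return Maximum absolute residual over the interior grid nodes.
#' @export
fick_residual <- function(D, cs, y_grid, t_grid, D_profile = D) {
  if (length(y_grid) < 3 || length(t_grid) < 3) {
    abort("degenerate grid: need at least 3 points per axis")
  }
  stopifnot(all(diff(y_grid) > 0), all(diff(t_grid) > 0))
  if (any(t_grid <= 0)) abort("t grid must be strictly positive")
  cmat <- outer(y_grid, t_grid, function(y, t) erf_profile(y, t, D_profile, cs))
  ny <- length(y_grid); nt <- length(t_grid)
  iy <- 2:(ny - 1); it <- 2:(nt - 1)
  dy <- diff(y_grid); dt <- diff(t_grid)
  if (stats::sd(dy) > 1e-12 * mean(dy) || stats::sd(dt) > 1e-12 * mean(dt)) {
    abort("fick_residual requires uniform grids")
  }
  hy <- mean(dy); ht <- mean(dt)
  c_t  <- (cmat[iy, it + 1] - cmat[iy, it - 1]) / (2 * ht)
  c_yy <- (cmat[iy + 1, it] - 2 * cmat[iy, it] + cmat[iy - 1, it]) / hy^2
  max(abs(c_t - D * c_yy))
}
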