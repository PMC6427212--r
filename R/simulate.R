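# Synthetic release data with the statistical structure the analysis
# assumes: a known generating model, additive Gaussian replicate noise on
# the fraction scale, optional lag, and a saturation plateau.

#' Simulate a cumulative-release profile
#'
#' Draws `n_reps` replicate release curves from a generating kinetic model
#' with additive Gaussian noise on the fraction scale (clamped at 0), then
#' applies a saturation plateau: beyond `plateau_after` hours the noiseless
#' mean is held at its value at `plateau_after`, emulating a medium that
#' saturates. The returned profile carries per-time mean and SD across
#' replicates, plus a ground-truth record sufficient to regenerate the
#' noiseless curve (attribute `"truth"`; the replicate matrix is attached
#' as attribute `"replicates"`).
#'
#' Defaults emulate a five-formulation dialysis release experiment: a
#' 10-point 0.5-24 h schedule, triplicates, noise SD 0.01 on the fraction
#' scale, saturation from 6 h.
#'
#' @param model Generating model name, one of [kinetic_models()].
#' @param params Named list/vector of generating parameters (see the model
#'   functions).
#' @param schedule Sampling times in hours, strictly increasing.
#' @param noise_sd Additive Gaussian SD per replicate (fraction scale).
#' @param n_reps Number of replicates.
#' @param t_lag Lag time in hours.
#' @param plateau_after Time after which the mean curve is clamped at its
#'   running maximum (`Inf` to disable).
#' @param formulation Label for the profile.
#' @param seed Optional integer seed; identical seeds give identical
#'   profiles, and the caller's RNG state is left untouched.
#' @return A [release_profile()] with attributes `truth` and `replicates`.
#' @examples
#' simulate_release("higuchi", list(alpha = 0.37), seed = 1)
#' @export
simulate_release <- function(model, params,
                             schedule = c(0.5, 1, 2, 3, 4, 5, 6, 8, 12, 24),
                             noise_sd = 0.01, n_reps = 3, t_lag = 0,
                             plateau_after = 6, formulation = NULL,
                             seed = NULL) {
  stopifnot(noise_sd >= 0, n_reps >= 1, all(diff(schedule) > 0))
  par <- unlist(params)
  mu <- eval_model(model, par, pmin(schedule, plateau_after), t_lag)
  reps <- with_local_seed(seed, {
    matrix(pmax(rep(mu, n_reps) + rnorm(length(mu) * n_reps, 0, noise_sd), 0),
           nrow = length(mu), ncol = n_reps)
  })
  pr <- release_profile(
    time_h = schedule,
    release = rowMeans(reps),
    sd = if (n_reps > 1) apply(reps, 1, stats::sd) else rep(NA_real_, length(mu)),
    n_reps = n_reps,
    formulation = formulation
  )
  attr(pr, "truth") <- list(model = model, params = par, t_lag = t_lag,
                            noise_sd = noise_sd, n_reps = n_reps,
                            schedule = schedule, plateau_after = plateau_after,
                            seed = seed)
  attr(pr, "replicates") <- reps
  pr
}

# run code under a seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Regenerate the noiseless curve from a simulated profile's ground truth
#'
#' @param profile A profile produced by [simulate_release()].
#' @param t Times at which to evaluate (default: the profile's schedule).
#' @return Noiseless model values including the saturation plateau.
#' @export
truth_curve <- function(profile, t = NULL) {
  tr <- attr(profile, "truth")
  if (is.null(tr)) abort("profile carries no ground-truth record")
  if (is.null(t)) t <- tr$schedule
  eval_model(tr$model, tr$params, pmin(t, tr$plateau_after), tr$t_lag)
}

#' Simulate a multi-formulation release panel
#'
#' Default panel mirrors the five-formulation experiment: four square-root
#' (Higuchi-type) generators with near-equal rate constants (alpha 0.3695
#' to 0.371 per sqrt-hour — within measurement noise of each other, so the
#' panel is statistically parallel, and ~90% of payload released by 6 h)
#' and one delayed sigmoidal generator (Weibull, alpha 0.15, beta 1.5,
#' 1 h lag) in position 2, the formulation that releases after a delay. Each
#' formulation consumes its own seed stream, `seed + index`, so adding a
#' formulation does not perturb earlier ones.
#'
#' @param n_formulations Number of formulations (`>= 2`); only used when
#'   `specs` is `NULL` and must then be 5 or fewer of the default specs are
#'   recycled from the square-root family.
#' @param specs Optional list of per-formulation specs, each a list with
#'   fields `model`, `params`, and optionally `t_lag`; overrides the
#'   default panel.
#' @param noise_sd,n_reps,schedule,plateau_after As in
#'   [simulate_release()].
#' @param seed Integer base seed.
#' @return A named list of release profiles.
#' @export
simulate_panel <- function(n_formulations = 5, specs = NULL,
                           noise_sd = 0.01, n_reps = 3,
                           schedule = c(0.5, 1, 2, 3, 4, 5, 6, 8, 12, 24),
                           plateau_after = 6, seed = NULL) {
  if (is.null(specs)) {
    stopifnot(n_formulations >= 2)
    sqrt_alphas <- c(0.3695, 0.3700, 0.3705, 0.3710)
    k <- 0
    specs <- purrr::map(seq_len(n_formulations), function(i) {
      if (i == 2) {
        list(model = "weibull", params = list(alpha = 0.15, beta = 1.5), t_lag = 1)
      } else {
        k <<- k + 1
        a <- sqrt_alphas[(k - 1) %% length(sqrt_alphas) + 1]
        list(model = "higuchi", params = list(alpha = a), t_lag = 0)
      }
    })
  }
  stopifnot(length(specs) >= 2)
  names(specs) <- names(specs) %||% paste0("F", seq_along(specs))
  purrr::imap(specs, function(sp, nm) {
    i <- match(nm, names(specs))
    simulate_release(sp$model, sp$params, schedule = schedule,
                     noise_sd = noise_sd, n_reps = n_reps,
                     t_lag = sp$t_lag %||% 0, plateau_after = plateau_after,
                     formulation = nm,
                     seed = if (is.null(seed)) NULL else seed + i)
  })
}

#' Simulate absorbance readings from concentrations
#'
#' Applies the UV calibration line and adds Gaussian reading noise:
#' `y = slope * x + intercept + N(0, noise_sd^2)`.
#'
#' @param concentrations Concentrations in µg/mL (`>= 0`).
#' @param noise_sd Gaussian SD of the absorbance reading.
#' @param seed Optional integer seed.
#' @param calibration Calibration line, as in
#'   [absorbance_from_concentration()].
#' @return Simulated absorbances.
#' @export
simulate_absorbances <- function(concentrations, noise_sd = 0.005,
                                 seed = NULL,
                                 calibration = default_calibration()) {
  stopifnot(all(concentrations >= 0), noise_sd >= 0)
  mu <- absorbance_from_concentration(concentrations, calibration)
  with_local_seed(seed, mu + rnorm(length(mu), 0, noise_sd))
}
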