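# Release profiles: a tibble of (time_h, release[, sd, n_reps]) carrying the
# formulation label and the m-infinity normalization state as attributes.

#' Construct a release profile
#'
#' A release profile is a tibble with columns `time_h` (hours, strictly
#' increasing), `release` (cumulative released fraction, mean over
#' replicates), and optionally `sd` (per-time standard deviation on the
#' fraction scale) and `n_reps` (replicate count). Attributes carry the
#' formulation label and whether the profile has been normalized to an
#' operational m-infinity.
#'
#' @param time_h Sampling times in hours, strictly increasing, `>= 0`.
#' @param release Cumulative released fraction at each time, `>= 0`.
#' @param sd Optional per-time standard deviation.
#' @param n_reps Optional replicate count (scalar or per-time).
#' @param formulation Optional label.
#' @param normalized Whether the profile is already m-infinity normalized.
#' @param t_ref Reference time of the normalization, if any.
#' @return A tibble of class `release_profile`.
#' @examples
#' release_profile(c(1, 2, 4), c(0.2, 0.35, 0.6), formulation = "F1")
#' @export
release_profile <- function(time_h, release, sd = NULL, n_reps = NULL,
                            formulation = NULL, normalized = FALSE,
                            t_ref = NULL) {
  stopifnot(is.numeric(time_h), is.numeric(release),
            length(time_h) == length(release))
  if (any(time_h < 0)) abort("times must be >= 0")
  if (any(diff(time_h) <= 0)) abort("times must be strictly increasing")
  if (any(release < 0)) abort("release values must be >= 0")
  out <- tibble::tibble(time_h = as.numeric(time_h),
                        release = as.numeric(release))
  if (!is.null(sd)) {
    stopifnot(length(sd) == nrow(out), all(sd >= 0 | is.na(sd)))
    out$sd <- as.numeric(sd)
  }
  if (!is.null(n_reps)) out$n_reps <- as.integer(rep_len(n_reps, nrow(out)))
  new_release_profile(out, formulation = formulation,
                      normalized = normalized, t_ref = t_ref)
}

new_release_profile <- function(data, formulation = NULL, normalized = FALSE,
                                t_ref = NULL) {
  structure(
    tibble::as_tibble(data),
    formulation = formulation,
    normalized = isTRUE(normalized),
    t_ref = t_ref,
    class = c("release_profile", class(tibble::tibble()))
  )
}

#' @export
print.release_profile <- function(x, ...) {
  lab <- attr(x, "formulation")
  cat("<release_profile", if (!is.null(lab)) paste0(" '", lab, "'"), ">",
      if (isTRUE(attr(x, "normalized")))
        paste0(" normalized (t_ref = ", attr(x, "t_ref"), " h)"),
      "\n", sep = "")
  NextMethod()
}

is_normalized <- function(profile) isTRUE(attr(profile, "normalized"))

#' Normalize a release profile to its operational m-infinity
#'
#' Divides all release values by the value at the reference time `t_ref`
#' (default 6 h), so that release at `t_ref` becomes exactly 1: the amount
#' released by `t_ref` is treated as m-infinity, i.e. 100% of the payload
#' released. When `t_ref` falls between sample times the divisor is obtained
#' by linear interpolation. Idempotent: renormalizing at the same `t_ref`
#' is a no-op.
#'
#' @param profile A [release_profile()] (or plain data frame with `time_h`,
#'   `release`).
#' @param t_ref Reference time in hours; must lie within the sampled range.
#' @return The normalized profile, with `sd` rescaled by the same divisor.
#' @export
normalize_to_minf <- function(profile, t_ref = 6) {
  stopifnot(all(c("time_h", "release") %in% names(profile)))
  if (t_ref < min(profile$time_h) || t_ref > max(profile$time_h)) {
    abort(paste0("t_ref = ", t_ref, " h is outside the sampled range [",
                 min(profile$time_h), ", ", max(profile$time_h), "] h"))
  }
  m_ref <- approx(profile$time_h, profile$release, xout = t_ref)$y
  if (!is.finite(m_ref) || m_ref <= 0) {
    abort("release at the reference time is zero; cannot normalize")
  }
  out <- profile
  out$release <- out$release / m_ref
  if ("sd" %in% names(out)) out$sd <- out$sd / m_ref
  new_release_profile(out, formulation = attr(profile, "formulation"),
                      normalized = TRUE, t_ref = t_ref)
}

#' Restrict a profile to a fitting window
#'
#' Keeps the points inside a time interval and/or below a release-fraction
#' cap (e.g. the first-60% rule for the Higuchi law). Ordering is preserved.
#'
#' @param profile A release profile.
#' @param t_min,t_max Time bounds in hours (inclusive).
#' @param cap Optional cumulative-release cap; points with
#'   `release > cap` are removed.
#' @return The windowed sub-profile, with the window recorded in the
#'   `"window"` attribute.
#' @export
select_window <- function(profile, t_min = -Inf, t_max = Inf, cap = NULL) {
  stopifnot(all(c("time_h", "release") %in% names(profile)))
  keep <- profile$time_h >= t_min & profile$time_h <= t_max
  if (!is.null(cap)) keep <- keep & profile$release <= cap
  if (!any(keep)) {
    abort(paste0("empty window: t in [", t_min, ", ", t_max, "]",
                 if (!is.null(cap)) paste0(", release <= ", cap),
                 " selects no points"))
  }
  out <- profile[keep, , drop = FALSE]
  out <- new_release_profile(out, formulation = attr(profile, "formulation"),
                             normalized = is_normalized(profile),
                             t_ref = attr(profile, "t_ref"))
  attr(out, "window") <- list(t_min = t_min, t_max = t_max, cap = cap)
  out
}

#' @describeIn release_profile Plot the profile as points with error bars.
#' @param object,x A `release_profile`.
#' @param ... Unused.
#' @method autoplot release_profile
#' @export
autoplot.release_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_h, y = .data$release)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(
      x = "time (h)",
      y = if (is_normalized(object)) "cumulative release (of m∞)"
          else "cumulative released fraction",
      title = attr(object, "formulation")
    )
  if ("sd" %in% names(object) && any(is.finite(object$sd))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$release - .data$sd,
                   ymax = .data$release + .data$sd),
      width = 0.1
    )
  }
  p
}
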