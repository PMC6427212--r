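# Slope-parallelism testing across formulations: are the square-root-law
# regression lines of different formulations parallel?

#' Build a slope panel from release profiles
#'
#' Regresses cumulative release on `sqrt(t)` for each formulation (straight
#' line with intercept) and collects slope, slope standard error, residual
#' degrees of freedom and residual variance — the inputs of
#' [parallelism_test()].
#'
#' @param profiles A named list of release profiles, or a data frame with
#'   columns `formulation`, `time_h`, `release`.
#' @param t_min,t_max,cap Optional common fitting window.
#' @return A tibble (`slope_panel`) with columns `formulation`, `slope`,
#'   `se`, `df`, `sigma2`, `r2`.
#' @export
slope_panel <- function(profiles, t_min = -Inf, t_max = Inf, cap = NULL) {
  if (is.data.frame(profiles)) {
    stopifnot(all(c("formulation", "time_h", "release") %in% names(profiles)))
    profiles <- split(profiles, profiles$formulation)
    profiles <- purrr::imap(profiles, function(d, nm) {
      release_profile(d$time_h, d$release, formulation = nm)
    })
  }
  if (is.null(names(profiles)) || any(names(profiles) == "")) {
    names(profiles) <- purrr::imap_chr(profiles, function(p, i) {
      attr(p, "formulation") %||% paste0("F", i)
    })
  }
  out <- purrr::imap_dfr(profiles, function(pr, nm) {
    win <- select_window(pr, t_min = t_min, t_max = t_max, cap = cap)
    lf <- fit_linear(sqrt(win$time_h), win$release)
    tibble::tibble(formulation = nm, slope = lf$slope, se = lf$se_slope,
                   df = lf$df, sigma2 = lf$sigma2, r2 = as.numeric(lf$r2))
  })
  class(out) <- c("slope_panel", class(out))
  out
}

#' Compare two regression slopes
#'
#' Two-sided t-test of slope equality between two independent regression
#' lines. The default (`method = "welch"`) uses
#' `t = (b_a - b_b) / sqrt(SE_a^2 + SE_b^2)` with `df = df_a + df_b`; the
#' pooled variant re-estimates a common residual variance from both fits
#' before forming the standard error.
#'
#' @param fit_a,fit_b Each either a `linear_fit` from [fit_linear()] or a
#'   list/one-row data frame with `slope`, `se`, `df` (and `sigma2` for the
#'   pooled method; `se` is interpreted as the slope standard error).
#' @param method `"welch"` (default) or `"pooled"`.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `slope_a`,
#'   `slope_b`, `method`.
#' @export
compare_two_slopes <- function(fit_a, fit_b, method = c("welch", "pooled")) {
  method <- match.arg(method)
  a <- as_slope(fit_a)
  b <- as_slope(fit_b)
  if (a$se == 0 && b$se == 0) {
    abort("both slope standard errors are zero; comparison is degenerate")
  }
  df <- a$df + b$df
  if (method == "welch") {
    se <- sqrt(a$se^2 + b$se^2)
  } else {
    if (is.null(a$sigma2) || is.null(b$sigma2) ||
        !is.finite(a$sigma2) || !is.finite(b$sigma2)) {
      abort("pooled method needs residual variances (sigma2)")
    }
    s2p <- (a$df * a$sigma2 + b$df * b$sigma2) / (a$df + b$df)
    # se^2 = sigma2 / Sxx, so sigma2/se^2 recovers Sxx
    se <- sqrt(s2p * (a$se^2 / a$sigma2 + b$se^2 / b$sigma2))
  }
  stat <- (a$slope - b$slope) / se
  tibble::tibble(statistic = stat, df = df,
                 p_value = 2 * pt(abs(stat), df, lower.tail = FALSE),
                 slope_a = a$slope, slope_b = b$slope, method = method)
}

as_slope <- function(x) {
  if (inherits(x, "linear_fit")) {
    return(list(slope = x$slope, se = x$se_slope, df = x$df, sigma2 = x$sigma2))
  }
  x <- as.list(x)
  if (!all(c("slope", "se", "df") %in% names(x))) {
    abort("slope entries need fields: slope, se, df")
  }
  list(slope = x$slope, se = x$se, df = x$df, sigma2 = x$sigma2)
}

#' Test parallelism of regression lines across formulations
#'
#' Applies [compare_two_slopes()] to the minimum-slope versus maximum-slope
#' pair — if the two extreme slopes are statistically indistinguishable the
#' whole panel is considered parallel — and returns the full pairwise
#' comparison matrix as supporting output. No multiple-testing correction
#' is applied by default; a Bonferroni adjustment of the pairwise matrix is
#' available.
#'
#' @param panel A `slope_panel` (or data frame with `formulation`, `slope`,
#'   `se`, `df`, optionally `sigma2`).
#' @param method Passed to [compare_two_slopes()].
#' @param bonferroni Apply a Bonferroni correction to the pairwise
#'   p-values (default `FALSE`, matching the convention of reporting the
#'   raw extreme-pair p-value).
#' @return A list of class `parallelism_test` with `extreme_pair` (one-row
#'   tibble for min vs max slope), `pairwise` (all pairs), and `parallel_at`
#'   helper fields.
#' @export
parallelism_test <- function(panel, method = c("welch", "pooled"),
                             bonferroni = FALSE) {
  method <- match.arg(method)
  stopifnot(is.data.frame(panel), nrow(panel) >= 2,
            all(c("formulation", "slope", "se", "df") %in% names(panel)))
  stopifnot(all(panel$df >= 1))
  rows <- purrr::transpose(as.list(panel[c("formulation", "slope", "se", "df",
                                           intersect("sigma2", names(panel)))]))
  names(rows) <- panel$formulation
  pairs <- utils::combn(panel$formulation, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(pp) {
    res <- compare_two_slopes(rows[[pp[1]]], rows[[pp[2]]], method = method)
    dplyr::mutate(res, formulation_a = pp[1], formulation_b = pp[2],
                  .before = 1)
  })
  if (bonferroni) {
    pairwise$p_adjusted <- pmin(1, pairwise$p_value * nrow(pairwise))
  }
  i_min <- which.min(panel$slope)
  i_max <- which.max(panel$slope)
  extreme <- if (i_min == i_max) {
    # all slopes identical: compare the first two entries
    compare_two_slopes(rows[[1]], rows[[2]], method = method)
  } else {
    compare_two_slopes(rows[[i_min]], rows[[i_max]], method = method)
  }
  extreme <- dplyr::mutate(extreme,
                           formulation_a = panel$formulation[[min(i_min, i_max)]],
                           formulation_b = panel$formulation[[max(i_min, i_max)]],
                           .before = 1)
  structure(list(extreme_pair = extreme, pairwise = pairwise,
                 method = method, bonferroni = bonferroni),
            class = "parallelism_test")
}

#' @export
print.parallelism_test <- function(x, ...) {
  cat("<parallelism_test> extreme-pair (min vs max slope) p = ",
      format(x$extreme_pair$p_value), "\n", sep = "")
  print(x$pairwise)
  invisible(x)
}

#' @rdname parallelism_test
#' @param x A `parallelism_test`.
#' @param ... Unused.
#' @method tidy parallelism_test
#' @export
tidy.parallelism_test <- function(x, ...) x$pairwise

#' @rdname parallelism_test
#' @method glance parallelism_test
#' @export
glance.parallelism_test <- function(x, ...) {
  tibble::tibble(extreme_pair_p = x$extreme_pair$p_value,
                 min_pairwise_p = min(x$pairwise$p_value),
                 n_pairs = nrow(x$pairwise), method = x$method)
}
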