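# Model-selection criteria and nested-model F-tests. All criteria consume
# the weighted SS computed in the untransformed release space.

#' Akaike information criterion from a sum of squares
#'
#' `AIC = N * ln(SS) + 2 * p`; lower is better. A perfect fit (`SS = 0`)
#' returns `-Inf` with attribute `perfect_fit = TRUE`.
#'
#' @param N Number of data points (positive integer).
#' @param SS Weighted residual sum of squares (`>= 0`).
#' @param p Number of model parameters.
#' @return The criterion value.
#' @export
aic_ss <- function(N, SS, p) {
  check_count(N, 1); check_count(p, 0)
  stopifnot(SS >= 0)
  if (SS == 0) return(structure(-Inf, perfect_fit = TRUE))
  N * log(SS) + 2 * p
}

#' Schwarz (Bayesian) criterion from a sum of squares
#'
#' `SC = N * ln(SS) + p * ln(N)`; lower is better. Note the identity
#' `SC - AIC = p * (ln N - 2)`, so SC penalizes harder than AIC exactly
#' when `N > e^2`.
#'
#' @inheritParams aic_ss
#' @export
schwarz_ss <- function(N, SS, p) {
  check_count(N, 2); check_count(p, 0)
  stopifnot(SS >= 0)
  if (SS == 0) return(structure(-Inf, perfect_fit = TRUE))
  N * log(SS) + p * log(N)
}

check_count <- function(x, min) {
  nm <- deparse(substitute(x))
  if (length(x) != 1 || !is.finite(x) || x != round(x) || x < min) {
    abort(paste0(nm, " must be a single integer >= ", min))
  }
}

#' Imbimbo confidence-band criterion
#'
#' `I_p = t_{q, N-p} * sqrt(SS * (1/(N-p) - 1/N)) / mean(fitted)`:
#' approximately the ratio between the area of the confidence band around
#' the fitted curve and the area under the curve itself. Lower is better;
#' the model with the minimum `I_p` has the narrowest confidence interval
#' relative to its predictions. The Student quantile defaults to the
#' two-sided 95% value (`quantile = 0.975`) and is configurable.
#'
#' @param fit A `release_fit`, or `NULL` if the components are given
#'   directly.
#' @param N,SS,p,mean_fitted Components, when no fit object is supplied.
#' @param quantile Student-t quantile probability (default `0.975`).
#' @return `I_p` (dimensionless, `>= 0`).
#' @examples
#' imbimbo(N = 10, SS = 4, p = 2, mean_fitted = 50)
#' @export
imbimbo <- function(fit = NULL, N = NULL, SS = NULL, p = NULL,
                    mean_fitted = NULL, quantile = 0.975) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "release_fit"))
    N <- fit$n; SS <- fit$ss; p <- fit$p
    mean_fitted <- mean(fit$fitted$fitted)
  }
  check_count(N, 1); check_count(p, 0)
  if (N <= p) abort("need N > p for the Imbimbo criterion")
  if (!is.finite(mean_fitted) || mean_fitted <= 0) {
    abort("mean fitted value must be positive")
  }
  if (SS == 0) return(0)
  qt(quantile, df = N - p) * sqrt(SS * (1 / (N - p) - 1 / N)) / mean_fitted
}

# ---------------------------------------------------------------------------
# Nesting registry: simple model = complex model with parameters fixed.
# `constrain` maps the simple model's parameters to the complex model's.

nesting_registry <- function() {
  list(
    list(simple = "zero_order_origin", complex = "power_law",
         constraint = "beta = 1", approximate = FALSE,
         constrain = function(par) c(alpha = unname(par[["k"]]), beta = 1)),
    list(simple = "higuchi", complex = "power_law",
         constraint = "beta = 0.5", approximate = FALSE,
         constrain = function(par) c(alpha = unname(par[["alpha"]]), beta = 0.5)),
    list(simple = "noyes_whitney", complex = "weibull",
         constraint = "beta = 1", approximate = FALSE,
         constrain = function(par) c(alpha = unname(par[["k"]]), beta = 1)),
    list(simple = "power_law", complex = "weibull",
         constraint = "small-argument degeneracy", approximate = TRUE,
         constrain = function(par) par[c("alpha", "beta")]),
    list(simple = "higuchi", complex = "weibull",
         constraint = "beta = 0.5, small-argument degeneracy",
         approximate = TRUE,
         constrain = function(par) c(alpha = unname(par[["alpha"]]), beta = 0.5))
  )
}

find_nesting <- function(simple, complex) {
  reg <- nesting_registry()
  hit <- purrr::detect(reg, ~ .x$simple == simple && .x$complex == complex)
  hit
}

#' Registered nested model pairs
#'
#' @return A tibble with columns `simple`, `complex`, `constraint`,
#'   `approximate`. The power-law-within-Weibull pair is approximate: the
#'   nesting holds only in the small-argument limit, and F-tests on it
#'   carry a caveat.
#' @export
nested_pairs <- function() {
  purrr::map_dfr(nesting_registry(), ~ tibble::tibble(
    simple = .x$simple, complex = .x$complex,
    constraint = .x$constraint, approximate = .x$approximate
  ))
}

#' Extra-sum-of-squares F-test between nested fits
#'
#' For a simple model with `q` parameters nested in a complex model with
#' `p > q` parameters fitted to the same data,
#' `F = ((SS_q - SS_p) / (df_q - df_p)) / (SS_p / df_p)` with
#' `df = N - (number of parameters)`, referred to the
#' `F(df_q - df_p, df_p)` distribution (upper tail). If the complex fit is
#' (numerically) worse, `F` is floored at 0 and flagged.
#'
#' @param fit_q `release_fit` of the simple model.
#' @param fit_p `release_fit` of the complex model.
#' @return A one-row tibble: `simple`, `complex`, `statistic`, `df1`,
#'   `df2`, `p_value`, `approximate`, `floored`.
#' @export
f_nested <- function(fit_q, fit_p) {
  stopifnot(inherits(fit_q, "release_fit"), inherits(fit_p, "release_fit"))
  pair <- find_nesting(fit_q$model, fit_p$model)
  if (is.null(pair)) {
    abort(paste0("'", fit_q$model, "' is not registered as nested in '",
                 fit_p$model, "'"))
  }
  if (fit_q$n != fit_p$n) {
    abort("nested fits must use the same data points (N differs)")
  }
  f_from_ss(fit_q$ss, fit_p$ss, n = fit_q$n, q = fit_q$p, p = fit_p$p,
            simple = fit_q$model, complex = fit_p$model,
            approximate = pair$approximate)
}

f_from_ss <- function(ss_q, ss_p, n, q, p, simple = "simple",
                      complex = "complex", approximate = FALSE) {
  if (p == q) {
    abort(paste0("'", simple, "' and '", complex, "' have the same number of ",
                 "parameters; the extra-sum-of-squares F-test is undefined ",
                 "(zero numerator degrees of freedom)"))
  }
  if (p < q) abort("complex model must have more parameters than the simple one")
  df_q <- n - q
  df_p <- n - p
  if (df_p < 1) abort("no residual degrees of freedom for the complex model")
  floored <- ss_q < ss_p
  if (floored) {
    warn("SS of the simple model is below the complex model's; F floored at 0")
  }
  stat <- if (floored || ss_p == 0) {
    if (ss_p == 0 && ss_q > ss_p) Inf else 0
  } else {
    ((ss_q - ss_p) / (df_q - df_p)) / (ss_p / df_p)
  }
  pval <- if (is.infinite(stat)) 0 else pf(stat, df_q - df_p, df_p, lower.tail = FALSE)
  tibble::tibble(simple = simple, complex = complex, statistic = stat,
                 df1 = df_q - df_p, df2 = df_p, p_value = pval,
                 approximate = approximate, floored = floored)
}

# ---------------------------------------------------------------------------

#' Rank competing model fits
#'
#' Scores every fit with the Akaike, Schwarz and Imbimbo criteria, runs the
#' extra-sum-of-squares F-test over every registered nested pair present,
#' and reports per-criterion rankings plus a consensus. All fits must be on
#' the same data window (same points), otherwise the SS are incomparable
#' and an error is raised. Criteria disagreement is surfaced in the report,
#' never silently resolved; the consensus rule (majority vote across the
#' three criteria, ties broken toward fewer parameters) is configurable.
#'
#' @param fits A list of `release_fit` objects for distinct models.
#' @param imbimbo_quantile Student quantile for [imbimbo()].
#' @param consensus `"majority"` (default) or `"aic"` (AIC alone decides).
#' @return An object of class `selection_report` with elements `table`
#'   (per-model criteria and ranks), `f_tests`, `consensus`,
#'   `disagreement`.
#' @export
rank_models <- function(fits, imbimbo_quantile = 0.975,
                        consensus = c("majority", "aic")) {
  consensus <- match.arg(consensus)
  stopifnot(is.list(fits), length(fits) >= 2,
            all(vapply(fits, inherits, logical(1), "release_fit")))
  models <- vapply(fits, function(f) f$model, character(1))
  if (anyDuplicated(models)) abort("duplicate models in the fit list")
  names(fits) <- models
  times <- lapply(fits, function(f) f$fitted$time_h)
  same <- all(vapply(times[-1], function(tt) {
    length(tt) == length(times[[1]]) && all(tt == times[[1]])
  }, logical(1)))
  if (!same) {
    abort("fits use different windows/points; SS values are not comparable")
  }

  tab <- purrr::map_dfr(fits, function(f) tibble::tibble(
    model = f$model, n = f$n, p = f$p, ss = f$ss, r2 = f$r2,
    aic = as.numeric(aic_ss(f$n, f$ss, f$p)),
    sc = as.numeric(schwarz_ss(f$n, f$ss, f$p)),
    imbimbo = imbimbo(f, quantile = imbimbo_quantile)
  ))
  tab <- dplyr::mutate(tab,
    rank_aic = rank(.data$aic, ties.method = "min"),
    rank_sc = rank(.data$sc, ties.method = "min"),
    rank_imbimbo = rank(.data$imbimbo, ties.method = "min")
  )

  ftests <- purrr::map_dfr(nesting_registry(), function(pr) {
    if (pr$simple %in% models && pr$complex %in% models &&
        fits[[pr$complex]]$p > fits[[pr$simple]]$p) {
      f_nested(fits[[pr$simple]], fits[[pr$complex]])
    } else {
      NULL
    }
  })

  winner_of <- function(score) {
    cand <- tab$model[score == min(score)]
    if (length(cand) > 1) cand <- cand[order(tab$p[match(cand, tab$model)], cand)]
    cand[[1]]
  }
  winners <- c(aic = winner_of(tab$aic), sc = winner_of(tab$sc),
               imbimbo = winner_of(tab$imbimbo))
  disagreement <- length(unique(winners)) > 1
  cons <- if (consensus == "aic") {
    winners[["aic"]]
  } else {
    votes <- table(winners)
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) top <- top[order(tab$p[match(top, tab$model)], top)]
    top[[1]]
  }
  ties <- purrr::map_lgl(c("aic", "sc", "imbimbo"), function(cr) {
    sum(tab[[cr]] == min(tab[[cr]])) > 1
  })

  structure(list(table = tab, f_tests = ftests,
                 criterion_winners = winners, consensus = cons,
                 disagreement = disagreement, tied = any(ties)),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report> consensus: '", x$consensus, "'",
      if (x$disagreement) "  [criteria disagree]",
      if (x$tied) "  [tie among models]", "\n", sep = "")
  print(x$table)
  if (nrow(x$f_tests)) {
    cat("nested-model F-tests:\n")
    print(x$f_tests)
  }
  invisible(x)
}

#' @rdname rank_models
#' @param x A `selection_report`.
#' @param ... Unused.
#' @method tidy selection_report
#' @export
tidy.selection_report <- function(x, ...) x$table

#' @rdname rank_models
#' @method glance selection_report
#' @export
glance.selection_report <- function(x, ...) {
  tibble::tibble(consensus = x$consensus,
                 winner_aic = x$criterion_winners[["aic"]],
                 winner_sc = x$criterion_winners[["sc"]],
                 winner_imbimbo = x$criterion_winners[["imbimbo"]],
                 disagreement = x$disagreement, tied = x$tied,
                 n_models = nrow(x$table), n_f_tests = nrow(x$f_tests))
}

#' @rdname rank_models
#' @param object A `selection_report`.
#' @method autoplot selection_report
#' @export
autoplot.selection_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$table, c("aic", "sc", "imbimbo"),
                              names_to = "criterion", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "criterion value (lower is better)")
}

#' Write a model-comparison table to CSV and JSON
#'
#' Emits the machine-readable comparison (columns `Model`, `AIC`, `SC`,
#' `Imbimbo`, `F`, `F_pvalue`), where each model's `F` row is the test of
#' that model nested inside its registered parent, when present among the
#' fits.
#'
#' @param report A `selection_report`.
#' @param path Output path without extension; `<path>.csv` and
#'   `<path>.json` are written.
#' @return The table, invisibly.
#' @export
write_selection_report <- function(report, path) {
  stopifnot(inherits(report, "selection_report"))
  ft <- report$f_tests
  tab <- dplyr::transmute(report$table,
    Model = .data$model, AIC = .data$aic, SC = .data$sc,
    Imbimbo = .data$imbimbo,
    F = purrr::map_dbl(.data$model, function(mdl) {
      i <- which(ft$simple == mdl)
      if (length(i)) ft$statistic[[i[1]]] else NA_real_
    }),
    F_pvalue = purrr::map_dbl(.data$model, function(mdl) {
      i <- which(ft$simple == mdl)
      if (length(i)) ft$p_value[[i[1]]] else NA_real_
    })
  )
  readr::write_csv(tab, paste0(path, ".csv"))
  jsonlite::write_json(
    list(table = tab, f_tests = ft,
         consensus = report$consensus,
         criterion_winners = as.list(report$criterion_winners),
         disagreement = report$disagreement),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(tab)
}
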