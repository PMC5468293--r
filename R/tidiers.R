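#' Tidy a fitted gait curve
#'
#' @param x A `gait_fit`.
#' @param conf.int Include 95% Wald confidence intervals (default `TRUE`).
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return One row per model parameter: `term`, `estimate`, `std.error` and
#'   optionally `conf.low`/`conf.high`.
#' @export
tidy.gait_fit <- function(x, conf.int = TRUE, conf.level = 0.95, ...) {
  out <- tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se)
  )
  if (conf.int) {
    crit <- qt(1 - (1 - conf.level) / 2, x$df)
    out$conf.low <- out$estimate - crit * out$std.error
    out$conf.high <- out$estimate + crit * out$std.error
  }
  out
}

#' @rdname tidy.gait_fit
#' @export
glance.gait_fit <- function(x, ...) {
  tibble::tibble(
    parameter = x$parameter, family = x$family, transform = x$transform,
    ss = x$ss, df = x$df, nobs = x$n,
    sigma = sqrt(x$ss / x$df),
    range_lower = x$range[1], range_upper = x$range[2],
    converged = x$converged,
    runs_test_p = x$diagnostics$runs_test_p,
    normality_p = x$diagnostics$normality_p
  )
}

#' Tidy a model-selection chain
#'
#' @param x A `gait_model_selection`.
#' @param ... Unused.
#' @return The chain of pairwise extra sum-of-squares tests as a tibble.
#' @export
tidy.gait_model_selection <- function(x, ...) x$chain

#' @rdname tidy.gait_model_selection
#' @export
glance.gait_model_selection <- function(x, ...) {
  fit <- x$preferred_fit
  tibble::tibble(
    parameter = x$parameter, preferred = x$preferred, alpha = x$alpha,
    ss = fit$ss, df = fit$df, nobs = fit$n
  )
}

#' Tidy a shared-curve comparison
#'
#' @param x A `gait_comparison`.
#' @param ... Unused.
#' @return `tidy()` returns the per-parameter shift summary (empty tibble
#'   when the curves are shared); `glance()` the one-row test summary.
#' @export
tidy.gait_comparison <- function(x, ...) {
  if (is.null(x$shift_summary)) {
    return(tibble::tibble(
      term = character(0), estimate_a = numeric(0), estimate_b = numeric(0),
      difference = numeric(0), se = numeric(0),
      conf_low = numeric(0), conf_high = numeric(0)
    ))
  }
  x$shift_summary
}

#' @rdname tidy.gait_comparison
#' @export
glance.gait_comparison <- function(x, ...) {
  tibble::tibble(
    parameter = x$parameter, family = x$family,
    ss_a = x$ss_a, ss_b = x$ss_b, ss_combined = x$ss_combined,
    statistic = x$F, df_num = x$df_num, df_den = x$df_den,
    p.value = x$p, alpha = x$alpha, shared = x$shared,
    degenerate = x$degenerate
  )
}
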