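#' Restrict a stride table to a velocity range
#'
#' The regression models are defined over a restricted walking range:
#' omitting the very slowest strides (accelerating, stopping, sniffing) and
#' the fastest (trotting) strides yields models that are reproducible across
#' baseline cohorts. The default walking range for mice is the closed
#' interval \[3, 16\] cm/s.
#'
#' @param data A stride table (or data frame with `stride_velocity_cm_s`).
#' @param range Length-2 numeric, closed interval of retained velocities
#'   (cm/s).
#' @return The restricted tibble with attribute `"range_report"` giving the
#'   number of excluded slow and fast strides. An empty result warns but is
#'   not an error.
#' @export
restrict_velocity_range <- function(data, range = c(3, 16)) {
  stopifnot(length(range) == 2, range[1] >= 0, range[1] < range[2])
  data <- tibble::as_tibble(data)
  v <- data$stride_velocity_cm_s
  slow <- sum(v < range[1])
  fast <- sum(v > range[2])
  out <- dplyr::filter(data, .data$stride_velocity_cm_s >= range[1],
                       .data$stride_velocity_cm_s <= range[2])
  if (nrow(out) == 0 && nrow(data) > 0) {
    warn("no strides remain in the requested velocity range")
  }
  attr(out, "range_report") <- list(
    range = range, excluded_slow = slow, excluded_fast = fast,
    retained = nrow(out)
  )
  out
}

#' Fit a velocity-dependence model to one gait parameter
#'
#' Least-squares fit of a `linear`, `one_phase` or `two_phase` model (see
#' [model_predict()] for the parameterizations) of a gait parameter against
#' stride velocity over a restricted walking range. Exponential families are
#' fitted by bounded Levenberg-Marquardt from multiple starts: rate constants
#' on a log-spaced grid in \[0.05, 2\] per cm/s, the remaining parameters at
#' their exact conditional least-squares values for each rate; ties between
#' equal-SS starts break toward the lowest rate constant.
#'
#' @param data A stride table.
#' @param parameter Name of the response column, e.g. `"stride_length_mm"`.
#' @param family Model family.
#' @param range Velocity range (cm/s), closed; default `c(3, 16)`.
#' @param transform `"identity"` or `"log"` (natural log of the response
#'   before fitting; stance duration is commonly fitted on the log scale).
#' @param n_starts Number of multi-start initializations (default 10).
#' @param seed Optional seed for any randomized component of the start set.
#' @return A `gait_fit` object: estimates with standard errors, residual sum
#'   of squares `ss`, degrees of freedom `df` (= points - parameters), point
#'   count, range, convergence flag and residual diagnostics (runs test and
#'   D'Agostino-Pearson normality, see [residual_diagnostics()]).
#' @export
#' @examples
#' tab <- simulate_gait_cohort(n_subjects = 4, strides_per_trial = 10, seed = 2)
#' fit <- fit_gait_curve(tab, "stride_length_mm", "one_phase")
#' tidy(fit)
#' glance(fit)
fit_gait_curve <- function(data, parameter,
                           family = c("linear", "one_phase", "two_phase"),
                           range = c(3, 16),
                           transform = c("identity", "log"),
                           n_starts = 10, seed = NULL) {
  family <- rlang::arg_match(family)
  transform <- rlang::arg_match(transform)
  data <- tibble::as_tibble(data)
  if (!parameter %in% names(data)) {
    abort(paste0("parameter column not found: ", parameter))
  }
  restricted <- restrict_velocity_range(data, range)
  v <- restricted$stride_velocity_cm_s
  y <- restricted[[parameter]]
  keep <- is.finite(v) & is.finite(y)
  v <- v[keep]; y <- y[keep]
  p <- model_n_par(family)
  if (length(v) < p + 5) {
    abort(paste0(
      "insufficient points for a ", family, " fit: need at least ", p + 5,
      " in range, have ", length(v)
    ))
  }
  if (diff(range(v)) < 5) {
    abort(paste0(
      "velocity span too narrow for a stable fit: need >= 5 cm/s, have ",
      signif(diff(range(v)), 3)
    ))
  }
  if (transform == "log") {
    if (any(y <= 0)) abort("log transform requires strictly positive responses")
    y <- log(y)
  }
  core <- fit_xy(v, y, family, n_starts = n_starts, seed = seed)
  se <- if (!is.null(core$vcov)) sqrt(diag(core$vcov)) else
    setNames(rep(NA_real_, p), names(core$pars))
  fitted_vals <- if (core$converged) model_predict(family, core$pars, v) else
    rep(NA_real_, length(v))
  fit <- structure(list(
    parameter = parameter,
    family = family,
    transform = transform,
    coefficients = core$pars,
    se = se,
    vcov = core$vcov,
    ss = core$ss,
    df = length(v) - p,
    n = length(v),
    range = range,
    converged = core$converged,
    data = tibble::tibble(velocity = v, response = y,
                          fitted = fitted_vals,
                          residual = y - fitted_vals),
    diagnostics = list(runs_test_p = NA_real_, normality_p = NA_real_)
  ), class = "gait_fit")
  if (fit$converged) fit$diagnostics <- residual_diagnostics(fit)
  fit
}

#' @export
print.gait_fit <- function(x, ...) {
  cat("<gait_fit> ", x$parameter, " ~ ", x$family,
      if (x$transform == "log") " (log response)" else "", "\n", sep = "")
  cat("  range [", x$range[1], ", ", x$range[2], "] cm/s, n = ", x$n,
      ", SS = ", signif(x$ss, 6), ", df = ", x$df,
      if (!x$converged) "  [NOT CONVERGED]" else "", "\n", sep = "")
  est <- rbind(estimate = x$coefficients, se = x$se)
  print(signif(est, 5))
  cat("  runs test p = ", signif(x$diagnostics$runs_test_p, 3),
      ", residual normality p = ", signif(x$diagnostics$normality_p, 3),
      "\n", sep = "")
  invisible(x)
}

#' Predict from a fitted gait curve
#'
#' @param object A `gait_fit`.
#' @param velocity Velocities (cm/s) at which to predict; defaults to the
#'   fitted points.
#' @param interval `"none"` or `"confidence"` for a 95% Wald confidence band
#'   from the estimate covariance.
#' @param level Confidence level (default 0.95).
#' @param ... Unused.
#' @return A tibble with `velocity`, `fit` and, for confidence bands, `lwr`
#'   and `upr`. Values are on the fitted (possibly log) response scale.
#' @export
predict.gait_fit <- function(object, velocity = NULL,
                             interval = c("none", "confidence"),
                             level = 0.95, ...) {
  interval <- rlang::arg_match(interval)
  if (is.null(velocity)) velocity <- object$data$velocity
  fit <- model_predict(object$family, object$coefficients, velocity)
  out <- tibble::tibble(velocity = velocity, fit = fit)
  if (interval == "confidence") {
    if (is.null(object$vcov)) abort("no covariance available for this fit")
    J <- model_jacobian(object$family, object$coefficients, velocity)
    se_fit <- sqrt(pmax(rowSums((J %*% object$vcov) * J), 0))
    crit <- qt(1 - (1 - level) / 2, object$df)
    out$lwr <- fit - crit * se_fit
    out$upr <- fit + crit * se_fit
  }
  out
}

# Extra sum-of-squares F comparing a simpler fit (SS1, DF1) with a more
# complex fit (SS2, DF2 < DF1) of the same data:
#   F = ((SS1 - SS2) / (DF1 - DF2)) / (SS2 / DF2)
# Clipped at 0 (p = 1) when the complex model fits no better, which can
# happen because the families are only quasi-nested.
extra_ss_f <- function(ss1, df1, ss2, df2) {
  stopifnot(df1 > df2)
  if (!is.finite(ss1) || !is.finite(ss2)) {
    return(list(F = NA_real_, p = NA_real_))
  }
  if (ss2 <= 0) {
    # perfect complex fit: infinitely strong evidence unless SS1 is 0 too
    if (ss1 <= 0) return(list(F = 0, p = 1))
    return(list(F = Inf, p = 0))
  }
  f <- ((ss1 - ss2) / (df1 - df2)) / (ss2 / df2)
  if (f < 0) return(list(F = 0, p = 1))
  list(F = f, p = pf(f, df1 - df2, df2, lower.tail = FALSE))
}

#' Select the simplest adequate velocity-dependence model
#'
#' Fits the candidate families in order of increasing parameter count and
#' walks the chain with extra sum-of-squares F-tests (simpler vs next): the
#' more complex model is preferred only when its improvement in residual sum
#' of squares is significant at `alpha`. The families are treated as
#' quasi-nested through their degree-of-freedom difference (linear, 2
#' parameters; one-phase, 3; two-phase, 5), matching standard curve-fitting
#' practice even though the linear family is not a strict submodel of the
#' exponentials.
#'
#' @inheritParams fit_gait_curve
#' @param candidates Character vector of families, ordered by increasing
#'   parameter count.
#' @param alpha Significance level for preferring the more complex model
#'   (default 0.05).
#' @return A `gait_model_selection` object with the fits, the chain of
#'   pairwise tests (`tidy()` returns it as a tibble) and the preferred fit.
#' @export
select_gait_model <- function(data, parameter,
                              candidates = c("linear", "one_phase",
                                             "two_phase"),
                              range = c(3, 16),
                              transform = c("identity", "log"),
                              alpha = 0.05, n_starts = 10, seed = NULL) {
  transform <- rlang::arg_match(transform)
  stopifnot(length(candidates) >= 1,
            all(candidates %in% MODEL_FAMILIES))
  np <- vapply(candidates, model_n_par, integer(1))
  if (is.unsorted(np, strictly = TRUE)) {
    abort("candidates must be ordered by strictly increasing parameter count")
  }
  fits <- lapply(candidates, function(fam) {
    fit_gait_curve(data, parameter, fam, range = range, transform = transform,
                   n_starts = n_starts, seed = seed)
  })
  names(fits) <- candidates
  chain <- tibble::tibble(
    simpler = character(0), complex = character(0),
    SS1 = numeric(0), DF1 = integer(0), SS2 = numeric(0), DF2 = integer(0),
    F = numeric(0), p = numeric(0), complex_preferred = logical(0),
    status = character(0)
  )
  preferred <- candidates[1]
  if (!fits[[preferred]]$converged) {
    abort("simplest candidate did not converge; selection aborted")
  }
  for (i in seq_along(candidates)[-1]) {
    simpler <- preferred
    complex <- candidates[i]
    f1 <- fits[[simpler]]; f2 <- fits[[complex]]
    if (!f2$converged) {
      chain <- dplyr::bind_rows(chain, tibble::tibble(
        simpler = simpler, complex = complex,
        SS1 = f1$ss, DF1 = f1$df, SS2 = NA_real_, DF2 = f2$df,
        F = NA_real_, p = NA_real_, complex_preferred = FALSE,
        status = "not_converged"
      ))
      next
    }
    test <- extra_ss_f(f1$ss, f1$df, f2$ss, f2$df)
    take_complex <- is.finite(test$p) && test$p <= alpha
    chain <- dplyr::bind_rows(chain, tibble::tibble(
      simpler = simpler, complex = complex,
      SS1 = f1$ss, DF1 = f1$df, SS2 = f2$ss, DF2 = f2$df,
      F = test$F, p = test$p, complex_preferred = take_complex,
      status = "ok"
    ))
    if (take_complex) preferred <- complex
  }
  structure(list(
    parameter = parameter, candidates = candidates, fits = fits,
    chain = chain, preferred = preferred,
    preferred_fit = fits[[preferred]], alpha = alpha, range = range
  ), class = "gait_model_selection")
}

#' @export
print.gait_model_selection <- function(x, ...) {
  cat("<gait_model_selection> ", x$parameter, ": preferred model = ",
      x$preferred, "\n", sep = "")
  print(as.data.frame(x$chain), digits = 4)
  invisible(x)
}

#' Scan velocity-range restrictions for model stability
#'
#' Systematically omits increasing ranges of the slowest velocities (lower
#' bound 0, 1, 2, ... cm/s) and/or of the highest velocities (upper bound
#' 25, 24, ... cm/s), re-running model selection on each restriction. The
#' report supports choosing a walking range over which the preferred model is
#' stable; no automatic "best range" decision is made. The default mouse
#' walking range is \[3, 16\] cm/s.
#'
#' @inheritParams select_gait_model
#' @param lower_bounds Candidate lower bounds (cm/s).
#' @param upper_bounds Candidate upper bounds (cm/s).
#' @return A tibble with one row per (lower, upper) pair: point count,
#'   preferred family, its SS, SS per point, diagnostics p-values, and a
#'   status (`"ok"` or `"skipped"` when a restriction leaves too little
#'   data).
#' @export
scan_velocity_ranges <- function(data, parameter,
                                 candidates = c("linear", "one_phase",
                                                "two_phase"),
                                 lower_bounds = 0:8,
                                 upper_bounds = 25:16,
                                 alpha = 0.05, n_starts = 10, seed = NULL) {
  grid <- expand.grid(lower = lower_bounds, upper = upper_bounds)
  grid <- grid[grid$lower < grid$upper, , drop = FALSE]
  rows <- purrr::pmap(grid, function(lower, upper) {
    sel <- tryCatch(
      select_gait_model(data, parameter, candidates,
                        range = c(lower, upper), alpha = alpha,
                        n_starts = n_starts, seed = seed),
      error = function(e) NULL
    )
    if (is.null(sel)) {
      return(tibble::tibble(
        lower = lower, upper = upper, n = NA_integer_,
        preferred = NA_character_, ss = NA_real_, ss_per_point = NA_real_,
        runs_test_p = NA_real_, normality_p = NA_real_, status = "skipped"
      ))
    }
    fit <- sel$preferred_fit
    tibble::tibble(
      lower = lower, upper = upper, n = fit$n,
      preferred = sel$preferred, ss = fit$ss, ss_per_point = fit$ss / fit$n,
      runs_test_p = fit$diagnostics$runs_test_p,
      normality_p = fit$diagnostics$normality_p, status = "ok"
    )
  })
  dplyr::bind_rows(rows)
}
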