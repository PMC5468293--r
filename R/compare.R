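#' Test whether two stride datasets share one velocity-dependence curve
#'
#' The core gait-signature-shift detector. The chosen model family is fitted
#' three times — to dataset A, to dataset B, and to the pooled data — and the
#' shared-curve hypothesis is tested by the extra sum-of-squares F-statistic
#'
#' \deqn{F = \frac{(SS_{combined} - (SS_A + SS_B)) /
#'   (DF_{combined} - (DF_A + DF_B))}{(SS_A + SS_B) / (DF_A + DF_B)}}
#'
#' A p-value below `alpha` means the datasets are so different that they are
#' best described by two separate curves: the intervention changed the gait
#' parameter beyond what its velocity change predicts (a signature shift).
#' `p > alpha` means one curve fits both (`shared = TRUE`).
#'
#' The same family is imposed on both groups and on the pooled fit; choose it
#' upstream with [select_gait_model()] on baseline data. When both separate
#' fits are perfect (SS = 0) the statistic degenerates; the result is
#' reported as F = Inf, p = 0 with a `degenerate` flag rather than an error,
#' since tiny toy datasets hit this.
#'
#' @param table_a,table_b Stride tables for the two conditions.
#' @param parameter Response column name.
#' @inheritParams fit_gait_curve
#' @param alpha Significance level for declaring separate curves
#'   (default 0.05).
#' @return A `gait_comparison` object: the three fits, all SS/DF fields, F,
#'   its numerator/denominator degrees of freedom, p, the `shared` flag and —
#'   when the curves are not shared — a per-parameter shift summary with
#'   approximate 95% Wald confidence intervals on the A-vs-B estimate
#'   differences.
#' @export
#' @examples
#' base <- simulate_gait_cohort(n_subjects = 6, strides_per_trial = 10, seed = 3)
#' shifted <- add_parameter_offset(base, "stride_length_mm", 5)
#' cmp <- compare_gait_curves(base, shifted, "stride_length_mm", "linear")
#' glance(cmp)
compare_gait_curves <- function(table_a, table_b, parameter,
                                family = c("linear", "one_phase",
                                           "two_phase"),
                                range = c(3, 16),
                                transform = c("identity", "log"),
                                alpha = 0.05, n_starts = 10, seed = NULL) {
  family <- rlang::arg_match(family)
  transform <- rlang::arg_match(transform)
  fit_a <- fit_gait_curve(table_a, parameter, family, range = range,
                          transform = transform, n_starts = n_starts,
                          seed = seed)
  fit_b <- fit_gait_curve(table_b, parameter, family, range = range,
                          transform = transform, n_starts = n_starts,
                          seed = seed)
  pooled <- dplyr::bind_rows(
    tibble::as_tibble(table_a)[, c("stride_velocity_cm_s", parameter)],
    tibble::as_tibble(table_b)[, c("stride_velocity_cm_s", parameter)]
  )
  fit_c <- fit_gait_curve(pooled, parameter, family, range = range,
                          transform = transform, n_starts = n_starts,
                          seed = seed)
  if (!fit_a$converged || !fit_b$converged || !fit_c$converged) {
    abort("comparison refused: at least one of the three fits did not converge")
  }
  ss_sep <- fit_a$ss + fit_b$ss
  df_sep <- fit_a$df + fit_b$df
  df_num <- fit_c$df - df_sep  # equals the family's parameter count
  # perfect separate fits (SS numerically zero at the response scale)
  scale_ss <- max(fit_c$ss, 1)
  degenerate <- ss_sep <= 1e-12 * scale_ss
  if (degenerate) {
    shared_perfect <- fit_c$ss <= 1e-12 * scale_ss
    f <- if (shared_perfect) 0 else Inf
    p <- if (shared_perfect) 1 else 0
  } else {
    f <- ((fit_c$ss - ss_sep) / df_num) / (ss_sep / df_sep)
    if (f < 0) f <- 0
    p <- pf(f, df_num, df_sep, lower.tail = FALSE)
  }
  shared <- p > alpha
  shift_summary <- NULL
  if (!shared) shift_summary <- shift_summary_table(fit_a, fit_b)
  structure(list(
    parameter = parameter, family = family, transform = transform,
    range = range, alpha = alpha,
    fit_a = fit_a, fit_b = fit_b, fit_combined = fit_c,
    ss_a = fit_a$ss, ss_b = fit_b$ss, ss_combined = fit_c$ss,
    df_a = fit_a$df, df_b = fit_b$df, df_combined = fit_c$df,
    F = f, df_num = df_num, df_den = df_sep, p = p,
    shared = shared, degenerate = degenerate,
    shift_summary = shift_summary
  ), class = "gait_comparison")
}

# per-parameter estimate differences (B - A) with approximate Wald CIs
shift_summary_table <- function(fit_a, fit_b, level = 0.95) {
  diff <- fit_b$coefficients - fit_a$coefficients
  se <- sqrt(fit_a$se^2 + fit_b$se^2)
  crit <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    term = names(diff),
    estimate_a = unname(fit_a$coefficients),
    estimate_b = unname(fit_b$coefficients),
    difference = unname(diff),
    se = unname(se),
    conf_low = unname(diff - crit * se),
    conf_high = unname(diff + crit * se)
  )
}

#' @export
print.gait_comparison <- function(x, ...) {
  cat("<gait_comparison> ", x$parameter, " ~ ", x$family, " on [",
      x$range[1], ", ", x$range[2], "] cm/s\n", sep = "")
  cat("  SS_A = ", signif(x$ss_a, 6), ", SS_B = ", signif(x$ss_b, 6),
      ", SS_combined = ", signif(x$ss_combined, 6), "\n", sep = "")
  cat("  F(", x$df_num, ", ", x$df_den, ") = ", signif(x$F, 5),
      ", p = ", format.pval(x$p, digits = 4), "\n", sep = "")
  cat(if (x$shared) "  one curve fits both datasets (no signature shift)\n"
      else "  separate curves required (gait signature shift)\n")
  if (!is.null(x$shift_summary)) {
    cat("  shift summary (B - A):\n")
    print(as.data.frame(x$shift_summary), digits = 4)
  }
  invisible(x)
}

#' All pairwise shared-curve tests among several datasets
#'
#' Runs [compare_gait_curves()] for every pair of named stride tables. No
#' family-wise adjustment is applied by default (each pairwise shared-curve
#' decision stands on its own); pass `alpha = 0.001` for a conservative
#' criterion.
#'
#' @param tables A named list of stride tables (>= 2).
#' @inheritParams compare_gait_curves
#' @return A tibble with one row per pair (`a`, `b`, F, degrees of freedom,
#'   p, `shared`) and the full `gait_comparison` objects in a list column
#'   `comparison`.
#' @export
compare_gait_groups <- function(tables, parameter,
                                family = c("linear", "one_phase",
                                           "two_phase"),
                                range = c(3, 16),
                                transform = c("identity", "log"),
                                alpha = 0.05, n_starts = 10, seed = NULL) {
  stopifnot(is.list(tables), length(tables) >= 2)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste0("group_", seq_along(tables))
  }
  pairs <- utils::combn(names(tables), 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(pr) {
    cmp <- compare_gait_curves(tables[[pr[1]]], tables[[pr[2]]], parameter,
                               family = family, range = range,
                               transform = transform, alpha = alpha,
                               n_starts = n_starts, seed = seed)
    tibble::tibble(a = pr[1], b = pr[2], F = cmp$F, df_num = cmp$df_num,
                   df_den = cmp$df_den, p = cmp$p, shared = cmp$shared,
                   comparison = list(cmp))
  })
  dplyr::bind_rows(rows)
}

#' Describe how a gait signature shifted
#'
#' For a comparison that rejected the shared curve, labels the shift from the
#' per-parameter difference confidence intervals. For the linear family the
#' label is `"intercept-shift"`, `"slope-shift"`, `"intercept-and-slope-shift"`
#' or `"indeterminate"` (significant F but no single coefficient CI excludes
#' zero); for the exponential families the raw parameter differences are
#' reported without a canonical label.
#'
#' @param comparison A `gait_comparison` with `shared = FALSE`.
#' @return A list with `label` and the `shift_summary` tibble.
#' @export
classify_shift <- function(comparison) {
  stopifnot(inherits(comparison, "gait_comparison"))
  if (comparison$shared) {
    abort("classify_shift requires a comparison that rejected the shared curve")
  }
  ss <- comparison$shift_summary
  excl0 <- ss$conf_low > 0 | ss$conf_high < 0
  if (comparison$family != "linear") {
    return(list(label = "nonlinear-parameter-shift", shift_summary = ss,
                terms_shifted = ss$term[excl0]))
  }
  int_moved <- excl0[ss$term == "intercept"]
  slope_moved <- excl0[ss$term == "slope"]
  label <- if (int_moved && slope_moved) "intercept-and-slope-shift"
  else if (int_moved) "intercept-shift"
  else if (slope_moved) "slope-shift"
  else "indeterminate"
  list(label = label, shift_summary = ss, terms_shifted = ss$term[excl0])
}
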