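#' Read and write stride tables as CSV
#'
#' The stride CSV schema has one row per stride with units baked into the
#' column names: `subject_id, trial_id, paw, cue, stride_velocity_cm_s,
#' stride_length_mm, stride_s, swing_s, stance_s, cadence_per_s,
#' swing_speed_mm_s` and optional `base_width_mm`. Comma-separated, header
#' mandatory, UTF-8, decimal point. Reading validates the stride identities
#' and warns with the offending row numbers when a velocity / length /
#' duration inconsistency exceeds tolerance.
#'
#' @param path File path.
#' @param tol Relative tolerance for the identity consistency check on read.
#' @return `read_stride_csv()` returns a [stride_table()];
#'   `write_stride_csv()` returns `path` invisibly.
#' @export
read_stride_csv <- function(path, tol = 1e-4) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(STRIDE_COLUMNS, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("stride CSV ", path, " is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  num_cols <- setdiff(STRIDE_COLUMNS, c("subject_id", "trial_id", "paw", "cue"))
  for (col in num_cols) {
    if (!is.numeric(x[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(x[[col]]))) &
                     !is.na(x[[col]]))
      abort(paste0("non-numeric values in column ", col, " at row(s): ",
                   paste(head(bad, 5), collapse = ", ")))
    }
  }
  x$subject_id <- as.character(x$subject_id)
  x$trial_id <- as.character(x$trial_id)
  # consistency check: velocity vs length/duration
  expected_v <- x$stride_length_mm / 10 / x$stride_s
  rel <- abs(x$stride_velocity_cm_s - expected_v) / pmax(abs(expected_v), 1e-12)
  bad <- which(rel > tol)
  if (length(bad) > 0) {
    warn(paste0(
      "stride velocity inconsistent with length/duration beyond tolerance ",
      "in row(s): ", paste(head(bad, 10), collapse = ", ")
    ))
  }
  stride_table(x, validate = FALSE)
}

#' @rdname read_stride_csv
#' @param table A stride table.
#' @export
write_stride_csv <- function(table, path) {
  table <- tibble::as_tibble(table)
  cols <- c(STRIDE_COLUMNS, intersect("base_width_mm", names(table)))
  readr::write_csv(table[, cols], path, progress = FALSE)
  invisible(path)
}

#' Read a footfall-event CSV
#'
#' Schema: one row per paw-lift/paw-land event with columns `subject_id,
#' trial_id, paw, swing_onset_s, swing_offset_s, touchdown_mm`, optional
#' `lateral_mm` and `cue`.
#'
#' @param path File path.
#' @return A tibble of footfall events ready for [strides_from_footfalls()].
#' @export
read_footfall_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("subject_id", "trial_id", "paw", "swing_onset_s",
                "swing_offset_s", "touchdown_mm")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("footfall CSV ", path, " is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in c("swing_onset_s", "swing_offset_s", "touchdown_mm")) {
    if (!is.numeric(x[[col]])) {
      abort(paste0("non-numeric values in column ", col))
    }
  }
  x$subject_id <- as.character(x$subject_id)
  x$trial_id <- as.character(x$trial_id)
  tibble::as_tibble(x)
}

#' Serialize analysis results to JSON
#'
#' Writes fits, model selections and curve comparisons (or plain lists) to a
#' versioned JSON report. Fit objects include family, estimates, standard
#' errors, SS, DF, n, range and diagnostics.
#'
#' @param results A `gait_fit`, `gait_model_selection`, `gait_comparison`,
#'   or a (possibly nested) list of them.
#' @param path Output file.
#' @param seed Optional seed to record in the report.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(results, path, seed = NULL) {
  payload <- list(
    schema = "gaitsig-results",
    schema_version = "1.0",
    package_version = as.character(utils::packageVersion("gaitsig")),
    seed = seed,
    results = serialize_result(results)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

serialize_result <- function(x) {
  if (inherits(x, "gait_fit")) {
    return(list(
      type = "gait_fit", parameter = x$parameter, family = x$family,
      transform = x$transform,
      estimates = as.list(x$coefficients), se = as.list(x$se),
      ss = x$ss, df = x$df, n = x$n, range = x$range,
      converged = x$converged, diagnostics = x$diagnostics
    ))
  }
  if (inherits(x, "gait_model_selection")) {
    return(list(
      type = "gait_model_selection", parameter = x$parameter,
      preferred = x$preferred, alpha = x$alpha,
      chain = x$chain,
      fits = lapply(x$fits, serialize_result)
    ))
  }
  if (inherits(x, "gait_comparison")) {
    return(list(
      type = "gait_comparison", parameter = x$parameter, family = x$family,
      ss_a = x$ss_a, ss_b = x$ss_b, ss_combined = x$ss_combined,
      df_a = x$df_a, df_b = x$df_b, df_combined = x$df_combined,
      F = x$F, df_num = x$df_num, df_den = x$df_den, p = x$p,
      alpha = x$alpha, shared = x$shared, degenerate = x$degenerate,
      shift_summary = x$shift_summary,
      fits = list(a = serialize_result(x$fit_a),
                  b = serialize_result(x$fit_b),
                  combined = serialize_result(x$fit_combined))
    ))
  }
  if (is.list(x) && !is.data.frame(x)) return(lapply(x, serialize_result))
  x
}
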