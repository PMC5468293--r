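#' Construct and validate a stride table
#'
#' A stride table is a tibble with one row per stride carrying the full
#' spatiotemporal parameter set: `subject_id`, `trial_id`, `paw`, `cue`
#' (`"uncued"`, `"olfactory"` or `"touch"`), `stride_velocity_cm_s`,
#' `stride_length_mm`, `stride_s`, `swing_s`, `stance_s`, `cadence_per_s`,
#' `swing_speed_mm_s` and optionally `base_width_mm`. Units are baked into the
#' column names so centimetres and millimetres cannot be silently confused.
#'
#' Five identities tie the columns together and are enforced by
#' [validate_stride_table()]:
#' stride = swing + stance, velocity = length / duration (with the mm-to-cm
#' factor), cadence = 1 / duration, and swing speed = length / swing.
#'
#' @param x A data frame with the columns listed above.
#' @param frame_rate Video frame rate in frames/s, or `NA` when strides were
#'   not derived from frame-quantised footfalls. Stored as an attribute and
#'   used as the tolerance (one frame period) for the additive identity.
#' @param validate Check the stride identities (default `TRUE`).
#' @return A tibble of class `stride_table`.
#' @export
#' @examples
#' tab <- simulate_gait_cohort(n_subjects = 2, strides_per_trial = 5, seed = 1)
#' stride_table(tab)
stride_table <- function(x, frame_rate = NA_real_, validate = TRUE) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(STRIDE_COLUMNS, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "stride table is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (!"base_width_mm" %in% names(x)) x$base_width_mm <- NA_real_
  x$base_width_mm <- as.numeric(x$base_width_mm)
  x$cue <- as.character(x$cue)
  bad_cue <- setdiff(unique(x$cue), CUE_LEVELS)
  if (length(bad_cue) > 0) {
    abort(paste0("unknown cue value(s): ", paste(bad_cue, collapse = ", ")))
  }
  out <- structure(x, class = c("stride_table", class(tibble::tibble())))
  attr(out, "frame_rate") <- frame_rate
  if (validate) validate_stride_table(out)
  out
}

#' @rdname stride_table
#' @param tol Relative tolerance for the ratio identities (velocity, cadence,
#'   swing speed). The additive identity stride = swing + stance is checked to
#'   one frame period when `frame_rate` is known, otherwise to `tol` of the
#'   stride duration.
#' @export
validate_stride_table <- function(x, tol = 1e-6) {
  stopifnot(is.data.frame(x))
  if (nrow(x) == 0) return(invisible(x))
  pos_cols <- c("stride_length_mm", "stride_s", "swing_s", "stance_s")
  for (col in pos_cols) {
    if (any(!is.finite(x[[col]]) | x[[col]] <= 0)) {
      abort(paste0("non-positive or missing values in ", col))
    }
  }
  frame_rate <- attr(x, "frame_rate") %||% NA_real_
  add_tol <- if (is.finite(frame_rate)) 1 / frame_rate else tol * max(x$stride_s)
  viol <- which(abs(x$stride_s - (x$swing_s + x$stance_s)) > add_tol + 1e-12)
  if (length(viol) > 0) {
    abort(paste0(
      "stride != swing + stance beyond tolerance in row(s): ",
      paste(head(viol, 5), collapse = ", ")
    ))
  }
  check_ratio <- function(observed, expected, label) {
    rel <- abs(observed - expected) / pmax(abs(expected), .Machine$double.eps)
    bad <- which(rel > tol)
    if (length(bad) > 0) {
      abort(paste0(
        label, " inconsistent beyond tolerance in row(s): ",
        paste(head(bad, 5), collapse = ", ")
      ))
    }
  }
  # stride_length is mm, velocity cm/s: 1 cm = 10 mm
  check_ratio(x$stride_velocity_cm_s, x$stride_length_mm / 10 / x$stride_s,
              "stride_velocity_cm_s")
  check_ratio(x$cadence_per_s, 1 / x$stride_s, "cadence_per_s")
  check_ratio(x$swing_speed_mm_s, x$stride_length_mm / x$swing_s,
              "swing_speed_mm_s")
  invisible(x)
}

#' Recompute the derived stride columns from length, velocity and swing
#'
#' Re-derives `stride_s`, `stance_s`, `cadence_per_s` and `swing_speed_mm_s`
#' from `stride_length_mm`, `stride_velocity_cm_s` and `swing_s`, so the five
#' stride identities hold exactly. Used after any manipulation that changes
#' one of the primary columns.
#'
#' @param x A stride table (or any data frame with the primary columns).
#' @return `x` with the derived columns replaced.
#' @export
rederive_strides <- function(x) {
  x$stride_s <- x$stride_length_mm / (10 * x$stride_velocity_cm_s)
  x$stance_s <- x$stride_s - x$swing_s
  x$cadence_per_s <- 1 / x$stride_s
  x$swing_speed_mm_s <- x$stride_length_mm / x$swing_s
  if (any(x$stance_s <= 0)) {
    abort("re-derivation produced non-positive stance durations")
  }
  x
}
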