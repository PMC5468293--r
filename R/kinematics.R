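#' Derive stride-to-stride gait parameters from footfall events
#'
#' Converts marked footfall events (swing onset, swing offset and touchdown
#' position per paw) into one stride record per consecutive event pair of the
#' same paw within a trial. A stride runs from one swing onset to the next
#' swing onset of the same paw, so stride duration = swing duration + stance
#' duration holds exactly:
#' * swing duration = swing offset - swing onset of the leading event,
#' * stride duration = next swing onset - current swing onset,
#' * stance duration = next swing onset - current swing offset,
#' * stride length = distance between consecutive touchdown positions.
#'
#' Velocity (cm/s), cadence (strides/s) and swing speed (mm/s) follow from the
#' stride identities. A paw with a single event yields no stride; that is not
#' an error.
#'
#' @param events A data frame of footfall events with columns `subject_id`,
#'   `trial_id`, `paw`, `swing_onset_s`, `swing_offset_s`, `touchdown_mm`,
#'   optionally `lateral_mm` and `cue` (default `"uncued"`).
#' @param frame_rate Frames/s of the source video; stored on the result and
#'   used as the quantisation tolerance for identity checks. `NA` for
#'   continuous-time input.
#' @param drop_boundary_strides Drop the first and last stride of each
#'   subject/trial/paw series, excluding starting and stopping steps
#'   (default `FALSE`).
#' @return A [stride_table()] with one row per stride.
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   subject_id = "m1", trial_id = "t1", paw = "LH",
#'   swing_onset_s = c(0, 0.5), swing_offset_s = c(0.1, 0.6),
#'   touchdown_mm = c(70, 140)
#' )
#' strides_from_footfalls(ev)
strides_from_footfalls <- function(events, frame_rate = NA_real_,
                                   drop_boundary_strides = FALSE) {
  events <- tibble::as_tibble(events)
  required <- c("subject_id", "trial_id", "paw", "swing_onset_s",
                "swing_offset_s", "touchdown_mm")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols) > 0) {
    abort(paste0("footfall events missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"cue" %in% names(events)) events$cue <- "uncued"
  if (!"lateral_mm" %in% names(events)) events$lateral_mm <- NA_real_

  bad <- which(events$swing_offset_s <= events$swing_onset_s)
  if (length(bad) > 0) {
    abort(paste0(
      "swing offset must follow swing onset; offending event row(s): ",
      paste(head(bad, 5), collapse = ", ")
    ))
  }

  per_paw <- function(df) {
    df <- df[order(df$swing_onset_s), , drop = FALSE]
    n <- nrow(df)
    if (n < 2) return(NULL)
    # next swing onset must not precede the current swing offset
    overlap <- which(df$swing_onset_s[-1] < df$swing_offset_s[-n])
    if (length(overlap) > 0) {
      abort(paste0(
        "overlapping swing phases for subject ", df$subject_id[1],
        " trial ", df$trial_id[1], " paw ", df$paw[1],
        " at event ", overlap[1] + 1
      ))
    }
    swing <- df$swing_offset_s[-n] - df$swing_onset_s[-n]
    stride <- df$swing_onset_s[-1] - df$swing_onset_s[-n]
    stance <- df$swing_onset_s[-1] - df$swing_offset_s[-n]
    len <- abs(df$touchdown_mm[-1] - df$touchdown_mm[-n])
    tibble::tibble(
      subject_id = df$subject_id[-n],
      trial_id = df$trial_id[-n],
      paw = df$paw[-n],
      cue = df$cue[-n],
      stride_velocity_cm_s = len / 10 / stride,
      stride_length_mm = len,
      stride_s = stride,
      swing_s = swing,
      stance_s = stance,
      cadence_per_s = 1 / stride,
      swing_speed_mm_s = len / swing,
      base_width_mm = NA_real_
    )
  }

  groups <- split(
    events,
    interaction(events$subject_id, events$trial_id, events$paw, drop = TRUE)
  )
  strides <- dplyr::bind_rows(lapply(groups, per_paw))
  if (nrow(strides) == 0) {
    empty <- tibble::as_tibble(stats::setNames(
      rep(list(character(0)), 4), c("subject_id", "trial_id", "paw", "cue")
    ))
    for (col in c("stride_velocity_cm_s", "stride_length_mm", "stride_s",
                  "swing_s", "stance_s", "cadence_per_s", "swing_speed_mm_s",
                  "base_width_mm")) {
      empty[[col]] <- numeric(0)
    }
    return(stride_table(empty, frame_rate = frame_rate, validate = FALSE))
  }
  if (drop_boundary_strides) {
    strides <- strides |>
      dplyr::group_by(.data$subject_id, .data$trial_id, .data$paw) |>
      dplyr::filter(dplyr::n() > 2,
                    dplyr::row_number() > 1,
                    dplyr::row_number() < dplyr::n()) |>
      dplyr::ungroup()
  }
  strides <- dplyr::arrange(strides, .data$subject_id, .data$trial_id,
                            .data$paw)
  stride_table(strides, frame_rate = frame_rate)
}

#' Apply the trial-level inclusion filters
#'
#' Removes trials with fewer than `min_strides` strides and (optionally) all
#' touch-cued strides, whose runway traversals are too erratic to analyse.
#' Olfactory-cued strides are retained but counted, so the cueing composition
#' of a cohort can be reported. Also optionally caps the number of retained
#' trials per subject (runway protocols analyse a fixed number of trials per
#' mouse and condition).
#'
#' @param table A stride table.
#' @param min_strides Minimum strides a trial must contain (default 3).
#' @param exclude_touch_cued Drop touch-cued strides before counting
#'   (default `TRUE`).
#' @param trials_per_subject Maximum retained trials per subject (first by
#'   trial id); `Inf` keeps all. Default 4.
#' @return The filtered stride table with attribute `"filter_report"`: a list
#'   with the number of touch-cued strides removed, short trials removed,
#'   trials capped, and the percentage of uncued / olfactory / touch strides
#'   in the input.
#' @export
filter_trials <- function(table, min_strides = 3, exclude_touch_cued = TRUE,
                          trials_per_subject = 4) {
  table <- tibble::as_tibble(table)
  n_in <- nrow(table)
  cue_counts <- table(factor(table$cue, levels = CUE_LEVELS))
  cue_pct <- if (n_in > 0) 100 * as.numeric(cue_counts) / n_in else rep(0, 3)
  names(cue_pct) <- CUE_LEVELS

  touch_removed <- 0L
  if (exclude_touch_cued) {
    touch_removed <- sum(table$cue == "touch")
    table <- dplyr::filter(table, .data$cue != "touch")
  }

  trial_sizes <- table |>
    dplyr::count(.data$subject_id, .data$trial_id)
  short <- dplyr::filter(trial_sizes, .data$n < min_strides)
  table <- dplyr::anti_join(table, short,
                            by = c("subject_id", "trial_id"))

  trials_capped <- 0L
  if (is.finite(trials_per_subject)) {
    keep <- table |>
      dplyr::distinct(.data$subject_id, .data$trial_id) |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::slice_head(n = trials_per_subject) |>
      dplyr::ungroup()
    n_trials_before <- nrow(dplyr::distinct(table, .data$subject_id,
                                            .data$trial_id))
    trials_capped <- n_trials_before - nrow(keep)
    table <- dplyr::semi_join(table, keep, by = c("subject_id", "trial_id"))
  }

  report <- list(
    n_input_strides = n_in,
    n_output_strides = nrow(table),
    touch_cued_strides_removed = touch_removed,
    short_trials_removed = nrow(short),
    trials_capped = trials_capped,
    cue_percent = cue_pct,
    empty_output = nrow(table) == 0
  )
  if (report$empty_output && n_in > 0) {
    warn("all strides removed by trial filters")
  }
  out <- stride_table(table, frame_rate = attr(table, "frame_rate") %||% NA_real_,
                      validate = FALSE)
  attr(out, "filter_report") <- report
  out
}

#' Derive per-trial human gait parameters from trial averages
#'
#' Instrumented-walkway human recordings report trial-average gait speed,
#' stride duration and swing duration; the remaining spatiotemporal
#' parameters follow arithmetically: stride length = gait speed x stride
#' duration, stance = stride - swing, cadence = 1/stride duration, swing
#' speed = stride length / swing duration, plus the natural log of stance
#' duration (stance is analysed on the log scale in humans).
#'
#' @param data A data frame with columns `gait_speed_m_s`, `stride_s`,
#'   `swing_s` (one row per subject-trial; any id columns are carried
#'   through).
#' @return A tibble with the input columns plus `stride_length_m`, `stance_s`,
#'   `cadence_per_s`, `cadence_steps_min` (2 steps per stride),
#'   `swing_speed_m_s` and `log_stance`.
#' @export
#' @examples
#' human_trial_params(tibble::tibble(
#'   gait_speed_m_s = 1.2, stride_s = 1.1, swing_s = 0.44
#' ))
human_trial_params <- function(data) {
  data <- tibble::as_tibble(data)
  required <- c("gait_speed_m_s", "stride_s", "swing_s")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(data$gait_speed_m_s <= 0 | data$stride_s <= 0 | data$swing_s <= 0)) {
    abort("gait speed and durations must be strictly positive")
  }
  if (any(data$swing_s >= data$stride_s)) {
    abort("swing duration must be shorter than stride duration")
  }
  data |>
    dplyr::mutate(
      stride_length_m = .data$gait_speed_m_s * .data$stride_s,
      stance_s = .data$stride_s - .data$swing_s,
      cadence_per_s = 1 / .data$stride_s,
      cadence_steps_min = 120 / .data$stride_s,
      swing_speed_m_s = .data$stride_length_m / .data$swing_s,
      log_stance = log(.data$stance_s)
    )
}
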