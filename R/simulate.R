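#' Default generating curves for the synthetic stride generator
#'
#' Plausible, explicitly synthetic parameter-versus-velocity curves shaped
#' like real mouse runway data (saturating stride length, shallowly
#' decreasing swing duration); they are not estimates from any recorded
#' cohort. Stride length (mm) follows a one-phase association and swing
#' duration (s) a shallow negative linear trend; stance duration, stride
#' duration, cadence and swing speed are then derived so the stride
#' identities hold exactly, which automatically yields a decreasing stance
#' curve and an increasing cadence curve.
#'
#' @return A named list with one entry per generated parameter:
#'   `family`, `pars`, `noise_sd`.
#' @export
default_generating_curves <- function() {
  list(
    stride_length_mm = list(
      family = "one_phase",
      pars = c(Y0 = 30, Plateau = 80, K = 0.15),
      noise_sd = 3
    ),
    swing_s = list(
      family = "linear",
      pars = c(intercept = 0.14, slope = -0.0025),
      noise_sd = 0.008
    )
  )
}

# inverse-CDF draw from a normal truncated to [lower, upper]
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm((lower - mean) / sd)
  phi <- pnorm((upper - mean) / sd)
  mean + sd * qnorm(runif(n, plo, phi))
}

# mean of the truncated normal, for moment checks
truncnorm_mean <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / (pnorm(b) - pnorm(a))
}

#' Simulate a cohort of stride-to-stride gait data
#'
#' Generates synthetic mouse runway data with the statistical structure the
#' velocity-dependence analyses assume. Stride velocities are drawn from a
#' truncated normal (default mean 9 cm/s, SD 6 cm/s — typical of mouse
#' walking — truncated to the walking range \[3, 16\] cm/s); stride length
#' and swing duration are each a generating curve of velocity plus additive
#' Gaussian noise; stride duration, stance duration, cadence and swing speed
#' are derived so every stride identity holds exactly. Subjects contribute
#' `trials_per_subject` trials of `strides_per_trial` strides each. Output is
#' fully reproducible from `seed`.
#'
#' @param n_subjects Number of subjects (default 6).
#' @param trials_per_subject Trials per subject (default 4).
#' @param strides_per_trial Strides per trial (default 10).
#' @param velocity_mean,velocity_sd Mean and SD (cm/s) of the underlying
#'   normal velocity distribution (defaults 9 and 6).
#' @param velocity_range Truncation interval (cm/s), default `c(3, 16)`.
#' @param curves Generating curves as returned by
#'   [default_generating_curves()]; entries for `stride_length_mm` and
#'   `swing_s` with `family`, `pars` and `noise_sd`.
#' @param seed Integer seed (required for reproducibility; default 1).
#' @return A [stride_table()].
#' @export
#' @examples
#' tab <- simulate_gait_cohort(n_subjects = 3, seed = 42)
#' dplyr::count(tab, subject_id, trial_id)
simulate_gait_cohort <- function(n_subjects = 6, trials_per_subject = 4,
                                 strides_per_trial = 10,
                                 velocity_mean = 9, velocity_sd = 6,
                                 velocity_range = c(3, 16),
                                 curves = default_generating_curves(),
                                 seed = 1) {
  stopifnot(n_subjects >= 1, trials_per_subject >= 1, strides_per_trial >= 1,
            velocity_sd > 0, length(velocity_range) == 2,
            velocity_range[1] < velocity_range[2])
  for (nm in c("stride_length_mm", "swing_s")) {
    if (is.null(curves[[nm]])) {
      abort(paste0("generating curves must include ", nm))
    }
    if (curves[[nm]]$noise_sd < 0) abort("noise_sd must be non-negative")
  }
  # reject configs whose curves go non-positive anywhere in range
  v_probe <- seq(velocity_range[1], velocity_range[2], length.out = 101)
  for (nm in c("stride_length_mm", "swing_s")) {
    cv <- curves[[nm]]
    if (any(model_predict(cv$family, cv$pars, v_probe) <= 0)) {
      abort(paste0("generating curve for ", nm,
                   " is non-positive inside the velocity range"))
    }
  }
  n <- n_subjects * trials_per_subject * strides_per_trial
  tab <- withr::with_seed(seed, {
    v <- rtruncnorm(n, velocity_mean, velocity_sd,
                    velocity_range[1], velocity_range[2])
    draw <- function(nm) {
      cv <- curves[[nm]]
      mu <- model_predict(cv$family, cv$pars, v)
      val <- mu + rnorm(n, 0, cv$noise_sd)
      # resample the rare draws that violate positivity or ordering
      val
    }
    len <- pmax(draw("stride_length_mm"), 1)
    stride_s <- len / (10 * v)
    # keep durations physical at noise tails: swing strictly inside (0, stride)
    swing <- pmin(pmax(draw("swing_s"), 1e-3), 0.9 * stride_s)
    tibble::tibble(
      subject_id = rep(sprintf("s%02d", seq_len(n_subjects)),
                       each = trials_per_subject * strides_per_trial),
      trial_id = rep(rep(sprintf("t%d", seq_len(trials_per_subject)),
                         each = strides_per_trial), times = n_subjects),
      paw = "LH",
      cue = "uncued",
      stride_velocity_cm_s = v,
      stride_length_mm = len,
      swing_s = swing
    )
  })
  tab <- rederive_strides(tab)
  tab$base_width_mm <- NA_real_
  stride_table(tab[, c(STRIDE_COLUMNS, "base_width_mm")])
}

#' Convert a stride table back into footfall events
#'
#' Inverse of [strides_from_footfalls()]: lays the strides of each
#' subject/trial/paw series end to end along the time and runway axes so that
#' re-deriving strides reproduces the original records (up to one frame
#' period when times are quantised to frames).
#'
#' @param table A stride table.
#' @param frame_rate Optional frames/s; when given, event times are rounded
#'   to the frame grid, emulating video-scored footfalls.
#' @return A tibble of footfall events.
#' @export
footfalls_from_strides <- function(table, frame_rate = NA_real_) {
  table <- tibble::as_tibble(table)
  per_series <- function(df) {
    k <- nrow(df)
    onsets <- c(0, cumsum(df$stride_s))
    offsets <- onsets[seq_len(k)] + df$swing_s
    # event i's touchdown; stride i spans touchdowns i -> i+1
    touchdowns <- c(0, cumsum(df$stride_length_mm))
    last_offset <- onsets[k + 1] + df$swing_s[k]  # terminal event needs an offset
    tibble::tibble(
      subject_id = df$subject_id[1], trial_id = df$trial_id[1],
      paw = df$paw[1], cue = c(df$cue, df$cue[k]),
      swing_onset_s = onsets,
      swing_offset_s = c(offsets, last_offset),
      touchdown_mm = touchdowns
    )
  }
  groups <- split(table,
                  interaction(table$subject_id, table$trial_id, table$paw,
                              drop = TRUE))
  events <- dplyr::bind_rows(lapply(groups, per_series))
  if (is.finite(frame_rate)) {
    events$swing_onset_s <- round(events$swing_onset_s * frame_rate) / frame_rate
    events$swing_offset_s <- round(events$swing_offset_s * frame_rate) / frame_rate
  }
  tibble::as_tibble(events)
}

#' Split a stride table into slow and fast halves with overlapping velocities
#'
#' The "velocity change without quality change" construction: one random
#' quarter of the records goes to the fast group and one random quarter to
#' the slow group, while the remaining half is ranked by stride velocity and
#' split, slower half to slow, faster half to fast. The two groups then
#' differ in velocity but share the same parameter-versus-velocity curve, so
#' a shared-curve test should not reject. Remainders of the division by four
#' stay with the ranked half; an odd ranked half sends its extra record to
#' the slow group.
#'
#' @param table A stride table with at least 8 records.
#' @param seed Integer seed for the random quarter assignment.
#' @return A named list `list(slow = , fast = )` of stride tables that
#'   partition the input.
#' @export
split_by_velocity <- function(table, seed = 1) {
  table <- tibble::as_tibble(table)
  n <- nrow(table)
  if (n < 8) abort("velocity split requires at least 8 records")
  q <- floor(n / 4)
  idx <- withr::with_seed(seed, sample.int(n, 2 * q))
  fast_idx <- idx[seq_len(q)]
  slow_idx <- idx[q + seq_len(q)]
  rest <- setdiff(seq_len(n), idx)
  rest <- rest[order(table$stride_velocity_cm_s[rest])]
  n_slow_rest <- ceiling(length(rest) / 2)
  slow_idx <- c(slow_idx, rest[seq_len(n_slow_rest)])
  fast_idx <- c(fast_idx, rest[-seq_len(n_slow_rest)])
  list(slow = table[sort(slow_idx), , drop = FALSE],
       fast = table[sort(fast_idx), , drop = FALSE])
}

#' Add a fixed offset to one gait parameter
#'
#' The "quality change" construction: shifts the named parameter by `delta`
#' in every record, emulating an intervention that changes the parameter out
#' of proportion to velocity. By default velocity is held fixed (the shifted
#' values are analysed against the original stride velocities) and the
#' dependent columns are re-derived so the stride identities still hold;
#' with `hold_velocity = FALSE` the stride duration is kept and velocity is
#' recomputed instead.
#'
#' @param table A stride table.
#' @param parameter One of `"stride_length_mm"` or `"swing_s"` (the primary
#'   columns; derived columns follow from the identities).
#' @param delta Offset in the parameter's units.
#' @param hold_velocity Keep stride velocity fixed and re-derive durations
#'   (default `TRUE`).
#' @return The shifted stride table.
#' @export
add_parameter_offset <- function(table, parameter, delta,
                                 hold_velocity = TRUE) {
  table <- tibble::as_tibble(table)
  if (!parameter %in% c("stride_length_mm", "swing_s")) {
    abort("offsets apply to the primary columns stride_length_mm or swing_s")
  }
  shifted <- table[[parameter]] + delta
  if (any(shifted <= 0)) {
    abort("offset would produce non-positive parameter values")
  }
  table[[parameter]] <- shifted
  if (parameter == "stride_length_mm" && !hold_velocity) {
    # keep the temporal record, let velocity absorb the length change
    table$stride_velocity_cm_s <- table$stride_length_mm / (10 * table$stride_s)
    table$swing_speed_mm_s <- table$stride_length_mm / table$swing_s
    return(stride_table(table))
  }
  stride_table(rederive_strides(table))
}

#' Signature-shift specifications and presets
#'
#' A shift specification transforms one gait parameter record-wise as
#' `y -> intercept_delta + slope_scale * y`. With `preserve_intercept = TRUE`
#' the intercept term is augmented by `(1 - slope_scale) * b0`, where `b0` is
#' the intercept of a linear fit of the parameter against velocity in the
#' table being shifted, so only the velocity dependence (the slope) changes —
#' the curve still passes through its original value at v = 0.
#'
#' Presets emulate the two classic parkinsonism phenotypes: `"mptp"`
#' (bilateral dopaminergic loss) shortens stride length by a fixed intercept
#' drop of 8 mm, which at matched velocities also raises cadence through the
#' stride identities; `"6ohda"` (unilateral nigral lesion) flattens the
#' velocity dependence of stride length (slope scaled to 0.8) without moving
#' its intercept.
#'
#' @param parameter Gait parameter column to shift.
#' @param intercept_delta Additive shift in response units (default 0).
#' @param slope_scale Multiplicative scaling of the response (> 0, default 1).
#' @param preserve_intercept Compensate the intercept so only the slope
#'   changes (default `FALSE`).
#' @return A `shift_spec` list.
#' @export
shift_spec <- function(parameter, intercept_delta = 0, slope_scale = 1,
                       preserve_intercept = FALSE) {
  if (slope_scale <= 0) abort("slope_scale must be strictly positive")
  structure(list(parameter = parameter, intercept_delta = intercept_delta,
                 slope_scale = slope_scale,
                 preserve_intercept = preserve_intercept),
            class = "shift_spec")
}

#' @rdname shift_spec
#' @param name `"mptp"` or `"6ohda"`.
#' @export
shift_preset <- function(name = c("mptp", "6ohda")) {
  name <- rlang::arg_match(name)
  switch(name,
    mptp = list(shift_spec("stride_length_mm", intercept_delta = -8)),
    `6ohda` = list(shift_spec("stride_length_mm", slope_scale = 0.8,
                              preserve_intercept = TRUE))
  )
}

#' Apply signature shifts to a stride table
#'
#' Applies one or more [shift_spec()] transformations (or a [shift_preset()])
#' to a stride table, optionally re-drawing fresh Gaussian noise on the
#' shifted parameter, then re-derives the dependent columns at fixed
#' velocity so the stride identities hold. An empty shift list returns the
#' table unchanged.
#'
#' @param table A stride table.
#' @param shifts A list of `shift_spec` objects (possibly empty).
#' @param noise_sd Optional named numeric: SD of fresh noise re-drawn on each
#'   shifted parameter (default none).
#' @param seed Seed for the noise re-draw.
#' @return The shifted stride table.
#' @export
apply_signature_shift <- function(table, shifts, noise_sd = NULL, seed = 1) {
  table <- tibble::as_tibble(table)
  if (length(shifts) == 0) return(stride_table(table))
  for (sh in shifts) {
    stopifnot(inherits(sh, "shift_spec"))
    pm <- sh$parameter
    if (!pm %in% c("stride_length_mm", "swing_s")) {
      abort("signature shifts apply to stride_length_mm or swing_s")
    }
    delta <- sh$intercept_delta
    if (sh$preserve_intercept && sh$slope_scale != 1) {
      b0 <- unname(coef(lm(table[[pm]] ~ table$stride_velocity_cm_s))[1])
      delta <- delta + (1 - sh$slope_scale) * b0
    }
    val <- delta + sh$slope_scale * table[[pm]]
    if (!is.null(noise_sd) && !is.null(noise_sd[[pm]])) {
      val <- withr::with_seed(seed,
                              val + rnorm(length(val), 0, noise_sd[[pm]]))
    }
    if (any(val <= 0)) abort("shift would produce non-positive values")
    table[[pm]] <- val
  }
  stride_table(rederive_strides(table))
}
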