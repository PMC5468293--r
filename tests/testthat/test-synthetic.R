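test_that("the generator is deterministic and zero-noise records lie on the curves", {
  a <- simulate_gait_cohort(n_subjects = 3, seed = 8)
  b <- simulate_gait_cohort(n_subjects = 3, seed = 8)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c_ <- simulate_gait_cohort(n_subjects = 3, seed = 9)
  expect_false(identical(a$stride_velocity_cm_s, c_$stride_velocity_cm_s))

  curves <- default_generating_curves()
  curves$stride_length_mm$noise_sd <- 0
  curves$swing_s$noise_sd <- 0
  zero <- simulate_gait_cohort(n_subjects = 2, strides_per_trial = 10,
                               curves = curves, seed = 4)
  mu_len <- model_predict("one_phase", curves$stride_length_mm$pars,
                          zero$stride_velocity_cm_s)
  mu_swing <- model_predict("linear", curves$swing_s$pars,
                            zero$stride_velocity_cm_s)
  expect_equal(zero$stride_length_mm, mu_len, tolerance = 1e-12)
  expect_equal(zero$swing_s, mu_swing, tolerance = 1e-12)
})

test_that("sampled velocities match the truncated-normal moment oracle", {
  tab <- simulate_gait_cohort(n_subjects = 10, strides_per_trial = 10,
                              seed = 12)  # 400 strides
  v <- tab$stride_velocity_cm_s
  expect_true(all(v >= 3 & v <= 16))
  mu <- gaitsig:::truncnorm_mean(9, 6, 3, 16)
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - mu), 3 * se)
})

test_that("generator output satisfies the stride identities and rejects bad configs", {
  tab <- simulate_gait_cohort(n_subjects = 4, seed = 14)
  expect_silent(validate_stride_table(stride_table(tab)))
  bad <- default_generating_curves()
  bad$swing_s$pars <- c(intercept = 0.01, slope = -0.01)  # negative in range
  expect_error(simulate_gait_cohort(curves = bad, seed = 1), "non-positive")
})

test_that("parameter recovery holds for all three generating families", {
  n <- 400
  # the two-phase case needs both phases visible, so its velocities span the
  # full runway speed range rather than the restricted walking range
  cases <- list(
    list(family = "linear", pars = c(intercept = 35, slope = 2.5), sd = 3,
         vlim = c(3, 16), range = c(3, 16)),
    list(family = "one_phase", pars = c(Y0 = 30, Plateau = 80, K = 0.15),
         sd = 3, vlim = c(3, 16), range = c(3, 16)),
    list(family = "two_phase",
         pars = c(Y0 = 20, SpanFast = 40, KFast = 1.2,
                  SpanSlow = 60, KSlow = 0.08), sd = 1,
         vlim = c(0.2, 20), range = c(0, 20))
  )
  for (cs in cases) {
    withr::with_seed(15, v <- runif(n, cs$vlim[1], cs$vlim[2]))
    withr::with_seed(16, {
      y <- model_predict(cs$family, cs$pars, v) + rnorm(n, 0, cs$sd)
    })
    tab <- tibble::tibble(stride_velocity_cm_s = v, stride_length_mm = y)
    fit <- fit_gait_curve(tab, "stride_length_mm", cs$family,
                          range = cs$range, seed = 2)
    expect_true(fit$converged)
    z <- abs(fit$coefficients - cs$pars[names(fit$coefficients)]) / fit$se
    expect_true(all(z < 3), label = paste(cs$family, "recovery within 3 SE"))
  }
})

test_that("the velocity split partitions records with the prescribed structure", {
  tab <- simulate_gait_cohort(n_subjects = 5, strides_per_trial = 5,
                              seed = 18)  # 100 strides
  sp <- split_by_velocity(tab, seed = 3)
  expect_equal(nrow(sp$slow), 50)
  expect_equal(nrow(sp$fast), 50)
  # disjoint union of the input
  joined <- dplyr::bind_rows(sp$slow, sp$fast)
  expect_equal(
    dplyr::arrange(joined, subject_id, trial_id, stride_velocity_cm_s),
    dplyr::arrange(tibble::as_tibble(tab), subject_id, trial_id,
                   stride_velocity_cm_s)
  )
  expect_lt(mean(sp$slow$stride_velocity_cm_s),
            mean(sp$fast$stride_velocity_cm_s))
  # every ranked-half record below the split point lands in the slow group:
  # reconstruct the random quarters from the seed
  n <- nrow(tab); q <- floor(n / 4)
  idx <- withr::with_seed(3, sample.int(n, 2 * q))
  rest <- setdiff(seq_len(n), idx)
  rest <- rest[order(tab$stride_velocity_cm_s[rest])]
  slow_ranked <- rest[seq_len(ceiling(length(rest) / 2))]
  key <- paste(tab$subject_id, tab$trial_id, tab$stride_velocity_cm_s)
  slow_keys <- paste(sp$slow$subject_id, sp$slow$trial_id,
                     sp$slow$stride_velocity_cm_s)
  expect_true(all(key[slow_ranked] %in% slow_keys))
  expect_error(split_by_velocity(tab[1:7, ], seed = 1), "at least 8")
})

test_that("parameter offsets shift records exactly and preserve the identities", {
  tab <- simulate_gait_cohort(n_subjects = 3, seed = 22)
  same <- add_parameter_offset(tab, "stride_length_mm", 0)
  expect_equal(same$stride_length_mm, tab$stride_length_mm)
  off <- add_parameter_offset(tab, "stride_length_mm", 5)
  expect_equal(off$stride_length_mm - tab$stride_length_mm,
               rep(5, nrow(tab)))
  # velocity held fixed by default; durations re-derived consistently
  expect_equal(off$stride_velocity_cm_s, tab$stride_velocity_cm_s)
  expect_silent(validate_stride_table(stride_table(off)))
  # alternative: keep the temporal record and let velocity move
  off_v <- add_parameter_offset(tab, "stride_length_mm", 5,
                                hold_velocity = FALSE)
  expect_equal(off_v$stride_s, tab$stride_s)
  expect_false(isTRUE(all.equal(off_v$stride_velocity_cm_s,
                                tab$stride_velocity_cm_s)))
  expect_error(add_parameter_offset(tab, "stride_length_mm", -1000),
               "non-positive")
})

test_that("signature-shift presets produce the advertised shift classes", {
  base <- simulate_gait_cohort(n_subjects = 8, strides_per_trial = 12,
                               seed = 26)
  expect_equal(
    tibble::as_tibble(apply_signature_shift(base, list())),
    tibble::as_tibble(stride_table(tibble::as_tibble(base)))
  )
  lesion_6ohda <- apply_signature_shift(base, shift_preset("6ohda"))
  cmp6 <- compare_gait_curves(base, lesion_6ohda, "stride_length_mm",
                              "linear")
  expect_false(cmp6$shared)
  expect_equal(classify_shift(cmp6)$label, "slope-shift")

  lesion_mptp <- apply_signature_shift(base, shift_preset("mptp"))
  cmp_m <- compare_gait_curves(base, lesion_mptp, "stride_length_mm",
                               "linear")
  expect_false(cmp_m$shared)
  shifted_terms <- classify_shift(cmp_m)$label
  expect_true(shifted_terms %in% c("intercept-shift",
                                   "intercept-and-slope-shift"))
  # shorter strides at matched velocity raise cadence
  expect_true(mean(lesion_mptp$cadence_per_s) > mean(base$cadence_per_s))
})
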