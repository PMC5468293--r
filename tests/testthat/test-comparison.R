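toy_pair <- function() {
  a <- tibble::tibble(stride_velocity_cm_s = c(4, 8, 12, 16),
                      stride_length_mm = c(40, 52, 58, 70))
  b <- tibble::tibble(stride_velocity_cm_s = c(4, 8, 12, 16),
                      stride_length_mm = c(46, 58, 64, 76))
  list(a = a, b = b)
}

test_that("identical datasets share one curve with F = 0", {
  tab <- simulate_gait_cohort(n_subjects = 4, strides_per_trial = 10,
                              seed = 19)
  cmp <- compare_gait_curves(tab, tab, "stride_length_mm", "linear")
  expect_equal(cmp$F, 0)
  expect_equal(cmp$p, 1)
  expect_true(cmp$shared)
  expect_equal(cmp$ss_combined, cmp$ss_a + cmp$ss_b, tolerance = 1e-8)
})

test_that("the shared-curve F and p match a closed-form OLS oracle on toy data", {
  tp <- toy_pair()
  # the package's linear fit requires >= 7 points per group, so replicate
  # each toy point 3x (leaves the OLS estimates unchanged but scales SS/DF);
  # the oracle computes all three regressions and the F by hand
  rep3 <- function(tab) tab[rep(seq_len(nrow(tab)), each = 3), ]
  a3 <- rep3(tp$a); b3 <- rep3(tp$b)
  oa <- ols_oracle(a3$stride_velocity_cm_s, a3$stride_length_mm)
  ob <- ols_oracle(b3$stride_velocity_cm_s, b3$stride_length_mm)
  pooled <- dplyr::bind_rows(a3, b3)
  oc <- ols_oracle(pooled$stride_velocity_cm_s, pooled$stride_length_mm)
  f_oracle <- ((oc$ss - (oa$ss + ob$ss)) / (oc$df - (oa$df + ob$df))) /
    ((oa$ss + ob$ss) / (oa$df + ob$df))
  p_oracle <- pf(f_oracle, oc$df - oa$df - ob$df, oa$df + ob$df,
                 lower.tail = FALSE)
  res <- compare_gait_curves(a3, b3, "stride_length_mm", "linear",
                             range = c(3, 16))
  expect_equal(res$ss_a, oa$ss, tolerance = 1e-8)
  expect_equal(res$ss_b, ob$ss, tolerance = 1e-8)
  expect_equal(res$ss_combined, oc$ss, tolerance = 1e-8)
  expect_equal(res$F, f_oracle, tolerance = 1e-8)
  expect_equal(res$p, p_oracle, tolerance = 1e-8)
  expect_equal(res$df_num, 2)  # one linear curve fitted once vs twice
  # the stored fields reproduce the statistic by brute force exactly
  expect_equal(res$F,
               ((res$ss_combined - (res$ss_a + res$ss_b)) /
                  (res$df_combined - (res$df_a + res$df_b))) /
                 ((res$ss_a + res$ss_b) / (res$df_a + res$df_b)))
})

test_that("comparison is symmetric in its arguments", {
  base <- simulate_gait_cohort(n_subjects = 4, strides_per_trial = 10,
                               seed = 23)
  shifted <- add_parameter_offset(base, "stride_length_mm", 3)
  ab <- compare_gait_curves(base, shifted, "stride_length_mm", "linear")
  ba <- compare_gait_curves(shifted, base, "stride_length_mm", "linear")
  expect_equal(ab$F, ba$F, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
})

test_that("separate fits never do worse than the shared fit on their own data", {
  for (s in 1:5) {
    a <- simulate_gait_cohort(n_subjects = 3, strides_per_trial = 8,
                              seed = 100 + s)
    b <- apply_signature_shift(
      simulate_gait_cohort(n_subjects = 3, strides_per_trial = 8,
                           seed = 200 + s),
      shift_preset("mptp")
    )
    cmp <- compare_gait_curves(a, b, "stride_length_mm", "one_phase",
                               seed = 1)
    expect_gte(cmp$ss_combined, cmp$ss_a + cmp$ss_b - 1e-6)
  }
})

test_that("a perfect-fit comparison is flagged degenerate instead of erroring", {
  v <- seq(3, 16, length.out = 10)
  a <- tibble::tibble(stride_velocity_cm_s = v,
                      stride_length_mm = 30 + 2 * v)
  b <- tibble::tibble(stride_velocity_cm_s = v,
                      stride_length_mm = 40 + 2 * v)
  cmp <- compare_gait_curves(a, b, "stride_length_mm", "linear")
  expect_true(cmp$degenerate)
  expect_equal(cmp$p, 0)
  expect_false(cmp$shared)
})

test_that("pairwise group comparisons flag only the shifted group", {
  base <- simulate_gait_cohort(n_subjects = 6, strides_per_trial = 10,
                               seed = 31)
  gfp_like <- simulate_gait_cohort(n_subjects = 6, strides_per_trial = 10,
                                   seed = 32)
  shifted <- add_parameter_offset(
    simulate_gait_cohort(n_subjects = 6, strides_per_trial = 10, seed = 33),
    "stride_length_mm", -8
  )
  res <- compare_gait_groups(
    list(baseline = base, gfp = gfp_like, lesioned = shifted),
    "stride_length_mm", "linear"
  )
  expect_equal(nrow(res), 3)
  expect_true(res$shared[res$a == "baseline" & res$b == "gfp"])
  expect_false(res$shared[res$a == "baseline" & res$b == "lesioned"])
  expect_false(res$shared[res$a == "gfp" & res$b == "lesioned"])
  # three identical tables all share
  same <- compare_gait_groups(list(x = base, y = base, z = base),
                              "stride_length_mm", "linear")
  expect_true(all(same$shared))
})

test_that("a conservative alpha flips a borderline shared decision", {
  # constructed borderline pair: small offset, moderate n, p between the
  # liberal (0.05) and conservative (0.001) criteria
  found <- FALSE
  for (s in 1:30) {
    a <- simulate_gait_cohort(n_subjects = 3, strides_per_trial = 8,
                              seed = 400 + s)
    b <- add_parameter_offset(
      simulate_gait_cohort(n_subjects = 3, strides_per_trial = 8,
                           seed = 500 + s),
      "stride_length_mm", 2
    )
    cmp <- compare_gait_curves(a, b, "stride_length_mm", "linear")
    if (cmp$p > 0.001 && cmp$p < 0.05) {
      found <- TRUE
      liberal <- compare_gait_curves(a, b, "stride_length_mm", "linear",
                                     alpha = 0.05)
      conservative <- compare_gait_curves(a, b, "stride_length_mm", "linear",
                                          alpha = 0.001)
      expect_false(liberal$shared)
      expect_true(conservative$shared)
      break
    }
  }
  expect_true(found)
})

test_that("shift classification labels intercept and slope changes correctly", {
  base <- simulate_gait_cohort(n_subjects = 8, strides_per_trial = 12,
                               seed = 41)
  # pure offset -> intercept shift
  off <- add_parameter_offset(base, "stride_length_mm", 5)
  cmp_off <- compare_gait_curves(base, off, "stride_length_mm", "linear")
  expect_false(cmp_off$shared)
  expect_equal(classify_shift(cmp_off)$label, "intercept-shift")
  # slope scaled, intercept preserved -> slope shift
  sloped <- apply_signature_shift(base, list(
    shift_spec("stride_length_mm", slope_scale = 0.7,
               preserve_intercept = TRUE)
  ))
  cmp_slope <- compare_gait_curves(base, sloped, "stride_length_mm", "linear")
  expect_false(cmp_slope$shared)
  expect_equal(classify_shift(cmp_slope)$label, "slope-shift")
  # classification refuses a shared result
  cmp_same <- compare_gait_curves(base, base, "stride_length_mm", "linear")
  expect_error(classify_shift(cmp_same), "shared")
})
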