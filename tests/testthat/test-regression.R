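make_xy_table <- function(v, y, parameter = "stride_length_mm") {
  tab <- tibble::tibble(stride_velocity_cm_s = v)
  tab[[parameter]] <- y
  tab
}

test_that("velocity-range restriction is a closed interval with an exclusion report", {
  tab <- make_xy_table(c(2, 3, 10, 16, 17), c(1, 2, 3, 4, 5))
  out <- restrict_velocity_range(tab, c(3, 16))
  expect_equal(out$stride_velocity_cm_s, c(3, 10, 16))
  rep_ <- attr(out, "range_report")
  expect_equal(rep_$excluded_slow, 1)
  expect_equal(rep_$excluded_fast, 1)
  # unbounded range is the identity
  all_in <- restrict_velocity_range(tab, c(0, Inf))
  expect_equal(nrow(all_in), 5)
  # exclusion counts match the velocity histogram tails of a known sample
  tab2 <- simulate_gait_cohort(n_subjects = 5, strides_per_trial = 10,
                               velocity_range = c(0.5, 30), seed = 5)
  out2 <- restrict_velocity_range(tab2, c(3, 16))
  r2 <- attr(out2, "range_report")
  expect_equal(r2$excluded_slow, sum(tab2$stride_velocity_cm_s < 3))
  expect_equal(r2$excluded_fast, sum(tab2$stride_velocity_cm_s > 16))
})

test_that("linear fits match the closed-form least-squares oracle to 1e-8 relative", {
  withr::with_seed(42, {
    v <- runif(60, 3, 16)
    y <- 35 + 2.8 * v + rnorm(60, 0, 2)
  })
  tab <- make_xy_table(v, y)
  fit <- fit_gait_curve(tab, "stride_length_mm", "linear")
  oracle <- ols_oracle(v, y)
  expect_equal(unname(fit$coefficients["intercept"]), oracle$intercept,
               tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["slope"]), oracle$slope,
               tolerance = 1e-8)
  expect_equal(fit$ss, oracle$ss, tolerance = 1e-8)
  expect_equal(fit$df, oracle$df)
})

test_that("exactly collinear points give a perfect linear fit", {
  v <- seq(3, 16, length.out = 12)
  tab <- make_xy_table(v, 2 + 0.5 * v)
  fit <- fit_gait_curve(tab, "stride_length_mm", "linear")
  expect_equal(unname(fit$coefficients), c(2, 0.5), tolerance = 1e-10)
  expect_lt(fit$ss, 1e-18)
})

test_that("one-phase fits recover generating parameters within 3 standard errors", {
  truth <- c(Y0 = 30, Plateau = 75, K = 0.25)
  withr::with_seed(7, {
    v <- runif(400, 3, 16)
    y <- model_predict("one_phase", truth, v) + rnorm(400, 0, 3)
  })
  fit <- fit_gait_curve(make_xy_table(v, y), "stride_length_mm", "one_phase")
  expect_true(fit$converged)
  z <- abs(fit$coefficients - truth) / fit$se
  expect_true(all(z < 3))
})

test_that("fit preconditions are enforced by name", {
  few <- make_xy_table(seq(3, 16, length.out = 6),
                       30 + seq(3, 16, length.out = 6))
  expect_error(fit_gait_curve(few, "stride_length_mm", "one_phase"),
               "insufficient points")
  narrow <- make_xy_table(seq(8, 11, length.out = 30), rnorm(30, 50, 2))
  expect_error(fit_gait_curve(narrow, "stride_length_mm", "linear",
                              range = c(3, 16)),
               "span")
})

test_that("fitted parameters are a local SS optimum", {
  tab <- simulate_gait_cohort(n_subjects = 5, strides_per_trial = 10,
                              seed = 13)
  fit <- fit_gait_curve(tab, "stride_length_mm", "one_phase", seed = 1)
  v <- fit$data$velocity
  y <- fit$data$response
  withr::with_seed(77, {
    for (i in 1:100) {
      pert <- fit$coefficients * (1 + rnorm(3, 0, 0.02))
      pert["K"] <- max(pert["K"], 1e-6)
      ss_pert <- sum((y - model_predict("one_phase", pert, v))^2)
      expect_gte(ss_pert, fit$ss - 1e-8)
    }
  })
})

test_that("one-phase predictions converge to a straight line as K -> 0", {
  # with (Plateau - Y0) * K held fixed, the small-K limit is y = Y0 + c * v
  v <- seq(3, 16, length.out = 50)
  y0 <- 30; rate_slope <- 0.5  # limiting slope c = (Plateau - Y0) * K
  k <- 1e-6
  pars <- c(Y0 = y0, Plateau = y0 + rate_slope / k, K = k)
  pred <- model_predict("one_phase", pars, v)
  expect_true(all(abs(pred - (y0 + rate_slope * v)) < 1e-4))
})

test_that("the model-selection F follows the nested-SS arithmetic and prefers simplicity", {
  # arithmetic check on the selection statistic
  expect_equal(brute_force_f(100, 98, 80, 97), 24.25)
  # SS1 = SS2: no improvement, F = 0, p = 1
  tab <- make_xy_table(seq(3, 16, length.out = 40),
                       2 + 0.5 * seq(3, 16, length.out = 40))
  sel <- select_gait_model(tab, "stride_length_mm",
                           candidates = c("linear", "one_phase"), seed = 1)
  expect_equal(sel$preferred, "linear")
  # every chain row reproduces the F statistic from its stored SS/DF exactly
  withr::with_seed(3, {
    v <- runif(120, 3, 16)
    y <- model_predict("one_phase", c(Y0 = 30, Plateau = 80, K = 0.3), v) +
      rnorm(120, 0, 2)
  })
  sel2 <- select_gait_model(make_xy_table(v, y), "stride_length_mm", seed = 1)
  ok <- sel2$chain$status == "ok" & sel2$chain$SS1 >= sel2$chain$SS2
  expect_true(any(ok))
  expect_equal(
    sel2$chain$F[ok],
    brute_force_f(sel2$chain$SS1[ok], sel2$chain$DF1[ok],
                  sel2$chain$SS2[ok], sel2$chain$DF2[ok])
  )
  expect_equal(sel2$preferred, "one_phase")
})

test_that("straight-line data prefers the linear model in most replicates", {
  n_rep <- 50
  prefs <- vapply(seq_len(n_rep), function(i) {
    withr::with_seed(1000 + i, {
      v <- runif(80, 3, 16)
      y <- 40 + 2 * v + rnorm(80, 0, 3)
    })
    select_gait_model(make_xy_table(v, y), "stride_length_mm",
                      seed = 1)$preferred
  }, character(1))
  expect_gte(mean(prefs == "linear"), 0.9)
})

test_that("the range scan marks unpopulated restrictions as skipped and detects curvature", {
  # linear on [3,16] but strongly curved below 3
  withr::with_seed(9, {
    v <- c(runif(150, 0.3, 3), runif(250, 3, 16))
    y <- ifelse(v < 3, 20 * (v / 3)^3 + 20, 20 + 2 * (v - 3) + 20) +
      rnorm(400, 0, 1.5)
  })
  tab <- make_xy_table(v, y)
  scan <- scan_velocity_ranges(tab, "stride_length_mm",
                               candidates = c("linear", "one_phase"),
                               lower_bounds = c(0, 3),
                               upper_bounds = c(25, 16), seed = 1)
  expect_true(all(c("ok") %in% scan$status))
  full <- scan[scan$lower == 0 & scan$upper == 25, ]
  restricted <- scan[scan$lower == 3 & scan$upper == 16, ]
  expect_equal(restricted$preferred, "linear")
  expect_false(full$preferred == "linear")
  # restricted SS per point does not exceed the full-range SS per point
  expect_lte(restricted$ss_per_point, full$ss_per_point)
  # a restriction leaving too narrow a span is skipped
  withr::with_seed(10, tab2 <- make_xy_table(runif(50, 3, 16),
                                             rnorm(50, 50, 2)))
  scan2 <- scan_velocity_ranges(tab2, "stride_length_mm",
                                candidates = "linear",
                                lower_bounds = c(3, 15),
                                upper_bounds = c(16), seed = 1)
  expect_equal(scan2$status[scan2$lower == 15], "skipped")
  expect_equal(scan2$status[scan2$lower == 3], "ok")
})

test_that("stance duration can be fitted on the log scale", {
  tab <- simulate_gait_cohort(n_subjects = 5, strides_per_trial = 10,
                              seed = 17)
  fit <- fit_gait_curve(tab, "stance_s", "linear", transform = "log")
  expect_equal(fit$transform, "log")
  expect_equal(fit$data$response,
               log(restrict_velocity_range(tab, c(3, 16))$stance_s))
})
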