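# fixture builders and independent oracles shared across the suite

# footfall events for a paw moving at exactly constant speed:
# equal time spacing and equal position spacing
constant_speed_events <- function(n_events = 6, stride_s = 0.5,
                                  swing_s = 0.1, stride_mm = 70,
                                  subject = "m1", trial = "t1", paw = "LH") {
  onsets <- (seq_len(n_events) - 1) * stride_s
  tibble::tibble(
    subject_id = subject, trial_id = trial, paw = paw,
    swing_onset_s = onsets,
    swing_offset_s = onsets + swing_s,
    touchdown_mm = (seq_len(n_events) - 1) * stride_mm
  )
}

# reconstruct a sample of size n with exactly the requested mean and sd
# (affine rescaling of an arbitrary base sample); oracle for summary t-tests
sample_with_moments <- function(mean, sd, n) {
  base <- seq_len(n)
  base <- (base - mean(base)) / stats::sd(base)
  mean + sd * base
}

# Monte-Carlo conditional runs-test oracle: permutes the observed signs and
# returns the two-sided permutation p for the run count
mc_runs_p <- function(signs, n_perm = 20000, seed = 99) {
  count_runs <- function(s) 1L + sum(s[-1] != s[-length(s)])
  r_obs <- count_runs(signs)
  withr::with_seed(seed, {
    r_null <- replicate(n_perm, count_runs(sample(signs)))
  })
  lower <- mean(r_null <= r_obs)
  upper <- mean(r_null >= r_obs)
  min(1, 2 * min(lower, upper))
}

# closed-form OLS oracle: intercept/slope and residual SS from the normal
# equations, independent of lm()
ols_oracle <- function(v, y) {
  n <- length(v)
  sxx <- sum((v - mean(v))^2)
  sxy <- sum((v - mean(v)) * (y - mean(y)))
  b1 <- sxy / sxx
  b0 <- mean(y) - b1 * mean(v)
  res <- y - b0 - b1 * v
  list(intercept = b0, slope = b1, ss = sum(res^2), df = n - 2)
}

# brute-force extra sum-of-squares F
brute_force_f <- function(ss1, df1, ss2, df2) {
  ((ss1 - ss2) / (df1 - df2)) / (ss2 / df2)
}
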