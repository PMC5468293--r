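#' Wald-Wolfowitz runs test on a sign sequence
#'
#' Tests whether the sequence of signs is random, i.e. free of systematic
#' clustering (too few runs, a lack-of-fit signature in residuals ordered by
#' the predictor) or systematic alternation (too many runs). Zeros are
#' dropped. The p-value is two-sided: twice the smaller conditional tail
#' probability of the run count given the numbers of positive and negative
#' signs, from the exact run-count distribution for n <= 200 and a normal
#' approximation beyond.
#'
#' When one sign is entirely absent the conditional distribution is
#' degenerate (the run count is always 1); the reported p-value then falls
#' back to the unconditional probability of a single run under fair
#' independent signs, `2^(1 - n)`, flagged in the result.
#'
#' @param x Numeric vector (signs are taken) or a logical/sign vector.
#' @return A list with `n_runs`, `n_pos`, `n_neg`, `p`, and `method`.
#' @export
runs_test <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  n <- length(s)
  if (n < 2) {
    return(list(n_runs = NA_integer_, n_pos = sum(s > 0), n_neg = sum(s < 0),
                p = NA_real_, method = "too few observations"))
  }
  r <- 1L + sum(s[-1] != s[-n])
  n1 <- sum(s > 0)
  n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0) {
    return(list(n_runs = r, n_pos = n1, n_neg = n2,
                p = min(1, 2^(1 - n)),
                method = "single-sign fallback (unconditional)"))
  }
  if (n <= 200) {
    probs <- exact_runs_distribution(n1, n2)
    lower <- sum(probs[seq_len(r)])
    upper <- sum(probs[r:length(probs)])
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- 1 + 2 * n1 * n2 / n
    sigma <- sqrt(2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1)))
    z <- (r - mu) / sigma
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(n_runs = r, n_pos = n1, n_neg = n2, p = p, method = method)
}

# exact conditional distribution of the run count given n1 positive and n2
# negative signs; returns P(R = r) for r = 1..(n1 + n2)
exact_runs_distribution <- function(n1, n2) {
  rmax <- n1 + n2
  probs <- numeric(rmax)
  denom <- lchoose(n1 + n2, n1)
  for (r in 2:min(rmax, 2 * min(n1, n2) + 1)) {
    if (r %% 2 == 0) {
      k <- r / 2
      probs[r] <- exp(log(2) + lchoose(n1 - 1, k - 1) +
                        lchoose(n2 - 1, k - 1) - denom)
    } else {
      k <- (r - 1) / 2
      probs[r] <- exp(lchoose(n1 - 1, k) + lchoose(n2 - 1, k - 1) - denom) +
        exp(lchoose(n1 - 1, k - 1) + lchoose(n2 - 1, k) - denom)
    }
  }
  probs
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Omnibus K-squared test combining a transformed-skewness statistic
#' (D'Agostino) and a transformed-kurtosis statistic (Anscombe-Glynn):
#' K2 = Z1^2 + Z2^2, referred to a chi-squared distribution with 2 degrees of
#' freedom. Requires at least 8 observations.
#'
#' @param x Numeric vector.
#' @return A list with `k2`, `z_skew`, `z_kurt`, `p`, `n`.
#' @export
dagostino_pearson_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) abort("D'Agostino-Pearson test requires at least 8 observations")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  if (m2 <= 0) abort("zero variance: normality test undefined")

  # transformed skewness (D'Agostino 1970)
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt(((n + 1) * (n + 3)) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # transformed kurtosis (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(k2 = k2, z_skew = z1, z_kurt = z2,
       p = pchisq(k2, df = 2, lower.tail = FALSE), n = n)
}

#' Residual diagnostics for a fitted gait curve
#'
#' Runs the Wald-Wolfowitz runs test on residual signs ordered by velocity
#' (lack-of-fit / systematic curvature check) and the D'Agostino-Pearson
#' omnibus normality test on the residuals. With fewer than 8 residuals the
#' normality test is refused (`NA`, flagged); the runs test is still
#' reported.
#'
#' @param fit A `gait_fit` object.
#' @return A list with `runs_test_p`, `normality_p` and `normality_refused`.
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "gait_fit"))
  dat <- fit$data[order(fit$data$velocity), ]
  rt <- runs_test(dat$residual)
  if (nrow(dat) < 8) {
    return(list(runs_test_p = rt$p, normality_p = NA_real_,
                normality_refused = TRUE))
  }
  dp <- dagostino_pearson_test(dat$residual)
  list(runs_test_p = rt$p, normality_p = dp$p, normality_refused = FALSE)
}
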