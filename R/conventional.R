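#' Two-sample t-test from group summaries
#'
#' Pooled-variance unpaired two-tailed t-test computed from means, standard
#' deviations and group sizes only — the form needed to check published
#' group contrasts when raw data are unavailable.
#'
#' @param mean_a,sd_a,n_a Summary of group A.
#' @param mean_b,sd_b,n_b Summary of group B.
#' @return A tibble with `t`, `df` (= n_a + n_b - 2) and the two-tailed `p`.
#' @export
#' @examples
#' # nose-to-tail body length, females vs males
#' t_from_summary(59.1, 2.3, 12, 66.9, 1.8, 12)
t_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) abort("both groups need n >= 2")
  if (sd_a < 0 || sd_b < 0) abort("standard deviations must be non-negative")
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
  t <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
  df <- n_a + n_b - 2
  tibble::tibble(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# normality gate shared by the routed comparisons; returns list(p, refused)
normality_gate <- function(x) {
  if (length(x) < 8) return(list(p = NA_real_, refused = TRUE))
  if (sd(x) == 0) return(list(p = NA_real_, refused = TRUE))
  list(p = dagostino_pearson_test(x)$p, refused = FALSE)
}

#' Normality-gated two-group comparison
#'
#' Each sample (or, for paired data, the within-pair differences) is first
#' screened with the D'Agostino-Pearson omnibus test; normally distributed
#' data are compared with a two-tailed t-test, otherwise with the
#' Mann-Whitney rank test (unpaired) or Wilcoxon signed-rank test (paired).
#' The routing decision is always reported, never silent. Samples too small
#' for the normality screen (n < 8) are routed to the rank test and flagged.
#'
#' @param x,y Numeric samples (equal length for the paired path).
#' @param gate_alpha Significance level of the normality screen
#'   (default 0.05).
#' @return A tibble with the test used, statistic, `p`, the normality screen
#'   p-values and a `routing` note.
#' @export
compare_unpaired <- function(x, y, gate_alpha = 0.05) {
  route_two_sample(x, y, paired = FALSE, gate_alpha = gate_alpha)
}

#' @rdname compare_unpaired
#' @export
compare_paired <- function(x, y, gate_alpha = 0.05) {
  if (length(x) != length(y)) abort("paired samples must have equal length")
  route_two_sample(x, y, paired = TRUE, gate_alpha = gate_alpha)
}

route_two_sample <- function(x, y, paired, gate_alpha) {
  if (paired) {
    d <- x - y
    if (sd(d) == 0) {
      return(tibble::tibble(
        test = "refused", statistic = NA_real_, p = NA_real_,
        normality_p_x = NA_real_, normality_p_y = NA_real_,
        routing = "zero-variance differences: no test applicable"
      ))
    }
    gate <- normality_gate(d)
    gates <- list(gate, gate)
  } else {
    gates <- list(normality_gate(x), normality_gate(y))
  }
  refused <- gates[[1]]$refused || gates[[2]]$refused
  normal <- !refused &&
    gates[[1]]$p >= gate_alpha && gates[[2]]$p >= gate_alpha
  if (normal) {
    ht <- t.test(x, y, paired = paired, var.equal = !paired)
    test <- if (paired) "paired t-test" else "unpaired t-test"
    routing <- "normality screen passed: t-test"
  } else {
    ht <- suppressWarnings(wilcox.test(x, y, paired = paired, exact = FALSE))
    test <- if (paired) "Wilcoxon signed-rank" else "Mann-Whitney rank test"
    routing <- if (refused) {
      "normality screen refused (n < 8 or zero variance): rank test"
    } else "normality screen failed: rank test"
  }
  tibble::tibble(
    test = test, statistic = unname(ht$statistic), p = ht$p.value,
    normality_p_x = gates[[1]]$p, normality_p_y = gates[[2]]$p,
    routing = routing
  )
}

#' Normality-gated multi-group comparison with pairwise follow-up
#'
#' Three or more groups are screened for normality; if every group passes,
#' one-way ANOVA is followed by Holm-Sidak-adjusted pairwise t-tests (pooled
#' error), otherwise Kruskal-Wallis is followed by Dunn's multiple comparison
#' test with a Sidak-style family correction, at a family-wise level of 0.05.
#' All pairwise adjusted p-values are reported.
#'
#' @param groups A named list of numeric samples (>= 3 groups, each n >= 3).
#' @param gate_alpha Normality-screen level (default 0.05).
#' @param family_alpha Family-wise significance level (default 0.05).
#' @return A list with the omnibus `test`, its statistic and p, the
#'   `routing` note, and a `pairwise` tibble of raw and adjusted p-values.
#' @export
compare_multi <- function(groups, gate_alpha = 0.05, family_alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 3)
  if (any(vapply(groups, length, integer(1)) < 3)) {
    abort("every group needs n >= 3")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group_", seq_along(groups))
  }
  gates <- lapply(groups, normality_gate)
  refused <- any(vapply(gates, `[[`, logical(1), "refused"))
  normal <- !refused &&
    all(vapply(gates, `[[`, numeric(1), "p") >= gate_alpha)
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), lengths(groups)),
                   levels = names(groups))
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  m <- length(pairs)

  if (normal) {
    fit <- aov(values ~ labels)
    an <- summary(fit)[[1]]
    omnibus <- list(test = "one-way ANOVA",
                    statistic = an$`F value`[1], p = an$`Pr(>F)`[1])
    mse <- an$`Mean Sq`[2]
    df_err <- an$Df[2]
    pw <- purrr::map(pairs, function(pr) {
      xa <- groups[[pr[1]]]; xb <- groups[[pr[2]]]
      se <- sqrt(mse * (1 / length(xa) + 1 / length(xb)))
      tstat <- (mean(xa) - mean(xb)) / se
      tibble::tibble(a = pr[1], b = pr[2], statistic = tstat,
                     p_raw = 2 * pt(-abs(tstat), df_err))
    })
    pw <- dplyr::bind_rows(pw)
    # Holm-Sidak: step-down Sidak adjustment, monotone in raw-p order
    ord <- order(pw$p_raw)
    adj <- numeric(m)
    running <- 0
    for (i in seq_len(m)) {
      a_i <- 1 - (1 - pw$p_raw[ord[i]])^(m - i + 1)
      running <- max(running, a_i)
      adj[ord[i]] <- min(1, running)
    }
    pw$p_adj <- adj
    routing <- "all groups passed the normality screen: ANOVA + Holm-Sidak"
  } else {
    kw <- kruskal.test(values ~ labels)
    omnibus <- list(test = "Kruskal-Wallis",
                    statistic = unname(kw$statistic), p = kw$p.value)
    # Dunn's test: rank-sum z with Sidak family correction
    n <- length(values)
    rk <- rank(values)
    ties <- table(rk)
    tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
    mean_ranks <- tapply(rk, labels, mean)
    sizes <- tapply(rk, labels, length)
    pw <- purrr::map(pairs, function(pr) {
      z <- (mean_ranks[[pr[1]]] - mean_ranks[[pr[2]]]) /
        sqrt((n * (n + 1) / 12 - tie_corr) *
               (1 / sizes[[pr[1]]] + 1 / sizes[[pr[2]]]))
      p_raw <- 2 * pnorm(-abs(z))
      tibble::tibble(a = pr[1], b = pr[2], statistic = z, p_raw = p_raw)
    })
    pw <- dplyr::bind_rows(pw)
    pw$p_adj <- pmin(1, 1 - (1 - pw$p_raw)^m)
    routing <- if (refused) {
      "normality screen refused for at least one group: Kruskal-Wallis + Dunn"
    } else "normality screen failed: Kruskal-Wallis + Dunn"
  }
  pw$significant <- pw$p_adj <= family_alpha
  list(test = omnibus$test, statistic = omnibus$statistic, p = omnibus$p,
       routing = routing, normality_p = vapply(gates, `[[`, numeric(1), "p"),
       pairwise = pw, family_alpha = family_alpha)
}

#' Sample size for a paired two-tailed t-test at exact noncentral-t power
#'
#' Smallest number of pairs whose two-tailed paired t-test attains the target
#' power against the standardized effect implied by pre/post summaries. The
#' mapping from the four summaries to a paired effect size is a convention,
#' exposed as a parameter because pre/post correlation is rarely published:
#' `"pooled"` (default) divides the mean change by the root mean square of
#' the two SDs, `"pre"` and `"post"` divide by the respective single SD.
#' Power is computed exactly from the noncentral t distribution
#' (noncentrality = effect x sqrt(n), df = n - 1), iterating n upward.
#'
#' @param mean_pre,sd_pre,mean_post,sd_post Pre/post summaries.
#' @param alpha Two-tailed type-I level (default 0.05).
#' @param power Target power (default 0.95).
#' @param effect_convention `"pooled"`, `"pre"` or `"post"`.
#' @return A tibble with the standardized `effect`, the required `n`, and
#'   the attained exact `power`.
#' @export
#' @examples
#' # open-field distance travelled, pre vs post lesion
#' paired_t_sample_size(21.4, 7.2, 11.6, 6.5)
paired_t_sample_size <- function(mean_pre, sd_pre, mean_post, sd_post,
                                 alpha = 0.05, power = 0.95,
                                 effect_convention = c("pooled", "pre",
                                                       "post")) {
  effect_convention <- rlang::arg_match(effect_convention)
  stopifnot(power > 0, power < 1, alpha > 0, alpha < 1)
  denom <- switch(effect_convention,
    pooled = sqrt((sd_pre^2 + sd_post^2) / 2),
    pre = sd_pre,
    post = sd_post
  )
  if (denom <= 0) abort("effect size undefined: zero standard deviation")
  effect <- abs(mean_pre - mean_post) / denom
  if (effect == 0) abort("zero effect: required sample size is infinite")
  exact_power <- function(n) {
    df <- n - 1
    ncp <- effect * sqrt(n)
    crit <- qt(1 - alpha / 2, df)
    pt(crit, df, ncp = ncp, lower.tail = FALSE) + pt(-crit, df, ncp = ncp)
  }
  n <- 2
  while (exact_power(n) < power && n < 1e6) n <- n + 1
  tibble::tibble(effect = effect, effect_convention = effect_convention,
                 n = n, power = exact_power(n), alpha = alpha,
                 target_power = power)
}
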