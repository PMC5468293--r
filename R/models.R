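# Model families for parameter-versus-velocity curves.
#
# linear:    y = b0 + b1 * v                                   (2 parameters)
# one_phase: y = Y0 + (Plateau - Y0) * (1 - exp(-K * v))       (3 parameters)
# two_phase: y = Y0 + SpanFast * (1 - exp(-KFast * v))
#               + SpanSlow * (1 - exp(-KSlow * v))             (5 parameters)
#
# These are the standard parameterizations of the saturating exponential
# ("one/two phase association") families used by commercial curve-fitting
# software, so fitted estimates are directly comparable with values reported
# from such software. Y0 is the response at v = 0; K (per cm/s) sets how
# quickly the curve approaches its plateau. Decreasing curves (e.g. stance
# duration) simply have Plateau < Y0 (or negative spans).

MODEL_FAMILIES <- c("linear", "one_phase", "two_phase")

model_par_names <- function(family) {
  switch(family,
    linear = c("intercept", "slope"),
    one_phase = c("Y0", "Plateau", "K"),
    two_phase = c("Y0", "SpanFast", "KFast", "SpanSlow", "KSlow"),
    abort(paste0("unknown model family: ", family))
  )
}

model_n_par <- function(family) length(model_par_names(family))

#' Evaluate a gait model family at given velocities
#'
#' @param family `"linear"`, `"one_phase"` or `"two_phase"`.
#' @param pars Named parameter vector (see [fit_gait_curve()] for the
#'   parameterizations).
#' @param v Stride velocities (cm/s).
#' @return Predicted response values.
#' @export
model_predict <- function(family, pars, v) {
  switch(family,
    linear = pars[["intercept"]] + pars[["slope"]] * v,
    one_phase = pars[["Y0"]] +
      (pars[["Plateau"]] - pars[["Y0"]]) * (1 - exp(-pars[["K"]] * v)),
    two_phase = pars[["Y0"]] +
      pars[["SpanFast"]] * (1 - exp(-pars[["KFast"]] * v)) +
      pars[["SpanSlow"]] * (1 - exp(-pars[["KSlow"]] * v)),
    abort(paste0("unknown model family: ", family))
  )
}

# bounds for the exponential rate constants (per cm/s)
K_LOWER <- 1e-6
K_UPPER <- 100

# For a fixed set of rate constants both exponential families are linear in
# the remaining parameters, so each multi-start begins from the exact
# conditional least-squares solution for that K (variable-projection style
# initialization); the full nonlinear refinement then runs on all parameters.
start_values <- function(family, v, y, n_starts) {
  k_grid <- exp(seq(log(0.05), log(2), length.out = max(n_starts, 2)))
  if (family == "one_phase") {
    lapply(k_grid, function(k) {
      X <- cbind(exp(-k * v), 1 - exp(-k * v))
      beta <- tryCatch(qr.solve(X, y), error = function(e) c(min(y), max(y)))
      c(Y0 = beta[1], Plateau = beta[2], K = k)
    })
  } else if (family == "two_phase") {
    pairs <- expand.grid(kf = k_grid, ks = k_grid)
    pairs <- pairs[pairs$kf > pairs$ks, , drop = FALSE]
    idx <- round(seq(1, nrow(pairs), length.out = min(n_starts, nrow(pairs))))
    lapply(idx, function(i) {
      kf <- pairs$kf[i]; ks <- pairs$ks[i]
      X <- cbind(1, 1 - exp(-kf * v), 1 - exp(-ks * v))
      beta <- tryCatch(qr.solve(X, y),
                       error = function(e) c(min(y), diff(range(y)) / 2,
                                             diff(range(y)) / 2))
      c(Y0 = beta[1], SpanFast = beta[2], KFast = kf,
        SpanSlow = beta[3], KSlow = ks)
    })
  } else {
    abort("start_values only applies to exponential families")
  }
}

model_bounds <- function(family) {
  nm <- model_par_names(family)
  lower <- setNames(rep(-Inf, length(nm)), nm)
  upper <- setNames(rep(Inf, length(nm)), nm)
  lower[grepl("^K", nm)] <- K_LOWER
  upper[grepl("^K", nm)] <- K_UPPER
  list(lower = lower, upper = upper)
}

# numerical Jacobian of the model surface at the solution, for Wald SEs
model_jacobian <- function(family, pars, v, eps = 1e-6) {
  p <- length(pars)
  J <- matrix(0, length(v), p)
  for (j in seq_len(p)) {
    h <- eps * max(abs(pars[j]), 1)
    up <- pars; up[j] <- up[j] + h
    dn <- pars; dn[j] <- dn[j] - h
    J[, j] <- (model_predict(family, up, v) - model_predict(family, dn, v)) /
      (2 * h)
  }
  colnames(J) <- names(pars)
  J
}

# core least-squares fit on velocity/response vectors; returns estimates,
# SS, covariance and convergence status
fit_xy <- function(v, y, family, n_starts = 10, seed = NULL) {
  n <- length(v)
  p <- model_n_par(family)
  if (family == "linear") {
    fit <- lm(y ~ v)
    pars <- setNames(coef(fit), c("intercept", "slope"))
    ss <- sum(residuals(fit)^2)
    vc <- suppressWarnings(vcov(fit))  # warns on an exactly perfect fit
    dimnames(vc) <- list(names(pars), names(pars))
    return(list(pars = pars, ss = ss, vcov = vc, converged = TRUE))
  }
  run_fit <- function() {
    starts <- start_values(family, v, y, n_starts)
    b <- model_bounds(family)
    best <- NULL
    for (st in starts) {
      st <- pmin(pmax(st, b$lower), b$upper)
      res <- tryCatch(
        minpack.lm::nls.lm(
          par = st,
          fn = function(par) y - model_predict(family, par, v),
          lower = b$lower, upper = b$upper,
          control = minpack.lm::nls.lm.control(
            ftol = 1e-10, ptol = 1e-10, maxiter = 500
          )
        ),
        error = function(e) NULL
      )
      if (is.null(res)) next
      ss <- sum(res$fvec^2)
      ok <- res$info %in% 1:4
      k_val <- res$par[[grep("^K", names(res$par))[1]]]
      better <- is.null(best) ||
        ss < best$ss * (1 - 1e-12) - 1e-300 ||
        (abs(ss - best$ss) <= 1e-12 * max(best$ss, 1) && k_val < best$k)
      if (better) best <- list(par = res$par, ss = ss, ok = ok, k = k_val)
    }
    best
  }
  best <- if (is.null(seed)) run_fit() else withr::with_seed(seed, run_fit())
  if (is.null(best)) {
    return(list(pars = setNames(rep(NA_real_, p), model_par_names(family)),
                ss = NA_real_, vcov = NULL, converged = FALSE))
  }
  pars <- unlist(best$par)
  # canonical ordering for the two-phase family: fast phase first
  if (family == "two_phase" && pars[["KFast"]] < pars[["KSlow"]]) {
    pars <- c(Y0 = pars[["Y0"]],
              SpanFast = pars[["SpanSlow"]], KFast = pars[["KSlow"]],
              SpanSlow = pars[["SpanFast"]], KSlow = pars[["KFast"]])
  }
  df <- n - p
  s2 <- best$ss / df
  J <- model_jacobian(family, pars, v)
  vc <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
  if (!is.null(vc)) dimnames(vc) <- list(names(pars), names(pars))
  list(pars = pars, ss = best$ss, vcov = vc, converged = best$ok)
}
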