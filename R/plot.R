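#' Export the plotted-curve data behind a signature figure
#'
#' Returns the evaluated fitted curves with 95% confidence bands on a
#' velocity grid — the exact data a signature plot renders — so figures are
#' testable without image comparison.
#'
#' @param fits A named list of `gait_fit` objects (one per group).
#' @param n_grid Number of grid points across the fitted range.
#' @return A tibble with `group`, `velocity`, `fit`, `lwr`, `upr`.
#' @export
signature_curve_data <- function(fits, n_grid = 100) {
  stopifnot(is.list(fits), length(fits) >= 1)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("group_", seq_along(fits))
  }
  purrr::imap(fits, function(fit, nm) {
    grid <- seq(fit$range[1], fit$range[2], length.out = n_grid)
    dplyr::mutate(
      predict(fit, velocity = grid, interval = "confidence"),
      group = nm, .before = 1
    )
  }) |>
    dplyr::bind_rows()
}

#' Plot gait parameters against stride velocity with fitted curves
#'
#' Scatter of stride-to-stride points versus velocity for one or more
#' groups, overlaid with the fitted parameter-versus-velocity curves and
#' their 95% confidence bands. With `transform = "log"` fits, the points are
#' drawn on the log scale to match the fitted response.
#'
#' @param tables A named list of stride tables (or one table).
#' @param parameter Response column.
#' @param fits A named list of `gait_fit` objects matching `tables` (or one
#'   fit). Optional; points alone are drawn when absent.
#' @param range Velocity range to display (defaults to the fits' range, else
#'   `c(3, 16)`).
#' @return A ggplot object.
#' @export
plot_gait_signature <- function(tables, parameter, fits = NULL,
                                range = NULL) {
  if (is.data.frame(tables)) tables <- list(data = tables)
  if (inherits(fits, "gait_fit")) fits <- list(data = fits)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste0("group_", seq_along(tables))
  }
  transform <- if (!is.null(fits)) fits[[1]]$transform else "identity"
  if (is.null(range)) {
    range <- if (!is.null(fits)) fits[[1]]$range else c(3, 16)
  }
  pts <- purrr::imap(tables, function(tab, nm) {
    tab <- restrict_velocity_range(tibble::as_tibble(tab), range)
    y <- tab[[parameter]]
    if (transform == "log") y <- log(y)
    tibble::tibble(group = nm, velocity = tab$stride_velocity_cm_s,
                   response = y)
  }) |>
    dplyr::bind_rows()
  ylab <- if (transform == "log") paste0("log(", parameter, ")") else parameter
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$velocity,
                                         y = .data$response,
                                         colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.4, size = 1) +
    ggplot2::labs(x = "stride velocity (cm/s)", y = ylab, colour = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(fits)) {
    curves <- signature_curve_data(fits)
    p <- p +
      ggplot2::geom_ribbon(
        data = curves,
        ggplot2::aes(x = .data$velocity, ymin = .data$lwr, ymax = .data$upr,
                     fill = .data$group),
        alpha = 0.15, inherit.aes = FALSE
      ) +
      ggplot2::geom_line(
        data = curves,
        ggplot2::aes(x = .data$velocity, y = .data$fit,
                     colour = .data$group),
        linewidth = 0.8, inherit.aes = FALSE
      )
  }
  p
}

#' @export
autoplot.gait_fit <- function(object, ...) {
  tab <- tibble::tibble(stride_velocity_cm_s = object$data$velocity)
  tab[[object$parameter]] <- if (object$transform == "log") {
    exp(object$data$response)
  } else {
    object$data$response
  }
  plot_gait_signature(list(fit = tab), object$parameter,
                      fits = list(fit = object))
}

#' @export
autoplot.gait_comparison <- function(object, ...) {
  a <- tibble::tibble(stride_velocity_cm_s = object$fit_a$data$velocity)
  b <- tibble::tibble(stride_velocity_cm_s = object$fit_b$data$velocity)
  back <- function(y) if (object$transform == "log") exp(y) else y
  a[[object$parameter]] <- back(object$fit_a$data$response)
  b[[object$parameter]] <- back(object$fit_b$data$response)
  plot_gait_signature(list(A = a, B = b), object$parameter,
                      fits = list(A = object$fit_a, B = object$fit_b)) +
    ggplot2::labs(subtitle = sprintf(
      "F(%d, %d) = %.3g, p = %.3g: %s", object$df_num, object$df_den,
      object$F, object$p,
      if (object$shared) "one shared curve" else "separate curves"
    ))
}
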