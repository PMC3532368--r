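# ggplot2 visualizations for each result type.

#' Plot an MSD curve
#'
#' Log-log MSD with standard-error bars; optionally overlays a fitted
#' subdiffusion + ballistic model and its two components.
#'
#' @param object An `"msd_curve"`.
#' @param fit Optional `"anomalous_fit"` to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msd_curve <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$msd)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$msd - .data$stderr, .data$msd * 1e-3),
                   ymax = .data$msd + .data$stderr),
      width = 0, color = "grey60"
    ) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lag time (s)", y = expression(MSD ~ (mu * m^2)))
  if (!is.null(fit) && fit$converged) {
    tt <- exp(seq(log(min(object$lag)), log(max(object$lag)), length.out = 200))
    comp <- tibble(
      lag = rep(tt, 3),
      msd = c(msd_model(tt, fit$D_alpha, fit$alpha, fit$v),
              4 * fit$D_alpha * tt^fit$alpha,
              fit$v^2 * tt^2),
      part = rep(c("model", "subdiffusion", "directed"), each = length(tt))
    )
    comp <- comp[comp$msd > 0, ]   # a zero component cannot sit on log axes
    p <- p + ggplot2::geom_line(
      data = comp,
      ggplot2::aes(linetype = .data$part, color = .data$part)
    ) +
      ggplot2::scale_color_manual(
        values = c(model = "red", subdiffusion = "black", directed = "blue")
      ) +
      ggplot2::scale_linetype_manual(
        values = c(model = "solid", subdiffusion = "dashed",
                   directed = "dotted")
      )
  }
  p
}

#' Plot a TICS diffusion map
#'
#' Tile heatmap of fitted local diffusion constants; masked (background or
#' failed) tiles are blank.
#'
#' @param object A `"diffusion_map"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.diffusion_map <- function(object, ...) {
  ggplot2::ggplot(
    dplyr::filter(object, !.data$masked),
    ggplot2::aes(x = .data$roi_col, y = .data$roi_row, fill = .data$D)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = expression(D ~ (mu * m^2 / s))) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "ROI column", y = "ROI row")
}

#' Plot N&B maps
#'
#' Raster panels of the mean-intensity, apparent-number and
#' apparent-brightness maps.
#'
#' @param object An `"nb_maps"`.
#' @param which One of `"B"`, `"N"`, `"mean"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nb_maps <- function(object, which = c("B", "N", "mean"), ...) {
  which <- match.arg(which)
  m <- switch(which, B = object$B_map, N = object$N_map,
              mean = object$mean_map)
  df <- tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = which, na.value = "white") +
    ggplot2::coord_equal()
}

#' Plot a temporal autocorrelation curve
#'
#' @param object A `"correlation_curve"`.
#' @param fit Optional `"diffusion_estimate"` from [fit_tics_diffusion()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.correlation_curve <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object[object$tau > 0, ],
                       ggplot2::aes(.data$tau, .data$r)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(tau ~ (s)), y = expression(r(tau)))
  if (!is.null(fit) && fit$converged) {
    tt <- seq(min(object$tau[object$tau > 0]), max(object$tau),
              length.out = 200)
    p <- p + ggplot2::geom_line(
      data = tibble(tau = tt, r = predict(fit$fit, list(tau = tt))),
      color = "red"
    )
  }
  p
}

#' Plot a RICS correlation surface
#'
#' Heatmap of the spatial autocorrelation over signed pixel lags; the
#' fast-scan axis is horizontal.
#'
#' @param object A `"correlation_surface"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.correlation_surface <- function(object, ...) {
  df <- tidyr::expand_grid(eta = object$eta, xi = object$xi)
  df$G <- as.vector(t(object$G))
  ggplot2::ggplot(df, ggplot2::aes(.data$xi, .data$eta, fill = .data$G)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(G[S])) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(xi ~ "(pixels, fast axis)"),
                  y = expression(eta ~ "(lines, slow axis)"))
}

#' Display a red/green temporal overlay
#'
#' @param overlay Array from [temporal_overlay()].
#' @return A ggplot drawing the RGB image.
#' @export
plot_overlay <- function(overlay) {
  ggplot2::ggplot() +
    ggplot2::annotation_raster(overlay, xmin = 0, xmax = ncol(overlay[, , 1]),
                               ymin = 0, ymax = nrow(overlay[, , 1])) +
    ggplot2::xlim(0, ncol(overlay[, , 1])) +
    ggplot2::ylim(0, nrow(overlay[, , 1])) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
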