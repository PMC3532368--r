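# Vesicle sizing by 2D Gaussian fitting.

#' Fit a 2D Gaussian to a spot
#'
#' Nonlinear least squares of
#' `A * exp(-((x-x0)^2 / (2 sx^2) + (y-y0)^2 / (2 sy^2))) + b`
#' to a square window around `initial_center`. Spot size is reported as
#' full width at half maximum per axis, `FWHM = 2 sqrt(2 log 2) * sigma`.
#' For sub-resolution objects the fitted FWHM reflects the point spread
#' function, so it is bounded below by the PSF width.
#'
#' @param stack An [image_stack()] or `float_stack` (single- or
#'   multi-frame).
#' @param initial_center Length-2 numeric `c(x, y)` in um.
#' @param window_um Half-width of the fit window (um); the window must
#'   contain the spot.
#' @param frame 1-based frame index to fit on.
#' @return A list of class `"spot_fit"`: `x0`, `y0` (um), `amplitude`,
#'   `fwhm_x`, `fwhm_y`, `fwhm` (geometric mean), `offset`,
#'   `residual_norm`, `converged`.
#' @export
fit_spot_gaussian <- function(stack, initial_center, window_um = 0.8,
                              frame = 1L) {
  fr <- stack_frames(stack)
  px <- stack$pixel_size
  img <- fr[frame, , ]
  nr <- nrow(img); nc <- ncol(img)
  cx <- initial_center[1]; cy <- initial_center[2]
  hw <- max(2L, round(window_um / px))
  j0 <- max(1L, round(cx / px + 0.5) - hw); j1 <- min(nc, round(cx / px + 0.5) + hw)
  i0 <- max(1L, round(cy / px + 0.5) - hw); i1 <- min(nr, round(cy / px + 0.5) + hw)
  if (j1 - j0 < 4 || i1 - i0 < 4) {
    abort("fit window does not contain enough pixels around the spot")
  }
  win <- img[i0:i1, j0:j1]
  xs <- (j0:j1 - 0.5) * px
  ys <- (i0:i1 - 0.5) * px
  df <- tibble(
    x = rep(xs, each = length(ys)),
    y = rep(ys, times = length(xs)),
    z = as.vector(win)
  )
  b0 <- min(win); a0 <- max(win) - b0
  s0 <- 0.45 / (2 * sqrt(2 * log(2)))
  fail <- structure(
    list(x0 = NA_real_, y0 = NA_real_, amplitude = NA_real_,
         fwhm_x = NA_real_, fwhm_y = NA_real_, fwhm = NA_real_,
         offset = NA_real_, residual_norm = NA_real_, converged = FALSE),
    class = "spot_fit"
  )
  f <- tryCatch(
    minpack.lm::nlsLM(
      z ~ A * exp(-((x - x0)^2 / (2 * sx^2) + (y - y0)^2 / (2 * sy^2))) + b,
      data = df,
      start = list(A = max(a0, 1e-6), x0 = cx, y0 = cy, sx = s0, sy = s0,
                   b = b0),
      lower = c(A = 0, x0 = min(xs), y0 = min(ys), sx = px / 10,
                sy = px / 10, b = -Inf),
      upper = c(A = Inf, x0 = max(xs), y0 = max(ys), sx = 10, sy = 10,
                b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 300)
    ),
    error = function(e) NULL
  )
  if (is.null(f)) return(fail)
  co <- coef(f)
  k <- 2 * sqrt(2 * log(2))
  structure(
    list(x0 = unname(co["x0"]), y0 = unname(co["y0"]),
         amplitude = unname(co["A"]),
         fwhm_x = unname(k * co["sx"]), fwhm_y = unname(k * co["sy"]),
         fwhm = unname(k * sqrt(co["sx"] * co["sy"])),
         offset = unname(co["b"]),
         residual_norm = sqrt(sum(stats::resid(f)^2)), converged = TRUE),
    class = "spot_fit"
  )
}

#' @export
print.spot_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<spot_fit> center (%.3f, %.3f) um, FWHM %.3f um (x %.3f, y %.3f)\n",
                x$x0, x$y0, x$fwhm, x$fwhm_x, x$fwhm_y))
  } else {
    cat("<spot_fit> not converged\n")
  }
  invisible(x)
}

#' Size many spots by 2D Gaussian fitting
#'
#' Runs [fit_spot_gaussian()] at every detection and returns a tidy table.
#'
#' @param stack Stack the detections refer to.
#' @param detections Tibble with `frame` (0-based), `x`, `y` (um).
#' @param window_um Fit window half-width (um).
#' @return A tibble with one row per detection: `frame`, `x0`, `y0`,
#'   `amplitude`, `fwhm_x`, `fwhm_y`, `fwhm`, `offset`, `residual_norm`,
#'   `converged`.
#' @export
fit_spots <- function(stack, detections, window_um = 0.8) {
  purrr::pmap_dfr(
    list(detections$frame, detections$x, detections$y),
    function(fr, x, y) {
      ft <- tryCatch(
        fit_spot_gaussian(stack, c(x, y), window_um, frame = fr + 1L),
        error = function(e) NULL
      )
      if (is.null(ft)) {
        return(tibble(frame = fr, x0 = NA_real_, y0 = NA_real_,
                      amplitude = NA_real_, fwhm_x = NA_real_,
                      fwhm_y = NA_real_, fwhm = NA_real_, offset = NA_real_,
                      residual_norm = NA_real_, converged = FALSE))
      }
      tibble(frame = fr, x0 = ft$x0, y0 = ft$y0, amplitude = ft$amplitude,
             fwhm_x = ft$fwhm_x, fwhm_y = ft$fwhm_y, fwhm = ft$fwhm,
             offset = ft$offset, residual_norm = ft$residual_norm,
             converged = ft$converged)
    }
  )
}
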