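# Temporal image correlation spectroscopy (TICS).

roi_or_full <- function(stack, roi) {
  d <- dim(stack$frames)[2:3]
  if (is.null(roi)) roi <- c(0L, d[1], 0L, d[2])
  if (length(roi) != 4L) {
    abort("`roi` must be c(row0, row1, col0, col1), 0-based half-open")
  }
  if (roi[1] < 0 || roi[3] < 0 || roi[2] > d[1] || roi[4] > d[2] ||
      roi[2] <= roi[1] || roi[4] <= roi[3]) {
    abort("`roi` is empty or outside the frame")
  }
  roi
}

#' Temporal autocorrelation of an image series
#'
#' Computes the normalized temporal intensity autocorrelation of a region
#' of interest,
#' \deqn{r(\tau) = \frac{\langle \delta i(t)\,\delta i(t+\tau)\rangle}
#'                      {\langle i(t)\rangle \langle i(t+\tau)\rangle},}
#' where \eqn{\delta i(t) = i(t) - \langle i(t)\rangle}, angle brackets
#' average over the ROI pixels of a frame, and the outer average runs over
#' all frame pairs separated by lag \eqn{\tau}. The normalization uses the
#' spatial means of the two lagged frames separately. Lags are reported up
#' to `n_frames / 2` by default (estimator variance grows with lag).
#'
#' @param stack An [image_stack()] with at least 20 frames.
#' @param roi Region `c(row0, row1, col0, col1)`, 0-based half-open;
#'   `NULL` uses the full frame.
#' @param max_lag_frames Largest lag in frames (default `n_frames %/% 2`).
#' @return An object of class `"correlation_curve"`: a tibble with columns
#'   `tau` (s, starting at 0), `r`, `n_pairs`, plus attributes `roi` and
#'   `n_frames_used`.
#' @export
temporal_autocorrelation <- function(stack, roi = NULL,
                                     max_lag_frames = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  n <- dim(stack$frames)[1]
  if (n < 20) abort("TICS needs at least 20 frames")
  roi <- roi_or_full(stack, roi)
  if (is.null(max_lag_frames)) max_lag_frames <- n %/% 2L
  max_lag_frames <- min(check_count(max_lag_frames, "max_lag_frames", 1L),
                        n - 1L)
  sub <- stack$frames[, (roi[1] + 1):roi[2], (roi[3] + 1):roi[4], drop = FALSE]
  m <- matrix(sub, nrow = n)               # frames x pixels
  mu <- rowMeans(m)
  if (any(mu == 0) || mean(mu) == 0) {
    abort("ROI has zero mean intensity in at least one frame: normalization undefined")
  }
  dm <- m - mu                              # per-frame spatial fluctuation
  lags <- 0:max_lag_frames
  r <- vapply(lags, function(L) {
    i1 <- 1:(n - L); i2 <- (1 + L):n
    num <- mean(rowMeans(dm[i1, , drop = FALSE] * dm[i2, , drop = FALSE]))
    den <- mean(mu[i1] * mu[i2])
    num / den
  }, 0.0)
  out <- tibble(tau = lags * stack$frame_interval, r = r,
                n_pairs = n - lags)
  attr(out, "roi") <- roi
  attr(out, "n_frames_used") <- n
  class(out) <- c("correlation_curve", class(out))
  out
}

new_diffusion_estimate <- function(D, se_D = NA_real_, amplitude = NA_real_,
                                   offset = NA_real_, n_fit = NA_integer_,
                                   residual_norm = NA_real_, model = "",
                                   converged = FALSE, fit = NULL) {
  structure(
    list(D = D, se_D = se_D, amplitude = amplitude, offset = offset,
         n_fit = n_fit, residual_norm = residual_norm, model = model,
         converged = converged, fit = fit),
    class = "diffusion_estimate"
  )
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("<diffusion_estimate: %s>\n", x$model))
  if (isTRUE(x$converged)) {
    cat(sprintf("  D = %.4g um^2/s (SE %.2g), amplitude %.3g, offset %.3g\n",
                x$D, x$se_D, x$amplitude, x$offset))
  } else {
    cat("  fit did not converge (non-decaying or degenerate data)\n")
  }
  invisible(x)
}

#' Fit a 2D two-photon diffusion model to a TICS curve
#'
#' Least-squares fit of
#' \deqn{r(\tau) = g_0 / (1 + 8 D \tau / \omega_0^2) + c}
#' to the temporal autocorrelation, the two-photon Gaussian-beam decay for
#' 2D diffusion (the same `8 D tau / omega_0^2` time scale as the raster
#' correlation model). The zero lag is excluded: shot noise is temporally
#' white and contaminates only r(0). The additive offset `c` absorbs an
#' immobile fraction and is reported.
#'
#' @param curve A `"correlation_curve"` from [temporal_autocorrelation()]
#'   with at least 5 positive lags.
#' @param omega_0 Beam waist (um).
#' @return A `"diffusion_estimate"` (model tag `"TICS-2P-2D"`). When the
#'   curve does not decay, `converged` is `FALSE` and `D` is `NA`.
#' @export
fit_tics_diffusion <- function(curve, omega_0 = 0.24) {
  check_number(omega_0, "omega_0", min = 0, strict_min = TRUE)
  df <- curve[curve$tau > 0, ]
  if (base::nrow(df) < 5) abort("need at least 5 positive lags to fit")
  r1 <- df$r[1]; rend <- mean(tail(df$r, max(3L, base::nrow(df) %/% 5L)))
  decay <- r1 - rend
  fail <- new_diffusion_estimate(NA_real_, model = "TICS-2P-2D")
  if (!is.finite(decay) || decay <= 0) return(fail)
  # half-decay initialization
  half <- rend + decay / 2
  idx <- which(df$r <= half)[1]
  tau_half <- if (is.na(idx)) max(df$tau) else df$tau[idx]
  starts <- list(
    c(g0 = decay, D = omega_0^2 / (8 * tau_half), c0 = rend),
    c(g0 = decay, D = omega_0^2 / (8 * df$tau[1]), c0 = rend)
  )
  best <- NULL
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(
        r ~ g0 / (1 + 8 * D * tau / omega_0^2) + c0,
        data = df, start = as.list(st),
        lower = c(g0 = 0, D = 0, c0 = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(f)) {
      rss <- sum(stats::resid(f)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
    }
  }
  if (is.null(best)) return(fail)
  co <- coef(best$fit)
  ses <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                  error = function(e) rep(NA_real_, 3))
  new_diffusion_estimate(
    D = unname(co["D"]), se_D = unname(ses["D"]),
    amplitude = unname(co["g0"]), offset = unname(co["c0"]),
    n_fit = base::nrow(df), residual_norm = sqrt(best$rss),
    model = "TICS-2P-2D", converged = TRUE, fit = best$fit
  )
}

#' Map local diffusion constants by tiled TICS
#'
#' Tiles the frame into `roi_size x roi_size` blocks, runs
#' [temporal_autocorrelation()] plus [fit_tics_diffusion()] per tile, and
#' masks background tiles (mean intensity below `mask_frac` of the stack
#' maximum) and tiles whose fit fails.
#'
#' @inheritParams temporal_autocorrelation
#' @param roi_size Tile side in pixels (default 32).
#' @param omega_0 Beam waist (um).
#' @param mask_frac Background threshold as a fraction of the stack maximum.
#' @return A `"diffusion_map"`: a tibble with one row per tile and columns
#'   `roi_row`, `roi_col` (0-based tile indices), `row0`, `col0` (pixel
#'   origin), `mean_intensity`, `D`, `se_D`, `residual`, `masked`.
#' @export
tics_diffusion_map <- function(stack, roi_size = 32L, omega_0 = 0.24,
                               mask_frac = 0.01, max_lag_frames = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  roi_size <- check_count(roi_size, "roi_size", 2L)
  d <- dim(stack$frames)[2:3]
  if (any(d < roi_size)) abort("frame smaller than `roi_size`")
  floor_int <- mask_frac * max(stack$frames)
  tiles <- tidyr::expand_grid(
    roi_row = 0:(d[1] %/% roi_size - 1L),
    roi_col = 0:(d[2] %/% roi_size - 1L)
  )
  res <- purrr::pmap_dfr(tiles, function(roi_row, roi_col) {
    row0 <- roi_row * roi_size; col0 <- roi_col * roi_size
    roi <- c(row0, row0 + roi_size, col0, col0 + roi_size)
    mi <- mean(stack$frames[, (row0 + 1):(row0 + roi_size),
                            (col0 + 1):(col0 + roi_size)])
    base <- tibble(roi_row = roi_row, roi_col = roi_col,
                   row0 = row0, col0 = col0, mean_intensity = mi)
    if (mi < floor_int || mi == 0) {
      return(dplyr::mutate(base, D = NA_real_, se_D = NA_real_,
                           residual = NA_real_, masked = TRUE))
    }
    est <- tryCatch({
      cur <- temporal_autocorrelation(stack, roi, max_lag_frames)
      fit_tics_diffusion(cur, omega_0)
    }, error = function(e) NULL)
    if (is.null(est) || !isTRUE(est$converged)) {
      return(dplyr::mutate(base, D = NA_real_, se_D = NA_real_,
                           residual = NA_real_, masked = TRUE))
    }
    dplyr::mutate(base, D = est$D, se_D = est$se_D,
                  residual = est$residual_norm, masked = FALSE)
  })
  attr(res, "roi_size") <- roi_size
  attr(res, "pixel_size") <- stack$pixel_size
  class(res) <- c("diffusion_map", class(res))
  res
}
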