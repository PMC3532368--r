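# Number & brightness (N&B) moment analysis.

#' Number and brightness analysis of an image series
#'
#' Per-pixel moment analysis of photon counts over time. With first moment
#' \eqn{\langle k\rangle} and variance \eqn{\sigma^2}, the apparent
#' brightness is \eqn{B = \sigma^2/\langle k\rangle = \varepsilon + 1} and
#' the apparent number \eqn{N = \langle k\rangle^2/\sigma^2}. Immobile
#' emitters obeying Poisson photon statistics give B = 1; mobile or
#' aggregated emitters broaden the count histogram and give B > 1.
#'
#' Pixels with zero mean intensity are masked (`NA` in the derived maps),
#' not an error.
#'
#' @param stack An [image_stack()]; fewer than 50 frames triggers a warning
#'   (moment estimates get noisy).
#' @param higher_moments Also return 3rd-5th central-moment maps.
#' @return An object of class `"nb_maps"`: list of matrices `mean_map`,
#'   `variance_map`, `B_map`, `N_map`, `epsilon_map` (and `moment3`,
#'   `moment4`, `moment5` if requested), plus `n_frames`.
#' @export
number_and_brightness <- function(stack, higher_moments = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  n <- dim(stack$frames)[1]
  if (n < 50) {
    warn(sprintf("only %d frames: N&B moment estimates will be noisy (>= 50 recommended)", n))
  }
  if (n < 2) abort("N&B needs at least 2 frames")
  mean_map <- apply(stack$frames, c(2, 3), mean)
  var_map <- apply(stack$frames, c(2, 3), var)
  pos <- mean_map > 0
  B <- ifelse(pos, var_map / mean_map, NA_real_)
  N <- ifelse(pos & var_map > 0, mean_map^2 / var_map, NA_real_)
  out <- list(
    mean_map = mean_map, variance_map = var_map,
    B_map = B, N_map = N, epsilon_map = B - 1,
    n_frames = n
  )
  if (higher_moments) {
    cm <- function(ord) apply(stack$frames, c(2, 3),
                              function(v) mean((v - mean(v))^ord))
    out$moment3 <- cm(3); out$moment4 <- cm(4); out$moment5 <- cm(5)
  }
  structure(out, class = "nb_maps")
}

#' @export
print.nb_maps <- function(x, ...) {
  ok <- is.finite(x$B_map)
  cat(sprintf(
    "<nb_maps> %d x %d px over %d frames; mean B (unmasked) = %.4f\n",
    nrow(x$mean_map), ncol(x$mean_map), x$n_frames, mean(x$B_map[ok])
  ))
  invisible(x)
}

#' @describeIn number_and_brightness Tidy the maps into one row per pixel
#'   (`row`, `col`, `mean`, `variance`, `B`, `N`, `epsilon`).
#' @param x An `"nb_maps"` object.
#' @param ... Unused.
#' @export
tidy.nb_maps <- function(x, ...) {
  d <- dim(x$mean_map)
  tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    mean = as.vector(x$mean_map),
    variance = as.vector(x$variance_map),
    B = as.vector(x$B_map),
    N = as.vector(x$N_map),
    epsilon = as.vector(x$epsilon_map)
  )
}

#' Photobleaching curve of an image series
#'
#' Extracts the per-frame mean intensity of a region and fits a
#' monoexponential decay `I(t) = A exp(-rate t) + c`. A rate compatible
#' with zero flags the absence of significant photobleaching; an
#' increasing intensity yields a negative rate and a warning.
#'
#' @param stack An [image_stack()] with at least 10 frames.
#' @param roi Optional region `c(row0, row1, col0, col1)`, 0-based
#'   half-open.
#' @return A list of class `"bleach_fit"`: `intensity` (tibble `t`,
#'   `mean_intensity`), `amplitude`, `rate` (1/s), `offset`, `se_rate`,
#'   `converged`.
#' @export
bleach_curve <- function(stack, roi = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  n <- dim(stack$frames)[1]
  if (n < 10) abort("bleach quantification needs at least 10 frames")
  roi <- roi_or_full(stack, roi)
  sub <- stack$frames[, (roi[1] + 1):roi[2], (roi[3] + 1):roi[4], drop = FALSE]
  I <- apply(sub, 1, mean)
  t <- (seq_len(n) - 1) * stack$frame_interval
  df <- tibble(t = t, mean_intensity = I)
  # log-linear initialization on the positive part
  span <- max(I) - min(I)
  c0 <- max(0, min(I) - 0.05 * span)
  slope0 <- unname(coef(lm(I ~ t))[2])
  rate0 <- if (mean(I) > 0) -slope0 / mean(I) else 0
  f <- tryCatch(
    minpack.lm::nlsLM(
      mean_intensity ~ A * exp(-rate * t) + c0p,
      data = df,
      start = list(A = max(span, 1e-12), rate = rate0, c0p = c0),
      control = minpack.lm::nls.lm.control(maxiter = 300)
    ),
    error = function(e) NULL
  )
  if (is.null(f)) {
    return(structure(list(intensity = df, amplitude = NA_real_,
                          rate = NA_real_, offset = NA_real_,
                          se_rate = NA_real_, converged = FALSE),
                     class = "bleach_fit"))
  }
  co <- coef(f)
  ses <- tryCatch(summary(f)$coefficients[, "Std. Error"],
                  error = function(e) rep(NA_real_, 3))
  if (is.finite(co["rate"]) && co["rate"] < 0) {
    warn("fitted decay rate is negative: intensity increases over time")
  }
  structure(
    list(intensity = df, amplitude = unname(co["A"]),
         rate = unname(co["rate"]), offset = unname(co["c0p"]),
         se_rate = unname(ses["rate"]), converged = TRUE),
    class = "bleach_fit"
  )
}
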