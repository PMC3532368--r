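# Raster image correlation spectroscopy (RICS).
#
# A raster scan samples adjacent pixels tau_p apart and adjacent lines
# tau_l apart, so the spatial autocorrelation of one frame encodes
# dynamics on two very different time scales along its two axes.

#' Spatial autocorrelation surface of a raster-scanned stack
#'
#' Computes the 2D spatial autocorrelation of intensity fluctuations,
#' averaged over frames:
#' \deqn{G_S(\xi, \eta) = \frac{\langle \delta i(x, y)\,
#'   \delta i(x+\xi, y+\eta) \rangle}{\langle i \rangle^2}.}
#' The per-pixel temporal mean is subtracted first, which removes immobile
#' structures; the estimator is the unbiased (overlap-normalized) linear
#' correlation, not a circular one. `xi` is the fast (pixel, within-line)
#' axis and `eta` the slow (line) axis.
#'
#' @param stack A raster-mode [image_stack()] (snapshot stacks are
#'   rejected: scan timing is required to interpret the surface).
#' @param region Optional `c(row0, row1, col0, col1)` (0-based half-open),
#'   at least 32 x 32 px; `NULL` uses the full frame.
#' @param lag_max Maximum spatial lag (pixels) on both axes (default 16).
#' @return An object of class `"correlation_surface"`: list with `xi`,
#'   `eta` (signed pixel lags), `G` (matrix eta x xi), `n_pairs` (pixel
#'   pairs per lag, per frame), `mean_intensity`, `n_frames`, `scan`,
#'   `region`.
#' @export
rics_autocorrelation <- function(stack, region = NULL, lag_max = 16L) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$mode != "raster") {
    abort("RICS requires a raster-mode stack (scan timing metadata)")
  }
  region <- roi_or_full(stack, region)
  nr <- region[2] - region[1]; nc <- region[4] - region[3]
  if (nr < 32 || nc < 32) abort("RICS region must be at least 32 x 32 px")
  lag_max <- min(check_count(lag_max, "lag_max", 1L), nr - 1L, nc - 1L)
  n <- dim(stack$frames)[1]
  sub <- stack$frames[, (region[1] + 1):region[2],
                      (region[3] + 1):region[4], drop = FALSE]
  # immobile-structure removal: per-pixel temporal mean
  pixmean <- apply(sub, c(2, 3), mean)
  grand_mean <- mean(sub)
  if (grand_mean == 0) abort("region has zero mean intensity")

  # zero-padded FFT linear autocorrelation, per frame, then averaged
  pr <- 2L * nr; pc <- 2L * nc
  acc <- matrix(0, pr, pc)
  for (f in seq_len(n)) {
    d <- sub[f, , ] - pixmean
    pad <- matrix(0, pr, pc)
    pad[1:nr, 1:nc] <- d
    F <- fft(pad)
    acc <- acc + Re(fft(F * Conj(F), inverse = TRUE)) / (pr * pc)
  }
  acc <- acc / n
  lags <- -lag_max:lag_max
  # overlap counts
  n_row <- nr - abs(lags); n_col <- nc - abs(lags)
  G <- matrix(0, length(lags), length(lags),
              dimnames = list(eta = lags, xi = lags))
  npairs <- outer(n_row, n_col)
  idx <- function(l, m) ifelse(l >= 0, l + 1L, 2L * m + l + 1L)
  for (a in seq_along(lags)) {        # eta: row lag
    for (b in seq_along(lags)) {      # xi: col lag
      G[a, b] <- acc[idx(lags[a], nr), idx(lags[b], nc)] / npairs[a, b]
    }
  }
  G <- G / grand_mean^2
  structure(
    list(xi = lags, eta = lags, G = G, n_pairs = npairs * n,
         mean_intensity = grand_mean, n_frames = n,
         scan = stack$scan, region = region),
    class = "correlation_surface"
  )
}

#' Model RICS correlation surface
#'
#' Evaluates the scanning-correlation model for 2D diffusion under a
#' two-photon Gaussian focal spot. With
#' \eqn{\theta(\xi,\eta) = 1 + 8 D |\xi \tau_p + \eta \tau_l| / \omega_0^2}
#' (the elapsed time between the two pixel samples), the surface is
#' \deqn{G_S(\xi,\eta) = \frac{\gamma}{N}\,\theta^{-p}\,
#'   \exp\!\left(-\frac{2\delta r^2(\xi^2+\eta^2)/\omega_0^2}{\theta}\right)
#'   + \mathrm{offset}.}
#' `p = 1` (model `"2P-2D"`) is the planar form matching motion confined to
#' the focal plane; `p = 3/2` (`"2P-3D"`) is the classical volume form. At
#' zero lag the scanning factor is exactly 1 and the diffusive factor is
#' `gamma / N`.
#'
#' @param xi,eta Signed pixel lags (vectors; the surface is evaluated on
#'   their grid).
#' @param D Diffusion constant (um^2/s).
#' @param N Apparent number of particles in the focal spot.
#' @param scan A [scan_params()].
#' @param model `"2P-2D"` or `"2P-3D"`.
#' @param offset Additive offset.
#' @return Matrix (eta x xi) of model correlation values.
#' @export
rics_model_surface <- function(xi, eta, D, N, scan,
                               model = c("2P-2D", "2P-3D"), offset = 0) {
  model <- match.arg(model)
  p <- if (model == "2P-2D") 1 else 3 / 2
  w2 <- scan$omega_0^2
  XI <- matrix(xi, nrow = length(eta), ncol = length(xi), byrow = TRUE)
  ETA <- matrix(eta, nrow = length(eta), ncol = length(xi))
  tau <- abs(XI * scan$tau_p + ETA * scan$tau_l)
  theta <- 1 + 8 * D * tau / w2
  S <- exp(-(2 * scan$delta_r^2 * (XI^2 + ETA^2) / w2) / theta)
  scan$gamma / N * theta^(-p) * S + offset
}

#' Fit the RICS diffusion model to a correlation surface
#'
#' Weighted nonlinear least squares of [rics_model_surface()] against a
#' measured surface, with free parameters `D`, `N` and an additive offset.
#' Weights are the number of pixel pairs contributing to each lag (the
#' estimator variance scales inversely with it). The zero-lag point is
#' excluded by default: uncorrelated shot noise adds a delta spike there.
#'
#' @param surface A `"correlation_surface"` from [rics_autocorrelation()],
#'   or one synthesized with [rics_model_surface()] wrapped in the same
#'   structure.
#' @param scan A [scan_params()]; defaults to the surface's own.
#' @param model Temporal exponent variant, see [rics_model_surface()].
#' @param exclude_zero Drop the (0,0) lag before fitting.
#' @return A `"diffusion_estimate"` with model tag `"RICS-<model>"`; on
#'   non-convergence, `converged = FALSE` with the residual norm of the
#'   best attempt.
#' @export
fit_rics <- function(surface, scan = NULL, model = c("2P-2D", "2P-3D"),
                     exclude_zero = TRUE) {
  model <- match.arg(model)
  stopifnot(inherits(surface, "correlation_surface"))
  if (is.null(scan)) scan <- surface$scan
  stopifnot(inherits(scan, "scan_params"))
  p <- if (model == "2P-2D") 1 else 3 / 2
  w2 <- scan$omega_0^2
  df <- tidyr::expand_grid(eta = surface$eta, xi = surface$xi)
  # expand_grid varies xi fastest; as.vector(t(G)) matches that order
  df$g <- as.vector(t(surface$G))
  df$w <- as.vector(t(surface$n_pairs))
  if (exclude_zero) df <- df[!(df$xi == 0 & df$eta == 0), ]
  g0 <- max(df$g)
  if (!is.finite(g0) || g0 <= 0) {
    return(new_diffusion_estimate(NA_real_, model = paste0("RICS-", model)))
  }
  df$tau <- abs(df$xi * scan$tau_p + df$eta * scan$tau_l)
  df$sp <- 2 * scan$delta_r^2 * (df$xi^2 + df$eta^2) / w2
  form <- stats::as.formula(eval(substitute(
    g ~ GAM / N * (1 + 8 * D * tau / W2)^(-P) *
      exp(-sp / (1 + 8 * D * tau / W2)) + c0,
    list(GAM = scan$gamma, W2 = w2, P = p)
  )))
  starts_D <- c(0.01, 0.1, 1, 10)
  best <- NULL
  for (D0 in starts_D) {
    st <- list(D = D0, N = scan$gamma / g0, c0 = 0)
    f <- tryCatch(
      minpack.lm::nlsLM(
        form, data = df, start = st, weights = df$w,
        lower = c(D = 0, N = 1e-12, c0 = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 300)
      ),
      error = function(e) NULL
    )
    if (!is.null(f)) {
      rss <- sum(stats::resid(f)^2 * df$w)
      if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
    }
  }
  if (is.null(best)) {
    return(new_diffusion_estimate(NA_real_, model = paste0("RICS-", model),
                                  residual_norm = Inf))
  }
  co <- coef(best$fit)
  ses <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                  error = function(e) rep(NA_real_, 3))
  new_diffusion_estimate(
    D = unname(co["D"]), se_D = unname(ses["D"]),
    amplitude = unname(scan$gamma / co["N"]), offset = unname(co["c0"]),
    n_fit = base::nrow(df),
    residual_norm = sqrt(sum(stats::resid(best$fit)^2)),
    model = paste0("RICS-", model), converged = TRUE, fit = best$fit
  )
}

#' Wrap a model surface in a correlation_surface object
#'
#' Utility for self-consistency checks: evaluates [rics_model_surface()]
#' on a lag grid and packages it like [rics_autocorrelation()] output.
#'
#' @inheritParams rics_model_surface
#' @param lag_max Maximum lag in pixels.
#' @return A `"correlation_surface"`.
#' @export
synthesize_rics_surface <- function(D, N, scan, lag_max = 16L,
                                    model = c("2P-2D", "2P-3D"),
                                    offset = 0) {
  model <- match.arg(model)
  lags <- -lag_max:lag_max
  G <- rics_model_surface(lags, lags, D, N, scan, model, offset)
  structure(
    list(xi = lags, eta = lags, G = G,
         n_pairs = matrix(1, length(lags), length(lags)),
         mean_intensity = NA_real_, n_frames = 0L,
         scan = scan, region = NULL),
    class = "correlation_surface"
  )
}
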