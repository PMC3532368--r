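# Fitting the combined anomalous-subdiffusion + directed-transport model.

#' Closed-form MSD of the combined motion model
#'
#' Evaluates `MSD(t) = 4 D_alpha t^alpha + v^2 t^2`: fractional-Brownian
#' subdiffusion plus an independent constant-velocity directed component.
#'
#' @param t Lag times (s).
#' @param D_alpha Anomalous diffusion constant (um^2/s^alpha).
#' @param alpha Anomalous exponent.
#' @param v Transport velocity (um/s).
#' @return MSD values (um^2).
#' @export
msd_model <- function(t, D_alpha, alpha, v) {
  4 * D_alpha * t^alpha + v^2 * t^2
}

#' Fit the subdiffusion + ballistic MSD model
#'
#' Weighted nonlinear least squares of
#' \deqn{MSD(t) = 4 D_\alpha t^\alpha + v^2 t^2}
#' with weights `1 / stderr^2` (the estimator is statistically most
#' significant at small lags, where the standard error is smallest).
#' Parameters are bounded (`D_alpha >= 0`, `0 < alpha <= 2`, `v >= 0`) and
#' the optimizer is multistarted over `alpha` in \{0.4, 0.7, 1.0\} with
#' `D_alpha` seeded from the first-lag MSD and `v` from the last-lag MSD;
#' the lowest weighted SSE wins, deterministically.
#'
#' The parameter standard deviation reported as `std` is derived from the
#' 95% confidence interval as `(CI_upper - estimate) / 1.96`, which equals
#' the standard error from the weighted Jacobian; both the CI bounds and
#' `std` are returned.
#'
#' @param msd An `"msd_curve"` with at least 6 lags. Curves with zero or
#'   missing `stderr` everywhere (noiseless oracles) are fitted
#'   unweighted.
#' @param lag_range Optional `c(min, max)` lag window (s) to fit on.
#' @return An object of class `"anomalous_fit"` with elements `D_alpha`,
#'   `alpha`, `v`, `std` (named length-3), `ci95_upper`, `ci95_lower`,
#'   `weighting`, `lag_range`, `n_lags`, `converged`, `fit`.
#' @export
fit_subdiffusion_ballistic <- function(msd, lag_range = NULL) {
  lag_in <- msd$lag; msd_in <- msd$msd; se_in <- msd$stderr
  df <- tibble(lag = lag_in, msd = msd_in, stderr = se_in)
  if (!is.null(lag_range)) {
    df <- df[df$lag >= lag_range[1] & df$lag <= lag_range[2], ]
  }
  df <- df[is.finite(df$lag) & is.finite(df$msd) & df$lag > 0, ]
  if (base::nrow(df) < 6) abort("need at least 6 lags with finite MSD")
  weighted <- all(is.finite(df$stderr)) && all(df$stderr > 0)
  w <- if (weighted) 1 / df$stderr^2 else rep(1, base::nrow(df))
  D0 <- max(df$msd[1] / (4 * df$lag[1]^0.7), 1e-12)
  v0 <- sqrt(max(df$msd[base::nrow(df)], 1e-12)) / df$lag[base::nrow(df)]
  starts <- purrr::map(c(0.4, 0.7, 1.0), function(a0) {
    list(D_alpha = max(df$msd[1] / (4 * df$lag[1]^a0), 1e-12),
         alpha = a0, v = v0)
  })
  best <- NULL
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(
        msd ~ 4 * D_alpha * lag^alpha + v^2 * lag^2,
        data = df, start = st, weights = w,
        lower = c(D_alpha = 0, alpha = 1e-6, v = 0),
        upper = c(D_alpha = Inf, alpha = 2, v = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (!is.null(f)) {
      wsse <- sum(w * stats::resid(f)^2)
      if (is.null(best) || wsse < best$wsse) best <- list(fit = f, wsse = wsse)
    }
  }
  if (is.null(best)) {
    return(structure(
      list(D_alpha = NA_real_, alpha = NA_real_, v = NA_real_,
           std = c(D_alpha = NA_real_, alpha = NA_real_, v = NA_real_),
           ci95_upper = NULL, ci95_lower = NULL,
           weighting = if (weighted) "1/stderr^2" else "uniform",
           lag_range = range(df$lag), n_lags = base::nrow(df),
           converged = FALSE, fit = NULL),
      class = "anomalous_fit"
    ))
  }
  f <- best$fit
  co <- coef(f)
  se <- tryCatch(summary(f)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 3), names(co)))
  ci_up <- co + 1.96 * se
  ci_lo <- co - 1.96 * se
  std <- (ci_up - co) / 1.96          # == se by construction; both reported
  structure(
    list(D_alpha = unname(co["D_alpha"]), alpha = unname(co["alpha"]),
         v = unname(co["v"]),
         std = std, ci95_upper = ci_up, ci95_lower = ci_lo,
         weighting = if (weighted) "1/stderr^2" else "uniform",
         lag_range = range(df$lag), n_lags = base::nrow(df),
         converged = TRUE, fit = f),
    class = "anomalous_fit"
  )
}

#' @export
print.anomalous_fit <- function(x, ...) {
  cat("<anomalous_fit> MSD(t) = 4 D_a t^a + v^2 t^2\n")
  if (x$converged) {
    cat(sprintf("  D_alpha = %.4g um^2/s^a (std %.2g)\n", x$D_alpha,
                x$std["D_alpha"]))
    cat(sprintf("  alpha   = %.4g (std %.2g)\n", x$alpha, x$std["alpha"]))
    cat(sprintf("  v       = %.4g um/s (std %.2g)\n", x$v, x$std["v"]))
    cat(sprintf("  %d lags in [%.3g, %.3g] s, weights: %s\n",
                x$n_lags, x$lag_range[1], x$lag_range[2], x$weighting))
  } else {
    cat("  fit failed (degenerate data)\n")
  }
  invisible(x)
}

#' @export
tidy.anomalous_fit <- function(x, ...) {
  tibble(
    term = c("D_alpha", "alpha", "v"),
    estimate = c(x$D_alpha, x$alpha, x$v),
    std = unname(x$std[c("D_alpha", "alpha", "v")]),
    ci95_lower = if (is.null(x$ci95_lower)) NA_real_ else
      unname(x$ci95_lower[c("D_alpha", "alpha", "v")]),
    ci95_upper = if (is.null(x$ci95_upper)) NA_real_ else
      unname(x$ci95_upper[c("D_alpha", "alpha", "v")])
  )
}

#' @export
glance.anomalous_fit <- function(x, ...) {
  tibble(
    converged = x$converged, n_lags = x$n_lags,
    lag_min = x$lag_range[1], lag_max = x$lag_range[2],
    weighting = x$weighting,
    sigma = if (x$converged) summary(x$fit)$sigma else NA_real_
  )
}

#' @export
tidy.diffusion_estimate <- function(x, ...) {
  tibble(term = c("D", "amplitude", "offset"),
         estimate = c(x$D, x$amplitude, x$offset),
         std.error = c(x$se_D, NA_real_, NA_real_))
}

#' @export
glance.diffusion_estimate <- function(x, ...) {
  tibble(converged = x$converged, model = x$model, n_fit = x$n_fit,
         residual_norm = x$residual_norm)
}

#' Log-log slope of an MSD curve
#'
#' Ordinary least squares of `log(msd)` against `log(lag)` over a portion
#' of the curve. The slope is the local anomalous exponent: 1 for Brownian
#' diffusion, 2 for ballistic motion; on the late part of a combined
#' subdiffusion + transport curve it lies in between and reveals the
#' superdiffusive crossover. `"last_third"` selects the largest third of
#' the lag axis (by lag value, not point count). Non-positive MSD values
#' are excluded with a warning.
#'
#' @param msd An `"msd_curve"`.
#' @param portion `"last_third"`, `"all"`, or a numeric `c(min, max)` lag
#'   window in seconds.
#' @return The fitted slope (single number).
#' @export
loglog_slope <- function(msd, portion = "last_third") {
  df <- tibble(lag = msd$lag, msd = msd$msd)
  if (is.character(portion)) {
    portion <- match.arg(portion, c("last_third", "all"))
    if (portion == "last_third") {
      thr <- max(df$lag) - (max(df$lag) - min(df$lag)) / 3
      df <- df[df$lag >= thr, ]
    }
  } else {
    df <- df[df$lag >= portion[1] & df$lag <= portion[2], ]
  }
  bad <- df$msd <= 0
  if (any(bad)) {
    warn(sprintf("%d non-positive MSD value(s) excluded from log-log fit",
                 sum(bad)))
    df <- df[!bad, ]
  }
  if (base::nrow(df) < 4) abort("need at least 4 lags in the selected portion")
  unname(coef(lm(log(msd) ~ log(lag), data = df))[2])
}
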