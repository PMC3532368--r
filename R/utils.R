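# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random state. seed = NULL means: use (and advance) the session RNG.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(seed, code)
  }
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` = %g is outside the allowed range %s%g, %g%s.",
      name, x, if (strict_min) "(" else "[", min, max,
      if (strict_max) ")" else "]"
    ))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# 2D gaussian blob sampled on a pixel grid, used by several renderers.
# Returns exp(-((x-x0)^2+(y-y0)^2) / denom) for pixel-center coordinates.
pixel_centers <- function(n, pixel_size) (seq_len(n) - 0.5) * pixel_size

frame_dims <- function(stack) dim(stack$frames)[2:3]

is_uniform_grid <- function(t, tol = 1e-8) {
  if (length(t) < 2L) return(TRUE)
  dt <- diff(t)
  max(abs(dt - dt[1])) <= tol * max(abs(dt[1]), 1e-300)
}
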