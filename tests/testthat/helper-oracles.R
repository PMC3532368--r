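# Independent brute-force reference implementations used to validate the
# package's estimators. These are deliberately naive (double loops), so
# agreement is meaningful.

# Time-averaged 2D MSD, lag n in 1..max_lag, plain double loop.
oracle_msd <- function(x, y, h, max_lag) {
  N <- length(x)
  msd <- numeric(max_lag)
  for (n in seq_len(max_lag)) {
    acc <- 0
    for (i in seq_len(N - n)) {
      acc <- acc + (x[i + n] - x[i])^2 + (y[i + n] - y[i])^2
    }
    msd[n] <- acc / (N - n)
  }
  tibble::tibble(lag = seq_len(max_lag) * h, msd = msd)
}

# Normalized temporal autocorrelation of a (frame, row, col) array,
# spatial means per frame, all frame pairs at each lag.
oracle_tics <- function(frames, max_lag) {
  n <- dim(frames)[1]
  mu <- numeric(n)
  for (f in seq_len(n)) mu[f] <- mean(frames[f, , ])
  r <- numeric(max_lag + 1)
  for (L in 0:max_lag) {
    num <- 0; den <- 0; cnt <- 0
    for (f in seq_len(n - L)) {
      d1 <- frames[f, , ] - mu[f]
      d2 <- frames[f + L, , ] - mu[f + L]
      num <- num + mean(d1 * d2)
      den <- den + mu[f] * mu[f + L]
      cnt <- cnt + 1
    }
    r[L + 1] <- (num / cnt) / (den / cnt)
  }
  r
}

# Spatial autocorrelation of intensity fluctuations at integer lags
# (eta = row lag, xi = col lag), per-pixel temporal mean subtracted,
# overlap-normalized, divided by the grand mean squared. Brute force.
oracle_rics <- function(frames, lag_max) {
  n <- dim(frames)[1]; nr <- dim(frames)[2]; nc <- dim(frames)[3]
  pixmean <- apply(frames, c(2, 3), mean)
  gm <- mean(frames)
  lags <- -lag_max:lag_max
  G <- matrix(0, length(lags), length(lags))
  for (a in seq_along(lags)) {
    for (b in seq_along(lags)) {
      eta <- lags[a]; xi <- lags[b]
      acc <- 0; cnt <- 0
      for (f in seq_len(n)) {
        d <- frames[f, , ] - pixmean
        for (i in seq_len(nr)) {
          ii <- i + eta
          if (ii < 1 || ii > nr) next
          for (j in seq_len(nc)) {
            jj <- j + xi
            if (jj < 1 || jj > nc) next
            acc <- acc + d[i, j] * d[ii, jj]
            cnt <- cnt + 1
          }
        }
      }
      G[a, b] <- (acc / cnt) / gm^2
    }
  }
  list(lags = lags, G = G)
}

# Straight-line constant-velocity detections for linking tests.
line_detections <- function(n_tracks, n_frames, speed = 0.2, spacing = 3) {
  purrr::map_dfr(seq_len(n_tracks), function(k) {
    tibble::tibble(
      frame = 0:(n_frames - 1),
      x = speed * (0:(n_frames - 1)) + 0.01 * k,
      y = spacing * k,
      response = 1, intensity = 1
    )
  })
}
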