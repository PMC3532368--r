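# Mean-square-displacement estimation from trajectories.

#' Time-averaged MSD of a single trajectory
#'
#' Overlapping-window, time-averaged estimator
#' \deqn{MSD(\Delta t = n h) = \frac{1}{N - n} \sum_{i=1}^{N-n}
#'   \left[(x_{i+n} - x_i)^2 + (y_{i+n} - y_i)^2\right],}
#' where `N` is the number of points and `h` the frame step (both
#' displacement components enter squared). The per-lag standard deviation
#' over the `N - n` overlapping squared displacements is returned as a
#' dispersion diagnostic; pair counts decrease with lag, so the estimator
#' is most reliable at small lags.
#'
#' @param traj Trajectory tibble for a single track (uniform time step).
#' @param max_lag_frames Largest lag `n` in frames; `NULL` uses the
#'   largest lag still supported by at least `min_pairs` displacement
#'   pairs.
#' @param min_pairs Minimum pairs per lag for the default lag range.
#' @return An `"msd_curve"` tibble with columns `lag` (s), `msd` (um^2),
#'   `stderr` (um^2; SD across overlapping pairs / sqrt(pairs)),
#'   `n_pairs`, `n_tracks`.
#' @export
compute_msd <- function(traj, max_lag_frames = NULL, min_pairs = 10L) {
  validate_trajectory(traj)
  if (length(unique(traj$track_id)) > 1L) {
    abort("compute_msd() expects a single track; see ensemble_msd()")
  }
  traj <- dplyr::arrange(traj, .data$t)
  N <- base::nrow(traj)
  if (N <= 1) abort("trajectory has fewer than 2 points: MSD undefined")
  if (!is_uniform_grid(traj$t)) abort("trajectory time step is not uniform")
  h <- diff(traj$t)[1]
  if (is.null(max_lag_frames)) {
    max_lag_frames <- max(1L, N - as.integer(min_pairs))
  }
  max_lag_frames <- min(max_lag_frames, N - 1L)
  if (max_lag_frames < 1) abort("trajectory too short for requested lags")
  lags <- seq_len(max_lag_frames)
  x <- traj$x; y <- traj$y
  msd_v <- numeric(max_lag_frames)
  se_v <- numeric(max_lag_frames)
  for (n in lags) {
    sq <- (x[(1 + n):N] - x[1:(N - n)])^2 + (y[(1 + n):N] - y[1:(N - n)])^2
    msd_v[n] <- mean(sq)
    se_v[n] <- if (N - n > 1) sd(sq) / sqrt(N - n) else NA_real_
  }
  res <- tibble(lag = lags * h, msd = msd_v, stderr = se_v,
                n_pairs = N - lags, n_tracks = 1L)
  class(res) <- c("msd_curve", class(res))
  res
}

# per-track MSD values at lags 1..max_lag (no tibble overhead)
msd_vector <- function(x, y, max_lag) {
  N <- length(x)
  vapply(seq_len(max_lag), function(n) {
    mean((x[(1 + n):N] - x[1:(N - n)])^2 + (y[(1 + n):N] - y[1:(N - n)])^2)
  }, 0.0)
}

#' Ensemble-averaged MSD across trajectories
#'
#' Computes the time-averaged MSD of each trajectory and averages across
#' tracks per lag; the standard error is the sample SD across tracks
#' divided by `sqrt(n_tracks)`. All tracks must share the same frame step;
#' lags are capped at the shortest track's maximum lag so every reported
#' lag averages the same number of tracks.
#'
#' @param trajs Trajectory tibble containing at least 2 `track_id`s with a
#'   common step `h`.
#' @param max_lag_frames Passed per track (default: shortest track's
#'   length minus `min_pairs`).
#' @param min_pairs Minimum overlapping pairs per per-track lag.
#' @return An `"msd_curve"` tibble (`lag`, `msd`, `stderr`, `n_pairs` =
#'   summed pairs, `n_tracks`).
#' @export
ensemble_msd <- function(trajs, max_lag_frames = NULL, min_pairs = 10L) {
  validate_trajectory(trajs)
  ids <- unique(trajs$track_id)
  if (length(ids) < 2) abort("ensemble_msd() needs at least 2 trajectories")
  hs <- trajs |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(h = diff(.data$t)[1], n = dplyr::n(), .groups = "drop")
  if (max(hs$h) - min(hs$h) > 1e-9 * max(hs$h)) {
    abort("trajectories have incompatible frame steps h")
  }
  nmin <- min(hs$n)
  if (is.null(max_lag_frames)) {
    max_lag_frames <- max(1L, nmin - as.integer(min_pairs))
  }
  max_lag_frames <- min(max_lag_frames, nmin - 1L)
  trajs <- dplyr::arrange(trajs, .data$track_id, .data$t)
  parts <- split(trajs[c("x", "y")], trajs$track_id)
  M <- vapply(parts, function(p) msd_vector(p$x, p$y, max_lag_frames),
              numeric(max_lag_frames))          # lags x tracks
  if (is.null(dim(M))) M <- matrix(M, nrow = max_lag_frames)
  n_tracks <- ncol(M)
  h <- hs$h[1]
  n_pairs_per <- vapply(parts, nrow, 0L) # points per track
  res <- tibble(
    lag = seq_len(max_lag_frames) * h,
    msd = rowMeans(M),
    stderr = apply(M, 1, sd) / sqrt(n_tracks),
    n_pairs = vapply(seq_len(max_lag_frames),
                     function(n) sum(pmax(n_pairs_per - n, 0L)), 0),
    n_tracks = n_tracks
  )
  class(res) <- c("msd_curve", class(res))
  res
}

#' End-to-end distance of trajectories
#'
#' `end_to_end()` returns the straight-line distance between the first and
#' last point of each track -- a simple indicator of directed motion.
#' `end_to_end_summary()` additionally reports, per condition, the mean
#' distance, the count and fraction of tracks exceeding a threshold, and a
#' histogram.
#'
#' @param trajs Trajectory tibble (one or more tracks, >= 2 points each).
#' @return A tibble `track_id`, `condition`, `end_to_end` (um).
#' @export
end_to_end <- function(trajs) {
  validate_trajectory(trajs)
  trajs |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::summarise(
      condition = if ("condition" %in% names(trajs))
        dplyr::first(.data$condition) else NA_character_,
      end_to_end = sqrt((dplyr::last(.data$x) - dplyr::first(.data$x))^2 +
                        (dplyr::last(.data$y) - dplyr::first(.data$y))^2),
      .groups = "drop"
    )
}

#' @rdname end_to_end
#' @param threshold Distance threshold (um) for the exceedance count
#'   (default 1).
#' @param breaks Histogram breaks passed to [graphics::hist()] semantics
#'   (number of bins).
#' @return For the summary: a list with `per_track` (the [end_to_end()]
#'   table), `summary` (per condition: `mean`, `n_tracks`, `n_above`,
#'   `frac_above`), and `histogram` (per condition bin counts).
#' @export
end_to_end_summary <- function(trajs, threshold = 1, breaks = 20) {
  per <- end_to_end(trajs)
  summ <- per |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      mean = mean(.data$end_to_end),
      n_tracks = dplyr::n(),
      n_above = sum(.data$end_to_end > threshold),
      frac_above = mean(.data$end_to_end > threshold),
      .groups = "drop"
    )
  hi <- per |>
    dplyr::group_by(.data$condition) |>
    dplyr::reframe({
      h <- graphics::hist(.data$end_to_end, breaks = breaks, plot = FALSE)
      tibble(bin_mid = h$mids, count = h$counts)
    })
  list(per_track = per, summary = summ, histogram = hi,
       threshold = threshold)
}

#' Displacement covariance of a trajectory
#'
#' Covariance matrix of the per-frame displacement vectors. Isotropic
#' diffusion gives a near-diagonal matrix; directed motion correlates the
#' x and y displacements, producing non-zero off-diagonal elements. The
#' normalized off-diagonal magnitude (|cov_xy| / sqrt(var_x var_y)) is
#' returned as a directionality indicator.
#'
#' @param traj Single-track trajectory tibble with >= 3 points.
#' @return A list: `cov` (2x2 matrix), `off_diagonal` (um^2),
#'   `directionality` (|correlation| of dx and dy, in \[0, 1\]).
#' @export
displacement_correlation <- function(traj) {
  validate_trajectory(traj)
  traj <- dplyr::arrange(traj, .data$t)
  if (base::nrow(traj) < 3) abort("need at least 3 points")
  d <- cbind(diff(traj$x), diff(traj$y))
  cv <- stats::cov(d)
  vv <- cv[1, 1] * cv[2, 2]
  list(cov = cv, off_diagonal = cv[1, 2],
       directionality = if (vv > 0) abs(cv[1, 2]) / sqrt(vv) else 0)
}
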