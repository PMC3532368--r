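#' Motion parameters for fractional Brownian motion with drift
#'
#' Bundles the parameters of the vesicle motion model: anomalous
#' subdiffusion by fractional Brownian motion (FBM) plus a constant-velocity
#' directed component. The two-dimensional ensemble mean-square displacement
#' implied by these parameters is
#' \deqn{MSD(t) = 4 D_\alpha t^\alpha + v^2 t^2,}
#' with independent FBM processes in x and y each contributing
#' \eqn{2 D_\alpha t^\alpha}.
#'
#' @param D_alpha Anomalous diffusion constant (um^2/s^alpha), >= 0.
#' @param alpha Anomalous exponent, in (0, 2]. `alpha = 1` is ordinary
#'   Brownian diffusion; `alpha < 1` subdiffusion; `alpha > 1` superdiffusion.
#' @param v Drift speed (um/s), >= 0.
#' @param drift_direction Unit vector (length 2) giving the drift direction,
#'   or `NULL` to draw a uniformly random direction per trajectory.
#' @param h Frame step (s).
#' @param n_steps Number of steps per trajectory (the trajectory has
#'   `n_steps + 1` points including the origin).
#' @param condition Free-text condition label attached to trajectories.
#'
#' @return A list of class `"motion_params"`.
#' @seealso [simulate_fbm_trajectory()], [add_drift()], [motion_presets()]
#' @export
motion_params <- function(D_alpha, alpha, v = 0,
                          drift_direction = NULL,
                          h = 1.05, n_steps = 100L,
                          condition = "control") {
  check_number(D_alpha, "D_alpha", min = 0)
  check_number(alpha, "alpha", min = 0, max = 2, strict_min = TRUE)
  check_number(v, "v", min = 0)
  check_number(h, "h", min = 0, strict_min = TRUE)
  n_steps <- check_count(n_steps, "n_steps", min = 1L)
  if (!is.null(drift_direction)) {
    if (length(drift_direction) != 2L || !all(is.finite(drift_direction))) {
      abort("`drift_direction` must be a finite length-2 vector.")
    }
    nrm <- sqrt(sum(drift_direction^2))
    if (abs(nrm - 1) > 1e-6) {
      abort("`drift_direction` must be a unit vector (|direction| = 1).")
    }
  }
  structure(
    list(D_alpha = D_alpha, alpha = alpha, v = v,
         drift_direction = drift_direction, h = h,
         n_steps = n_steps, condition = condition),
    class = "motion_params"
  )
}

#' Study-condition presets for vesicle motion
#'
#' Fitted control-condition parameters of the combined
#' subdiffusion + directed-transport model for sterol-vesicle motion, and
#' the two cytoskeleton-disruption conditions expressed as the reported
#' percentage reductions of `D_alpha` and `v` applied to the control values
#' (with the treated anomalous exponent of 0.65).
#'
#' @return A tibble with columns `condition`, `D_alpha`, `alpha`, `v`,
#'   `n_tracks`, `h`.
#' @export
motion_presets <- function() {
  ctrl_D <- 1.95e-3
  ctrl_v <- 5.52e-3
  tibble(
    condition = c("control", "nocodazole", "cytochalasinD"),
    D_alpha   = c(ctrl_D, ctrl_D * (1 - 0.39), ctrl_D * (1 - 0.40)),
    alpha     = c(0.62, 0.65, 0.65),
    v         = c(ctrl_v, ctrl_v * (1 - 0.52), ctrl_v * (1 - 0.33)),
    n_tracks  = c(210L, 132L, 111L),
    h         = 1.05
  )
}

# Covariance matrix of fractional Gaussian noise (unit variance per step)
# with Hurst exponent H: gamma(k) = 0.5 (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}).
fgn_autocov <- function(k, H) {
  0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

# Cholesky factor (upper) of the n x n fGn covariance. Exact generator:
# sampling z %*% L gives increments with the exact FBM covariance, so the
# ensemble MSD is unbiased at every lag.
fgn_chol <- function(n, H) {
  g <- fgn_autocov(0:(n - 1), H)
  S <- stats::toeplitz(g)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    # near-degenerate (alpha close to 2): ridge-regularize minimally
    ch <- chol(S + diag(1e-10, n))
  }
  ch
}

# Draw `m` independent fGn sample paths of length n (rows = paths).
draw_fgn <- function(m, n, H, chol_factor = NULL) {
  if (abs(H - 0.5) < 1e-12) {
    return(matrix(rnorm(m * n), nrow = m))
  }
  if (abs(H - 1) < 1e-12) {
    # fully correlated increments: B(t) = t * Z
    z <- rnorm(m)
    return(matrix(z, nrow = m, ncol = n))
  }
  if (is.null(chol_factor)) chol_factor <- fgn_chol(n, H)
  matrix(rnorm(m * n), nrow = m) %*% chol_factor
}

new_trajectory_tbl <- function(track_id, t, x, y, condition) {
  tibble(
    track_id = track_id,
    frame = seq_along(t) - 1L,
    t = t, x = x, y = y,
    condition = condition
  )
}

#' Simulate a fractional Brownian motion trajectory
#'
#' Generates a 2D trajectory whose x and y coordinates are independent
#' fractional Brownian motions with Hurst exponent `H = alpha/2`, scaled so
#' that the ensemble MSD is `4 * D_alpha * t^alpha`. Increments are drawn
#' with the exact fractional-Gaussian-noise covariance (Cholesky
#' factorization), so the generator is free of discretization bias. The
#' drift speed in `params` is *not* applied here; use [add_drift()] or
#' [simulate_vesicle_ensemble()].
#'
#' @param params A [motion_params()] object.
#' @param seed Optional integer seed; `NULL` uses the session RNG.
#' @return A trajectory tibble with columns `track_id`, `frame`, `t`
#'   (seconds), `x`, `y` (micrometers), `condition`.
#' @export
simulate_fbm_trajectory <- function(params, seed = NULL) {
  stopifnot(inherits(params, "motion_params"))
  simulate_fbm_trajectories(1L, params, seed = seed)
}

#' Simulate an ensemble of FBM trajectories (no drift)
#'
#' Vectorized version of [simulate_fbm_trajectory()]: the fGn covariance is
#' factorized once and reused for all tracks.
#'
#' @inheritParams simulate_fbm_trajectory
#' @param n_tracks Number of trajectories.
#' @return A single trajectory tibble with `n_tracks` distinct `track_id`s.
#' @export
simulate_fbm_trajectories <- function(n_tracks, params, seed = NULL) {
  stopifnot(inherits(params, "motion_params"))
  n_tracks <- check_count(n_tracks, "n_tracks")
  n <- params$n_steps
  H <- params$alpha / 2
  t <- params$h * (0:n)
  # per-axis increment scale: Var X(t) = 2 D t^alpha  =>  sd = sqrt(2 D) h^H
  sdev <- sqrt(2 * params$D_alpha) * params$h^H
  with_seed_(seed, {
    if (params$D_alpha == 0) {
      dx <- dy <- matrix(0, nrow = n_tracks, ncol = n)
    } else {
      ch <- if (abs(H - 0.5) > 1e-12 && abs(H - 1) > 1e-12) fgn_chol(n, H) else NULL
      dx <- sdev * draw_fgn(n_tracks, n, H, ch)
      dy <- sdev * draw_fgn(n_tracks, n, H, ch)
    }
    purrr::map_dfr(seq_len(n_tracks), function(i) {
      new_trajectory_tbl(
        track_id = i,
        t = t,
        x = c(0, cumsum(dx[i, ])),
        y = c(0, cumsum(dy[i, ])),
        condition = params$condition
      )
    })
  })
}

#' Add a constant-velocity drift to a trajectory
#'
#' Shifts the position at time `t` by `v * t` along `direction`, modelling
#' motor-protein pulling at constant speed. The deterministic contribution
#' to the MSD is exactly `v^2 t^2`, so on top of FBM the ensemble MSD
#' becomes `4 D_alpha t^alpha + v^2 t^2`.
#'
#' @param traj A trajectory tibble (possibly several `track_id`s).
#' @param v Drift speed (um/s).
#' @param direction Length-2 unit vector.
#' @return The trajectory tibble with displaced `x`, `y`.
#' @export
add_drift <- function(traj, v, direction = c(1, 0)) {
  check_number(v, "v", min = 0)
  if (length(direction) != 2L || abs(sqrt(sum(direction^2)) - 1) > 1e-6) {
    abort("`direction` must be a length-2 unit vector.")
  }
  dplyr::mutate(traj,
    x = .data$x + v * direction[1] * .data$t,
    y = .data$y + v * direction[2] * .data$t
  )
}

#' Simulate an ensemble of FBM + drift vesicle trajectories
#'
#' The complete forward model for vesicle motion: each track is an
#' independent FBM realization plus a constant drift of speed `params$v`.
#' The drift direction is `params$drift_direction` if given, otherwise a
#' uniformly random direction per track (isotropic ensemble).
#'
#' @inheritParams simulate_fbm_trajectories
#' @return A trajectory tibble.
#' @export
simulate_vesicle_ensemble <- function(n_tracks, params, seed = NULL) {
  stopifnot(inherits(params, "motion_params"))
  with_seed_(seed, {
    trajs <- simulate_fbm_trajectories(n_tracks, params, seed = NULL)
    if (params$v > 0) {
      if (is.null(params$drift_direction)) {
        th <- runif(n_tracks, 0, 2 * pi)
        dirs <- cbind(cos(th), sin(th))
      } else {
        dirs <- matrix(params$drift_direction, nrow = n_tracks, ncol = 2,
                       byrow = TRUE)
      }
      trajs <- trajs |>
        dplyr::group_by(.data$track_id) |>
        dplyr::group_modify(function(df, key) {
          d <- dirs[key$track_id, ]
          dplyr::mutate(df,
            x = .data$x + params$v * d[1] * .data$t,
            y = .data$y + params$v * d[2] * .data$t
          )
        }) |>
        dplyr::ungroup()
    }
    trajs
  })
}

validate_trajectory <- function(traj) {
  need <- c("track_id", "t", "x", "y")
  missing <- setdiff(need, names(traj))
  if (length(missing)) {
    abort(paste0("trajectory is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!all(is.finite(traj$x)) || !all(is.finite(traj$y))) {
    abort("trajectory positions must be finite")
  }
  invisible(traj)
}

#' Write / read trajectory tables
#'
#' Trajectories are stored as plain CSV with columns
#' `track_id, frame, t_s, x_um, y_um, condition` and a schema-version
#' comment header. Readers reject files whose major schema version is
#' unknown.
#'
#' @param traj Trajectory tibble.
#' @param path File path.
#' @return `write_trajectories()` returns `path` invisibly;
#'   `read_trajectories()` returns a trajectory tibble.
#' @export
write_trajectories <- function(traj, path) {
  validate_trajectory(traj)
  out <- tibble(
    track_id = traj$track_id,
    frame = if ("frame" %in% names(traj)) traj$frame else
      stats::ave(traj$t, traj$track_id, FUN = seq_along) - 1,
    t_s = traj$t, x_um = traj$x, y_um = traj$y,
    condition = if ("condition" %in% names(traj)) traj$condition else NA_character_
  )
  writeLines("# fluctrack_trajectory_schema: 1.0", path)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("fluctrack_trajectory_schema", first)) {
    ver <- sub(".*schema:\\s*", "", first)
    major <- as.integer(strsplit(ver, "[.]")[[1]][1])
    if (!is.na(major) && major > 1L) {
      abort(sprintf("unsupported trajectory schema version %s", ver))
    }
  }
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  out <- tibble(
    track_id = df$track_id, frame = df$frame,
    t = df$t_s, x = df$x_um, y = df$y_um,
    condition = if ("condition" %in% names(df)) df$condition else NA_character_
  )
  validate_trajectory(out)
  out
}
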