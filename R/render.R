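# Photon-count image formation through a two-photon Gaussian focal spot.
#
# The molecular detection function (MDF) of a 2P microscope with lateral
# 1/e^2 beam waist omega_0 is exp(-4 r^2 / omega_0^2): excitation intensity
# squared. `epsilon` is the molecular brightness in expected counts per
# particle per pixel dwell at beam center. Observed counts are Poisson.

mdf_sigma <- function(omega_0) omega_0 / (2 * sqrt(2))

# Add amplitude * exp(-(d^2)/(2 sigma^2)) blobs to an image (matrix), with
# positions in um, pixel centers at (i - 0.5) * pixel_size. Out-of-frame
# contributions are clipped at the frame edge.
add_gaussians <- function(img, x, y, amp, sigma, pixel_size) {
  nr <- nrow(img); nc <- ncol(img)
  sigma <- rep_len(sigma, length(x))
  for (k in seq_along(x)) {
    half <- ceiling(4 * sigma[k] / pixel_size) + 1L
    # column index from x, row index from y
    cj <- x[k] / pixel_size + 0.5
    ri <- y[k] / pixel_size + 0.5
    j0 <- max(1L, floor(cj) - half); j1 <- min(nc, ceiling(cj) + half)
    i0 <- max(1L, floor(ri) - half); i1 <- min(nr, ceiling(ri) + half)
    if (j0 > j1 || i0 > i1) next
    px <- (j0:j1 - 0.5) * pixel_size
    py <- (i0:i1 - 0.5) * pixel_size
    gx <- exp(-(px - x[k])^2 / (2 * sigma[k]^2))
    gy <- exp(-(py - y[k])^2 / (2 * sigma[k]^2))
    img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + amp[k] * outer(gy, gx)
  }
  img
}

poisson_frame <- function(mu) {
  m <- matrix(rpois(length(mu), mu), nrow = nrow(mu))
  m
}

#' Render a snapshot-mode photon-count stack from particle positions
#'
#' Forward model for whole-frame acquisition: each frame is sampled at one
#' instant. Per-pixel expected intensity is the sum over particles of
#' `epsilon * exp(-4 d^2 / omega_0^2)` (two-photon Gaussian detection
#' profile); observed counts are independent Poisson draws.
#'
#' @param positions Tibble with columns `frame` (0-based), `x`, `y` (um).
#'   Positions may lie outside the field of view; they simply contribute
#'   nothing.
#' @param epsilon Molecular brightness: expected counts per particle per
#'   pixel dwell at beam center (>= 0).
#' @param omega_0 Beam waist (um).
#' @param nrow,ncol Frame size in pixels.
#' @param pixel_size Pixel size (um).
#' @param frame_interval Frame interval (s).
#' @param noise Draw Poisson counts (`TRUE`) or return the rounded
#'   expectation (`FALSE`, for noise-free oracles).
#' @param seed Optional integer seed.
#' @return An [image_stack()] in snapshot mode.
#' @export
render_snapshot_stack <- function(positions, epsilon, omega_0 = 0.24,
                                  nrow = 64L, ncol = 64L, pixel_size = 0.1,
                                  frame_interval = 0.1,
                                  noise = TRUE, seed = NULL) {
  check_number(epsilon, "epsilon", min = 0)
  frames_idx <- sort(unique(positions$frame))
  n_frames <- length(frames_idx)
  sigma <- mdf_sigma(omega_0)
  arr <- array(0L, dim = c(n_frames, nrow, ncol))
  with_seed_(seed, {
    for (fi in seq_len(n_frames)) {
      sel <- positions$frame == frames_idx[fi]
      mu <- matrix(0, nrow, ncol)
      if (any(sel)) {
        mu <- add_gaussians(mu, positions$x[sel], positions$y[sel],
                            rep(epsilon, sum(sel)), sigma, pixel_size)
      }
      arr[fi, , ] <- if (noise) poisson_frame(mu) else round(mu)
    }
  })
  image_stack(arr, pixel_size = pixel_size, frame_interval = frame_interval,
              mode = "snapshot")
}

# Brownian positions in a periodic box covering the field of view plus a
# margin; D may be a constant or a function(x, y) -> local D (um^2/s),
# evaluated at the step start (spatially varying mobility).
brownian_step <- function(x, y, D, dt, Lx, Ly) {
  Dloc <- if (is.function(D)) D(x, y) else rep(D, length(x))
  s <- sqrt(2 * pmax(Dloc, 0) * dt)
  list(x = (x + rnorm(length(x), 0, s)) %% Lx,
       y = (y + rnorm(length(y), 0, s)) %% Ly)
}

#' Simulate a snapshot stack of diffusing monomers
#'
#' Convenience forward model for TICS and N&B validation: `n_particles`
#' Brownian monomers in a periodic box extending `margin` um beyond the
#' field of view on every side, propagated exactly between frames and
#' rendered with [render_snapshot_stack()]'s image formation.
#'
#' @param D Diffusion constant (um^2/s), or a `function(x, y)` returning the
#'   local diffusion constant (spatially heterogeneous mobility). `D = 0`
#'   gives immobile emitters.
#' @param n_particles Number of monomers.
#' @param n_frames Number of frames.
#' @inheritParams render_snapshot_stack
#' @param margin Width of the off-field border of the periodic box (um).
#' @param decay_rate Optional per-second exponential intensity decay rate
#'   (photobleaching emulation); 0 disables.
#' @return An [image_stack()] in snapshot mode.
#' @export
simulate_monomer_stack <- function(D, n_particles = 200L, n_frames = 100L,
                                   nrow = 64L, ncol = 64L, pixel_size = 0.1,
                                   frame_interval = 0.05, epsilon = 0.5,
                                   omega_0 = 0.24, margin = 1,
                                   decay_rate = 0, seed = NULL) {
  n_particles <- check_count(n_particles, "n_particles")
  n_frames <- check_count(n_frames, "n_frames")
  Lx <- ncol * pixel_size + 2 * margin
  Ly <- nrow * pixel_size + 2 * margin
  sigma <- mdf_sigma(omega_0)
  arr <- array(0L, dim = c(n_frames, nrow, ncol))
  with_seed_(seed, {
    x <- runif(n_particles, 0, Lx)
    y <- runif(n_particles, 0, Ly)
    for (f in seq_len(n_frames)) {
      if (f > 1) {
        st <- brownian_step(x, y, D, frame_interval, Lx, Ly)
        x <- st$x; y <- st$y
      }
      eps_f <- epsilon * exp(-decay_rate * (f - 1) * frame_interval)
      mu <- add_gaussians(matrix(0, nrow, ncol), x - margin, y - margin,
                          rep(eps_f, n_particles), sigma, pixel_size)
      arr[f, , ] <- poisson_frame(mu)
    }
  })
  image_stack(arr, pixel_size = pixel_size, frame_interval = frame_interval,
              mode = "snapshot")
}

#' Render a raster-scanned photon-count stack of diffusing particles
#'
#' Forward model for raster acquisition: pixel (i, j) of frame f is sampled
#' at time `(f-1) * frame_time + (i-1) * tau_l + (j-1) * tau_p`, and
#' particle motion is propagated exactly (Brownian increments) between
#' consecutive pixel sample times, so fast diffusion imprints on the spatial
#' autocorrelation within a frame. Counts are Poisson. With `D = 0` the
#' expectation is identical to the snapshot renderer on the same scene.
#'
#' @param D Diffusion constant (um^2/s).
#' @param n_particles Number of particles in the periodic box.
#' @param n_frames Number of frames.
#' @param nrow,ncol Frame size in pixels.
#' @param scan A [scan_params()]; `delta_r` is the pixel size.
#' @param epsilon Counts per particle per pixel dwell at beam center.
#' @param margin Off-field border of the periodic box (um).
#' @param seed Optional integer seed.
#' @return An [image_stack()] in raster mode.
#' @export
render_raster_stack <- function(D, n_particles = 200L, n_frames = 50L,
                                nrow = 64L, ncol = 64L,
                                scan = scan_params(), epsilon = 1,
                                margin = 1, seed = NULL) {
  stopifnot(inherits(scan, "scan_params"))
  check_number(D, "D", min = 0)
  check_number(epsilon, "epsilon", min = 0)
  n_particles <- check_count(n_particles, "n_particles")
  n_frames <- check_count(n_frames, "n_frames")
  if (scan$tau_l < ncol * scan$tau_p) {
    abort("scan tau_l is shorter than ncol * tau_p: pixels overrun the line")
  }
  scan_span <- (nrow - 1) * scan$tau_l + (ncol - 1) * scan$tau_p
  if (scan$frame_time <= scan_span) {
    abort("scan frame_time is shorter than the time needed to scan the frame")
  }
  pixel_size <- scan$delta_r
  Lx <- ncol * pixel_size + 2 * margin
  Ly <- nrow * pixel_size + 2 * margin
  w2 <- scan$omega_0^2
  n_px <- nrow * ncol
  # raster order: row-major, time within frame for sample k
  cols <- rep(seq_len(ncol), times = nrow)
  rows <- rep(seq_len(nrow), each = ncol)
  t_px <- (rows - 1) * scan$tau_l + (cols - 1) * scan$tau_p
  dts <- diff(t_px)
  gap <- scan$frame_time - t_px[n_px]
  px <- (cols - 0.5) * pixel_size + margin
  py <- (rows - 0.5) * pixel_size + margin
  arr <- array(0L, dim = c(n_frames, nrow, ncol))
  with_seed_(seed, {
    x <- runif(n_particles, 0, Lx)
    y <- runif(n_particles, 0, Ly)
    for (f in seq_len(n_frames)) {
      if (D > 0) {
        sds <- sqrt(2 * D * dts)
        dX <- rbind(0, matrix(rnorm((n_px - 1) * n_particles), n_px - 1) * sds)
        dY <- rbind(0, matrix(rnorm((n_px - 1) * n_particles), n_px - 1) * sds)
        X <- sweep(apply(dX, 2, cumsum), 2, x, "+") %% Lx
        Y <- sweep(apply(dY, 2, cumsum), 2, y, "+") %% Ly
      } else {
        X <- matrix(x, n_px, n_particles, byrow = TRUE)
        Y <- matrix(y, n_px, n_particles, byrow = TRUE)
      }
      mu <- epsilon * rowSums(exp(-4 * ((X - px)^2 + (Y - py)^2) / w2))
      cnt <- rpois(n_px, mu)
      arr[f, , ] <- matrix(cnt, nrow = nrow, ncol = ncol, byrow = TRUE)
      # advance to next frame start
      x <- X[n_px, ]; y <- Y[n_px, ]
      if (D > 0) {
        st <- brownian_step(x, y, D, gap, Lx, Ly)
        x <- st$x; y <- st$y
      }
    }
  })
  image_stack(arr, pixel_size = pixel_size,
              frame_interval = scan$frame_time, mode = "raster", scan = scan)
}

#' Render vesicle-like Gaussian spots
#'
#' Draws an image of diffraction-limited-or-larger spots as 2D Gaussians
#' with `sigma = FWHM / (2 sqrt(2 log 2))` on a constant background, with
#' optional Poisson noise. Spots centered outside the frame are clipped at
#' the frame edge with a warning.
#'
#' @param centers Two-column matrix or data frame of spot centers (um).
#' @param fwhm Spot FWHM values (um), recycled to the number of spots.
#' @param amplitude Peak amplitudes (expected counts), recycled.
#' @param background Constant background (expected counts).
#' @param nrow,ncol Frame size (pixels).
#' @param pixel_size Pixel size (um).
#' @param noise Poisson noise on/off.
#' @param seed Optional integer seed.
#' @return A single-frame [image_stack()] (snapshot mode).
#' @export
render_vesicle_spots <- function(centers, fwhm, amplitude = 50,
                                 background = 2, nrow = 64L, ncol = 64L,
                                 pixel_size = 0.1, noise = TRUE,
                                 seed = NULL) {
  centers <- as.matrix(centers)
  n <- base::nrow(centers)
  if (any(fwhm <= 0)) abort("`fwhm` must be positive")
  fwhm <- rep_len(fwhm, n)
  amplitude <- rep_len(amplitude, n)
  if (any(amplitude < 0)) abort("`amplitude` must be non-negative")
  check_number(background, "background", min = 0)
  outside <- centers[, 1] < 0 | centers[, 1] > ncol * pixel_size |
    centers[, 2] < 0 | centers[, 2] > nrow * pixel_size
  if (any(outside)) {
    warn(sprintf("%d spot(s) outside the frame; clipped at the edge",
                 sum(outside)))
  }
  sigmas <- fwhm / (2 * sqrt(2 * log(2)))
  mu <- matrix(background, nrow, ncol)
  for (k in seq_len(n)) {
    mu <- add_gaussians(mu, centers[k, 1], centers[k, 2], amplitude[k],
                        sigmas[k], pixel_size)
  }
  frame <- with_seed_(seed, if (noise) poisson_frame(mu) else round(mu))
  arr <- array(0L, dim = c(1L, nrow, ncol))
  arr[1, , ] <- frame
  image_stack(arr, pixel_size = pixel_size, frame_interval = 1,
              mode = "snapshot")
}

#' Render a movie of moving vesicle spots from trajectories
#'
#' Produces a snapshot-mode time-lapse in which each trajectory is drawn as
#' a Gaussian spot per frame -- the fixture for the tracking chain
#' (detection, linking, MSD) with known ground truth.
#'
#' @param traj Trajectory tibble (`track_id`, `frame`, `x`, `y` in um).
#' @param fwhm Spot FWHM (um), one value or one per track (recycled by
#'   `track_id` order).
#' @param amplitude Peak amplitude per spot (expected counts).
#' @param background Constant background (expected counts).
#' @param nrow,ncol,pixel_size Frame geometry.
#' @param frame_interval Frame interval (s); defaults to the trajectory step.
#' @param noise,seed As in [render_vesicle_spots()].
#' @return An [image_stack()] in snapshot mode.
#' @export
render_trajectory_stack <- function(traj, fwhm = 0.45, amplitude = 100,
                                    background = 2, nrow = 128L, ncol = 128L,
                                    pixel_size = 0.1, frame_interval = NULL,
                                    noise = TRUE, seed = NULL) {
  validate_trajectory(traj)
  if (any(fwhm <= 0)) abort("`fwhm` must be positive")
  if (any(amplitude < 0)) abort("`amplitude` must be non-negative")
  check_number(background, "background", min = 0)
  ids <- sort(unique(traj$track_id))
  fwhm <- setNames(rep_len(fwhm, length(ids)), ids)
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  frames_idx <- sort(unique(traj$frame))
  n_frames <- length(frames_idx)
  if (is.null(frame_interval)) {
    ts <- sort(unique(traj$t))
    frame_interval <- if (length(ts) > 1) diff(ts)[1] else 1
  }
  arr <- array(0L, dim = c(n_frames, nrow, ncol))
  with_seed_(seed, {
    for (fi in seq_len(n_frames)) {
      sub <- traj[traj$frame == frames_idx[fi], ]
      mu <- matrix(background, nrow, ncol)
      if (base::nrow(sub)) {
        mu <- add_gaussians(mu, sub$x, sub$y,
                            rep_len(amplitude, base::nrow(sub)),
                            sig[as.character(sub$track_id)], pixel_size)
      }
      arr[fi, , ] <- if (noise) poisson_frame(mu) else round(mu)
    }
  })
  image_stack(arr, pixel_size = pixel_size, frame_interval = frame_interval,
              mode = "snapshot")
}
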