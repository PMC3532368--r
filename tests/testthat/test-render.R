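test_that("mdf_sigma converts the 2P beam waist to a Gaussian sigma", {
  # exp(-4 r^2 / w^2) == exp(-r^2 / (2 sigma^2))  =>  sigma = w / (2 sqrt 2)
  w <- 0.24
  s <- fluctrack:::mdf_sigma(w)
  r <- 0.17
  expect_equal(exp(-4 * r^2 / w^2), exp(-r^2 / (2 * s^2)))
})

test_that("snapshot renderer: zero particles give all-zero counts", {
  pos <- tibble::tibble(frame = 0:4, x = rep(-100, 5), y = rep(-100, 5))
  st <- render_snapshot_stack(pos, epsilon = 10, nrow = 16, ncol = 16,
                              noise = FALSE)
  expect_true(all(st$frames == 0))
  st2 <- render_snapshot_stack(pos, epsilon = 10, nrow = 16, ncol = 16,
                               noise = TRUE, seed = 1)
  expect_true(all(st2$frames == 0))
})

test_that("negative brightness is a parameter error", {
  pos <- tibble::tibble(frame = 0, x = 1, y = 1)
  expect_error(render_snapshot_stack(pos, epsilon = -1), "epsilon")
})

test_that("noise-free expectation peaks at the particle pixel", {
  pos <- tibble::tibble(frame = 0, x = 0.85, y = 1.25)
  st <- render_snapshot_stack(pos, epsilon = 500, nrow = 24, ncol = 24,
                              pixel_size = 0.1, noise = FALSE)
  pk <- which(st$frames[1, , ] == max(st$frames[1, , ]), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(13, 9))  # row from y, col from x
})

test_that("one immobile particle gives Poisson counts (var/mean ~ 1)", {
  pos <- tidyr::expand_grid(frame = 0:999) |>
    dplyr::mutate(x = 0.8, y = 0.8)
  st <- render_snapshot_stack(pos, epsilon = 20, nrow = 16, ncol = 16,
                              pixel_size = 0.1, seed = 12)
  center <- st$frames[, 8, 8]
  expect_gt(mean(center), 5)
  expect_equal(var(center) / mean(center), 1, tolerance = 0.15)
})

test_that("raster and snapshot renderers agree in expectation when D = 0", {
  sc <- scan_params(tau_p = 1e-5, tau_l = 1e-3, delta_r = 0.1,
                    frame_time = 0.1)
  n_frames <- 400
  st_r <- render_raster_stack(D = 0, n_particles = 30, n_frames = n_frames,
                              nrow = 20, ncol = 20, scan = sc, epsilon = 5,
                              margin = 0.5, seed = 31)
  # rebuild the same static scene for the snapshot renderer: D = 0 keeps
  # the initial uniform draw, which depends only on the seed
  mean_r <- apply(st_r$frames, c(2, 3), mean)
  st_r2 <- render_raster_stack(D = 0, n_particles = 30, n_frames = n_frames,
                               nrow = 20, ncol = 20, scan = sc, epsilon = 5,
                               margin = 0.5, seed = 31)
  mean_r2 <- apply(st_r2$frames, c(2, 3), mean)
  expect_identical(mean_r, mean_r2)  # reproducible
  # Poisson mean agreement between the two acquisition models: compare
  # the raster time-average to the snapshot time-average of the same scene
  set.seed(31)
  # draw the same initial positions the renderer used
  # (first two runif calls inside with_seed_)
  x <- runif(30, 0, 20 * 0.1 + 1); y <- runif(30, 0, 20 * 0.1 + 1)
  pos <- purrr::map_dfr(0:(n_frames - 1), function(f) {
    tibble::tibble(frame = f, x = x - 0.5, y = y - 0.5)
  })
  st_s <- render_snapshot_stack(pos, epsilon = 5, omega_0 = sc$omega_0,
                                nrow = 20, ncol = 20, pixel_size = 0.1,
                                seed = 77)
  mean_s <- apply(st_s$frames, c(2, 3), mean)
  # same expectation, independent Poisson sampling: differences are
  # within a few standard errors of the per-pixel mean
  se <- sqrt((mean_r + mean_s + 1e-9) / n_frames)
  expect_lt(max(abs(mean_r - mean_s) / se), 6)
})

test_that("raster scan validates its timing", {
  sc <- scan_params(tau_p = 1e-5, tau_l = 1e-3, delta_r = 0.1,
                    frame_time = 0.01)
  expect_error(
    render_raster_stack(D = 1, n_particles = 5, n_frames = 1,
                        nrow = 64, ncol = 64, scan = sc),
    "frame_time"
  )
  sc2 <- scan_params(tau_p = 1e-4, tau_l = 1e-3, delta_r = 0.1,
                     frame_time = 1)
  expect_error(
    render_raster_stack(D = 1, n_particles = 5, n_frames = 1,
                        nrow = 5, ncol = 64, scan = sc2),
    "overrun"
  )
})

test_that("vesicle spots: sigma follows FWHM and clipping warns", {
  ctr <- rbind(c(1.6, 1.6))
  st <- render_vesicle_spots(ctr, fwhm = 0.45, amplitude = 100,
                             background = 0, nrow = 32, ncol = 32,
                             pixel_size = 0.1, noise = FALSE)
  img <- st$frames[1, , ]
  # half-maximum contour has diameter FWHM: value at r = FWHM/2 is A/2
  sig <- 0.45 / (2 * sqrt(2 * log(2)))
  expect_equal(img[16, 16], round(100 * exp(-(0.05^2 + 0.05^2) / (2 * sig^2))))
  expect_warning(
    render_vesicle_spots(rbind(c(-1, -1)), fwhm = 0.4, nrow = 16, ncol = 16),
    "outside the frame"
  )
  expect_error(render_vesicle_spots(ctr, fwhm = -0.1), "fwhm")
})

test_that("trajectory stack draws each track at its per-frame position", {
  traj <- tibble::tibble(
    track_id = 1L, frame = 0:1, t = c(0, 1),
    x = c(1.05, 2.05), y = c(1.55, 1.55), condition = "c"
  )
  st <- render_trajectory_stack(traj, fwhm = 0.4, amplitude = 200,
                                background = 0, nrow = 32, ncol = 32,
                                pixel_size = 0.1, noise = FALSE)
  f1 <- st$frames[1, , ]; f2 <- st$frames[2, , ]
  expect_equal(unname(which(f1 == max(f1), arr.ind = TRUE)[1, ]), c(16, 11))
  expect_equal(unname(which(f2 == max(f2), arr.ind = TRUE)[1, ]), c(16, 21))
})

test_that("monomer stack supports spatially varying mobility and bleaching", {
  st <- simulate_monomer_stack(D = function(x, y) ifelse(x < 2, 0.01, 1),
                               n_particles = 50, n_frames = 25,
                               nrow = 16, ncol = 16, seed = 5)
  expect_s3_class(st, "image_stack")
  expect_equal(dim(st$frames), c(25, 16, 16))
  # bleaching decay reduces late-frame intensity
  stb <- simulate_monomer_stack(D = 0, n_particles = 200, n_frames = 60,
                                nrow = 16, ncol = 16, epsilon = 5,
                                frame_interval = 0.1, decay_rate = 0.5,
                                seed = 6)
  early <- mean(stb$frames[1:10, , ]); late <- mean(stb$frames[51:60, , ])
  expect_lt(late, 0.5 * early)
})
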