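test_that("parallel straight lines link into one track each", {
  det <- line_detections(n_tracks = 5, n_frames = 20, speed = 0.2,
                         spacing = 3)
  tr <- link_trajectories(det, max_disp_um = 0.5, frame_interval = 0.1)
  expect_equal(dplyr::n_distinct(tr$track_id), 5)
  expect_equal(nrow(tr), 100)
  one <- tr[tr$track_id == tr$track_id[1], ]
  expect_equal(diff(one$x), rep(0.2, 19))
  expect_equal(one$t, one$frame * 0.1)
})

test_that("gap bridging keeps a track through a missing frame", {
  det <- line_detections(1, 11, speed = 0.2)
  miss <- det[det$frame != 5, ]
  no_gap <- link_trajectories(miss, max_disp_um = 0.3, max_gap_frames = 0,
                              min_length = 2)
  expect_equal(dplyr::n_distinct(no_gap$track_id), 2)
  gap <- link_trajectories(miss, max_disp_um = 0.3, max_gap_frames = 1,
                           min_length = 2)
  expect_equal(dplyr::n_distinct(gap$track_id), 1)
  expect_equal(nrow(gap), 10)
  expect_false(5 %in% gap$frame)
})

test_that("displacements beyond the gate start a new track", {
  det <- tibble::tibble(
    frame = c(0L, 1L), x = c(0, 5), y = c(0, 0),
    response = 1, intensity = 1
  )
  tr <- link_trajectories(det, max_disp_um = 1, min_length = 1)
  expect_equal(dplyr::n_distinct(tr$track_id), 2)
  tr2 <- link_trajectories(det, max_disp_um = 6, min_length = 1)
  expect_equal(dplyr::n_distinct(tr2$track_id), 1)
})

test_that("the result is invariant to within-frame detection order", {
  det <- line_detections(4, 12, speed = 0.15, spacing = 2)
  set.seed(3)
  shuffled <- det[sample(nrow(det)), ]
  a <- link_trajectories(det, max_disp_um = 0.5)
  b <- link_trajectories(shuffled, max_disp_um = 0.5)
  expect_identical(a, b)
})

test_that("crossing tracks resolve by nearest displacement", {
  # two constant-velocity tracks crossing; the greedy ascending-cost
  # assignment keeps each on its own line
  f <- 0:10
  det <- dplyr::bind_rows(
    tibble::tibble(frame = f, x = 0.3 * f, y = 2 + 0.0 * f,
                   response = 1, intensity = 1),
    tibble::tibble(frame = f, x = 3 - 0.3 * f, y = 2.2 + 0.0 * f,
                   response = 1, intensity = 1)
  )
  tr <- link_trajectories(det, max_disp_um = 0.5)
  expect_equal(dplyr::n_distinct(tr$track_id), 2)
  expect_equal(nrow(tr), 22)
  # each frame still has both detections assigned
  expect_true(all(table(tr$frame) == 2))
})

test_that("min_length filters short tracks and empty input is fine", {
  det <- dplyr::bind_rows(
    line_detections(1, 10),
    tibble::tibble(frame = 3L, x = 50, y = 50, response = 1, intensity = 1)
  )
  tr <- link_trajectories(det, max_disp_um = 0.5, min_length = 3)
  expect_equal(dplyr::n_distinct(tr$track_id), 1)
  expect_equal(nrow(tr), 10)
  empty <- link_trajectories(det[0, ])
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("track_id", "frame", "t", "x", "y", "condition"))
  expect_error(link_trajectories(det, max_disp_um = 0), "max_disp_um")
})

test_that("interpolate_gaps restores the uniform frame grid", {
  det <- line_detections(1, 11, speed = 0.2)
  miss <- det[!det$frame %in% c(4, 7), ]
  tr <- link_trajectories(miss, max_disp_um = 0.5, max_gap_frames = 1,
                          frame_interval = 0.5)
  expect_equal(nrow(tr), 9)
  filled <- interpolate_gaps(tr)
  expect_equal(filled$frame, 0:10)
  expect_equal(diff(filled$t), rep(0.5, 10))
  # linear motion interpolates exactly
  expect_equal(filled$x, 0.2 * (0:10) + 0.01, tolerance = 1e-12)
  # gap-free input passes through unchanged
  tr2 <- link_trajectories(det, max_disp_um = 0.5, frame_interval = 0.5)
  expect_equal(interpolate_gaps(tr2)$x, tr2$x)
  # the filled track is accepted by the MSD estimator
  expect_no_error(compute_msd(filled, max_lag_frames = 5))
})

test_that("detect -> link recovers simulated vesicle tracks", {
  p <- motion_params(D_alpha = 1.95e-3, alpha = 0.62, v = 5.52e-3,
                     h = 1.05, n_steps = 30)
  traj <- simulate_vesicle_ensemble(12, p, seed = 14)
  traj <- dplyr::mutate(traj,
                        x = x + rep(runif(12, 2, 10), each = 31),
                        y = y + rep(runif(12, 2, 10), each = 31))
  st <- render_trajectory_stack(traj, fwhm = 0.45, amplitude = 150,
                                background = 2, nrow = 128, ncol = 128,
                                pixel_size = 0.1, seed = 15)
  dn <- denoise_stack(st, 0.5)
  resp <- spot_enhance(dn, scale_um = 0.19)
  thr <- median(resp$frames) + 6 * mad(resp$frames)
  det <- detect_spots(resp, threshold = thr, intensity_stack = st)
  tr <- link_trajectories(det, max_disp_um = 0.5, max_gap_frames = 1,
                          frame_interval = p$h, min_length = 20)
  expect_gte(dplyr::n_distinct(tr$track_id), 10)
  # localization: match each recovered point to the nearest truth point
  # of the same frame and check the RMSE
  err <- dplyr::inner_join(
    tr, traj, by = "frame", suffix = c("", "_true"),
    relationship = "many-to-many"
  ) |>
    dplyr::mutate(d2 = (x - x_true)^2 + (y - y_true)^2) |>
    dplyr::group_by(track_id, frame, x, y) |>
    dplyr::summarise(d2 = min(d2), .groups = "drop")
  expect_lt(sqrt(mean(err$d2)), 0.08)
})
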