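test_that("motion_params validates its fields and names the offender", {
  expect_error(motion_params(D_alpha = -1, alpha = 0.6), "D_alpha")
  expect_error(motion_params(D_alpha = 1, alpha = 0), "alpha")
  expect_error(motion_params(D_alpha = 1, alpha = 2.5), "alpha")
  expect_error(motion_params(D_alpha = 1, alpha = 1, v = -1), "v")
  expect_error(
    motion_params(D_alpha = 1, alpha = 1, drift_direction = c(1, 1)),
    "unit vector"
  )
  p <- motion_params(D_alpha = 1e-3, alpha = 0.62, v = 5e-3)
  expect_s3_class(p, "motion_params")
})

test_that("D_alpha = 0 pins the trajectory to the origin", {
  p <- motion_params(D_alpha = 0, alpha = 0.62, n_steps = 20)
  tr <- simulate_fbm_trajectory(p, seed = 1)
  expect_equal(tr$x, rep(0, 21))
  expect_equal(tr$y, rep(0, 21))
  expect_equal(nrow(tr), 21)
  expect_true(all(diff(tr$t) - 1.05 < 1e-12))
})

test_that("alpha = 1 reduces to ordinary Brownian motion", {
  # increments must be iid normal with per-axis sd sqrt(2 D h)
  p <- motion_params(D_alpha = 0.5, alpha = 1, h = 0.2, n_steps = 50)
  tr <- simulate_fbm_trajectories(800, p, seed = 42)
  dx <- unlist(tapply(tr$x, tr$track_id, diff), use.names = FALSE)
  expect_equal(mean(dx), 0, tolerance = 0.01)
  expect_equal(sd(dx), sqrt(2 * 0.5 * 0.2), tolerance = 0.01)
  # lag-1 increment autocorrelation ~ 0 for Brownian
  one <- tr[tr$track_id == 1, ]
  d1 <- diff(one$x)
  expect_lt(abs(cor(d1[-1], d1[-length(d1)])), 0.35)
})

test_that("ensemble MSD matches 4 D t^alpha within 3 SE at every lag", {
  for (alpha in c(0.5, 0.62, 1.0)) {
    p <- motion_params(D_alpha = 2e-3, alpha = alpha, h = 1.05,
                       n_steps = 40)
    tr <- simulate_fbm_trajectories(600, p, seed = 7 + round(100 * alpha))
    curve <- ensemble_msd(tr, max_lag_frames = 30)
    expected <- 4 * 2e-3 * curve$lag^alpha
    z <- abs(curve$msd - expected) / curve$stderr
    expect_lt(max(z), 3)
  }
})

test_that("add_drift shifts by v t and is exactly invertible", {
  p <- motion_params(D_alpha = 1e-3, alpha = 0.7, n_steps = 30)
  tr <- simulate_fbm_trajectory(p, seed = 3)
  shifted <- add_drift(tr, v = 5.52e-3, direction = c(0, 1))
  expect_equal(shifted$y - tr$y, 5.52e-3 * tr$t)
  expect_equal(shifted$x, tr$x)
  back <- add_drift(shifted, v = 0)
  expect_identical(back, shifted)          # v = 0 is the identity
  recovered <- dplyr::mutate(shifted, y = y - 5.52e-3 * t)
  expect_equal(recovered$y, tr$y)
  expect_error(add_drift(tr, v = 1, direction = c(2, 0)), "unit vector")
})

test_that("drift-only displacement is v t", {
  p <- motion_params(D_alpha = 0, alpha = 1, n_steps = 100, h = 1)
  tr <- simulate_fbm_trajectory(p, seed = 1)
  tr <- add_drift(tr, v = 5.52e-3, direction = c(1, 0))
  expect_equal(tr$x[tr$t == 100], 0.552, tolerance = 1e-12)
})

test_that("vesicle ensemble MSD follows 4 D t^a + v^2 t^2", {
  p <- motion_params(D_alpha = 2e-3, alpha = 0.62, v = 0.02, h = 1.05,
                     n_steps = 40)
  tr <- simulate_vesicle_ensemble(600, p, seed = 11)
  curve <- ensemble_msd(tr, max_lag_frames = 30)
  expected <- msd_model(curve$lag, 2e-3, 0.62, 0.02)
  z <- abs(curve$msd - expected) / curve$stderr
  expect_lt(max(z), 4)
})

test_that("fixed drift direction is honored in the ensemble", {
  p <- motion_params(D_alpha = 0, alpha = 1, v = 0.01,
                     drift_direction = c(0, 1), h = 1, n_steps = 10)
  tr <- simulate_vesicle_ensemble(3, p, seed = 5)
  expect_equal(tr$y, rep(0.01 * (0:10), 3))
  expect_equal(tr$x, rep(0, 33))
})

test_that("trajectory CSV round trip preserves data and schema", {
  p <- motion_params(D_alpha = 1e-3, alpha = 0.62, n_steps = 15)
  tr <- simulate_fbm_trajectories(3, p, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(tr, path)
  expect_match(readLines(path, n = 1), "fluctrack_trajectory_schema: 1.0")
  back <- read_trajectories(path)
  expect_equal(back$x, tr$x)
  expect_equal(back$y, tr$y)
  expect_equal(back$t, tr$t)
  expect_equal(back$track_id, tr$track_id)
})

test_that("readers reject unknown major schema versions", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# fluctrack_trajectory_schema: 2.0",
               "track_id,frame,t_s,x_um,y_um,condition",
               "1,0,0,0,0,NA"), path)
  expect_error(read_trajectories(path), "schema version")
})

test_that("motion presets carry the three study conditions", {
  pr <- motion_presets()
  expect_setequal(pr$condition, c("control", "nocodazole", "cytochalasinD"))
  ctrl <- pr[pr$condition == "control", ]
  expect_equal(ctrl$alpha, 0.62)
  expect_equal(ctrl$D_alpha, 1.95e-3)
  expect_equal(ctrl$v, 5.52e-3)
  expect_equal(ctrl$h, 1.05)
  # disrupted conditions reduce transport relative to control
  expect_true(all(pr$D_alpha[pr$condition != "control"] < ctrl$D_alpha))
  expect_true(all(pr$v[pr$condition != "control"] < ctrl$v))
})
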