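# Shared small configuration: strong capture, fast turnover, dense
# binders -- equilibrates in a few hundred steps.
binding_base <- function(...) {
  args <- utils::modifyList(
    list(n_particles = 800L, n_binders = 60L, D_free = 1, D_binder = 0.01,
         k_on = 180, k_off = 5, capture_radius = 0.1, box_size = 5,
         dt = 0.002, n_frames = 1200L),
    list(...)
  )
  do.call(binding_sim_params, args)
}

test_that("binding_sim_params validates fields", {
  expect_error(binding_sim_params(n_particles = 0), "n_particles")
  expect_error(binding_sim_params(D_free = 0), "D_free")
  expect_error(binding_sim_params(k_on = -1), "k_on")
  expect_error(binding_sim_params(capture_radius = 0), "capture_radius")
  expect_error(binding_sim_params(capture_radius = 0.2,
                                  release_radius = 0.1), "release_radius")
  p <- binding_sim_params()
  expect_equal(p$k_on, 0.23)
  expect_equal(p$k_off, 0.5)
  expect_equal(p$release_radius, 1.05 * p$capture_radius)
})

test_that("k_on = 0 gives zero bound particles at every frame", {
  s <- simulate_binding_diffusion(binding_base(k_on = 0, n_frames = 50L),
                                  seed = 1)
  expect_true(all(s$bound_count == 0))
  expect_false(any(s$particles$bound))
})

test_that("particle count is conserved every frame", {
  s <- suppressWarnings(
    simulate_binding_diffusion(binding_base(n_frames = 200L), seed = 2)
  )
  counts <- table(s$particles$frame)
  expect_true(all(counts == 800))
  per_frame_bound <- tapply(s$particles$bound, s$particles$frame, sum)
  expect_equal(unname(as.vector(per_frame_bound)), s$bound_count)
})

test_that("particles stay inside the reflective box", {
  s <- suppressWarnings(
    simulate_binding_diffusion(binding_base(D_free = 50, n_frames = 100L),
                               seed = 3)
  )
  expect_true(all(s$particles$x >= 0 & s$particles$x <= 5))
  expect_true(all(s$particles$y >= 0 & s$particles$y <= 5))
  expect_true(all(s$binders$x >= 0 & s$binders$x <= 5))
})

test_that("lower k_off increases the steady-state bound count", {
  tail_mean <- function(s) mean(utils::tail(s$bound_count, 400))
  hi <- suppressWarnings(
    simulate_binding_diffusion(binding_base(k_off = 5), seed = 4)
  )
  lo <- suppressWarnings(
    simulate_binding_diffusion(binding_base(k_off = 0.5), seed = 4)
  )
  expect_gt(tail_mean(lo), tail_mean(hi) * 1.1)
})

test_that("faster free diffusion decreases the steady-state bound count", {
  tail_mean <- function(s) mean(utils::tail(s$bound_count, 400))
  slow <- suppressWarnings(
    simulate_binding_diffusion(binding_base(D_free = 0.5, n_frames = 1500L),
                               seed = 5)
  )
  fast <- suppressWarnings(
    simulate_binding_diffusion(binding_base(D_free = 300, n_frames = 1500L),
                               seed = 5)
  )
  expect_gt(tail_mean(slow), tail_mean(fast) * 1.2)
})

test_that("bound counts reach a plateau", {
  s <- suppressWarnings(
    simulate_binding_diffusion(binding_base(n_frames = 1500L), seed = 6)
  )
  bc <- s$bound_count
  m1 <- mean(bc[1201:1300]); m2 <- mean(bc[1401:1500])
  noise <- stats::sd(bc[1201:1500]) / 10  # SE scale of a 100-frame mean
  expect_lt(abs(m2 - m1), max(6 * noise, 0.05 * m1))
})

test_that("coarse time steps trigger the rate-resolution warning", {
  expect_warning(
    simulate_binding_diffusion(
      binding_base(dt = 0.1, k_on = 5, n_frames = 5L, n_particles = 50L,
                   n_binders = 5L)
    ),
    "approximation"
  )
})

test_that("the simulation is reproducible from its seed", {
  a <- suppressWarnings(
    simulate_binding_diffusion(binding_base(n_frames = 60L), seed = 77)
  )
  b <- suppressWarnings(
    simulate_binding_diffusion(binding_base(n_frames = 60L), seed = 77)
  )
  expect_identical(a$particles, b$particles)
  expect_identical(a$bound_count, b$bound_count)
})
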