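spot_scene <- function(centers, fwhm = 0.45, amplitude = 150,
                       background = 2, nrow = 48, ncol = 48, noise = TRUE,
                       seed = NULL) {
  render_vesicle_spots(centers, fwhm = fwhm, amplitude = amplitude,
                       background = background, nrow = nrow, ncol = ncol,
                       pixel_size = 0.1, noise = noise, seed = seed)
}

test_that("denoising preserves the frame mean and sigma = 0 is identity", {
  st <- spot_scene(rbind(c(2, 2), c(3.4, 1.2)), seed = 1)
  dn <- denoise_stack(st, gaussian_sigma = 1)
  expect_equal(mean(dn$frames[1, , ]), mean(st$frames[1, , ]),
               tolerance = 1e-3)
  id <- denoise_stack(st, gaussian_sigma = 0)
  expect_equal(id$frames[1, , ], st$frames[1, , ] + 0)
  # smoothing reduces pixel-to-pixel variance
  expect_lt(var(as.vector(dn$frames)), var(as.vector(st$frames + 0)))
})

test_that("median prefilter removes salt-and-pepper outliers", {
  st <- spot_scene(rbind(c(2.4, 2.4)), noise = FALSE)
  frames <- st$frames
  frames[1, 10, 10] <- 5000L
  st2 <- image_stack(frames, st$pixel_size, st$frame_interval)
  dn <- denoise_stack(st2, gaussian_sigma = 0.5, median_prefilter = TRUE)
  expect_lt(dn$frames[1, 10, 10], 100)
})

test_that("LoG enhancement is zero on flat input and peaks at the blob", {
  flat <- image_stack(array(7L, dim = c(1, 32, 32)), 0.1, 1)
  r <- spot_enhance(flat, scale_um = 0.19)
  expect_lt(max(abs(r$frames)), 1e-8)
  st <- spot_scene(rbind(c(2.4, 1.6)), noise = FALSE)
  resp <- spot_enhance(st, scale_um = 0.45 / (2 * sqrt(2 * log(2))))
  pk <- which(resp$frames[1, , ] == max(resp$frames[1, , ]), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(16, 24))  # row = y/px, col = x/px
})

test_that("detect_spots finds sub-pixel centers of noiseless spots", {
  ctr <- rbind(c(1.23, 2.47), c(3.61, 1.09), c(2.5, 3.8))
  st <- spot_scene(ctr, noise = FALSE)
  resp <- spot_enhance(st, scale_um = 0.19)
  det <- detect_spots(resp, threshold = 1, intensity_stack = st)
  expect_equal(nrow(det), 3)
  det <- det[order(det$x), ]
  ctr <- ctr[order(ctr[, 1]), ]
  expect_lt(max(abs(det$x - ctr[, 1])), 0.04)
  expect_lt(max(abs(det$y - ctr[, 2])), 0.04)
  expect_true(all(det$frame == 0))
  expect_true(all(det$intensity > 50))
})

test_that("non-maximum suppression keeps the stronger of two close spots", {
  ctr <- rbind(c(2.0, 2.0), c(2.15, 2.0))
  st1 <- render_vesicle_spots(rbind(c(2.0, 2.0)), fwhm = 0.45,
                              amplitude = 200, background = 0,
                              nrow = 48, ncol = 48, pixel_size = 0.1,
                              noise = FALSE)
  st2 <- render_vesicle_spots(rbind(c(2.15, 2.0)), fwhm = 0.45,
                              amplitude = 100, background = 0,
                              nrow = 48, ncol = 48, pixel_size = 0.1,
                              noise = FALSE)
  st <- image_stack(st1$frames + st2$frames, 0.1, st1$frame_interval)
  resp <- spot_enhance(st, scale_um = 0.19)
  det <- detect_spots(resp, threshold = 1, min_separation_um = 0.3)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x - 2.0), 0.12)   # pulled slightly toward the dimmer spot
})

test_that("empty frames give an empty, well-typed detection table", {
  st <- image_stack(array(0L, dim = c(2, 16, 16)), 0.1, 1)
  det <- detect_spots(st, threshold = 0.5)
  expect_equal(nrow(det), 0)
  expect_named(det, c("frame", "x", "y", "response", "intensity"))
  expect_error(detect_spots(st, threshold = -1), "threshold")
})

test_that("registration recovers a known integer translation", {
  set.seed(9)
  base <- matrix(rpois(64 * 64, 3), 64, 64)
  base[20:24, 30:34] <- base[20:24, 30:34] + 80
  base[40:42, 12:14] <- base[40:42, 12:14] + 60
  shifted <- matrix(0, 64, 64)
  shifted[(1 + 3):64, (1 + 2):64] <- base[1:(64 - 3), 1:(64 - 2)]
  arr <- array(0L, dim = c(2, 64, 64))
  arr[1, , ] <- as.integer(base); arr[2, , ] <- as.integer(shifted)
  st <- image_stack(arr, 0.1, 1)
  reg <- register_translation(st)
  expect_equal(reg$shifts$dy_px[2], 3, tolerance = 0.15)
  expect_equal(reg$shifts$dx_px[2], 2, tolerance = 0.15)
  expect_false(any(reg$shifts$low_confidence))
  # registered frame 2 matches frame 1 away from the borders
  a <- reg$stack$frames[1, 10:50, 10:50]
  b <- reg$stack$frames[2, 10:50, 10:50]
  expect_gt(cor(as.vector(a), as.vector(b)), 0.95)
})

test_that("featureless frames are flagged low-confidence with zero shift", {
  arr <- array(0L, dim = c(2, 32, 32))
  arr[1, 10, 10] <- 100L          # ref has content, frame 2 is blank
  st <- image_stack(arr, 0.1, 1)
  reg <- register_translation(st)
  expect_true(reg$shifts$low_confidence[2])
  expect_equal(reg$shifts$dx_px[2], 0)
  expect_error(register_translation(
    image_stack(array(0L, dim = c(1, 8, 8)), 0.1, 1)
  ), "at least 2")
})
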