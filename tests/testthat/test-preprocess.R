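test_that("background sampling is in-frame, border-dense and honours exclusions", {
  pts <- sample_background_points(c(512, 512))
  expect_true(all(pts[, 1] >= 1 & pts[, 1] <= 512))
  expect_true(all(pts[, 2] >= 1 & pts[, 2] <= 512))
  # density near the border exceeds density in the centre band
  border <- pts[, 1] <= 51 | pts[, 1] >= 462 | pts[, 2] <= 51 | pts[, 2] >= 462
  border_area <- 1 - (410 / 512)^2
  expect_gt(mean(border) / border_area, (1 - mean(border)) / (1 - border_area))

  mask <- matrix(FALSE, 512, 512); mask[, 1:256] <- TRUE
  pts2 <- sample_background_points(c(512, 512), mask)
  expect_true(all(pts2[, 2] > 256))

  mask95 <- matrix(TRUE, 512, 512); mask95[1:114, 1:114] <- FALSE
  expect_error(sample_background_points(c(512, 512), mask95), "90%")
})

test_that("flatfield interpolates a constant and a plane", {
  img <- matrix(500, 128, 128)
  pts <- sample_background_points(c(128, 128))
  ff <- fit_flatfield(img, pts)
  expect_equal(max(abs(ff$surface - 500)) / 500, 0, tolerance = 1e-6)
  # exact reproduction at sample points
  expect_equal(ff$surface[ff$points], ff$values, tolerance = 1e-6)

  ramp <- 100 + 0.5 * matrix(seq_len(128), 128, 128, byrow = TRUE)
  ff2 <- fit_flatfield(ramp, pts)
  held_out <- cbind(sample(10:119, 50), sample(10:119, 50))
  expect_lt(max(abs(ff2$surface[held_out] - ramp[held_out]) / ramp[held_out]),
            0.005)
})

test_that("correcting a rendered biased frame flattens the background", {
  opt <- optics_params(image_shape_px = c(128L, 128L), bias_amplitude_frac = 0.2,
                       noise_model = "none",
                       pillar_centers_px = rbind(c(10, 10), c(118, 118)),
                       pillar_radius_px = 4)
  fr <- render_frame(single_cell_truth(0, 0, 1, 1)[0, ], opt)
  dark <- render_darkfield(opt)
  pts <- sample_background_points(dim(fr$fxm), fr$pillars)
  ff <- fit_flatfield(fr$fxm, pts)
  corr <- correct_illumination(fr$fxm, dark, ff)
  bg <- corr[!fr$pillars]
  expect_equal(mean(bg), 1.0, tolerance = 0.01)
  expect_lt(stats::sd(bg) / mean(bg), 0.01)
})

test_that("correction identities hold", {
  pts <- sample_background_points(c(64, 64))
  surf <- 200 + outer(seq_len(64), seq_len(64), function(r, c) 0.3 * r + 0.1 * c)
  ff <- fit_flatfield(surf, pts)
  expect_equal(correct_illumination(surf, 0, ff),
               matrix(1, 64, 64), tolerance = 1e-6)
  dark <- matrix(50, 64, 64)
  ff2 <- fit_flatfield(surf, pts)
  expect_equal(correct_illumination(dark, dark, ff2),
               matrix(0, 64, 64), tolerance = 1e-9)
  # surface not exceeding darkfield anywhere is rejected
  expect_error(correct_illumination(surf, 1e4, ff), "darkfield")
})

test_that("correction commutes with global intensity scaling", {
  opt <- optics_params(image_shape_px = c(96L, 96L), noise_model = "none")
  tf <- single_cell_truth(31.2, 31.2, 5, 5)
  fr <- render_frame(tf, opt)
  dark <- render_darkfield(opt)
  pts <- sample_background_points(dim(fr$fxm), fr$pillars)
  c1 <- correct_illumination(fr$fxm, dark, fit_flatfield(fr$fxm, pts))
  sc <- 3.7
  c2 <- correct_illumination(fr$fxm * sc, dark * sc,
                             fit_flatfield(fr$fxm * sc, pts))
  expect_equal(c1, c2, tolerance = 1e-8)
})

test_that("correction is idempotent up to refit on background", {
  opt <- optics_params(image_shape_px = c(96L, 96L), noise_model = "none",
                       bias_amplitude_frac = 0.2)
  fr <- render_frame(single_cell_truth(0, 0, 1, 1)[0, ], opt)
  dark <- render_darkfield(opt)
  pts <- sample_background_points(dim(fr$fxm), fr$pillars)
  c1 <- correct_illumination(fr$fxm, dark, fit_flatfield(fr$fxm, pts))
  c2 <- correct_illumination(c1, 0, fit_flatfield(c1, pts))
  bg <- !fr$pillars
  expect_lt(max(abs(c2[bg] - c1[bg]) / c1[bg]), 0.005)
})

test_that("degenerate sample sets are rejected or regularised", {
  img <- matrix(100, 32, 32)
  expect_error(fit_flatfield(img, cbind(1:5, 1:5)), "at least 10")
  dup <- cbind(rep(c(2, 30, 16, 5, 9, 25, 13, 20, 28, 7, 18), 2),
               rep(c(3, 29, 14, 22, 6, 11, 27, 17, 8, 24, 19), 2))
  ff <- fit_flatfield(img, dup)  # duplicates collapsed, still interpolates
  expect_equal(mean(ff$surface), 100, tolerance = 1e-6)
})
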