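test_that("Scharr magnitude matches hand-convolved references", {
  expect_true(all(edge_magnitude(matrix(7, 20, 20)) == 0))
  # unit vertical step: derivative taps (-1,0,1)/2 give 0.5 in the two
  # columns adjacent to the step, smoothing weights sum to 1 along rows
  img <- matrix(0, 11, 12); img[, 7:12] <- 1
  m <- edge_magnitude(img)
  expect_equal(m[3:9, 6], rep(0.5, 7))
  expect_equal(m[3:9, 7], rep(0.5, 7))
  expect_true(all(m[, c(1:4, 9:12)] == 0))
  # 45-degree step: Gx = Gy = 13/32 next to the step (hand-convolved), so the
  # peak magnitude is sqrt(2) * 13/32 = 0.5745, ~15% above the vertical case
  diag_img <- outer(1:24, 1:24, function(r, c) as.numeric(c - r >= 0))
  md <- edge_magnitude(diag_img)
  expect_equal(max(md[8:16, 8:16]), sqrt(2) * 13 / 32, tolerance = 1e-12)
})

test_that("Scharr magnitude agrees with a naive direct convolution", {
  set.seed(4)
  img <- matrix(runif(18 * 15), 18, 15)
  sm <- c(3, 10, 3) / 16; dv <- c(-1, 0, 1) / 2
  kx <- outer(sm, dv); ky <- outer(dv, sm)
  ref <- matrix(0, 18, 15)
  cl <- function(i, n) pmin(pmax(i, 1), n)
  for (r in 1:18) for (c in 1:15) {
    gx <- 0; gy <- 0
    for (dr in -1:1) for (dc in -1:1) {
      v <- img[cl(r + dr, 18), cl(c + dc, 15)]
      gx <- gx + kx[dr + 2, dc + 2] * v
      gy <- gy + ky[dr + 2, dc + 2] * v
    }
    ref[r, c] <- sqrt(gx^2 + gy^2)
  }
  expect_equal(edge_magnitude(img), ref, tolerance = 1e-12)
})

test_that("log-space thresholding matches the log-normal closed form", {
  set.seed(7)
  mag <- matrix(rlnorm(1e6), 1000, 1000)
  mask <- threshold_edges(mag)
  # threshold e^(mu + sigma) = e for lognormal(0, 1)
  expect_lt(abs(attr(mask, "threshold") - exp(1)), 0.01)
  # marked fraction 1 - Phi(1) = 15.9%
  expect_lt(abs(mean(mask) - (1 - pnorm(1))), 0.002)
})

test_that("degenerate magnitude fields yield empty masks", {
  m <- matrix(2, 16, 16)
  expect_false(any(threshold_edges(m)))  # sd = 0, strict threshold
  expect_warning(z <- threshold_edges(matrix(0, 8, 8)), "zero")
  expect_false(any(z))
})

test_that("flood fill closes rings but not open or separate contours", {
  ring <- ring_mask(c(41, 41), 21, 21, 8, 10)
  filled <- fill_foreground(ring)
  expect_true(all(filled[disk_mask(c(41, 41), 21, 21, 8)]))
  gap <- ring
  gap[20:22, 29:41] <- FALSE  # 3-px breach
  expect_equal(sum(fill_foreground(gap)), sum(gap))
  two <- ring_mask(c(41, 81), 21, 21, 6, 8) | ring_mask(c(41, 81), 21, 60, 6, 8)
  f2 <- fill_foreground(two)
  expect_equal(max(EBImage::bwlabel(EBImage::Image(f2 * 1))), 2)
})

test_that("seed detection finds spot centres and obeys the merge rule", {
  sh <- c(64, 64)
  spot <- function(cr, cc) {
    rows <- matrix(seq_len(sh[1]), sh[1], sh[2])
    cols <- matrix(seq_len(sh[2]), sh[1], sh[2], byrow = TRUE)
    500 * exp(-((rows - cr)^2 + (cols - cc)^2) / (2 * 2.5^2))
  }
  two <- 100 + spot(20, 20) + spot(20, 50)
  s <- detect_seeds(two)
  expect_equal(nrow(s), 2)
  expect_true(all(abs(s[, 1] - 20) <= 1))
  expect_true(all(abs(sort(s[, 2]) - c(20, 50)) <= 1))

  expect_equal(nrow(detect_seeds(matrix(100, 64, 64))), 0)
  set.seed(1)
  blank_noisy <- matrix(100 + rnorm(64 * 64, 0, 3), 64, 64)
  expect_equal(nrow(detect_seeds(blank_noisy)), 0)

  close2 <- 100 + spot(30, 30) + spot(30, 32)
  expect_equal(nrow(detect_seeds(close2, d_min = 5)), 1)
})

test_that("seeded watershed splits touching disks and partitions the foreground", {
  fg <- disk_mask(c(50, 80), 25, 25, 12) | disk_mask(c(50, 80), 25, 48, 12)
  lab <- label_cells(fg, rbind(c(25, 25), c(25, 48)))
  expect_setequal(unique(as.vector(lab[lab > 0])), c(1L, 2L))
  a1 <- sum(lab == 1); a2 <- sum(lab == 2)
  disk_area <- sum(disk_mask(c(50, 80), 25, 25, 12))
  expect_equal(a1, disk_area, tolerance = 0.05)
  expect_equal(a2, disk_area, tolerance = 0.05)
  expect_equal(a1 + a2, sum(fg))  # labels partition the foreground

  one <- label_cells(fg, rbind(c(25, 25)))
  expect_equal(sum(one == 1), sum(fg))

  expect_warning(empty <- label_cells(fg, NULL), "no seeds")
  expect_true(all(empty == 0))
  expect_warning(label_cells(fg, rbind(c(25, 25), c(1, 79))), "dropped")
})

test_that("constrained dilation grows labels without collisions", {
  fg <- disk_mask(c(60, 60), 30, 30, 10)
  lab <- label_cells(fg, rbind(c(30, 30)))
  expect_identical(dilate_labels(lab, 0), lab)
  d2 <- dilate_labels(lab, 2)
  expect_equal(sum(d2 == 1), pi * 12^2, tolerance = 0.05)
  expect_equal(max(d2), 1L)

  # two adjacent labels: dilation must not overlap or change ownership
  fg2 <- disk_mask(c(50, 90), 25, 28, 12) | disk_mask(c(50, 90), 25, 51, 12)
  lab2 <- label_cells(fg2, rbind(c(25, 28), c(25, 51)))
  d3 <- dilate_labels(lab2, 3)
  expect_true(all(d3[lab2 == 1] == 1))
  expect_true(all(d3[lab2 == 2] == 2))
  expect_gte(sum(d3 == 1), sum(lab2 == 1))
  # pillars stay unlabelled
  pil <- matrix(FALSE, 60, 60); pil[45:60, ] <- TRUE
  d4 <- dilate_labels(lab, 5, pillars = pil)
  expect_true(all(d4[pil] == 0))
})

test_that("segmentation is invariant to global intensity scaling", {
  opt <- optics_params(image_shape_px = c(96L, 96L), noise_model = "none")
  tf <- rbind(single_cell_truth(26, 26, 5, 5),
              single_cell_truth(41.6, 41.6, 6, 4, cell_id = 2L))
  fr <- render_frame(tf, opt)
  dark <- render_darkfield(opt)
  pts <- sample_background_points(dim(fr$fxm), fr$pillars)
  corr <- correct_illumination(fr$fxm, dark, fit_flatfield(fr$fxm, pts))
  seg_of <- function(img) {
    edges <- threshold_edges(edge_magnitude(img))
    fill_foreground(edges)
  }
  expect_identical(seg_of(corr), seg_of(corr * 11.3))
})
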