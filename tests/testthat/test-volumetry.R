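test_that("alpha calibration validates its inputs", {
  cal <- alpha_calibration(1.0, 0.1, 8)
  expect_equal(cal$alpha, 0.9 / 8)
  expect_error(alpha_calibration(0.1, 1.0, 8), "exceed")
  expect_error(alpha_calibration(1.0, 0.1, 0), "h_chamber")
})

test_that("local background takes the annulus median and excludes neighbours", {
  img <- matrix(1.0, 60, 60)
  lab <- matrix(0L, 60, 60)
  lab[disk_mask(c(60, 60), 30, 30, 8)] <- 1L
  expect_equal(local_background(img, lab, 1), 1.0)

  # neighbour occupying part of the annulus at half intensity is excluded
  lab2 <- lab
  nb <- disk_mask(c(60, 60), 30, 45, 6)
  lab2[nb] <- 2L
  img2 <- img
  img2[nb] <- 0.5
  expect_equal(local_background(img2, lab2, 1), 1.0)

  # fully crowded annulus flags the cell as unmeasurable
  lab3 <- lab
  lab3[lab3 == 0] <- 2L
  bgv <- local_background(img, lab3, 1)
  expect_true(is.na(bgv))
  expect_true(attr(bgv, "unmeasurable"))
})

test_that("dye-exclusion volume follows the deficit sum", {
  lab <- matrix(0L, 20, 20)
  lab[8:12, 8:12] <- 1L
  img <- matrix(1.0, 20, 20)
  expect_equal(as.numeric(cell_volume(img, lab, 1, 1.0, 0.1125, 0.65^2)), 0)

  # one pixel at pillar level: V = h * pixel_area
  lab1 <- matrix(0L, 20, 20); lab1[10, 10] <- 1L
  img1 <- matrix(1.0, 20, 20); img1[10, 10] <- 0.1
  cal <- alpha_calibration(1.0, 0.1, 8)
  expect_equal(as.numeric(cell_volume(img1, lab1, 1, 1.0, cal, 0.65^2)),
               8 * 0.65^2, tolerance = 1e-12)

  # negative total floors at zero with a flag
  imgn <- matrix(1.2, 20, 20)
  vn <- cell_volume(imgn, lab, 1, 1.0, cal, 0.65^2)
  expect_equal(as.numeric(vn), 0)
  expect_true(attr(vn, "flagged"))
  ve <- cell_volume(img, lab, 99, 1.0, cal, 0.65^2)
  expect_equal(as.numeric(ve), 0)
  expect_true(attr(ve, "flagged"))
})

test_that("volumes are invariant to global intensity scaling", {
  opt <- clean_optics(shape = c(96L, 96L),
                      pillar_centers_px = rbind(c(8, 8)), pillar_radius_px = 3)
  H <- hemisphere_heights(c(96, 96), 48, 48, 4, opt$pixel_size_um)
  fr <- render_from_heights(H, opt)
  corr <- (fr$fxm - opt$darkfield_counts) / opt$i_max_counts
  lab <- matrix(0L, 96, 96)
  lab[H > 0] <- 1L
  lab <- dilate_labels(lab, 2)
  measure <- function(img) {
    imax <- local_background(img, lab, 1, pillars = fr$pillars)
    imin <- pillar_i_min(img, fr$pillars)
    cal <- alpha_calibration(imax, imin, opt$chamber_height_um)
    as.numeric(cell_volume(img, lab, 1, imax, cal, opt$pixel_size_um^2))
  }
  v1 <- measure(corr)
  v2 <- measure(corr * 7.3)
  expect_equal(v1, v2, tolerance = 1e-12)
  expect_equal(v1, 2 / 3 * pi * 4^3, tolerance = 0.02)
})

test_that("volumetry is additive over disjoint cells", {
  opt <- clean_optics(shape = c(96L, 96L),
                      pillar_centers_px = rbind(c(8, 8)), pillar_radius_px = 3)
  H1 <- hemisphere_heights(c(96, 96), 30, 30, 4, opt$pixel_size_um)
  H2 <- hemisphere_heights(c(96, 96), 64, 64, 3.5, opt$pixel_size_um)
  fr <- render_from_heights(H1 + H2, opt)
  corr <- (fr$fxm - opt$darkfield_counts) / opt$i_max_counts
  cal <- alpha_calibration(1.0, opt$i_min_counts / opt$i_max_counts,
                           opt$chamber_height_um)
  pa <- opt$pixel_size_um^2
  lab_joint <- matrix(0L, 96, 96); lab_joint[H1 + H2 > 0] <- 1L
  lab_sep <- matrix(0L, 96, 96); lab_sep[H1 > 0] <- 1L; lab_sep[H2 > 0] <- 2L
  v_joint <- as.numeric(cell_volume(corr, lab_joint, 1, 1.0, cal, pa))
  v_sep <- as.numeric(cell_volume(corr, lab_sep, 1, 1.0, cal, pa)) +
    as.numeric(cell_volume(corr, lab_sep, 2, 1.0, cal, pa))
  expect_equal(v_joint, v_sep, tolerance = 1e-12)
})

test_that("renderer and volumetry are adjoint for arbitrary noiseless height fields", {
  set.seed(5)
  opt <- clean_optics(shape = c(96L, 96L),
                      pillar_centers_px = rbind(c(8, 8)), pillar_radius_px = 3)
  for (rep in 1:5) {
    H <- matrix(0, 96, 96)
    for (b in 1:4) {
      cr <- runif(1, 25, 70); cc <- runif(1, 25, 70)
      sg <- runif(1, 3, 8); amp <- runif(1, 1, 6)
      rows <- matrix(seq_len(96), 96, 96)
      cols <- matrix(seq_len(96), 96, 96, byrow = TRUE)
      H <- H + amp * exp(-((rows - cr)^2 + (cols - cc)^2) / (2 * sg^2))
    }
    H <- pmin(H, opt$chamber_height_um)
    H[fxmtools::pillar_mask(opt)] <- 0
    fr <- render_from_heights(H, opt)
    corr <- (fr$fxm - opt$darkfield_counts) / opt$i_max_counts
    cal <- alpha_calibration(1.0, opt$i_min_counts / opt$i_max_counts,
                             opt$chamber_height_um)
    v <- sum(1.0 - corr[!fr$pillars]) / cal$alpha * opt$pixel_size_um^2
    expect_equal(v, sum(H) * opt$pixel_size_um^2, tolerance = 0.01)
  }
})

test_that("trace normalisation uses the pre-stimulus window", {
  tr <- data.frame(t_s = seq(0, 990, by = 10), volume_um3 = 250)
  out <- normalize_trace(tr, t_stim_s = 600)
  expect_true(all(out$normalized == 1.0))
  expect_true(all(out$rolling_um3 == 250))

  tr2 <- tr
  tr2$volume_um3 <- ifelse(tr2$t_s >= 600, 500, 250)
  out2 <- normalize_trace(tr2, t_stim_s = 600)
  expect_true(all(out2$normalized[out2$t_s >= 600] == 2.0))

  # insufficient pre-stimulus coverage: kept raw, excluded from normalisation
  tr3 <- tr[tr$t_s >= 560, ]
  out3 <- normalize_trace(tr3, t_stim_s = 600)
  expect_true(all(is.na(out3$normalized)))
  expect_equal(out3$volume_um3, tr3$volume_um3)
})

test_that("population summary averages per-replicate medians with a t CI", {
  one <- data.frame(replicate = 1, cell_id = rep(1:5, 2),
                    t_s = rep(c(0, 10), each = 5), normalized = 1.0)
  s1 <- population_volume_summary(one)
  expect_equal(s1$mean, c(1, 1))
  expect_equal(s1$ci_hi - s1$ci_lo, c(0, 0))

  three <- data.frame(replicate = rep(1:3, each = 2), cell_id = rep(1:2, 3),
                      t_s = 0, normalized = rep(c(1.10, 1.15, 1.20), each = 2))
  s3 <- population_volume_summary(three)
  expect_equal(s3$mean, 1.15)
  expect_equal(s3$n_replicates, 3)
  expect_true(s3$ci_lo < 1.15 && s3$ci_hi > 1.15)
})

test_that("simulated replicates recover the configured swelling in the CI", {
  meds <- vapply(1:4, function(r) {
    gt <- simulate_kinetics(kinetics_params(n_cells = 40, seed = 100 + r))
    p <- attr(gt, "params")
    nv <- unlist(lapply(split(gt, gt$cell_id), function(g)
      g$volume_um3 / mean(g$volume_um3[g$t_s >= 480 & g$t_s < 600])))
    median(nv[gt$t_s == p$stim_time_s + 1200])
  }, numeric(1))
  df <- data.frame(replicate = 1:4, cell_id = 1, t_s = 0, normalized = meds)
  s <- population_volume_summary(df)
  expect_true(s$ci_lo <= 1.15 && s$ci_hi >= 1.15)
})
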