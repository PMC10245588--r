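test_that("windowed velocity matches closed forms", {
  still <- data.frame(t_s = seq(10, 200, by = 10), x_um = 4, y_um = -2)
  v <- velocity(still, tau = 3)
  expect_true(all(v[4:17] == 0))
  expect_true(all(is.na(v[c(1:3, 18:20)])))

  line <- data.frame(t_s = seq(0, 300, by = 10),
                     x_um = seq(0, 300, by = 10) * 0.2 * 0.6,
                     y_um = seq(0, 300, by = 10) * 0.2 * 0.8)
  for (tau in c(1, 3, 5))
    expect_true(all(abs(na.omit(velocity(line, tau)) - 0.2) < 1e-12))

  # back-and-forth path returning to start each 2-tau window
  zig <- data.frame(t_s = seq(10, 400, by = 10),
                    x_um = rep(c(0, 3), 20), y_um = 0)
  expect_true(all(na.omit(velocity(zig, tau = 1)) == 0))

  bad <- data.frame(t_s = c(1, 2, 2, 3), x_um = 0, y_um = 0)
  expect_error(velocity(bad), "strictly increasing")
})

test_that("velocity is invariant under time reversal", {
  tr <- persistent_track(60, seed = 3)
  rev_tr <- data.frame(t_s = tr$t_s, x_um = rev(tr$x_um), y_um = rev(tr$y_um))
  expect_equal(velocity(tr, 3), rev(velocity(rev_tr, 3)))
})

test_that("angular alignment hits its endpoints", {
  straight <- data.frame(x_um = seq(0, 40, by = 2), y_um = 0)
  a <- angular_alignment(straight, spacing_um = 10)
  expect_true(all(na.omit(a) == 1))

  # out-and-back: at the turning point the path ahead retraces the path behind
  outback <- data.frame(x_um = c(seq(0, 20, by = 2), seq(18, 0, by = -2)),
                        y_um = 0)
  turn <- 11  # index of x = 20
  expect_equal(angular_alignment(outback, spacing_um = 10)[turn], -1)

  # right-angle turn maps to 0
  corner <- data.frame(x_um = c(seq(0, 20, by = 2), rep(20, 10)),
                       y_um = c(rep(0, 11), seq(2, 20, by = 2)))
  expect_equal(angular_alignment(corner, spacing_um = 10)[11], 0)
})

test_that("Brownian walks give near-zero median alignment", {
  tr <- random_walk_track(600, step_um = 1, seed = 11)
  a <- na.omit(angular_alignment(tr, spacing_um = 10))
  expect_gte(length(a), 200)
  expect_lt(abs(median(a)), 0.1)
})

test_that("alignment is bounded and invariant to rotation and translation", {
  # step length chosen away from an exact divisor of the spacing so that the
  # A/C sample choice is not on a floating-point knife edge under rotation
  tr <- persistent_track(80, step_um = 1.9, seed = 7)
  a <- angular_alignment(tr)
  expect_true(all(na.omit(a) >= -1 & na.omit(a) <= 1))
  th <- 1.1
  rot <- data.frame(x_um = cos(th) * tr$x_um - sin(th) * tr$y_um + 50,
                    y_um = sin(th) * tr$x_um + cos(th) * tr$y_um - 20)
  expect_equal(angular_alignment(rot), a, tolerance = 1e-9)
})

test_that("alignment is stable to the spacing choice on persistent walks", {
  meds <- vapply(1:6, function(s) {
    tr <- persistent_track(400, step_um = 2, turn_sd = 0.25, seed = s)
    vapply(c(8, 10, 12), function(sp)
      median(angular_alignment(tr, spacing_um = sp), na.rm = TRUE), numeric(1))
  }, numeric(3))
  spread <- apply(meds, 2, function(m) max(m) - min(m))
  expect_lt(mean(spread), 0.1)  # +/- 0.05 around the 10-um value
  expect_gt(median(meds[2, ]), 0.5)  # persistent post-stimulus walks align
})

test_that("population motility summary aggregates medians with an SD band", {
  one <- data.frame(replicate = 1, t_s = rep(c(0, 10), each = 3), value = 0.2)
  s1 <- population_motility_summary(one)
  expect_equal(s1$mean, c(0.2, 0.2))
  expect_equal(s1$sd, c(0, 0))

  three <- data.frame(replicate = rep(1:3, each = 2), t_s = 0,
                      value = rep(c(0.1, 0.2, 0.3), each = 2))
  s3 <- population_motility_summary(three)
  expect_equal(s3$mean, 0.2)
  expect_equal(s3$sd, 0.1)
})

test_that("simulated kinetics recover the configured plateau speed", {
  # run past the speed ramp (~3 time constants) and measure with a short
  # window so the persistent walk's chord shortening stays negligible
  gt <- simulate_kinetics(kinetics_params(n_cells = 30, duration_s = 4200,
                                          seed = 21))
  p <- attr(gt, "params")
  v <- unlist(lapply(split(gt, gt$cell_id), velocity, tau = 1))
  late <- gt$t_s > p$stim_time_s + 3 * p$speed_tau_s
  vm <- median(v[late], na.rm = TRUE)
  expect_equal(unname(vm), p$post_speed_um_s, tolerance = 0.1)
})
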