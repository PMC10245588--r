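# Shared fixture builders. Everything is generated in code at test time.

# One-row ground-truth table for a single paraboloid cell.
single_cell_truth <- function(x_um, y_um, radius_um, dome_height_um,
                              cell_id = 1L, frame = 1L) {
  data.frame(cell_id = cell_id, frame = frame, t_s = 0,
             x_um = x_um, y_um = y_um,
             volume_um3 = pi * radius_um^2 * dome_height_um / 2,
             area_um2 = pi * radius_um^2,
             dome_height_um = dome_height_um, radius_um = radius_um)
}

# Clean optics for analytic checks: no bias, no noise, no pillars in the
# centre of a small frame.
clean_optics <- function(shape = c(64L, 64L), ...) {
  optics_params(image_shape_px = shape, bias_amplitude_frac = 0,
                noise_model = "none", ...)
}

# Hemispherical cap height field (um) centred at (cr, cc) px.
hemisphere_heights <- function(shape, cr, cc, radius_um, pixel_size_um) {
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  r2 <- ((rows - cr)^2 + (cols - cc)^2) * pixel_size_um^2
  h2 <- radius_um^2 - r2
  sqrt(pmax(h2, 0))
}

# Binary ring (circular annulus) mask.
ring_mask <- function(shape, cr, cc, r_in, r_out) {
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  d <- sqrt((rows - cr)^2 + (cols - cc)^2)
  d >= r_in & d <= r_out
}

disk_mask <- function(shape, cr, cc, r) {
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (rows - cr)^2 + (cols - cc)^2 <= r^2
}

# Isotropic random-walk track (um), unit steps of length step_um.
random_walk_track <- function(n, step_um = 1, seed = 1) {
  set.seed(seed)
  th <- runif(n - 1, 0, 2 * pi)
  data.frame(t_s = seq_len(n) * 10,
             x_um = c(0, cumsum(step_um * cos(th))),
             y_um = c(0, cumsum(step_um * sin(th))))
}

# Persistent walk with gaussian turning noise.
persistent_track <- function(n, step_um = 2, turn_sd = 0.25, seed = 1) {
  set.seed(seed)
  th <- cumsum(c(runif(1, 0, 2 * pi), rnorm(n - 2, 0, turn_sd)))
  data.frame(t_s = seq_len(n) * 10,
             x_um = c(0, cumsum(step_um * cos(th))),
             y_um = c(0, cumsum(step_um * sin(th))))
}
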