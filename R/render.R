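#' Rasterise ground-truth cells into a per-pixel height field
#'
#' Each cell is a paraboloid dome \eqn{h(r) = h_{apex}(1 - r^2/R^2)} centred
#' on its ground-truth centroid. Overlapping domes add and the total is capped
#' at the chamber height.
#'
#' @param truth_frame rows of an `fxm_ground_truth` data frame for one frame
#'   (columns `x_um`, `y_um`, `dome_height_um`, `radius_um`).
#' @param optics an [optics_params()] object.
#' @return numeric matrix of heights (um), same shape as the frame.
#' @export
height_field <- function(truth_frame, optics) {
  stopifnot(inherits(optics, "fxm_optics_params"))
  nr <- optics$image_shape_px[1]; nc <- optics$image_shape_px[2]
  px <- optics$pixel_size_um
  H <- matrix(0, nr, nc)
  for (k in seq_len(nrow(truth_frame))) {
    # image convention: row ~ y, col ~ x
    cr <- truth_frame$y_um[k] / px + 0.5
    cc <- truth_frame$x_um[k] / px + 0.5
    R <- truth_frame$radius_um[k] / px
    h0 <- truth_frame$dome_height_um[k]
    r0 <- max(1L, floor(cr - R)); r1 <- min(nr, ceiling(cr + R))
    c0 <- max(1L, floor(cc - R)); c1 <- min(nc, ceiling(cc + R))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; ccx <- c0:c1
    d2 <- outer((rr - cr)^2, (ccx - cc)^2, `+`)
    dome <- h0 * pmax(0, 1 - d2 / R^2)
    H[rr, ccx] <- H[rr, ccx] + dome
  }
  pmin(H, optics$chamber_height_um)
}

apply_noise <- function(img, optics) {
  switch(optics$noise_model,
         none = img,
         poisson = matrix(stats::rpois(length(img), pmax(img, 0)),
                          nrow(img), ncol(img)),
         gaussian = img + matrix(stats::rnorm(length(img), 0,
                                              optics$gaussian_sd_counts),
                                 nrow(img), ncol(img)))
}

#' Render one multi-channel FxM frame from ground truth
#'
#' Produces the dye-exclusion (FxM), nuclei and cytoplasm channels for a
#' single frame under the imaging model of [optics_params()]: the FxM signal
#' falls linearly with object height, pillars render at the pillar-level
#' signal, a smooth multiplicative bias and additive darkfield are applied,
#' and noise is added last. Cells whose footprint intersects a pillar are
#' occluded by the pillar and reported in attribute `pillar_overlaps` with a
#' warning.
#'
#' @param truth_frame ground-truth rows for one frame (see [height_field()]).
#' @param optics an [optics_params()] object.
#' @param seed optional integer seed for the noise draw.
#' @return list with matrices `fxm`, `nuclei`, `cyto` (counts) and the
#'   logical `pillars` mask; attribute `pillar_overlaps` lists occluded cell
#'   ids.
#' @export
render_frame <- function(truth_frame, optics, seed = NULL) {
  stopifnot(inherits(optics, "fxm_optics_params"))
  nr <- optics$image_shape_px[1]; nc <- optics$image_shape_px[2]
  px <- optics$pixel_size_um
  H <- height_field(truth_frame, optics)
  pil <- pillar_mask(optics)

  overlaps <- integer(0)
  if (nrow(truth_frame) && any(pil & H > 0)) {
    for (k in seq_len(nrow(truth_frame))) {
      cr <- truth_frame$y_um[k] / px + 0.5
      cc <- truth_frame$x_um[k] / px + 0.5
      d <- sqrt((which(pil, arr.ind = TRUE)[, 1] - cr)^2 +
                  (which(pil, arr.ind = TRUE)[, 2] - cc)^2)
      if (any(d <= truth_frame$radius_um[k] / px))
        overlaps <- c(overlaps, truth_frame$cell_id[k])
    }
    if (length(overlaps))
      warning("cells overlapping pillars are occluded: ",
              paste(overlaps, collapse = ", "), call. = FALSE)
  }

  fxm <- fxm_signal_from_heights(H, optics, pil)
  B <- bias_field(optics)

  nuc <- matrix(0, nr, nc)
  cyto <- matrix(0, nr, nc)
  if (nrow(truth_frame)) {
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    s2 <- 2 * optics$nucleus_sigma_px^2
    for (k in seq_len(nrow(truth_frame))) {
      cr <- truth_frame$y_um[k] / px + 0.5
      cc <- truth_frame$x_um[k] / px + 0.5
      nuc <- nuc + optics$nucleus_amplitude_counts *
        exp(-((rows - cr)^2 + (cols - cc)^2) / s2)
    }
    cyto <- optics$cyto_amplitude_counts * (H > 0.05)
  }
  nuc <- optics$darkfield_counts + B * nuc
  cyto <- optics$darkfield_counts + B * cyto

  out <- with_seed(seed, list(fxm = apply_noise(fxm, optics),
                              nuclei = apply_noise(nuc, optics),
                              cyto = apply_noise(cyto, optics),
                              pillars = pil))
  attr(out, "pillar_overlaps") <- overlaps
  out
}

# Noiseless FxM channel for a height field: dark + B * (i_max - alpha*h),
# pillars at the pillar-level signal.
fxm_signal_from_heights <- function(H, optics, pil = pillar_mask(optics)) {
  alpha <- (optics$i_max_counts - optics$i_min_counts) / optics$chamber_height_um
  signal <- optics$i_max_counts - alpha * pmin(H, optics$chamber_height_um)
  signal[pil] <- optics$i_min_counts
  optics$darkfield_counts + bias_field(optics) * signal
}

#' Render the FxM channel from an arbitrary height field
#'
#' Low-level renderer used for validation against analytic shapes: any
#' per-pixel height map (um) is converted to the dye-exclusion signal under
#' the same imaging model as [render_frame()] (heights capped at the chamber
#' height, pillars at the pillar-level signal, bias and darkfield applied,
#' then noise).
#'
#' @param heights numeric matrix of object heights (um), shape matching
#'   `optics$image_shape_px`.
#' @param optics an [optics_params()] object.
#' @param seed optional integer seed for the noise draw.
#' @return list with matrix `fxm` and logical `pillars`.
#' @export
render_from_heights <- function(heights, optics, seed = NULL) {
  stopifnot(inherits(optics, "fxm_optics_params"),
            all(dim(heights) == optics$image_shape_px))
  pil <- pillar_mask(optics)
  fxm <- fxm_signal_from_heights(heights, optics, pil)
  list(fxm = with_seed(seed, apply_noise(fxm, optics)), pillars = pil)
}

#' Darkfield reference frame
#'
#' The camera offset image used for darkfield subtraction. Treated as a
#' noise-averaged calibration image, i.e. constant.
#'
#' @param optics an [optics_params()] object.
#' @return numeric matrix of darkfield counts.
#' @export
render_darkfield <- function(optics) {
  matrix(optics$darkfield_counts,
         optics$image_shape_px[1], optics$image_shape_px[2])
}

#' Write a rendered scene to disk
#'
#' Renders every frame of a ground-truth table and writes one multi-page
#' 16-bit TIFF per channel plus a darkfield TIFF, the ground truth as CSV and
#' the scene configuration as YAML.
#'
#' @param truth an `fxm_ground_truth` table from [simulate_kinetics()].
#' @param optics an [optics_params()] object.
#' @param dir output directory (created if missing).
#' @param seed integer seed for the per-frame noise draws.
#' @param scale counts-to-\[0,1\] divisor used for TIFF encoding (recorded in
#'   the YAML so readers can undo it).
#' @return invisibly, the paths written.
#' @export
write_scene <- function(truth, optics, dir, seed = 1L, scale = 4096) {
  stopifnot(inherits(truth, "fxm_ground_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  frames <- sort(unique(truth$frame))
  chans <- list(fxm = list(), nuclei = list(), cyto = list())
  for (f in frames) {
    fr <- render_frame(truth[truth$frame == f, , drop = FALSE], optics,
                       seed = seed + f)
    for (ch in names(chans)) chans[[ch]][[length(chans[[ch]]) + 1L]] <-
        pmin(pmax(fr[[ch]] / scale, 0), 1)
  }
  paths <- character(0)
  for (ch in names(chans)) {
    p <- file.path(dir, paste0(ch, ".tif"))
    tiff::writeTIFF(chans[[ch]], p, bits.per.sample = 16L)
    paths <- c(paths, p)
  }
  pdark <- file.path(dir, "darkfield.tif")
  tiff::writeTIFF(pmin(render_darkfield(optics) / scale, 1), pdark,
                  bits.per.sample = 16L)
  pcsv <- file.path(dir, "ground_truth.csv")
  utils::write.csv(truth[, c("frame", "cell_id", "x_um", "y_um",
                             "volume_um3", "area_um2")],
                   pcsv, row.names = FALSE)
  pyml <- file.path(dir, "scene.yaml")
  cfg <- attr(truth, "params")
  yaml::write_yaml(list(kinetics = unclass(cfg),
                        optics = lapply(unclass(optics), function(x)
                          if (is.matrix(x)) apply(x, 1, as.list) else x),
                        tiff_scale = scale, seed = seed),
                   pyml)
  invisible(c(paths, pdark, pcsv, pyml))
}
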