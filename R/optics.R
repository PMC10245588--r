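#' Optical and chamber parameters for synthetic FxM scenes
#'
#' Describes the imaging model used by [render_frame()]. The FxM chamber has a
#' flat roof of height `chamber_height_um` supported by pillars; extracellular
#' dye fills everything not occupied by cells or pillars, so the noiseless FxM
#' signal at a pixel of object height \eqn{h(x,y)} is
#' \deqn{I(x,y) = D + B(x,y)\,[I_{max} - \alpha\,h(x,y)], \quad
#'       \alpha = (I_{max} - I_{min})/h_{chamber},}
#' where \eqn{D} is the additive darkfield offset, \eqn{B} a smooth
#' multiplicative illumination bias (vignette) of amplitude
#' `bias_amplitude_frac`, and \eqn{I_{min}} the residual pillar-level signal
#' (pillars span the whole chamber height). Shot or read noise is applied
#' last according to `noise_model`.
#'
#' @param image_shape_px image size as (rows, cols).
#' @param pixel_size_um pixel pitch (um/px).
#' @param chamber_height_um chamber (roof) height (um).
#' @param i_max_counts background dye signal above darkfield (counts).
#' @param i_min_counts pillar-level signal above darkfield (counts); must be
#'   below `i_max_counts`.
#' @param darkfield_counts additive camera offset (counts).
#' @param bias_amplitude_frac peak-to-trough amplitude of the multiplicative
#'   illumination bias, as a fraction of 1.
#' @param noise_model one of `"poisson"` (shot noise on total counts),
#'   `"gaussian"` (additive, sd `gaussian_sd_counts`) or `"none"`.
#' @param gaussian_sd_counts sd of gaussian read noise (counts).
#' @param pillar_centers_px matrix of pillar centres (row, col) in px;
#'   defaults to one pillar 16 px inside each corner.
#' @param pillar_radius_px pillar radius (px).
#' @param nucleus_amplitude_counts,nucleus_sigma_px amplitude and width of
#'   the Gaussian nuclear spots in the nuclei channel.
#' @param cyto_amplitude_counts amplitude of the cytoplasmic channel over the
#'   cell footprint.
#' @return an object of class `fxm_optics_params`.
#' @export
optics_params <- function(image_shape_px = c(256L, 256L),
                          pixel_size_um = 0.65,
                          chamber_height_um = 8,
                          i_max_counts = 1000,
                          i_min_counts = 100,
                          darkfield_counts = 100,
                          bias_amplitude_frac = 0.2,
                          noise_model = c("poisson", "gaussian", "none"),
                          gaussian_sd_counts = 5,
                          pillar_centers_px = NULL,
                          pillar_radius_px = 6,
                          nucleus_amplitude_counts = 800,
                          nucleus_sigma_px = 2.5,
                          cyto_amplitude_counts = 400) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(image_shape_px) == 2L, all(image_shape_px >= 16))
  check_scalar(pixel_size_um, "pixel_size_um", lower = 0, open_lower = TRUE)
  check_scalar(chamber_height_um, "chamber_height_um", lower = 0, open_lower = TRUE)
  check_scalar(darkfield_counts, "darkfield_counts", lower = 0)
  check_scalar(i_max_counts, "i_max_counts", lower = 0, open_lower = TRUE)
  check_scalar(i_min_counts, "i_min_counts", lower = 0)
  if (i_max_counts <= i_min_counts)
    stop("i_max_counts must exceed i_min_counts", call. = FALSE)
  check_scalar(bias_amplitude_frac, "bias_amplitude_frac", lower = 0, upper = 1,
               open_upper = TRUE)
  if (is.null(pillar_centers_px)) {
    nr <- image_shape_px[1]; nc <- image_shape_px[2]
    pillar_centers_px <- rbind(c(16, 16), c(16, nc - 15),
                               c(nr - 15, 16), c(nr - 15, nc - 15))
  }
  pillar_centers_px <- as.matrix(pillar_centers_px)
  p <- list(image_shape_px = as.integer(image_shape_px),
            pixel_size_um = pixel_size_um,
            chamber_height_um = chamber_height_um,
            i_max_counts = i_max_counts, i_min_counts = i_min_counts,
            darkfield_counts = darkfield_counts,
            bias_amplitude_frac = bias_amplitude_frac,
            noise_model = noise_model,
            gaussian_sd_counts = gaussian_sd_counts,
            pillar_centers_px = pillar_centers_px,
            pillar_radius_px = pillar_radius_px,
            nucleus_amplitude_counts = nucleus_amplitude_counts,
            nucleus_sigma_px = nucleus_sigma_px,
            cyto_amplitude_counts = cyto_amplitude_counts)
  class(p) <- "fxm_optics_params"
  p
}

#' Binary mask of the chamber pillars
#'
#' @param optics an [optics_params()] object.
#' @return logical matrix, `TRUE` on pillar pixels.
#' @export
pillar_mask <- function(optics) {
  stopifnot(inherits(optics, "fxm_optics_params"))
  nr <- optics$image_shape_px[1]; nc <- optics$image_shape_px[2]
  m <- matrix(FALSE, nr, nc)
  r2 <- optics$pillar_radius_px^2
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (i in seq_len(nrow(optics$pillar_centers_px))) {
    ctr <- optics$pillar_centers_px[i, ]
    m <- m | ((rows - ctr[1])^2 + (cols - ctr[2])^2 <= r2)
  }
  m
}

#' Multiplicative illumination bias field
#'
#' A smooth radially symmetric vignette centred on the frame,
#' \eqn{B = (1 - a/2) + a\,\exp(-2\rho^2)} with \eqn{\rho} the radius
#' normalised to the half-diagonal, so that B spans `bias_amplitude_frac`
#' peak-to-trough.
#'
#' @param optics an [optics_params()] object.
#' @return numeric matrix of per-pixel multiplicative bias.
#' @export
bias_field <- function(optics) {
  stopifnot(inherits(optics, "fxm_optics_params"))
  nr <- optics$image_shape_px[1]; nc <- optics$image_shape_px[2]
  a <- optics$bias_amplitude_frac
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  rho2 <- ((rows - (nr + 1) / 2)^2 + (cols - (nc + 1) / 2)^2) /
    (((nr - 1)^2 + (nc - 1)^2) / 4)
  (1 - a / 2) + a * exp(-2 * rho2)
}
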