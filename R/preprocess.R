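#' Sinusoidally spaced background sample points
#'
#' Deterministic sampling pattern for flatfield estimation: grid coordinates
#' are placed at \eqn{(1-\cos\pi u)/2} for equispaced \eqn{u}, which
#' compresses the spacing towards every frame border (background statistics
#' are scarcest there, and illumination falls off fastest). Points falling in
#' the exclusion mask (cells, pillars) are dropped; the grid is refined until
#' at least `n_min` points survive.
#'
#' @param image_shape (rows, cols) of the frame.
#' @param exclusion_mask optional logical matrix marking pixels that must not
#'   be sampled (foreground and pillars).
#' @param n_per_axis initial number of grid lines per axis.
#' @param n_min minimum number of returned points.
#' @return integer matrix with columns `row`, `col`.
#' @export
sample_background_points <- function(image_shape, exclusion_mask = NULL,
                                     n_per_axis = 24, n_min = 40) {
  nr <- image_shape[1]; nc <- image_shape[2]
  if (!is.null(exclusion_mask)) {
    stopifnot(all(dim(exclusion_mask) == c(nr, nc)))
    if (mean(exclusion_mask) > 0.9)
      stop("exclusion mask covers more than 90% of the frame; ",
           "background cannot be estimated", call. = FALSE)
  }
  k <- n_per_axis
  repeat {
    u <- (seq_len(k) - 0.5) / k
    rows <- pmin(pmax(round(1 + (nr - 1) * (1 - cos(pi * u)) / 2), 1L), nr)
    cols <- pmin(pmax(round(1 + (nc - 1) * (1 - cos(pi * u)) / 2), 1L), nc)
    pts <- unique(cbind(row = rep(rows, times = length(cols)),
                        col = rep(cols, each = length(rows))))
    if (!is.null(exclusion_mask))
      pts <- pts[!exclusion_mask[pts], , drop = FALSE]
    if (nrow(pts) >= n_min || k > 16 * n_per_axis) break
    k <- ceiling(k * 1.5)
  }
  if (nrow(pts) < n_min)
    stop("could not place ", n_min, " background points outside the ",
         "exclusion mask", call. = FALSE)
  pts
}

#' Fit a multiquadric flatfield surface to background samples
#'
#' Interpolates the background intensity with multiquadric radial basis
#' functions \eqn{\phi(r) = \sqrt{r^2 + \epsilon^2}} centred on the sample
#' points, augmented with an affine polynomial term (the standard
#' augmentation that makes constant and planar backgrounds reproduced
#' exactly), then evaluates the surface over the whole frame. The shape
#' parameter defaults to the mean nearest-neighbour sample spacing, a
#' standard well-conditioned choice. Duplicate sample points are collapsed;
#' if the interpolation system is numerically singular a small ridge is
#' added and a warning raised.
#'
#' @param image numeric matrix (raw FxM frame).
#' @param points sample points from [sample_background_points()].
#' @param eps multiquadric shape parameter (px); default mean NN spacing.
#' @param ridge optional ridge added to the RBF block diagonal (smoothing
#'   instead of exact interpolation).
#' @return object of class `fxm_flatfield` with elements `points`, `values`,
#'   `eps`, `weights`, `poly` (affine coefficients) and the evaluated
#'   `surface` (same shape as `image`).
#' @export
fit_flatfield <- function(image, points, eps = NULL, ridge = 0) {
  image <- as_matrix_image(image)
  points <- unique(as.matrix(points))
  m <- nrow(points)
  if (m < 10)
    stop("need at least 10 sample points to fit a flatfield", call. = FALSE)
  vals <- image[points]
  d2 <- outer(points[, 1], points[, 1], `-`)^2 +
        outer(points[, 2], points[, 2], `-`)^2
  if (is.null(eps)) {
    dd <- sqrt(d2); diag(dd) <- Inf
    eps <- mean(apply(dd, 1, min))
  }
  phi <- sqrt(d2 + eps^2)
  if (ridge > 0) phi <- phi + diag(ridge, m)
  P <- cbind(1, points[, 1], points[, 2])
  A <- rbind(cbind(phi, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(vals, 0, 0, 0)
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    warning("flatfield interpolation matrix is numerically singular; ",
            "adding a small ridge", call. = FALSE)
    A[seq_len(m), seq_len(m)] <- A[seq_len(m), seq_len(m)] +
      diag(1e-8 * mean(diag(phi)), m)
    solve(A, rhs)
  })
  w <- sol[seq_len(m)]
  poly <- sol[m + 1:3]
  surface <- eval_multiquadric(dim(image), points, w, poly, eps)
  structure(list(points = points, values = vals, eps = eps, weights = w,
                 poly = poly, surface = surface),
            class = "fxm_flatfield")
}

# Evaluate the augmented multiquadric expansion over a full frame, in row
# blocks to bound the size of the pixel-by-centre distance matrix.
eval_multiquadric <- function(shape, points, weights, poly, eps, block = 64L) {
  nr <- shape[1]; nc <- shape[2]
  out <- matrix(0, nr, nc)
  cols <- seq_len(nc)
  dc2 <- outer(cols, points[, 2], `-`)^2   # nc x m, reused for every row block
  for (r0 in seq(1L, nr, by = block)) {
    r1 <- min(nr, r0 + block - 1L)
    rows <- r0:r1
    dr2 <- outer(rows, points[, 1], `-`)^2  # b x m
    acc <- matrix(0, length(rows), nc)
    for (j in seq_len(nrow(points))) {
      acc <- acc + weights[j] *
        sqrt(outer(dr2[, j], dc2[, j], `+`) + eps^2)
    }
    out[rows, ] <- acc + poly[1] + poly[2] * rows +
      matrix(poly[3] * cols, length(rows), nc, byrow = TRUE)
  }
  out
}

#' Darkfield-subtract and flatfield-normalise an FxM frame
#'
#' Subtracts the darkfield from both the raw frame and the fitted flatfield
#' surface, then divides, so that dye-filled background pixels come out at
#' ~1.0 and intensities become independent of the illumination profile and of
#' any global intensity scale.
#'
#' @param raw numeric matrix, raw FxM frame.
#' @param darkfield darkfield image (matrix) or scalar offset.
#' @param model an `fxm_flatfield` fitted on the same frame.
#' @return normalised image (matrix); background approximately 1.0.
#' @export
correct_illumination <- function(raw, darkfield, model) {
  raw <- as_matrix_image(raw)
  stopifnot(inherits(model, "fxm_flatfield"))
  if (is.matrix(darkfield)) stopifnot(all(dim(darkfield) == dim(raw)))
  denom <- model$surface - darkfield
  if (any(denom <= 0))
    stop("flatfield surface does not exceed the darkfield everywhere; ",
         "cannot normalise", call. = FALSE)
  (raw - darkfield) / denom
}

#' Light Gaussian denoiser (default pre-segmentation hook)
#'
#' The segmentation stage accepts any `function(image) -> image` as its
#' denoiser; this default applies a small Gaussian blur, enough to tame shot
#' noise before edge enhancement without displacing cell boundaries.
#'
#' @param image numeric matrix.
#' @param sigma Gaussian sd in px.
#' @return smoothed matrix.
#' @export
denoise_gaussian <- function(image, sigma = 1) {
  as_matrix_image(EBImage::gblur(as_matrix_image(image), sigma = sigma))
}
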