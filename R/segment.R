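#' Scharr gradient magnitude
#'
#' Edge enhancement with the Scharr operator: smoothing taps (3, 10, 3)/16
#' along one axis and central-difference taps (-1, 0, 1)/2 along the other,
#' with replicate border padding. Returns
#' \eqn{\sqrt{G_x^2 + G_y^2}} per pixel.
#'
#' @param image 2-D numeric matrix.
#' @return matrix of non-negative gradient magnitudes.
#' @export
edge_magnitude <- function(image) {
  image <- as_matrix_image(image)
  sm <- c(3, 10, 3) / 16
  dv <- c(-1, 0, 1) / 2
  gx <- filter3_sep(image, sm, dv)  # derivative across columns
  gy <- filter3_sep(image, dv, sm)  # derivative down rows
  sqrt(gx^2 + gy^2)
}

#' Threshold an edge-magnitude field at one log-space SD above the mean
#'
#' Edge magnitudes in FxM frames are approximately log-normal, so the
#' statistics are taken on log-magnitudes (zeros excluded): a pixel is called
#' edge when \eqn{\log m > \mu_{\log} + \sigma_{\log}}, i.e.
#' \eqn{m > e^{\mu + \sigma}}. For an exactly log-normal field this marks the
#' brightest ~15.9 percent of pixels.
#'
#' @param magnitude matrix from [edge_magnitude()].
#' @return logical edge mask with attributes `threshold`, `log_mean`,
#'   `log_sd`. All-zero input yields an empty mask with a warning.
#' @export
threshold_edges <- function(magnitude) {
  magnitude <- as_matrix_image(magnitude)
  pos <- magnitude[magnitude > 0]
  if (!length(pos)) {
    warning("edge magnitudes are identically zero; returning empty mask",
            call. = FALSE)
    mask <- matrix(FALSE, nrow(magnitude), ncol(magnitude))
    attr(mask, "threshold") <- NA_real_
    return(mask)
  }
  lm <- log(pos)
  thr <- exp(mean(lm) + stats::sd(lm))
  mask <- magnitude > thr
  attr(mask, "threshold") <- thr
  attr(mask, "log_mean") <- mean(lm)
  attr(mask, "log_sd") <- stats::sd(lm)
  mask
}

#' Flood-fill the regions enclosed by an edge mask
#'
#' Regions fully encapsulated by edges become foreground (the edges
#' themselves included); anything connected to the frame border remains
#' background, so open contours do not fill.
#'
#' @param edges logical edge mask.
#' @return logical foreground mask.
#' @export
fill_foreground <- function(edges) {
  edges <- as_matrix_image(edges) > 0
  filled <- EBImage::fillHull(EBImage::Image(edges * 1))
  as_matrix_image(filled) > 0
}

#' Detect nuclear seed points
#'
#' Pluggable seed detector used to nucleate instance separation: the nuclei
#' channel is smoothed and regional maxima (plateaus of the grayscale
#' max-filter) above an adaptive intensity floor become seeds. The floor is
#' `median + max(8 * mad, rel_floor * (max - median))`, which returns no
#' seeds on a blank (noise-only) frame. Seeds closer than `d_min` px are
#' merged, keeping the brighter one. Any `function(image) ->
#' matrix(row, col)` with the same contract can replace this in the
#' pipeline.
#'
#' @param nuclei numeric matrix (nuclei channel).
#' @param sigma smoothing sd (px).
#' @param d_min minimum mutual seed distance (px); also sets the
#'   neighbourhood of the regional-maximum test.
#' @param rel_floor relative intensity floor as a fraction of the frame's
#'   dynamic range above the median.
#' @return integer matrix with columns `row`, `col` (possibly 0 rows).
#' @export
detect_seeds <- function(nuclei, sigma = 2, d_min = 5, rel_floor = 0.1) {
  nuclei <- as_matrix_image(nuclei)
  sm <- as_matrix_image(EBImage::gblur(nuclei, sigma = sigma))
  med <- stats::median(sm)
  thr <- med + max(8 * stats::mad(sm), rel_floor * (max(sm) - med))
  win <- max(3L, 2L * (as.integer(d_min) %/% 2L) + 1L)
  mx <- as_matrix_image(EBImage::dilate(sm, EBImage::makeBrush(win, "box")))
  peaks <- sm >= mx & sm > thr
  if (!any(peaks)) return(cbind(row = integer(0), col = integer(0)))
  # collapse plateau pixels of one maximum into a single point
  lab <- as_matrix_image(EBImage::bwlabel(EBImage::Image(peaks * 1)))
  idx <- which(lab > 0)
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  labs <- lab[idx]
  cr <- round(tapply(rows, labs, mean))
  cc <- round(tapply(cols, labs, mean))
  peak <- tapply(sm[idx], labs, max)
  seeds <- cbind(row = cr, col = cc)
  # brightest-first greedy merge of seeds closer than d_min
  ord <- order(-peak)
  keep <- integer(0)
  for (i in ord) {
    if (!length(keep) ||
        all((seeds[keep, 1] - seeds[i, 1])^2 +
            (seeds[keep, 2] - seeds[i, 2])^2 >= d_min^2))
      keep <- c(keep, i)
  }
  out <- seeds[sort(keep), , drop = FALSE]
  storage.mode(out) <- "integer"
  rownames(out) <- NULL
  out
}

#' Separate the foreground into cells by seeded watershed
#'
#' Partitions the binary foreground among the seed points by region growing
#' on geodesic distance within the mask (the watershed of the inverted
#' distance transform for blob-shaped objects). Seeds falling outside the
#' foreground are dropped with a warning; with no usable seeds an empty label
#' map is returned with a warning. Pillar pixels are never labelled.
#'
#' @param foreground logical foreground mask.
#' @param seeds matrix (row, col) of seed points.
#' @param pillars optional logical pillar mask.
#' @return integer label matrix (0 = background, k = cell k).
#' @export
label_cells <- function(foreground, seeds, pillars = NULL) {
  fg <- as_matrix_image(foreground) > 0
  if (!is.null(pillars)) fg <- fg & !pillars
  empty <- matrix(0L, nrow(fg), ncol(fg))
  if (is.null(seeds) || nrow(seeds) == 0) {
    warning("no seeds supplied; returning empty label map", call. = FALSE)
    return(empty)
  }
  inside <- fg[as.matrix(seeds)]
  if (!all(inside)) {
    warning(sum(!inside), " seed(s) fall outside the foreground and were dropped",
            call. = FALSE)
    seeds <- seeds[inside, , drop = FALSE]
  }
  if (nrow(seeds) == 0) {
    warning("no seeds inside the foreground; returning empty label map",
            call. = FALSE)
    return(empty)
  }
  seed_img <- empty
  seed_img[as.matrix(seeds)] <- seq_len(nrow(seeds))
  lab <- EBImage::propagate(EBImage::Image(matrix(0, nrow(fg), ncol(fg))),
                            EBImage::Image(seed_img), mask = fg)
  out <- as_matrix_image(lab)
  storage.mode(out) <- "integer"
  out
}

#' Dilate labels without label collisions
#'
#' Grows every label outward by `radius` px (disc structuring element) into
#' unlabelled, non-pillar space. Expansion is shared by geodesic proximity,
#' so adjacent labels stop at their mutual boundary and never overlap. Used
#' to measure a slightly larger area than the cell footprint so scattered
#' dye signal at the cell border is captured in the volume sum.
#'
#' @param labels integer label matrix.
#' @param radius dilation radius in px; 0 returns the input unchanged.
#' @param pillars optional logical pillar mask that must stay unlabelled.
#' @return integer label matrix with the same label set.
#' @export
dilate_labels <- function(labels, radius = 2, pillars = NULL) {
  labels <- as_matrix_image(labels)
  storage.mode(labels) <- "integer"
  if (radius == 0 || !any(labels > 0)) return(labels)
  fg <- labels > 0
  brush <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  grown <- as_matrix_image(EBImage::dilate(EBImage::Image(fg * 1), brush)) > 0
  if (!is.null(pillars)) grown <- grown & !pillars
  grown <- grown | fg
  out <- as_matrix_image(
    EBImage::propagate(EBImage::Image(matrix(0, nrow(fg), ncol(fg))),
                       EBImage::Image(labels), mask = grown))
  storage.mode(out) <- "integer"
  out
}

#' Remove connected foreground specks below a minimum area
#'
#' @param foreground logical mask.
#' @param min_area_px smallest component area kept.
#' @return cleaned logical mask.
#' @export
prune_small_components <- function(foreground, min_area_px = 20) {
  fg <- as_matrix_image(foreground) > 0
  if (!any(fg)) return(fg)
  lab <- as_matrix_image(EBImage::bwlabel(EBImage::Image(fg * 1)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area_px)
  matrix(lab %in% keep, nrow(fg), ncol(fg))
}
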