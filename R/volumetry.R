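#' Intensity-to-height calibration for FxM
#'
#' The dye signal falls linearly with object height; the conversion factor is
#' \deqn{\alpha = (I_{max} - I_{min}) / h_{chamber}}
#' where `i_max` is the cell-free (local background) intensity, `i_min` the
#' intensity over the pillars that span the full chamber height, and
#' `h_chamber` the chamber height in um. In flatfield-normalised units
#' `i_max` is ~1.
#'
#' @param i_max background (zero-height) intensity.
#' @param i_min pillar (full-height) intensity; must be below `i_max`.
#' @param h_chamber chamber height (um), > 0.
#' @return object of class `fxm_alpha` with elements `i_max`, `i_min`,
#'   `h_chamber`, `alpha` (intensity per um).
#' @export
alpha_calibration <- function(i_max, i_min, h_chamber) {
  check_scalar(h_chamber, "h_chamber", lower = 0, open_lower = TRUE)
  if (!is.finite(i_max) || !is.finite(i_min) || i_max <= i_min)
    stop("i_max must exceed i_min", call. = FALSE)
  structure(list(i_max = i_max, i_min = i_min, h_chamber = h_chamber,
                 alpha = (i_max - i_min) / h_chamber),
            class = "fxm_alpha")
}

#' Pillar-level intensity of a corrected frame
#'
#' @param corrected flatfield-normalised frame.
#' @param pillars logical pillar mask.
#' @return median corrected intensity over the pillar pixels.
#' @export
pillar_i_min <- function(corrected, pillars) {
  if (!any(pillars)) stop("pillar mask is empty", call. = FALSE)
  stats::median(corrected[pillars])
}

#' Local background intensity around one cell
#'
#' Estimates the counterfactual cell-free signal `i_max` for a cell as the
#' median corrected intensity over the annulus `inner_px` to `outer_px`
#' pixels away from the cell's (dilated) label boundary, excluding pixels
#' belonging to any other label and to pillars. With a 0.65 um pixel the
#' default annulus spans 1.3 to 6.5 um from the border.
#'
#' @param corrected flatfield-normalised frame.
#' @param labels integer label matrix (dilated labels recommended).
#' @param cell_id label of the cell of interest.
#' @param inner_px,outer_px annulus distances from the label boundary (px).
#' @param pillars optional logical pillar mask.
#' @return median background intensity, or `NA` (with attribute
#'   `unmeasurable = TRUE`) when the annulus is empty.
#' @export
local_background <- function(corrected, labels, cell_id,
                             inner_px = 2, outer_px = 10, pillars = NULL) {
  idx <- which(labels == cell_id, arr.ind = TRUE)
  if (!nrow(idx)) stop("cell ", cell_id, " not present in frame", call. = FALSE)
  nr <- nrow(labels); nc <- ncol(labels)
  pad <- ceiling(outer_px) + 1L
  r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(nr, max(idx[, 1]) + pad)
  c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(nc, max(idx[, 2]) + pad)
  sub_lab <- labels[r0:r1, c0:c1, drop = FALSE]
  cell <- sub_lab == cell_id
  # distance of every non-cell pixel to the cell boundary
  d <- as_matrix_image(EBImage::distmap(EBImage::Image((!cell) * 1)))
  ann <- d >= inner_px & d <= outer_px & sub_lab == 0
  if (!is.null(pillars)) ann <- ann & !pillars[r0:r1, c0:c1, drop = FALSE]
  if (!any(ann)) {
    out <- NA_real_
    attr(out, "unmeasurable") <- TRUE
    return(out)
  }
  stats::median(corrected[r0:r1, c0:c1, drop = FALSE][ann])
}

#' Absolute cell volume from the dye-exclusion deficit
#'
#' Sums the intensity deficit relative to the local background over the cell
#' footprint and converts to um^3:
#' \deqn{V = A_{px} \sum_{x,y \in A} (I_{max} - I(x,y)) / \alpha}
#' with \eqn{A_{px}} the pixel area in um^2. Negative per-pixel deficits
#' (noise) are retained in the sum; a negative total is floored at 0 and
#' flagged.
#'
#' @param corrected flatfield-normalised frame.
#' @param labels integer label matrix.
#' @param cell_id label of the cell.
#' @param i_max local background intensity (from [local_background()]).
#' @param alpha an `fxm_alpha` calibration or a plain positive number
#'   (intensity per um).
#' @param pixel_area_um2 pixel area (um^2).
#' @return volume in um^3, with attribute `flagged = TRUE` when the label was
#'   empty or the total deficit negative.
#' @export
cell_volume <- function(corrected, labels, cell_id, i_max, alpha,
                        pixel_area_um2) {
  a <- if (inherits(alpha, "fxm_alpha")) alpha$alpha else alpha
  if (!is.finite(a) || a <= 0) stop("alpha must be positive", call. = FALSE)
  sel <- labels == cell_id
  if (!any(sel)) {
    v <- 0
    attr(v, "flagged") <- TRUE
    return(v)
  }
  v <- pixel_area_um2 * sum(i_max - corrected[sel]) / a
  if (v < 0) {
    v <- 0
    attr(v, "flagged") <- TRUE
  }
  v
}

#' Measure every cell in one corrected frame
#'
#' Convenience wrapper running [local_background()], [pillar_i_min()] /
#' [alpha_calibration()] and [cell_volume()] for each label of a frame.
#'
#' @param corrected flatfield-normalised frame.
#' @param labels integer label matrix (dilated).
#' @param pillars logical pillar mask (for `i_min` and annulus exclusion).
#' @param pixel_size_um pixel pitch (um/px).
#' @param chamber_height_um chamber height (um).
#' @param inner_px,outer_px local-background annulus (px).
#' @return data.frame with one row per label: `label`, `x_um`, `y_um`
#'   (centroid), `area_um2`, `i_max`, `volume_um3`, `measurable`.
#' @export
measure_frame <- function(corrected, labels, pillars, pixel_size_um,
                          chamber_height_um, inner_px = 2, outer_px = 10) {
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids))
    return(data.frame(label = integer(0), x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0), i_max = numeric(0),
                      volume_um3 = numeric(0), measurable = logical(0)))
  i_min <- pillar_i_min(corrected, pillars)
  px_area <- pixel_size_um^2
  out <- lapply(ids, function(id) {
    im <- local_background(corrected, labels, id, inner_px, outer_px, pillars)
    idx <- which(labels == id, arr.ind = TRUE)
    meas <- is.finite(im) && im > i_min
    v <- if (meas) {
      cal <- alpha_calibration(im, i_min, chamber_height_um)
      as.numeric(cell_volume(corrected, labels, id, im, cal, px_area))
    } else NA_real_
    data.frame(label = id,
               x_um = (mean(idx[, 2]) - 0.5) * pixel_size_um,
               y_um = (mean(idx[, 1]) - 0.5) * pixel_size_um,
               area_um2 = nrow(idx) * px_area,
               i_max = if (is.finite(im)) im else NA_real_,
               volume_um3 = v, measurable = meas)
  })
  do.call(rbind, out)
}

#' Normalise a raw volume trace to its pre-stimulus baseline
#'
#' Divides the raw volume trace by the mean raw volume over the window
#' `[t_stim - window_s, t_stim)` and adds a centred rolling-median trace
#' (window `roll_k` samples). A track covering less than `min_coverage` of
#' the pre-stimulus window is excluded from normalised statistics: its
#' `normalized` column is `NA` while the raw values are kept.
#'
#' @param trace data.frame with columns `t_s` and `volume_um3` (one cell).
#' @param t_stim_s stimulus time (s).
#' @param window_s pre-stimulus baseline window length (s).
#' @param min_coverage minimum fraction of the window the track must cover.
#' @param roll_k rolling-median window (odd number of samples).
#' @return the input with columns `rolling_um3` and `normalized` added.
#' @export
normalize_trace <- function(trace, t_stim_s, window_s = 120,
                            min_coverage = 0.5, roll_k = 5) {
  stopifnot(all(c("t_s", "volume_um3") %in% names(trace)))
  trace <- trace[order(trace$t_s), , drop = FALSE]
  v <- trace$volume_um3
  ok <- is.finite(v)
  trace$rolling_um3 <- NA_real_
  if (sum(ok) >= roll_k)
    trace$rolling_um3[ok] <- stats::runmed(v[ok], roll_k, endrule = "median")
  else trace$rolling_um3[ok] <- v[ok]
  pre <- ok & trace$t_s >= (t_stim_s - window_s) & trace$t_s < t_stim_s
  dt <- stats::median(diff(trace$t_s))
  expected <- max(1, floor(window_s / dt))
  if (sum(pre) >= min_coverage * expected && mean(v[pre]) > 0) {
    trace$normalized <- v / mean(v[pre])
  } else {
    trace$normalized <- NA_real_
  }
  trace
}

#' Population volume summary: mean of per-replicate medians with 95% CI
#'
#' For each time point, takes the median normalised volume across cells
#' within each replicate, then the mean of those medians across replicates
#' with a Student-t 95 percent confidence interval. With a single replicate
#' the CI has zero width.
#'
#' @param traces data.frame with columns `replicate`, `cell_id`, `t_s` and
#'   `normalized`.
#' @param conf confidence level.
#' @return data.frame `t_s`, `mean`, `ci_lo`, `ci_hi`, `n_replicates`.
#' @export
population_volume_summary <- function(traces, conf = 0.95) {
  aggregate_two_level(traces, value_col = "normalized", band = "ci", conf = conf)
}

# Shared two-level aggregation: per-replicate median per time point, then
# mean across replicates with either a t-based CI or an SD band.
aggregate_two_level <- function(df, value_col, band = c("ci", "sd"),
                                conf = 0.95) {
  band <- match.arg(band)
  stopifnot(all(c("replicate", "t_s", value_col) %in% names(df)))
  df <- df[is.finite(df[[value_col]]), , drop = FALSE]
  med <- stats::aggregate(df[[value_col]],
                          by = list(replicate = df$replicate, t_s = df$t_s),
                          FUN = stats::median)
  names(med)[3] <- "med"
  out <- lapply(split(med, med$t_s), function(g) {
    n <- nrow(g)
    m <- mean(g$med)
    if (band == "ci") {
      half <- if (n > 1) stats::qt(1 - (1 - conf) / 2, n - 1) *
        stats::sd(g$med) / sqrt(n) else 0
      data.frame(t_s = g$t_s[1], mean = m, ci_lo = m - half, ci_hi = m + half,
                 n_replicates = n)
    } else {
      s <- if (n > 1) stats::sd(g$med) else 0
      data.frame(t_s = g$t_s[1], mean = m, sd = s, n_replicates = n)
    }
  })
  out <- do.call(rbind, out)
  out <- out[order(out$t_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}
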