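#' Windowed track velocity
#'
#' Central-difference speed at frame i over a window of `tau` frames:
#' \deqn{v_i = \frac{\sqrt{(x_{i+\tau}-x_{i-\tau})^2 + (y_{i+\tau}-y_{i-\tau})^2}}
#'                  {t_{i+\tau} - t_{i-\tau}}}
#' Displacement-based, not path-length-based: a path returning to its start
#' has zero velocity. The first and last `tau` frames are undefined (`NA`),
#' with no padding. With a 10 s frame interval the default `tau = 3` spans
#' roughly a one-minute window.
#'
#' @param track data.frame with columns `t_s`, `x_um`, `y_um`, sorted or
#'   sortable by time; timestamps must be strictly increasing.
#' @param tau half-window in frames.
#' @return numeric vector of speeds (um/s) aligned with the track rows, `NA`
#'   at the ends.
#' @export
velocity <- function(track, tau = 3) {
  stopifnot(all(c("t_s", "x_um", "y_um") %in% names(track)))
  o <- order(track$t_s)
  track <- track[o, , drop = FALSE]
  t <- track$t_s
  if (any(diff(t) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  n <- nrow(track)
  v <- rep(NA_real_, n)
  if (n > 2 * tau) {
    i <- (tau + 1L):(n - tau)
    v[i] <- sqrt((track$x_um[i + tau] - track$x_um[i - tau])^2 +
                 (track$y_um[i + tau] - track$y_um[i - tau])^2) /
      (t[i + tau] - t[i - tau])
  }
  v[order(o)]
}

#' Angular alignment along a track at fixed travelled distance
#'
#' For each position B on the track, finds the earlier position A and later
#' position C separated from B by at least `spacing_um` of cumulative
#' distance travelled, computes the angle at B,
#' \eqn{\theta = \mathrm{atan2}(\lVert \vec{BA} \times \vec{BC} \rVert,
#' \vec{BA} \cdot \vec{BC}) \in [0, \pi]}, and rescales it to
#' \eqn{2\theta/\pi - 1 \in [-1, 1]}: +1 for a perfectly straight path
#' (A and C on opposite sides of B), -1 for a complete reversal, and a
#' median near 0 for Brownian motion. Note the affine rescale: the range
#' statement (reversal at -1) forces \eqn{2\theta/\pi - 1}; a bare division
#' by \eqn{\pi} could never be negative.
#'
#' @param track data.frame with `x_um`, `y_um` (and optionally `t_s` for
#'   ordering), one cell.
#' @param spacing_um cumulative-distance offset of A and C from B (um).
#' @return numeric vector aligned with the track rows; `NA` where the path
#'   on either side is shorter than `spacing_um` or a reference vector is
#'   degenerate.
#' @export
angular_alignment <- function(track, spacing_um = 10) {
  stopifnot(all(c("x_um", "y_um") %in% names(track)))
  if ("t_s" %in% names(track)) track <- track[order(track$t_s), , drop = FALSE]
  x <- track$x_um; y <- track$y_um
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n < 3) return(out)
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  for (i in seq_len(n)) {
    back <- which(s[i] - s >= spacing_um)
    fwd <- which(s - s[i] >= spacing_um)
    if (!length(back) || !length(fwd)) next
    a <- max(back)   # nearest sample at least spacing_um behind
    c_ <- min(fwd)   # nearest sample at least spacing_um ahead
    ba <- c(x[a] - x[i], y[a] - y[i])
    bc <- c(x[c_] - x[i], y[c_] - y[i])
    if (all(ba == 0) || all(bc == 0)) next
    cross <- ba[1] * bc[2] - ba[2] * bc[1]
    dotp <- sum(ba * bc)
    theta <- atan2(abs(cross), dotp)
    out[i] <- 2 * theta / pi - 1
  }
  out
}

#' Population motility summary: mean of per-replicate medians with SD band
#'
#' Same two-level aggregation as [population_volume_summary()] but with a
#' standard-deviation band instead of a confidence interval.
#'
#' @param series data.frame with columns `replicate`, `t_s` and `value`
#'   (e.g. per-cell velocity or alignment samples).
#' @return data.frame `t_s`, `mean`, `sd`, `n_replicates`.
#' @export
population_motility_summary <- function(series) {
  aggregate_two_level(series, value_col = "value", band = "sd")
}
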