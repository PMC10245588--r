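#' Refractive-index to density calibration for Percoll gradients
#'
#' Percoll solution density is linear in refractive index, so two measured
#' standards define the calibration line. Defaults are the low- and
#' high-density gradient endpoints: RI 1.3419 at 1.045 g/mL and RI 1.3467 at
#' 1.074 g/mL.
#'
#' @param ri refractive indices of the two anchors.
#' @param density densities of the two anchors (g/mL).
#' @return object of class `fxm_density_cal` with `slope` (g/mL per RI unit)
#'   and `intercept`; reproduces both anchors exactly.
#' @export
density_calibration <- function(ri = c(1.3419, 1.3467),
                                density = c(1.045, 1.074)) {
  stopifnot(length(ri) == 2L, length(density) == 2L)
  if (ri[1] == ri[2]) stop("anchor refractive indices coincide", call. = FALSE)
  slope <- diff(density) / diff(ri)
  if (slope <= 0) stop("calibration slope must be positive", call. = FALSE)
  structure(list(ri = ri, density = density, slope = slope,
                 intercept = density[1] - slope * ri[1]),
            class = "fxm_density_cal")
}

#' Convert refractive index to density
#'
#' @param ri refractive index (vectorised).
#' @param cal a [density_calibration()] object.
#' @return density in g/mL.
#' @examples
#' ri_to_density(1.3443)  # midpoint of the default anchors
#' @export
ri_to_density <- function(ri, cal = density_calibration()) {
  stopifnot(inherits(cal, "fxm_density_cal"))
  cal$intercept + cal$slope * ri
}

#' Build and validate a gradient fractionation table
#'
#' @param fraction fraction indices (1 = top of gradient).
#' @param ri measured refractive index per fraction.
#' @param count cells counted per fraction.
#' @param cal a [density_calibration()] object.
#' @return data.frame `fraction`, `ri`, `density_g_ml`, `count`; warns when
#'   densities are not monotone across fractions (gradient linearity check).
#' @export
gradient_table <- function(fraction, ri, count, cal = density_calibration()) {
  stopifnot(length(fraction) == length(ri), length(ri) == length(count))
  d <- ri_to_density(ri, cal)
  o <- order(fraction)
  tab <- data.frame(fraction = fraction[o], ri = ri[o], density_g_ml = d[o],
                    count = count[o])
  dd <- diff(tab$density_g_ml)
  if (any(dd > 0) && any(dd < 0))
    warning("fraction densities are not monotone; gradient may be non-linear",
            call. = FALSE)
  tab
}

#' Modal buoyant density of a fractionated population
#'
#' Smooths the per-fraction cell counts with a centred moving average over
#' `smooth_k` fractions and returns the density of the peak fraction
#' (count-weighted mode). Ties resolve to the first (least dense, for a
#' top-loaded gradient) fraction.
#'
#' @param table a [gradient_table()] data.frame.
#' @param smooth_k moving-average window (odd).
#' @return modal density, g/mL.
#' @export
population_density_mode <- function(table, smooth_k = 3) {
  stopifnot(all(c("density_g_ml", "count") %in% names(table)))
  n <- nrow(table)
  h <- smooth_k %/% 2
  sm <- vapply(seq_len(n), function(i) {
    w <- max(1, i - h):min(n, i + h)
    mean(table$count[w])
  }, numeric(1))
  table$density_g_ml[which.max(sm)]
}

#' Buoyant density after mass-conserving swelling
#'
#' A cell of density `rho0` that takes up a volume fraction `f` of fluid of
#' density `rho_fluid` reaches
#' \deqn{\rho' = (\rho_0 + f\,\rho_{fluid}) / (1 + f).}
#'
#' @param rho0 initial density (g/mL).
#' @param f fractional volume increase (e.g. 0.15).
#' @param rho_fluid density of the influxed fluid (g/mL); default dilute
#'   saline.
#' @return post-swelling density (g/mL).
#' @export
density_after_swelling <- function(rho0, f, rho_fluid = 1.0026) {
  (rho0 + f * rho_fluid) / (1 + f)
}

#' Fractional volume change implied by a buoyant-density shift
#'
#' Inverts [density_after_swelling()] under conservation of dry mass:
#' \deqn{\Delta V / V = (\rho_0 - \rho_1) / (\rho_1 - \rho_{fluid}).}
#' Note: for the observed stimulated shift 1.055 to 1.050 g/mL this gives
#' about +10.5 percent, somewhat below the ~15 percent swelling measured by
#' imaging and impedance sizing; the two estimates are reported as-is and not
#' reconciled.
#'
#' @param rho0,rho1 densities before and after (g/mL).
#' @param rho_fluid density of the exchanged fluid (g/mL); must be below
#'   `rho1`.
#' @return fractional volume change.
#' @examples
#' volume_change_from_density(1.055, 1.050)
#' @export
volume_change_from_density <- function(rho0, rho1, rho_fluid = 1.0026) {
  if (any(rho1 <= rho_fluid))
    stop("rho1 must exceed rho_fluid", call. = FALSE)
  (rho0 - rho1) / (rho1 - rho_fluid)
}

#' Bin gradient fractions into approximately equal-count groups
#'
#' Splits the ordered fractions into `n_bins` contiguous ranges whose total
#' cell counts are as close as achievable to `total / n_bins` (minimising the
#' summed absolute deviation by exhaustive search over cut points). Counts
#' are conserved exactly.
#'
#' @param counts per-fraction cell counts, in gradient order.
#' @param n_bins number of bins.
#' @return integer vector assigning each fraction to a bin (1..n_bins).
#' @examples
#' bin_fractions(rep(1, 48))            # 16/16/16
#' bin_fractions(c(10, 0, 0, 10, 10))   # 10/10/10
#' @export
bin_fractions <- function(counts, n_bins = 3) {
  n <- length(counts)
  if (n < n_bins) stop("fewer fractions than bins", call. = FALSE)
  target <- sum(counts) / n_bins
  cuts <- utils::combn(n - 1L, n_bins - 1L)
  cs <- c(0, cumsum(counts))
  best <- NULL; best_dev <- Inf
  for (j in seq_len(ncol(cuts))) {
    b <- c(0L, cuts[, j], n)
    sizes <- cs[b[-1] + 1L] - cs[b[-length(b)] + 1L]
    dev <- sum(abs(sizes - target))
    if (dev < best_dev - 1e-12) {
      best_dev <- dev
      best <- b
    }
  }
  rep(seq_len(n_bins), times = diff(best))
}

#' Median cell volume from a Coulter diameter histogram
#'
#' Drops diameter bins below the debris gate, converts bin diameters to
#' sphere volumes \eqn{(\pi/6) d^3} and returns the count-weighted median
#' volume in fL (1 um^3 = 1 fL).
#'
#' @param diameter_um bin centre diameters (um).
#' @param count cells per bin.
#' @param gate_um debris gate: bins with diameter below this are excluded.
#' @return median volume, fL.
#' @examples
#' coulter_median(10, 100)  # (pi/6) * 1000
#' @export
coulter_median <- function(diameter_um, count, gate_um = 6) {
  stopifnot(length(diameter_um) == length(count))
  keep <- diameter_um >= gate_um
  if (!any(keep & count > 0))
    stop("no counts above the debris gate", call. = FALSE)
  d <- diameter_um[keep]; ct <- count[keep]
  o <- order(d)
  d <- d[o]; ct <- ct[o]
  vol <- pi / 6 * d^3
  cum <- cumsum(ct)
  vol[which(cum >= sum(ct) / 2)[1]]
}

#' Simulate gradient fraction counts for a banded population
#'
#' Distributes `n_cells` across the fractions of a gradient with a Gaussian
#' density profile centred at `center_g_ml` - a synthetic stand-in for a
#' fractionated cell band, used to exercise the densitometry statistics.
#'
#' @param densities fraction densities (g/mL), gradient order.
#' @param center_g_ml band centre density.
#' @param sd_g_ml band width (g/mL).
#' @param n_cells total cells to distribute.
#' @param seed integer seed.
#' @return integer counts per fraction (multinomial draw; sums to `n_cells`).
#' @export
simulate_gradient_counts <- function(densities, center_g_ml, sd_g_ml = 0.003,
                                     n_cells = 1e5, seed = 1L) {
  w <- stats::dnorm(densities, center_g_ml, sd_g_ml)
  if (sum(w) == 0) stop("band does not overlap the gradient", call. = FALSE)
  with_seed(seed,
            as.integer(stats::rmultinom(1, n_cells, w / sum(w))))
}
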