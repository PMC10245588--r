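#' Parameters for synthetic chemoattractant-response kinetics
#'
#' Bundles the ground-truth model of how neutrophil-like cells respond to an
#' acute chemoattractant stimulus in a shallow FxM chamber. The volume of each
#' cell follows
#' \deqn{V(t) = V_0 [1 - L\,s(t') + S\,w(t') + F\,f(t')\,1(t'>0)]}
#' with \eqn{t' = t - t_{stim}}, where \eqn{s} is a unit-peak spreading-loss
#' pulse \eqn{(t'/\tau_s)e^{1 - t'/\tau_s}}, \eqn{w} a saturating swelling rise
#' \eqn{\tanh(t'/\tau_w)}, and \eqn{f} a zero-mean oscillation with a random
#' per-cell phase emulating motility-coupled volume fluctuations. Motility is a
#' random walk whose speed ramps from `pre_speed_um_s` to `post_speed_um_s`
#' after the stimulus while headings become persistent (Gaussian turning
#' noise).
#'
#' Defaults encode the stereotyped primary-neutrophil response: a 5-8 percent
#' spreading-induced volume dip within the first two minutes of stimulation,
#' swelling to ~15 percent above baseline by 20 minutes, ~5 percent
#' motility-coupled fluctuations, and a ten-fold chemokinetic speed increase.
#'
#' @param n_cells number of cells to simulate.
#' @param baseline_volume_um3 resting median cell volume (um^3).
#' @param baseline_cv lognormal coefficient of variation of per-cell resting
#'   volumes (unitless).
#' @param spread_loss_frac peak fractional volume loss during spreading.
#' @param spread_tau_s time constant of the spreading pulse (s); the loss
#'   peaks at `spread_tau_s` seconds post-stimulus.
#' @param swell_frac plateau fractional swelling.
#' @param swell_tau_s swelling time constant (s).
#' @param fluct_amp_frac amplitude of motility-coupled volume fluctuations.
#' @param fluct_period_s fluctuation period (s).
#' @param pre_speed_um_s pre-stimulus (Brownian) speed, um/s.
#' @param post_speed_um_s post-stimulus plateau speed, um/s.
#' @param speed_tau_s time constant of the speed ramp (s).
#' @param turn_sd_rad per-frame heading noise of the persistent post-stimulus
#'   walk (radians); smaller is straighter.
#' @param min_sep_um excluded-volume distance between cell centres (um):
#'   cells are solid, so a step that would bring two centres closer than this
#'   is re-drawn (touching footprints are allowed, interpenetration is not).
#' @param stim_time_s stimulus (uncaging) time from the start of the series (s).
#' @param duration_s total duration of the series (s).
#' @param frame_interval_s frame interval (s).
#' @param dome_height_rest_um apex height of the resting cell dome (um); must
#'   not exceed the chamber height at render time.
#' @param dome_height_spread_um apex height of a fully spread cell (um). The
#'   dome flattens monotonically post-stimulus, which (at roughly conserved
#'   volume) makes the footprint area increase monotonically.
#' @param seed integer seed; a fixed seed gives bit-identical ground truth.
#' @return an object of class `fxm_kinetics_params` (a validated list).
#' @seealso [simulate_kinetics()]
#' @export
kinetics_params <- function(n_cells = 60,
                            baseline_volume_um3 = 300,
                            baseline_cv = 0.1,
                            spread_loss_frac = 0.065,
                            spread_tau_s = 60,
                            swell_frac = 0.15,
                            swell_tau_s = 600,
                            fluct_amp_frac = 0.05,
                            fluct_period_s = 100,
                            pre_speed_um_s = 0.02,
                            post_speed_um_s = 0.2,
                            speed_tau_s = 600,
                            turn_sd_rad = 0.25,
                            min_sep_um = 10,
                            stim_time_s = 600,
                            duration_s = 2400,
                            frame_interval_s = 10,
                            dome_height_rest_um = 6,
                            dome_height_spread_um = 3.5,
                            seed = 1L) {
  check_scalar(n_cells, "n_cells", lower = 0)
  check_scalar(baseline_volume_um3, "baseline_volume_um3", lower = 0, open_lower = TRUE)
  check_scalar(baseline_cv, "baseline_cv", lower = 0, upper = 1, open_upper = TRUE)
  for (nm in c("spread_loss_frac", "swell_frac", "fluct_amp_frac"))
    check_scalar(get(nm), nm, lower = 0, upper = 1, open_upper = TRUE)
  for (nm in c("spread_tau_s", "swell_tau_s", "fluct_period_s", "speed_tau_s",
               "frame_interval_s", "duration_s"))
    check_scalar(get(nm), nm, lower = 0, open_lower = TRUE)
  check_scalar(stim_time_s, "stim_time_s", lower = 0)
  check_scalar(pre_speed_um_s, "pre_speed_um_s", lower = 0)
  check_scalar(post_speed_um_s, "post_speed_um_s", lower = 0)
  check_scalar(turn_sd_rad, "turn_sd_rad", lower = 0)
  check_scalar(min_sep_um, "min_sep_um", lower = 0)
  check_scalar(dome_height_rest_um, "dome_height_rest_um", lower = 0, open_lower = TRUE)
  check_scalar(dome_height_spread_um, "dome_height_spread_um", lower = 0, open_lower = TRUE)
  if (duration_s < stim_time_s)
    stop("duration_s must be at least stim_time_s", call. = FALSE)
  p <- list(n_cells = as.integer(n_cells),
            baseline_volume_um3 = baseline_volume_um3,
            baseline_cv = baseline_cv,
            spread_loss_frac = spread_loss_frac, spread_tau_s = spread_tau_s,
            swell_frac = swell_frac, swell_tau_s = swell_tau_s,
            fluct_amp_frac = fluct_amp_frac, fluct_period_s = fluct_period_s,
            pre_speed_um_s = pre_speed_um_s, post_speed_um_s = post_speed_um_s,
            speed_tau_s = speed_tau_s, turn_sd_rad = turn_sd_rad,
            min_sep_um = min_sep_um,
            stim_time_s = stim_time_s, duration_s = duration_s,
            frame_interval_s = frame_interval_s,
            dome_height_rest_um = dome_height_rest_um,
            dome_height_spread_um = dome_height_spread_um,
            seed = as.integer(seed))
  class(p) <- "fxm_kinetics_params"
  p
}

# Unit-peak spreading pulse: 0 at t'=0, peak 1 at t'=tau, relaxes to 0.
spread_pulse <- function(tp, tau) ifelse(tp > 0, (tp / tau) * exp(1 - tp / tau), 0)

# Saturating swelling rise in [0, 1).
swell_rise <- function(tp, tau) ifelse(tp > 0, tanh(tp / tau), 0)

#' Simulate ground-truth single-cell kinetics (no images)
#'
#' Generates per-cell, per-frame true volumes, positions, footprint areas and
#' dome geometry under the chemoattractant-response model described in
#' [kinetics_params()]. Positions follow an isotropic random walk at
#' `pre_speed_um_s` before the stimulus and a persistent random walk whose
#' speed ramps to `post_speed_um_s` afterwards; cells reflect off the walls of
#' the arena so they stay fully inside the field of view.
#'
#' Cells are modelled as paraboloid domes of apex height \eqn{h(t)} and
#' footprint radius \eqn{R(t)}, so that \eqn{V = \pi R^2 h / 2}. The apex
#' height relaxes monotonically from `dome_height_rest_um` to
#' `dome_height_spread_um` post-stimulus, which makes the footprint area
#' \eqn{\pi R^2 = 2V/h} increase monotonically as cells spread.
#'
#' @param params an [kinetics_params()] object.
#' @param arena_um arena width and height (um) within which cells roam.
#' @param margin_um minimum distance between a cell centre and the arena edge
#'   (um); keeps footprints and local-background annuli inside the frame and
#'   away from the corner pillars.
#' @return a `data.frame` of class `fxm_ground_truth` with columns
#'   `cell_id`, `frame`, `t_s`, `x_um`, `y_um`, `volume_um3`, `area_um2`,
#'   `dome_height_um`, `radius_um`; the generating parameters are attached as
#'   attribute `params`.
#' @examples
#' gt <- simulate_kinetics(kinetics_params(n_cells = 5, duration_s = 900))
#' head(gt)
#' @export
simulate_kinetics <- function(params, arena_um = c(166.4, 166.4),
                              margin_um = 20) {
  stopifnot(inherits(params, "fxm_kinetics_params"))
  if (margin_um * 2 >= min(arena_um))
    stop("margin_um too large for the arena", call. = FALSE)
  p <- params
  t_s <- seq(0, p$duration_s, by = p$frame_interval_s)
  nf <- length(t_s)
  tp <- t_s - p$stim_time_s

  lo <- c(margin_um, margin_um)
  hi <- arena_um - margin_um

  if (p$n_cells == 0L) {
    gt <- data.frame(cell_id = integer(0), frame = integer(0), t_s = numeric(0),
                     x_um = numeric(0), y_um = numeric(0),
                     volume_um3 = numeric(0), area_um2 = numeric(0),
                     dome_height_um = numeric(0), radius_um = numeric(0))
    attr(gt, "params") <- p
    attr(gt, "arena_um") <- arena_um
    class(gt) <- c("fxm_ground_truth", "data.frame")
    return(gt)
  }

  with_seed(p$seed, {
    phase <- stats::runif(p$n_cells, 0, 2 * pi)
    v0 <- p$baseline_volume_um3 *
      exp(stats::rnorm(p$n_cells, 0, sqrt(log(1 + p$baseline_cv^2))))
    heading <- stats::runif(p$n_cells, 0, 2 * pi)

    s <- spread_pulse(tp, p$spread_tau_s)
    w <- swell_rise(tp, p$swell_tau_s)
    post <- tp > 0
    speed_t <- ifelse(post,
                      p$pre_speed_um_s + (p$post_speed_um_s - p$pre_speed_um_s) *
                        (1 - exp(-pmax(tp, 0) / p$speed_tau_s)),
                      p$pre_speed_um_s)
    h_t <- ifelse(post,
                  p$dome_height_rest_um -
                    (p$dome_height_rest_um - p$dome_height_spread_um) *
                    (1 - exp(-pmax(tp, 0) / p$spread_tau_s)),
                  p$dome_height_rest_um)

    # initial placement with hard-core spacing (sequential rejection)
    X <- matrix(NA_real_, nf, p$n_cells)
    Y <- matrix(NA_real_, nf, p$n_cells)
    for (k in seq_len(p$n_cells)) {
      for (try in 1:500) {
        cx <- stats::runif(1, lo[1], hi[1])
        cy <- stats::runif(1, lo[2], hi[2])
        if (k == 1L ||
            all((X[1, seq_len(k - 1)] - cx)^2 +
                (Y[1, seq_len(k - 1)] - cy)^2 >= p$min_sep_um^2)) break
      }
      X[1, k] <- cx; Y[1, k] <- cy
    }

    # joint walk with excluded volume: a step that would bring two centres
    # closer than min_sep_um is re-drawn (the cell stays put if none works)
    for (i in seq_len(nf - 1L)) {
      X[i + 1L, ] <- X[i, ]; Y[i + 1L, ] <- Y[i, ]
      step <- speed_t[i] * p$frame_interval_s
      for (k in seq_len(p$n_cells)) {
        th <- if (post[i]) heading[k] + stats::rnorm(1, 0, p$turn_sd_rad)
              else stats::runif(1, 0, 2 * pi)
        placed <- FALSE
        for (try in 1:8) {
          xn <- X[i, k] + step * cos(th)
          yn <- Y[i, k] + step * sin(th)
          if (xn < lo[1] || xn > hi[1]) {
            xn <- pmin(pmax(2 * pmin(pmax(xn, lo[1]), hi[1]) - xn, lo[1]), hi[1])
            th <- pi - th
          }
          if (yn < lo[2] || yn > hi[2]) {
            yn <- pmin(pmax(2 * pmin(pmax(yn, lo[2]), hi[2]) - yn, lo[2]), hi[2])
            th <- -th
          }
          other <- setdiff(seq_len(p$n_cells), k)
          if (!length(other) ||
              all((X[i + 1L, other] - xn)^2 + (Y[i + 1L, other] - yn)^2 >=
                  p$min_sep_um^2)) {
            X[i + 1L, k] <- xn; Y[i + 1L, k] <- yn
            heading[k] <- th
            placed <- TRUE
            break
          }
          th <- stats::runif(1, 0, 2 * pi)
        }
        if (!placed) heading[k] <- stats::runif(1, 0, 2 * pi)
      }
    }

    out <- vector("list", p$n_cells)
    for (k in seq_len(p$n_cells)) {
      fluct <- ifelse(post, sin(2 * pi * pmax(tp, 0) / p$fluct_period_s + phase[k]), 0)
      vol_slow <- v0[k] * (1 - p$spread_loss_frac * s + p$swell_frac * w)
      vol <- vol_slow + v0[k] * p$fluct_amp_frac * fluct
      # footprint follows the slow (spreading + swelling) volume component;
      # motility-coupled fluctuations are carried by the dome height, keeping
      # the post-stimulus area increase monotone as observed
      radius <- sqrt(2 * vol_slow / (pi * h_t))
      out[[k]] <- data.frame(cell_id = k, frame = seq_len(nf), t_s = t_s,
                             x_um = X[, k], y_um = Y[, k], volume_um3 = vol,
                             area_um2 = pi * radius^2,
                             dome_height_um = h_t * vol / vol_slow,
                             radius_um = radius)
    }
    gt <- do.call(rbind, out)
    rownames(gt) <- NULL
    attr(gt, "params") <- p
    attr(gt, "arena_um") <- arena_um
    class(gt) <- c("fxm_ground_truth", "data.frame")
    gt
  })
}

#' Equilibrium cell volume after an osmotic shift (Boyle-van't Hoff)
#'
#' Predicts the equilibrium volume of a cell moved from `osm_initial` to
#' `osm_final` assuming a fixed osmotically inactive volume fraction `b`:
#' \deqn{V = V_0 [b + (1 - b)\,\Pi_0/\Pi].}
#' With the default `inactive_fraction = 0.25`, diluting 315 mOsm/kg media by
#' 20 percent (v/v) with water (to 262.5 mOsm/kg) predicts a 15 percent volume
#' increase, the magnitude used to rescue swelling-deficient cells by mild
#' hypoosmotic shock.
#'
#' @param v0 initial volume (any unit).
#' @param osm_initial,osm_final initial and final osmolarity (mOsm/kg), > 0.
#' @param inactive_fraction osmotically inactive volume fraction in \[0, 1\].
#' @return equilibrium volume, same unit as `v0`. Vectorised over all
#'   arguments.
#' @examples
#' osmotic_volume(300, 315, 315 / 1.2)  # 20% v/v dilution -> +15%
#' @export
osmotic_volume <- function(v0, osm_initial, osm_final, inactive_fraction = 0.25) {
  if (any(!is.finite(osm_initial)) || any(osm_initial <= 0) ||
      any(!is.finite(osm_final)) || any(osm_final <= 0))
    stop("osmolarities must be positive", call. = FALSE)
  if (any(inactive_fraction < 0) || any(inactive_fraction > 1))
    stop("inactive_fraction must be in [0, 1]", call. = FALSE)
  b <- inactive_fraction
  v0 * (b + (1 - b) * osm_initial / osm_final)
}

#' Fractional change in cell water content implied by a volume change
#'
#' If a fraction `water_fraction` of the resting cell volume is water and a
#' volume change is carried entirely by water, the relative change in water
#' content is `volume_gain / water_fraction`. For a neutrophil that is ~65
#' percent water, a 15 percent volume gain corresponds to a ~23 percent
#' (almost a quarter) increase in cell water.
#'
#' @param volume_gain fractional volume change (e.g. 0.15 for +15 percent).
#' @param water_fraction resting water volume fraction in (0, 1\].
#' @return fractional change in water content.
#' @examples
#' water_content_gain(0.15)  # ~0.231
#' @export
water_content_gain <- function(volume_gain, water_fraction = 0.65) {
  if (any(water_fraction <= 0) || any(water_fraction > 1))
    stop("water_fraction must be in (0, 1]", call. = FALSE)
  volume_gain / water_fraction
}
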