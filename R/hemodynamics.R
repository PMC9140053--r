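# Prazosin hemodynamic model: a piecewise-exponential mean arterial pressure
# (MAP) trace with three landmarks (baseline plateau, post-injection minimum,
# recovery plateau), and a per-bed speed-multiplier schedule that couples
# commanded microbubble speeds to the normalized MAP excursion.

#' Hemodynamic model parameters
#'
#' Landmark defaults follow the prazosin response in anesthetized rats:
#' baseline MAP 84 mmHg, maximum drop to 54 mmHg reached about 67 s after
#' injection (center of the 52-82 s range), recovery plateau 65 mmHg.
#' `scan_multipliers` gives, per vascular bed, the ratio of each scan's mean
#' commanded speed to the baseline (scan-1) speed. Defaults encode a
#' prazosin response in the cortical arteries/arterioles (1.59 -> 1.14 ->
#' 1.18 mm/s) and outer-medulla descending vasa recta (0.70 -> 0.66 -> 0.69
#' mm/s) and no response elsewhere.
#'
#' @param map_baseline,map_min,map_recovery MAP landmarks in mmHg;
#'   `map_min < map_recovery < map_baseline` required.
#' @param t_drop_onset,t_drop_peak seconds after injection at which the MAP
#'   starts to fall and reaches its minimum.
#' @param tau_recovery recovery time constant (s).
#' @param noise_sd additive Gaussian measurement noise on the trace (mmHg).
#' @param scan_multipliers 6 x 3 matrix (beds x scans) of per-scan speed
#'   multipliers relative to the bed's base speed; all > 0.
#' @return list of class `hemo_params`.
#' @export
hemo_params <- function(map_baseline = 84, map_min = 54, map_recovery = 65,
                        t_drop_onset = 10, t_drop_peak = 67,
                        tau_recovery = 90, noise_sd = 4,
                        scan_multipliers = default_scan_multipliers()) {
  stop_if_not(map_min < map_recovery && map_recovery < map_baseline,
              "require map_min < map_recovery < map_baseline")
  stop_if_not(t_drop_peak > t_drop_onset,
              "t_drop_peak must exceed t_drop_onset")
  stop_if_not(all(scan_multipliers > 0), "scan multipliers must be > 0")
  structure(list(map_baseline = map_baseline, map_min = map_min,
                 map_recovery = map_recovery, t_drop_onset = t_drop_onset,
                 t_drop_peak = t_drop_peak, tau_recovery = tau_recovery,
                 noise_sd = noise_sd, scan_multipliers = scan_multipliers),
            class = "hemo_params")
}

#' Default per-bed, per-scan speed multipliers
#'
#' Scan-mean speed ratios relative to scan 1, taken from the observed bed
#' means: cortical arteries/arterioles 1.59/1.14/1.18 mm/s and outer-medulla
#' descending vasa recta 0.70/0.66/0.69 mm/s; the remaining beds showed no
#' significant response and keep multiplier 1.
#' @return 6 x 3 numeric matrix, rows named by bed, columns scan1..scan3.
#' @export
default_scan_multipliers <- function() {
  m <- matrix(1, nrow = 6, ncol = 3,
              dimnames = list(renal_beds(), paste0("scan", 1:3)))
  m["cortex_art", ] <- c(1, 1.14 / 1.59, 1.18 / 1.59)
  m["om_dvr", ]     <- c(1, 0.66 / 0.70, 0.69 / 0.70)
  m
}

# Noise-free MAP value at t_rel seconds after injection (vectorized).
map_value <- function(t_rel, p) {
  e4 <- exp(-4)
  tau_d <- (p$t_drop_peak - p$t_drop_onset) / 4
  out <- rep(p$map_baseline, length(t_rel))
  drop <- t_rel >= p$t_drop_onset & t_rel < p$t_drop_peak
  out[drop] <- p$map_min + (p$map_baseline - p$map_min) *
    (exp(-(t_rel[drop] - p$t_drop_onset) / tau_d) - e4) / (1 - e4)
  rec <- t_rel >= p$t_drop_peak
  out[rec] <- p$map_recovery - (p$map_recovery - p$map_min) *
    exp(-(t_rel[rec] - p$t_drop_peak) / p$tau_recovery)
  out
}

# Normalized MAP excursion in [0, 1]: 0 at baseline, 1 at the minimum.
map_excursion <- function(t_rel, p) {
  (p$map_baseline - map_value(t_rel, p)) / (p$map_baseline - p$map_min)
}

#' Simulate a MAP trace for one scan
#'
#' Noise-free shape: baseline plateau until `t_drop_onset` after injection,
#' exponential descent reaching exactly `map_min` at `t_drop_peak`, then
#' exponential relaxation toward `map_recovery`. Gaussian noise of sd
#' `noise_sd` is added on top.
#'
#' @param params a [hemo_params()].
#' @param duration scan duration in s.
#' @param t_inj injection time in s on the scan clock (`Inf` for scans
#'   without an injection); `0 <= t_inj < duration` or `Inf`.
#' @param rate sampling rate in Hz (default 1).
#' @param seed optional RNG seed.
#' @param noise logical; set `FALSE` for the noise-free trace.
#' @return data.frame with columns `t` (s) and `map` (mmHg).
#' @export
simulate_map_trace <- function(params, duration, t_inj, rate = 1,
                               seed = NULL, noise = TRUE) {
  stop_if_not(is.infinite(t_inj) || (duration > t_inj && t_inj >= 0),
              "require duration > t_inj >= 0")
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  map <- map_value(t - t_inj, params)
  if (noise && params$noise_sd > 0) map <- map + stats::rnorm(length(t), 0, params$noise_sd)
  data.frame(t = t, map = map)
}

# Scaling of the scan-2 speed modulation: commanded multiplier is
# m(t) = 1 - alpha * x(t - t_inj) with x the normalized MAP excursion, and
# alpha chosen so the mean multiplier over the analysis window
# [t_inj, t_inj + window] equals the configured scan-2 target. This makes
# the commanded window mean equal the target at any window length.
scan2_alpha <- function(bed, p, t_inj, window) {
  m2 <- p$scan_multipliers[bed, 2]
  if (m2 == 1) return(0)
  tt <- seq(0, window, by = 0.1)
  xbar <- mean(map_excursion(tt, p))
  stop_if_not(xbar > 0, "analysis window has no MAP excursion; cannot scale modulation")
  alpha <- (1 - m2) / xbar
  stop_if_not(alpha * max(map_excursion(tt, p)) < 1,
              "scan-2 target not reachable: commanded speed would cross zero")
  alpha
}

#' Commanded speed multiplier for a bed at time t
#'
#' Scan 1 and scan 3 use the configured constant multipliers; scan 2 is 1
#' before the injection and `1 - alpha * excursion(t - t_inj)` after, with
#' `alpha` normalized so the mean over the analysis window hits the
#' configured scan-2 multiplier.
#'
#' @param bed bed name (see [renal_beds()]).
#' @param t time(s) on the scan clock, s.
#' @param scan scan number 1, 2 or 3.
#' @param params a [hemo_params()].
#' @param t_inj injection time (scan-2 clock), s.
#' @param window analysis window length after injection, s.
#' @return numeric vector of multipliers.
#' @export
speed_multiplier <- function(bed, t, scan, params, t_inj = NA, window = 410) {
  if (scan == 1) return(rep(params$scan_multipliers[bed, 1], length(t)))
  if (scan == 3) return(rep(params$scan_multipliers[bed, 3], length(t)))
  stop_if_not(is.finite(t_inj), "scan 2 requires t_inj")
  alpha <- scan2_alpha(bed, params, t_inj, window)
  m <- rep(1, length(t))
  post <- t >= t_inj
  m[post] <- 1 - alpha * map_excursion(t[post] - t_inj, params)
  m
}
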