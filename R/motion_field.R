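# Residual respiratory tissue motion: a smooth, periodic, spatially varying
# displacement field. The temporal factor is sinusoidal at the ventilation
# rate; the spatial envelope is a Gaussian profile in depth with peak 1, so
# the maximum displacement magnitude equals the configured amplitude at the
# phase peak.

#' Tissue motion parameters
#'
#' @param amplitude_mm peak displacement magnitude (mm); 0 disables motion.
#' @param freq_hz respiration frequency, default 69/60 Hz (69 breaths/min).
#' @param phase phase offset in radians.
#' @param direction unit-direction of displacement (x = lateral, y = axial
#'   down); normalized internally. Default is mostly axial.
#' @param profile_center_y depth (mm) at which the spatial envelope peaks;
#'   pick a pixel-row center so the on-grid maximum is exactly the amplitude.
#' @param profile_sigma_mm width (mm) of the Gaussian depth envelope.
#' @return list of class `motion_params`.
#' @export
motion_params <- function(amplitude_mm = 0.1, freq_hz = 69 / 60, phase = 0,
                          direction = c(0.3, 0.95),
                          profile_center_y = 3.225, profile_sigma_mm = 2.5) {
  stop_if_not(amplitude_mm >= 0, "amplitude must be >= 0")
  d <- direction / sqrt(sum(direction^2))
  structure(list(amplitude_mm = amplitude_mm, freq_hz = freq_hz,
                 phase = phase, direction = d,
                 profile_center_y = profile_center_y,
                 profile_sigma_mm = profile_sigma_mm),
            class = "motion_params")
}

#' Evaluate the tissue displacement at arbitrary positions
#'
#' @param params a [motion_params()].
#' @param x,y positions in mm.
#' @param t time in s.
#' @return list with numeric vectors `dx`, `dy` (mm).
#' @export
tissue_displacement_at <- function(params, x, y, t) {
  if (params$amplitude_mm == 0) {
    z <- numeric(length(x))
    return(list(dx = z, dy = z))
  }
  s <- sin(2 * pi * params$freq_hz * t + params$phase)
  w <- exp(-(y - params$profile_center_y)^2 / (2 * params$profile_sigma_mm^2))
  mag <- params$amplitude_mm * s * w
  list(dx = mag * params$direction[1], dy = mag * params$direction[2])
}

#' Dense tissue displacement field on an image grid
#'
#' @param t time in s.
#' @param params a [motion_params()].
#' @param n_row,n_col grid size in pixels.
#' @param pixel_pitch mm per pixel.
#' @return list with matrices `dx`, `dy` (mm) over pixel centers.
#' @export
apply_tissue_motion <- function(t, params, n_row, n_col, pixel_pitch) {
  xs <- (seq_len(n_col) - 0.5) * pixel_pitch
  ys <- (seq_len(n_row) - 0.5) * pixel_pitch
  X <- outer(rep(1, n_row), xs)
  Y <- outer(ys, rep(1, n_col))
  d <- tissue_displacement_at(params, as.vector(X), as.vector(Y), t)
  list(dx = matrix(d$dx, n_row, n_col), dy = matrix(d$dy, n_row, n_col))
}
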