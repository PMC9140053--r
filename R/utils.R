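# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' Convert a displacement step to a flow angle in degrees
#'
#' Angles follow the mathematical convention on the image plane with the
#' axial (row) axis pointing down: 0 deg is flow toward increasing lateral
#' position (right), 90 deg is flow toward the transducer (up, decreasing
#' depth). Returned angles are in `[0, 360)`.
#'
#' @param dx,dy displacement components in mm; `dy` is positive downward
#'   (increasing depth).
#' @return angle(s) in degrees in `[0, 360)`.
#' @export
step_angle_deg <- function(dx, dy) {
  a <- atan2(-dy, dx) * 180 / pi
  (a %% 360)
}

#' Circular mean of angles in degrees
#'
#' @param angles_deg angles in degrees.
#' @param w non-negative weights (default equal).
#' @return circular mean in `[0, 360)`, or `NA` if the resultant is zero.
#' @export
circ_mean_deg <- function(angles_deg, w = NULL) {
  stop_if_not(length(angles_deg) > 0, "no angles supplied")
  if (is.null(w)) w <- rep(1, length(angles_deg))
  stop_if_not(all(w >= 0) && sum(w) > 0, "weights must be non-negative with positive sum")
  rad <- angles_deg * pi / 180
  s <- sum(w * sin(rad)); c <- sum(w * cos(rad))
  if (sqrt(s^2 + c^2) < 1e-12 * sum(w)) return(NA_real_)
  out <- (atan2(s, c) * 180 / pi) %% 360
  if (out > 360 - 1e-9) out <- 0
  out
}

#' Angular distance between two angles in degrees
#'
#' @param a,b angles in degrees (any range).
#' @return absolute angular distance in `[0, 180]`.
#' @export
ang_dist_deg <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

# Bilinear interpolation of a matrix-valued field sampled at regular centers.
# xs, ys are the strictly increasing coordinates of the columns/rows of `m`;
# query points outside are clamped to the border value.
bilinear_at <- function(m, xs, ys, x, y) {
  nx <- length(xs); ny <- length(ys)
  x <- pmin(pmax(x, xs[1]), xs[nx])
  y <- pmin(pmax(y, ys[1]), ys[ny])
  ix <- pmin(pmax(findInterval(x, xs), 1L), nx - 1L)
  iy <- pmin(pmax(findInterval(y, ys), 1L), ny - 1L)
  if (nx == 1L) { ix <- 1L; tx <- 0 } else tx <- (x - xs[ix]) / (xs[ix + 1L] - xs[ix])
  if (ny == 1L) { iy <- 1L; ty <- 0 } else ty <- (y - ys[iy]) / (ys[iy + 1L] - ys[iy])
  ix1 <- pmin(ix + 1L, nx); iy1 <- pmin(iy + 1L, ny)
  m[cbind(iy, ix)] * (1 - tx) * (1 - ty) +
    m[cbind(iy, ix1)] * tx * (1 - ty) +
    m[cbind(iy1, ix)] * (1 - tx) * ty +
    m[cbind(iy1, ix1)] * tx * ty
}
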