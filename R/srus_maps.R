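# Super-resolved images: track positions accumulated on an upsampled grid
# (density) and RGB maps encoding flow direction as hue and speed as
# brightness on a color wheel.

#' Accumulate track positions into a super-resolved density image
#'
#' Each track position increments the high-resolution pixel containing it;
#' the image total equals the number of in-grid positions.
#'
#' @param tracks an `mb_tracks` data.frame (columns `x_mm`, `y_mm`).
#' @param n_row,n_col acquisition grid size in pixels.
#' @param pixel_pitch acquisition pixel pitch, mm.
#' @param upsample integer upsampling factor (>= 1, default 4).
#' @return object of class `srus_image`: integer count matrix with
#'   attributes `pixel_pitch` (high-res) and `upsample`.
#' @export
accumulate_density <- function(tracks, n_row, n_col, pixel_pitch,
                               upsample = 4L) {
  stop_if_not(upsample >= 1, "upsample factor must be >= 1")
  hp <- pixel_pitch / upsample
  nr <- n_row * upsample; nc <- n_col * upsample
  img <- matrix(0L, nr, nc)
  if (nrow(tracks)) {
    r <- floor(tracks$y_mm / hp) + 1L
    c_ <- floor(tracks$x_mm / hp) + 1L
    ok <- r >= 1L & r <= nr & c_ >= 1L & c_ <= nc
    if (any(ok)) {
      tab <- table(r[ok] + (c_[ok] - 1L) * nr)
      idx <- as.integer(names(tab))
      img[idx] <- img[idx] + as.integer(tab)
    }
  }
  structure(img, class = c("srus_image", "matrix"),
            pixel_pitch = hp, upsample = upsample, kind = "density")
}

#' RGB direction/velocity map from tracks
#'
#' Per high-resolution pixel the mean velocity vector of the contributing
#' track positions is computed; the hue encodes its direction on the color
#' wheel, the brightness (HSV value) is `min(speed, vmax) / vmax`, so
#' brighter colors are faster and speeds above `vmax` saturate.
#'
#' @param tracks an `mb_tracks` data.frame (columns `x_mm`, `y_mm`, `vx`,
#'   `vy`).
#' @param n_row,n_col,pixel_pitch,upsample as in [accumulate_density()].
#' @param vmax display velocity ceiling in mm/s (20 for the cortex, 5 for
#'   the medulla are typical choices).
#' @return `srus_image` array `[row, col, 3]` with RGB in \[0, 1\].
#' @export
velocity_map <- function(tracks, n_row, n_col, pixel_pitch, upsample = 4L,
                         vmax = 20) {
  stop_if_not(vmax > 0, "vmax must be > 0")
  hp <- pixel_pitch / upsample
  nr <- n_row * upsample; nc <- n_col * upsample
  rgb_arr <- array(0, c(nr, nc, 3))
  if (nrow(tracks)) {
    r <- floor(tracks$y_mm / hp) + 1L
    c_ <- floor(tracks$x_mm / hp) + 1L
    ok <- r >= 1L & r <= nr & c_ >= 1L & c_ <= nc
    if (any(ok)) {
      key <- r[ok] + (c_[ok] - 1L) * nr
      mvx <- rowsum(tracks$vx[ok], key) / as.vector(table(key))
      mvy <- rowsum(tracks$vy[ok], key) / as.vector(table(key))
      idx <- as.integer(rownames(mvx))
      speed <- sqrt(mvx[, 1]^2 + mvy[, 1]^2)
      hue <- step_angle_deg(mvx[, 1], mvy[, 1]) / 360
      val <- pmin(speed, vmax) / vmax
      col <- grDevices::hsv(h = hue, s = 1, v = val)
      m <- grDevices::col2rgb(col) / 255
      for (ch in 1:3) {
        plane <- matrix(0, nr, nc)
        plane[idx] <- m[ch, ]
        rgb_arr[, , ch] <- plane
      }
    }
  }
  structure(rgb_arr, class = c("srus_image", "array"),
            pixel_pitch = hp, upsample = upsample, kind = "velocity",
            vmax = vmax)
}
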