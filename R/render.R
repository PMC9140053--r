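# Frame rendering: microbubbles as isotropic Gaussian intensity blobs on the
# contrast channel plus additive Gaussian background noise; the B-mode
# channel is a static speckle pattern warped by the tissue motion field.

# Separable Gaussian blur by row/column operator matrices (edge-renormalized).
# Cached per (n, sigma) since localization calls this once per frame.
.blur_cache <- new.env(parent = emptyenv())

blur_operator <- function(n, sigma) {
  key <- sprintf("%d_%.6g", n, sigma)
  op <- .blur_cache[[key]]
  if (!is.null(op)) return(op)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  k <- exp(-d^2 / (2 * sigma^2))
  k[d > ceiling(4 * sigma)] <- 0
  op <- k / rowSums(k)
  .blur_cache[[key]] <- op
  op
}

#' Gaussian smoothing of a 2-D frame
#'
#' @param m numeric matrix.
#' @param sigma_px Gaussian sigma in pixels; 0 returns `m` unchanged.
#' @return smoothed matrix of the same size.
#' @export
gauss_smooth <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  R <- blur_operator(nrow(m), sigma_px)
  C <- blur_operator(ncol(m), sigma_px)
  R %*% m %*% t(C)
}

#' Render contrast and B-mode frame stacks from ground-truth trajectories
#'
#' Each in-frame microbubble is rendered as an isotropic Gaussian blob at
#' its (motion-displaced) true position; per-bubble peak amplitudes are
#' log-normal around `mb_amplitude`. The B-mode channel is a fixed
#' speckle-like texture (Gaussian-smoothed white noise) warped backward by
#' the same tissue motion field, optionally rendered only every
#' `bmode_every`-th frame. Bubbles whose center leaves the grid are silently
#' out of view (counted in attribute `n_out_of_view`).
#'
#' @param trajectories data.frame from [simulate_microbubbles()] (columns
#'   `frame`, `x_mm`, `y_mm`, `trajectory_id`).
#' @param n_row,n_col grid size in pixels.
#' @param pixel_pitch mm per pixel.
#' @param frame_rate frames per second.
#' @param n_frames number of frames; defaults to the trajectory attribute.
#' @param psf_sigma point-spread sigma in mm (> 0).
#' @param mb_amplitude mean peak blob intensity (a.u.).
#' @param mb_amp_cv log-normal coefficient of variation of per-bubble
#'   amplitudes (0 = identical bubbles).
#' @param noise_sd additive Gaussian noise sd on the contrast channel.
#' @param motion `NULL` or a [motion_params()].
#' @param bmode render the B-mode channel? (skipping it saves memory).
#' @param bmode_every render B-mode every k-th frame (k >= 1).
#' @param speckle_sigma_px correlation length of the speckle texture.
#' @param bmode_noise_sd per-frame additive noise on B-mode.
#' @param seed optional RNG seed.
#' @return list with `contrast` and (optionally) `bmode` [frame_stack()]s.
#' @export
render_frames <- function(trajectories, n_row, n_col, pixel_pitch,
                          frame_rate = 54, n_frames = NULL,
                          psf_sigma = 0.075, mb_amplitude = 10,
                          mb_amp_cv = 0.2, noise_sd = 0.5, motion = NULL,
                          bmode = TRUE, bmode_every = 1L,
                          speckle_sigma_px = 1.5, bmode_noise_sd = 0.05,
                          seed = NULL) {
  stop_if_not(psf_sigma > 0, "psf_sigma must be > 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_frames)) n_frames <- attr(trajectories, "n_frames")
  stop_if_not(!is.null(n_frames) && n_frames >= 1, "n_frames required")
  n_frames <- as.integer(n_frames)

  # per-bubble amplitudes (log-normal, mean mb_amplitude)
  ids <- unique(trajectories$trajectory_id)
  amp <- rep(mb_amplitude, length(ids))
  if (length(ids) && mb_amp_cv > 0) {
    s <- sqrt(log(1 + mb_amp_cv^2))
    amp <- mb_amplitude * exp(stats::rnorm(length(ids), -s^2 / 2, s))
  }
  names(amp) <- as.character(ids)

  ts <- (seq_len(n_frames) - 1) / frame_rate
  by_frame <- if (nrow(trajectories)) {
    split(seq_len(nrow(trajectories)),
          factor(trajectories$frame, levels = seq_len(n_frames)))
  } else NULL

  hw <- ceiling(3.5 * psf_sigma / pixel_pitch)
  two_s2 <- 2 * (psf_sigma / pixel_pitch)^2  # sigma in pixel units
  n_oov <- 0L

  contrast <- array(0, c(n_row, n_col, n_frames))
  for (f in seq_len(n_frames)) {
    fr <- if (noise_sd > 0) {
      matrix(stats::rnorm(n_row * n_col, 0, noise_sd), n_row, n_col)
    } else matrix(0, n_row, n_col)
    idx <- by_frame[[f]]
    if (length(idx)) {
      x <- trajectories$x_mm[idx]; y <- trajectories$y_mm[idx]
      if (!is.null(motion)) {
        d <- tissue_displacement_at(motion, x, y, ts[f])
        x <- x + d$dx; y <- y + d$dy
      }
      cj <- x / pixel_pitch + 0.5  # continuous 1-based column index
      ri <- y / pixel_pitch + 0.5
      a <- amp[as.character(trajectories$trajectory_id[idx])]
      for (m in seq_along(idx)) {
        r0 <- floor(ri[m] - hw); r1 <- ceiling(ri[m] + hw)
        c0 <- floor(cj[m] - hw); c1 <- ceiling(cj[m] + hw)
        if (r1 < 1 || r0 > n_row || c1 < 1 || c0 > n_col) {
          n_oov <- n_oov + 1L
          next
        }
        rs <- max(1, r0):min(n_row, r1)
        cs <- max(1, c0):min(n_col, c1)
        blob <- a[m] * exp(-(rs - ri[m])^2 / two_s2) %o%
          exp(-(cs - cj[m])^2 / two_s2)
        fr[rs, cs] <- fr[rs, cs] + blob
      }
    }
    contrast[, , f] <- fr
  }
  out <- list(contrast = frame_stack(contrast, pixel_pitch, frame_rate,
                                     channel = "contrast"))
  attr(out$contrast, "n_out_of_view") <- n_oov

  if (bmode) {
    base <- gauss_smooth(matrix(stats::rnorm(n_row * n_col), n_row, n_col),
                         speckle_sigma_px)
    base <- base / stats::sd(base)
    xs <- (seq_len(n_col) - 0.5) * pixel_pitch
    ys <- (seq_len(n_row) - 0.5) * pixel_pitch
    X <- as.vector(outer(rep(1, n_row), xs))
    Y <- as.vector(outer(ys, rep(1, n_col)))
    fb <- seq(1L, n_frames, by = as.integer(bmode_every))
    barr <- array(0, c(n_row, n_col, length(fb)))
    for (j in seq_along(fb)) {
      tj <- ts[fb[j]]
      if (!is.null(motion) && motion$amplitude_mm > 0) {
        d <- tissue_displacement_at(motion, X, Y, tj)
        warped <- bilinear_at(base, xs, ys, X - d$dx, Y - d$dy)
        bfr <- matrix(warped, n_row, n_col)
      } else bfr <- base
      if (bmode_noise_sd > 0)
        bfr <- bfr + matrix(stats::rnorm(n_row * n_col, 0, bmode_noise_sd),
                            n_row, n_col)
      barr[, , j] <- bfr
    }
    out$bmode <- frame_stack(barr, pixel_pitch,
                             frame_rate = frame_rate / bmode_every,
                             channel = "bmode",
                             timestamps = ts[fb])
    attr(out$bmode, "source_frames") <- fb
  }
  out
}
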