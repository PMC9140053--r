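# Microbubble detection and sub-pixel localization: Gaussian smoothing,
# intensity thresholding, connected components, weighted centroids.
#
# Coordinate convention: pixel (r, c) (0-based) has its center at
# ((c + 0.5) * pitch, (r + 0.5) * pitch) = (x = lateral, y = axial depth),
# origin at the image's top-left corner; all positions reported in mm.

#' Detect candidate microbubble regions in one frame
#'
#' The frame is Gaussian-smoothed first, then thresholded; connected
#' components (4-connectivity) of supra-threshold pixels smaller than
#' `min_area` pixels are discarded.
#'
#' @param frame numeric matrix (a.u.); all values must be finite.
#' @param threshold absolute intensity threshold (> 0) applied to the
#'   smoothed frame, or if `percentile = TRUE` a percentile in (0, 100).
#' @param smooth_sigma Gaussian sigma in pixels (>= 0; 0 disables).
#' @param min_area minimum component size in pixels.
#' @param percentile interpret `threshold` as a percentile of smoothed
#'   intensities instead of an absolute level.
#' @return list of candidate regions; each has `rows`, `cols` (0-based
#'   pixel indices), `w` (smoothed intensities) and `peak`.
#' @export
detect_candidates <- function(frame, threshold, smooth_sigma = 1,
                              min_area = 3L, percentile = FALSE) {
  stop_if_not(all(is.finite(frame)), "frame contains non-finite values")
  stop_if_not(threshold > 0, "threshold must be > 0")
  stop_if_not(smooth_sigma >= 0, "smooth_sigma must be >= 0")
  sm <- gauss_smooth(frame, smooth_sigma)
  thr <- if (percentile) stats::quantile(sm, threshold / 100) else threshold
  lab <- label_components(sm > thr)
  if (max(lab) == 0L) return(list())
  idx <- which(lab > 0L)
  ids <- lab[idx]
  rows0 <- (idx - 1L) %% nrow(frame)
  cols0 <- (idx - 1L) %/% nrow(frame)
  w <- sm[idx]
  keep <- which(tabulate(ids) >= min_area)
  out <- lapply(keep, function(k) {
    sel <- ids == k
    list(rows = rows0[sel], cols = cols0[sel], w = w[sel], peak = max(w[sel]))
  })
  out
}

# 4-connected component labeling of a logical mask (EBImage's C routine).
label_components <- function(mask) {
  m <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  storage.mode(m) <- "integer"
  m
}

#' Intensity-weighted centroid of a candidate region
#'
#' Returns `sum(w_i p_i) / sum(w_i)` over pixel centers, in mm.
#'
#' @param region list with `rows`, `cols` (0-based pixel indices) and `w`
#'   (non-negative weights with positive total).
#' @param pixel_pitch mm per pixel.
#' @return named vector `c(x, y)` in mm.
#' @export
weighted_centroid <- function(region, pixel_pitch = 1) {
  stop_if_not(length(region$rows) > 0, "region is empty")
  W <- sum(region$w)
  stop_if_not(W > 0, "degenerate region: total intensity is zero")
  c(x = (sum(region$w * region$cols) / W + 0.5) * pixel_pitch,
    y = (sum(region$w * region$rows) / W + 0.5) * pixel_pitch)
}

#' Localize microbubbles in every frame of a contrast stack
#'
#' Per-frame composition of [detect_candidates()] and
#' [weighted_centroid()], vectorized over components within a frame.
#'
#' Components whose intensity-weighted shape is strongly elongated
#' (axis ratio above `max_elongation`) are rejected: single microbubbles
#' image as near-isotropic blobs, while two bubbles merging into one
#' component produce an elongated blob whose centroid tracks neither.
#'
#' @param stack a contrast [frame_stack()].
#' @param threshold,smooth_sigma,min_area,percentile see
#'   [detect_candidates()].
#' @param max_elongation maximum sqrt eigenvalue ratio of the
#'   intensity-weighted second-moment matrix (`Inf` disables).
#' @return data.frame with columns `frame`, `t`, `x_mm`, `y_mm`,
#'   `intensity` (smoothed peak), `area` (pixels).
#' @export
localize_stack <- function(stack, threshold = 2, smooth_sigma = 1,
                           min_area = 3L, percentile = FALSE,
                           max_elongation = 2) {
  nf <- n_frames(stack)
  p <- stack$pixel_pitch
  res <- vector("list", nf)
  for (f in seq_len(nf)) {
    fr <- stack$frames[, , f]
    stop_if_not(all(is.finite(fr)), "frame contains non-finite values")
    sm <- gauss_smooth(fr, smooth_sigma)
    thr <- if (percentile) stats::quantile(sm, threshold / 100) else threshold
    lab <- label_components(sm > thr)
    if (max(lab) == 0L) next
    idx <- which(lab > 0L)
    ids <- lab[idx]
    area <- tabulate(ids)
    keep <- area >= min_area
    if (!any(keep)) next
    w <- sm[idx]
    rows0 <- (idx - 1L) %% nrow(fr)
    cols0 <- (idx - 1L) %/% nrow(fr)
    sw <- rowsum(w, ids)[, 1]
    sx <- rowsum(w * cols0, ids)[, 1]
    sy <- rowsum(w * rows0, ids)[, 1]
    pk <- vapply(split(w, ids), max, numeric(1))
    mx <- sx / sw; my <- sy / sw
    if (is.finite(max_elongation)) {
      cxx <- rowsum(w * cols0^2, ids)[, 1] / sw - mx^2
      cyy <- rowsum(w * rows0^2, ids)[, 1] / sw - my^2
      cxy <- rowsum(w * cols0 * rows0, ids)[, 1] / sw - mx * my
      tr2 <- (cxx + cyy) / 2
      det_ <- cxx * cyy - cxy^2
      disc <- sqrt(pmax(tr2^2 - det_, 0))
      l1 <- tr2 + disc; l2 <- pmax(tr2 - disc, 1e-12)
      keep <- keep & sqrt(l1 / l2) <= max_elongation
      if (!any(keep)) next
    }
    res[[f]] <- data.frame(
      frame = f, t = stack$timestamps[f],
      x_mm = (mx[keep] + 0.5) * p,
      y_mm = (my[keep] + 0.5) * p,
      intensity = pk[keep], area = area[keep])
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(frame = integer(), t = numeric(), x_mm = numeric(),
                      y_mm = numeric(), intensity = numeric(),
                      area = integer())
  rownames(out) <- NULL
  out
}
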