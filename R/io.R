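# File interfaces: multi-frame TIFF + JSON sidecar for frame stacks,
# CSV for ground-truth trajectories, tracks and MAP traces, JSON for
# session metadata, and PNG/TIFF label images for region masks.

#' Write a frame stack as multi-frame TIFF with a JSON sidecar
#'
#' Intensities are scaled to \[0, 1\] for 16-bit storage; the scale and the
#' acquisition metadata (pixel pitch, frame rate, channel, extra entries
#' such as `t_inj` or the simulation seed) go to `<path>.json`.
#'
#' @param stack a [frame_stack()].
#' @param path output path without extension.
#' @param meta named list of extra metadata stored in the sidecar.
#' @return invisibly, the two file paths.
#' @export
write_frame_stack <- function(stack, path, meta = list()) {
  lo <- min(stack$frames); hi <- max(stack$frames)
  scale <- if (hi > lo) hi - lo else 1
  frames <- lapply(seq_len(n_frames(stack)), function(f)
    (stack$frames[, , f] - lo) / scale)
  tif <- paste0(path, ".tif"); js <- paste0(path, ".json")
  tiff::writeTIFF(frames, tif, bits.per.sample = 16L, compression = "none")
  side <- c(list(pixel_pitch = stack$pixel_pitch,
                 frame_rate = stack$frame_rate,
                 t0 = stack$timestamps[1], channel = stack$channel,
                 intensity_offset = lo, intensity_scale = scale,
                 n_frames = n_frames(stack)), meta)
  jsonlite::write_json(side, js, auto_unbox = TRUE, digits = NA)
  invisible(c(tif, js))
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param path path without extension.
#' @return a [frame_stack()]; sidecar metadata in attribute `meta`.
#' @export
read_frame_stack <- function(path) {
  frames <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arr <- array(0, c(nrow(frames[[1]]), ncol(frames[[1]]), length(frames)))
  for (f in seq_along(frames))
    arr[, , f] <- frames[[f]] * side$intensity_scale + side$intensity_offset
  st <- frame_stack(arr, side$pixel_pitch, side$frame_rate,
                    t0 = side$t0, channel = side$channel)
  attr(st, "meta") <- side
  st
}

#' Write / read ground-truth trajectories as CSV
#'
#' Columns: `trajectory_id, frame, x_mm, y_mm, speed_mm_s, bed`.
#' @param trajectories data.frame from [simulate_microbubbles()].
#' @param file CSV path.
#' @export
write_ground_truth <- function(trajectories, file) {
  utils::write.csv(
    trajectories[, c("trajectory_id", "frame", "x_mm", "y_mm",
                     "speed_mm_s", "bed")],
    file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}

#' Write / read a MAP trace as CSV (`t`, `map` at 1 Hz)
#' @param map data.frame with `t` (s) and `map` (mmHg).
#' @param file CSV path.
#' @export
write_map_trace <- function(map, file) {
  utils::write.csv(map, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_map_trace
#' @export
read_map_trace <- function(file) {
  utils::read.csv(file)
}

#' Read a region label image (PNG or TIFF, values 0-3)
#'
#' Accepts either integer-coded images (0 = background, 1 = cortex,
#' 2 = outer medulla, 3 = inner medulla) or normalized intensities in
#' steps of 1/255 as written by common viewers.
#'
#' @param file image path (`.png` or `.tif`).
#' @param pixel_pitch mm per pixel of the acquisition grid.
#' @return a [region_label_map()].
#' @export
read_region_labels <- function(file, pixel_pitch) {
  img <- if (grepl("\\.png$", file, ignore.case = TRUE)) {
    png::readPNG(file)
  } else {
    tiff::readTIFF(file)
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  vals <- img
  if (max(vals) <= 1) vals <- vals * 255
  lab <- round(vals)
  stop_if_not(all(lab %in% 0:3), "label image must be coded 0..3")
  region_label_map(matrix(as.integer(lab), nrow(img), ncol(img)),
                   pixel_pitch)
}

#' Write per-bed track positions as CSV
#'
#' Columns: `track_id, frame, t, x_mm, y_mm, vx, vy, speed, bed`.
#' @param beds named list of track data.frames (one per bed).
#' @param file CSV path.
#' @export
write_bed_tracks <- function(beds, file) {
  rows <- lapply(names(beds), function(b) {
    d <- beds[[b]]
    if (nrow(d) == 0) return(NULL)
    d$bed <- b
    d[, c("track_id", "frame", "t", "x_mm", "y_mm", "vx", "vy",
          "speed", "bed")]
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}
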