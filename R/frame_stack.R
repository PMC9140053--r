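# FrameStack: time-ordered 2-D image frames of one channel (contrast or
# B-mode) with pixel pitch and timestamps.

#' Construct a frame stack
#'
#' @param frames 3-D numeric array `[row = axial, col = lateral, frame]`.
#' @param pixel_pitch mm per pixel.
#' @param frame_rate frames per second (default 54).
#' @param t0 timestamp of the first frame, s.
#' @param channel `"contrast"` or `"bmode"`.
#' @param timestamps optional explicit timestamps (s); default
#'   `t0 + (0:(n-1))/frame_rate`. Must be strictly increasing with spacing
#'   `1/frame_rate`.
#' @return object of class `frame_stack`.
#' @export
frame_stack <- function(frames, pixel_pitch, frame_rate = 54, t0 = 0,
                        channel = c("contrast", "bmode"), timestamps = NULL) {
  channel <- match.arg(channel)
  stop_if_not(is.array(frames) && length(dim(frames)) == 3,
              "frames must be a 3-D array [row, col, frame]")
  n <- dim(frames)[3]
  if (is.null(timestamps)) timestamps <- t0 + (seq_len(n) - 1) / frame_rate
  stop_if_not(length(timestamps) == n, "one timestamp per frame required")
  if (n > 1) {
    d <- diff(timestamps)
    stop_if_not(all(d > 0), "timestamps must be strictly increasing")
    stop_if_not(all(abs(d - 1 / frame_rate) < 1e-9),
                "timestamp spacing must equal 1/frame_rate")
  }
  structure(list(frames = frames, pixel_pitch = pixel_pitch,
                 frame_rate = frame_rate, timestamps = timestamps,
                 channel = channel),
            class = "frame_stack")
}

#' Number of frames in a stack
#' @param stack a [frame_stack()].
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame_stack (%s): %d x %d px, %d frames at %.3g Hz, pitch %.3g mm\n",
              x$channel, d[1], d[2], d[3], x$frame_rate, x$pixel_pitch))
  invisible(x)
}
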