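# End-to-end orchestration: simulate a scan, run the
# localization -> motion-compensation -> tracking pipeline, separate beds,
# and assemble scan sessions. Also the desk-scale reference session used
# for parameter-recovery checks.

#' Run the ULM pipeline on a contrast (+ B-mode) frame stack
#'
#' Localizes microbubbles in every contrast frame, optionally estimates
#' tissue motion from the B-mode stack (first frame as reference) and
#' removes it from the localizations, then links them into Kalman tracks.
#'
#' @param contrast contrast [frame_stack()].
#' @param bmode optional B-mode [frame_stack()] for motion compensation.
#' @param threshold,smooth_sigma,min_area localization settings, see
#'   [localize_stack()].
#' @param track_params a [tracker_params()].
#' @param search_px motion-estimation search radius in pixels.
#' @return list with `localizations` (corrected), `fields` (or `NULL`) and
#'   `tracks`.
#' @export
run_srus_pipeline <- function(contrast, bmode = NULL, threshold = 2,
                              smooth_sigma = 1, min_area = 3L,
                              track_params = tracker_params(),
                              search_px = 6L) {
  locs <- localize_stack(contrast, threshold = threshold,
                         smooth_sigma = smooth_sigma, min_area = min_area)
  fields <- NULL
  if (!is.null(bmode)) {
    fields <- estimate_motion_fields(bmode, ref_frame = 1L,
                                     search_px = search_px)
    locs <- compensate_localizations(locs, fields)
  }
  tracks <- build_tracks(locs, frame_rate = contrast$frame_rate,
                         params = track_params,
                         n_frames = n_frames(contrast))
  list(localizations = locs, fields = fields, tracks = tracks)
}

#' Simulate and analyze one scan of the reference synthetic session
#'
#' Generates ground-truth trajectories for the requested scan, renders the
#' contrast and B-mode channels, runs the full pipeline, and splits tracks
#' into the six beds with the phantom's ground-truth label map and flow
#' sectors.
#'
#' @param phantom a [build_renal_phantom()] result.
#' @param hemo a [hemo_params()].
#' @param scan scan number (1, 2 or 3).
#' @param duration scan duration, s.
#' @param t_inj injection time (scan-2 clock), s.
#' @param window scan-2 post-injection analysis window, s.
#' @param arrival_rate microbubble arrivals per vessel per second.
#' @param frame_rate frames per second.
#' @param motion a [motion_params()] or `NULL` to disable tissue motion.
#' @param bmode_every render/use B-mode every k-th frame.
#' @param track_params a [tracker_params()].
#' @param seed RNG seed for this scan.
#' @return list with `trajectories`, `tracks`, `split` (bed track sets),
#'   `beds`, `map` (1 Hz MAP trace), `duration`.
#' @export
simulate_scan <- function(phantom, hemo, scan, duration = 120, t_inj = 20,
                          window = 100, arrival_rate = 0.3, frame_rate = 54,
                          motion = motion_params(), bmode_every = 2L,
                          track_params = tracker_params(), seed = 1) {
  traj <- simulate_microbubbles(phantom, hemo, scan = scan,
                                duration = duration,
                                arrival_rate = arrival_rate,
                                frame_rate = frame_rate,
                                t_inj = if (scan == 2) t_inj else NA,
                                window = window, seed = seed)
  cfg <- phantom$config
  rf <- render_frames(traj, cfg$n_row, cfg$n_col, cfg$pixel_pitch,
                      frame_rate = frame_rate,
                      n_frames = floor(duration * frame_rate),
                      motion = motion,
                      bmode = !is.null(motion), bmode_every = bmode_every,
                      seed = seed + 1000L)
  pipe <- run_srus_pipeline(rf$contrast, rf$bmode,
                            track_params = track_params)
  split <- split_beds(pipe$tracks, phantom$labels, phantom$sectors)
  map <- simulate_map_trace(hemo, duration,
                            t_inj = if (scan == 2) t_inj else Inf,
                            seed = seed + 2000L)
  list(trajectories = traj, localizations = pipe$localizations,
       tracks = pipe$tracks, split = split, beds = split$beds,
       map = map, duration = duration)
}

#' Commanded mean speed of a bed over a scan's analysis window
#'
#' The ground-truth value the pipeline should recover: base bed speed times
#' the mean commanded multiplier over the scan's aligned window.
#'
#' @param phantom a [build_renal_phantom()] result.
#' @param hemo a [hemo_params()].
#' @param bed bed name.
#' @param scan scan number.
#' @param t_inj,window scan-2 alignment, s.
#' @return commanded mean speed, mm/s.
#' @export
commanded_mean_speed <- function(phantom, hemo, bed, scan, t_inj = 20,
                                 window = 100) {
  base <- phantom$config$bed_speeds[[bed]]
  if (scan == 2) {
    tt <- seq(t_inj, t_inj + window, by = 0.1)
    base * mean(speed_multiplier(bed, tt, 2, hemo, t_inj = t_inj,
                                 window = window))
  } else {
    base * hemo$scan_multipliers[bed, scan]
  }
}

#' Desk-scale reference recovery run
#'
#' Builds the default phantom, simulates the requested scans (120 s at
#' 54 Hz on the 128 x 128 grid by default), runs the full pipeline and
#' reports commanded vs pipeline-recovered scan-mean speeds per bed.
#' Scan means use the aligned windows: scan 1/3 the first `duration` s
#' available (up to the window), scan 2 the `window` s after `t_inj`.
#'
#' @param scans integer vector of scans to run.
#' @param seed base RNG seed; per-scan seeds are derived from it.
#' @param duration scan duration, s.
#' @param t_inj injection time, s (scan 2).
#' @param window scan-2 post-injection window, s.
#' @param arrival_rate microbubble arrivals per vessel per second.
#' @param ... passed on to [simulate_scan()].
#' @return data.frame with `bed`, `scan`, `commanded`, `recovered`,
#'   `n_positions`, `n_tracks`, `rel_error`.
#' @export
reference_recovery <- function(scans = c(1, 2), seed = 1, duration = 120,
                               t_inj = 20, window = 100,
                               arrival_rate = 0.3, ...) {
  phantom <- build_renal_phantom()
  hemo <- hemo_params()
  rows <- list()
  for (scan in scans) {
    res <- simulate_scan(phantom, hemo, scan, duration = duration,
                         t_inj = t_inj, window = window,
                         arrival_rate = arrival_rate,
                         seed = seed + 17L * scan, ...)
    w <- if (scan == 2) c(t_inj, t_inj + window) else
      c(0, min(duration, window + t_inj))
    for (bed in renal_beds()) {
      d <- res$beds[[bed]]
      sel <- d$t >= w[1] & d$t < w[2]
      rows[[length(rows) + 1L]] <- data.frame(
        bed = bed, scan = scan,
        commanded = commanded_mean_speed(phantom, hemo, bed, scan,
                                         t_inj = t_inj, window = window),
        recovered = if (any(sel)) mean(d$speed[sel]) else NA_real_,
        n_positions = sum(sel),
        n_tracks = length(unique(d$track_id[sel])))
    }
  }
  out <- do.call(rbind, rows)
  out$rel_error <- (out$recovered - out$commanded) / out$commanded
  rownames(out) <- NULL
  out
}
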