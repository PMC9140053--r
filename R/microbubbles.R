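# Ground-truth microbubble trajectories: Poisson arrivals per vessel,
# advection along the vessel centerline at the commanded (possibly
# time-varying) bed speed, optional acoustic disruption.

#' Simulate ground-truth microbubble trajectories
#'
#' Microbubbles arrive in each vessel as a Poisson process and are advected
#' along the vessel centerline at the bed's commanded speed
#' `base_speed * multiplier(t)` (see [speed_multiplier()]). Per-frame
#' positions advance by exactly `speed / frame_rate` along the centerline,
#' so the recorded per-step speed is the instantaneous commanded speed.
#' A trajectory ends when the microbubble exits the vessel, the scan ends,
#' or the bubble is disrupted (exponential lifetime with per-second hazard
#' `-log(1 - disruption_prob)`).
#'
#' @param phantom a [build_renal_phantom()] result.
#' @param hemo a [hemo_params()].
#' @param scan scan number (1, 2 or 3).
#' @param duration scan duration, s.
#' @param arrival_rate mean microbubble arrivals per vessel per second.
#' @param frame_rate frames per second (default 54).
#' @param t_inj injection time on the scan-2 clock, s (required for scan 2).
#' @param window scan-2 analysis window length, s (see [speed_multiplier()]).
#' @param disruption_prob per-second probability that a bubble is destroyed
#'   (default 0.02; set 0 to disable).
#' @param seed optional RNG seed (recorded as an attribute).
#' @return data.frame with columns `trajectory_id`, `vessel_id`, `bed`,
#'   `frame` (1-based), `t` (s), `x_mm`, `y_mm`, `speed_mm_s`;
#'   attribute `seed` echoes the seed.
#' @export
simulate_microbubbles <- function(phantom, hemo, scan = 1, duration = 120,
                                  arrival_rate = 0.3, frame_rate = 54,
                                  t_inj = NA, window = 410,
                                  disruption_prob = 0.02, seed = NULL) {
  stop_if_not(arrival_rate > 0, "arrival_rate must be > 0")
  stop_if_not(duration > 0, "duration must be > 0")
  stop_if_not(disruption_prob >= 0 && disruption_prob < 1,
              "disruption_prob must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)

  n_frames <- floor(duration * frame_rate)
  tk <- (seq_len(n_frames) - 1) / frame_rate
  dt <- 1 / frame_rate
  haz <- if (disruption_prob > 0) -log(1 - disruption_prob) else 0

  beds <- unique(vapply(phantom$vessels, function(v) v$bed, character(1)))
  # commanded speed shared by all vessels of a bed (up to base_speed scale)
  mult <- lapply(beds, function(b)
    speed_multiplier(b, tk, scan, hemo, t_inj = t_inj, window = window))
  names(mult) <- beds

  out <- vector("list", 512)
  n_out <- 0L
  tid <- 0L
  for (v in phantom$vessels) {
    vspeed <- v$base_speed * mult[[v$bed]]
    n_mb <- stats::rpois(1, arrival_rate * duration)
    if (n_mb == 0) next
    entries <- sort(stats::runif(n_mb, 0, duration))
    lifetimes <- if (haz > 0) stats::rexp(n_mb, rate = haz) else rep(Inf, n_mb)
    for (i in seq_len(n_mb)) {
      k0 <- ceiling(entries[i] * frame_rate) + 1L   # first frame at/after entry
      if (k0 > n_frames) next
      ks <- k0:n_frames
      # arc length: s[1] = 0 at entry frame, then += speed * dt per step
      sp <- vspeed[ks]
      s <- c(0, cumsum(sp[-length(sp)] * dt))
      keep <- s <= v$length_mm & (tk[ks] - entries[i]) <= lifetimes[i]
      if (!any(keep)) next
      keep_to <- which(!keep)[1]
      if (!is.na(keep_to)) keep <- seq_len(keep_to - 1L) else keep <- seq_along(ks)
      ks <- ks[keep]; s <- s[keep]; sp <- sp[keep]
      tid <- tid + 1L
      n_out <- n_out + 1L
      if (n_out > length(out)) out <- c(out, vector("list", length(out)))
      out[[n_out]] <- data.frame(
        trajectory_id = tid, vessel_id = v$id, bed = v$bed,
        frame = ks, t = tk[ks],
        x_mm = v$centerline[1, 1] + s * v$flow_direction[1],
        y_mm = v$centerline[1, 2] + s * v$flow_direction[2],
        speed_mm_s = sp)
    }
  }
  res <- if (n_out > 0) do.call(rbind, out[seq_len(n_out)]) else
    data.frame(trajectory_id = integer(), vessel_id = integer(),
               bed = character(), frame = integer(), t = numeric(),
               x_mm = numeric(), y_mm = numeric(), speed_mm_s = numeric())
  rownames(res) <- NULL
  attr(res, "seed") <- seed
  attr(res, "frame_rate") <- frame_rate
  attr(res, "n_frames") <- n_frames
  res
}
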