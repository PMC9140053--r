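# Bed velocity series and period summaries: 30-s moving averages,
# injection-aligned analysis windows (50 s before to 410 s after the
# prazosin injection; scans 1 and 3 use their first 410 s), the lowest-MAP
# 30-s window, and per-bed/per-scan summary statistics.

#' Moving-average series of time-stamped speed samples
#'
#' Centered windows: the value at time `t` is the mean of all samples in
#' `[t - window/2, t + window/2]`; windows with no samples are missing.
#'
#' @param samples data.frame with columns `t` (s) and `speed` (mm/s).
#' @param window window length in s (default 30).
#' @param step grid step in s (default 1).
#' @param t_range length-2 range of the output grid; defaults to the
#'   sample range.
#' @return data.frame with `t`, `mean` (NA where empty) and `n`.
#' @export
moving_average_series <- function(samples, window = 30, step = 1,
                                  t_range = NULL) {
  stop_if_not(window > 0, "window must be > 0")
  if (is.null(t_range)) {
    if (nrow(samples) == 0) t_range <- c(0, 0)
    else t_range <- range(samples$t)
  }
  grid <- seq(t_range[1], t_range[2], by = step)
  if (nrow(samples) == 0)
    return(data.frame(t = grid, mean = NA_real_, n = 0L))
  o <- order(samples$t)
  ts <- samples$t[o]; vs <- samples$speed[o]
  cs <- c(0, cumsum(vs))
  lo <- findInterval(grid - window / 2, ts, left.open = TRUE)   # first idx - 1
  hi <- findInterval(grid + window / 2, ts)                     # last idx
  n <- hi - lo
  m <- ifelse(n > 0, (cs[hi + 1] - cs[lo + 1]) / n, NA_real_)
  data.frame(t = grid, mean = m, n = n)
}

#' Scan session container
#'
#' Bundles the three scans' bed track sets and MAP traces with the
#' injection time, the unit on which period alignment and statistics
#' operate.
#'
#' @param scans list of three lists, each with elements `beds` (named list
#'   of track data.frames), `map` (data.frame `t`, `map`) and `duration`
#'   (s).
#' @param t_inj injection time on the scan-2 clock, s (51-184 s in the
#'   full-scale protocol).
#' @param pre_window,post_window display/analysis window lengths around the
#'   injection, s (defaults 50 and 410).
#' @return object of class `scan_session`.
#' @export
scan_session <- function(scans, t_inj, pre_window = 50, post_window = 410) {
  stop_if_not(length(scans) == 3, "a session has exactly three scans")
  stop_if_not(t_inj >= 0 && t_inj < scans[[2]]$duration,
              "t_inj must fall within scan 2")
  structure(list(scans = scans, t_inj = t_inj, pre_window = pre_window,
                 post_window = post_window),
            class = "scan_session")
}

#' Injection-aligned analysis windows of a session
#'
#' Scan 2's display span runs from `pre_window` s before to `post_window` s
#' after the injection (460 s with the defaults); its mean window is the
#' `post_window` s after injection. Scans 1 and 3 use their first
#' `post_window` s.
#'
#' @param session a [scan_session()].
#' @return list with `display_span`, `scan2_mean_window`,
#'   `scan13_window` (each length-2, s) and `display_length`.
#' @export
align_to_injection <- function(session) {
  ti <- session$t_inj
  pre <- session$pre_window; post <- session$post_window
  stop_if_not(ti - pre >= 0,
              "truncation: display span starts before scan 2 (t_inj too early)")
  stop_if_not(ti + post <= session$scans[[2]]$duration,
              "truncation: t_inj + analysis window exceeds scan-2 length")
  stop_if_not(session$scans[[1]]$duration >= post &&
              session$scans[[3]]$duration >= post,
              "truncation: scans 1/3 shorter than the analysis window")
  list(display_span = c(ti - pre, ti + post),
       scan2_mean_window = c(ti, ti + post),
       scan13_window = c(0, post),
       display_length = pre + post)
}

#' Locate the contiguous lowest-MAP window after the injection
#'
#' Among all contiguous windows of `width` s starting at trace samples at
#' or after `t_inj`, returns the one minimizing the mean MAP (earliest on
#' ties). Samples in `[start, start + width)` count.
#'
#' @param map data.frame with columns `t` and `map`.
#' @param t_inj injection time, s.
#' @param width window length, s (default 30).
#' @return list with `start` (s) and `mean` (mmHg).
#' @export
lowest_map_window <- function(map, t_inj, width = 30) {
  o <- order(map$t)
  ts <- map$t[o]; vals <- map$map[o]
  starts <- ts[ts >= t_inj & ts <= max(ts) - width + (ts[2] - ts[1])]
  stop_if_not(length(starts) > 0, "trace does not cover the search range")
  cs <- c(0, cumsum(vals))
  lo <- findInterval(starts, ts, left.open = TRUE)
  hi <- findInterval(starts + width, ts, left.open = TRUE)
  n <- hi - lo
  means <- (cs[hi + 1] - cs[lo + 1]) / n
  i <- which.min(means)  # earliest on ties
  list(start = starts[i], mean = means[i])
}

#' Per-bed, per-scan velocity summaries and coverage statistics
#'
#' Scan means use every per-position speed sample in the aligned window
#' (scans 1 and 3: first `post_window` s; scan 2: `post_window` s after
#' injection). Scan-2 sub-periods are the first 30 s of the scan
#' (baseline), the 30 s with lowest MAP, and the last 30 s (recovery).
#' Coverage: seconds with at least one sample and samples per second.
#'
#' @param session a [scan_session()].
#' @param subperiod_width sub-period length in s (default 30).
#' @return data.frame with columns `bed`, `scan`, `period`, `mean`, `sd`,
#'   `n`, `seconds_with_estimates`, `positions_per_s`, `window_start`,
#'   `window_end`. Empty beds yield `NA` means with a warning.
#' @export
bed_summaries <- function(session, subperiod_width = 30) {
  al <- align_to_injection(session)
  rows <- list()
  add <- function(bed, scan, period, d, w) {
    sel <- d$t >= w[1] & d$t < w[2]
    sp <- d$speed[sel]
    rows[[length(rows) + 1L]] <<- data.frame(
      bed = bed, scan = scan, period = period,
      mean = if (length(sp)) mean(sp) else NA_real_,
      sd = if (length(sp) > 1) stats::sd(sp) else NA_real_,
      n = length(sp),
      seconds_with_estimates = length(unique(floor(d$t[sel]))),
      positions_per_s = length(sp) / (w[2] - w[1]),
      window_start = w[1], window_end = w[2])
  }
  for (scan in 1:3) {
    sc <- session$scans[[scan]]
    w_scan <- if (scan == 2) al$scan2_mean_window else al$scan13_window
    for (bed in names(sc$beds)) {
      d <- sc$beds[[bed]]
      if (nrow(d) == 0)
        warning("bed ", bed, " has no samples in scan ", scan)
      add(bed, scan, "scan", d, w_scan)
      if (scan == 2) {
        dur <- sc$duration
        add(bed, scan, "baseline30", d, c(0, subperiod_width))
        lw <- lowest_map_window(sc$map, session$t_inj, subperiod_width)
        add(bed, scan, "lowmap30", d, c(lw$start, lw$start + subperiod_width))
        add(bed, scan, "recovery30", d, c(dur - subperiod_width, dur))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Variance-stabilizing transform of bed speeds
#'
#' Natural log for cortical beds, square root for medullary beds.
#'
#' @param speeds numeric vector of speeds (mm/s).
#' @param region `"cortex"`, `"outer_medulla"` or `"inner_medulla"`.
#' @return transformed values.
#' @export
transform_speeds <- function(speeds,
                             region = c("cortex", "outer_medulla",
                                        "inner_medulla")) {
  region <- match.arg(region)
  if (region == "cortex") {
    stop_if_not(all(speeds > 0), "cortical speeds must be > 0 for the log transform")
    log(speeds)
  } else {
    stop_if_not(all(speeds >= 0), "medullary speeds must be >= 0 for the sqrt transform")
    sqrt(speeds)
  }
}

#' Mean and SD across subjects of per-bed moving-average series
#'
#' Aligns a list of per-subject series on their common time grid and
#' returns mean and SD at each step; missing values stay missing (no
#' interpolation).
#'
#' @param series_list list of data.frames from [moving_average_series()]
#'   with identical `t` grids.
#' @return data.frame `t`, `mean`, `sd`, `n_subjects`.
#' @export
aggregate_subject_series <- function(series_list) {
  stop_if_not(length(series_list) >= 1, "need at least one series")
  tg <- series_list[[1]]$t
  for (s in series_list) stop_if_not(all(s$t == tg), "series grids differ")
  m <- sapply(series_list, function(s) s$mean)
  if (is.null(dim(m))) m <- matrix(m, ncol = length(series_list))
  data.frame(t = tg,
             mean = rowMeans(m, na.rm = TRUE),
             sd = apply(m, 1, stats::sd, na.rm = TRUE),
             n_subjects = rowSums(!is.na(m)))
}
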