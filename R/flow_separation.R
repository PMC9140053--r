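# Direction-based separation of arterial and venous tracks: a mean arterial
# flow angle per region plus an angular acceptance sector (total span 125
# deg in the cortex, 90 deg in the medulla) classify each track as
# arterial, venous (opposed direction) or excluded.

#' Flow sector for one region
#'
#' @param region `"cortex"`, `"outer_medulla"` or `"inner_medulla"`.
#' @param mean_angle_deg mean arterial flow angle, degrees.
#' @param span_deg TOTAL angular width of the acceptance sector; must be in
#'   (0, 180) so the arterial and venous sectors are disjoint. Tracks
#'   within `span_deg / 2` of the mean angle are arterial; within
#'   `span_deg / 2` of the opposed angle, venous.
#' @return list of class `flow_sector`.
#' @export
flow_sector <- function(region, mean_angle_deg, span_deg) {
  stop_if_not(span_deg > 0 && span_deg < 180,
              "span must be in (0, 180) degrees so sectors are disjoint")
  structure(list(region = region,
                 mean_angle_deg = mean_angle_deg %% 360,
                 span_deg = span_deg),
            class = "flow_sector")
}

# Per-step displacements of a set of tracks: midpoints, angles, lengths.
track_steps <- function(tracks) {
  if (nrow(tracks) < 2)
    return(data.frame(track_id = integer(), x = numeric(), y = numeric(),
                      angle = numeric(), len = numeric()))
  same <- tracks$track_id[-1] == tracks$track_id[-nrow(tracks)]
  dx <- diff(tracks$x_mm)[same]
  dy <- diff(tracks$y_mm)[same]
  i0 <- which(same)
  data.frame(track_id = tracks$track_id[i0],
             x = (tracks$x_mm[i0] + tracks$x_mm[i0 + 1]) / 2,
             y = (tracks$y_mm[i0] + tracks$y_mm[i0 + 1]) / 2,
             angle = step_angle_deg(dx, dy),
             len = sqrt(dx^2 + dy^2))
}

#' Mean arterial flow angle of tracks in a region of interest
#'
#' Length-weighted circular mean of the per-step displacement directions of
#' all track steps whose midpoint falls in the ROI.
#'
#' @param tracks an `mb_tracks` data.frame.
#' @param roi optional logical matrix on the acquisition grid (with
#'   `pixel_pitch` attribute or given via `pixel_pitch`); `NULL` uses all
#'   steps.
#' @param pixel_pitch mm per pixel of `roi`.
#' @return mean angle in degrees, `[0, 360)`.
#' @export
mean_arterial_angle <- function(tracks, roi = NULL, pixel_pitch = NULL) {
  st <- track_steps(tracks)
  if (!is.null(roi)) {
    p <- pixel_pitch %||% attr(roi, "pixel_pitch")
    stop_if_not(!is.null(p), "pixel_pitch required with a roi mask")
    r <- floor(st$y / p) + 1L
    c_ <- floor(st$x / p) + 1L
    ok <- r >= 1L & r <= nrow(roi) & c_ >= 1L & c_ <= ncol(roi)
    ok[ok] <- roi[cbind(r[ok], c_[ok])]
    st <- st[ok, ]
  }
  stop_if_not(nrow(st) > 0, "no track steps in the region of interest")
  circ_mean_deg(st$angle, st$len)
}

#' Classify one track as arterial, venous or excluded
#'
#' The track direction is the length-weighted circular mean of its steps
#' (optionally restricted to steps inside a region mask). Arterial if the
#' angular distance to the sector's mean angle is `<= span/2`; venous if
#' within `span/2` of the opposed direction (mean + 180 deg); excluded
#' otherwise.
#'
#' @param track data.frame of one track's positions (`x_mm`, `y_mm`,
#'   `track_id`).
#' @param sector a [flow_sector()].
#' @param region_mask optional logical matrix restricting which steps count.
#' @param pixel_pitch mm per pixel for `region_mask`.
#' @return `"arterial"`, `"venous"` or `"excluded"`.
#' @export
classify_track <- function(track, sector, region_mask = NULL,
                           pixel_pitch = NULL) {
  st <- track_steps(track)
  if (!is.null(region_mask)) {
    p <- pixel_pitch %||% attr(region_mask, "pixel_pitch")
    r <- floor(st$y / p) + 1L
    c_ <- floor(st$x / p) + 1L
    ok <- r >= 1L & r <= nrow(region_mask) & c_ >= 1L & c_ <= ncol(region_mask)
    ok[ok] <- region_mask[cbind(r[ok], c_[ok])]
    st <- st[ok, ]
  }
  if (nrow(st) == 0 || sum(st$len) == 0) return("excluded")
  dir <- circ_mean_deg(st$angle, st$len)
  if (is.na(dir)) return("excluded")
  half <- sector$span_deg / 2
  if (ang_dist_deg(dir, sector$mean_angle_deg) <= half) return("arterial")
  if (ang_dist_deg(dir, sector$mean_angle_deg + 180) <= half) return("venous")
  "excluded"
}

#' Split tracks into the six renal vascular beds
#'
#' Each track is assigned to the region containing the majority of its
#' positions, then classified as arterial or venous from the region's flow
#' sector. Arterial maps to cortex_art / om_dvr / im_dvr, venous to
#' cortex_ven / om_avr / im_avr. Tracks in the background or outside every
#' sector are excluded and reported with counts.
#'
#' @param tracks an `mb_tracks` data.frame.
#' @param labels a [region_label_map()].
#' @param sectors named list of [flow_sector()]s, one per region present.
#' @return list with `beds` (named list of track data.frames),
#'   `excluded` (track data.frame), `counts` (named integer vector) and
#'   `assignments` (data.frame `track_id`, `region`, `class`, `bed`).
#' @export
split_beds <- function(tracks, labels, sectors) {
  bed_of <- c(cortex.arterial = "cortex_art", cortex.venous = "cortex_ven",
              outer_medulla.arterial = "om_dvr", outer_medulla.venous = "om_avr",
              inner_medulla.arterial = "im_dvr", inner_medulla.venous = "im_avr")
  empty <- tracks[0, ]
  beds <- stats::setNames(rep(list(empty), 6), renal_beds())
  if (nrow(tracks) == 0) {
    return(list(beds = beds, excluded = empty,
                counts = stats::setNames(integer(8), c(renal_beds(), "excluded", "total")),
                assignments = data.frame(track_id = integer(),
                                         region = character(),
                                         class = character(),
                                         bed = character())))
  }
  reg <- region_at(labels, tracks$x_mm, tracks$y_mm)
  ids <- unique(tracks$track_id)
  # majority region per track
  maj <- vapply(split(reg, factor(tracks$track_id, levels = ids)), function(rr) {
    tb <- sort(table(rr), decreasing = TRUE)
    names(tb)[1]
  }, character(1))

  region_masks <- lapply(stats::setNames(nm = names(sectors)), function(rn)
    labels$labels == region_levels()[[rn]])

  cls <- character(length(ids))
  by_track <- split(tracks, factor(tracks$track_id, levels = ids))
  for (i in seq_along(ids)) {
    rn <- maj[i]
    if (rn == "background" || is.null(sectors[[rn]])) {
      cls[i] <- "excluded"
      next
    }
    stop_if_not(!is.null(sectors[[rn]]),
                paste0("no flow sector for region ", rn))
    cls[i] <- classify_track(by_track[[i]], sectors[[rn]],
                             region_mask = region_masks[[rn]],
                             pixel_pitch = labels$pixel_pitch)
  }
  bed <- ifelse(cls == "excluded", "excluded",
                bed_of[paste(maj, cls, sep = ".")])
  assignments <- data.frame(track_id = ids, region = unname(maj),
                            class = cls, bed = unname(bed))
  for (b in renal_beds()) {
    sel <- ids[bed == b]
    beds[[b]] <- tracks[tracks$track_id %in% sel, ]
  }
  excl <- tracks[tracks$track_id %in% ids[bed == "excluded"], ]
  counts <- c(vapply(beds, function(d) length(unique(d$track_id)), integer(1)),
              excluded = length(unique(excl$track_id)),
              total = length(ids))
  list(beds = beds, excluded = excl, counts = counts,
       assignments = assignments)
}
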