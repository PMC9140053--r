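# Synthetic renal vascular phantom: a wedge-shaped fan of straight vessels
# in three concentric regions (cortex, outer medulla, inner medulla) of a
# coronal cross-section. Arterial-side beds (cortical arteries/arterioles,
# descending vasa recta) and venous-side beds (cortical veins/venules,
# ascending vasa recta) run in opposed directions along the same fan.

#' Names of the six renal vascular beds
#' @export
renal_beds <- function() {
  c("cortex_art", "cortex_ven", "om_dvr", "om_avr", "im_dvr", "im_avr")
}

bed_region <- function(bed) {
  c(cortex_art = "cortex", cortex_ven = "cortex",
    om_dvr = "outer_medulla", om_avr = "outer_medulla",
    im_dvr = "inner_medulla", im_avr = "inner_medulla")[bed]
}

bed_is_arterial <- function(bed) bed %in% c("cortex_art", "om_dvr", "im_dvr")

region_levels <- function() {
  c(background = 0L, cortex = 1L, outer_medulla = 2L, inner_medulla = 3L)
}

#' Configuration for the renal phantom
#'
#' Defaults describe a desk-scale coronal cross-section: a 128 x 128 grid at
#' 0.05 mm pitch (6.4 x 6.4 mm field) with the kidney "center" (papilla tip)
#' near the bottom of the field and vessels fanning upward. Region radii
#' delimit the inner medulla, outer medulla and cortex as nested bands.
#' Default bed speeds are mean speeds for scan 1 (baseline): 1.59 mm/s in the
#' cortical arteries/arterioles and 0.70 mm/s in the outer-medulla descending
#' vasa recta, with slower venous/ascending and inner-medulla beds.
#'
#' @param n_row,n_col grid size in pixels.
#' @param pixel_pitch mm per pixel.
#' @param center_mm kidney center (x = lateral, y = axial depth) in mm;
#'   default places it at mid-width, 4.4 mm depth.
#' @param radii_mm named vector with outer radii (mm) of `inner_medulla`,
#'   `outer_medulla`, `cortex`; must be strictly increasing.
#' @param axis_deg direction of the wedge axis (90 = toward the transducer).
#' @param wedge_deg named vector: total angular extent of the vessel fan in
#'   the cortex and in the medulla (degrees).
#' @param n_vessels named integer vector: vessels per bed.
#' @param bed_speeds named vector: baseline mean speed (mm/s) per bed, each
#'   in \[0, 15\].
#' @param vessel_radius_mm vessel half-width used for ground-truth checks.
#' @param sector_span_deg total angular acceptance (degrees) of the arterial
#'   flow sector per region (cortex 125, medulla 90).
#' @return a list of class `phantom_config`.
#' @export
phantom_config <- function(n_row = 128L, n_col = 128L, pixel_pitch = 0.05,
                           center_mm = NULL,
                           radii_mm = c(inner_medulla = 1.2, outer_medulla = 2.2, cortex = 3.1),
                           axis_deg = 90,
                           wedge_deg = c(cortex = 110, medulla = 80),
                           n_vessels = c(cortex_art = 6L, cortex_ven = 6L,
                                         om_dvr = 3L, om_avr = 3L,
                                         im_dvr = 3L, im_avr = 3L),
                           bed_speeds = c(cortex_art = 1.59, cortex_ven = 0.85,
                                          om_dvr = 0.70, om_avr = 0.55,
                                          im_dvr = 0.60, im_avr = 0.50),
                           vessel_radius_mm = 0.05,
                           sector_span_deg = c(cortex = 125, outer_medulla = 90,
                                               inner_medulla = 90)) {
  if (is.null(center_mm)) {
    center_mm <- c(x = n_col * pixel_pitch / 2, y = 4.4 / 6.4 * n_row * pixel_pitch)
  }
  cfg <- list(n_row = as.integer(n_row), n_col = as.integer(n_col),
              pixel_pitch = pixel_pitch, center_mm = center_mm,
              radii_mm = radii_mm, axis_deg = axis_deg, wedge_deg = wedge_deg,
              n_vessels = n_vessels, bed_speeds = bed_speeds,
              vessel_radius_mm = vessel_radius_mm,
              sector_span_deg = sector_span_deg)
  class(cfg) <- "phantom_config"
  cfg
}

# Point on the kidney polar grid: angle theta (deg, math convention with the
# depth axis pointing down) and radius r (mm) -> image coordinates (x, y) mm.
polar_point <- function(center, r, theta_deg) {
  th <- theta_deg * pi / 180
  c(x = unname(center[1]) + r * cos(th), y = unname(center[2]) - r * sin(th))
}

#' Build the renal phantom: vessels, region label map and flow sectors
#'
#' Vessels are straight radial segments fanning from the kidney center.
#' Arterial-side flow points outward in the cortex (toward the renal surface)
#' and inward in the medulla (descending vasa recta, toward the papilla);
#' the paired venous-side bed runs opposed (180 deg) in interleaved vessels.
#'
#' @param config a [phantom_config()].
#' @return an object of class `renal_phantom`: list with `vessels` (list of
#'   `PhantomVessel`-style lists), `labels` (a [region_label_map()]),
#'   `sectors` (ground-truth [flow_sector()] per region) and `config`.
#' @export
build_renal_phantom <- function(config = phantom_config()) {
  cfg <- config
  r <- cfg$radii_mm
  stop_if_not(all(c("inner_medulla", "outer_medulla", "cortex") %in% names(r)),
              "radii_mm must name inner_medulla, outer_medulla, cortex")
  stop_if_not(r[["inner_medulla"]] < r[["outer_medulla"]] &&
              r[["outer_medulla"]] < r[["cortex"]],
              "invalid geometry: region radii must be strictly increasing (nested regions)")
  stop_if_not(all(cfg$bed_speeds >= 0 & cfg$bed_speeds <= 15),
              "bed speeds must lie in [0, 15] mm/s")

  margin <- 0.1
  spans <- list(
    cortex        = c(r[["outer_medulla"]] + margin, r[["cortex"]] - margin),
    outer_medulla = c(r[["inner_medulla"]] + margin, r[["outer_medulla"]] - margin),
    inner_medulla = c(0.35, r[["inner_medulla"]] - margin))

  vessels <- list()
  vid <- 0L
  add_vessel <- function(bed, region, ends) {
    d <- ends[2, ] - ends[1, ]
    len <- sqrt(sum(d^2))
    vid <<- vid + 1L
    vessels[[vid]] <<- list(
      id = vid, bed = bed, region = region,
      centerline = unname(ends), length_mm = len,
      radius = cfg$vessel_radius_mm,
      base_speed = unname(cfg$bed_speeds[[bed]]),
      flow_direction = unname(d / len),
      angle_deg = step_angle_deg(d[1], d[2]))
  }
  for (bed in renal_beds()) {
    n <- as.integer(cfg$n_vessels[[bed]] %||% 0L)
    if (n <= 0L) next
    region <- unname(bed_region(bed))
    if (region == "inner_medulla") {
      # vasa recta bundles of the inner medulla: near-parallel chords along
      # the wedge axis, descending (arterial-side) flow toward the papilla
      r_im <- cfg$radii_mm[["inner_medulla"]]
      hr <- r_im - 0.5
      offs <- if (n == 1) 0 else seq(-hr, hr, length.out = n)
      if (!bed_is_arterial(bed)) offs <- offs + (if (n > 1) hr / (n - 1) else 0.1)
      th <- cfg$axis_deg * pi / 180
      e_ax <- c(cos(th), -sin(th))            # unit vector along the axis
      e_pp <- c(-e_ax[2], e_ax[1])            # perpendicular
      for (o in offs) {
        reach <- sqrt(max(0.04, (r_im - 0.1)^2 - o^2))
        p_near <- cfg$center_mm + o * e_pp + 0.15 * e_ax
        p_far <- cfg$center_mm + o * e_pp + reach * e_ax
        ends <- if (bed_is_arterial(bed)) rbind(p_far, p_near) else
          rbind(p_near, p_far)
        add_vessel(bed, region, ends)
      }
      next
    }
    hw <- if (region == "cortex") cfg$wedge_deg[["cortex"]] / 2 else cfg$wedge_deg[["medulla"]] / 2
    # arterial beds on one comb of angles; venous interleaved half a step
    # off, alternating sides so the venous mean direction mirrors the
    # arterial mean exactly
    step <- 2 * hw / n
    offset <- if (bed_is_arterial(bed)) 0 else
      step / 2 * (-1)^(seq_len(n) - 1)
    thetas <- cfg$axis_deg - hw + step * (seq_len(n) - 0.5) + offset
    rr <- spans[[region]]
    outward <- if (region == "cortex") bed_is_arterial(bed) else !bed_is_arterial(bed)
    for (th in thetas) {
      p_in <- polar_point(cfg$center_mm, rr[1], th)
      p_out <- polar_point(cfg$center_mm, rr[2], th)
      ends <- if (outward) rbind(p_in, p_out) else rbind(p_out, p_in)
      add_vessel(bed, region, ends)
    }
  }

  labels <- region_label_map_from_radii(cfg)
  sectors <- ground_truth_sectors(cfg)
  structure(list(vessels = vessels, labels = labels, sectors = sectors,
                 config = cfg),
            class = "renal_phantom")
}

# Nested-annulus region labels on the acquisition grid.
region_label_map_from_radii <- function(cfg) {
  xs <- (seq_len(cfg$n_col) - 0.5) * cfg$pixel_pitch
  ys <- (seq_len(cfg$n_row) - 0.5) * cfg$pixel_pitch
  dx <- outer(rep(1, cfg$n_row), xs) - cfg$center_mm[[1]]
  dy <- outer(ys, rep(1, cfg$n_col)) - cfg$center_mm[[2]]
  rr <- sqrt(dx^2 + dy^2)
  lab <- matrix(0L, cfg$n_row, cfg$n_col)
  lab[rr <= cfg$radii_mm[["cortex"]]] <- 1L
  lab[rr <= cfg$radii_mm[["outer_medulla"]]] <- 2L
  lab[rr <= cfg$radii_mm[["inner_medulla"]]] <- 3L
  region_label_map(lab, cfg$pixel_pitch)
}

ground_truth_sectors <- function(cfg) {
  art_angle <- function(region) {
    if (region == "cortex") cfg$axis_deg %% 360 else (cfg$axis_deg + 180) %% 360
  }
  sectors <- lapply(c("cortex", "outer_medulla", "inner_medulla"), function(reg)
    flow_sector(reg, art_angle(reg), cfg$sector_span_deg[[reg]]))
  names(sectors) <- c("cortex", "outer_medulla", "inner_medulla")
  sectors
}

#' Region label map
#'
#' @param labels integer matrix with values 0 (background), 1 (cortex),
#'   2 (outer medulla), 3 (inner medulla).
#' @param pixel_pitch mm per pixel.
#' @return object of class `region_label_map`.
#' @export
region_label_map <- function(labels, pixel_pitch) {
  stop_if_not(is.matrix(labels), "labels must be a matrix")
  stop_if_not(all(labels %in% region_levels()),
              "labels must be coded 0..3 (background, cortex, OM, IM)")
  structure(list(labels = labels, pixel_pitch = pixel_pitch,
                 levels = region_levels()),
            class = "region_label_map")
}

#' Look up region names at positions
#'
#' @param map a [region_label_map()].
#' @param x,y positions in mm.
#' @return character vector of region names (`"background"` outside).
#' @export
region_at <- function(map, x, y) {
  p <- map$pixel_pitch
  r <- floor(y / p) + 1L
  c_ <- floor(x / p) + 1L
  ok <- r >= 1L & r <= nrow(map$labels) & c_ >= 1L & c_ <= ncol(map$labels)
  lab <- rep(0L, length(x))
  lab[ok] <- map$labels[cbind(r[ok], c_[ok])]
  names(region_levels())[match(lab, region_levels())]
}

#' @export
print.renal_phantom <- function(x, ...) {
  beds <- vapply(x$vessels, function(v) v$bed, character(1))
  cat("renal_phantom:", length(x$vessels), "vessels\n")
  if (length(beds)) print(table(beds))
  cat(sprintf("grid %d x %d px at %.3g mm\n",
              x$config$n_row, x$config$n_col, x$config$pixel_pitch))
  invisible(x)
}
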