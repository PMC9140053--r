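# Non-rigid motion estimation from B-mode frames: normalized
# cross-correlation (NCC) in overlapping patches (3 x 3 mm, 80% overlap by
# default), sub-pixel parabolic peak refinement, bilinear interpolation of
# the patch vectors to a dense field, and removal of the estimated motion
# from microbubble localizations.

# Summed-area table with a zero-padded first row/column, so the sum over the
# h x w window with top-left (r, c) (1-based) is
# S[r+h, c+w] - S[r, c+w] - S[r+h, c] + S[r, c].
# Double cumulative sums are done as triangular matrix products (BLAS),
# with the triangular factors cached per dimension.
.tri_cache <- new.env(parent = emptyenv())

tri_ones <- function(n, lower) {
  key <- sprintf("%d_%d", n, lower)
  m <- .tri_cache[[key]]
  if (is.null(m)) {
    m <- matrix(0, n, n)
    m[if (lower) lower.tri(m, diag = TRUE) else upper.tri(m, diag = TRUE)] <- 1
    .tri_cache[[key]] <- m
  }
  m
}

sat <- function(M) {
  S <- matrix(0, nrow(M) + 1L, ncol(M) + 1L)
  S[-1L, -1L] <- tri_ones(nrow(M), TRUE) %*% M %*% tri_ones(ncol(M), FALSE)
  S
}

wsum <- function(S, r, c, h, w) {
  S[cbind(r + h, c + w)] - S[cbind(r, c + w)] - S[cbind(r + h, c)] +
    S[cbind(r, c)]
}

#' Estimate a non-rigid displacement field between two B-mode frames
#'
#' Per patch, the displacement maximizing the normalized cross-correlation
#' over integer shifts within `search_px`, refined to sub-pixel precision by
#' a 1-D parabolic fit per axis. Patch stride is
#' `patch_mm * (1 - overlap)` (0.6 mm with the defaults). Flat
#' (zero-variance) patches get zero displacement and a low-confidence flag.
#'
#' @param ref_bmode,cur_bmode numeric matrices of the same size.
#' @param pixel_pitch mm per pixel.
#' @param patch_mm patch side length in mm (default 3).
#' @param overlap patch overlap fraction (default 0.8).
#' @param search_px integer search radius in pixels around `center_px`.
#' @param center_px integer shift (row, col) at the center of the search
#'   window; a warm start from a neighboring frame keeps the search small.
#' @param margin_px patches keep this margin from the frame border so every
#'   patch can shift by up to `margin_px` pixels; fixed independently of
#'   the search so the patch grid is stable across frames.
#' @return object of class `displacement_field`: patch-center coordinates
#'   `px`, `py` (mm), displacement matrices `dx`, `dy` (mm, rows = py,
#'   cols = px), logical `confidence`, attribute `at_boundary` (TRUE when a
#'   best shift sits on the search-window edge), and the patch geometry.
#' @export
estimate_patch_motion <- function(ref_bmode, cur_bmode, pixel_pitch,
                                  patch_mm = 3, overlap = 0.8,
                                  search_px = 6L, center_px = c(0L, 0L),
                                  margin_px = 6L) {
  stop_if_not(all(dim(ref_bmode) == dim(cur_bmode)),
              "frames must have the same shape")
  nr <- nrow(ref_bmode); nc <- ncol(ref_bmode)
  patch <- round(patch_mm / pixel_pitch)
  stop_if_not(patch < nr && patch < nc, "patch must be smaller than the frame")
  stride <- max(1L, round(patch * (1 - overlap)))
  m <- min(margin_px, (min(nr, nc) - patch) %/% 2)
  r0 <- unique(c(seq(1L + m, nr - patch + 1L - m, by = stride),
                 nr - patch + 1L - m))
  c0 <- unique(c(seq(1L + m, nc - patch + 1L - m, by = stride),
                 nc - patch + 1L - m))
  np_r <- length(r0); np_c <- length(c0)
  rr <- rep(r0, times = np_c); cc <- rep(c0, each = np_r)  # column-major patches
  npatch <- length(rr)
  npx <- patch * patch

  Sr <- sat(ref_bmode); Sr2 <- sat(ref_bmode^2)
  Sc <- sat(cur_bmode); Sc2 <- sat(cur_bmode^2)
  sum_r <- wsum(Sr, rr, cc, patch, patch)
  sum_r2 <- wsum(Sr2, rr, cc, patch, patch)
  var_r <- sum_r2 - sum_r^2 / npx

  shifts <- as.matrix(expand.grid(
    dr = (center_px[1] - search_px):(center_px[1] + search_px),
    dc = (center_px[2] - search_px):(center_px[2] + search_px)))
  ncc <- matrix(NA_real_, npatch, nrow(shifts))
  curs <- matrix(0, nr, nc)
  for (s in seq_len(nrow(shifts))) {
    dr <- shifts[s, 1]; dc <- shifts[s, 2]
    ri <- max(1L, 1L - dr):min(nr, nr - dr)   # rows where cur[i+dr] valid
    ci <- max(1L, 1L - dc):min(nc, nc - dc)
    curs[] <- 0
    curs[ri, ci] <- cur_bmode[ri + dr, ci + dc]
    Sp <- sat(ref_bmode * curs)
    valid <- rr + dr >= 1L & rr + patch - 1L + dr <= nr &
             cc + dc >= 1L & cc + patch - 1L + dc <= nc
    if (!any(valid)) next
    rv <- rr[valid]; cv <- cc[valid]
    cross <- wsum(Sp, rv, cv, patch, patch)
    sum_c <- wsum(Sc, rv + dr, cv + dc, patch, patch)
    sum_c2 <- wsum(Sc2, rv + dr, cv + dc, patch, patch)
    var_c <- sum_c2 - sum_c^2 / npx
    den <- sqrt(pmax(var_r[valid], 0) * pmax(var_c, 0))
    num <- cross - sum_r[valid] * sum_c / npx
    v <- ifelse(den > 1e-9, num / den, NA_real_)
    ncc[valid, s] <- v
  }

  dr_rng <- range(shifts[, 1]); dc_rng <- range(shifts[, 2])
  dx <- dy <- numeric(npatch)
  conf <- rep(TRUE, npatch)
  at_boundary <- FALSE
  flat <- var_r < 1e-9 * npx
  for (i in seq_len(npatch)) {
    row <- ncc[i, ]
    if (flat[i] || all(is.na(row))) { conf[i] <- FALSE; next }
    b <- which.max(row)
    bdr <- shifts[b, 1]; bdc <- shifts[b, 2]
    if (bdr %in% dr_rng || bdc %in% dc_rng) at_boundary <- TRUE
    if (row[b] >= 1 - 1e-12) {
      # perfect correlation: exact integer alignment, skip refinement
      dy[i] <- bdr * pixel_pitch
      dx[i] <- bdc * pixel_pitch
      next
    }
    # parabolic sub-pixel refinement per axis where neighbors exist
    sub <- function(fm, f0, fp) {
      den <- fm - 2 * f0 + fp
      if (!is.finite(den) || abs(den) < 1e-12) return(0)
      max(-0.5, min(0.5, 0.5 * (fm - fp) / den))
    }
    ddr <- ddc <- 0
    im <- match_shift(shifts, bdr - 1L, bdc); ip <- match_shift(shifts, bdr + 1L, bdc)
    if (!is.na(im) && !is.na(ip) && is.finite(row[im]) && is.finite(row[ip]))
      ddr <- sub(row[im], row[b], row[ip])
    jm <- match_shift(shifts, bdr, bdc - 1L); jp <- match_shift(shifts, bdr, bdc + 1L)
    if (!is.na(jm) && !is.na(jp) && is.finite(row[jm]) && is.finite(row[jp]))
      ddc <- sub(row[jm], row[b], row[jp])
    dy[i] <- (bdr + ddr) * pixel_pitch
    dx[i] <- (bdc + ddc) * pixel_pitch
  }
  dx[!conf] <- 0; dy[!conf] <- 0

  out <- structure(list(
    px = (c0 - 1 + patch / 2) * pixel_pitch,
    py = (r0 - 1 + patch / 2) * pixel_pitch,
    dx = matrix(dx, np_r, np_c), dy = matrix(dy, np_r, np_c),
    confidence = matrix(conf, np_r, np_c),
    pixel_pitch = pixel_pitch, patch_mm = patch_mm, overlap = overlap,
    stride_mm = stride * pixel_pitch),
    class = "displacement_field")
  attr(out, "at_boundary") <- at_boundary
  out
}

match_shift <- function(shifts, dr, dc) {
  i <- which(shifts[, 1] == dr & shifts[, 2] == dc)
  if (length(i)) i[1] else NA_integer_
}

#' Interpolate a displacement field at arbitrary positions
#'
#' Bilinear interpolation of the patch vectors; positions outside the patch
#' grid are clamped to the nearest border value.
#'
#' @param field a `displacement_field`.
#' @param x,y positions in mm.
#' @return list with vectors `dx`, `dy` (mm).
#' @export
field_at <- function(field, x, y) {
  list(dx = bilinear_at(field$dx, field$px, field$py, x, y),
       dy = bilinear_at(field$dy, field$px, field$py, x, y))
}

#' Estimate displacement fields for a whole B-mode stack
#'
#' The first frame gets a full search of radius `search_px`; subsequent
#' frames reuse the previous frame's median integer shift as a warm start
#' and search only `track_search_px` around it (tissue motion between
#' consecutive frames is well below a pixel at respiratory rates). A best
#' shift on the search-window edge triggers a full re-search for that
#' frame.
#'
#' @param bmode a B-mode [frame_stack()].
#' @param ref_frame index of the reference frame (default 1, the first
#'   frame of the scan).
#' @param search_px full search radius in pixels.
#' @param track_search_px warm-started search radius.
#' @param ... passed to [estimate_patch_motion()].
#' @return object of class `motion_field_seq`: list of fields and their
#'   timestamps.
#' @export
estimate_motion_fields <- function(bmode, ref_frame = 1L, search_px = 6L,
                                   track_search_px = 2L, ...) {
  ref <- bmode$frames[, , ref_frame]
  nf <- n_frames(bmode)
  fields <- vector("list", nf)
  center <- c(0L, 0L)
  for (f in seq_len(nf)) {
    sp <- if (f == 1L) search_px else track_search_px
    fld <- estimate_patch_motion(ref, bmode$frames[, , f], bmode$pixel_pitch,
                                 search_px = sp, center_px = center,
                                 margin_px = search_px, ...)
    if (f > 1L && isTRUE(attr(fld, "at_boundary"))) {
      fld <- estimate_patch_motion(ref, bmode$frames[, , f],
                                   bmode$pixel_pitch,
                                   search_px = search_px,
                                   center_px = c(0L, 0L),
                                   margin_px = search_px, ...)
    }
    center <- c(as.integer(round(stats::median(fld$dy) / bmode$pixel_pitch)),
                as.integer(round(stats::median(fld$dx) / bmode$pixel_pitch)))
    fields[[f]] <- fld
    fields[[f]]$t <- bmode$timestamps[f]
  }
  structure(list(fields = fields, times = bmode$timestamps),
            class = "motion_field_seq")
}

#' Remove estimated tissue motion from localizations
#'
#' Each localization is corrected with the nearest-in-time displacement
#' field: corrected position = observed position - interpolated
#' displacement. Positions outside the field domain use the clamped border
#' value.
#'
#' @param locs localization data.frame (columns `t`, `x_mm`, `y_mm`).
#' @param fields a `motion_field_seq` or a single `displacement_field`
#'   (applied to all localizations).
#' @return `locs` with corrected `x_mm`, `y_mm` (raw positions kept as
#'   `x_raw_mm`, `y_raw_mm`).
#' @export
compensate_localizations <- function(locs, fields) {
  if (nrow(locs) == 0) return(locs)
  locs$x_raw_mm <- locs$x_mm
  locs$y_raw_mm <- locs$y_mm
  if (inherits(fields, "displacement_field")) {
    d <- field_at(fields, locs$x_mm, locs$y_mm)
    locs$x_mm <- locs$x_mm - d$dx
    locs$y_mm <- locs$y_mm - d$dy
    return(locs)
  }
  stop_if_not(inherits(fields, "motion_field_seq"),
              "fields must be a motion_field_seq or displacement_field")
  ft <- fields$times
  mids <- (ft[-1] + ft[-length(ft)]) / 2
  nearest <- findInterval(locs$t, mids) + 1L
  for (j in unique(nearest)) {
    sel <- nearest == j
    d <- field_at(fields$fields[[j]], locs$x_mm[sel], locs$y_mm[sel])
    locs$x_mm[sel] <- locs$x_mm[sel] - d$dx
    locs$y_mm[sel] <- locs$y_mm[sel] - d$dy
  }
  locs
}
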