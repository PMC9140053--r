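# Shared fixtures and independent oracles. Oracles are deliberately naive
# (enumeration, flood fill, direct formulas) and never call the package
# code paths they check.

# Small phantom for quick end-to-end scenes: 64 x 64 px at 0.05 mm.
tiny_phantom <- function(...) {
  build_renal_phantom(phantom_config(
    n_row = 64L, n_col = 64L, pixel_pitch = 0.05,
    center_mm = c(x = 1.6, y = 2.2),
    radii_mm = c(inner_medulla = 0.6, outer_medulla = 1.1, cortex = 1.55),
    n_vessels = c(cortex_art = 4L, cortex_ven = 4L, om_dvr = 3L,
                  om_avr = 3L, im_dvr = 2L, im_avr = 2L),
    ...))
}

# Render a set of hand-specified positions (one data.frame row per frame
# presence) into a contrast stack.
render_positions <- function(df, n_row = 64, n_col = 64, pitch = 0.05,
                             n_frames = max(df$frame), noise_sd = 0,
                             psf_sigma = 0.075, seed = 1, ...) {
  render_frames(df, n_row, n_col, pitch, n_frames = n_frames,
                noise_sd = noise_sd, psf_sigma = psf_sigma,
                mb_amp_cv = 0, bmode = FALSE, seed = seed, ...)$contrast
}

# Straight-line trajectory data.frame at constant velocity.
line_trajectory <- function(id = 1L, x0, y0, vx, vy, n, frame_rate = 54,
                            frame0 = 1L) {
  k <- seq_len(n) - 1
  data.frame(trajectory_id = id, vessel_id = id, bed = "cortex_art",
             frame = frame0 + k, t = (frame0 + k - 1) / frame_rate,
             x_mm = x0 + vx * k / frame_rate,
             y_mm = y0 + vy * k / frame_rate,
             speed_mm_s = sqrt(vx^2 + vy^2))
}

# --- oracles ---------------------------------------------------------------

# Flood-fill (4-connectivity) component count on a logical mask.
oracle_component_count <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (!mask[r, c] || lab[r, c] > 0L) next
    cur <- cur + 1L
    stack <- list(c(r, c))
    lab[r, c] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- p[1] + d[1]; cc <- p[2] + d[2]
        if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask) &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  cur
}

# Brute-force minimum-cost assignment by enumeration (maximum cardinality
# among allowed pairs, minimum total cost among those).
oracle_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  best <- NULL; best_card <- -1L; best_cost <- Inf
  cols <- c(seq_len(m), rep(NA_integer_, max(0, n - m)))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  for (p in perms(cols)) {
    a <- p[seq_len(n)]
    tot <- 0; card <- 0L; ok <- TRUE
    for (i in seq_len(n)) {
      if (is.na(a[i])) next
      if (!is.finite(cost[i, a[i]])) { a[i] <- NA_integer_; next }
      tot <- tot + cost[i, a[i]]; card <- card + 1L
    }
    if (card > best_card || (card == best_card && tot < best_cost)) {
      best <- a; best_card <- card; best_cost <- tot
    }
  }
  list(assignment = best, cost = best_cost, cardinality = best_card)
}

# Greenhouse-Geisser epsilon straight from the covariance-entry sums.
oracle_gg_epsilon <- function(Y) {
  S <- stats::cov(Y)
  k <- ncol(Y)
  sbar <- mean(S)
  sdiag <- mean(diag(S))
  srow <- rowMeans(S)
  num <- (k * (sdiag - sbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(srow^2) + k^2 * sbar^2)
  num / den
}

# Within-subject F from explicit sums.
oracle_rm_F <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  gm <- mean(Y)
  ss_cond <- n * sum((colMeans(Y) - gm)^2)
  ss_sub <- k * sum((rowMeans(Y) - gm)^2)
  ss_tot <- sum((Y - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_sub
  (ss_cond / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
}

# Paired t from the textbook formula.
oracle_paired_t <- function(x, y) {
  d <- x - y; n <- length(d)
  mean(d) / (stats::sd(d) / sqrt(n))
}

# Pearson r^2 as the covariance ratio.
oracle_r2 <- function(x, y) {
  (sum((x - mean(x)) * (y - mean(y))))^2 /
    (sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
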