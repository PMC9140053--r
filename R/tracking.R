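# Hierarchical Kalman multi-target tracking of microbubble localizations.
# Constant-velocity Kalman filtering per track, tiered gated association
# (confirmed before tentative; within a tier, slow tracks before fast),
# M-of-N track lifecycle, Rauch-Tung-Striebel smoothing of finished tracks,
# and a 0-15 mm/s per-step speed span.

#' Tracker parameters
#'
#' @param process_sd white-acceleration process noise sd (mm/s^2).
#' @param meas_sd measurement noise sd (mm); default half the pixel pitch
#'   of the 0.05 mm default grid.
#' @param max_speed tracking velocity span ceiling (mm/s, default 15).
#' @param confirm_hits hits needed to confirm a tentative track (M, >= 2).
#' @param max_miss consecutive missed frames that terminate a track (N).
#' @param min_track_length minimum observed positions for a track to be
#'   kept.
#' @param slow_tier_max speed (mm/s) separating the slow association tier
#'   from the fast tier.
#' @param init_speed_sd prior sd on the unknown initial velocity (mm/s);
#'   large values let the data dominate.
#' @return list of class `tracker_params`.
#' @export
tracker_params <- function(process_sd = 2, meas_sd = 0.025, max_speed = 15,
                           confirm_hits = 3L, max_miss = 2L,
                           min_track_length = 5L, slow_tier_max = 5,
                           init_speed_sd = 50) {
  stop_if_not(max_speed > 0, "max_speed must be > 0")
  stop_if_not(confirm_hits >= 2L, "confirm_hits must be >= 2")
  stop_if_not(max_miss >= 0L, "max_miss must be >= 0")
  structure(list(process_sd = process_sd, meas_sd = meas_sd,
                 max_speed = max_speed, confirm_hits = as.integer(confirm_hits),
                 max_miss = as.integer(max_miss),
                 min_track_length = as.integer(min_track_length),
                 slow_tier_max = slow_tier_max,
                 init_speed_sd = init_speed_sd),
            class = "tracker_params")
}

kf_F <- function(dt) matrix(c(1, 0, 0, 0,
                              0, 1, 0, 0,
                              dt, 0, 1, 0,
                              0, dt, 0, 1), 4, 4)

kf_Q <- function(dt, q) {
  # white-noise acceleration, independent per axis
  q2 <- q^2
  a <- dt^4 / 4 * q2; b <- dt^3 / 2 * q2; c <- dt^2 * q2
  matrix(c(a, 0, b, 0,
           0, a, 0, b,
           b, 0, c, 0,
           0, b, 0, c), 4, 4)
}

#' One Kalman predict/update step with a constant-velocity model
#'
#' State is `(x, y, vx, vy)`. Predicts with constant-velocity dynamics,
#' then updates with the measurement if one is given; with no measurement
#' the prediction is returned unchanged (position advances by
#' `velocity * dt` exactly).
#'
#' @param state numeric length-4 state vector.
#' @param P 4 x 4 state covariance.
#' @param measurement length-2 position (mm) or `NULL` for a missed frame.
#' @param dt time step, s (> 0).
#' @param params a [tracker_params()].
#' @return list with `state`, `P`, `innovation` (length-2 or `NULL`) and
#'   `S` (innovation covariance or `NULL`).
#' @export
kalman_step <- function(state, P, measurement, dt, params = tracker_params()) {
  stop_if_not(dt > 0, "dt must be > 0")
  F <- kf_F(dt)
  xp <- as.vector(F %*% state)
  Pp <- F %*% P %*% t(F) + kf_Q(dt, params$process_sd)
  if (is.null(measurement)) {
    return(list(state = xp, P = Pp, innovation = NULL, S = NULL))
  }
  stop_if_not(length(measurement) == 2 && all(is.finite(measurement)),
              "measurement must be a finite length-2 position")
  S <- Pp[1:2, 1:2] + diag(params$meas_sd^2 + 1e-12, 2)
  K <- Pp[, 1:2] %*% solve(S)
  innov <- measurement - xp[1:2]
  xn <- xp + as.vector(K %*% innov)
  Pn <- Pp - K %*% Pp[1:2, ]
  list(state = xn, P = Pn, innovation = innov, S = S)
}

#' Gated, tiered association of predicted tracks to localizations
#'
#' Tracks are processed in tiers: confirmed before tentative, and within
#' each status tier slow tracks (estimated speed <= `slow_tier_max`) before
#' fast ones. Candidate pairs are gated by Euclidean distance
#' `<= max_speed * dt + 3 * meas_sd`; within the gate the assignment
#' minimizing total squared innovation distance is found per tier, each
#' localization used at most once.
#'
#' Confirmed tracks additionally tighten their gate to
#' `speed * dt + 4 * sqrt(innovation sd)` (capped by the global gate): once
#' the velocity is known, candidates far beyond the expected displacement
#' are implausible and would stitch neighboring vessels together.
#'
#' @param pred data.frame with predicted track states: columns `x`, `y`,
#'   `speed`, `confirmed` (logical), optionally `gate` (per-track gate
#'   radius in mm; defaults to the global gate).
#' @param locs matrix/data.frame with columns `x`, `y` of localizations.
#' @param params a [tracker_params()].
#' @param dt frame interval, s.
#' @return list with `matches` (data.frame `track`, `loc`),
#'   `unassigned_tracks`, `unassigned_locs` (integer indices).
#' @export
associate <- function(pred, locs, params, dt) {
  nt <- nrow(pred); nl <- nrow(locs)
  matches <- data.frame(track = integer(), loc = integer())
  if (nt == 0 || nl == 0) {
    return(list(matches = matches,
                unassigned_tracks = seq_len(nt %||% 0),
                unassigned_locs = seq_len(nl %||% 0)))
  }
  gate <- params$max_speed * dt + 3 * params$meas_sd
  track_gate <- if ("gate" %in% names(pred)) pmin(pred$gate, gate) else
    rep(gate, nt)
  lx <- locs[, 1]; ly <- locs[, 2]
  free_locs <- rep(TRUE, nl)
  tiers <- list(
    which(pred$confirmed & pred$speed <= params$slow_tier_max),
    which(pred$confirmed & pred$speed > params$slow_tier_max),
    which(!pred$confirmed & pred$speed <= params$slow_tier_max),
    which(!pred$confirmed & pred$speed > params$slow_tier_max))
  for (tier in tiers) {
    if (!length(tier) || !any(free_locs)) next
    fl <- which(free_locs)
    d2 <- outer(pred$x[tier], lx[fl], "-")^2 + outer(pred$y[tier], ly[fl], "-")^2
    cost <- d2
    cost[sqrt(d2) > track_gate[tier]] <- Inf
    if (all(is.infinite(cost))) next
    a <- solve_assignment(cost)
    hit <- which(!is.na(a))
    if (length(hit)) {
      matches <- rbind(matches, data.frame(track = tier[hit], loc = fl[a[hit]]))
      free_locs[fl[a[hit]]] <- FALSE
    }
  }
  list(matches = matches,
       unassigned_tracks = setdiff(seq_len(nt), matches$track),
       unassigned_locs = which(free_locs))
}

# -- internal mutable track record ------------------------------------------

new_track_rec <- function(id, x, y, frame, t, params) {
  e <- new.env(parent = emptyenv())
  e$id <- id
  e$state <- c(x, y, 0, 0)
  e$P <- diag(c(params$meas_sd^2, params$meas_sd^2,
                params$init_speed_sd^2, params$init_speed_sd^2))
  e$hits <- 1L; e$miss <- 0L; e$confirmed <- FALSE
  cap <- 64L
  e$cap <- cap; e$n <- 1L
  e$xf <- matrix(0, 4, cap); e$xp <- matrix(0, 4, cap)
  e$Pf <- array(0, c(4, 4, cap)); e$Pp <- array(0, c(4, 4, cap))
  e$frames <- integer(cap); e$times <- numeric(cap)
  e$obs <- logical(cap); e$mx <- numeric(cap); e$my <- numeric(cap)
  e$xf[, 1] <- e$state; e$xp[, 1] <- e$state
  e$Pf[, , 1] <- e$P; e$Pp[, , 1] <- e$P
  e$frames[1] <- frame; e$times[1] <- t
  e$obs[1] <- TRUE; e$mx[1] <- x; e$my[1] <- y
  e
}

grow_track <- function(e) {
  cap2 <- e$cap * 2L
  e$xf <- cbind(e$xf, matrix(0, 4, e$cap))
  e$xp <- cbind(e$xp, matrix(0, 4, e$cap))
  Pf2 <- array(0, c(4, 4, cap2)); Pf2[, , seq_len(e$cap)] <- e$Pf; e$Pf <- Pf2
  Pp2 <- array(0, c(4, 4, cap2)); Pp2[, , seq_len(e$cap)] <- e$Pp; e$Pp <- Pp2
  length(e$frames) <- cap2; length(e$times) <- cap2
  length(e$obs) <- cap2; length(e$mx) <- cap2; length(e$my) <- cap2
  e$cap <- cap2
}

push_step <- function(e, xp, Pp, xf, Pf, frame, t, obs, mx, my) {
  if (e$n + 1L > e$cap) grow_track(e)
  k <- e$n + 1L
  e$xp[, k] <- xp; e$Pp[, , k] <- Pp
  e$xf[, k] <- xf; e$Pf[, , k] <- Pf
  e$frames[k] <- frame; e$times[k] <- t
  e$obs[k] <- obs; e$mx[k] <- mx; e$my[k] <- my
  e$n <- k
}

# RTS smoothing over the stored steps; returns 4 x n smoothed states.
rts_smooth <- function(e) {
  n <- e$n
  xs <- matrix(0, 4, n)
  xs[, n] <- e$xf[, n]
  Ps <- e$Pf[, , n]
  if (n > 1) {
    for (k in (n - 1):1) {
      Pp1 <- e$Pp[, , k + 1]
      Ck <- tryCatch(
        e$Pf[, , k] %*% t(kf_F(e$times[k + 1] - e$times[k])) %*%
          solve(Pp1 + diag(1e-10 * max(diag(Pp1), 1e-12), 4)),
        error = function(err) matrix(0, 4, 4))  # degenerate: keep filtered
      xs[, k] <- e$xf[, k] + as.vector(Ck %*% (xs[, k + 1] - e$xp[, k + 1]))
      Ps <- e$Pf[, , k] + Ck %*% (Ps - e$Pp[, , k + 1]) %*% t(Ck)
    }
  }
  xs
}

finalize_track <- function(e, params) {
  # trim trailing missed (predicted-only) steps
  n <- e$n
  while (n > 0 && !e$obs[n]) n <- n - 1L
  if (n == 0) return(NULL)
  e$n <- n
  if (!e$confirmed || sum(e$obs[seq_len(n)]) < params$min_track_length)
    return(NULL)
  xs <- rts_smooth(e)
  speed <- sqrt(xs[3, ]^2 + xs[4, ]^2)
  df <- data.frame(
    track_id = e$id, frame = e$frames[seq_len(n)], t = e$times[seq_len(n)],
    x_mm = xs[1, ], y_mm = xs[2, ], vx = xs[3, ], vy = xs[4, ],
    speed = speed, observed = e$obs[seq_len(n)])
  # enforce the tracking velocity span: break the track where a per-step
  # speed exceeds max_speed and keep sufficiently long segments
  over <- df$speed > params$max_speed
  if (!any(over)) return(df)
  seg <- cumsum(over)
  parts <- split(df[!over, ], seg[!over])
  parts <- Filter(function(d) sum(d$observed) >= params$min_track_length, parts)
  if (!length(parts)) return(NULL)
  do.call(rbind, parts)
}

#' Build microbubble tracks from per-frame localizations
#'
#' Full multi-target lifecycle: unmatched localizations spawn tentative
#' tracks, tracks confirm after `confirm_hits` hits, terminate after
#' `max_miss` consecutive misses, and tracks shorter than
#' `min_track_length` observed positions are discarded. Finished tracks are
#' Rauch-Tung-Striebel smoothed; per-position velocity vectors and speeds
#' come from the smoothed states. Steps whose speed exceeds `max_speed`
#' break the track.
#'
#' @param locs localization data.frame (columns `frame`, `t`, `x_mm`,
#'   `y_mm`), frames time-ordered.
#' @param frame_rate frames per second.
#' @param params a [tracker_params()].
#' @param n_frames total frames (default: max frame in `locs`).
#' @return data.frame of class `mb_tracks`: columns `track_id`, `frame`,
#'   `t`, `x_mm`, `y_mm`, `vx`, `vy`, `speed`, `observed`.
#' @export
build_tracks <- function(locs, frame_rate = 54, params = tracker_params(),
                         n_frames = NULL) {
  if (is.null(n_frames)) n_frames <- if (nrow(locs)) max(locs$frame) else 0L
  dt <- 1 / frame_rate
  by_frame <- if (nrow(locs)) {
    split(seq_len(nrow(locs)), factor(locs$frame, levels = seq_len(n_frames)))
  } else NULL
  active <- list()
  finished <- list()
  next_id <- 1L

  for (f in seq_len(n_frames)) {
    idx <- by_frame[[f]]
    tf <- (f - 1) / frame_rate
    nt <- length(active)

    # predict
    preds <- vector("list", nt)
    if (nt) {
      F <- kf_F(dt); Q <- kf_Q(dt, params$process_sd)
      for (i in seq_len(nt)) {
        e <- active[[i]]
        xp <- as.vector(F %*% e$state)
        Pp <- F %*% e$P %*% t(F) + Q
        preds[[i]] <- list(xp = xp, Pp = Pp)
      }
    }

    # associate
    if (nt && length(idx)) {
      spd <- vapply(preds, function(p) sqrt(p$xp[3]^2 + p$xp[4]^2), numeric(1))
      conf <- vapply(active, function(e) e$confirmed, logical(1))
      inn_sd <- vapply(preds, function(p)
        sqrt(max(p$Pp[1, 1], p$Pp[2, 2]) + params$meas_sd^2), numeric(1))
      pred_df <- data.frame(
        x = vapply(preds, function(p) p$xp[1], numeric(1)),
        y = vapply(preds, function(p) p$xp[2], numeric(1)),
        speed = spd, confirmed = conf,
        gate = ifelse(conf, spd * dt + 4 * inn_sd, Inf))
      lm <- cbind(x = locs$x_mm[idx], y = locs$y_mm[idx])
      asg <- associate(pred_df, lm, params, dt)
    } else {
      asg <- list(matches = data.frame(track = integer(), loc = integer()),
                  unassigned_tracks = seq_len(nt),
                  unassigned_locs = seq_along(idx))
    }

    # measurement updates
    for (r in seq_len(nrow(asg$matches))) {
      i <- asg$matches$track[r]; j <- asg$matches$loc[r]
      e <- active[[i]]; p <- preds[[i]]
      z <- c(locs$x_mm[idx[j]], locs$y_mm[idx[j]])
      S <- p$Pp[1:2, 1:2] + diag(params$meas_sd^2 + 1e-12, 2)
      K <- p$Pp[, 1:2] %*% solve(S)
      e$state <- p$xp + as.vector(K %*% (z - p$xp[1:2]))
      e$P <- p$Pp - K %*% p$Pp[1:2, ]
      e$hits <- e$hits + 1L; e$miss <- 0L
      if (e$hits >= params$confirm_hits) e$confirmed <- TRUE
      push_step(e, p$xp, p$Pp, e$state, e$P, f, tf, TRUE, z[1], z[2])
    }

    # missed tracks
    drop <- logical(nt)
    for (i in asg$unassigned_tracks) {
      e <- active[[i]]; p <- preds[[i]]
      e$miss <- e$miss + 1L
      if (e$miss >= params$max_miss || (!e$confirmed && e$miss >= 1L)) {
        tr <- finalize_track(e, params)
        if (!is.null(tr)) finished[[length(finished) + 1L]] <- tr
        drop[i] <- TRUE
      } else {
        e$state <- p$xp; e$P <- p$Pp
        push_step(e, p$xp, p$Pp, p$xp, p$Pp, f, tf, FALSE, NA_real_, NA_real_)
      }
    }
    if (nt) active <- active[!drop]

    # spawn tentative tracks from leftover localizations
    for (j in asg$unassigned_locs) {
      e <- new_track_rec(next_id, locs$x_mm[idx[j]], locs$y_mm[idx[j]],
                         f, tf, params)
      next_id <- next_id + 1L
      active[[length(active) + 1L]] <- e
    }
  }

  for (e in active) {
    tr <- finalize_track(e, params)
    if (!is.null(tr)) finished[[length(finished) + 1L]] <- tr
  }
  out <- if (length(finished)) do.call(rbind, finished) else
    data.frame(track_id = integer(), frame = integer(), t = numeric(),
               x_mm = numeric(), y_mm = numeric(), vx = numeric(),
               vy = numeric(), speed = numeric(), observed = logical())
  rownames(out) <- NULL
  class(out) <- c("mb_tracks", "data.frame")
  out
}
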