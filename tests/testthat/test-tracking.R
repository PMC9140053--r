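kf_init <- function(z, params) {
  list(state = c(z, 0, 0),
       P = diag(c(params$meas_sd^2, params$meas_sd^2,
                  params$init_speed_sd^2, params$init_speed_sd^2)))
}

test_that("noise-free linear motion converges to the exact velocity", {
  p <- tracker_params(process_sd = 0, meas_sd = 0)
  dt <- 1 / 54
  kf <- kf_init(c(0, 0), p)
  for (k in 1:10) {
    r <- kalman_step(kf$state, kf$P, c(k * dt, 0), dt, p)
    kf <- list(state = r$state, P = r$P)
  }
  expect_lt(abs(kf$state[3] - 1), 1e-6)
  expect_lt(abs(kf$state[4]), 1e-6)
})

test_that("a missed frame propagates the prediction exactly", {
  p <- tracker_params()
  st <- c(1, 2, 0.5, -0.25)
  r <- kalman_step(st, diag(4) * 1e-4, NULL, 0.2, p)
  expect_equal(r$state[1:2], c(1 + 0.5 * 0.2, 2 - 0.25 * 0.2))
  expect_equal(r$state[3:4], st[3:4])
  expect_null(r$innovation)
  expect_error(kalman_step(st, diag(4), c(NA, 1), 0.2, p), "finite")
})

test_that("velocity estimates stay within 10% under measurement noise", {
  p <- tracker_params(meas_sd = 0.01)
  dt <- 1 / 54
  set.seed(42)
  errs <- replicate(100, {
    kf <- NULL
    for (k in 1:50) {
      z <- c((k - 1) * dt + rnorm(1, 0, 0.01), rnorm(1, 0, 0.01))
      if (is.null(kf)) kf <- kf_init(z, p)
      else {
        r <- kalman_step(kf$state, kf$P, z, dt, p)
        kf <- list(state = r$state, P = r$P)
      }
    }
    abs(sqrt(kf$state[3]^2 + kf$state[4]^2) - 1)
  })
  expect_lt(mean(errs), 0.1)
  expect_gte(mean(errs < 0.1), 0.9)
})

test_that("association gates and assigns one-to-one at minimum cost", {
  p <- tracker_params()
  dt <- 1 / 54
  pred <- data.frame(x = c(1, 2), y = c(1, 1), speed = c(1, 1),
                     confirmed = c(TRUE, TRUE))
  # both localizations in gate; swapped pairing is cheaper than naive greedy
  locs <- cbind(x = c(1.02, 0.99), y = c(1, 1))
  a <- associate(pred, locs, p, dt)
  d2 <- outer(pred$x, locs[, 1], "-")^2 + outer(pred$y, locs[, 2], "-")^2
  o <- oracle_assignment(d2)
  got <- merge(a$matches, data.frame(track = 1:2, oracle = o$assignment))
  expect_equal(got$loc, got$oracle)

  # out-of-gate localization stays unassigned
  a2 <- associate(pred, cbind(x = 5, y = 5), p, dt)
  expect_equal(nrow(a2$matches), 0)
  expect_equal(a2$unassigned_locs, 1L)
})

test_that("a single noise-free bubble yields one track at the true speed", {
  tr <- line_trajectory(1L, 0.5, 1.6, 1.0, 0, n = 40)
  st <- render_positions(tr, n_frames = 40)
  locs <- localize_stack(st, threshold = 2)
  trk <- build_tracks(locs, 54, params = tracker_params(process_sd = 0.2),
                      n_frames = 40)
  expect_equal(length(unique(trk$track_id)), 1)
  expect_true(all(abs(trk$speed - 1.0) < 0.02))
})

test_that("per-step smoothed speed is exact on noise-free localizations", {
  # feed exact positions (no rendering) with zero-noise tracker settings
  n <- 30; dt <- 1 / 54
  locs <- data.frame(frame = 1:n, t = (0:(n - 1)) * dt,
                     x_mm = 0.2 + (0:(n - 1)) * 1.0 * dt,
                     y_mm = 1 + (0:(n - 1)) * 0.5 * dt)
  p <- tracker_params(process_sd = 0, meas_sd = 0)
  trk <- build_tracks(locs, 54, params = p, n_frames = n)
  expect_equal(length(unique(trk$track_id)), 1)
  expect_true(all(abs(trk$speed - sqrt(1 + 0.25)) < 1e-6))
})

test_that("bubbles above the 15 mm/s span produce no confirmed track", {
  # several passes of a 20 mm/s bubble crossing the field
  tr <- do.call(rbind, lapply(0:4, function(k)
    line_trajectory(k + 1L, 0.1, 0.4 + 0.5 * k, 20, 0, n = 8,
                    frame0 = 1L + 10L * k)))
  st <- render_positions(tr, n_frames = 50)
  locs <- localize_stack(st, threshold = 2)
  expect_gt(nrow(locs), 30)
  trk <- build_tracks(locs, 54, n_frames = 50)
  expect_equal(nrow(trk), 0)
})

test_that("well-separated parallel bubbles are tracked without identity swaps", {
  p <- tracker_params()
  gate <- 15 / 54 + 3 * p$meas_sd
  tr1 <- line_trajectory(1L, 0.4, 1.0, 1.2, 0, n = 40)
  tr2 <- line_trajectory(2L, 0.4, 1.0 + 3 * gate, 1.2, 0, n = 40)
  st <- render_positions(rbind(tr1, tr2), n_frames = 40)
  locs <- localize_stack(st, threshold = 2)
  trk <- build_tracks(locs, 54, n_frames = 40)
  expect_equal(length(unique(trk$track_id)), 2)
  # each track stays on one line: depth never strays toward the other
  for (id in unique(trk$track_id)) {
    ys <- trk$y_mm[trk$track_id == id]
    expect_lt(diff(range(ys)), gate)
  }
  # no localization is used by two tracks: per frame, observed track
  # positions never outnumber localizations
  obs_per_frame <- table(trk$frame[trk$observed])
  locs_per_frame <- table(locs$frame)
  expect_true(all(obs_per_frame <=
                    locs_per_frame[names(obs_per_frame)]))
})

test_that("resolvable ground-truth trajectories are recovered with accurate
           speeds", {
  # Two bubbles merge into one image component out to roughly 0.35 mm
  # (sum of their supra-threshold radii at the rendering PSF), and merged
  # components are deliberately not resolved into multiple emitters.
  # Recovery is therefore assessed on resolvable trajectories: those whose
  # positions stay > 0.35 mm from every other bubble for >= 70% of their
  # lifetime.
  ph <- build_renal_phantom()
  he <- hemo_params()
  traj <- simulate_microbubbles(ph, he, duration = 12, arrival_rate = 0.25,
                                seed = 21)
  rf <- render_frames(traj, 128, 128, 0.05, n_frames = 648, bmode = FALSE,
                      seed = 22)
  locs <- localize_stack(rf$contrast)
  trk <- build_tracks(locs, 54, n_frames = 648)

  by_frame <- split(seq_len(nrow(traj)), traj$frame)
  iso <- rep(TRUE, nrow(traj))
  for (ix in by_frame) {
    if (length(ix) < 2) next
    D <- as.matrix(stats::dist(traj[ix, c("x_mm", "y_mm")]))
    diag(D) <- Inf
    iso[ix] <- apply(D, 1, min) > 0.35
  }
  iso_frac <- tapply(iso, traj$trajectory_id, mean)
  lens <- table(traj$trajectory_id)
  ids <- as.integer(names(lens)[lens >= 10 & iso_frac >= 0.7])
  expect_gt(length(ids), 30)

  hit <- 0; sp_err <- numeric(0)
  for (gid in ids) {
    g <- traj[traj$trajectory_id == gid, ]
    cand <- trk[trk$frame %in% g$frame, ]
    if (nrow(cand) == 0) next
    d <- sqrt((cand$x_mm - g$x_mm[match(cand$frame, g$frame)])^2 +
              (cand$y_mm - g$y_mm[match(cand$frame, g$frame)])^2)
    near <- cand[d < 0.08, ]
    if (length(unique(near$frame)) >= 0.5 * nrow(g)) {
      hit <- hit + 1
      sp_err <- c(sp_err, abs(mean(near$speed) - mean(g$speed_mm_s)) /
                    mean(g$speed_mm_s))
    }
  }
  expect_gte(hit / length(ids), 0.9)
  expect_lt(mean(sp_err), 0.1)
})
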