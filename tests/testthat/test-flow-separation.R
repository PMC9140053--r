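test_that("circular means handle weighting and wrap-around", {
  expect_equal(circ_mean_deg(c(0, 0, 0)), 0)
  expect_equal(circ_mean_deg(c(10, 50)), 30)
  expect_equal(circ_mean_deg(c(350, 10)), 0)
  expect_equal(circ_mean_deg(c(0, 90), w = c(3, 1)),
               atan2(1, 3) * 180 / pi, tolerance = 1e-9)
  expect_true(is.na(circ_mean_deg(c(0, 180))))  # zero resultant
})

test_that("mean arterial angle is the length-weighted circular mean of steps", {
  # two steps: length 2 east (0 deg) and length 1 north (90 deg)
  tr <- data.frame(track_id = c(1L, 1L, 2L, 2L),
                   x_mm = c(0.1, 2.1, 1.0, 1.0),
                   y_mm = c(1.0, 1.0, 1.0, 0.0),
                   frame = c(1, 2, 1, 2), t = c(0, 1, 0, 1))
  got <- mean_arterial_angle(tr)
  expect_equal(got, atan2(1, 2) * 180 / pi, tolerance = 1e-9)
  expect_error(mean_arterial_angle(tr[0, ]), "no track steps")
})

test_that("sector classification follows the angular-distance rule", {
  mk <- function(angle_deg, len = 1) {
    th <- angle_deg * pi / 180
    data.frame(track_id = 1L, frame = 1:2, t = c(0, 1),
               x_mm = c(1, 1 + len * cos(th)),
               y_mm = c(1, 1 - len * sin(th)))
  }
  cortex <- flow_sector("cortex", 90, 125)
  medulla <- flow_sector("outer_medulla", 90, 90)
  expect_equal(classify_track(mk(140), cortex), "arterial")   # 50 <= 62.5
  expect_equal(classify_track(mk(270), cortex), "venous")     # mean + 180
  expect_equal(classify_track(mk(140), medulla), "excluded")  # 50 > 45
  expect_equal(classify_track(mk(120), medulla), "arterial")
  # invariance under adding 360 to the mean angle
  cortex2 <- flow_sector("cortex", 90 + 360, 125)
  expect_equal(classify_track(mk(140), cortex2), "arterial")
  # sectors must stay disjoint
  expect_error(flow_sector("cortex", 90, 200), "\\(0, 180\\)")
})

test_that("arterial and venous sectors are disjoint for any span < 180", {
  for (span in c(60, 90, 125, 179)) {
    sec <- flow_sector("cortex", 33, span)
    ang <- seq(0, 359.5, by = 0.5)
    art <- ang_dist_deg(ang, sec$mean_angle_deg) <= span / 2
    ven <- ang_dist_deg(ang, sec$mean_angle_deg + 180) <= span / 2
    expect_false(any(art & ven))
  }
})

test_that("ground-truth trajectories split into their true beds", {
  ph <- build_renal_phantom()
  he <- hemo_params()
  traj <- simulate_microbubbles(ph, he, duration = 20, arrival_rate = 0.3,
                                seed = 31)
  # use ground-truth positions directly as ideal tracks
  tr <- data.frame(track_id = traj$trajectory_id, frame = traj$frame,
                   t = traj$t, x_mm = traj$x_mm, y_mm = traj$y_mm)
  sp <- split_beds(tr, ph$labels, ph$sectors)
  truth <- tapply(traj$bed, traj$trajectory_id, function(b) b[1])
  miss <- 0
  for (i in seq_len(nrow(sp$assignments))) {
    a <- sp$assignments[i, ]
    if (a$bed != truth[[as.character(a$track_id)]]) miss <- miss + 1
  }
  expect_equal(miss, 0)
  # bed counts sum to total minus excluded
  expect_equal(sum(sp$counts[renal_beds()]),
               sp$counts[["total"]] - sp$counts[["excluded"]])
  # paired beds run opposed
  d_dvr <- mean_arterial_angle(sp$beds$om_dvr)
  d_avr <- mean_arterial_angle(sp$beds$om_avr)
  expect_gt(ang_dist_deg(d_dvr, d_avr), 180 - 45)
})

test_that("degenerate inputs are handled", {
  ph <- build_renal_phantom()
  empty <- data.frame(track_id = integer(), frame = integer(), t = numeric(),
                      x_mm = numeric(), y_mm = numeric())
  sp <- split_beds(empty, ph$labels, ph$sectors)
  expect_true(all(vapply(sp$beds, nrow, integer(1)) == 0))
  # a track fully in the background is excluded
  bg <- data.frame(track_id = 1L, frame = 1:3, t = 0:2 / 54,
                   x_mm = c(0.05, 0.06, 0.07), y_mm = c(0.05, 0.05, 0.05))
  sp2 <- split_beds(bg, ph$labels, ph$sectors)
  expect_equal(sp2$counts[["excluded"]], 1L)
})
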