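test_that("moving averages reproduce constants, gaps and step changes", {
  const <- data.frame(t = seq(0, 100, by = 0.5), speed = 1.0)
  ma <- moving_average_series(const)
  expect_true(all(ma$mean[!is.na(ma$mean)] == 1.0))

  none <- data.frame(t = numeric(), speed = numeric())
  ma0 <- moving_average_series(none, t_range = c(0, 50))
  expect_true(all(is.na(ma0$mean)))
  expect_true(all(ma0$n == 0))

  # step 1 -> 2 at t = 30 with uniform 10 Hz sampling: centered window mean
  # at the step time is 1.5
  t <- seq(0, 60, by = 0.1)
  step <- data.frame(t = t, speed = ifelse(t < 30, 1, 2))
  ms <- moving_average_series(step)
  expect_equal(ms$mean[ms$t == 30], 1.5, tolerance = 0.01)
})

test_that("alignment windows follow the injection time exactly", {
  mk_session <- function(t_inj, dur2 = 600) {
    empty <- data.frame(track_id = integer(), frame = integer(),
                        t = numeric(), x_mm = numeric(), y_mm = numeric(),
                        vx = numeric(), vy = numeric(), speed = numeric())
    sc <- function(dur) list(beds = list(cortex_art = empty),
                             map = data.frame(t = 0:(dur - 1), map = 80),
                             duration = dur)
    scan_session(list(sc(450), sc(dur2), sc(450)), t_inj = t_inj)
  }
  al <- align_to_injection(mk_session(51))
  expect_equal(al$display_span, c(1, 461))
  expect_equal(al$display_length, 460)
  al2 <- align_to_injection(mk_session(184))
  expect_equal(al2$scan2_mean_window, c(184, 594))
  expect_equal(al2$scan13_window, c(0, 410))
  expect_error(align_to_injection(mk_session(200)), "truncation")
})

test_that("the lowest-MAP window search minimizes and breaks ties early", {
  # V-shaped noise-free trace: trough at t = 150
  t <- 0:299
  v <- 80 - pmax(0, 30 - abs(t - 150))
  lw <- lowest_map_window(data.frame(t = t, map = v), t_inj = 100)
  expect_equal(lw$start + 15, 150, tolerance = 1)
  # constant trace: earliest window wins
  lc <- lowest_map_window(data.frame(t = t, map = 80), t_inj = 42)
  expect_equal(lc$start, 42)
  expect_equal(lc$mean, 80)
})

test_that("speed transforms are region-specific with exact inverses", {
  expect_equal(transform_speeds(1.0, "cortex"), 0)
  expect_equal(transform_speeds(4.0, "outer_medulla"), 2)
  x <- c(0.2, 1.7, 3.3)
  expect_equal(exp(transform_speeds(x, "cortex")), x, tolerance = 1e-12)
  expect_equal(transform_speeds(x, "inner_medulla")^2, x, tolerance = 1e-12)
  expect_error(transform_speeds(c(1, 0), "cortex"), "> 0")
  expect_error(transform_speeds(-1, "outer_medulla"), ">= 0")
})

test_that("bed summaries count coverage and average positions per window", {
  empty <- data.frame(track_id = integer(), frame = integer(), t = numeric(),
                      x_mm = numeric(), y_mm = numeric(), vx = numeric(),
                      vy = numeric(), speed = numeric())
  # bed with samples in exactly 100 distinct seconds
  smp <- data.frame(track_id = 1L, frame = 1:200,
                    t = rep(seq(0, 99), each = 2) + c(0.2, 0.7),
                    x_mm = 1, y_mm = 1, vx = 1, vy = 0, speed = 2.0)
  sc <- function(beds, dur) list(beds = beds,
                                 map = data.frame(t = 0:(dur - 1),
                                                  map = 80 - (0:(dur - 1) %% 7)),
                                 duration = dur)
  ses <- scan_session(list(sc(list(b = smp), 450),
                           sc(list(b = smp), 600),
                           sc(list(b = empty), 450)),
                      t_inj = 60)
  expect_warning(sm <- bed_summaries(ses), "no samples")
  s1 <- sm[sm$scan == 1 & sm$period == "scan", ]
  expect_equal(s1$seconds_with_estimates, 100)
  expect_equal(s1$mean, 2.0)
  expect_equal(s1$n, 200)
  s3 <- sm[sm$scan == 3 & sm$period == "scan", ]
  expect_true(is.na(s3$mean))
  # scan 2 gets the three 30-s sub-periods
  expect_setequal(sm$period[sm$scan == 2],
                  c("scan", "baseline30", "lowmap30", "recovery30"))
})

test_that("subject series aggregate without interpolation", {
  s1 <- data.frame(t = 0:5, mean = c(1, 2, NA, 4, 5, 6), n = 1)
  s2 <- data.frame(t = 0:5, mean = c(3, 2, NA, 2, NA, 4), n = 1)
  ag <- aggregate_subject_series(list(s1, s2))
  expect_equal(ag$mean[1], 2)
  expect_true(is.nan(ag$mean[3]))
  expect_equal(ag$n_subjects, c(2, 2, 0, 2, 1, 2))
})
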