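gauss_frame <- function(n, rc, cc, amp = 10, sigma_px = 1.5) {
  r <- seq_len(n) - 1; c_ <- seq_len(n) - 1
  amp * exp(-(r - rc)^2 / (2 * sigma_px^2)) %o%
    exp(-(c_ - cc)^2 / (2 * sigma_px^2))
}

test_that("detection returns nothing on an empty frame and one region per blob", {
  expect_length(detect_candidates(matrix(0, 32, 32), threshold = 5), 0)
  fr <- gauss_frame(32, 15, 15, amp = 10)
  regs <- detect_candidates(fr, threshold = 2, smooth_sigma = 0)
  expect_length(regs, 1)
  expect_error(detect_candidates(matrix(c(NA, 0, 0, 0), 2, 2), 1),
               "non-finite")
})

test_that("component count matches a flood-fill oracle on valley-separated blobs", {
  set.seed(4)
  for (rep in 1:5) {
    fr <- matrix(0, 40, 40)
    n_blobs <- sample(2:4, 1)
    for (b in seq_len(n_blobs)) {
      fr <- fr + gauss_frame(40, runif(1, 5, 35), runif(1, 5, 35),
                             amp = 10, sigma_px = 1.2)
    }
    sm <- gauss_smooth(fr, 1)
    mask <- sm > 3
    regs <- detect_candidates(fr, threshold = 3, smooth_sigma = 1,
                              min_area = 1L)
    expect_equal(length(regs), oracle_component_count(mask))
  }
})

test_that("weighted centroid follows the direct weighted-sum arithmetic", {
  # single pixel: its own center
  expect_equal(weighted_centroid(list(rows = 4, cols = 7, w = 2),
                                 pixel_pitch = 0.05),
               c(x = 7.5 * 0.05, y = 4.5 * 0.05))
  # weights 1 and 3 on rows 0 and 1 of column 1 (unit pitch):
  # centroid at row 0.75, col 1.0 -> pixel-center convention adds 0.5
  reg <- list(rows = c(0L, 1L), cols = c(1L, 1L), w = c(1, 3))
  expect_equal(weighted_centroid(reg, pixel_pitch = 1),
               c(x = 1.5, y = 1.25))
  expect_error(weighted_centroid(list(rows = 1, cols = 1, w = 0)),
               "degenerate")
})

test_that("noiseless Gaussian blobs localize to sub-pixel accuracy", {
  # true center offset by 0.3 px from a pixel center
  fr <- gauss_frame(32, 15.3, 14.7)
  regs <- detect_candidates(fr, threshold = 1, smooth_sigma = 1)
  cen <- weighted_centroid(regs[[1]], pixel_pitch = 1)
  expect_lt(abs(cen[["y"]] - (15.3 + 0.5)), 0.05)
  expect_lt(abs(cen[["x"]] - (14.7 + 0.5)), 0.05)
  # symmetric blob centered on a pixel center: exact to numerical precision
  fr2 <- gauss_frame(33, 16, 16)
  regs2 <- detect_candidates(fr2, threshold = 1, smooth_sigma = 1)
  cen2 <- weighted_centroid(regs2[[1]], pixel_pitch = 0.05)
  expect_equal(unname(cen2), c(16.5, 16.5) * 0.05, tolerance = 1e-9)
})

test_that("centroids are translation-equivariant by whole pixels", {
  fr <- gauss_frame(40, 12.2, 17.6)
  sh <- rbind(fr[-(1:3), ], matrix(0, 3, 40))  # content moved up 3 rows
  r1 <- detect_candidates(fr, threshold = 1, smooth_sigma = 1)[[1]]
  r2 <- detect_candidates(sh, threshold = 1, smooth_sigma = 1)[[1]]
  c1 <- weighted_centroid(r1, 0.05); c2 <- weighted_centroid(r2, 0.05)
  expect_equal(c1[["y"]] - c2[["y"]], 3 * 0.05, tolerance = 1e-6)
  expect_equal(c1[["x"]], c2[["x"]], tolerance = 1e-6)
})

test_that("localize_stack finds one localization per rendered bubble", {
  tr <- line_trajectory(1L, 0.6, 0.6, 1.0, 0.5, n = 30)
  st <- render_positions(tr, n_frames = 30)
  locs <- localize_stack(st, threshold = 2)
  expect_equal(nrow(locs), 30)
  expect_equal(locs$frame, 1:30)
  # localization count per frame never exceeds candidate-region count
  for (f in c(1, 15, 30)) {
    regs <- detect_candidates(st$frames[, , f], threshold = 2)
    expect_lte(sum(locs$frame == f), length(regs))
  }
  # against ground truth: RMS error < psf_sigma / 4
  err <- sqrt((locs$x_mm - tr$x_mm)^2 + (locs$y_mm - tr$y_mm)^2)
  expect_lt(sqrt(mean(err^2)), 0.075 / 4)
  # empty stack
  st0 <- frame_stack(array(0, c(16, 16, 4)), 0.05)
  expect_equal(nrow(localize_stack(st0, threshold = 1)), 0)
})

test_that("merged elongated components are rejected by the shape gate", {
  fr <- gauss_frame(40, 20, 16) + gauss_frame(40, 20, 21)
  st <- frame_stack(array(fr, c(40, 40, 1)), 0.05)
  expect_equal(nrow(localize_stack(st, threshold = 2)), 0)
  expect_equal(nrow(localize_stack(st, threshold = 2,
                                   max_elongation = Inf)), 1)
})
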