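cfg <- tracker_config()

test_that("colour mask is an inclusive per-channel range test", {
  mk <- function(rgb) {
    fr <- array(0L, dim = c(4, 5, 3))
    for (ch in 1:3) fr[, , ch] <- rgb[ch]
    fr
  }
  expect_true(all(color_mask(mk(c(200, 50, 50)), cfg)))
  expect_false(any(color_mask(mk(c(140, 0, 0)), cfg)))
  ## boundary values are inside
  expect_true(all(color_mask(mk(c(150, 0, 0)), cfg)))
  expect_true(all(color_mask(mk(c(255, 100, 100)), cfg)))
  expect_error(color_mask(matrix(1, 4, 5), cfg), "RGB")
})

test_that("mask monotonicity: widening the range never removes pixels", {
  sc <- simulate_display_video(display_params(duration = 1, fps = 10))
  fr <- sc$frames[[3]]
  narrow <- color_mask(fr, tracker_config(color_lo = c(180, 10, 10),
                                          color_hi = c(220, 60, 60)))
  wide <- color_mask(fr, cfg)
  expect_true(all(wide[narrow]))
})

test_that("quadrant coverage equals brute-force per-cell counting", {
  set.seed(5)
  mask <- matrix(runif(40 * 60) < 0.3, 40, 60)
  cc <- tracker_config(grid = c(7, 5))   # uneven cells at the edges
  cov <- quadrant_coverage(mask, cc)
  oracle <- oracle_quadrant_counts(mask, cw = ceiling(60 / 7),
                                   ch = ceiling(40 / 5), n_cols = 7,
                                   n_rows = 5)
  expect_equal(unclass(cov), oracle, ignore_attr = TRUE)
  expect_true(all(cov >= 0 & cov <= 1))
  expect_equal(unname(quadrant_coverage(matrix(TRUE, 16, 16), cfg)[1, 1]), 1)
})

test_that("the worked quadrant example: 400 red pixels in a 30x30 cell", {
  mask <- matrix(FALSE, 90, 90)
  mask[1:20, 1:20] <- TRUE                   # 400 pixels in cell (1,1)
  cov <- quadrant_coverage(mask, tracker_config(grid = c(3, 3)))
  expect_equal(cov[1, 1], 400 / 900)
  expect_equal(sum(cov > 0), 1)
  expect_true(detect_males(cov, cfg)$n_cells == 1)       # 0.444 >= 0.40
})

test_that("detection thresholding and merging follow the contract", {
  ## coverage just below threshold -> no detection
  mask <- matrix(FALSE, 90, 90)
  mask[1:10, 1:35] <- TRUE                   # 350/900 = 0.389 in cell (1,1)
  cov <- quadrant_coverage(mask, tracker_config(grid = c(3, 3)))
  expect_equal(nrow(detect_males(cov, cfg)), 0L)
  ## two touching saturated cells merge into one male
  mask2 <- matrix(FALSE, 32, 32)
  mask2[1:8, 1:16] <- TRUE                   # fills cells (1,1) and (1,2)
  cov2 <- quadrant_coverage(mask2, cfg)
  det <- detect_males(cov2, cfg)
  expect_equal(nrow(det), 1L)
  expect_equal(det$n_cells, 2L)
  ## threshold monotonicity: raising it never adds detections
  sc <- simulate_display_video(display_params(duration = 1, fps = 10))
  cov3 <- quadrant_coverage(color_mask(sc$frames[[1]], cfg), cfg)
  n_lo <- nrow(detect_males(cov3, tracker_config(coverage_threshold = 0.3)))
  n_hi <- nrow(detect_males(cov3, tracker_config(coverage_threshold = 0.7)))
  expect_lte(n_hi, n_lo)
})

test_that("edge rule picks the male nearest the female, or the far side", {
  det <- data.frame(x = c(10, 50), y = c(5, 7), n_cells = 1,
                    peak_coverage = 1)
  frames <- list(det, det, det)
  near_female <- edge_male_series(frames,
                                  tracker_config(female_column = 60),
                                  fps = 10)
  expect_equal(unique(near_female$y), 7)     # x=50 male is closer to her
  leftmost <- edge_male_series(frames,
                               tracker_config(dance_direction = "left"),
                               fps = 10)
  expect_equal(unique(leftmost$y), 5)        # x=10 male
  expect_error(edge_male_series(list(det[0, ], det[0, ]), cfg, fps = 10),
               "no frames")
})

test_that("handoff requires strict horizontal passing", {
  d1 <- data.frame(x = 50, y = 1, n_cells = 1, peak_coverage = 1)
  both <- data.frame(x = c(50, 55), y = c(1, 2), n_cells = 1,
                     peak_coverage = 1)
  cc <- tracker_config(dance_direction = "right")
  s <- edge_male_series(list(d1, both, both), cc, fps = 10)
  expect_equal(s$y, c(1, 2, 2))              # x=55 passes x=50: handoff
  ## with hysteresis 10 px the 5 px pass is ignored
  cc2 <- tracker_config(dance_direction = "right", handoff_eps = 10)
  s2 <- edge_male_series(list(d1, both, both), cc2, fps = 10)
  expect_equal(s2$y, c(1, 1, 1))
})

test_that("short dropouts are bridged, long ones split the series", {
  d <- data.frame(x = 10, y = 3, n_cells = 1, peak_coverage = 1)
  none <- d[0, ]
  bridged <- edge_male_series(c(rep(list(d), 3), list(none, none),
                                rep(list(d), 3)),
                              tracker_config(max_gap = 3), fps = 10)
  expect_equal(length(bridged$y), 8L)
  expect_equal(unique(bridged$y), 3)
  expect_warning(
    split_series <- edge_male_series(
      c(rep(list(d), 6), rep(list(none), 5), rep(list(d), 3)),
      tracker_config(max_gap = 2), fps = 10),
    "longest")
  expect_equal(length(split_series$y), 8L)   # 6 detections + 2 bridged
})

test_that("downsampling keeps every k-th sample and the oscillation count", {
  s <- display_series(seq_len(600), fps = 30)
  d <- downsample_series(s, 15)
  expect_length(d$y, 300L)
  expect_equal(d$fps, 15)
  expect_equal(d$y, seq(1, 600, by = 2))
  expect_error(downsample_series(s, 14), "divide")
  ## constant series stays constant; 2 Hz sine keeps its peak count
  expect_equal(unique(downsample_series(display_series(rep(2, 60), 30),
                                        15)$y), 2)
  t <- (0:599) / 30
  sine <- sin(2 * pi * 2 * t)
  f30 <- cartwheel_frequency(display_series(-sine, 30))
  f15 <- cartwheel_frequency(downsample_series(display_series(-sine, 30), 15))
  expect_equal(f30, f15)
})

test_that("tracked noise-free scenes match ground truth within one cell", {
  sc <- simulate_display_video(display_params(
    n_males = 2, duration = 5, fps = 30, timing_noise_sd = 0,
    height_noise_sd = 0))
  tr <- track_scene(sc, cfg, downsample = FALSE)
  expect_length(tr$y, length(sc$truth_trace))
  agree <- mean(abs(tr$y - sc$truth_trace) <= cfg$cell_px)
  expect_gte(agree, 0.99)
})

test_that("tracking works without a female via the dance direction", {
  sc <- simulate_display_video(display_params(
    n_males = 3, duration = 3, fps = 15, female_present = FALSE,
    dance_direction = "left", timing_noise_sd = 0, height_noise_sd = 0))
  tr <- track_scene(sc, tracker_config(dance_direction = "left"),
                    downsample = FALSE)
  agree <- mean(abs(tr$y - sc$truth_trace) <= cfg$cell_px)
  expect_gte(agree, 0.99)
})

test_that("calibration sweep finds the constructed-optimal threshold", {
  ## heads covering 45% of a quadrant plus a 35% spurious patch:
  ## 0.30 admits the spurious patch, 0.50-0.70 miss the head -> best 0.40
  sc <- make_calibration_scene(n_frames = 4, head_frac = 0.45,
                               spur_frac = 0.35)
  cc <- tracker_config(cell_px = 10L)
  cal <- calibrate_threshold(list(sc), config = cc)
  expect_equal(cal$best_threshold, 0.40)
  expect_gt(cal$curve$error[cal$curve$threshold == 0.30], 0)
  expect_equal(cal$curve$error[cal$curve$threshold == 0.40], 0)
  expect_true(all(cal$curve$error[cal$curve$threshold >= 0.50] > 0))
  ## without the spurious patch both low thresholds are error-free and the
  ## tie breaks to the smallest
  clean <- make_calibration_scene(n_frames = 4, head_frac = 0.45)
  cal2 <- calibrate_threshold(list(clean), config = cc)
  expect_equal(cal2$best_threshold, 0.30)
  ## single candidate is returned as best
  expect_equal(calibrate_threshold(list(clean), candidates = 0.5,
                                   config = cc)$best_threshold, 0.5)
  expect_error(calibrate_threshold(list(), config = cc), "at least one")
})
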