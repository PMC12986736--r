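test_that("tip extraction: degenerate static mask gives zero displacement", {
  masks <- static_column_masks()
  traj <- extract_tip_series(masks, fps = 30, mm_per_px = 0.25)
  expect_true(all(traj$displacement == 0))
  expect_true(all(traj$flag == "observed"))
  expect_equal(diff(traj$time), rep(1 / 30, 19))
})

test_that("tip extraction recovers the rendered sinusoid within one pixel (RMS)", {
  cl <- render_clip(tiny_clip_spec(seed = 13), return_frames = FALSE)
  traj <- extract_tip_series(cl$truth$masks, fps = 30, mm_per_px = 0.5)
  # magnitude comparison: at centre crossings the two lateral extremes are
  # equidistant from baseline and sub-pixel rasterization decides the
  # side, so the signed series can differ there while the measured
  # magnitude stays within quantization
  err <- abs(traj$displacement) - abs(cl$truth$tip_x_true)
  expect_lt(sqrt(mean(err^2)), 0.5)  # 1 px x mm_per_px
  # away from crossings the signed series agrees too
  clear <- abs(cl$truth$tip_x_true) > 0.7 * max(abs(cl$truth$tip_x_true))
  err_signed <- (traj$displacement - cl$truth$tip_x_true)[clear]
  expect_lt(sqrt(mean(err_signed^2)), 0.5)
})

test_that("tip extraction interpolates short gaps and rejects bad input", {
  masks <- static_column_masks(n_frames = 9)
  masks[, , 5] <- 0  # single missing frame
  traj <- extract_tip_series(masks, fps = 30, mm_per_px = 0.25)
  expect_equal(traj$flag[5], "interpolated")
  expect_equal(traj$displacement[5],
               mean(traj$displacement[c(4, 6)]))

  empty <- array(0, c(10, 10, 5))
  expect_error(extract_tip_series(empty, 30, 0.25), "empty")

  long_gap <- static_column_masks(n_frames = 30)
  long_gap[, , 8:22] <- 0  # 15-frame gap > 10-frame limit
  expect_error(extract_tip_series(long_gap, 30, 0.25), "limit")
})

test_that("cycle counting matches the analytic oracle and discards partial cycles", {
  tt <- seq(0, 5 - 1 / 30, by = 1 / 30)
  expect_equal(count_cycles(sin(2 * pi * 2 * tt), fps = 30), 10L)
  expect_equal(count_cycles(rep(1.3, 150), fps = 30), 0L)
  # 1.5 periods: only one complete left-right-left cycle
  expect_equal(count_cycles(sin(2 * pi * 0.3 * tt), fps = 30), 1L)
})

test_that("cycle counting is invariant to sign flip, offset, and sub-hysteresis noise", {
  tt <- seq(0, 5 - 1 / 30, by = 1 / 30)
  base <- 7 * sin(2 * pi * 1.8 * tt + 0.7)
  n0 <- count_cycles(base, fps = 30)
  expect_equal(count_cycles(-base, fps = 30), n0)
  expect_equal(count_cycles(base + 42, fps = 30), n0)
  h <- 0.2 * max(abs(base))
  set.seed(99)
  for (r in 1:10) {
    noisy <- base + rnorm(length(base), 0, h / 3.5)
    expect_equal(count_cycles(noisy, fps = 30), n0)
  }
})

test_that("feature arithmetic follows the task definitions", {
  traj <- synth_trajectory(freq = 2, amp = 14.6, quantize = FALSE)
  ft <- compute_features(traj)
  expect_equal(ft$n_cycles, 10L)
  expect_equal(ft$frequency, 2)          # Ncycles / T with T = 5 s
  expect_close(ft$max_amplitude, 14.6, 0.15)  # sampling sits near the peaks
  expect_close(ft$normalized_frequency, 2 / 14.6, 2e-3)

  # 2 Hz at 14.49 mm amplitude sits at the ALS group mean of ~0.138 Hz/mm
  traj2 <- synth_trajectory(freq = 2, amp = 14.49, quantize = FALSE)
  ft2 <- compute_features(traj2)
  expect_close(ft2$normalized_frequency, 0.138, 1e-3)

  # amplitude guard: near-zero amplitudes are refused
  small <- synth_trajectory(freq = 2, amp = 0.5, quantize = FALSE)
  expect_error(compute_features(small), "guard")

  short <- synth_trajectory(freq = 2, amp = 10, duration = 3)
  expect_error(compute_features(short), "shorter")
})

test_that("cycle counts match a brute-force threshold oracle across frequencies", {
  # independent oracle: alternating +/-h crossings of the continuous
  # sinusoid on a fine grid; every completed pair is one cycle
  oracle_cycles <- function(f, duration = 5, h_frac = 0.2) {
    tt <- seq(0, duration - 1e-6, by = 1e-5)
    s <- sin(2 * pi * f * tt)
    h <- h_frac * max(abs(s))
    state <- 0L; alt <- 0L
    above <- s > h; below <- s < -h
    for (i in seq_along(s)) {
      if (above[i] && state != 1L) { alt <- alt + 1L; state <- 1L }
      else if (below[i] && state != -1L) { alt <- alt + 1L; state <- -1L }
    }
    alt %/% 2L
  }
  for (f in c(0.7, 1.1, 1.34, 2.21, 3.14)) {
    traj <- synth_trajectory(freq = f, amp = 10, phase = 0, quantize = FALSE)
    ft <- compute_features(traj)
    expect_equal(ft$n_cycles, oracle_cycles(f))
    # when the residual fraction of a period is below half, the count
    # also equals floor(5 f): the trailing partial cycle never reaches
    # the far side
    if (5 * f - floor(5 * f) < 0.5)
      expect_equal(ft$frequency, floor(f * 5) / 5)
    expect_close(ft$max_amplitude, 10, 0.25)
  }
})

test_that("trial averaging is the feature-wise mean with single-trial fallback", {
  t1 <- compute_features(synth_trajectory(2, 10))
  expect_equal(average_trials(t1, t1), t1)

  t2 <- compute_features(synth_trajectory(1, 10))
  t1$normalized_frequency <- 0.10
  t2$normalized_frequency <- 0.20
  avg <- average_trials(t1, t2)
  expect_equal(avg$normalized_frequency, 0.15)
  expect_equal(avg$frequency, (t1$frequency + t2$frequency) / 2)

  expect_warning(res <- average_trials(t1), "single")
  expect_identical(res, t1)
})
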