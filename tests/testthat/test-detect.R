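# Single-event detection, exclusion rules and event metrics.

test_that("defaults carry the analysis constants", {
  p <- detection_params()
  expect_equal(p$smooth_window_frames, 4L)
  expect_equal(p$peak_min_height_pct, 0.5)
  expect_equal(p$refractory_s, 2.0)
  expect_equal(p$elevated_baseline_ratio, 0.5)
  expect_equal(p$bound_threshold_pct, 0.5)
  expect_equal(p$interruption_rise_pct, 1.0)
  expect_equal(p$baseline_window_s, 15)
  expect_equal(p$baseline_percentile, 1)
  expect_equal(p$fwhm_min_prominence_pct, 0.5)
  expect_equal(p$network_fraction_threshold, 0.20)
  expect_equal(p$network_min_duration_s, 2.5)
  expect_error(detection_params(bogus = 1), "unknown")
  expect_error(detection_params(refractory_s = -1), "positive")
})

test_that("peak detection applies the strict height gate", {
  expect_equal(detect_peaks(triangle_trace(apex_pct = 2))[["1"]], 20L)
  expect_length(detect_peaks(triangle_trace(apex_pct = 0.4))[["1"]], 0)
  flat <- trace_matrix(matrix(0, 1, 50), fs_hz = FS, stage = "smoothed")
  expect_length(detect_peaks(flat)[["1"]], 0)
  # plateau maxima report their first frame
  x <- c(0, 0, 1, 2, 2, 2, 1, 0)
  tm <- trace_matrix(matrix(x, 1), fs_hz = FS, stage = "smoothed")
  expect_equal(detect_peaks(tm)[["1"]], 3L)
})

test_that("raising the height threshold never increases the peak count", {
  set.seed(7)
  for (r in 1:20) {
    tm <- trace_matrix(matrix(cumsum(rnorm(300, sd = 0.3)), 1), fs_hz = FS,
                       stage = "smoothed")
    counts <- vapply(c(0.2, 0.5, 1, 2, 4), function(h) {
      length(detect_peaks(tm, detection_params(peak_min_height_pct = h))[[1]])
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("amplitude is measured against the preceding inter-event minimum", {
  # lone peak 2% over a 0 baseline
  x <- unclass(triangle_trace(apex_pct = 2))[1, ]
  expect_equal(measure_amplitude(x, 20L), 2)
  # second peak of 3% with a preceding inter-peak minimum of 1%
  y <- c(0, 1, 2, 1.5, 1, 1.4, 3, 1, 0)
  expect_equal(measure_amplitude(y, c(2L, 6L)), c(2, 2))
  # identical back-to-back peaks separated by a return to 0
  z <- c(0, 2, 0, 2, 0)
  expect_equal(measure_amplitude(z, c(1L, 3L)), c(2, 2))
})

test_that("refractory and elevated-baseline rules flag the right peaks", {
  fs <- FS
  # peaks 1.5 s apart: the second is refractory (1.5 < 2.0)
  gap <- round(1.5 * fs)               # 13 frames = 1.459 s
  x <- numeric(60); x[c(6, 6 + gap)] <- 2
  pk <- c(5L, 5L + gap)
  fl <- flag_exclusions(pk, measure_amplitude(x, pk), x,
                        detection_params(), fs)
  expect_equal(fl$refractory_excluded, c(FALSE, TRUE))

  # peak at 3% dF/F with amplitude 1%: elevated baseline (1 < 0.5 * 3)
  y <- c(rep(2, 10), 2.5, 3, 2.5, rep(2, 10))
  amp <- measure_amplitude(y, 11L)
  expect_equal(amp, 1)
  fl2 <- flag_exclusions(11L, amp, y, detection_params(), fs)
  expect_true(fl2$elevated_baseline_excluded)

  # isolated peak rising from a 0 baseline: no flags
  z <- unclass(triangle_trace())[1, ]
  fl3 <- flag_exclusions(20L, measure_amplitude(z, 20L), z,
                         detection_params(), fs)
  expect_false(any(unlist(fl3)))
})

test_that("event delineation finds threshold crossings and interruptions", {
  # boxcar above threshold over frames 10..19 -> [10, 20)
  x <- numeric(40); x[11:20] <- 2; x[15] <- 2.5
  b <- delineate_event(x, 14L)
  expect_equal(b, list(start_frame = 10L, end_frame = 20L))

  # peak in the first frames with no preceding sub-threshold frame
  y <- c(2, 2.5, 2, 1, 0.4, 0, 0)
  expect_null(delineate_event(y, 1L))

  # decay reaches 0.8%, then rises to 2.0% (rise 1.2% > 1%): the event
  # ends at the 0.8% trough frame
  z <- c(0, 1, 3, 1.5, 0.8, 1.2, 2, 2.2, 0)
  b2 <- delineate_event(z, 2L)
  expect_equal(b2, list(start_frame = 1L, end_frame = 4L))

  # trace that never returns to threshold has no clear termination
  w <- c(0, 1, 3, 2.5, 2, 1.8, 1.7)
  expect_null(delineate_event(w, 2L))
})

test_that("AUC matches closed-form trapezoids", {
  fs <- FS
  expect_equal(compute_auc(numeric(20), 2L, 12L, fs), 0)
  # constant 2% over 10 sample intervals
  x <- rep(2, 30)
  expect_equal(compute_auc(x, 5L, 16L, fs), 2 * 10 / fs)
  # symmetric triangle, height 4 over 8 intervals: h * b / 2 exactly
  tri <- c(numeric(3), 0:4, 3:0, numeric(3))
  expect_equal(compute_auc(tri, 3L, 12L, fs), 4 * 8 / 2 / fs)
  expect_error(compute_auc(x, -1L, 10L, fs), "bounds")
  expect_error(compute_auc(x, 5L, 40L, fs), "bounds")
})

test_that("inter-event intervals are peak-to-peak times", {
  fs <- 8.91
  expect_equal(compute_iei(c(0L, 89L), fs), 89 / 8.91)
  expect_length(compute_iei(42L, fs), 0)
  expect_equal(compute_iei(c(10L, 30L, 50L, 70L), fs), rep(20 / fs, 3))
})

test_that("half-decay interpolates the half-amplitude crossing", {
  fs <- FS
  # instantaneous drop below the half level within one frame
  x <- c(0, 5, 0, 0)
  expect_lte(half_decay_time(x, 1L, 5, fs), 1 / fs)
  # exponential decay: t_half ~ tau * log(2) at dense sampling
  fs_d <- 100
  tau <- 0.7
  t <- seq(0, 6, by = 1 / fs_d)
  y <- 5 * exp(-t / tau)
  hd <- half_decay_time(y, 0L, 5, fs_d)
  expect_lt(abs(hd - tau * log(2)), 1 / fs_d)
  # monotone rise after the peak: undefined
  z <- c(0, 1, 1.5, 2, 3, 4)
  expect_true(is.na(half_decay_time(z, 1L, 1, fs)))
})

test_that("full detection recovers isolated high-SNR events", {
  counts <- recovery_counts(seed = 1, noise_sd_pct = 0.2,
                            unflagged_only = TRUE)
  expect_equal(unname(counts["fn"]), 0)          # every true event found
  expect_gte(f1_from_counts(counts), 0.95)
})

test_that("empty input yields an empty transient table", {
  tm <- trace_matrix(matrix(0, 3, 300), fs_hz = FS)
  tr <- detect_transients(tm)
  expect_equal(nrow(tr), 0)
  expect_s3_class(tr, "transient_table")
})

test_that("doubling the traces doubles amplitude and AUC of clean events", {
  # steep-edged events so the 0.5% boundary crossings land on the same
  # frames before and after scaling (bounds do not change regime)
  n <- 402
  x <- numeric(n)
  shape <- c(2, 4, 2, 1, 0.8)
  for (p0 in c(30, 160, 290)) x[p0 + seq_along(shape)] <- shape
  tm <- trace_matrix(matrix(x, 1), fs_hz = FS, stage = "smoothed")
  d1 <- detect_transients(tm)
  d2 <- detect_transients(trace_matrix(matrix(2 * x, 1), fs_hz = FS,
                                       stage = "smoothed"))
  m1 <- d1[!is.na(d1$auc_pct_s), ]
  m2 <- d2[!is.na(d2$auc_pct_s), ]
  expect_equal(nrow(m1), 3)
  expect_equal(m2$peak_frame, m1$peak_frame)
  expect_equal(m2$start_frame, m1$start_frame)
  expect_equal(m2$end_frame, m1$end_frame)
  expect_equal(m2$amplitude_pct, 2 * m1$amplitude_pct, tolerance = 1e-12)
  expect_equal(m2$auc_pct_s, 2 * m1$auc_pct_s, tolerance = 1e-12)
})

test_that("transient tables satisfy their structural invariants", {
  fov <- simulate_fov("KO", duration_s = 120, n_neurons = 10, seed = 21)
  tr <- detect_transients(fov$traces)
  measured <- !is.na(tr$duration_s)
  expect_true(all(tr$duration_s[measured] > 0))
  expect_true(all(tr$start_frame[measured] <= tr$peak_frame[measured]))
  expect_true(all(tr$end_frame[measured] > tr$peak_frame[measured]))
  flagged <- tr$refractory_excluded | tr$elevated_baseline_excluded
  expect_true(all(is.na(tr$amplitude_pct[flagged])))
  expect_true(all(is.na(tr$duration_s[flagged | tr$no_clear_bounds])))
  expect_true(all(is.na(tr$auc_pct_s[flagged | tr$no_clear_bounds])))
  # determinism: identical inputs give identical tables
  expect_identical(tr, detect_transients(fov$traces))
  expect_true(!is.unsorted(order(tr$neuron_id, tr$peak_frame)))
})
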