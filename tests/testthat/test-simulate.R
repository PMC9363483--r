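# Synthetic generator: schedules, kernel rendering, toy movies.

test_that("zero-rate presets give empty schedules", {
  p <- regime_preset("WT", burst_rate_per_min = 0, network_rate_per_min = 0)
  gt <- generate_ground_truth(p, duration_s = 120, n_neurons = 5, seed = 1)
  expect_equal(nrow(gt$bursts), 0)
  expect_equal(nrow(gt$network), 0)
})

test_that("ground truth is a pure function of arguments and seed", {
  p <- regime_preset("KO")
  a <- generate_ground_truth(p, duration_s = 120, n_neurons = 10, seed = 7)
  b <- generate_ground_truth(p, duration_s = 120, n_neurons = 10, seed = 7)
  expect_identical(a, b)
  c <- generate_ground_truth(p, duration_s = 120, n_neurons = 10, seed = 8)
  expect_false(identical(a$bursts, c$bursts))
  # times within the recording, participants are valid neuron ids
  expect_true(all(a$bursts$burst_time_s >= 0 &
                    a$bursts$burst_time_s < a$duration_s))
  expect_true(all(unlist(a$network$participants) %in% seq_len(10)))
  expect_true(all(a$bursts$n_spikes >= 1))
})

test_that("invalid generator arguments signal errors", {
  p <- regime_preset("WT")
  expect_error(generate_ground_truth(p, duration_s = -1, seed = 1),
               "duration")
  expect_error(generate_ground_truth(p, fs = 0, duration_s = 10,
                                     n_neurons = 2, seed = 1), "fs")
  expect_error(regime_preset("WT", participation_prob = 1.5), "0, 1")
  expect_error(
    generate_ground_truth(p, duration_s = 10, n_neurons = 2, seed = 1,
                          tau_rise_s = 0.9, tau_decay_s = 0.8) |>
      render_traces(seed = 1),
    "tau")
})

test_that("Monte-Carlo burst counts match the Poisson mean", {
  # WT solo-burst process at 1 burst/min over 300 s: mean 5 per neuron
  p <- regime_preset("WT", network_rate_per_min = 0)
  counts <- unlist(lapply(1:200, function(s) {
    gt <- generate_ground_truth(p, duration_s = 300, n_neurons = 40,
                                seed = s)
    tabulate(gt$bursts$neuron_id, nbins = 40)
  }))
  lambda <- p$burst_rate_per_min * 5
  se <- sqrt(lambda / length(counts))
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("empirical network-event rate matches the preset rate", {
  p <- regime_preset("KO_HET")
  n_ev <- vapply(1:100, function(s) {
    nrow(generate_ground_truth(p, duration_s = 300, n_neurons = 5,
                               seed = s)$network)
  }, numeric(1))
  lambda <- p$network_rate_per_min * 5
  se <- sqrt(lambda / length(n_ev))
  expect_lt(abs(mean(n_ev) - lambda), 3 * se)
})

test_that("ground-truth burst frequency orders KO > KO_HET > WT across seeds", {
  mean_bursts <- function(preset, s) {
    gt <- generate_ground_truth(regime_preset(preset), duration_s = 300,
                                n_neurons = 40, seed = s)
    nrow(gt$bursts) / 40
  }
  ok <- vapply(1:100, function(s) {
    wt <- mean_bursts("WT", s)
    het <- mean_bursts("KO_HET", s)
    ko <- mean_bursts("KO", s)
    ko > het && het > wt
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("rendering a spike-free schedule without noise gives zero traces", {
  p <- regime_preset("WT", burst_rate_per_min = 0, network_rate_per_min = 0)
  gt <- generate_ground_truth(p, duration_s = 60, n_neurons = 3, seed = 1)
  tr <- render_traces(gt, noise_sd_pct = 0, drift_amplitude_pct = 0,
                      seed = 1)
  expect_equal(max(abs(tr)), 0)
  expect_identical(trace_stage(tr), "raw")
})

test_that("a single spike renders the analytic kernel exactly", {
  p <- regime_preset("WT", burst_rate_per_min = 0, network_rate_per_min = 0,
                     amplitude_per_spike_pct = 4)
  gt <- generate_ground_truth(p, duration_s = 30, n_neurons = 1, seed = 1)
  t0 <- 5.2
  gt$bursts <- data.frame(neuron_id = 1L, burst_time_s = t0, n_spikes = 1L,
                          from_network = FALSE)
  tr <- render_traces(gt, noise_sd_pct = 0, drift_amplitude_pct = 0,
                      seed = 1)
  # independent oracle: evaluate the difference of exponentials directly
  ft <- (seq_len(gt$n_frames) - 1) / gt$fs_hz
  tp <- 0.1 * 0.8 / 0.7 * log(8)
  kmax <- exp(-tp / 0.8) - exp(-tp / 0.1)
  expected <- ifelse(ft >= t0,
                     4 * (exp(-(ft - t0) / 0.8) - exp(-(ft - t0) / 0.1)) / kmax,
                     0)
  expect_equal(as.numeric(unclass(tr)[1, ]), expected, tolerance = 1e-12)
  # sampled maximum sits within one frame of the analytic kernel peak
  expect_lte(abs((which.max(unclass(tr)[1, ]) - 1) / gt$fs_hz - (t0 + tp)),
             1 / gt$fs_hz)
  expect_lte(max(tr), 4)
})

test_that("overlapping spikes superpose linearly (convolution oracle)", {
  p <- regime_preset("WT", burst_rate_per_min = 0, network_rate_per_min = 0,
                     amplitude_per_spike_pct = 3)
  gt <- generate_ground_truth(p, duration_s = 20, n_neurons = 1, seed = 1)
  fs <- gt$fs_hz
  t1 <- 4; t2 <- 4 + 1 / fs     # two spikes one frame apart
  gt$bursts <- data.frame(neuron_id = c(1L, 1L), burst_time_s = c(t1, t2),
                          n_spikes = c(1L, 1L), from_network = FALSE)
  tr <- render_traces(gt, noise_sd_pct = 0, drift_amplitude_pct = 0,
                      seed = 1)
  ft <- (seq_len(gt$n_frames) - 1) / fs
  brute <- numeric(gt$n_frames)
  for (ts in c(t1, t2)) {
    brute <- brute + 3 * ca_kernel(ft - ts)
  }
  expect_equal(as.numeric(unclass(tr)[1, ]), brute, tolerance = 1e-12)
})

test_that("rendered traces are reproducible and respect spike counts", {
  gt <- generate_ground_truth(regime_preset("KO"), duration_s = 60,
                              n_neurons = 5, seed = 11)
  a <- render_traces(gt, seed = 3)
  b <- render_traces(gt, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a, render_traces(gt, seed = 4)))
})

test_that("toy movies render deterministically with matching ROIs", {
  tm <- trace_matrix(matrix(0, 4, 10), fs_hz = FS)
  out <- render_movie(tm, shot_noise_sd = 0)
  expect_s3_class(out$rois, "roi_set")
  expect_equal(nrow(out$rois), 4)
  # all-zero traces, zero noise: every frame identical to the first
  m <- unclass(out$movie)
  for (t in 2:dim(m)[1]) expect_equal(m[t, , ], m[1, , ])
  # fixed seed: bit-identical stacks
  tm2 <- trace_matrix(matrix(rnorm(40, 5, 1), 4, 10), fs_hz = FS)
  a <- render_movie(tm2, shot_noise_sd = 2, seed = 9)
  b <- render_movie(tm2, shot_noise_sd = 2, seed = 9)
  expect_identical(a$movie, b$movie)
  expect_error(render_movie(tm, grid_spacing_px = 6, roi_radius_px = 3),
               "overlap")
})
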