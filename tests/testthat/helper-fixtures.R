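# Shared fixture builders. Frames are 0-based everywhere, matching the
# package's reported tables; helpers take 0-based frame arguments.

FS <- 8.91

# A trace matrix with a single triangular bump per neuron.
triangle_trace <- function(apex_pct = 2, apex_frame = 20, half_width = 5,
                           n_frames = 60, fs = FS, stage = "smoothed") {
  x <- numeric(n_frames)
  for (k in -half_width:half_width) {
    f <- apex_frame + k
    if (f >= 0 && f < n_frames) {
      x[f + 1] <- apex_pct * (1 - abs(k) / half_width)
    }
  }
  trace_matrix(matrix(x, nrow = 1), fs_hz = fs, stage = stage)
}

# Active-interval table covering [start, end) for the given neurons.
interval_block <- function(neurons, start, end) {
  data.frame(neuron_id = neurons, start_frame = start, end_frame = end,
             peak_frame = start)
}

# Brute-force coactive fraction: per-frame membership count by explicit
# looping over neurons and frames (independent of the diff/cumsum path).
brute_fraction <- function(intervals, n_neurons, n_frames) {
  active <- matrix(FALSE, n_neurons, n_frames)
  for (k in seq_len(nrow(intervals))) {
    fr <- (intervals$start_frame[k] + 1):intervals$end_frame[k]
    active[intervals$neuron_id[k], fr] <- TRUE
  }
  colSums(active) / n_neurons
}

# Brute-force network-event scan: walk frames, accumulate runs strictly
# above threshold, apply the minimum duration.
brute_network_events <- function(fraction, thr, min_dur_s, fs) {
  runs <- list()
  in_run <- FALSE
  for (t in seq_along(fraction)) {
    if (fraction[t] > thr && !in_run) { s <- t; in_run <- TRUE }
    if (fraction[t] <= thr && in_run) {
      runs[[length(runs) + 1]] <- c(s, t); in_run <- FALSE
    }
  }
  if (in_run) runs[[length(runs) + 1]] <- c(s, length(fraction) + 1)
  out <- do.call(rbind, runs)
  if (is.null(out)) {
    return(data.frame(start_frame = integer(0), end_frame = integer(0)))
  }
  df <- data.frame(start_frame = out[, 1] - 1L, end_frame = out[, 2] - 1L)
  df[(df$end_frame - df$start_frame) / fs >= min_dur_s, , drop = FALSE]
}

# Random merged interval set for oracle-equivalence runs.
random_intervals <- function(n_neurons, n_frames, mean_per_neuron = 4) {
  rows <- lapply(seq_len(n_neurons), function(i) {
    k <- rpois(1, mean_per_neuron)
    if (!k) return(NULL)
    s <- sort(sample.int(n_frames - 1, k))
    e <- pmin(s + sample(3:45, k, replace = TRUE), n_frames)
    # merge overlaps so the diff/cumsum path sees one neuron once per frame
    ms <- s[1]; me <- e[1]; out <- NULL
    for (j in seq_len(k)[-1]) {
      if (s[j] <= me) me <- max(me, e[j]) else {
        out <- rbind(out, c(ms, me)); ms <- s[j]; me <- e[j]
      }
    }
    out <- rbind(out, c(ms, me))
    data.frame(neuron_id = i, start_frame = out[, 1], end_frame = out[, 2],
               peak_frame = out[, 1])
  })
  do.call(rbind, rows)
}

# Greedy F1 of detected peak times against true event times (seconds).
match_f1 <- function(true_s, det_s, tol_s = 0.25) {
  tp <- 0; fn <- 0
  used <- rep(FALSE, length(det_s))
  for (t0 in true_s) {
    j <- which(!used & abs(det_s - t0) <= tol_s)
    if (length(j)) { used[j[1]] <- TRUE; tp <- tp + 1 } else fn <- fn + 1
  }
  c(tp = tp, fp = sum(!used), fn = fn)
}

f1_from_counts <- function(m) {
  unname(2 * m["tp"] / (2 * m["tp"] + m["fp"] + m["fn"]))
}

# One isolated-events recovery run; returns tp/fp/fn against ground truth.
recovery_counts <- function(seed, noise_sd_pct, amplitude_pct = 5,
                            unflagged_only = FALSE, tol_s = 0.25) {
  p <- regime_preset("WT", burst_rate_per_min = 2, spikes_per_burst_mean = 1,
                     amplitude_per_spike_pct = amplitude_pct,
                     noise_sd_pct = noise_sd_pct, drift_amplitude_pct = 0,
                     network_rate_per_min = 0)
  gt <- generate_ground_truth(p, duration_s = 300, n_neurons = 40,
                              seed = seed, min_gap_s = 4)
  det <- detect_transients(render_traces(gt, seed = seed + 1000L))
  if (unflagged_only) {
    det <- det[!det$refractory_excluded & !det$elevated_baseline_excluded, ]
  }
  delay <- ca_kernel_peak_time()
  tot <- c(tp = 0, fp = 0, fn = 0)
  for (i in seq_len(gt$n_neurons)) {
    true_s <- gt$bursts$burst_time_s[gt$bursts$neuron_id == i] + delay
    det_s <- det$peak_frame[det$neuron_id == i] / gt$fs_hz
    tot <- tot + match_f1(true_s, det_s, tol_s)
  }
  tot
}
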