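# Synthetic ground truth, fluorescence rendering and toy movies.

# Intra-burst spike spacing (s). Spikes inside a burst are laid out at a
# fixed 4 Hz so burst size maps deterministically onto both transient
# amplitude (overlapping kernels sum) and duration (longer bursts stay
# elevated longer), the signature of burst firing in the indicator.
INTRA_BURST_ISI_S <- 0.25

# Network-recruited bursts draw their spike count with twice the solo
# mean: synaptically driven network bursts sustain firing longer than
# intrinsic bursts, which is what lets coactivity outlast the 2.5 s
# network-event minimum.
NETWORK_BURST_SPIKE_FACTOR <- 2

#' Generate a ground-truth activity schedule
#'
#' Draws per-neuron burst schedules and a field-of-view-wide network
#' event schedule from independent homogeneous Poisson processes, as
#' specified by an activity-regime preset. Each burst carries a spike
#' count drawn from a shifted Poisson (minimum one spike). Each network
#' event recruits every neuron independently with the preset's
#' participation probability; recruited neurons receive a synchronized
#' burst jittered uniformly by +/-0.1 s so coactivity is realistic but
#' not frame-perfect. Network-recruited bursts draw their spike count
#' with twice the solo mean: synaptically driven network bursts sustain
#' firing longer than intrinsic single-neuron bursts.
#'
#' @param preset a [regime_preset()].
#' @param fs frame rate in Hz (default 8.91, the acquisition default).
#' @param duration_s recording duration in seconds.
#' @param n_neurons number of neurons (default 40, one field of view).
#' @param seed integer seed; identical arguments and seed give
#'   bit-identical output.
#' @param min_gap_s optional minimum spacing (s) between bursts of the
#'   same neuron; bursts closer than this to an accepted earlier burst
#'   are thinned out. Default 0 keeps the pure Poisson process. Useful
#'   for producing isolated, well-separated events for recovery
#'   benchmarks.
#' @param tau_rise_s,tau_decay_s indicator kernel time constants stored
#'   in the schedule and used by [render_traces()].
#' @return a `ground_truth` list: `seed`, `fs_hz`, `n_frames`,
#'   `duration_s`, `n_neurons`, `preset`, `kinetics`, `bursts` (data
#'   frame `neuron_id`, `burst_time_s`, `n_spikes`, `from_network`), and
#'   `network` (data frame `event_time_s`, `participants` list column).
#' @export
#' @examples
#' gt <- generate_ground_truth(regime_preset("WT"), duration_s = 60,
#'                             n_neurons = 5, seed = 1)
#' nrow(gt$bursts)
generate_ground_truth <- function(preset, fs = 8.91, duration_s = 300,
                                  n_neurons = 40, seed,
                                  min_gap_s = 0,
                                  tau_rise_s = 0.1, tau_decay_s = 0.8) {
  if (!inherits(preset, "regime_preset")) preset <- validate_preset(preset)
  stopifnot_scalar_pos(fs, "fs")
  stopifnot_scalar_pos(duration_s, "duration_s")
  if (n_neurons < 1) stop("`n_neurons` must be >= 1", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  n_frames <- round_half_away(duration_s * fs)

  with_seed(seed, {
    bursts <- draw_bursts(preset, duration_s, n_neurons, min_gap_s)
    network <- draw_network_schedule(preset, duration_s, n_neurons)
    # recruit a synchronized, jittered burst in each participant
    if (nrow(network) > 0) {
      extra <- lapply(seq_len(nrow(network)), function(k) {
        ids <- network$participants[[k]]
        if (!length(ids)) return(NULL)
        t0 <- network$event_time_s[k] + runif(length(ids), -0.1, 0.1)
        t0 <- pmin(pmax(t0, 0), duration_s - 1e-9)
        mu <- NETWORK_BURST_SPIKE_FACTOR * preset$spikes_per_burst_mean - 1
        data.frame(neuron_id = ids, burst_time_s = t0,
                   n_spikes = 1L + rpois(length(ids), mu),
                   from_network = TRUE)
      })
      bursts <- rbind(bursts, do.call(rbind, extra))
    }
    bursts <- bursts[order(bursts$neuron_id, bursts$burst_time_s), ,
                     drop = FALSE]
    rownames(bursts) <- NULL

    structure(list(seed = as.integer(seed), fs_hz = fs,
                   n_frames = n_frames, duration_s = duration_s,
                   n_neurons = as.integer(n_neurons),
                   preset = preset,
                   kinetics = list(tau_rise_s = tau_rise_s,
                                   tau_decay_s = tau_decay_s),
                   bursts = bursts, network = network),
              class = "ground_truth")
  })
}

draw_bursts <- function(preset, duration_s, n_neurons, min_gap_s) {
  rate_s <- preset$burst_rate_per_min / 60
  out <- vector("list", n_neurons)
  for (i in seq_len(n_neurons)) {
    n <- rpois(1, rate_s * duration_s)
    times <- sort(runif(n, 0, duration_s))
    if (min_gap_s > 0 && length(times) > 1) {
      keep <- logical(length(times))
      last <- -Inf
      for (k in seq_along(times)) {
        if (times[k] - last >= min_gap_s) {
          keep[k] <- TRUE
          last <- times[k]
        }
      }
      times <- times[keep]
    }
    n <- length(times)
    out[[i]] <- data.frame(
      neuron_id = rep.int(i, n),
      burst_time_s = times,
      n_spikes = if (n) 1L + rpois(n, preset$spikes_per_burst_mean - 1)
                 else integer(0),
      from_network = rep.int(FALSE, n))
  }
  do.call(rbind, out)
}

draw_network_schedule <- function(preset, duration_s, n_neurons) {
  rate_s <- preset$network_rate_per_min / 60
  n <- rpois(1, rate_s * duration_s)
  times <- sort(runif(n, 0, duration_s))
  participants <- lapply(seq_len(n), function(k) {
    which(runif(n_neurons) < preset$participation_prob)
  })
  out <- data.frame(event_time_s = times)
  out$participants <- participants
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth '%s'> %d neurons, %.0f s @ %.2f Hz, %d bursts, %d network events (seed %d)\n",
    x$preset$name, x$n_neurons, x$duration_s, x$fs_hz,
    nrow(x$bursts), nrow(x$network), x$seed))
  invisible(x)
}

#' Indicator response kernel
#'
#' Difference-of-exponentials calcium-indicator impulse response,
#' normalized to unit peak:
#' \eqn{k(t) = (e^{-t/\tau_d} - e^{-t/\tau_r}) / k_{max}} for
#' \eqn{t \ge 0}, zero before the spike. The peak occurs at
#' \eqn{t^* = \tau_r\tau_d/(\tau_d-\tau_r)\,\log(\tau_d/\tau_r)}.
#'
#' @param t times in seconds (may be negative; kernel is causal).
#' @param tau_rise_s,tau_decay_s rise and decay time constants in
#'   seconds; must satisfy `tau_rise_s < tau_decay_s`.
#' @return kernel values, unit peak.
#' @export
ca_kernel <- function(t, tau_rise_s = 0.1, tau_decay_s = 0.8) {
  check_kinetics(tau_rise_s, tau_decay_s)
  tp <- ca_kernel_peak_time(tau_rise_s, tau_decay_s)
  kmax <- exp(-tp / tau_decay_s) - exp(-tp / tau_rise_s)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (exp(-t[pos] / tau_decay_s) - exp(-t[pos] / tau_rise_s)) / kmax
  out
}

#' @rdname ca_kernel
#' @return `ca_kernel_peak_time()`: the spike-to-peak latency in seconds.
#' @export
ca_kernel_peak_time <- function(tau_rise_s = 0.1, tau_decay_s = 0.8) {
  check_kinetics(tau_rise_s, tau_decay_s)
  tau_rise_s * tau_decay_s / (tau_decay_s - tau_rise_s) *
    log(tau_decay_s / tau_rise_s)
}

check_kinetics <- function(tau_rise_s, tau_decay_s) {
  if (tau_rise_s <= 0 || tau_decay_s <= 0 || tau_rise_s >= tau_decay_s) {
    stop("kinetics require 0 < tau_rise_s < tau_decay_s", call. = FALSE)
  }
  invisible(NULL)
}

# Expand a burst schedule into spike times: n_spikes spikes at a fixed
# 20 Hz intra-burst rate starting at the burst time.
burst_spike_times <- function(bursts) {
  if (nrow(bursts) == 0) {
    return(data.frame(neuron_id = integer(0), spike_time_s = numeric(0)))
  }
  reps <- bursts$n_spikes
  data.frame(
    neuron_id = rep.int(bursts$neuron_id, reps),
    spike_time_s = rep.int(bursts$burst_time_s, reps) +
      INTRA_BURST_ISI_S * (sequence(reps) - 1))
}

#' Render dF/F traces from a ground-truth schedule
#'
#' Converts the spike schedule into \eqn{\Delta F/F} traces (percent):
#' every spike contributes one unit-peak difference-of-exponentials
#' kernel scaled to the preset's per-spike amplitude, contributions sum
#' linearly, and a slow sinusoidal drift (period 60 s, random phase per
#' neuron) plus white Gaussian noise are added.
#'
#' @param truth a `ground_truth` from [generate_ground_truth()].
#' @param noise_sd_pct white-noise SD in percent (default: preset value).
#' @param drift_amplitude_pct drift amplitude in percent (default:
#'   preset value).
#' @param seed integer seed for noise and drift phases.
#' @return a [trace_matrix()] at stage `"raw"`.
#' @export
render_traces <- function(truth, noise_sd_pct = NULL,
                          drift_amplitude_pct = NULL, seed) {
  stopifnot(inherits(truth, "ground_truth"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (is.null(noise_sd_pct)) noise_sd_pct <- truth$preset$noise_sd_pct
  if (is.null(drift_amplitude_pct)) {
    drift_amplitude_pct <- truth$preset$drift_amplitude_pct
  }
  if (noise_sd_pct < 0) stop("`noise_sd_pct` must be >= 0", call. = FALSE)
  tau_r <- truth$kinetics$tau_rise_s
  tau_d <- truth$kinetics$tau_decay_s
  check_kinetics(tau_r, tau_d)

  n <- truth$n_neurons
  nf <- truth$n_frames
  fs <- truth$fs_hz
  amp <- truth$preset$amplitude_per_spike_pct
  frame_t <- (seq_len(nf) - 1) / fs

  vals <- matrix(0, nrow = n, ncol = nf)
  spikes <- burst_spike_times(truth$bursts)
  # kernels are summed to the end of the trace (no tail truncation), so
  # superposition is exact and rendering matches a direct convolution
  for (k in seq_len(nrow(spikes))) {
    i <- spikes$neuron_id[k]
    t0 <- spikes$spike_time_s[k]
    j0 <- max(1L, floor(t0 * fs) + 1L)
    if (j0 > nf) next
    jj <- j0:nf
    vals[i, jj] <- vals[i, jj] +
      amp * ca_kernel(frame_t[jj] - t0, tau_r, tau_d)
  }

  with_seed(seed, {
    if (drift_amplitude_pct > 0) {
      phases <- runif(n, 0, 2 * pi)
      drift <- drift_amplitude_pct *
        sin(outer(phases, 2 * pi * frame_t / 60, `+`))
      vals <- vals + drift
    }
    if (noise_sd_pct > 0) {
      vals <- vals + matrix(rnorm(n * nf, sd = noise_sd_pct), n, nf)
    }
  })
  trace_matrix(vals, fs_hz = fs, stage = "raw")
}

#' Render a toy movie stack from traces
#'
#' Renders each trace as a circular soma on a grid: pixel intensity
#' inside ROI i at frame t is
#' `baseline_intensity * (1 + dff(i, t)/100) * falloff(r)`, with a
#' radial falloff from the disc centre; background pixels sit at a
#' constant fraction of the baseline. Optional Gaussian shot noise is
#' added per pixel and frame. Because \eqn{\Delta F/F} is invariant to a
#' static per-pixel gain, the minimum-projection normalisation recovers
#' the input traces exactly when the noise is zero and each trace
#' touches zero.
#'
#' @param traces a [trace_matrix()] (any stage; values are used as
#'   rendered \eqn{\Delta F/F} percent).
#' @param grid_spacing_px centre-to-centre spacing of the soma grid.
#' @param roi_radius_px soma radius in pixels; must satisfy
#'   `2 * roi_radius_px < grid_spacing_px` (no overlap).
#' @param baseline_intensity baseline soma intensity in counts.
#' @param shot_noise_sd per-pixel Gaussian noise SD in counts.
#' @param seed integer seed for the noise.
#' @return list with elements `movie` (a [movie_stack()]) and `rois`
#'   (a [roi_set()] matching the rendered positions).
#' @export
render_movie <- function(traces, grid_spacing_px = 12, roi_radius_px = 4,
                         baseline_intensity = 100, shot_noise_sd = 0,
                         seed = 0) {
  stopifnot(inherits(traces, "trace_matrix"))
  if (2 * roi_radius_px >= grid_spacing_px) {
    stop("ROIs overlap: need 2 * roi_radius_px < grid_spacing_px",
         call. = FALSE)
  }
  stopifnot_scalar_pos(baseline_intensity, "baseline_intensity")
  n <- nrow(traces); nf <- ncol(traces)
  n_col <- ceiling(sqrt(n))
  n_row <- ceiling(n / n_col)
  margin <- grid_spacing_px / 2
  w <- as.integer(ceiling(n_col * grid_spacing_px))
  h <- as.integer(ceiling(n_row * grid_spacing_px))
  cx <- margin + ((seq_len(n) - 1) %% n_col) * grid_spacing_px
  cy <- margin + ((seq_len(n) - 1) %/% n_col) * grid_spacing_px
  rois <- roi_set(neuron_ids(traces), cx, cy, roi_radius_px,
                  image_dim = c(h, w))

  bg <- 0.2 * baseline_intensity
  dat <- array(bg, dim = c(nf, h, w))
  # pixel-centre coordinates (0-based): x = col-1, y = row-1
  for (i in seq_len(n)) {
    px <- which(outer((0:(h - 1) - cy[i])^2, (0:(w - 1) - cx[i])^2, `+`) <=
                  roi_radius_px^2, arr.ind = TRUE)
    r2 <- (px[, 1] - 1 - cy[i])^2 + (px[, 2] - 1 - cx[i])^2
    falloff <- 1 - 0.5 * r2 / roi_radius_px^2
    f <- baseline_intensity * (1 + unclass(traces)[i, ] / 100)
    for (k in seq_len(nrow(px))) {
      dat[, px[k, 1], px[k, 2]] <- f * falloff[k]
    }
  }
  if (shot_noise_sd > 0) {
    dat <- with_seed(seed, {
      dat + array(rnorm(length(dat), sd = shot_noise_sd), dim = dim(dat))
    })
    dat[dat < 0] <- 0
  }
  list(movie = movie_stack(dat, fs_hz = trace_fs(traces)), rois = rois)
}

#' Simulate a complete synthetic field of view
#'
#' Convenience wrapper: draws a ground-truth schedule for the given
#' regime and renders it into \eqn{\Delta F/F} traces.
#'
#' @inheritParams generate_ground_truth
#' @param preset a preset name (`"WT"`, `"KO"`, `"KO_HET"`) or a
#'   [regime_preset()] object.
#' @param ... passed on to [generate_ground_truth()].
#' @return list with `truth` and `traces`.
#' @export
#' @examples
#' fov <- simulate_fov("WT", duration_s = 60, n_neurons = 5, seed = 1)
#' fov$traces
simulate_fov <- function(preset, fs = 8.91, duration_s = 300,
                         n_neurons = 40, seed, ...) {
  if (is.character(preset)) preset <- regime_preset(preset)
  truth <- generate_ground_truth(preset, fs = fs, duration_s = duration_s,
                                 n_neurons = n_neurons, seed = seed, ...)
  traces <- render_traces(truth, seed = seed + 1L)
  list(truth = truth, traces = traces)
}
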