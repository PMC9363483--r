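# Single Ca2+ transient detection and event metrics.
#
# Conventions: frames are 0-based in all reported tables; event
# intervals are half-open [start_frame, end_frame); durations are
# (end - start) / fs. Peaks are detected and amplitudes measured on the
# smoothed trace; event boundaries, AUC and half-decay are measured on
# the baseline-adjusted trace.

#' Default detection parameters
#'
#' Returns the constants of the analysis: a 4-frame moving mean, a 0.5%
#' minimum peak height, a 2 s refractory period, exclusion of events
#' whose amplitude is below 50% of their absolute \eqn{\Delta F/F}, a
#' 0.5% boundary-crossing threshold with a 1% interruption rise, a 15 s
#' / 1st-percentile baseline window, FWHM active intervals gated at 0.5%
#' prominence, a 20% coactive-fraction threshold and a 2.5 s minimum
#' network-event duration.
#'
#' @param ... named overrides of individual fields.
#' @return a `detection_params` list.
#' @export
#' @examples
#' detection_params()$peak_min_height_pct
detection_params <- function(...) {
  p <- list(
    smooth_window_frames = 4L,
    peak_min_height_pct = 0.5,
    peak_criterion = "height",       # or "prominence"
    refractory_s = 2.0,
    elevated_baseline_ratio = 0.5,
    bound_threshold_pct = 0.5,
    interruption_rise_pct = 1.0,
    baseline_window_s = 15,
    baseline_percentile = 1,
    fwhm_min_prominence_pct = 0.5,
    fwhm_reference = "half_prominence",  # or "half_height"
    network_fraction_threshold = 0.20,
    network_min_duration_s = 2.5,
    count_flagged_in_frequency = TRUE
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  num <- c("peak_min_height_pct", "refractory_s", "elevated_baseline_ratio",
           "bound_threshold_pct", "interruption_rise_pct",
           "baseline_window_s", "fwhm_min_prominence_pct",
           "network_fraction_threshold", "network_min_duration_s")
  for (f in num) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || p[[f]] <= 0) {
      stop(sprintf("`%s` must be a positive number", f), call. = FALSE)
    }
  }
  if (p$elevated_baseline_ratio > 1 || p$network_fraction_threshold > 1) {
    stop("ratio parameters must lie in (0, 1]", call. = FALSE)
  }
  p$peak_criterion <- match.arg(p$peak_criterion, c("height", "prominence"))
  p$fwhm_reference <- match.arg(p$fwhm_reference,
                                c("half_prominence", "half_height"))
  class(p) <- "detection_params"
  p
}

# Local maxima of a numeric vector, 0-based frame indices. A maximum is
# a frame strictly greater than both neighbours; a flat-topped maximum
# reports the first frame of the plateau. Trace endpoints never qualify.
find_local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  nz <- which(d != 0)
  if (length(nz) < 2L) return(integer(0))
  s <- sign(d[nz])
  up_down <- which(s[-length(s)] > 0 & s[-1] < 0)
  nz[up_down]  # 1-based index of last rising frame = first plateau frame - 1
  # first plateau frame (1-based) is nz[k] + 1 -> 0-based: nz[k]
}

#' Detect transient peaks on smoothed traces
#'
#' A frame is a peak when the smoothed trace is strictly greater than
#' both neighbours (the first frame of a flat-topped maximum for
#' plateaus) and exceeds the minimum height
#' (`peak_min_height_pct`, strictly). With
#' `peak_criterion = "prominence"` the gate is applied to the peak's
#' topographic prominence instead of its height.
#'
#' @param smoothed a [trace_matrix()] at stage `"smoothed"`.
#' @param params a [detection_params()].
#' @return named list (one element per neuron id) of 0-based peak frame
#'   vectors, ascending.
#' @export
detect_peaks <- function(smoothed, params = detection_params()) {
  stopifnot(inherits(smoothed, "trace_matrix"))
  if (trace_stage(smoothed) != "smoothed") {
    stop("`smoothed` must be at stage 'smoothed'", call. = FALSE)
  }
  ids <- neuron_ids(smoothed)
  out <- lapply(seq_len(nrow(smoothed)), function(i) {
    x <- unclass(smoothed)[i, ]
    pk <- find_local_maxima(x)           # 0-based
    if (!length(pk)) return(integer(0))
    if (params$peak_criterion == "height") {
      pk[x[pk + 1L] > params$peak_min_height_pct]
    } else {
      prom <- vapply(pk, function(p) peak_prominence(x, p), numeric(1))
      pk[prom > params$peak_min_height_pct]
    }
  })
  names(out) <- ids
  out
}

#' Measure event amplitudes
#'
#' Amplitude of peak k is the smoothed-trace value at the peak minus the
#' minimum of the trace over the preceding inter-event interval (frames
#' strictly after the previous peak, up to the peak); the first peak's
#' interval starts at frame 0.
#'
#' @param trace_row numeric vector, one smoothed trace.
#' @param peaks 0-based peak frames, ascending.
#' @return numeric vector of amplitudes in percent, aligned with
#'   `peaks`.
#' @export
measure_amplitude <- function(trace_row, peaks) {
  if (!length(peaks)) return(numeric(0))
  vapply(seq_along(peaks), function(k) {
    from <- if (k == 1L) 0L else peaks[k - 1L] + 1L
    seg <- trace_row[(from + 1L):(peaks[k] + 1L)]  # 1-based slice
    trace_row[peaks[k] + 1L] - min(seg)
  }, numeric(1))
}

#' Apply the exclusion rules to detected peaks
#'
#' Two rules exclude events from amplitude/duration/AUC measurement
#' while keeping them in the peak list (they still count toward event
#' frequency and inter-event intervals): (1) refractory — the peak
#' occurs less than `refractory_s` after the previous peak; (2) elevated
#' baseline — the amplitude is less than `elevated_baseline_ratio`
#' times the peak's absolute \eqn{\Delta F/F} value, indicating already
#' elevated calcium.
#'
#' @param peaks 0-based peak frames, ascending.
#' @param amplitudes from [measure_amplitude()], aligned with `peaks`.
#' @param trace_row the smoothed trace.
#' @param params a [detection_params()].
#' @param fs frame rate in Hz.
#' @return data frame with logical columns `refractory_excluded`,
#'   `elevated_baseline_excluded`.
#' @export
flag_exclusions <- function(peaks, amplitudes, trace_row,
                            params = detection_params(), fs) {
  n <- length(peaks)
  refr <- rep(FALSE, n)
  if (n > 1L) refr[-1L] <- diff(peaks) / fs < params$refractory_s
  elev <- amplitudes <
    params$elevated_baseline_ratio * trace_row[peaks + 1L]
  data.frame(refractory_excluded = refr,
             elevated_baseline_excluded = as.logical(elev))
}

#' Delineate event boundaries around a peak
#'
#' On the baseline-adjusted trace, the event start is the last upward
#' crossing of `bound_threshold_pct` before the peak (the first frame at
#' or above the threshold). Scanning forward from the peak while
#' tracking the running minimum, the event ends at the first frame at or
#' below the threshold; if instead the trace rises more than
#' `interruption_rise_pct` above the running minimum first — the
#' signature of a following event — the event ends at the
#' running-minimum frame. Both bounds are 0-based and the interval is
#' half-open `[start, end)`. If either bound is not found before the
#' trace edge the event has no clear initiation or termination and
#' `NULL` is returned.
#'
#' @param adj_row numeric vector, one baseline-adjusted trace.
#' @param peak_frame 0-based peak frame.
#' @param params a [detection_params()].
#' @return `list(start_frame, end_frame)` or `NULL` when undefined.
#' @export
delineate_event <- function(adj_row, peak_frame,
                            params = detection_params()) {
  thr <- params$bound_threshold_pct
  n <- length(adj_row)
  p <- peak_frame + 1L                    # 1-based
  if (p < 1L || p > n) stop("peak outside trace", call. = FALSE)
  if (adj_row[p] < thr) return(NULL)

  # backward: first frame at/above threshold of the last upward crossing
  s <- p
  while (s > 1L && adj_row[s - 1L] >= thr) s <- s - 1L
  if (s == 1L) return(NULL)               # never below threshold before peak

  # forward: threshold crossing or interruption
  run_min <- adj_row[p]; run_min_at <- p
  e <- NA_integer_
  j <- p + 1L
  while (j <= n) {
    if (adj_row[j] <= thr) { e <- j; break }
    if (adj_row[j] < run_min) { run_min <- adj_row[j]; run_min_at <- j }
    if (adj_row[j] - run_min > params$interruption_rise_pct) {
      e <- run_min_at; break
    }
    j <- j + 1L
  }
  if (is.na(e)) return(NULL)
  list(start_frame = s - 1L, end_frame = e - 1L)
}

#' Area under the curve of an event
#'
#' Trapezoidal integral of the baseline-adjusted trace over the event's
#' samples `[start_frame, end_frame)`, scaled by the frame interval.
#' Units: percent times seconds.
#'
#' @param adj_row baseline-adjusted trace.
#' @param start_frame,end_frame 0-based half-open bounds.
#' @param fs frame rate in Hz.
#' @return AUC in %*s.
#' @export
compute_auc <- function(adj_row, start_frame, end_frame, fs) {
  n <- length(adj_row)
  if (start_frame < 0 || end_frame > n || end_frame <= start_frame) {
    stop("event bounds outside the trace", call. = FALSE)
  }
  seg <- adj_row[(start_frame + 1L):end_frame]
  if (length(seg) < 2L) return(0)
  pracma::trapz(seg) / fs
}

#' Inter-event intervals
#'
#' Time between consecutive transient peaks of one neuron.
#'
#' @param peaks 0-based peak frames, ascending (all peaks, including
#'   flagged ones).
#' @param fs frame rate in Hz.
#' @return numeric vector of length `length(peaks) - 1` (empty for
#'   fewer than two peaks), in seconds.
#' @export
compute_iei <- function(peaks, fs) {
  if (length(peaks) < 2L) return(numeric(0))
  diff(peaks) / fs
}

#' Half-decay time of an event
#'
#' Time from the peak to the first subsequent crossing of
#' `peak value - amplitude / 2`, linearly interpolated between the
#' bracketing frames. The search runs to the event end when bounds are
#' defined, otherwise to the trace edge; `NA` when the half level is
#' never reached.
#'
#' @param adj_row baseline-adjusted trace.
#' @param peak_frame 0-based peak frame.
#' @param amplitude event amplitude in percent.
#' @param fs frame rate in Hz.
#' @param end_frame optional 0-based exclusive search bound.
#' @return seconds, or `NA_real_`.
#' @export
half_decay_time <- function(adj_row, peak_frame, amplitude, fs,
                            end_frame = NULL) {
  p <- peak_frame + 1L
  half <- adj_row[p] - amplitude / 2
  last <- if (is.null(end_frame)) length(adj_row) else end_frame
  if (p >= last) return(NA_real_)
  for (j in (p + 1L):last) {
    if (adj_row[j] <= half) {
      # interpolate between frames j-1 and j
      frac <- (adj_row[j - 1L] - half) / (adj_row[j - 1L] - adj_row[j])
      return(((j - 1L - p) + frac) / fs)
    }
  }
  NA_real_
}

#' Detect and measure all Ca2+ transients in a field of view
#'
#' Full single-event analysis: smooths raw traces with the moving mean,
#' detects peaks and measures amplitudes on the smoothed traces, applies
#' the refractory and elevated-baseline exclusion rules, then performs
#' the windowed-percentile baseline adjustment and measures event
#' boundaries, duration, AUC and half-decay on the adjusted traces.
#' Flagged events and events without clear bounds keep their peak (they
#' count toward frequency and inter-event intervals) but carry no
#' duration/AUC measurements.
#'
#' @param traces a [trace_matrix()] at stage `"raw"` or `"smoothed"`.
#' @param params a [detection_params()].
#' @return a `transient_table` data frame, one row per detected peak,
#'   ordered by (`neuron_id`, `peak_frame`), with columns `neuron_id`,
#'   `peak_frame`, `peak_dff_pct`, `amplitude_pct`, `start_frame`,
#'   `end_frame`, `duration_s`, `auc_pct_s`, `iei_prev_s`,
#'   `half_decay_s`, `refractory_excluded`,
#'   `elevated_baseline_excluded`, `no_clear_bounds`. Undefined values
#'   are `NA`. Attributes: `fs_hz`, `n_frames`, `neuron_ids`, `params`.
#' @export
#' @examples
#' fov <- simulate_fov("WT", duration_s = 60, n_neurons = 4, seed = 2)
#' tr <- detect_transients(fov$traces)
#' head(tr)
detect_transients <- function(traces, params = detection_params()) {
  stopifnot(inherits(traces, "trace_matrix"))
  if (trace_stage(traces) == "raw") {
    traces <- smooth_traces(traces, params$smooth_window_frames)
  }
  if (trace_stage(traces) != "smoothed") {
    stop("`traces` must be at stage 'raw' or 'smoothed'", call. = FALSE)
  }
  fs <- trace_fs(traces)
  adjusted <- adjust_baseline(traces, window_s = params$baseline_window_s,
                              percentile = params$baseline_percentile)
  ids <- neuron_ids(traces)
  peaks_by_neuron <- detect_peaks(traces, params)

  rows <- lapply(seq_along(ids), function(i) {
    x <- unclass(traces)[i, ]
    a <- unclass(adjusted)[i, ]
    pk <- peaks_by_neuron[[i]]
    n <- length(pk)
    if (!n) return(NULL)
    amp <- measure_amplitude(x, pk)
    flags <- flag_exclusions(pk, amp, x, params, fs)
    iei <- c(NA_real_, compute_iei(pk, fs))
    df <- data.frame(
      neuron_id = ids[i], peak_frame = pk, peak_dff_pct = x[pk + 1L],
      amplitude_pct = amp,
      start_frame = NA_integer_, end_frame = NA_integer_,
      duration_s = NA_real_, auc_pct_s = NA_real_,
      iei_prev_s = iei, half_decay_s = NA_real_,
      refractory_excluded = flags$refractory_excluded,
      elevated_baseline_excluded = flags$elevated_baseline_excluded,
      no_clear_bounds = FALSE)
    for (k in seq_len(n)) {
      if (df$refractory_excluded[k] || df$elevated_baseline_excluded[k]) {
        # excluded from amplitude/duration/AUC analysis
        df$amplitude_pct[k] <- NA_real_
        next
      }
      b <- delineate_event(a, pk[k], params)
      if (is.null(b)) {
        df$no_clear_bounds[k] <- TRUE
        next
      }
      df$start_frame[k] <- b$start_frame
      df$end_frame[k] <- b$end_frame
      df$duration_s[k] <- (b$end_frame - b$start_frame) / fs
      df$auc_pct_s[k] <- compute_auc(a, b$start_frame, b$end_frame, fs)
      df$half_decay_s[k] <- half_decay_time(a, pk[k], amp[k], fs,
                                            end_frame = b$end_frame)
    }
    df
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      neuron_id = integer(0), peak_frame = integer(0),
      peak_dff_pct = numeric(0), amplitude_pct = numeric(0),
      start_frame = integer(0), end_frame = integer(0),
      duration_s = numeric(0), auc_pct_s = numeric(0),
      iei_prev_s = numeric(0), half_decay_s = numeric(0),
      refractory_excluded = logical(0),
      elevated_baseline_excluded = logical(0),
      no_clear_bounds = logical(0))
  }
  out <- out[order(out$neuron_id, out$peak_frame), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fs_hz") <- fs
  attr(out, "n_frames") <- ncol(traces)
  attr(out, "neuron_ids") <- ids
  attr(out, "params") <- params
  class(out) <- c("transient_table", "data.frame")
  out
}
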