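# Network synchrony: FWHM active intervals, coactive fraction, events.

# Topographic prominence of the local maximum at 0-based frame `p`:
# extend left/right until a strictly higher value; the base on each
# side is the minimum over that span; prominence is the peak value
# minus the higher of the two bases.
peak_prominence <- function(x, p) {
  n <- length(x)
  i <- p + 1L
  v <- x[i]
  l <- i
  while (l > 1L && x[l - 1L] <= v) l <- l - 1L
  left_base <- min(x[l:i])
  r <- i
  while (r < n && x[r + 1L] <= v) r <- r + 1L
  right_base <- min(x[i:r])
  v - max(left_base, right_base)
}

#' Per-neuron active intervals (full width at half maximum)
#'
#' A neuron is considered active around every local maximum of its
#' smoothed trace whose topographic prominence is at least
#' `fwhm_min_prominence_pct`. The active interval is the full width at
#' half maximum: the span between the left and right crossings of the
#' reference level `peak - prominence/2` (or `peak/2` with
#' `fwhm_reference = "half_height"`), linearly interpolated between
#' frames and then rounded outward so the neuron is active for every
#' frame the half-height span touches. Overlapping or adjacent
#' intervals of one neuron are merged.
#'
#' @param smoothed a [trace_matrix()] at stage `"smoothed"`.
#' @param params a [detection_params()].
#' @return data frame `neuron_id`, `start_frame`, `end_frame`
#'   (half-open, 0-based), `peak_frame` (the source peak; for merged
#'   intervals the most prominent one).
#' @export
active_intervals <- function(smoothed, params = detection_params()) {
  stopifnot(inherits(smoothed, "trace_matrix"))
  if (trace_stage(smoothed) != "smoothed") {
    stop("`smoothed` must be at stage 'smoothed'", call. = FALSE)
  }
  ids <- neuron_ids(smoothed)
  nf <- ncol(smoothed)
  rows <- lapply(seq_along(ids), function(i) {
    x <- unclass(smoothed)[i, ]
    pk <- find_local_maxima(x)
    if (!length(pk)) return(NULL)
    prom <- vapply(pk, function(p) peak_prominence(x, p), numeric(1))
    keep <- prom >= params$fwhm_min_prominence_pct
    pk <- pk[keep]; prom <- prom[keep]
    if (!length(pk)) return(NULL)
    iv <- lapply(seq_along(pk), function(k) {
      ref <- if (params$fwhm_reference == "half_prominence") {
        x[pk[k] + 1L] - prom[k] / 2
      } else {
        x[pk[k] + 1L] / 2
      }
      fwhm_bounds(x, pk[k], ref, nf)
    })
    data.frame(neuron_id = ids[i],
               start_frame = vapply(iv, `[[`, integer(1), "start"),
               end_frame = vapply(iv, `[[`, integer(1), "end"),
               peak_frame = pk, prominence = prom)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(neuron_id = integer(0), start_frame = integer(0),
                      end_frame = integer(0), peak_frame = integer(0)))
  }
  out <- merge_neuron_intervals(out)
  rownames(out) <- NULL
  out
}

# Half-height crossings around a peak, interpolated then rounded
# outward; truncated at the trace edges if the level is never crossed
# (possible in half-height mode).
fwhm_bounds <- function(x, p, ref, nf) {
  i <- p + 1L
  # left: largest j < i with x[j] < ref
  j <- i - 1L
  while (j >= 1L && x[j] >= ref) j <- j - 1L
  if (j < 1L) {
    s <- 0L
  } else {
    xc <- (j - 1L) + (ref - x[j]) / (x[j + 1L] - x[j])  # 0-based position
    s <- as.integer(floor(xc))
  }
  # right: smallest j > i with x[j] < ref
  j <- i + 1L
  while (j <= nf && x[j] >= ref) j <- j + 1L
  if (j > nf) {
    e <- nf
  } else {
    xc <- (j - 2L) + (x[j - 1L] - ref) / (x[j - 1L] - x[j])  # 0-based
    e <- as.integer(ceiling(xc)) + 1L  # half-open
  }
  list(start = s, end = min(e, nf))
}

merge_neuron_intervals <- function(df) {
  pieces <- lapply(split(df, df$neuron_id), function(d) {
    d <- d[order(d$start_frame), , drop = FALSE]
    s <- d$start_frame; e <- d$end_frame
    pkf <- d$peak_frame; pr <- d$prominence
    out_s <- s[1]; out_e <- e[1]; out_p <- pkf[1]; out_pr <- pr[1]
    res <- list()
    for (k in seq_len(nrow(d))[-1]) {
      if (s[k] <= out_e) {               # overlap or adjacency: merge
        out_e <- max(out_e, e[k])
        if (pr[k] > out_pr) { out_p <- pkf[k]; out_pr <- pr[k] }
      } else {
        res[[length(res) + 1L]] <- c(out_s, out_e, out_p)
        out_s <- s[k]; out_e <- e[k]; out_p <- pkf[k]; out_pr <- pr[k]
      }
    }
    res[[length(res) + 1L]] <- c(out_s, out_e, out_p)
    m <- do.call(rbind, res)
    data.frame(neuron_id = d$neuron_id[1], start_frame = as.integer(m[, 1]),
               end_frame = as.integer(m[, 2]), peak_frame = as.integer(m[, 3]))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Fraction of simultaneously active neurons per frame
#'
#' For every frame, the number of distinct neurons whose merged active
#' intervals cover that frame, divided by the number of neurons in the
#' field of view.
#'
#' @param intervals data frame from [active_intervals()] (half-open,
#'   0-based `start_frame`/`end_frame`).
#' @param n_neurons total neurons in the FOV.
#' @param n_frames recording length in frames.
#' @return numeric vector of length `n_frames`, values in `[0, 1]`.
#' @export
coactive_fraction <- function(intervals, n_neurons, n_frames) {
  stopifnot(n_neurons >= 1, n_frames >= 1)
  if (nrow(intervals)) {
    if (any(intervals$start_frame < 0 | intervals$end_frame > n_frames |
              intervals$start_frame >= intervals$end_frame)) {
      stop("interval outside [0, n_frames) or empty", call. = FALSE)
    }
  }
  counts <- numeric(n_frames + 1L)
  # merged per-neuron intervals never double-count a neuron
  for (k in seq_len(nrow(intervals))) {
    s <- intervals$start_frame[k]; e <- intervals$end_frame[k]
    counts[s + 1L] <- counts[s + 1L] + 1
    counts[e + 1L] <- counts[e + 1L] - 1
  }
  cumsum(counts)[seq_len(n_frames)] / n_neurons
}

#' Detect network events from the coactive fraction
#'
#' A network event is a maximal run of frames during which the coactive
#' fraction strictly exceeds `network_fraction_threshold` (frames at
#' exactly the threshold do not count). Candidate events shorter than
#' `network_min_duration_s` are excluded.
#'
#' @param fraction per-frame coactive fraction from
#'   [coactive_fraction()].
#' @param params a [detection_params()].
#' @param fs frame rate in Hz.
#' @return data frame `start_frame`, `end_frame` (half-open, 0-based),
#'   `duration_s`, `peak_coactive_fraction`.
#' @export
detect_network_events <- function(fraction, params = detection_params(),
                                  fs) {
  stopifnot(all(fraction >= 0 & fraction <= 1 + 1e-12))
  above <- fraction > params$network_fraction_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(start_frame = starts[keep] - 1L,
                    end_frame = ends[keep])      # half-open, 0-based
  out$duration_s <- (out$end_frame - out$start_frame) / fs
  out <- out[out$duration_s >= params$network_min_duration_s, ,
             drop = FALSE]
  out$peak_coactive_fraction <- vapply(seq_len(nrow(out)), function(k) {
    max(fraction[(out$start_frame[k] + 1L):out$end_frame[k]])
  }, numeric(1))
  rownames(out) <- NULL
  out
}

#' Neuron participation in a network event
#'
#' Percentage of neurons in the field of view that were active at any
#' time during the event window.
#'
#' @param intervals data frame from [active_intervals()].
#' @param event one row of the [detect_network_events()] table (or any
#'   list with `start_frame`, `end_frame`).
#' @param n_neurons total neurons in the FOV.
#' @return percent in `(0, 100]`.
#' @export
participation <- function(intervals, event, n_neurons) {
  overlap <- intervals$start_frame < event$end_frame &
    intervals$end_frame > event$start_frame
  100 * length(unique(intervals$neuron_id[overlap])) / n_neurons
}

#' Percentage of the recording spent in network events
#'
#' @param events data frame from [detect_network_events()]
#'   (non-overlapping by construction).
#' @param n_frames recording length in frames.
#' @param fs frame rate in Hz.
#' @return percent of the recording duration in `[0, 100]`.
#' @export
network_time_fraction <- function(events, n_frames, fs) {
  if (!nrow(events)) return(0)
  100 * sum(events$duration_s) / (n_frames / fs)
}

#' Full network-synchrony analysis of a field of view
#'
#' Convenience wrapper: computes active intervals, the coactive
#' fraction, network events with per-event participation, and the
#' time-in-network summary.
#'
#' @param smoothed a [trace_matrix()] at stage `"smoothed"`.
#' @param params a [detection_params()].
#' @return list with `intervals`, `fraction`, `events` (with a
#'   `participation_pct` column), `network_time_pct`.
#' @export
analyze_network <- function(smoothed, params = detection_params()) {
  iv <- active_intervals(smoothed, params)
  n <- nrow(smoothed); nf <- ncol(smoothed)
  frac <- coactive_fraction(iv, n, nf)
  ev <- detect_network_events(frac, params, trace_fs(smoothed))
  ev$participation_pct <- vapply(seq_len(nrow(ev)), function(k) {
    participation(iv, ev[k, ], n)
  }, numeric(1))
  list(intervals = iv, fraction = frac, events = ev,
       network_time_pct = network_time_fraction(ev, nf, trace_fs(smoothed)))
}
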