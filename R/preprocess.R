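# Movie -> dF/F -> per-ROI traces, smoothing and baseline adjustment.

#' Normalise a movie stack to dF/F percent
#'
#' The per-pixel baseline is the minimum-intensity projection over all
#' frames; the output is `100 * (F - Fmin) / Fmin` per pixel and frame.
#' A rolling baseline is deliberately not used: hyperactive cultures can
#' contain few quiescent frames, and the global per-pixel minimum is the
#' only estimate guaranteed to sit at or below the true baseline.
#'
#' @param movie a [movie_stack()] in intensity counts; every pixel's
#'   minimum over frames must be positive.
#' @return a [movie_stack()] with `units = "dff_pct"`; values are
#'   non-negative and attain 0 at each pixel's argmin frame.
#' @export
compute_dff_movie <- function(movie) {
  stopifnot(inherits(movie, "movie_stack"))
  if (attr(movie, "units") != "counts") {
    stop("`movie` is already normalised", call. = FALSE)
  }
  fmin <- apply(unclass(movie), c(2, 3), min)
  n_bad <- sum(fmin <= 0)
  if (n_bad > 0) {
    stop(sprintf(
      "degenerate baseline: %d pixel(s) have minimum intensity <= 0; cannot divide",
      n_bad), call. = FALSE)
  }
  nf <- dim(movie)[1]
  base <- aperm(array(fmin, dim = c(dim(fmin), nf)), c(3, 1, 2))
  out <- 100 * (unclass(movie) - base) / base
  movie_stack(out, fs_hz = attr(movie, "fs_hz"), units = "dff_pct")
}

#' Extract per-ROI mean traces from a dF/F movie
#'
#' Each trace value is the arithmetic mean of \eqn{\Delta F/F} over all
#' pixels whose centre lies within the ROI disc (radius inclusive).
#' Rows follow ascending ROI id order.
#'
#' @param dff_movie a [movie_stack()] with `units = "dff_pct"`.
#' @param rois a [roi_set()]; every disc must lie inside the movie frame.
#' @return a [trace_matrix()] at stage `"raw"` (zero rows for an empty
#'   ROI set is not representable; an empty set returns a 0 x frames
#'   plain matrix wrapped with the movie's frame rate).
#' @export
extract_traces <- function(dff_movie, rois) {
  stopifnot(inherits(dff_movie, "movie_stack"))
  if (attr(dff_movie, "units") != "dff_pct") {
    stop("`dff_movie` must be normalised first (see compute_dff_movie)",
         call. = FALSE)
  }
  d <- dim(dff_movie)
  nf <- d[1]; h <- d[2]; w <- d[3]
  if (nrow(rois) == 0) {
    m <- matrix(numeric(0), nrow = 0, ncol = nf)
    return(structure(m, fs_hz = attr(dff_movie, "fs_hz"), stage = "raw",
                     class = c("trace_matrix", "matrix", "array")))
  }
  ord <- order(rois$id)
  rois <- rois[ord, , drop = FALSE]
  vals <- matrix(0, nrow = nrow(rois), ncol = nf)
  flat <- matrix(unclass(dff_movie), nrow = nf)  # frames x (h*w), column-major y fastest
  for (k in seq_len(nrow(rois))) {
    cx <- rois$center_x_px[k]; cy <- rois$center_y_px[k]
    r <- rois$radius_px[k]
    if (cx - r < 0 || cx + r > w - 1 || cy - r < 0 || cy + r > h - 1) {
      stop(sprintf("ROI %d extends outside the image", rois$id[k]),
           call. = FALSE)
    }
    # pixel centres: y = row-1 (0-based), x = col-1
    sel <- which(outer((0:(h - 1) - cy)^2, (0:(w - 1) - cx)^2, `+`) <= r^2)
    vals[k, ] <- rowMeans(flat[, sel, drop = FALSE])
  }
  trace_matrix(vals, fs_hz = attr(dff_movie, "fs_hz"), stage = "raw",
               neuron_ids = rois$id)
}

#' Smooth traces with a centred moving mean
#'
#' Applies a moving mean of width `window` frames to every trace. For an
#' even window the span covers `window/2` frames before and
#' `window/2 - 1` frames after the current frame; at the trace edges the
#' mean is taken over the available samples only (shrinking window, no
#' padding), so no artificial values enter the threshold logic
#' downstream. Output length equals input length.
#'
#' @param traces a [trace_matrix()] at stage `"raw"`.
#' @param window window width in frames (default 4).
#' @return a [trace_matrix()] at stage `"smoothed"`.
#' @export
smooth_traces <- function(traces, window = 4L) {
  stopifnot(inherits(traces, "trace_matrix"))
  if (trace_stage(traces) != "raw") {
    stop("`traces` must be at stage 'raw'", call. = FALSE)
  }
  if (window < 1) stop("`window` must be >= 1", call. = FALSE)
  window <- as.integer(window)
  vals <- t(apply(unclass(traces), 1, moving_mean, window = window))
  if (ncol(traces) == 1L) vals <- matrix(vals, ncol = 1L)
  trace_matrix(vals, fs_hz = trace_fs(traces), stage = "smoothed",
               neuron_ids = neuron_ids(traces))
}

# Centred moving mean, even windows lean one frame into the past,
# shrinking at the edges. O(n) via cumulative sums.
moving_mean <- function(x, window) {
  n <- length(x)
  if (window == 1L || n == 1L) return(x)
  before <- window %/% 2L
  after <- window - before - 1L
  i <- seq_len(n)
  lo <- pmax(i - before, 1L)
  hi <- pmin(i + after, n)
  cs <- c(0, cumsum(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Remove slow baseline drift by windowed-percentile subtraction
#'
#' Partitions each trace into consecutive non-overlapping windows of
#' `round(window_s * fs)` frames (the last window may be shorter), takes
#' the `percentile`-th percentile of each window as a baseline anchor at
#' the window centre, linearly interpolates between anchors (constant
#' extrapolation beyond the first/last anchor) and subtracts the result.
#' This shifts the 1st percentile of the trace within each window to
#' approximately zero so that event durations and areas do not inherit
#' preceding bouts of activity.
#'
#' If the trace is shorter than one window the function falls back to a
#' single global percentile shift and emits a message.
#'
#' @param traces a [trace_matrix()] at stage `"smoothed"`.
#' @param window_s window length in seconds (default 15).
#' @param percentile percentile used as the baseline estimate
#'   (default 1).
#' @return a [trace_matrix()] at stage `"baseline_adjusted"`.
#' @export
adjust_baseline <- function(traces, window_s = 15, percentile = 1) {
  stopifnot(inherits(traces, "trace_matrix"))
  if (trace_stage(traces) != "smoothed") {
    stop("`traces` must be at stage 'smoothed'", call. = FALSE)
  }
  fs <- trace_fs(traces)
  win <- round_half_away(window_s * fs)
  if (win < 2) stop("window_s * fs must be >= 2 frames", call. = FALSE)
  nf <- ncol(traces)
  vals <- unclass(traces)
  if (nf < win) {
    message(sprintf(
      "trace (%d frames) shorter than one %d-frame window; applying a single global %g%%-percentile shift",
      nf, win, percentile))
    shift <- apply(vals, 1, quantile, probs = percentile / 100, names = FALSE)
    out <- vals - shift
  } else {
    starts <- seq(1L, nf, by = win)
    ends <- pmin(starts + win - 1L, nf)
    centers <- (starts + ends) / 2
    out <- vals
    for (i in seq_len(nrow(vals))) {
      anchors <- vapply(seq_along(starts), function(k) {
        quantile(vals[i, starts[k]:ends[k]], probs = percentile / 100,
                 names = FALSE)
      }, numeric(1))
      base <- if (length(anchors) == 1L) rep(anchors, nf) else {
        approx(x = centers, y = anchors, xout = seq_len(nf), rule = 2)$y
      }
      out[i, ] <- vals[i, ] - base
    }
  }
  trace_matrix(out, fs_hz = fs, stage = "baseline_adjusted",
               neuron_ids = neuron_ids(traces))
}
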