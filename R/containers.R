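# Lightweight S3 containers for the pipeline stages.

#' Construct a trace matrix
#'
#' A `trace_matrix` holds \eqn{\Delta F/F} time series in percent units
#' for all ROIs of one field of view: one row per neuron, one column per
#' frame. The object carries the frame rate and a processing-stage tag;
#' stages advance only `raw` -> `smoothed` -> `baseline_adjusted`.
#'
#' @param values numeric matrix, neurons x frames, \eqn{\Delta F/F} in
#'   percent. All values must be finite.
#' @param fs_hz frame rate in Hz.
#' @param stage one of `"raw"`, `"smoothed"`, `"baseline_adjusted"`.
#' @param neuron_ids optional integer ids (default `seq_len(nrow)`), used
#'   as row names.
#' @return a `trace_matrix` object.
#' @export
#' @examples
#' tm <- trace_matrix(matrix(0, 2, 100), fs_hz = 8.91)
#' dim(tm)
trace_matrix <- function(values, fs_hz, stage = "raw", neuron_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (neurons x frames)",
         call. = FALSE)
  }
  if (ncol(values) < 1L) stop("need at least one frame", call. = FALSE)
  if (!all(is.finite(values))) {
    stop("trace values must all be finite", call. = FALSE)
  }
  stopifnot_scalar_pos(fs_hz, "fs_hz")
  stage <- match.arg(stage, c("raw", "smoothed", "baseline_adjusted"))
  if (is.null(neuron_ids)) neuron_ids <- seq_len(nrow(values))
  if (length(neuron_ids) != nrow(values)) {
    stop("`neuron_ids` length must match the number of rows", call. = FALSE)
  }
  rownames(values) <- neuron_ids
  structure(values,
            fs_hz = fs_hz, stage = stage,
            class = c("trace_matrix", "matrix", "array"))
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix> %d neurons x %d frames @ %.3f Hz, stage '%s'\n",
              nrow(x), ncol(x), attr(x, "fs_hz"), attr(x, "stage")))
  invisible(x)
}

#' Frame rate and stage accessors
#' @param x a `trace_matrix` or `movie_stack`.
#' @return `trace_fs()` the frame rate in Hz; `trace_stage()` the stage tag.
#' @export
trace_fs <- function(x) attr(x, "fs_hz")

#' @rdname trace_fs
#' @export
trace_stage <- function(x) attr(x, "stage")

#' Neuron ids of a trace matrix
#' @param x a `trace_matrix`.
#' @return integer vector of neuron ids (row order).
#' @export
neuron_ids <- function(x) as.integer(rownames(x))

#' Construct a movie stack
#'
#' A `movie_stack` is a 3-D array (frames x height x width) of
#' non-negative intensities (arbitrary camera units, or percent when it
#' holds a \eqn{\Delta F/F} movie) with an attached frame rate.
#'
#' @param data numeric array frames x height x width; finite,
#'   non-negative, at least 2 frames.
#' @param fs_hz frame rate in Hz.
#' @param units `"counts"` for raw intensity or `"dff_pct"` after
#'   normalisation.
#' @return a `movie_stack` object.
#' @export
movie_stack <- function(data, fs_hz, units = "counts") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-D array (frames x height x width)",
         call. = FALSE)
  }
  if (dim(data)[1] < 2L) {
    stop("a movie stack needs at least 2 frames", call. = FALSE)
  }
  if (!all(is.finite(data))) stop("movie values must be finite", call. = FALSE)
  if (units == "counts" && any(data < 0)) {
    stop("movie intensities must be non-negative", call. = FALSE)
  }
  stopifnot_scalar_pos(fs_hz, "fs_hz")
  units <- match.arg(units, c("counts", "dff_pct"))
  structure(data, fs_hz = fs_hz, units = units,
            class = c("movie_stack", "array"))
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<movie_stack> %d frames x %d x %d px @ %.3f Hz [%s]\n",
              d[1], d[2], d[3], attr(x, "fs_hz"), attr(x, "units")))
  invisible(x)
}

#' Construct a set of circular ROIs
#'
#' Circular regions of interest over neuronal somata. Coordinates are
#' 0-based pixel positions of the disc centre; a pixel belongs to an ROI
#' when its centre lies within the disc (radius inclusive).
#'
#' @param id integer ids, unique.
#' @param center_x_px,center_y_px disc centres in pixels (0-based).
#' @param radius_px disc radii in pixels.
#' @param image_dim optional `c(height, width)`; when given, every disc
#'   must lie fully inside the image.
#' @return a `roi_set` data frame.
#' @export
roi_set <- function(id, center_x_px, center_y_px, radius_px,
                    image_dim = NULL) {
  n <- length(id)
  if (anyDuplicated(id)) stop("ROI ids must be unique", call. = FALSE)
  if (length(center_x_px) != n || length(center_y_px) != n) {
    stop("centre coordinates must match `id` length", call. = FALSE)
  }
  radius_px <- rep_len(radius_px, n)
  if (any(radius_px <= 0)) stop("ROI radii must be positive", call. = FALSE)
  df <- data.frame(id = as.integer(id),
                   center_x_px = as.numeric(center_x_px),
                   center_y_px = as.numeric(center_y_px),
                   radius_px = as.numeric(radius_px))
  if (!is.null(image_dim)) {
    h <- image_dim[1]; w <- image_dim[2]
    inside <- df$center_x_px - df$radius_px >= 0 &
      df$center_x_px + df$radius_px <= w - 1 &
      df$center_y_px - df$radius_px >= 0 &
      df$center_y_px + df$radius_px <= h - 1
    if (!all(inside)) {
      stop(sprintf("%d ROI(s) extend outside the %d x %d image",
                   sum(!inside), h, w), call. = FALSE)
    }
    attr(df, "image_dim") <- as.integer(image_dim)
  }
  class(df) <- c("roi_set", "data.frame")
  df
}
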