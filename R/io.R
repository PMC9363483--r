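# Delimited-table, JSON and TIFF input/output.
#
# All tables are tab-separated with '#'-prefixed metadata header lines
# (key: value) so frame rate and processing stage travel with the data.

write_meta <- function(con, meta) {
  for (k in names(meta)) writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
}

read_meta <- function(path) {
  lines <- readLines(path, n = 50L)
  ml <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (l in ml) {
    kv <- sub("^# ", "", l)
    k <- sub(":.*$", "", kv)
    meta[[k]] <- trimws(sub("^[^:]+:", "", kv))
  }
  meta
}

#' Read and write trace tables
#'
#' Traces are stored as a tab-separated table: metadata lines
#' (`# fs_hz: ...`, `# stage: ...`), a header row, then one row per
#' neuron (`neuron_id` followed by one column per frame).
#'
#' @param traces a [trace_matrix()].
#' @param path file path.
#' @return `read_traces()` returns a [trace_matrix()];
#'   `write_traces()` returns `path` invisibly.
#' @export
write_traces <- function(traces, path) {
  stopifnot(inherits(traces, "trace_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  write_meta(con, list(fs_hz = format(trace_fs(traces), digits = 15),
                       stage = trace_stage(traces)))
  df <- data.frame(neuron_id = neuron_ids(traces), unclass(traces))
  colnames(df) <- c("neuron_id", paste0("f", seq_len(ncol(traces)) - 1L))
  write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  meta <- read_meta(path)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  vals <- as.matrix(df[, -1, drop = FALSE])
  dimnames(vals) <- NULL
  trace_matrix(vals, fs_hz = as.numeric(meta$fs_hz),
               stage = meta$stage %||% "raw",
               neuron_ids = df$neuron_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write ROI tables
#'
#' Tab-separated table with columns `id`, `center_x_px`, `center_y_px`,
#' `radius_px` (0-based pixel coordinates).
#'
#' @param rois a [roi_set()].
#' @param path file path.
#' @return `read_rois()` returns a [roi_set()].
#' @export
write_rois <- function(rois, path) {
  write.table(as.data.frame(rois), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  roi_set(df$id, df$center_x_px, df$center_y_px, df$radius_px)
}

#' Write an event or summary table
#'
#' Tab-separated, `#`-prefixed metadata, logical flags as 0/1, `NA`
#' (undefined) values as empty cells.
#'
#' @param df a data frame (e.g. a `transient_table`).
#' @param path file path.
#' @param meta optional named list of metadata lines.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(attr(df, "fs_hz")) && is.null(meta$fs_hz)) {
    meta$fs_hz <- format(attr(df, "fs_hz"), digits = 15)
  }
  if (length(meta)) write_meta(con, meta)
  out <- as.data.frame(df)
  for (j in seq_along(out)) {
    if (is.logical(out[[j]])) out[[j]] <- as.integer(out[[j]])
  }
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             na.strings = "")
}

#' Serialize a ground-truth schedule to JSON
#'
#' The schedule round-trips exactly (seed, rates, burst and network
#' tables) so synthetic experiments can be archived and replayed.
#'
#' @param truth a `ground_truth`.
#' @param path file path.
#' @return `read_ground_truth()` returns a `ground_truth`.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  x <- unclass(truth)
  x$version <- as.character(packageVersion("cadet"))
  x$preset <- unclass(x$preset)
  x$network <- list(event_time_s = x$network$event_time_s,
                    participants = x$network$participants)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyMatrix = FALSE)
  x$version <- NULL
  x$preset <- validate_preset(x$preset)
  bursts <- as.data.frame(x$bursts)
  if (!nrow(bursts)) {
    bursts <- data.frame(neuron_id = integer(0), burst_time_s = numeric(0),
                         n_spikes = integer(0), from_network = logical(0))
  }
  bursts$neuron_id <- as.integer(bursts$neuron_id)
  bursts$n_spikes <- as.integer(bursts$n_spikes)
  x$bursts <- bursts
  nw <- x$network
  net <- data.frame(event_time_s = as.numeric(nw$event_time_s %||% numeric(0)))
  net$participants <- lapply(as.list(nw$participants %||% list()),
                             as.integer)
  x$network <- net
  x$seed <- as.integer(x$seed)
  x$n_frames <- as.integer(x$n_frames)
  x$n_neurons <- as.integer(x$n_neurons)
  structure(x[c("seed", "fs_hz", "n_frames", "duration_s", "n_neurons",
                "preset", "kinetics", "bursts", "network")],
            class = "ground_truth")
}

# Movies are stored as multi-page 16-bit grayscale TIFF with intensities
# scaled by 1/65535 (the writer clips values outside [0,1]). dF/F is
# invariant to this static scale, so the convention is lossless for the
# pipeline up to 16-bit quantization.
MOVIE_TIFF_SCALE <- 65535

#' Read and write movie stacks as multi-page TIFF
#'
#' @param movie a [movie_stack()] in counts; values must lie in
#'   `[0, 65535]`.
#' @param path file path.
#' @param fs_hz frame rate to attach on read.
#' @return `read_movie()` returns a [movie_stack()].
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  if (max(movie) > MOVIE_TIFF_SCALE) {
    stop("movie intensities exceed the 16-bit storage range", call. = FALSE)
  }
  pages <- lapply(seq_len(dim(movie)[1]), function(t) {
    unclass(movie)[t, , ] / MOVIE_TIFF_SCALE
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path, fs_hz) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  dat <- array(0, dim = c(length(pages), d[1], d[2]))
  for (t in seq_along(pages)) dat[t, , ] <- pages[[t]] * MOVIE_TIFF_SCALE
  movie_stack(dat, fs_hz = fs_hz)
}
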