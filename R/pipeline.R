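# End-to-end orchestration.

#' Run the full analysis pipeline
#'
#' Takes one input source — a synthetic simulation block, a trace table,
#' or a movie stack with an ROI table — and runs dF/F extraction (movies
#' only), smoothing, baseline adjustment, transient detection, network
#' analysis and the descriptive summaries. When `out_dir` is given,
#' every stage is written as a delimited table together with a
#' provenance log (`provenance.yaml`) holding all parameters, the seed
#' and the package version; re-running an identical config reproduces
#' byte-identical outputs.
#'
#' @param config a named list, or path to a YAML file, with keys:
#'   \describe{
#'     \item{simulate}{list(`preset`, `seed`, optional `duration_s`,
#'       `n_neurons`, `fs_hz`, `min_gap_s`) — synthetic input.}
#'     \item{traces}{list(`path`) — pre-extracted trace table.}
#'     \item{movie}{list(`path`, `roi_path`, `fs_hz`) — TIFF movie plus
#'       ROI table.}
#'     \item{params}{optional named overrides of [detection_params()].}
#'     \item{group}{optional condition label for the FOV summary.}
#'     \item{fov_id}{optional identifier (default 1).}
#'   }
#'   Exactly one of `simulate` / `traces` / `movie` must be present.
#' @param out_dir optional output directory (created if needed).
#' @return (invisibly when writing) a list: `traces_raw`,
#'   `traces_smoothed`, `traces_adjusted`, `transients`, `network`
#'   (intervals, fraction, events, network_time_pct), `neuron_summary`,
#'   `fov_summary`, `truth` (synthetic runs only), `config`.
#' @export
#' @examples
#' res <- run_pipeline(list(simulate = list(preset = "WT", seed = 1,
#'                                          duration_s = 60,
#'                                          n_neurons = 5)))
#' res$fov_summary
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    stop("`config` must be a list or a YAML file path", call. = FALSE)
  }
  sources <- intersect(c("simulate", "traces", "movie"), names(config))
  if (length(sources) != 1L) {
    stop(sprintf(
      "config must name exactly one input source (simulate | traces | movie); found: %s",
      if (length(sources)) paste(sources, collapse = ", ") else "none"),
      call. = FALSE)
  }
  params <- do.call(detection_params, config$params %||% list())

  truth <- NULL
  if (sources == "simulate") {
    s <- config$simulate
    if (is.null(s$preset)) stop("config key `simulate.preset` is missing",
                                call. = FALSE)
    if (is.null(s$seed)) stop("config key `simulate.seed` is missing",
                              call. = FALSE)
    preset <- if (is.character(s$preset)) regime_preset(s$preset)
              else validate_preset(s$preset)
    truth <- generate_ground_truth(
      preset, fs = s$fs_hz %||% 8.91, duration_s = s$duration_s %||% 300,
      n_neurons = s$n_neurons %||% 40, seed = s$seed,
      min_gap_s = s$min_gap_s %||% 0)
    raw <- render_traces(truth, seed = s$seed + 1L)
  } else if (sources == "traces") {
    if (is.null(config$traces$path)) {
      stop("config key `traces.path` is missing", call. = FALSE)
    }
    raw <- read_traces(config$traces$path)
  } else {
    m <- config$movie
    if (is.null(m$path) || is.null(m$roi_path) || is.null(m$fs_hz)) {
      stop("config keys `movie.path`, `movie.roi_path`, `movie.fs_hz` are required",
           call. = FALSE)
    }
    movie <- read_movie(m$path, fs_hz = m$fs_hz)
    rois <- read_rois(m$roi_path)
    raw <- extract_traces(compute_dff_movie(movie), rois)
  }

  fs <- trace_fs(raw)
  duration_s <- ncol(raw) / fs
  smoothed <- smooth_traces(raw, params$smooth_window_frames)
  adjusted <- adjust_baseline(smoothed, params$baseline_window_s,
                              params$baseline_percentile)
  transients <- detect_transients(smoothed, params)
  network <- analyze_network(smoothed, params)
  neuron_summary <- summarize_neurons(transients, duration_s)
  fov_summary <- summarize_fov(neuron_summary, network, duration_s,
                               fov_id = config$fov_id %||% 1L,
                               group = config$group %||% NA_character_)

  res <- list(traces_raw = raw, traces_smoothed = smoothed,
              traces_adjusted = adjusted, transients = transients,
              network = network, neuron_summary = neuron_summary,
              fov_summary = fov_summary, truth = truth, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_pipeline_outputs(res, out_dir, params)
    return(invisible(res))
  }
  res
}

write_pipeline_outputs <- function(res, out_dir, params) {
  fp <- function(f) file.path(out_dir, f)
  write_traces(res$traces_raw, fp("traces_raw.tsv"))
  write_traces(res$traces_smoothed, fp("traces_smoothed.tsv"))
  write_traces(res$traces_adjusted, fp("traces_adjusted.tsv"))
  write_event_table(res$transients, fp("transients.tsv"))
  write_event_table(res$network$intervals, fp("active_intervals.tsv"))
  write_event_table(res$network$events, fp("network_events.tsv"))
  frac <- trace_matrix(matrix(res$network$fraction, nrow = 1),
                       fs_hz = trace_fs(res$traces_raw), stage = "raw")
  write_traces(frac, fp("coactive_fraction.tsv"))
  write_event_table(res$neuron_summary, fp("neuron_summary.tsv"))
  write_event_table(res$fov_summary, fp("fov_summary.tsv"))
  if (!is.null(res$truth)) write_ground_truth(res$truth, fp("ground_truth.json"))
  prov <- list(
    package = "cadet",
    version = as.character(packageVersion("cadet")),
    config = res$config,
    params = unclass(params),
    fs_hz = trace_fs(res$traces_raw),
    n_frames = ncol(res$traces_raw),
    n_neurons = nrow(res$traces_raw))
  yaml::write_yaml(prov, fp("provenance.yaml"))
  invisible(out_dir)
}
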