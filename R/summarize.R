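# Per-neuron and per-FOV descriptive summaries.

#' Per-neuron event summary
#'
#' Event frequency (events per minute) and means of the single-event
#' metrics. Frequency counts every detected peak by default, including
#' flagged ones (switch with the `count_flagged_in_frequency`
#' parameter); amplitude means cover events passing the refractory and
#' elevated-baseline rules, and duration/AUC/half-decay means cover the
#' subset that also has clear boundaries. Means are `NA` when no event
#' qualifies. Inferential statistics are out of scope; the tables are
#' descriptive and self-contained.
#'
#' @param transients a `transient_table` from [detect_transients()].
#' @param recording_duration_s recording length in seconds.
#' @param neuron_ids neurons to report (default: the table's
#'   `neuron_ids` attribute); neurons without events get frequency 0
#'   and `NA` means.
#' @param params a [detection_params()] (for the frequency switch;
#'   default: the table's own).
#' @return data frame, one row per neuron: `neuron_id`,
#'   `event_frequency_per_min`, `mean_amplitude_pct`, `mean_duration_s`,
#'   `mean_auc_pct_s`, `mean_iei_s`, `mean_half_decay_s`,
#'   `n_events_total`, `n_events_measured`.
#' @export
summarize_neurons <- function(transients, recording_duration_s,
                              neuron_ids = NULL, params = NULL) {
  stopifnot_scalar_pos(recording_duration_s, "recording_duration_s")
  if (is.null(neuron_ids)) neuron_ids <- attr(transients, "neuron_ids")
  if (is.null(neuron_ids)) neuron_ids <- sort(unique(transients$neuron_id))
  if (is.null(params)) params <- attr(transients, "params")
  count_flagged <- is.null(params) || isTRUE(params$count_flagged_in_frequency)

  mean_or_na <- function(x) if (any(!is.na(x))) mean(x, na.rm = TRUE)
                            else NA_real_
  rows <- lapply(neuron_ids, function(id) {
    d <- transients[transients$neuron_id == id, , drop = FALSE]
    flagged <- d$refractory_excluded | d$elevated_baseline_excluded
    measured <- !flagged & !d$no_clear_bounds
    n_freq <- if (count_flagged) nrow(d) else sum(!d$refractory_excluded)
    data.frame(
      neuron_id = id,
      event_frequency_per_min = 60 * n_freq / recording_duration_s,
      mean_amplitude_pct = mean_or_na(d$amplitude_pct[!flagged]),
      mean_duration_s = mean_or_na(d$duration_s[measured]),
      mean_auc_pct_s = mean_or_na(d$auc_pct_s[measured]),
      mean_iei_s = mean_or_na(d$iei_prev_s),
      mean_half_decay_s = mean_or_na(d$half_decay_s[measured]),
      n_events_total = nrow(d),
      n_events_measured = sum(measured))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-field-of-view summary
#'
#' Unweighted means across neurons of the per-neuron metrics, plus the
#' network-level measures.
#'
#' @param neuron_summary from [summarize_neurons()].
#' @param network result list from [analyze_network()] (or `NULL` to
#'   skip network columns).
#' @param recording_duration_s recording length in seconds.
#' @param fov_id identifier for this field of view.
#' @param group genotype / condition label.
#' @return one-row data frame: `fov_id`, `group`, `n_neurons`,
#'   `mean_frequency_per_min`, `mean_amplitude_pct`, `mean_duration_s`,
#'   `mean_auc_pct_s`, `n_network_events`, `network_event_rate_per_min`,
#'   `network_time_pct`, `mean_participation_pct`.
#' @export
summarize_fov <- function(neuron_summary, network = NULL,
                          recording_duration_s, fov_id = 1L,
                          group = NA_character_) {
  stopifnot_scalar_pos(recording_duration_s, "recording_duration_s")
  mean_or_na <- function(x) if (any(!is.na(x))) mean(x, na.rm = TRUE)
                            else NA_real_
  n_ev <- if (is.null(network)) NA_integer_ else nrow(network$events)
  data.frame(
    fov_id = fov_id, group = group, n_neurons = nrow(neuron_summary),
    mean_frequency_per_min = mean_or_na(neuron_summary$event_frequency_per_min),
    mean_amplitude_pct = mean_or_na(neuron_summary$mean_amplitude_pct),
    mean_duration_s = mean_or_na(neuron_summary$mean_duration_s),
    mean_auc_pct_s = mean_or_na(neuron_summary$mean_auc_pct_s),
    n_network_events = n_ev,
    network_event_rate_per_min =
      if (is.null(network)) NA_real_ else 60 * n_ev / recording_duration_s,
    network_time_pct =
      if (is.null(network)) NA_real_ else network$network_time_pct,
    mean_participation_pct =
      if (is.null(network) || n_ev == 0) NA_real_
      else mean(network$events$participation_pct))
}
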