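# Activity-regime presets for the synthetic generator.
#
# Magnitudes are calibrated only to reproduce the qualitative genotype
# orderings of cultured-neuron activity (hyperactive knockout > rescued
# heterozygote > wild type); no absolute rates are published for these
# cultures. Amplitude-per-spike, noise and drift are shared across
# regimes so that amplitude and duration differences emerge from burst
# size alone.

.regime_table <- list(
  WT = list(
    name = "WT",
    burst_rate_per_min = 1.0,
    spikes_per_burst_mean = 2,
    network_rate_per_min = 0.5,
    participation_prob = 0.4,
    amplitude_per_spike_pct = 2.5,
    noise_sd_pct = 0.2,
    drift_amplitude_pct = 0.2
  ),
  KO_HET = list(
    name = "KO_HET",
    burst_rate_per_min = 2.0,
    spikes_per_burst_mean = 4,
    network_rate_per_min = 1.2,
    participation_prob = 0.6,
    amplitude_per_spike_pct = 2.5,
    noise_sd_pct = 0.2,
    drift_amplitude_pct = 0.2
  ),
  KO = list(
    name = "KO",
    burst_rate_per_min = 3.0,
    spikes_per_burst_mean = 6,
    network_rate_per_min = 2.0,
    participation_prob = 0.8,
    amplitude_per_spike_pct = 2.5,
    noise_sd_pct = 0.2,
    drift_amplitude_pct = 0.2
  )
)

#' Activity-regime presets
#'
#' Returns the parameter set describing one synthetic activity regime.
#' Three presets are provided, labelled after the genotypes whose
#' activity structure they emulate: `"WT"` (sparse activity), `"KO"`
#' (hyperactive: more frequent, larger, longer events and stronger
#' network participation) and `"KO_HET"` (intermediate rescue). The
#' hyperactive preset strictly exceeds the wild-type preset in burst
#' rate, spikes per burst and participation probability, and `"KO_HET"`
#' lies strictly between them on those components.
#'
#' @param name `"WT"`, `"KO"` or `"KO_HET"`.
#' @param ... named overrides of individual preset fields.
#' @return a `regime_preset` list with fields `name`,
#'   `burst_rate_per_min`, `spikes_per_burst_mean`,
#'   `network_rate_per_min`, `participation_prob`,
#'   `amplitude_per_spike_pct`, `noise_sd_pct`, `drift_amplitude_pct`.
#' @export
#' @examples
#' regime_preset("KO")$burst_rate_per_min
regime_preset <- function(name = c("WT", "KO", "KO_HET"), ...) {
  name <- match.arg(name)
  p <- .regime_table[[name]]
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) {
      stop("unknown preset field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  validate_preset(p)
}

validate_preset <- function(p) {
  rates <- c("burst_rate_per_min", "spikes_per_burst_mean",
             "network_rate_per_min", "amplitude_per_spike_pct",
             "noise_sd_pct", "drift_amplitude_pct")
  for (f in rates) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || p[[f]] < 0) {
      stop(sprintf("preset field `%s` must be a non-negative number", f),
           call. = FALSE)
    }
  }
  if (p$spikes_per_burst_mean < 1) {
    stop("`spikes_per_burst_mean` must be >= 1 (bursts have >= 1 spike)",
         call. = FALSE)
  }
  pp <- p$participation_prob
  if (!is.numeric(pp) || pp < 0 || pp > 1) {
    stop("`participation_prob` must lie in [0, 1]", call. = FALSE)
  }
  class(p) <- "regime_preset"
  p
}

#' @export
print.regime_preset <- function(x, ...) {
  cat(sprintf("<regime_preset '%s'>\n", x$name))
  for (f in setdiff(names(x), "name")) {
    cat(sprintf("  %-24s %g\n", f, x[[f]]))
  }
  invisible(x)
}
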