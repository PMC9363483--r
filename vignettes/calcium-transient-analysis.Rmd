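---
title: "Detecting calcium transients and network events in cultured neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting calcium transients and network events in cultured neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cadet)
```

## The measurement problem

Cultured hippocampal neurons expressing a red calcium indicator
(jRGECO1a) report somatic spiking as fluorescence transients. In
disease models of mTORC1 hyperactivation (conditional Tsc1 knockout),
cultures become hyperactive: transients are more frequent, larger and
longer, and the network fires in synchronized bursts. Quantifying
that phenotype — and its partial rescue by heterozygous Raptor
deletion — requires an analysis chain that is robust to two awkward
properties of such recordings: hyperactive cultures have *few
quiescent frames*, so baselines estimated from running averages are
biased upward, and persistent activity elevates the trace between
events, so naive peak metrics inherit the history of preceding
events.

`cadet` implements that chain as composable stages, each of which can
be driven by synthetic data with known ground truth.

## Pipeline stages and their assumptions

### ΔF/F from the minimum projection

`compute_dff_movie()` normalises each pixel against its minimum over
all frames. The minimum projection is the only baseline guaranteed to
sit at or below the true resting fluorescence when activity is
persistent; the cost is a static positive offset under pixel noise,
since the minimum of $n$ noisy samples sits below their mean (about
$2.2\sigma$ at $n = 50$). This offset cancels in every downstream
measure that subtracts a within-trace reference (amplitude, the
windowed-percentile baseline), and the closed-loop tests confirm exact
trace recovery at zero noise and fluctuating error below the injected
pixel noise floor otherwise. A rolling baseline is deliberately not
offered.

ΔF/F is carried in **percent** everywhere so that the detection
constants (0.5%, 1%, 50%) apply literally.

### Smoothing and the shrinking window

`smooth_traces()` applies a four-frame moving mean (at the default
8.91 Hz, ~0.45 s). For an even window the span leans one frame into
the past (offsets $-2\ldots+1$); at the edges the mean is taken over
the available samples only, so no padded values can cross a detection
threshold. The hand-enumerable consequence, frozen in the tests: the
trace $(0, 0, 4, 0, 0, 0)$ smooths to $(0, 4/3, 1, 1, 1, 0)$.

### Windowed-percentile baseline adjustment

Before duration and AUC are measured, `adjust_baseline()` shifts the
1st percentile of each consecutive 15 s window to zero: window length
`round(window_s * fs)` frames (134 at 8.91 Hz; seconds-to-frames
conversions round half away from zero), anchors at window centres,
piecewise-linear interpolation between anchors with constant
extrapolation beyond the first and last. Linear interpolation was
chosen over a spline for reproducibility and monotone behaviour
between anchors; the windowing step and interpolation scheme are
design choices of this package, documented here because upstream
descriptions of such routines leave them open. Traces shorter than
one window fall back to a single global percentile shift, with a
message.

### Single-event detection and exclusion rules

Peaks are local maxima of the smoothed trace (first frame of a
plateau) with **height** strictly above 0.5% ΔF/F. Reading the
detection constant as a minimum height rather than topographic
prominence is a deliberate choice — the two are indistinguishable in a
one-line description of a `findpeaks`-style call — and a
`peak_criterion = "prominence"` switch is provided. Amplitude is the
peak value minus the minimum over the preceding inter-event interval
(from frame 0 for the first event), measured on the smoothed,
*pre-adjustment* trace, matching the stated order of operations.

Two rules exclude events from metric analysis while keeping them in
the frequency and inter-event-interval counts: a 2 s refractory rule,
and an elevated-baseline rule (amplitude < 50% of the peak's absolute
ΔF/F, where "absolute" is read as the peak's value above the global
minimum-projection baseline). Whether refractory peaks should count
toward frequency is not fully pinned down by the source description;
they do by default (`count_flagged_in_frequency`), and the switch is
exposed. The refractory rule also absorbs the near-threshold ripple
duplicates that any fixed-height detector produces on event decays.

Event bounds on the adjusted trace: start at the last upward 0.5%
crossing before the peak; scanning forward, end at the first frame at
or below 0.5%, or — if the decay is interrupted by a rise of more than
1% above the running minimum, the signature of a following event — at
the running-minimum frame, the natural trough boundary. Intervals are
half-open `[start, end)` in 0-based frames; no sub-frame interpolation
is used except in the half-decay time. Events without a clear
initiation or termination are flagged and carry no duration or AUC.
AUC is the trapezoidal integral (via `pracma::trapz`) over the event
samples divided by the frame rate.

### Network events

Active intervals are full-width-at-half-maximum spans around peaks
with prominence ≥ 0.5%; the reference level is half-prominence
(`peak − prominence/2`), the standard width definition consistent with
a prominence-gated peak set (a `fwhm_reference = "half_height"` switch
exists, since the phrase "half maximum" alone is ambiguous).
Crossings are interpolated, then rounded *outward*, so a neuron is
active for every frame its half-height span touches; overlapping
spans of one neuron are merged. The coactive fraction is evaluated
frame-wise with no temporal smoothing, and a network event is a
maximal run with fraction strictly above 20% (frames at exactly 20%
do not count) lasting at least 2.5 s. A standard-deviation-based
threshold is deliberately not offered: it would selectively suppress
detection in persistently active cultures. Note that the *count* of
network events is not monotone in the fraction threshold — a long run
can split into several valid runs — but the total time in events is;
the tests assert the latter.

## The synthetic generator

The generator emulates the statistical structure of three activity
regimes; its preset magnitudes are calibrated to reproduce the
qualitative orderings of the phenotype (no absolute rates are
published for these cultures), chosen once as:

| preset | bursts/min | spikes/burst | network/min | participation |
|--------|-----------:|-------------:|------------:|--------------:|
| WT     | 1.0        | 2            | 0.5         | 0.40          |
| KO_HET | 2.0        | 4            | 1.2         | 0.60          |
| KO     | 3.0        | 6            | 2.0         | 0.80          |

Amplitude per spike (2.5%), noise (0.2% SD) and drift (0.2%, 60 s
sinusoid) are shared across regimes, so amplitude and duration
differences *emerge* from burst size rather than being injected
directly. Bursts are homogeneous Poisson per neuron; spike counts are
shifted Poisson (minimum one); spikes within a burst are spaced at
4 Hz so longer bursts hold the indicator elevated for seconds.
Network events are an independent Poisson process; each recruits
every neuron with the participation probability, as a synchronized
burst jittered by ±0.1 s whose spike count is drawn at twice the solo
mean — synaptically driven network bursts sustain firing longer than
intrinsic ones, which is what lets coactivity outlast the 2.5 s
event minimum. An optional `min_gap_s` thins the solo process for
recovery benchmarks that require isolated events.

The indicator kernel is a difference of exponentials,
$a\,(e^{-t/\tau_d} - e^{-t/\tau_r})$ normalised to unit peak, with
$\tau_r = 0.1$ s and $\tau_d = 0.8$ s — plausible red-indicator
kinetics, configurable, since the source gives none. Kernels sum
linearly with no saturation, bleaching or motion artifacts
(deliberate non-goals), so passing tests demonstrate correctness of
the *analysis*, not robustness to optical artifacts real data may
contain.

Two calibration constraints deserve emphasis. First, the smoothed
noise floor (raw SD / 2 = 0.1%) sits five standard deviations below
the 0.5% detection threshold. This is not cosmetic: any usable
recording analysed with a fixed absolute threshold must have this
property, otherwise baseline noise excursions register as events at a
rate of tens per neuron per recording (at 0.5% raw noise the smoothed
floor is at 2σ of the threshold and a measured ~40 spurious peaks per
neuron per 300 s follow; the recovery benchmarks quantify this
honestly at both noise levels). Likewise the drift amplitude must stay
below the absolute threshold, since detection precedes baseline
adjustment. Second, wild-type cultures must appear mostly silent with
discrete transients — which the 5σ margin delivers.

```{r example}
fov <- simulate_fov("KO", duration_s = 120, n_neurons = 10, seed = 1)
tr <- detect_transients(fov$traces)
head(tr[!is.na(tr$duration_s),
        c("neuron_id", "peak_frame", "amplitude_pct", "duration_s",
          "auc_pct_s")])
```

## Numerical choices and degenerate inputs

* Seconds→frames: round half away from zero (15 s × 8.91 Hz → 134
  frames).
* Percentiles: `stats::quantile()` type 7 (the R default); at the 1st
  percentile of a 134-frame window the difference between quantile
  definitions is far below the 0.5% threshold scale.
* Ties/plateaus: a flat-topped maximum reports its first frame; trace
  endpoints are never peaks.
* A movie pixel whose minimum is ≤ 0 makes ΔF/F undefined; the error
  names the number of offending pixels rather than returning
  infinities.
* Movies are archived as 16-bit TIFF with intensities scaled by
  1/65535 (the writer clips outside [0, 1]); ΔF/F is invariant to that
  static scale, and the ~1-count truncation error is bounded in the
  round-trip tests.
* Determinism: all generators are pure functions of (arguments, seed);
  RNG state is saved and restored around every draw, and the pipeline
  writes a provenance log (parameters, seed, package version, no
  timestamps) sufficient to reproduce a run byte-for-byte.

## Problem sizes used in the checks

The test-suite and acceptance benchmarks run at desk scale, chosen as
the package's own verification conditions: 100 random 10-neuron ×
500-frame instances for the brute-force network oracle; ten 40-neuron
× 300 s fields of view for transient recovery; twenty simulated fields
of view per regime for the group-ordering checks; Monte-Carlo rate
checks over 100–200 seeds.

## Known limitations

* The fixed-height criterion has no noise adaptivity by design
  (faithfulness to the source method); its false-positive rate rises
  steeply once the smoothed noise floor approaches 0.5% ΔF/F, as the
  recovery benchmark at 0.5% raw noise documents (F1 ≈ 0.24 there,
  ≈ 0.998 over unflagged events at the calibrated 0.2% noise).
* The minimum-projection baseline carries a static noise-dependent
  offset (~2.2σ of pixel noise at 50 frames); amplitude and
  baseline-adjusted measures are immune, raw ΔF/F magnitudes are not.
* Group summaries are descriptive only; inferential statistics are
  intentionally left to downstream tools.
* Motion correction and ROI segmentation are out of scope; movies are
  assumed motion-corrected and ROIs provided.
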