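Package: cadet
Title: Calcium Transient Detection and Network Synchrony Analysis for
    Cultured Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for widefield calcium-imaging recordings of
    cultured hippocampal neurons. Converts movie stacks to per-ROI dF/F
    traces using a minimum-intensity-projection baseline, detects single
    calcium transients with threshold and exclusion rules (refractory
    period, elevated-baseline ratio, event delineation with an
    interruption rule), measures amplitude, duration, area under the
    curve, inter-event intervals and half-decay times, and detects
    network synchrony events from the fraction of simultaneously active
    neurons using full-width-at-half-maximum active intervals. Includes
    a synthetic-data generator that renders spike schedules through a
    difference-of-exponentials indicator kernel into dF/F traces and toy
    movie stacks, emulating wild-type and hyperactive activity regimes,
    so every analysis stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
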