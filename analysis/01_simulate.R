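#!/usr/bin/env Rscript

# Simulate one field of view per activity regime (WT, KO, KO_HET):
# 40 neurons, 300 s at 8.91 Hz, with the regime presets' burst rates,
# burst sizes and network-event structure. Writes the ground-truth
# schedules and rendered dF/F traces under results/simulated/.

library(cadet)

out_root <- "results/simulated"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

for (preset in c("WT", "KO", "KO_HET")) {
  fov <- simulate_fov(preset, seed = 1)
  dir <- file.path(out_root, preset)
  dir.create(dir, showWarnings = FALSE)
  write_ground_truth(fov$truth, file.path(dir, "ground_truth.json"))
  write_traces(fov$traces, file.path(dir, "traces_raw.tsv"))
  cat(sprintf(
    "%-7s %4d bursts (%.1f per neuron), %2d scheduled network events\n",
    preset, nrow(fov$truth$bursts), nrow(fov$truth$bursts) / 40,
    nrow(fov$truth$network)))
}
cat("wrote schedules and traces under", out_root, "\n")
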