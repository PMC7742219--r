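#!/usr/bin/env Rscript
# Step 1: synthesize one example subject's recording with known common
# drive and write it in the TSV interchange format (signal matrix + marker
# table + ground-truth JSON).
source("analysis/00_config.R")

dir.create(EXAMPLE_DIR, recursive = TRUE, showWarnings = FALSE)

message("Synthesizing one subject at the default acquisition scale ...")
out <- synthesize_recording(sim_config)
print(out$recording)
message(sprintf("Clipped envelope samples: %.3f%% (target < 1%%)",
                100 * out$truth$clip_fraction))

write_recording_tsv(out$recording,
                    file.path(EXAMPLE_DIR, "emg_signals.tsv"),
                    file.path(EXAMPLE_DIR, "markers.tsv"))
write_ground_truth(out$truth, file.path(EXAMPLE_DIR, "ground_truth.json"))

message(sprintf(
  "Wrote %d channels x %d samples (%.0f s at %g Hz), %d markers -> %s",
  nrow(out$recording$samples), ncol(out$recording$samples),
  ncol(out$recording$samples) / out$recording$fs, out$recording$fs,
  nrow(out$recording$markers), EXAMPLE_DIR))
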