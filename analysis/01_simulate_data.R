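#!/usr/bin/env Rscript
# Step 1 -- simulate the study's raw material.
#
# Builds the toy head model, the task timeline (300 trials, 150 per flicker
# frequency), and a ground-truth coupled theta network, then writes one
# synthetic subject's continuous frequency-tagged EEG as a BrainVision
# triplet plus a JSON sidecar with the ground truth. Later steps re-read
# that triplet like any lab recording.

library(aebnet)

out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

task <- task_config()                      # full design: 300 trials
head <- make_toy_leadfield(32L, c(6L, 6L, 6L), seed = 1)
net <- study_coupling_network("placebo", "planning")

# one subject at the recorded rate; a short task keeps the demo quick
demo_task <- task_config(n_trials = 24L, trials_per_freq = c(12L, 12L))
rec <- simulate_tagged_eeg(demo_task, head, net, fs = 500, ssvep_amp = 3,
                           snr = 3, seed = 42)

write_brainvision(rec, file.path(out_dir, "subject01"), "IEEE_FLOAT_32")
jsonlite::write_json(
  list(node_voxels = as.list(rec$node_voxels),
       tagged_sensors = rec$tagged_sensors,
       lin_adj = rec$ground_truth$lin_adj,
       nl_adj = rec$ground_truth$nl_adj,
       task = unclass(demo_task)),
  file.path(out_dir, "subject01_truth.json"), auto_unbox = TRUE, digits = NA)

utils::write.table(rec$events_table, file.path(out_dir, "subject01_events.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d channels x %d samples at %g Hz (%d trials, %d correct)\n",
            nrow(rec$data), ncol(rec$data), rec$fs,
            nrow(rec$events_table), sum(rec$events_table$correct)))
cat(sprintf("tagged sensors: %s\n",
            paste(rec$channel_names[rec$tagged_sensors], collapse = " ")))
cat(sprintf("wrote BrainVision triplet + ground-truth sidecar to %s/\n", out_dir))
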