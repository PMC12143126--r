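#!/usr/bin/env Rscript
# Step 2 -- read the BrainVision recording and preprocess it.
#
# Round-trips the triplet written by step 1, downsamples 500 -> 256 Hz,
# band-passes 0.5-40 Hz, and cuts cue-locked and action-effect-locked
# epochs (-2000..4000 ms and -2000..2000 ms).

library(aebnet)

raw <- read_brainvision("results/sim/subject01.vhdr")
print(raw)

rs <- resample_recording(raw, 256)
bp <- bandpass_recording(rs, 0.5, 40)

events <- utils::read.table("results/sim/subject01_events.tsv", sep = "\t",
                            header = TRUE)
md <- events[!is.na(events$effect_onset), ]

cue_ep <- epoch_recording(bp, "S  1", c(-2000, 4000), lock = "cue",
                          metadata = events)
eff_ep <- epoch_recording(bp, "S  2", c(-2000, 2000), lock = "effect",
                          metadata = md)
print(cue_ep)
print(eff_ep)

# epochs are regenerated downstream from the triplet; only a summary is kept
summary <- data.frame(
  stage = c("raw", "resampled", "epoch_cue", "epoch_effect"),
  fs = c(raw$fs, rs$fs, cue_ep$fs, eff_ep$fs),
  n = c(ncol(raw$data), ncol(rs$data), dim(cue_ep$data)[1],
        dim(eff_ep$data)[1]),
  unit = c("samples", "samples", "trials", "trials"))
utils::write.table(summary, "results/preprocess_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote results/preprocess_summary.tsv\n")
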