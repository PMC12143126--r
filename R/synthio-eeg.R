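# alpha-band (8-13 Hz) narrowband Gaussian noise, unit variance
alpha_noise <- function(n, fs) {
  bf <- signal::butter(2, c(8, 13) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n + 2000))[-(1:2000)]
  x / stats::sd(x)
}

# 1/f-shaped Gaussian noise (spectral exponent 1), unit variance;
# generated at a 2-3-5-smooth FFT length and truncated
pink_noise <- function(n) {
  n2 <- stats::nextn(n, c(2, 3, 5))
  white <- stats::rnorm(n2)
  X <- stats::fft(white)
  f <- c(1, seq_len(n2 - 1))                      # avoid DC blow-up
  f <- pmin(f, n2 - f + 1)                        # symmetric frequency index
  X <- X / sqrt(f)
  X[1] <- 0
  x <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)] / n2
  x / stats::sd(x)
}

#' Simulate continuous frequency-tagged sensor EEG
#'
#' Builds a continuous multichannel recording for one synthetic subject:
#' coupled theta-band source dynamics (from `net`) are injected at one voxel
#' per network node and projected through the toy leadfield; during each
#' trial's action-effect interval the sensors closest to the occipital region
#' carry a steady-state sinusoid at the trial's flicker frequency (plus a
#' first harmonic 6 dB down); 1/f-shaped Gaussian sensor noise is added
#' everywhere. All randomness derives from `seed`.
#'
#' @param task an [task_config()] object.
#' @param head an [make_toy_leadfield()] object.
#' @param net an [ground_truth_network()] object (one node per ROI).
#' @param fs sampling rate in Hz.
#' @param ssvep_amp amplitude of the tagging sinusoid in microvolt.
#' @param snr tagging signal-to-noise ratio: `ssvep_amp / noise SD`.
#'   `snr = 3` therefore means a tag at 3 x noise SD.
#' @param alpha_ratio amplitude of a stationary alpha-band (8-13 Hz)
#'   background relative to the 1/f noise SD; gives the sensors an EEG-like
#'   resting spectrum with an alpha bump.
#' @param source_amp total sensor-level RMS of each projected source (the
#'   unit-norm gain column times a unit-SD source), in microvolt.
#' @param accuracy passed to [simulate_trial_events()].
#' @param n_tagged number of posterior (occipital-weighted) tagged sensors.
#' @param theta_amp oscillatory drive passed to [simulate_source_dynamics()].
#' @param seed RNG seed.
#' @return a `raw_recording` (see [raw_recording()]) with extra fields:
#'   `events_table` (the full trial table), `tagged_sensors`,
#'   `source_series`, `node_voxels`, `ground_truth` (adjacency list),
#'   and `parts` (per-component sensor signals, for energy accounting).
#' @export
simulate_tagged_eeg <- function(task, head, net, fs = 500,
                                ssvep_amp = 2, snr = 3, source_amp = 1,
                                accuracy = 0.97, n_tagged = 6L,
                                theta_amp = 1, alpha_ratio = 1, seed = 1L) {
  stopifnot(inherits(task, "aeb_task"), inherits(head, "aeb_head"),
            inherits(net, "aeb_network"))
  events <- simulate_trial_events(task, fs = fs, accuracy = accuracy,
                                  seed = seed)
  ms2smp <- function(ms) round(ms / 1000 * fs)
  n_total <- max(events$trial_start) +
    ms2smp(task$pre_cue_fixation + task$cue_duration +
           task$response_window + task$effect_duration)
  n_sens <- nrow(head$leadfield)

  node_voxels <- region_center_voxels(head, net$node_names[net$node_names %in%
                                      unique(head$voxel_labels)])
  if (length(node_voxels) != net$n_nodes)
    stop_config("node-to-voxel map missing: head has no voxels for some network node")

  dyn <- simulate_source_dynamics(net, n_total, fs = fs, seed = seed + 1L,
                                  theta_amp = theta_amp)
  # project through the unit-norm gain columns so every source deposits the
  # same total energy across the array
  proj <- matrix(0, n_sens, n_total)
  for (m in seq_along(node_voxels)) {
    g <- head$leadfield[, node_voxels[m]]
    src <- dyn$series[m, ]
    proj <- proj + outer(g, src / stats::sd(src) * source_amp)
  }

  # tagged sensors: largest summed gain to OCC voxels
  occ <- which(head$voxel_labels == "OCC")
  occ_gain <- rowSums(head$leadfield[, occ, drop = FALSE])
  tagged <- order(occ_gain, decreasing = TRUE)[seq_len(n_tagged)]

  ssvep <- matrix(0, n_sens, n_total)
  tvec <- seq_len(n_total) / fs
  for (r in seq_len(nrow(events))) {
    if (is.na(events$effect_onset[r])) next
    idx <- events$effect_onset[r] + seq_len(ms2smp(task$effect_duration)) - 1L
    idx <- idx[idx <= n_total]
    f0 <- events$flicker_freq[r]
    wave <- ssvep_amp * (sin(2 * pi * f0 * tvec[idx]) +
                         0.5 * sin(2 * pi * 2 * f0 * tvec[idx]))
    ssvep[tagged, idx] <- ssvep[tagged, idx] +
      matrix(wave, length(tagged), length(idx), byrow = TRUE)
  }

  noise_sd <- if (snr > 0) ssvep_amp / snr else 0
  noise <- matrix(0, n_sens, n_total)
  if (noise_sd > 0)
    for (ch in seq_len(n_sens))
      noise[ch, ] <- noise_sd * (pink_noise(n_total) +
                                 alpha_ratio * alpha_noise(n_total, fs))

  data <- proj + ssvep + noise
  ev <- data.frame(sample = events$cue_onset, code = "S  1",
                   stringsAsFactors = FALSE)
  eff <- events$effect_onset[!is.na(events$effect_onset)]
  ev <- rbind(ev, data.frame(sample = eff, code = "S  2"))
  ev <- ev[order(ev$sample), ]
  rec <- raw_recording(data, fs = fs, channel_names = head$sensor_names,
                       events = ev)
  rec$events_table <- events
  rec$tagged_sensors <- tagged
  rec$source_series <- dyn$series
  rec$node_voxels <- node_voxels
  rec$ground_truth <- list(lin_adj = dyn$lin_adj, nl_adj = dyn$nl_adj)
  rec$parts <- list(source = proj, ssvep = ssvep, noise = noise)
  rec
}
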