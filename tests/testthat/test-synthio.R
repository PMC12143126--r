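test_that("trial event tables respect the design counts and timeline order", {
  task <- task_config()
  ev <- simulate_trial_events(task, fs = 500, accuracy = 1, seed = 11)
  expect_equal(nrow(ev), 300L)
  expect_equal(sum(!is.na(ev$effect_onset)), 300L)
  expect_equal(unname(table(ev$flicker_freq)), c(150L, 150L),
               ignore_attr = TRUE)
  # fixation -> cue -> response window -> effect, strictly ordered
  expect_true(all(ev$trial_start < ev$cue_onset))
  expect_true(all(ev$cue_onset < ev$response))
  ok <- !is.na(ev$effect_onset)
  expect_true(all(ev$effect_onset[ok] >= ev$response[ok]))
  # responses fall after cue offset, within the response window
  cue_off <- ev$cue_onset + round(task$cue_duration / 1000 * 500)
  expect_true(all(ev$response >= cue_off))
  expect_true(all(ev$response < cue_off + round(task$response_window / 1000 * 500)))
})

test_that("accuracy controls effect onsets and matches an independent redraw", {
  task <- task_config(n_trials = 100L, trials_per_freq = c(50L, 50L))
  ev0 <- simulate_trial_events(task, accuracy = 0, seed = 5)
  expect_equal(sum(!is.na(ev0$effect_onset)), 0L)

  ev <- simulate_trial_events(task, accuracy = 0.97, seed = 42)
  # regenerating with the same seed must give the identical realized draw
  ev2 <- simulate_trial_events(task, accuracy = 0.97, seed = 42)
  expect_identical(ev, ev2)
  expect_equal(sum(!is.na(ev$effect_onset)), sum(ev$correct))

  expect_error(simulate_trial_events(task, accuracy = 1.5), "accuracy")
  expect_error(task_config(cue_duration = -1), "durations")
  expect_error(task_config(trials_per_freq = c(10L, 10L)), "sum")
})

test_that("null networks give white noise and empty adjacency", {
  A <- array(0, dim = c(3, 3, 2))
  net <- ground_truth_network(A)
  dyn <- simulate_source_dynamics(net, 2000, seed = 1)
  expect_false(any(dyn$lin_adj))
  expect_false(any(dyn$nl_adj))
  # lag-1 autocorrelation of white noise ~ 0
  ac <- apply(dyn$series, 1, function(x) stats::cor(x[-1], x[-length(x)]))
  expect_true(all(abs(ac) < 0.08))
})

test_that("a single directed edge shows up in lagged cross-correlation and matches a direct AR oracle", {
  net <- single_edge_network(a = 0.8)
  dyn <- simulate_source_dynamics(net, 4000, seed = 9, burn_in = 200)
  x <- dyn$series
  lag1_xc <- function(a, b) stats::cor(a[-length(a)], b[-1])   # a leads b
  c12 <- abs(lag1_xc(x[1, ], x[2, ]))
  c13 <- abs(lag1_xc(x[1, ], x[3, ]))
  c23 <- abs(lag1_xc(x[2, ], x[3, ]))
  c21 <- abs(lag1_xc(x[2, ], x[1, ]))
  expect_gt(c12, max(c13, c23, c21) + 0.2)
  expect_true(dyn$lin_adj[1, 2])
  expect_equal(sum(dyn$lin_adj), 1L)

  # value agrees with an independently coded AR recursion at matched size
  A <- array(0, dim = c(3, 3, 2))
  for (i in 1:3) A[i, i, 1] <- 0.3
  A[2, 1, 1] <- 0.8
  xo <- ar_recursion_oracle(A, 4000, seed = 17)
  c12_o <- abs(lag1_xc(xo[1, ], xo[2, ]))
  expect_lt(abs(c12 - c12_o), 0.08)
})

test_that("quadratic coupling is invisible to linear correlation but visible to x^2", {
  A <- array(0, dim = c(3, 3, 1))
  for (i in 1:3) A[i, i, 1] <- 0.3
  net <- ground_truth_network(A, nl_terms = list(
    nl_term("quadratic", from = 1, to = 3, gain = 0.5, lag = 1)))
  cors <- t(vapply(1:10, function(s) {
    x <- simulate_source_dynamics(net, 10000, seed = s)$series
    c(lin = stats::cor(x[1, -10000], x[3, -1]),
      sq = stats::cor(x[1, -10000]^2, x[3, -1]))
  }, numeric(2)))
  expect_lt(mean(abs(cors[, "lin"])), 0.05)
  expect_gt(mean(cors[, "sq"]), 0.3)
})

test_that("unstable coefficient sets are rejected with the spectral radius named", {
  A <- array(0, dim = c(2, 2, 1))
  A[1, 1, 1] <- 1.05
  expect_error(ground_truth_network(A), "spectral radius 1.05")
})

test_that("toy leadfield has the contracted shape, smooth distance structure and labels", {
  head <- make_toy_leadfield(16L, c(5L, 5L, 5L), seed = 2)
  expect_equal(dim(head$leadfield), c(16L, 125L))
  expect_length(head$voxel_labels, 125L)
  expect_true(all(c("ATL", "IC", "IFC") %in% unique(head$voxel_labels)))
  expect_true(all(colSums(abs(head$leadfield)) > 0))

  # gain is maximal at the nearest sensor
  for (v in c(1L, 63L, 125L)) {
    d <- rowSums(sweep(head$sensor_pos, 2, head$voxel_coords[v, ])^2)
    expect_equal(which.max(head$leadfield[, v]), which.min(d))
  }

  # distinct voxels give non-collinear gain columns
  cs <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  set.seed(1)
  pairs <- replicate(25, sample(125L, 2L))
  sims <- apply(pairs, 2, function(pr)
    cs(head$leadfield[, pr[1]], head$leadfield[, pr[2]]))
  expect_true(all(sims < 0.999))

  expect_error(make_toy_leadfield(4L), "n_sensors")
  expect_error(make_toy_leadfield(16L, c(3L, 5L, 5L)), "grid_shape")
})

test_that("tagged EEG carries the flicker frequency at tagged sensors", {
  task <- small_task(8L)
  head <- small_head()
  net <- study_coupling_network("placebo", "planning")
  rec <- simulate_tagged_eeg(task, head, net, fs = 256, ssvep_amp = 3,
                             snr = 6, seed = 21)
  ev <- rec$events_table
  ch <- rec$tagged_sensors[1]
  eff_len <- round(2000 / 1000 * 256)

  # spectral peak exactly at the trial's flicker bin (high SNR)
  tr <- which(!is.na(ev$effect_onset))[1]
  seg <- rec$data[ch, ev$effect_onset[tr] + 0:(eff_len - 1)]
  spec <- Mod(stats::fft(seg))[1:(eff_len / 2)]
  fgrid <- (seq_len(eff_len / 2) - 1) * 256 / eff_len
  spec_band <- spec
  spec_band[fgrid <= 2 | fgrid >= 20] <- 0
  expect_equal(fgrid[which.max(spec_band)], ev$flicker_freq[tr])

  # 4.5 Hz Welch power greater in 4.5 Hz trials than in 8 Hz trials
  pw <- vapply(which(!is.na(ev$effect_onset)), function(tr) {
    seg <- rec$data[ch, ev$effect_onset[tr] + 0:(eff_len - 1)]
    welch_power_at(seg, 256, 4.5, seg_len = 256)
  }, numeric(1))
  f <- ev$flicker_freq[!is.na(ev$effect_onset)]
  expect_gt(mean(pw[f == 4.5]), 2 * mean(pw[f == 8]))
})

test_that("zero tagging amplitude leaves no 4.5 Hz excess during flicker", {
  task <- small_task(8L)
  head <- small_head()
  net <- study_coupling_network("placebo", "planning")
  n_sig <- 0L
  for (s in 1:10) {
    rec <- simulate_tagged_eeg(task, head, net, fs = 256, ssvep_amp = 0,
                               snr = 0, source_amp = 0.5, seed = 100 + s)
    ev <- rec$events_table
    ch <- rec$tagged_sensors[1]
    len <- round(500 / 1000 * 256)
    ok <- which(!is.na(rec$events_table$effect_onset))
    flick <- vapply(ok, function(tr)
      welch_power_at(rec$data[ch, ev$effect_onset[tr] + 0:(len - 1)],
                     256, 4.5, len), numeric(1))
    base <- vapply(ok, function(tr)
      welch_power_at(rec$data[ch, ev$trial_start[tr] + 0:(len - 1)],
                     256, 4.5, len), numeric(1))
    p <- stats::t.test(flick, base, paired = TRUE)$p.value
    if (p < 0.05) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 1L)
})

test_that("sensor variance decomposes into source + tag + noise parts", {
  task <- small_task(6L)
  head <- small_head()
  net <- study_coupling_network("placebo", "planning")
  rel_err <- vapply(1:20, function(s) {
    rec <- simulate_tagged_eeg(task, head, net, fs = 256, ssvep_amp = 2,
                               snr = 2, seed = 300 + s)
    tot <- mean(apply(rec$data, 1, stats::var))
    parts <- sum(vapply(rec$parts, function(p)
      mean(apply(p, 1, stats::var)), numeric(1)))
    abs(tot - parts) / tot
  }, numeric(1))
  expect_lt(mean(rel_err), 0.05)
})

test_that("all generators are bit-reproducible under a fixed seed", {
  task <- small_task(6L)
  head1 <- make_toy_leadfield(16L, c(5L, 5L, 5L), seed = 7)
  head2 <- make_toy_leadfield(16L, c(5L, 5L, 5L), seed = 7)
  expect_identical(head1, head2)
  net <- study_coupling_network("mph", "perception")
  d1 <- simulate_source_dynamics(net, 500, seed = 3)
  d2 <- simulate_source_dynamics(net, 500, seed = 3)
  expect_identical(d1, d2)
  r1 <- simulate_tagged_eeg(task, head1, net, fs = 256, seed = 4)
  r2 <- simulate_tagged_eeg(task, head1, net, fs = 256, seed = 4)
  expect_identical(r1$data, r2$data)
})

test_that("study coupling networks encode the condition-by-phase reversal", {
  base <- study_coupling_network("placebo", "planning")
  expect_equal(base$lin_coeffs[3, 1, 1], base$lin_coeffs[1, 3, 1])
  pla <- study_coupling_network("placebo", "perception")
  mph <- study_coupling_network("mph", "perception")
  # placebo: ATL -> IFC strong; mph: reversed
  expect_gt(pla$lin_coeffs[3, 1, 1], pla$lin_coeffs[1, 3, 1])
  expect_gt(mph$lin_coeffs[1, 3, 1], mph$lin_coeffs[3, 1, 1])
  expect_equal(pla$lin_coeffs[3, 1, 1], mph$lin_coeffs[1, 3, 1])
})
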