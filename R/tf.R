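# complex 'same' convolution via FFT (zero-padded to a 2-3-5-smooth length)
conv_same <- function(x, kern) {
  n <- length(x); m <- length(kern)
  L <- stats::nextn(n + m - 1L, c(2, 3, 5))
  X <- stats::fft(c(x, rep(0, L - n)))
  Kf <- stats::fft(c(kern, rep(0, L - m)))
  full <- stats::fft(X * Kf, inverse = TRUE) / L
  start <- (m - 1L) %/% 2L + 1L
  full[start:(start + n - 1L)]
}

# Morlet kernel at frequency f: complex exponential under a Gaussian with
# sigma_t = n_cycles / (2 pi f), truncated at +/- trunc_sd sigma, normalized
# so a unit-amplitude sinusoid at f yields |conv| ~= 1
morlet_kernel <- function(f, fs, n_cycles = 5, trunc_sd = 3) {
  sigma <- n_cycles / (2 * pi * f)
  t <- seq(-trunc_sd * sigma, trunc_sd * sigma, by = 1 / fs)
  env <- exp(-t^2 / (2 * sigma^2))
  k <- env * exp(1i * 2 * pi * f * t)
  k / (sum(env) / 2)
}

#' Morlet time-frequency decomposition
#'
#' Convolves every trial and channel with complex Morlet wavelets
#' (`n_cycles` cycles; Gaussian support truncated at `trunc_sd` standard
#' deviations, i.e. a wavelet length of 3 sigma on either side by default)
#' and averages squared magnitude over trials. Power is normalized so a
#' unit-amplitude sinusoid at a wavelet's centre frequency has power 1.
#'
#' @param epochs an [epoch_recording()] result.
#' @param freqs frequencies of interest in Hz, strictly increasing.
#' @param n_cycles wavelet cycles (scalar or per-frequency).
#' @param trunc_sd truncation of the Gaussian envelope, in SD units.
#' @param keep_trials if `TRUE`, also return the per-trial power array.
#' @return object of class `"tfr"`: `power` (channels x freqs x times),
#'   `freqs`, `times_ms`, `n_cycles`, `n_trials`, and optionally
#'   `trial_power` (trials x channels x freqs x times).
#' @export
morlet_tfr <- function(epochs, freqs, n_cycles = 5, trunc_sd = 3,
                       keep_trials = FALSE) {
  stopifnot(inherits(epochs, "epoched_eeg"))
  if (is.unsorted(freqs, strictly = TRUE))
    stop_config("`freqs` must be strictly increasing")
  n_cycles <- rep_len(n_cycles, length(freqs))
  dims <- dim(epochs$data)
  epoch_sec <- dims[3] / epochs$fs
  for (i in seq_along(freqs))
    if (epoch_sec < n_cycles[i] / freqs[i])
      stop_config("frequency %g Hz unresolvable: epoch %.2fs < %g cycles",
                  freqs[i], epoch_sec, n_cycles[i])
  kerns <- lapply(seq_along(freqs), function(i)
    morlet_kernel(freqs[i], epochs$fs, n_cycles[i], trunc_sd))
  tp <- array(0, dim = c(dims[1], dims[2], length(freqs), dims[3]))
  for (tr in seq_len(dims[1]))
    for (ch in seq_len(dims[2])) {
      x <- epochs$data[tr, ch, ]
      for (fi in seq_along(freqs))
        tp[tr, ch, fi, ] <- Mod(conv_same(x, kerns[[fi]]))^2
    }
  power <- apply(tp, c(2, 3, 4), mean)
  out <- structure(list(power = power, freqs = freqs,
                        times_ms = epochs$times_ms, n_cycles = n_cycles,
                        n_trials = dims[1], fs = epochs$fs,
                        lock = epochs$lock,
                        channel_names = epochs$channel_names),
                   class = "tfr")
  if (keep_trials) out$trial_power <- tp
  out
}

#' Baseline-relative power change
#'
#' `relchange(c, f, t) = (P(c, f, t) - B(c, f)) / B(c, f)` where `B` is the
#' mean power over the baseline window (endpoints inclusive at sample
#' resolution).
#'
#' @param tfr a [morlet_tfr()] result.
#' @param baseline_window length-2 ms window, default `c(-350, -150)`
#'   (cue-locked).
#' @return object of class `"rel_tfr"` with `relchange` shaped like
#'   `tfr$power`, plus axis metadata.
#' @export
relative_power_change <- function(tfr, baseline_window = c(-350, -150)) {
  stopifnot(inherits(tfr, "tfr"))
  sel <- tfr$times_ms >= baseline_window[1] & tfr$times_ms <= baseline_window[2]
  if (!any(sel)) stop_config("baseline window outside epoch")
  B <- apply(tfr$power[, , sel, drop = FALSE], c(1, 2), mean)
  if (any(B <= 0)) {
    bad <- which(B <= 0, arr.ind = TRUE)[1, ]
    stop_config("degenerate baseline: zero power at channel %d, %g Hz",
                bad[1], tfr$freqs[bad[2]])
  }
  rel <- sweep(sweep(tfr$power, c(1, 2), B, "-"), c(1, 2), B, "/")
  structure(list(relchange = rel, freqs = tfr$freqs, times_ms = tfr$times_ms,
                 baseline_window = baseline_window, fs = tfr$fs,
                 lock = tfr$lock, channel_names = tfr$channel_names),
            class = "rel_tfr")
}

#' Pointwise paired contrast with FDR correction
#'
#' Paired two-sided t-tests at every (electrode, time) point between two
#' per-subject measures (e.g. relative power at the 4.5 Hz and 8 Hz measured
#' frequencies), with Benjamini-Hochberg correction applied jointly across
#' all tested points. Points with zero within-pair variance yield an
#' undefined statistic and are excluded from the FDR family.
#'
#' @param a,b numeric arrays `subjects x electrodes x times`, aligned by
#'   subject.
#' @param alpha FDR level for the significance mask.
#' @return list with matrices `t`, `p`, `p_fdr`, `mask`
#'   (electrodes x times), plus `n` and `n_excluded`.
#' @export
pointwise_paired_contrast <- function(a, b, alpha = 0.05) {
  if (!identical(dim(a), dim(b)))
    stop_config("pairing error: input arrays differ in shape")
  n <- dim(a)[1]
  if (n < 3) stop_config("need at least 3 subjects")
  d <- a - b
  m <- apply(d, c(2, 3), mean)
  s <- apply(d, c(2, 3), stats::sd)
  # zero within-pair variance (up to float noise) is undefined, not p = 0
  degenerate <- s <= 1e-10 * pmax(1, abs(m))
  tmat <- ifelse(!degenerate, m / (s / sqrt(n)), NA_real_)
  pmat <- 2 * stats::pt(-abs(tmat), df = n - 1)
  padj <- matrix(NA_real_, nrow(pmat), ncol(pmat))
  ok <- !is.na(pmat)
  padj[ok] <- stats::p.adjust(pmat[ok], method = "BH")
  mask <- !is.na(padj) & padj < alpha
  list(t = tmat, p = pmat, p_fdr = padj, mask = mask,
       n = n, n_excluded = sum(!ok))
}

#' Analysis phase windows
#'
#' The three successive 1000 ms analysis phases: "planning" (0-1000 ms,
#' cue-locked), "standby" (1000-2000 ms, cue-locked) and "perception"
#' (0-1000 ms, action-effect-locked).
#'
#' @return named list of `list(window_ms =, lock =)` entries.
#' @export
phase_windows <- function() {
  list(planning   = list(window_ms = c(0, 1000),    lock = "cue"),
       standby    = list(window_ms = c(1000, 2000), lock = "cue"),
       perception = list(window_ms = c(0, 1000),    lock = "effect"))
}

#' Slice phase windows out of a time axis
#'
#' Half-open `[start, end)` selection at sample resolution. The object's
#' lock must match the phase's lock.
#'
#' @param times_ms time axis in ms.
#' @param lock lock of the data the axis belongs to (`"cue"`/`"effect"`).
#' @param phases phase definitions, default [phase_windows()].
#' @param phase optional single phase name; requesting a phase whose lock
#'   does not match `lock` is an error.
#' @return named list of integer index vectors, one per matching phase.
#' @export
segment_phases <- function(times_ms, lock, phases = phase_windows(),
                           phase = NULL) {
  if (!is.null(phase)) {
    if (is.null(phases[[phase]])) stop_config("unknown phase '%s'", phase)
    if (phases[[phase]]$lock != lock)
      stop_config("lock mismatch: phase '%s' is %s-locked, data are %s-locked",
                  phase, phases[[phase]]$lock, lock)
    phases <- phases[phase]
  }
  out <- list()
  for (nm in names(phases)) {
    ph <- phases[[nm]]
    if (ph$lock != lock) next
    idx <- which(times_ms >= ph$window_ms[1] & times_ms < ph$window_ms[2])
    if (!length(idx) ||
        ph$window_ms[1] < min(times_ms) || ph$window_ms[2] > max(times_ms) + 1)
      stop_config("phase '%s' window outside the %s-locked epoch", nm, lock)
    out[[nm]] <- idx
  }
  if (!length(out))
    stop_config("no phase defined for lock '%s'", lock)
  out
}
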