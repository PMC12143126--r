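#' Task configuration for the action-effect binding experiment
#'
#' Describes the forced-choice task timeline: a fixation circle, a colored cue
#' presented for 2 s, a 1 s response window after cue offset, and -- for
#' correct responses only -- immediate presentation of a flickering visual
#' action effect (4.5 or 8 Hz) for 2 s. The defaults reproduce the study
#' design: 300 trials, 150 per flicker frequency.
#'
#' @param n_trials total number of trials.
#' @param flicker_freqs length-2 numeric, the two tagging frequencies in Hz.
#' @param trials_per_freq length-2 integer, trials per flicker frequency;
#'   must sum to `n_trials`.
#' @param cue_duration,response_window,effect_duration,pre_cue_fixation
#'   durations in ms.
#' @return an object of class `"aeb_task"`.
#' @export
task_config <- function(n_trials = 300L,
                        flicker_freqs = c(4.5, 8),
                        trials_per_freq = c(150L, 150L),
                        cue_duration = 2000,
                        response_window = 1000,
                        effect_duration = 2000,
                        pre_cue_fixation = 2000) {
  n_trials <- check_count(n_trials, "n_trials")
  if (length(flicker_freqs) != 2L || anyDuplicated(flicker_freqs))
    stop_config("`flicker_freqs` must be two distinct frequencies")
  if (length(trials_per_freq) != 2L || sum(trials_per_freq) != n_trials)
    stop_config("`trials_per_freq` must sum to n_trials (%d)", n_trials)
  for (d in c(cue_duration, response_window, effect_duration, pre_cue_fixation))
    if (!is.finite(d) || d <= 0) stop_config("all durations must be > 0")
  structure(list(n_trials = n_trials,
                 flicker_freqs = as.numeric(flicker_freqs),
                 trials_per_freq = as.integer(trials_per_freq),
                 cue_duration = cue_duration,
                 response_window = response_window,
                 effect_duration = effect_duration,
                 pre_cue_fixation = pre_cue_fixation),
            class = "aeb_task")
}

#' Simulate a randomized trial event table
#'
#' Draws a randomized trial order (exactly `trials_per_freq` trials per
#' flicker frequency), response times, and correctness flags. The per-trial
#' timeline is fixation -> cue -> response window -> action effect; correct
#' responses trigger the action effect immediately at the response sample,
#' while incorrect or missing responses yield no effect onset (`NA`).
#'
#' @param task an [task_config()] object.
#' @param fs sampling rate in Hz used to place events on a sample grid.
#' @param accuracy probability of a correct (and in-time) response.
#' @param rt_mean,rt_sd response-time distribution (ms), truncated to
#'   (100, response_window).
#' @param seed integer RNG seed; identical seeds give identical tables.
#' @return a `data.frame` with one row per trial: `trial`, `flicker_freq`,
#'   `trial_start`, `cue_onset`, `response`, `effect_onset` (samples, 1-based),
#'   and logical `correct`.
#' @export
simulate_trial_events <- function(task, fs = 500, accuracy = 0.97,
                                  rt_mean = 285, rt_sd = 50, seed = 1L) {
  stopifnot(inherits(task, "aeb_task"))
  check_scalar_num(accuracy, "accuracy", 0, 1)
  check_scalar_num(fs, "fs", 1)
  set.seed(seed)
  n <- task$n_trials
  freqs <- sample(rep(task$flicker_freqs, times = task$trials_per_freq))
  ms2smp <- function(ms) round(ms / 1000 * fs)
  trial_len <- ms2smp(task$pre_cue_fixation + task$cue_duration +
                      task$response_window + task$effect_duration)
  trial_start <- 1L + (seq_len(n) - 1L) * trial_len
  cue_onset <- trial_start + ms2smp(task$pre_cue_fixation)
  rt <- pmin(pmax(stats::rnorm(n, rt_mean, rt_sd), 100), task$response_window - 1)
  correct <- stats::runif(n) < accuracy
  # responses follow cue offset, within the response window
  response <- cue_onset + ms2smp(task$cue_duration) + ms2smp(rt)
  effect_onset <- ifelse(correct, response, NA_integer_)
  data.frame(trial = seq_len(n),
             flicker_freq = freqs,
             trial_start = as.integer(trial_start),
             cue_onset = as.integer(cue_onset),
             response = as.integer(response),
             effect_onset = as.integer(effect_onset),
             correct = correct)
}
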