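#' Ground-truth coupling network for one condition and phase
#'
#' Builds the 3-node (ATL, IC, IFC) network used by the synthetic
#' within-subject study. Every node has a stable private AR(2) backbone.
#' Cross-couplings between every pair are symmetric at `base`, except the
#' manipulated pair during the `asym_phase`, where the coupling is
#' asymmetric (`strong` one way, `weak` the other) -- and the asymmetric
#' direction is reversed between the two conditions. This mirrors a
#' condition-by-phase reversal of directed-communication asymmetry with a
#' known direction of truth. Optionally the same manipulation is applied to
#' a quadratic nonlinear coupling.
#'
#' @param condition `"placebo"` or `"mph"`.
#' @param phase `"planning"`, `"standby"` or `"perception"`.
#' @param base symmetric cross-coupling strength (lag 1).
#' @param strong,weak asymmetric coupling strengths in the manipulated
#'   phase.
#' @param asym_phase phase carrying the asymmetry.
#' @param asym_pair manipulated pair, indices into (ATL, IC, IFC); the
#'   `strong` direction under placebo runs `asym_pair[1] -> asym_pair[2]`.
#' @param nl_gain gain of quadratic couplings on the manipulated pair
#'   (0 = linear-only scenario).
#' @param noise_sd innovation SD.
#' @return an [ground_truth_network()] object.
#' @export
study_coupling_network <- function(condition = c("placebo", "mph"),
                                   phase = c("planning", "standby",
                                             "perception"),
                                   base = 0.15, strong = 0.45, weak = 0.05,
                                   asym_phase = "perception",
                                   asym_pair = c(1L, 3L),
                                   nl_gain = 0, noise_sd = 1) {
  condition <- match.arg(condition)
  phase <- match.arg(phase)
  K <- 3L; p <- 3L
  A <- array(0, dim = c(K, K, p))
  for (i in seq_len(K)) { A[i, i, 1] <- 0.5; A[i, i, 2] <- -0.3 }
  pairs <- utils::combn(K, 2)
  for (q in seq_len(ncol(pairs))) {
    a <- pairs[1, q]; b <- pairs[2, q]
    A[b, a, 1] <- base; A[a, b, 1] <- base     # symmetric default (j -> i)
  }
  nl <- list()
  if (phase == asym_phase) {
    a <- asym_pair[1]; b <- asym_pair[2]
    fwd <- condition == "placebo"              # placebo: a -> b strong
    A[b, a, 1] <- if (fwd) strong else weak
    A[a, b, 1] <- if (fwd) weak else strong
    if (nl_gain > 0)
      nl <- list(nl_term("quadratic",
                         from = if (fwd) a else b,
                         to = if (fwd) b else a, gain = nl_gain, lag = 1L))
  }
  ground_truth_network(A, nl_terms = nl, noise_sd = noise_sd)
}

#' Simulate per-subject ROI dynamics for the full study design
#'
#' Generates, for every subject, condition and phase, one multichannel ROI
#' time series from [study_coupling_network()] via
#' [simulate_source_dynamics()]. Between-subject variability enters through
#' independent innovation streams (per-subject seeds).
#'
#' @param n_subjects number of subjects.
#' @param n_samples samples per subject x condition x phase series.
#' @param fs sampling rate in Hz.
#' @param seed master seed; per-cell seeds are derived deterministically.
#' @param conditions,phases design cells.
#' @param ... coupling parameters passed to [study_coupling_network()].
#' @return nested list `study[[condition]][[phase]]`, each a list of
#'   `n_subjects` series matrices (`3 x n_samples`), with the generating
#'   networks attached as `attr(, "network")`.
#' @export
simulate_roi_study <- function(n_subjects = 54L, n_samples = 2000L,
                               fs = 256, seed = 1L,
                               conditions = c("placebo", "mph"),
                               phases = c("planning", "standby",
                                          "perception"), ...) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  study <- list()
  cell <- 0L
  for (cond in conditions) {
    study[[cond]] <- list()
    for (ph in phases) {
      cell <- cell + 1L
      net <- study_coupling_network(cond, ph, ...)
      subj <- lapply(seq_len(n_subjects), function(s)
        simulate_source_dynamics(net, n_samples, fs = fs,
                                 seed = seed * 100000L + cell * 1000L + s)$series)
      attr(subj, "network") <- net
      study[[cond]][[ph]] <- subj
    }
  }
  study
}

#' Fit connectivity for every cell of a simulated study
#'
#' Runs [estimate_connectivity()] per subject x condition x phase and stacks
#' the results into the arrays expected by [build_connectivity_report()].
#'
#' @param study output of [simulate_roi_study()].
#' @param ... hyperparameters passed to [estimate_connectivity()]
#'   (`p`, `n_hidden`, `maxit`, ...).
#' @return nested list `conn[[condition]][[phase]]$linear` /
#'   `$nonlinear`, arrays `subjects x 3 x 3` indexed `[ , from, to]`.
#' @export
fit_study_connectivity <- function(study, ...) {
  conn <- list()
  for (cond in names(study)) {
    conn[[cond]] <- list()
    for (ph in names(study[[cond]])) {
      subj <- study[[cond]][[ph]]
      n <- length(subj); K <- nrow(subj[[1]])
      lin <- array(NA_real_, c(n, K, K))
      nl <- array(NA_real_, c(n, K, K))
      for (s in seq_len(n)) {
        est <- estimate_connectivity(subj[[s]], ...)
        lin[s, , ] <- est$linear
        nl[s, , ] <- est$nonlinear
      }
      conn[[cond]][[ph]] <- list(linear = lin, nonlinear = nl)
    }
  }
  conn
}

#' Simulate paired behavioral data (RT and accuracy)
#'
#' Per-subject mean RTs and accuracies for the two conditions with a true
#' within-subject RT speed-up under the active condition. Defaults emulate
#' the study's behavioral profile: placebo RT around 293 ms, an average
#' 16.5 ms RT advantage for the active condition, and accuracies near
#' ceiling.
#'
#' @param n_subjects number of subjects.
#' @param rt_placebo mean placebo RT (ms).
#' @param rt_effect true RT difference, placebo minus active (ms).
#' @param rt_between between-subject SD of mean RT (ms).
#' @param rt_within SD of the paired RT difference (ms).
#' @param acc_placebo,acc_effect,acc_within accuracy analogues.
#' @param seed RNG seed.
#' @return list of two data.frames (`rt`, `accuracy`) in the long format
#'   required by [behavioral_stats()].
#' @export
simulate_behavioral <- function(n_subjects = 54L, rt_placebo = 293,
                                rt_effect = 16.5, rt_between = 50,
                                rt_within = 31,
                                acc_placebo = 0.97, acc_effect = -0.005,
                                acc_within = 0.04, seed = 1L) {
  set.seed(seed)
  base_rt <- stats::rnorm(n_subjects, rt_placebo, rt_between)
  diff_rt <- stats::rnorm(n_subjects, rt_effect, rt_within)
  base_acc <- pmin(1, stats::rnorm(n_subjects, acc_placebo, 0.02))
  diff_acc <- stats::rnorm(n_subjects, acc_effect, acc_within)
  subj <- seq_len(n_subjects)
  rt <- rbind(data.frame(subject = subj, condition = "placebo", rt = base_rt),
              data.frame(subject = subj, condition = "mph",
                         rt = base_rt - diff_rt))
  acc <- rbind(data.frame(subject = subj, condition = "placebo",
                          accuracy = base_acc),
               data.frame(subject = subj, condition = "mph",
                          accuracy = pmin(1, base_acc - diff_acc)))
  list(rt = rt, accuracy = acc)
}
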