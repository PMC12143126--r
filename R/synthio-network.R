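#' Nonlinear coupling term for a ground-truth network
#'
#' One directed nonlinear interaction feeding node `to` at lag `lag`.
#' Supported forms: `"quadratic"` (`gain * x_from(t-lag)^2`), `"product"`
#' (`gain * x_from(t-lag) * x_from2(t-lag)`), and `"tanh"`
#' (`gain * tanh(x_from(t-lag))`, a saturating transfer).
#'
#' @param form one of `"quadratic"`, `"product"`, `"tanh"`.
#' @param from,to node indices (source and target).
#' @param gain coupling gain.
#' @param lag lag in samples, `>= 1`.
#' @param from2 second source node, required for `"product"`.
#' @export
nl_term <- function(form, from, to, gain, lag = 1L, from2 = NULL) {
  form <- match.arg(form, c("quadratic", "product", "tanh"))
  if (form == "product" && is.null(from2))
    stop_config("product terms need `from2`")
  if (!is.finite(gain)) stop_config("nonlinear gain must be finite")
  list(form = form, from = as.integer(from), to = as.integer(to),
       gain = gain, lag = check_count(lag, "lag"), from2 = from2)
}

#' Ground-truth directed network for synthetic source dynamics
#'
#' Defines a K-node nonlinear multivariate autoregressive system with known
#' linear coefficients and nonlinear coupling terms, used to generate node
#' time series whose directed-connectivity structure is known exactly.
#' Stationarity of the linear part is enforced through the spectral radius of
#' the companion matrix.
#'
#' @param lin_coeffs numeric array `K x K x p`; `lin_coeffs[i, j, k]` is the
#'   coefficient of `x_j(t-k)` in the equation of `x_i(t)` (so `j -> i`).
#' @param nl_terms list of [nl_term()] descriptors.
#' @param noise_sd innovation standard deviation.
#' @param node_names node labels; defaults to the study's ROI names.
#' @return an object of class `"aeb_network"` with fields `lin_coeffs`,
#'   `nl_terms`, `noise_sd`, `order`, `n_nodes`, `node_names`,
#'   `spectral_radius`.
#' @export
ground_truth_network <- function(lin_coeffs,
                                 nl_terms = list(),
                                 noise_sd = 1,
                                 node_names = NULL) {
  if (length(dim(lin_coeffs)) != 3L || dim(lin_coeffs)[1] != dim(lin_coeffs)[2])
    stop_config("`lin_coeffs` must be a K x K x p array")
  K <- dim(lin_coeffs)[1]
  p <- dim(lin_coeffs)[3]
  if (is.null(node_names))
    node_names <- if (K == 3L) c("ATL", "IC", "IFC") else paste0("n", seq_len(K))
  check_scalar_num(noise_sd, "noise_sd", 0)
  rho <- companion_spectral_radius(lin_coeffs)
  if (rho >= 1)
    stop_config("unstable linear coefficient set: companion spectral radius %.3f >= 1", rho)
  for (term in nl_terms) {
    if (!is.list(term) || is.null(term$form)) stop_config("nl_terms must be nl_term() objects")
    if (term$from > K || term$to > K) stop_config("nl_term node index out of range")
  }
  structure(list(n_nodes = K, order = p, lin_coeffs = lin_coeffs,
                 nl_terms = nl_terms, noise_sd = noise_sd,
                 node_names = node_names, spectral_radius = rho),
            class = "aeb_network")
}

#' Spectral radius of the VAR companion matrix
#'
#' @param lin_coeffs `K x K x p` coefficient array.
#' @return largest eigenvalue modulus of the `Kp x Kp` companion matrix.
#' @export
companion_spectral_radius <- function(lin_coeffs) {
  K <- dim(lin_coeffs)[1]; p <- dim(lin_coeffs)[3]
  comp <- matrix(0, K * p, K * p)
  for (k in seq_len(p))
    comp[1:K, (k - 1) * K + 1:K] <- lin_coeffs[, , k]
  if (p > 1)
    comp[(K + 1):(K * p), 1:(K * (p - 1))] <- diag(K * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Ground-truth adjacency matrices of a network
#'
#' @param net an [ground_truth_network()] object.
#' @return list of two `K x K` logical matrices (`linear`, `nonlinear`)
#'   indexed `[from, to]`; exactly the support of the nonzero couplings,
#'   diagonal always `FALSE`.
#' @export
network_adjacency <- function(net) {
  stopifnot(inherits(net, "aeb_network"))
  K <- net$n_nodes
  lin <- matrix(FALSE, K, K, dimnames = list(net$node_names, net$node_names))
  for (j in seq_len(K)) for (i in seq_len(K))
    if (i != j && any(net$lin_coeffs[i, j, ] != 0)) lin[j, i] <- TRUE
  nl <- matrix(FALSE, K, K, dimnames = dimnames(lin))
  for (term in net$nl_terms) {
    if (term$from != term$to) nl[term$from, term$to] <- TRUE
    if (!is.null(term$from2) && term$from2 != term$to) nl[term$from2, term$to] <- TRUE
  }
  list(linear = lin, nonlinear = nl)
}

#' Simulate coupled source dynamics with known directed ground truth
#'
#' Runs the nonlinear multivariate autoregression
#' `x_i(t) = sum_j sum_k a[i,j,k] x_j(t-k) + sum(nl terms -> i) + drive + e_i(t)`
#' forward from zero initial conditions, discarding a burn-in. An optional
#' oscillatory theta drive at `drive_freq` can be added per node to give the
#' sources a band-limited spectral signature.
#'
#' @param net an [ground_truth_network()] object.
#' @param n_samples samples to return (after burn-in).
#' @param fs sampling rate in Hz (used only for the oscillatory drive).
#' @param seed RNG seed.
#' @param theta_amp per-node amplitude(s) of a sinusoidal drive (0 = none).
#' @param drive_freq drive frequency in Hz.
#' @param burn_in samples discarded at the start.
#' @return list with `series` (`K x n_samples`), `lin_adj`, `nl_adj`
#'   (logical `K x K`, `[from, to]`), and `fs`.
#' @export
simulate_source_dynamics <- function(net, n_samples, fs = 256, seed = 1L,
                                     theta_amp = 0, drive_freq = 4.5,
                                     burn_in = 500L) {
  stopifnot(inherits(net, "aeb_network"))
  n_samples <- check_count(n_samples, "n_samples")
  K <- net$n_nodes; p <- net$order
  ntot <- n_samples + burn_in
  theta_amp <- rep_len(theta_amp, K)
  set.seed(seed)
  eps <- matrix(stats::rnorm(K * ntot, sd = net$noise_sd), K, ntot)
  # quasi-periodic drive: per-node slow phase random walks (~1 s coherence
  # time) keep each rhythm narrowband without phase-locking it to the
  # stimulus or to the other nodes -- coherence between nodes should come
  # from the coupling, not from a shared oscillator
  drive <- matrix(0, K, ntot)
  tgrid <- 2 * pi * drive_freq * seq_len(ntot) / fs
  for (i in seq_len(K))
    if (theta_amp[i] != 0) {
      phase <- stats::runif(1, 0, 2 * pi) +
        cumsum(stats::rnorm(ntot, 0, sqrt(2 / fs)))
      drive[i, ] <- theta_amp[i] * sin(tgrid + phase)
    }
  x <- matrix(0, K, ntot)
  A <- net$lin_coeffs
  for (t in (p + 1):ntot) {
    acc <- eps[, t] + drive[, t]
    for (k in seq_len(p)) acc <- acc + A[, , k] %*% x[, t - k]
    for (term in net$nl_terms) {
      v <- x[term$from, t - term$lag]
      val <- switch(term$form,
                    quadratic = term$gain * v^2,
                    product   = term$gain * v * x[term$from2, t - term$lag],
                    tanh      = term$gain * tanh(v))
      acc[term$to] <- acc[term$to] + val
    }
    x[, t] <- acc
  }
  adj <- network_adjacency(net)
  series <- x[, (burn_in + 1):ntot, drop = FALSE]
  rownames(series) <- net$node_names
  list(series = series, lin_adj = adj$linear, nl_adj = adj$nonlinear, fs = fs)
}
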