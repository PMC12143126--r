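# Independent oracles and shared fixtures for the test suite.
# Everything here is deliberately written from first principles (brute
# force / definitional), independent of the package's implementation paths.

# --- brute-force Benjamini-Hochberg step-up rejection set ---------------
# returns the logical rejection vector at level q by the literal step-up
# definition: largest k with p_(k) <= k/m * q, reject all p <= p_(k)
bh_reject_bruteforce <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- max(c(0L, which(ps <= seq_len(m) / m * q)))
  if (k == 0L) return(rep(FALSE, m))
  p <= ps[k]
}

# --- naive direct AR recursion (independent of simulate_source_dynamics) -
# coefs: K x K x p ([i, j, k] coefficient of x_j(t-k) in x_i)
ar_recursion_oracle <- function(coefs, n, seed, noise_sd = 1, burn = 200) {
  K <- dim(coefs)[1]; p <- dim(coefs)[3]
  set.seed(seed)
  x <- matrix(0, K, n + burn)
  for (t in (p + 1):(n + burn)) {
    v <- stats::rnorm(K, sd = noise_sd)
    for (i in 1:K) for (j in 1:K) for (k in 1:p)
      v[i] <- v[i] + coefs[i, j, k] * x[j, t - k]
    x[, t] <- v
  }
  x[, (burn + 1):(burn + n), drop = FALSE]
}

# --- DBSCAN oracle: connected components of the core-point graph --------
# (border points attach to the first core neighbor in index order,
# matching deterministic input-order semantics)
dbscan_oracle <- function(coords, eps, min_samples) {
  skip_if_not_installed("igraph")
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_samples
  g <- igraph::make_empty_graph(n, directed = FALSE)
  for (i in which(core)) for (j in nb[[i]])
    if (core[j] && j > i) g <- igraph::add_edges(g, c(i, j))
  comp <- igraph::components(g)$membership
  labels <- integer(n)
  core_comps <- sort(unique(comp[core]))
  relabel <- stats::setNames(seq_along(core_comps), core_comps)
  labels[core] <- relabel[as.character(comp[core])]
  for (i in which(!core)) {
    cn <- nb[[i]][core[nb[[i]]]]
    if (length(cn)) labels[i] <- labels[cn[1]]
  }
  labels
}

# --- Welch-style band power (mean periodogram over segments) ------------
welch_power_at <- function(x, fs, freq, seg_len = 512) {
  n <- length(x)
  starts <- seq(1, n - seg_len + 1, by = seg_len %/% 2)
  vals <- vapply(starts, function(s0) {
    seg <- x[s0:(s0 + seg_len - 1)]
    h <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = seg_len))
    coef <- sum(seg * h * exp(-1i * 2 * pi * freq * (0:(seg_len - 1)) / fs))
    Mod(coef * 2 / sum(h))^2
  }, numeric(1))
  mean(vals)
}

# --- small shared fixtures ----------------------------------------------
small_head <- function(seed = 3) make_toy_leadfield(24L, c(5L, 5L, 5L), seed = seed)

small_task <- function(n = 10L) {
  half <- n %/% 2L
  task_config(n_trials = n, trials_per_freq = c(half, n - half))
}

# quick hyperparameters for connectivity fits in tests
quick_fit <- list(p = 2L, n_hidden = 6L, maxit = 80L)

# single-edge VAR network: from -> to with coefficient a at lag 1,
# mild self-dynamics on each node
single_edge_network <- function(K = 3, from = 1, to = 2, a = 0.8,
                                lag = 1, p = 2) {
  A <- array(0, dim = c(K, K, p))
  for (i in 1:K) A[i, i, 1] <- 0.3
  A[to, from, lag] <- a
  ground_truth_network(A, node_names = paste0("n", 1:K))
}
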