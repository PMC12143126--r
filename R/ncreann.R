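#' Lag-embed a multichannel series for one-step prediction
#'
#' Row `t` of the design matrix holds `x_j(t-1), ..., x_j(t-p)` for every
#' channel `j`, channel-major (channel 1's lags first); the matching target
#' row is `x(t)`. A list of series (trials) is embedded per trial and row-
#' bound, so no design row straddles a trial boundary.
#'
#' @param series numeric `K x T` matrix, or a list of such matrices.
#' @param p model order (lags).
#' @return list with `design` (`(T-p) x (K*p)`) and `target` (`(T-p) x K`).
#' @export
embed_lags <- function(series, p) {
  p <- check_count(p, "p")
  if (is.list(series)) {
    parts <- lapply(series, embed_lags, p = p)
    return(list(design = do.call(rbind, lapply(parts, `[[`, "design")),
                target = do.call(rbind, lapply(parts, `[[`, "target"))))
  }
  K <- nrow(series); Tn <- ncol(series)
  if (Tn <= p) stop_config("series too short for order %d", p)
  rows <- (p + 1):Tn
  design <- matrix(NA_real_, length(rows), K * p)
  for (j in seq_len(K))
    for (k in seq_len(p))
      design[, (j - 1) * p + k] <- series[j, rows - k]
  list(design = design, target = t(series[, rows, drop = FALSE]))
}

# tanh MLP forward pass
mlp_forward <- function(par, X) {
  Z <- tanh(X %*% t(par$W_in) + rep(par$b_h, each = nrow(X)))
  Z %*% t(par$W_out) + rep(par$b_o, each = nrow(X))
}

mlp_unpack <- function(w, nin, H, K) {
  list(W_in  = matrix(w[seq_len(H * nin)], H, nin),
       b_h   = w[H * nin + seq_len(H)],
       W_out = matrix(w[H * nin + H + seq_len(K * H)], K, H),
       b_o   = w[H * nin + H + K * H + seq_len(K)])
}

#' Fit a neural-network nonlinear multivariate autoregressive model
#'
#' A single-hidden-layer tanh network predicting `x(t)` from the lag-embedded
#' past is fitted by full-batch BFGS (analytic gradients, deterministic
#' seeded initialization) on z-scored data. The train/test split is
#' contiguous (first `train_frac` of embedding rows), respecting temporal
#' dependence. Per-channel MSE and R-squared are computed on the z-scored
#' scale for both splits; a model whose mean test R-squared falls below
#' `r2_floor` is flagged (not silently used).
#'
#' @param series `K x T` matrix or list of per-trial matrices (trials are
#'   demeaned per channel before concatenated embedding).
#' @param p model order (lags).
#' @param n_hidden hidden units.
#' @param maxit BFGS iteration budget.
#' @param train_frac fraction of rows used for training.
#' @param decay L2 weight penalty.
#' @param r2_floor flag threshold on mean test R-squared.
#' @param seed RNG seed for weight initialization.
#' @return object of class `"nmvar"`: weight matrices `W_in`, `b_h`,
#'   `W_out`, `b_o`, `p`, `n_hidden`, `scaler` (per-channel mean/SD from the
#'   train split), `metrics` (train/test MSE and R-squared per channel),
#'   `flagged`, `node_names`, `config`.
#' @export
train_nmvar <- function(series, p = 3L, n_hidden = 10L, maxit = 200L,
                        train_frac = 0.8, decay = 1e-3, r2_floor = 0.1,
                        seed = 1L) {
  p <- check_count(p, "p"); n_hidden <- check_count(n_hidden, "n_hidden")
  check_scalar_num(train_frac, "train_frac", 0.1, 0.95)
  if (is.list(series)) {
    series <- lapply(series, function(s) s - rowMeans(s))
    K <- nrow(series[[1]])
    node_names <- rownames(series[[1]])
    Ttot <- sum(vapply(series, ncol, integer(1)))
  } else {
    K <- nrow(series)
    node_names <- rownames(series)
    Ttot <- ncol(series)
  }
  if (Ttot <= p + 10 * K * p)
    stop_config("too few samples (%d) for K=%d, p=%d", Ttot, K, p)
  if (is.null(node_names)) node_names <- paste0("n", seq_len(K))

  emb <- embed_lags(series, p)
  n_rows <- nrow(emb$design)
  n_train <- floor(train_frac * n_rows)
  tr_idx <- seq_len(n_train); te_idx <- (n_train + 1):n_rows

  # scaler from the train split, per channel (applies to lags identically)
  centre <- colMeans(emb$target[tr_idx, , drop = FALSE])
  scale <- apply(emb$target[tr_idx, , drop = FALSE], 2, stats::sd)
  if (any(scale <= 0))
    stop_config("zero-variance channel %d in train split",
                which(scale <= 0)[1])
  Yz <- zscore_apply(emb$target, centre, scale)
  Xz <- zscore_apply(emb$design, rep(centre, each = p), rep(scale, each = p))

  Xtr <- Xz[tr_idx, , drop = FALSE]; Ytr <- Yz[tr_idx, , drop = FALSE]
  nin <- ncol(Xtr); H <- n_hidden
  set.seed(seed)
  w0 <- stats::runif(H * (nin + 1) + K * (H + 1), -0.5, 0.5) / sqrt(nin)
  Tn <- nrow(Xtr)
  fn <- function(w) {
    par <- mlp_unpack(w, nin, H, K)
    E <- mlp_forward(par, Xtr) - Ytr
    v <- mean(E^2) + decay * sum(w^2)
    if (!is.finite(v)) stop_config("divergent training: non-finite loss")
    v
  }
  gr <- function(w) {
    par <- mlp_unpack(w, nin, H, K)
    A <- Xtr %*% t(par$W_in) + rep(par$b_h, each = Tn)
    Z <- tanh(A)
    E <- Z %*% t(par$W_out) + rep(par$b_o, each = Tn) - Ytr
    cc <- 2 / (Tn * K)
    D <- (E %*% par$W_out) * (1 - Z^2)
    c(as.vector(cc * t(D) %*% Xtr), cc * colSums(D),
      as.vector(cc * t(E) %*% Z), cc * colSums(E)) + 2 * decay * w
  }
  opt <- stats::optim(w0, fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  par <- mlp_unpack(opt$par, nin, H, K)

  split_metrics <- function(idx) {
    P <- mlp_forward(par, Xz[idx, , drop = FALSE])
    Yv <- Yz[idx, , drop = FALSE]
    mse <- colMeans((P - Yv)^2)
    sst <- colSums(sweep(Yv, 2, colMeans(Yv))^2)
    r2 <- ifelse(sst > 0, 1 - colSums((P - Yv)^2) / sst, NA_real_)
    list(mse = mse, r2 = r2)
  }
  metrics <- list(train = split_metrics(tr_idx), test = split_metrics(te_idx))
  flagged <- mean(metrics$test$r2, na.rm = TRUE) < r2_floor
  structure(list(W_in = par$W_in, b_h = par$b_h, W_out = par$W_out,
                 b_o = par$b_o, p = p, n_hidden = H, n_channels = K,
                 scaler = list(centre = centre, scale = scale),
                 metrics = metrics, flagged = flagged,
                 node_names = node_names,
                 config = list(maxit = maxit, train_frac = train_frac,
                               decay = decay, seed = seed,
                               convergence = opt$convergence)),
            class = "nmvar")
}

#' @export
print.nmvar <- function(x, ...) {
  cat(sprintf("nmvar: K=%d, p=%d, %d hidden; test R2 = %s%s\n",
              x$n_channels, x$p, x$n_hidden,
              paste(sprintf("%.2f", x$metrics$test$r2), collapse = " "),
              if (x$flagged) " [FLAGGED: poor fit]" else ""))
  invisible(x)
}

# z-score a raw series (or trial list) with the model's scaler and embed it
embed_with_scaler <- function(model, series) {
  zs <- function(s) (s - model$scaler$centre) / model$scaler$scale
  series <- if (is.list(series))
    lapply(series, function(s) zs(s - rowMeans(s))) else zs(series)
  emb_raw <- embed_lags(series, model$p)
  list(design = emb_raw$design, target = emb_raw$target)
}

#' Taylor decomposition of a fitted network
#'
#' First-order expansion of the network around the z-scored data mean
#' (`z = 0`): with hidden pre-activation `u_h(z) = W_in[h, ] z + b_h`,
#' `A[i, (j,k)] = sum_h W_out[i, h] sech^2(b_h) W_in[h, (j,k)]` is the
#' linear map, and the nonlinear component is the exact residual
#' `nl(z) = f(z) - A z - f(0)`, so `f(z) = A z + nl(z) + f(0)` holds at
#' every point.
#'
#' @param model an [train_nmvar()] fit.
#' @return list with `A` (`K x K*p`), `f0` (output at `z = 0`), and
#'   function `nonlinear(Z)` evaluating the residual on design rows.
#' @export
taylor_decompose <- function(model) {
  stopifnot(inherits(model, "nmvar"))
  sech2 <- 1 / cosh(model$b_h)^2
  A <- model$W_out %*% (model$W_in * sech2)
  f0 <- as.numeric(model$W_out %*% tanh(model$b_h) + model$b_o)
  nonlinear <- function(Z) {
    full <- mlp_forward(model, Z)
    full - Z %*% t(A) - rep(f0, each = nrow(Z))
  }
  list(A = A, f0 = f0, nonlinear = nonlinear)
}

#' Directed linear connectivity from a fitted model
#'
#' `L[j -> i]` is the time-averaged magnitude of channel `j`'s first-order
#' contribution to the prediction of channel `i`:
#' `mean_t | sum_k A[i, (j,k)] x_j(t-k) |`, on the z-scored scale.
#'
#' @param model an [train_nmvar()] fit.
#' @param series the series (or trial list) to evaluate on.
#' @return `K x K` matrix indexed `[from, to]`, diagonal `NA`.
#' @export
linear_connectivity <- function(model, series) {
  emb <- embed_with_scaler(model, series)
  dec <- taylor_decompose(model)
  K <- model$n_channels; p <- model$p
  L <- matrix(NA_real_, K, K,
              dimnames = list(model$node_names, model$node_names))
  for (j in seq_len(K)) {
    cols <- (j - 1) * p + seq_len(p)
    contrib <- emb$design[, cols, drop = FALSE] %*%
      t(dec$A[, cols, drop = FALSE])           # T x K targets
    for (i in seq_len(K)) if (i != j) L[j, i] <- mean(abs(contrib[, i]))
  }
  L
}

#' Directed nonlinear connectivity from a fitted model
#'
#' `NL[j -> i]` is the time-averaged deviation of the network's
#' instantaneous sensitivity from the global linear term:
#' `mean_{t,k} | J_i,(j,k)(z_t) - A[i,(j,k)] |` where
#' `J_i,(j,k)(z) = sum_h W_out[i,h] sech^2(u_h(z)) W_in[h,(j,k)]` is the
#' network Jacobian at the observed point.
#'
#' @inheritParams linear_connectivity
#' @return `K x K` matrix indexed `[from, to]`, diagonal `NA`.
#' @export
nonlinear_connectivity <- function(model, series) {
  emb <- embed_with_scaler(model, series)
  K <- model$n_channels; p <- model$p
  U <- emb$design %*% t(model$W_in) + rep(model$b_h, each = nrow(emb$design))
  Dev <- 1 / cosh(U)^2 - rep(1 / cosh(model$b_h)^2, each = nrow(U))  # T x H
  NL <- matrix(NA_real_, K, K,
               dimnames = list(model$node_names, model$node_names))
  for (i in seq_len(K)) {
    Wi <- model$W_in * model$W_out[i, ]        # H x (K p), rows weighted
    Mi <- Dev %*% Wi                           # T x (K p)
    for (j in seq_len(K)) if (i != j) {
      cols <- (j - 1) * p + seq_len(p)
      NL[j, i] <- mean(abs(Mi[, cols]))
    }
  }
  NL
}

#' Evaluate a fitted model on held-out data
#'
#' @param model an [train_nmvar()] fit.
#' @param series held-out `K x T` series (or trial list); z-scored with the
#'   model's scaler.
#' @return list with per-channel `mse`, `r2` (NA for zero-variance
#'   channels), and `mean_mse`, `mean_r2`.
#' @export
evaluate_model <- function(model, series) {
  emb <- embed_with_scaler(model, series)
  P <- mlp_forward(model, emb$design)
  Yv <- emb$target
  mse <- colMeans((P - Yv)^2)
  sst <- colSums(sweep(Yv, 2, colMeans(Yv))^2)
  r2 <- ifelse(sst > 0, 1 - colSums((P - Yv)^2) / sst, NA_real_)
  list(mse = mse, r2 = r2, mean_mse = mean(mse), mean_r2 = mean(r2, na.rm = TRUE))
}

#' Fit and summarize directed connectivity for one series
#'
#' Convenience wrapper: fits [train_nmvar()] and evaluates
#' [linear_connectivity()] and [nonlinear_connectivity()] on the same data.
#'
#' @inheritParams train_nmvar
#' @param ... passed to [train_nmvar()].
#' @return object of class `"connectivity"`: `linear`, `nonlinear`
#'   (`K x K`, `[from, to]`, diagonal `NA`), and the `model`.
#' @export
estimate_connectivity <- function(series, ...) {
  model <- train_nmvar(series, ...)
  structure(list(linear = linear_connectivity(model, series),
                 nonlinear = nonlinear_connectivity(model, series),
                 model = model),
            class = "connectivity")
}
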