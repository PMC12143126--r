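#' Cross-spectral density at one frequency
#'
#' Per trial, the windowed data are Hann-tapered and projected onto a complex
#' exponential at `freq`; the CSD is the trial average of the outer products
#' of these Fourier coefficients, Hermitian by construction.
#'
#' @param epochs an [epoch_recording()] result.
#' @param freq frequency in Hz.
#' @param window_ms analysis window within the epoch (default: whole epoch);
#'   must span at least 2 cycles of `freq`.
#' @return object of class `"csd"`: `matrix` (channels x channels, complex),
#'   `freq`, `window_ms`, `n_trials`, `taper`.
#' @export
compute_csd <- function(epochs, freq, window_ms = NULL) {
  stopifnot(inherits(epochs, "epoched_eeg"))
  if (is.null(window_ms))
    window_ms <- range(epochs$times_ms) + c(0, 1000 / epochs$fs)
  idx <- which(epochs$times_ms >= window_ms[1] & epochs$times_ms < window_ms[2])
  if (length(idx) / epochs$fs < 2 / freq)
    stop_config("CSD window %.0f ms too short for %g Hz (need >= 2 cycles)",
                length(idx) / epochs$fs * 1000, freq)
  nt <- dim(epochs$data)[1]; nch <- dim(epochs$data)[2]
  h <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = length(idx)))
  ex <- exp(-1i * 2 * pi * freq * (idx - idx[1]) / epochs$fs) * h * 2 / sum(h)
  C <- matrix(0 + 0i, nch, nch)
  for (tr in seq_len(nt)) {
    coef <- epochs$data[tr, , idx, drop = TRUE] %*% ex   # nch complex
    C <- C + coef %*% Conj(t(coef))
  }
  structure(list(matrix = C / nt, freq = freq, window_ms = window_ms,
                 n_trials = nt, taper = "hann"),
            class = "csd")
}

# shared unit-gain minimum-variance filter: w = Cinv l / (l' Cinv l)
mv_filters <- function(Creg, leadfield, voxels) {
  Cinv <- tryCatch(solve(Creg),
                   error = function(e)
                     stop_config(paste0("covariance inversion failed (%s); ",
                                        "use lambda_frac > 0"), conditionMessage(e)))
  W <- matrix(0, length(voxels), nrow(leadfield))
  for (i in seq_along(voxels)) {
    l <- leadfield[, voxels[i]]
    cl <- Cinv %*% l
    W[i, ] <- cl / as.numeric(crossprod(l, cl))
  }
  W
}

#' DICS source power map
#'
#' Frequency-domain beamformer: with `C_reg = Re(C) + lambda * mean(diag(Re(C))) * I`,
#' each voxel's unit-gain filter is `w = C_reg^-1 l / (l' C_reg^-1 l)` and its
#' power `Re(w' C w)`.
#'
#' @param csd a [compute_csd()] result.
#' @param head an [make_toy_leadfield()] object (rows must match channels).
#' @param lambda_frac regularization as a fraction of mean sensor power.
#' @return object of class `"source_power_map"`: `power` (per voxel),
#'   `lambda_frac`, `freq`, and the `head` reference.
#' @export
dics_power <- function(csd, head, lambda_frac = 0.05) {
  stopifnot(inherits(csd, "csd"), inherits(head, "aeb_head"))
  if (nrow(head$leadfield) != nrow(csd$matrix))
    stop_config("leadfield rows (%d) != CSD channels (%d)",
                nrow(head$leadfield), nrow(csd$matrix))
  check_scalar_num(lambda_frac, "lambda_frac", 0)
  Cre <- Re(csd$matrix)
  Creg <- Cre + lambda_frac * mean(diag(Cre)) * diag(nrow(Cre))
  W <- mv_filters(Creg, head$leadfield, seq_len(ncol(head$leadfield)))
  power <- vapply(seq_len(nrow(W)), function(v) {
    w <- W[v, ]
    Re(Conj(w) %*% csd$matrix %*% w)[1]
  }, numeric(1))
  structure(list(power = power, lambda_frac = lambda_frac, freq = csd$freq,
                 head = head),
            class = "source_power_map")
}

#' Select the top percentage of source-power voxels
#'
#' Keeps the `ceil(pct/100 * n_voxels)` highest-power voxels; ties at the cut
#' are all included.
#'
#' @param map a [dics_power()] result (or a bare numeric power vector).
#' @param pct percentage in (0, 100).
#' @return logical voxel mask.
#' @export
threshold_top_percent <- function(map, pct = 3) {
  power <- if (inherits(map, "source_power_map")) map$power else map
  check_scalar_num(pct, "pct", 1e-12, 100 - 1e-12)
  k <- ceiling(pct / 100 * length(power))
  cut <- sort(power, decreasing = TRUE)[k]
  power >= cut
}

#' DBSCAN clustering of selected voxels
#'
#' Classic DBSCAN (core / border / noise semantics) on Euclidean distances;
#' deterministic given the input order. Points not assigned to any cluster
#' are labeled `0` (noise).
#'
#' @param coords numeric matrix, points x 3 (mm or cm, consistent with `eps`).
#' @param eps neighborhood radius.
#' @param min_samples minimum neighborhood size (including the point itself)
#'   for a core point.
#' @return integer vector of cluster labels (`0` = noise).
#' @export
cluster_voxels <- function(coords, eps, min_samples = 3L) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop_config("coords must be finite")
  check_scalar_num(eps, "eps", 1e-12)
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_samples
  labels <- integer(n)          # 0 = unvisited/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      if (!core[q]) next
      for (j in nb[[q]]) {
        if (labels[j] == 0L) {
          labels[j] <- cl
          if (core[j]) queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

#' Consolidate voxel clusters into named ROIs
#'
#' Each non-noise cluster is assigned the majority region label of its
#' voxels (ties broken by lexicographic label order, with a message);
#' clusters mapping to the same target label are merged; voxels carrying a
#' subcortical label are dropped before voting; only the requested ROI names
#' are retained.
#'
#' @param selected_idx integer voxel indices (into the head model) that
#'   entered clustering.
#' @param clusters cluster labels from [cluster_voxels()], aligned with
#'   `selected_idx`.
#' @param head an [make_toy_leadfield()] object.
#' @param roi_names required ROI names.
#' @param subcortical_labels labels excluded from ROIs.
#' @return object of class `"roi_set"`: named list `rois` of voxel-index
#'   vectors plus a `provenance` data.frame (cluster id, vote label).
#' @export
rois_from_clusters <- function(selected_idx, clusters, head,
                               roi_names = c("ATL", "IC", "IFC"),
                               subcortical_labels = character()) {
  stopifnot(inherits(head, "aeb_head"),
            length(selected_idx) == length(clusters))
  if (!any(clusters > 0)) stop_config("no non-noise clusters")
  rois <- stats::setNames(vector("list", length(roi_names)), roi_names)
  prov <- NULL
  for (cl in sort(unique(clusters[clusters > 0]))) {
    vox <- selected_idx[clusters == cl]
    labs <- head$voxel_labels[vox]
    keep <- !(labs %in% subcortical_labels)
    vox <- vox[keep]; labs <- labs[keep]
    if (!length(vox)) next
    tab <- table(labs)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) > 1)
      message(sprintf("cluster %d: label tie (%s), taking '%s'",
                      cl, paste(winners, collapse = "/"), min(winners)))
    lab <- min(winners)           # lexicographic tie-break
    prov <- rbind(prov, data.frame(cluster = cl, label = lab,
                                   n_voxels = length(vox)))
    if (lab %in% roi_names)
      rois[[lab]] <- sort(unique(c(rois[[lab]], vox)))
  }
  empty <- roi_names[vapply(rois, is.null, logical(1))]
  if (length(empty))
    stop_config("incomplete ROI set: no voxels for %s",
                paste(empty, collapse = ", "))
  structure(list(rois = rois, provenance = prov), class = "roi_set")
}

#' LCMV virtual-sensor time series for ROIs
#'
#' Time-domain minimum-variance beamformer: the sensor covariance over the
#' analysis window is regularized as in [dics_power()], per-voxel unit-gain
#' filters are applied to every trial, voxel series within an ROI are
#' sign-aligned to the first voxel (correlation sign) and averaged.
#'
#' @param epochs an [epoch_recording()] result.
#' @param head an [make_toy_leadfield()] object.
#' @param rois a [rois_from_clusters()] result (or a named list of voxel
#'   indices).
#' @param lambda_frac regularization fraction.
#' @return object of class `"virtual_sensors"`: `data`
#'   (trials x rois x time), `fs`, `times_ms`, `lock`, `roi_names`.
#' @export
lcmv_virtual_sensors <- function(epochs, head, rois, lambda_frac = 0.05) {
  stopifnot(inherits(epochs, "epoched_eeg"), inherits(head, "aeb_head"))
  roi_list <- if (inherits(rois, "roi_set")) rois$rois else rois
  dims <- dim(epochs$data)
  # time-domain covariance from demeaned concatenated trials
  X <- matrix(aperm(epochs$data, c(2, 3, 1)), nrow = dims[2])
  X <- X - rowMeans(X)
  C <- tcrossprod(X) / ncol(X)
  Creg <- C + lambda_frac * mean(diag(C)) * diag(nrow(C))
  out <- array(0, dim = c(dims[1], length(roi_list), dims[3]))
  for (r in seq_along(roi_list)) {
    vox <- roi_list[[r]]
    W <- mv_filters(Creg, head$leadfield, vox)     # n_vox x nch
    series <- W %*% X                              # n_vox x (time*trials)
    sgn <- c(1, vapply(seq_len(nrow(series))[-1], function(v) {
      s <- stats::cor(series[1, ], series[v, ])
      if (is.na(s) || s >= 0) 1 else -1
    }, numeric(1)))
    roi_cat <- colMeans(series * sgn)
    out[, r, ] <- t(matrix(roi_cat, nrow = dims[3]))
  }
  structure(list(data = out, fs = epochs$fs, times_ms = epochs$times_ms,
                 lock = epochs$lock, roi_names = names(roi_list)),
            class = "virtual_sensors")
}

#' Theta power of ROI virtual sensors per phase
#'
#' Morlet power at `freq` computed per trial and ROI, averaged over the time
#' samples of each phase window and over trials.
#'
#' @param vs a [lcmv_virtual_sensors()] result.
#' @param freq analysis frequency in Hz.
#' @param n_cycles Morlet cycles.
#' @param phases phase definitions, default [phase_windows()]; only phases
#'   matching the data's lock are computed.
#' @return matrix phases x ROIs of mean power.
#' @export
roi_theta_power <- function(vs, freq = 4.5, n_cycles = 5,
                            phases = phase_windows()) {
  stopifnot(inherits(vs, "virtual_sensors"))
  idx <- segment_phases(vs$times_ms, vs$lock, phases)
  kern <- morlet_kernel(freq, vs$fs, n_cycles)
  dims <- dim(vs$data)
  pw <- array(0, dim = c(dims[1], dims[2], dims[3]))
  for (tr in seq_len(dims[1]))
    for (r in seq_len(dims[2]))
      pw[tr, r, ] <- Mod(conv_same(vs$data[tr, r, ], kern))^2
  out <- matrix(NA_real_, length(idx), dims[2],
                dimnames = list(names(idx), vs$roi_names))
  for (ph in seq_along(idx))
    out[ph, ] <- apply(pw[, , idx[[ph]], drop = FALSE], 2, mean)
  out
}
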