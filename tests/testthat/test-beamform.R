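epochs_from_matrix <- function(X, fs = 256, n_trials = 1) {
  # X: channels x samples, replicated across trials
  arr <- array(0, dim = c(n_trials, nrow(X), ncol(X)))
  for (tr in seq_len(n_trials)) arr[tr, , ] <- X
  trials_epochs(arr, fs)
}

trials_epochs <- function(arr, fs = 256) {
  # arr: trials x channels x samples
  structure(list(data = arr, fs = fs,
                 window_ms = c(0, dim(arr)[3] / fs * 1000), lock = "effect",
                 times_ms = (0:(dim(arr)[3] - 1)) / fs * 1000,
                 channel_names = paste0("E", seq_len(dim(arr)[2])),
                 metadata = NULL, n_dropped = 0L),
            class = "epoched_eeg")
}

test_that("CSD is Hermitian-PSD, sees perfect coherence, and matches Welch on the diagonal", {
  fs <- 256; n <- 512
  x <- sin(2 * pi * 4.5 * (0:(n - 1)) / fs)
  ep <- epochs_from_matrix(rbind(x, x))
  csd <- compute_csd(ep, 4.5)
  M <- csd$matrix
  expect_lt(max(abs(M - Conj(t(M)))), 1e-10)
  coh <- Mod(M[1, 2])^2 / (Re(M[1, 1]) * Re(M[2, 2]))
  expect_equal(coh, 1, tolerance = 1e-6)

  # diagonal equals Welch band power for a single sinusoid channel
  wp <- welch_power_at(x, fs, 4.5, seg_len = n)
  expect_lt(abs(Re(M[1, 1]) - wp) / wp, 0.05)

  expect_error(compute_csd(ep, 4.5, window_ms = c(0, 100)), "too short")
})

test_that("independent white-noise channels show negligible coherence", {
  fs <- 256; nt <- 500; ns <- 128
  cohs <- vapply(1:10, function(s) {
    set.seed(s)
    arr <- array(rnorm(nt * 2 * ns), dim = c(nt, 2, ns))
    M <- compute_csd(trials_epochs(arr), 8)$matrix
    Mod(M[1, 2])^2 / (Re(M[1, 1]) * Re(M[2, 2]))
  }, numeric(1))
  expect_lt(max(cohs), 0.05)
})

test_that("DICS recovers a point source and stays flat on pure noise", {
  head <- small_head()
  fs <- 256; ns <- 512; nt <- 30
  eig_ok <- 0
  for (s in 1:3) {
    v_true <- c(20L, 60L, 100L)[s]
    src <- sin(2 * pi * 4.5 * (0:(ns - 1)) / fs + s)
    g <- head$leadfield[, v_true]
    arr <- array(0, dim = c(nt, nrow(head$leadfield), ns))
    set.seed(s)
    for (tr in 1:nt)
      arr[tr, , ] <- outer(g, src * rnorm(1, 1, 0.1)) +
        matrix(rnorm(length(g) * ns, sd = 1e-6 * max(g)), ncol = ns)
    map <- dics_power(compute_csd(trials_epochs(arr), 4.5), head,
                      lambda_frac = 1e-6)
    expect_equal(which.max(map$power), v_true)
  }

  # null flatness: pure sensor noise gives no dominant voxel
  ratios <- vapply(1:10, function(s) {
    set.seed(400 + s)
    arr <- array(rnorm(20 * nrow(head$leadfield) * 256),
                 dim = c(20, nrow(head$leadfield), 256))
    map <- dics_power(compute_csd(trials_epochs(arr), 4.5), head, 0.05)
    max(map$power) / stats::median(map$power)
  }, numeric(1))
  expect_lt(max(ratios), 5)
})

test_that("unit-gain constraint holds for every voxel filter", {
  head <- small_head()
  set.seed(5)
  C <- crossprod(matrix(rnorm(40 * nrow(head$leadfield)), 40))
  Creg <- C + 0.05 * mean(diag(C)) * diag(nrow(C))
  W <- aebnet:::mv_filters(Creg, head$leadfield, seq_len(50))
  gains <- vapply(1:50, function(v) sum(W[v, ] * head$leadfield[, v]),
                  numeric(1))
  expect_lt(max(abs(gains - 1)), 1e-8)
})

test_that("two independent equal-power sources both appear as map maxima", {
  head <- small_head()
  fs <- 256; ns <- 512; nt <- 40
  v1 <- 20L; v2 <- 105L
  set.seed(9)
  arr <- array(0, dim = c(nt, nrow(head$leadfield), ns))
  for (tr in 1:nt) {
    s1 <- sin(2 * pi * 4.5 * (0:(ns - 1)) / fs + runif(1, 0, 2 * pi))
    s2 <- sin(2 * pi * 4.5 * (0:(ns - 1)) / fs + runif(1, 0, 2 * pi))
    arr[tr, , ] <- outer(head$leadfield[, v1] / max(head$leadfield[, v1]), s1) +
                   outer(head$leadfield[, v2] / max(head$leadfield[, v2]), s2) +
      matrix(rnorm(nrow(head$leadfield) * ns, sd = 0.01), ncol = ns)
  }
  map <- dics_power(compute_csd(trials_epochs(arr), 4.5), head, 0.01)
  top <- order(map$power, decreasing = TRUE)[1:10]
  d <- function(a, b) sqrt(sum((head$voxel_coords[a, ] - head$voxel_coords[b, ])^2))
  expect_lt(min(vapply(top, d, numeric(1), b = v1)), 1.5 * head$grid_spacing)
  expect_lt(min(vapply(top, d, numeric(1), b = v2)), 1.5 * head$grid_spacing)
})

test_that("top-percent thresholding implements the ceil rule with tie inclusion", {
  expect_equal(sum(threshold_top_percent(1:100, 3)), 3L)
  expect_true(all(threshold_top_percent(rep(1, 50), 3)))   # all tied
  m <- threshold_top_percent(1:200, 3)
  expect_equal(which(m), 195:200)                          # ceil(6) = 6
  expect_error(threshold_top_percent(1:10, 0), "pct")
})

test_that("DBSCAN separates distant groups, labels isolates as noise, and matches the graph oracle", {
  set.seed(2)
  g1 <- matrix(rnorm(30, sd = 0.2), 10, 3)
  g2 <- matrix(rnorm(30, sd = 0.2), 10, 3) + 10
  cl <- cluster_voxels(rbind(g1, g2), eps = 2, min_samples = 3)
  expect_equal(length(unique(cl)), 2L)
  expect_false(any(cl == 0))
  expect_true(all(cl[1:10] == cl[1]) && all(cl[11:20] == cl[11]))

  iso <- cluster_voxels(rbind(g1, c(50, 50, 50)), eps = 2, min_samples = 3)
  expect_equal(iso[11], 0L)

  # marginally bridged fixtures vs an independent graph formulation:
  # the noise set and the core-point partition are the deterministic parts
  # of DBSCAN semantics and must agree exactly
  for (s in 1:5) {
    set.seed(s)
    pts <- rbind(matrix(runif(60, 0, 4), ncol = 3),
                 matrix(runif(60, 3, 7), ncol = 3))
    eps <- 1.0
    ours <- cluster_voxels(pts, eps, 4)
    oracle <- dbscan_oracle(pts, eps, 4)
    expect_equal(which(ours == 0), which(oracle == 0))
    D <- as.matrix(dist(pts))
    core <- vapply(seq_len(nrow(pts)), function(i)
      sum(D[i, ] <= eps), numeric(1)) >= 4
    co_ours <- outer(ours[core], ours[core], "==")
    co_oracle <- outer(oracle[core], oracle[core], "==")
    expect_equal(co_ours, co_oracle)
  }
})

test_that("ROI consolidation follows majority labels with lexicographic ties", {
  head <- small_head()
  atl <- which(head$voxel_labels == "ATL")[1:4]
  ifc <- which(head$voxel_labels == "IFC")[1:4]
  sel <- c(atl, ifc)
  cl <- c(rep(1L, 4), rep(2L, 4))
  rs <- rois_from_clusters(sel, cl, head, roi_names = c("ATL", "IFC"))
  expect_equal(sort(rs$rois$ATL), sort(atl))
  expect_equal(sort(rs$rois$IFC), sort(ifc))

  # 60/40 majority
  ic <- which(head$voxel_labels == "IC")[1:2]
  mixed <- c(which(head$voxel_labels == "IC")[3:5], atl[1:2])
  rs2 <- rois_from_clusters(c(mixed, ifc), c(rep(1L, 5), rep(2L, 4)), head,
                            roi_names = c("IC", "IFC"))
  expect_true(all(mixed %in% rs2$rois$IC))

  # 50/50 tie -> lexicographically first label, with a message
  tie <- c(atl[1:2], ic)
  expect_message(
    rs3 <- rois_from_clusters(c(tie, ifc), c(rep(1L, 4), rep(2L, 4)), head,
                              roi_names = c("ATL", "IFC")),
    "tie")
  expect_true(all(tie %in% rs3$rois$ATL))

  expect_error(rois_from_clusters(atl, rep(1L, 4), head,
                                  roi_names = c("ATL", "IC", "IFC")),
               "incomplete ROI")
})

test_that("LCMV virtual sensors recover in-ROI sources and reject out-of-ROI leakage", {
  head <- small_head()
  fs <- 256; ns <- 768; nt <- 20
  nodes <- region_center_voxels(head, c("ATL", "IFC"))
  net <- single_edge_network(K = 2, a = 0)
  rois <- list(ATL = as.integer(nodes["ATL"] + c(0, 1)),
               IFC = as.integer(nodes["IFC"] + c(0, 1)))

  # noiseless single source in ATL
  set.seed(12)
  src <- as.numeric(arima.sim(list(ar = c(0.5, -0.3)), ns * nt))
  arr <- array(0, dim = c(nt, nrow(head$leadfield), ns))
  for (tr in 1:nt)
    arr[tr, , ] <- outer(head$leadfield[, nodes["ATL"]],
                         src[(tr - 1) * ns + 1:ns]) +
      matrix(rnorm(nrow(head$leadfield) * ns, sd = 1e-8), ncol = ns)
  vs <- lcmv_virtual_sensors(trials_epochs(arr), head, rois, lambda_frac = 1e-8)
  rec_atl <- as.numeric(t(vs$data[, 1, ]))
  expect_gt(abs(stats::cor(rec_atl, src)), 0.99)

  # independent sources in the two ROIs separate cleanly at SNR 10
  set.seed(13)
  s1 <- as.numeric(arima.sim(list(ar = 0.5), ns * nt))
  s2 <- as.numeric(arima.sim(list(ar = 0.5), ns * nt))
  amp <- function(g) g / max(abs(g))
  for (tr in 1:nt)
    arr[tr, , ] <- outer(amp(head$leadfield[, nodes["ATL"]]),
                         s1[(tr - 1) * ns + 1:ns]) +
                   outer(amp(head$leadfield[, nodes["IFC"]]),
                         s2[(tr - 1) * ns + 1:ns]) +
      matrix(rnorm(nrow(head$leadfield) * ns, sd = 0.1), ncol = ns)
  vs2 <- lcmv_virtual_sensors(trials_epochs(arr), head, rois, 0.01)
  r_atl <- as.numeric(t(vs2$data[, 1, ])); r_ifc <- as.numeric(t(vs2$data[, 2, ]))
  expect_gt(abs(stats::cor(r_atl, s1)), 0.9)
  expect_gt(abs(stats::cor(r_ifc, s2)), 0.9)
  expect_lt(abs(stats::cor(r_atl, r_ifc)), 0.2)

  # a source far from both ROIs leaks weakly
  occ <- region_center_voxels(head, "OCC")
  set.seed(14)
  s3 <- as.numeric(arima.sim(list(ar = 0.5), ns * nt))
  for (tr in 1:nt)
    arr[tr, , ] <- outer(amp(head$leadfield[, occ]), s3[(tr - 1) * ns + 1:ns]) +
      matrix(rnorm(nrow(head$leadfield) * ns, sd = 0.05), ncol = ns)
  vs3 <- lcmv_virtual_sensors(trials_epochs(arr), head, rois, 0.01)
  expect_lt(abs(stats::cor(as.numeric(t(vs3$data[, 1, ])), s3)), 0.3)
})

test_that("ROI theta power obeys the amplitude square law and matches a Fourier oracle", {
  fs <- 256; ns <- 6 * fs
  t <- (0:(ns - 1)) / fs
  # cue-locked virtual sensor: amplitude doubles in the standby phase
  amp <- ifelse(t - 2 >= 1 & t - 2 < 2, 2, 1)     # times_ms = (t-2)*1000
  x <- amp * sin(2 * pi * 4.5 * t)
  vs <- structure(list(data = array(x, dim = c(1, 1, ns)), fs = fs,
                       times_ms = (t - 2) * 1000, lock = "cue",
                       roi_names = "ATL"),
                  class = "virtual_sensors")
  # windows kept clear of the amplitude step by > 3 wavelet SDs
  margin_phases <- list(
    pre  = list(window_ms = c(100, 750), lock = "cue"),
    post = list(window_ms = c(1300, 1900), lock = "cue"))
  pw <- roi_theta_power(vs, 4.5, n_cycles = 2, phases = margin_phases)
  expect_equal(unname(pw["post", 1] / pw["pre", 1]), 4, tolerance = 0.05)

  # constant sinusoid: power equal across phases and ~1 (unit amplitude)
  vs$data[1, 1, ] <- sin(2 * pi * 4.5 * t)
  pw2 <- roi_theta_power(vs, 4.5)
  expect_equal(unname(pw2["planning", 1]), unname(pw2["standby", 1]),
               tolerance = 0.02)
  fo <- welch_power_at(sin(2 * pi * 4.5 * t), fs, 4.5, seg_len = 1024)
  expect_lt(abs(pw2["planning", 1] - fo) / fo, 0.05)
})
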