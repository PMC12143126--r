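#' Build a toy spherical head model with leadfield and region labels
#'
#' Sensors are placed on the upper hemisphere of a 10 cm sphere (Fibonacci
#' lattice, so no two sensors coincide); voxels fill a regular grid inside the
#' head. Gains fall off with the inverse square of sensor-voxel distance,
#' which gives smooth, full-diversity leadfield columns without any tissue
#' modeling. Voxels are partitioned into four named regions by nearest region
#' seed: stand-ins for the anterior temporal lobe (`ATL`), insular cortex
#' (`IC`), inferior frontal cortex (`IFC`), and an occipital patch (`OCC`)
#' that hosts the visual tagging response.
#'
#' @param n_sensors number of sensors, `>= 8`.
#' @param grid_shape integer length-3, voxels per axis, each `>= 4`.
#' @param seed RNG seed (small sensor jitter only).
#' @param jitter sd of tangential sensor jitter in cm.
#' @return an object of class `"aeb_head"` with `leadfield`
#'   (sensors x voxels), `voxel_coords` (voxels x 3, cm), `voxel_labels`,
#'   `sensor_pos`, `sensor_names`, `grid_spacing` (cm).
#' @export
make_toy_leadfield <- function(n_sensors = 32L, grid_shape = c(6L, 6L, 6L),
                               seed = 1L, jitter = 0.05) {
  n_sensors <- check_count(n_sensors, "n_sensors", min = 8L)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    stop_config("`grid_shape` must be three counts >= 4")
  set.seed(seed)
  # Fibonacci lattice on the upper hemisphere, radius 10 cm
  i <- seq_len(n_sensors) - 0.5
  golden <- (1 + sqrt(5)) / 2
  z <- i / n_sensors            # in (0, 1): upper hemisphere
  phi <- 2 * pi * i / golden
  r_xy <- sqrt(pmax(0, 1 - z^2))
  sens <- 10 * cbind(r_xy * cos(phi), r_xy * sin(phi), z)
  sens <- sens + matrix(stats::rnorm(3 * n_sensors, sd = jitter), ncol = 3)
  dup <- which(as.matrix(stats::dist(sens)) < 1e-6 &
               upper.tri(matrix(TRUE, n_sensors, n_sensors)), arr.ind = TRUE)
  if (nrow(dup) > 0) stop_config("degenerate geometry: coincident sensors")

  ax <- lapply(grid_shape, function(m) seq(-6, 6, length.out = m))
  vox <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  spacing <- min(vapply(ax, function(a) diff(a)[1], numeric(1)))

  # inverse-square falloff; soft core keeps gains finite. Columns are
  # normalized to unit L2 norm so beamformer maps carry no depth bias.
  d2 <- outer(rowSums(sens^2), rowSums(vox^2), "+") - 2 * sens %*% t(vox)
  leadfield <- 1 / (d2 + 4)     # cm^2 soft core
  leadfield <- sweep(leadfield, 2L, sqrt(colSums(leadfield^2)), "/")

  seeds <- rbind(ATL = c(4, -4, 0), IC = c(2, 2, 2),
                 IFC = c(4, 4, 4), OCC = c(-5, 0, 2))
  dseed <- outer(rowSums(vox^2), rowSums(seeds^2), "+") - 2 * vox %*% t(seeds)
  voxel_labels <- rownames(seeds)[apply(dseed, 1, which.min)]

  structure(list(leadfield = leadfield,
                 voxel_coords = vox,
                 voxel_labels = voxel_labels,
                 sensor_pos = sens,
                 sensor_names = sprintf("E%02d", seq_len(n_sensors)),
                 grid_spacing = spacing),
            class = "aeb_head")
}

#' Pick one representative voxel per region of a toy head model
#'
#' Returns, for each requested label, the voxel closest to the centroid of
#' that label's voxels -- a convenient place to inject simulated sources.
#'
#' @param head an [make_toy_leadfield()] object.
#' @param labels region labels to map.
#' @return named integer vector of voxel indices.
#' @export
region_center_voxels <- function(head, labels = c("ATL", "IC", "IFC")) {
  stopifnot(inherits(head, "aeb_head"))
  out <- vapply(labels, function(lb) {
    idx <- which(head$voxel_labels == lb)
    if (!length(idx)) stop_config("no voxels labeled %s", lb)
    ctr <- colMeans(head$voxel_coords[idx, , drop = FALSE])
    idx[which.min(rowSums(sweep(head$voxel_coords[idx, , drop = FALSE], 2, ctr)^2))]
  }, integer(1))
  names(out) <- labels
  out
}
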