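## Group network-mask definition from sham-condition seed connectivity:
## a group-level one-sample z map of seed connectivity, a simulated
## Gaussian-noise cluster-size threshold for mask formation, and the
## threshold-cluster-dilate mask builder.

#' Group-level seed connectivity map
#'
#' Per subject, correlates the (possibly individualized) seed's mean
#' series with every voxel of the search mask and Fisher-z transforms;
#' then a one-sample t across subjects against 0 per voxel, standardized
#' to z.
#'
#' @param runs list of [bold_run()]s, one per subject (e.g. sham runs).
#' @param seed one [network_mask()] shared by all subjects, or a list of
#'   per-subject masks aligned with `runs`.
#' @param brain_mask search [network_mask()]; default the whole grid.
#' @return An object of class `group_map`: `t_map`, `z_map` (3D arrays),
#'   `df`, `n`, `mask`.
#' @export
group_seed_map <- function(runs, seed, brain_mask = NULL) {
  n <- length(runs)
  if (n < 2) stop("need at least 2 subjects")
  geom <- runs[[1]]$geometry
  if (is.null(brain_mask))
    brain_mask <- network_mask(seq_len(prod(geom$shape)), geom, "brain")
  seeds <- if (inherits(seed, "network_mask")) rep(list(seed), n) else seed
  stopifnot(length(seeds) == n)
  Z <- do.call(rbind, lapply(seq_len(n), function(i)
    seed_z_values(runs[[i]], seeds[[i]]$voxels, brain_mask$voxels)))
  m <- colMeans(Z)
  v <- (colSums(Z^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  t <- ifelse(v == 0, ifelse(m == 0, 0, sign(m) * Inf),
              m / sqrt(v / n))
  zz <- t_to_z(t, df = n - 1)
  t_map <- array(NA_real_, geom$shape)
  z_map <- array(NA_real_, geom$shape)
  t_map[brain_mask$voxels] <- t
  z_map[brain_mask$voxels] <- zz
  structure(list(t_map = t_map, z_map = z_map, df = n - 1L, n = n,
                 mask = brain_mask),
            class = "group_map")
}

#' Simulated Gaussian-noise cluster-size threshold
#'
#' The mask-formation analogue of the Monte-Carlo cluster simulation:
#' draws `n_sim` Gaussian noise fields on the grid, smooths them to
#' `smooth_fwhm_mm` (rescaled to unit variance), thresholds two-sided at
#' the `voxel_p` quantile, and records the maximum cluster size; the
#' returned threshold is the smallest size whose exceedance proportion is
#' below `alpha`.
#'
#' @param mask a [network_mask()] defining grid and search region.
#' @param smooth_fwhm_mm smoothness of the simulated fields (mm FWHM).
#' @param voxel_p two-sided voxelwise p threshold, in (0, 1).
#' @param n_sim number of simulated fields (>= 100).
#' @param alpha cluster-level rate, in (0, 1).
#' @param adjacency cluster connectivity.
#' @param seed optional integer.
#' @return Integer threshold in voxels (>= 1).
#' @export
noise_cluster_threshold <- function(mask, smooth_fwhm_mm = 4,
                                    voxel_p = 1e-8, n_sim = 200,
                                    alpha = 0.01, adjacency = 6,
                                    seed = NULL) {
  stopifnot(voxel_p > 0, voxel_p < 1, n_sim >= 100)
  local_seed(seed)
  geom <- mask$geometry
  shape <- geom$shape
  zc <- stats::qnorm(1 - voxel_p / 2)
  vf <- smooth_var_factor(smooth_fwhm_mm, geom$voxel_size_mm)
  sizes <- integer(n_sim)
  for (s in seq_len(n_sim)) {
    field <- array(stats::rnorm(prod(shape)), shape)
    if (smooth_fwhm_mm > 0)
      field <- smooth_volume(field, smooth_fwhm_mm,
                             geom$voxel_size_mm) / sqrt(vf)
    fv <- field[mask$voxels]
    sizes[s] <- max(
      max_component_size(mask$voxels[fv > zc], shape, adjacency),
      max_component_size(mask$voxels[fv < -zc], shape, adjacency))
  }
  size_threshold(sizes, alpha)
}

#' Define a network mask from a group map
#'
#' Thresholds the group z map at the `voxel_p` quantile (positive tail by
#' default: networks are positive-connectivity structures), keeps
#' clusters of at least `cluster_threshold` voxels, dilates, and
#' intersects with the search mask. Errors on an empty result, since
#' connectedness needs a non-empty network.
#'
#' @param group_map a [group_seed_map()] result.
#' @param voxel_p voxelwise p threshold (default 1e-8), mapped to z via
#'   the standard-normal quantile.
#' @param cluster_threshold minimum cluster size in voxels (e.g. from
#'   [noise_cluster_threshold()]).
#' @param dilate_iters dilation iterations after clustering (default 1).
#' @param adjacency cluster/dilation connectivity.
#' @param two_sided admit negative-tail voxels too.
#' @param name mask name.
#' @return A [network_mask()].
#' @export
define_network <- function(group_map, voxel_p = 1e-8,
                           cluster_threshold = 1, dilate_iters = 1,
                           adjacency = 6, two_sided = FALSE,
                           name = "network") {
  zc <- if (two_sided) stats::qnorm(1 - voxel_p / 2)
        else stats::qnorm(1 - voxel_p)
  cl <- label_clusters(group_map$z_map, group_map$mask, zc, adjacency)
  if (!two_sided) cl <- cl[cl$sign == "+", , drop = FALSE]
  cl <- cl[cl$n_voxels >= cluster_threshold, , drop = FALSE]
  vox <- unique(unlist(cl$voxels))
  if (!length(vox))
    stop("no voxels survive network definition; network would be empty")
  m <- network_mask(vox, group_map$mask$geometry, name = name)
  m <- dilate_mask(m, dilate_iters, adjacency)
  network_mask(intersect(m$voxels, group_map$mask$voxels),
               group_map$mask$geometry, name = name)
}

#' Voxel overlap between two masks
#'
#' The overlap of the two network masks is a first-class reported
#' quantity of the mask-definition step.
#'
#' @param a,b [network_mask()]s on compatible geometry.
#' @return Integer count of shared voxels.
#' @export
mask_overlap <- function(a, b) {
  stopifnot(geometry_compatible(a$geometry, b$geometry))
  length(intersect(a$voxels, b$voxels))
}
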