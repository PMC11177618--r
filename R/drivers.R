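## Step 2: hotspot-seeded, network-constrained connectivity contrasts to
## find the "drivers" of each hotspot's connectedness change.

#' Spatially averaged hotspot seed series
#'
#' Unweighted per-frame mean of the run's series over the hotspot's
#' member voxels (all frames; censoring stays flagged on the run).
#'
#' @param run a [bold_run()].
#' @param voxels integer linear voxel indices of the hotspot (non-empty),
#'   or a one-row `cluster_set` subset.
#' @return Numeric series of length `n_frames`.
#' @export
hotspot_seed_series <- function(run, voxels) {
  if (is.data.frame(voxels)) voxels <- voxels$voxels[[1]]
  voxels <- as.integer(unlist(voxels))
  if (!length(voxels)) stop("empty hotspot")
  d <- dim(run$data)
  stopifnot(all(voxels >= 1), all(voxels <= prod(d[1:3])))
  M <- matrix(run$data, prod(d[1:3]), d[4])
  colMeans(M[voxels, , drop = FALSE])
}

## Fisher-z seed connectivity of one run with each candidate voxel
seed_z_values <- function(run, seed_voxels, candidate_voxels) {
  frames <- valid_frames(run)
  s <- hotspot_seed_series(run, seed_voxels)[frames]
  if (stats::sd(s) == 0) stop("constant hotspot seed series")
  s <- (s - mean(s)) / sqrt(sum((s - mean(s))^2))
  X <- run_matrix(run, candidate_voxels, frames)
  u <- unit_columns(X)
  r <- as.vector(crossprod(u$Z, s))
  r[u$const] <- NaN
  suppressWarnings(fisher_z(r))
}

#' Find the drivers of each hotspot
#'
#' Step 2 of the two-step analysis. For every hotspot, its spatially
#' averaged series seeds a voxelwise connectivity map (Fisher-z Pearson
#' r with every network voxel, non-censored frames) per subject and
#' condition; the paired contrast is standardized to z, a per-hotspot
#' sign-flip permutation null calibrates the cluster-size threshold, and
#' clusters at `voxel_z` surviving `max(threshold, floor_voxels)` are the
#' drivers. The hotspot's own voxels are excluded from candidacy by
#' default (the seed trivially correlates with itself).
#'
#' @param hotspots a `cluster_set` from [find_hotspots()].
#' @param runs_a,runs_b subject-aligned run lists for the same contrast
#'   the hotspots came from (checked structurally).
#' @param network the [network_mask()] the analysis is constrained to.
#' @param voxel_z cluster-forming threshold (default 3.291, two-tailed
#'   p < 0.001).
#' @param n_perm,alpha permutation settings (one null per hotspot).
#' @param floor_voxels hard minimum driver size imposed on top of the
#'   permutation threshold (default 20).
#' @param adjacency cluster connectivity (6/18/26).
#' @param allow_self_drivers keep the hotspot's own voxels as candidates.
#' @param seed optional integer; per-hotspot permutation seeds are
#'   derived from it.
#' @return A `cluster_set` of driver records (`parent_id` = hotspot id),
#'   with attribute `perms`, the list of per-hotspot
#'   `perm_distribution`s.
#' @export
find_drivers <- function(hotspots, runs_a, runs_b, network,
                         voxel_z = 3.291, n_perm = 100, alpha = 0.05,
                         floor_voxels = 20, adjacency = 6,
                         allow_self_drivers = FALSE, seed = NULL) {
  stopifnot(length(runs_a) == length(runs_b), length(runs_a) >= 2)
  hs_contrast <- attr(hotspots, "contrast")
  check_contrast(runs_a, runs_b, hs_contrast)
  geom <- network$geometry
  out <- list()
  perms <- list()
  for (h in seq_len(nrow(hotspots))) {
    hvox <- hotspots$voxels[[h]]
    cand <- if (allow_self_drivers) network$voxels
            else setdiff(network$voxels, hvox)
    if (length(cand) < 2) next
    cmask <- network_mask(cand, geom, name = network$name)
    A <- do.call(rbind, lapply(runs_a, seed_z_values, seed_voxels = hvox,
                               candidate_voxels = cand))
    B <- do.call(rbind, lapply(runs_b, seed_z_values, seed_voxels = hvox,
                               candidate_voxels = cand))
    perm <- perm_cluster_threshold(A, B, cmask, voxel_z, n_perm = n_perm,
                                   alpha = alpha, adjacency = adjacency,
                                   seed = child_seed(seed, h))
    zmap <- observed_z_map(A, B, cmask)
    cl <- label_clusters(zmap, cmask, voxel_z, adjacency, role = "driver")
    cl <- apply_cluster_threshold(cl, perm$threshold_voxels, floor_voxels)
    if (nrow(cl)) cl$parent_id <- hotspots$id[h]
    perms[[h]] <- perm
    out[[h]] <- cl
  }
  res <- if (length(out)) do.call(rbind, out) else
    new_cluster_set(list(), character(0),
                    array(0, geom$shape), geom, "driver")
  if (nrow(res)) res$id <- seq_len(nrow(res))
  rownames(res) <- NULL
  attr(res, "geometry") <- geom
  attr(res, "contrast") <- hs_contrast
  attr(res, "perms") <- perms
  class(res) <- c("cluster_set", "data.frame")
  res
}
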