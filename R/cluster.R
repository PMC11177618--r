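## Connected-component clustering on the voxel grid, cluster summary
## statistics, and Monte-Carlo sign-flip permutation calibration of
## cluster-size thresholds.

adjacency_offsets <- function(adjacency) {
  if (!adjacency %in% c(6L, 18L, 26L))
    stop("adjacency must be 6, 18 or 26")
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  d <- rowSums(abs(g))
  keep <- switch(as.character(adjacency),
                 "6"  = d == 1,
                 "18" = d >= 1 & d <= 2,
                 "26" = d >= 1)
  unname(g[keep, , drop = FALSE])
}

## connected components of a voxel set (linear indices) under the given
## adjacency; frontier-at-a-time BFS, vectorized over the frontier
connected_components <- function(lin, shape, adjacency = 6) {
  if (!length(lin)) return(list())
  off <- adjacency_offsets(adjacency)
  pos <- integer(prod(shape))
  pos[lin] <- seq_along(lin)
  ijk <- linear_to_ijk(lin, shape)
  label <- integer(length(lin))
  comps <- list()
  for (s in seq_along(lin)) {
    if (label[s]) next
    lab <- length(comps) + 1L
    label[s] <- lab
    members <- s
    frontier <- s
    while (length(frontier)) {
      fi <- ijk[frontier, , drop = FALSE]
      nb <- fi[rep(seq_len(nrow(fi)), each = nrow(off)), , drop = FALSE] +
        off[rep(seq_len(nrow(off)), times = nrow(fi)), , drop = FALSE]
      ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
            nb[, 2] >= 1 & nb[, 2] <= shape[2] &
            nb[, 3] >= 1 & nb[, 3] <= shape[3]
      nb <- nb[ok, , drop = FALSE]
      p <- pos[ijk_to_linear(nb, shape)]
      p <- unique(p[p > 0L])
      p <- p[label[p] == 0L]
      label[p] <- lab
      members <- c(members, p)
      frontier <- p
    }
    comps[[lab]] <- sort(lin[members])
  }
  comps
}

## largest component size among the given voxels (0 if none)
max_component_size <- function(lin, shape, adjacency = 6) {
  if (!length(lin)) return(0L)
  max(lengths(connected_components(lin, shape, adjacency)))
}

#' Complete a cluster's summary statistics
#'
#' Center of mass (unweighted mean of member voxel-center world
#' coordinates), volume in mm^3 (`n_voxels * voxel volume`), and the peak
#' standardized statistic (the member z of maximal magnitude, signed).
#'
#' @param voxels integer vector of linear voxel indices (non-empty).
#' @param z_map 3D array of standardized statistics.
#' @param geometry a [vol_geometry()].
#' @return One-row data frame: `n_voxels, x, y, z, volume_mm3, peak_z`.
#' @export
cluster_stats <- function(voxels, z_map, geometry) {
  if (!length(voxels)) stop("empty cluster")
  w <- world_coords(linear_to_ijk(voxels, geometry$shape), geometry)
  ctr <- colMeans(w)
  zv <- z_map[voxels]
  data.frame(n_voxels = length(voxels),
             x = ctr[1], y = ctr[2], z = ctr[3],
             volume_mm3 = length(voxels) * prod(geometry$voxel_size_mm),
             peak_z = zv[which.max(abs(zv))],
             row.names = NULL)
}

new_cluster_set <- function(comps, signs, z_map, geometry, role,
                            parent_id = NA_integer_, contrast = NULL) {
  if (!length(comps)) {
    df <- data.frame(id = integer(0), role = character(0),
                     parent_id = integer(0), sign = character(0),
                     n_voxels = integer(0), x = numeric(0), y = numeric(0),
                     z = numeric(0), volume_mm3 = numeric(0),
                     peak_z = numeric(0))
    df$voxels <- list()
  } else {
    stats <- do.call(rbind, lapply(comps, cluster_stats, z_map = z_map,
                                   geometry = geometry))
    df <- cbind(data.frame(id = seq_along(comps), role = role,
                           parent_id = parent_id, sign = signs,
                           stringsAsFactors = FALSE),
                stats)
    df$voxels <- I(comps)
    ## larger clusters first, matching reporting convention
    o <- order(-df$n_voxels)
    df <- df[o, , drop = FALSE]
    df$id <- seq_len(nrow(df))
    rownames(df) <- NULL
  }
  attr(df, "geometry") <- geometry
  attr(df, "contrast") <- contrast
  class(df) <- c("cluster_set", "data.frame")
  df
}

#' Label suprathreshold clusters in a z map
#'
#' Voxels with `z > voxel_z_threshold` and voxels with
#' `z < -voxel_z_threshold` are clustered separately (positive and
#' negative clusters never merge) by connected components restricted to
#' the mask.
#'
#' @param z_map 3D array of standardized statistics (values outside the
#'   mask are ignored).
#' @param mask a [network_mask()].
#' @param voxel_z_threshold positive cluster-forming threshold on the z
#'   scale (e.g. 1.96 for two-tailed p < 0.05).
#' @param adjacency 6 (faces, default), 18 (+edges) or 26 (+corners).
#' @param role record label, `"hotspot"` or `"driver"`.
#' @return A `cluster_set` data frame (possibly empty): one row per
#'   cluster with sign, size, center world coordinates, volume and peak z;
#'   member voxels in the `voxels` list column.
#' @export
label_clusters <- function(z_map, mask, voxel_z_threshold, adjacency = 6,
                           role = "hotspot") {
  stopifnot(voxel_z_threshold > 0)
  shape <- mask$geometry$shape
  zm <- z_map[mask$voxels]
  pos <- mask$voxels[!is.na(zm) & zm > voxel_z_threshold]
  neg <- mask$voxels[!is.na(zm) & zm < -voxel_z_threshold]
  cp <- connected_components(pos, shape, adjacency)
  cn <- connected_components(neg, shape, adjacency)
  new_cluster_set(c(cp, cn), c(rep("+", length(cp)), rep("-", length(cn))),
                  z_map, mask$geometry, role = role)
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(nrow(x), " cluster(s)\n", sep = "")
  if (nrow(x))
    print.data.frame(x[, setdiff(names(x), "voxels")], digits = 4)
  invisible(x)
}

## smallest integer s with #{sizes >= s} / n_perm < alpha
size_threshold <- function(sizes, alpha) {
  n <- length(sizes)
  allow <- ceiling(alpha * n) - 1L        # max permissible exceedance count
  sorted <- sort(sizes, decreasing = TRUE)
  as.integer(sorted[allow + 1L] + 1L)
}

## coerce per-subject maps (list of 3D arrays, or subjects x voxels
## matrix already restricted to the mask) to a subjects x voxels matrix
maps_to_matrix <- function(maps, mask) {
  if (is.matrix(maps)) {
    stopifnot(ncol(maps) == length(mask$voxels))
    return(maps)
  }
  do.call(rbind, lapply(maps, function(m) {
    v <- if (inherits(m, "connectedness_map")) m$values else m
    v[mask$voxels]
  }))
}

## paired t -> z maps for a bank of sign patterns, fully vectorized:
## sign-flipping a subject's (a, b) pair negates its difference d_i and
## leaves d_i^2 unchanged, so only the permuted means need recomputing
signflip_z_matrix <- function(D, S) {
  n <- ncol(S)
  M <- (S %*% D) / n
  ssq <- matrix(colSums(D^2), nrow(S), ncol(D), byrow = TRUE)
  v <- (ssq - n * M^2) / (n - 1)
  v[v < 0] <- 0
  t <- M / sqrt(v / n)
  t[v == 0 & M == 0] <- 0
  t[v == 0 & M != 0] <- sign(M[v == 0 & M != 0]) * Inf
  zm <- t_to_z(t, df = n - 1)
  matrix(zm, nrow(t), ncol(t))
}

#' Permutation null distribution of maximum cluster size
#'
#' Builds the Monte-Carlo null used to calibrate cluster-size thresholds:
#' for each permutation, condition labels are swapped for a uniformly
#' random subset of exactly `floor(n/2)` subjects (equivalently, those
#' subjects' paired differences are sign-flipped), the voxelwise paired t
#' is recomputed and standardized, clusters are labeled at
#' `voxel_z_threshold`, and the maximum cluster size across both signs is
#' recorded. The returned threshold is the smallest integer `s` whose
#' exceedance proportion among the permuted maxima is below `alpha`.
#'
#' @param maps_a,maps_b per-subject 3D maps for the two conditions: lists
#'   of arrays (or of `connectedness_map`s), or subjects x voxels matrices
#'   restricted to the mask. Subject order must align.
#' @param mask a [network_mask()].
#' @param voxel_z_threshold cluster-forming threshold on the z scale.
#' @param n_perm number of permutations (>= 1).
#' @param alpha family-wise rate, in (0, 1).
#' @param adjacency cluster connectivity (6/18/26).
#' @param seed optional integer; fixing it makes the draw deterministic.
#' @return An object of class `perm_distribution`: `max_cluster_sizes`,
#'   `n_perm`, `alpha`, `threshold_voxels`, `voxel_z_threshold`.
#' @export
perm_cluster_threshold <- function(maps_a, maps_b, mask, voxel_z_threshold,
                                   n_perm = 100, alpha = 0.05,
                                   adjacency = 6, seed = NULL) {
  A <- maps_to_matrix(maps_a, mask)
  B <- maps_to_matrix(maps_b, mask)
  stopifnot(nrow(A) == nrow(B), ncol(A) == ncol(B))
  n <- nrow(A)
  if (n < 2) stop("need at least 2 subjects")
  stopifnot(n_perm >= 1, alpha > 0, alpha < 1)
  D <- A - B
  local_seed(seed)
  S <- matrix(1, n_perm, n)
  for (p in seq_len(n_perm))
    S[p, sample.int(n, n %/% 2)] <- -1
  Z <- signflip_z_matrix(D, S)
  shape <- mask$geometry$shape
  sizes <- integer(n_perm)
  for (p in seq_len(n_perm)) {
    zp <- Z[p, ]
    supra <- mask$voxels[abs(zp) > voxel_z_threshold]
    if (!length(supra)) next
    zs <- zp[match(supra, mask$voxels)]
    sizes[p] <- max(max_component_size(supra[zs > 0], shape, adjacency),
                    max_component_size(supra[zs < 0], shape, adjacency))
  }
  structure(list(max_cluster_sizes = sizes, n_perm = n_perm, alpha = alpha,
                 threshold_voxels = size_threshold(sizes, alpha),
                 voxel_z_threshold = voxel_z_threshold),
            class = "perm_distribution")
}

#' @export
print.perm_distribution <- function(x, ...) {
  cat("perm_distribution: ", x$n_perm, " permutations at |z| > ",
      x$voxel_z_threshold, "; alpha ", x$alpha,
      " cluster-size threshold = ", x$threshold_voxels, " voxels\n",
      sep = "")
  invisible(x)
}

#' Filter clusters by size
#'
#' Keeps clusters with at least `max(threshold_voxels, floor_voxels)`
#' member voxels. The floor implements the conservative minimum imposed
#' on driver clusters (20 voxels) on top of the permutation-derived
#' threshold.
#'
#' @param clusters a `cluster_set`.
#' @param threshold_voxels permutation-calibrated minimum size (>= 1).
#' @param floor_voxels hard minimum applied in addition (default 0).
#' @return The filtered `cluster_set` (ids preserved).
#' @export
apply_cluster_threshold <- function(clusters, threshold_voxels,
                                    floor_voxels = 0) {
  stopifnot(threshold_voxels >= 1)
  eff <- max(threshold_voxels, floor_voxels)
  out <- clusters[clusters$n_voxels >= eff, , drop = FALSE]
  attributes(out)$geometry <- attr(clusters, "geometry")
  attributes(out)$contrast <- attr(clusters, "contrast")
  class(out) <- class(clusters)
  out
}

#' Dilate a mask
#'
#' Grows the mask by `iters` steps of the given adjacency, clipped to the
#' grid.
#'
#' @param mask a [network_mask()].
#' @param iters number of dilation iterations (0 = identity).
#' @param adjacency 6/18/26 neighborhood.
#' @return The dilated [network_mask()].
#' @export
dilate_mask <- function(mask, iters = 1, adjacency = 6) {
  if (iters == 0) return(mask)
  shape <- mask$geometry$shape
  off <- adjacency_offsets(adjacency)
  vox <- mask$voxels
  for (it in seq_len(iters)) {
    ijk <- linear_to_ijk(vox, shape)
    nb <- ijk[rep(seq_len(nrow(ijk)), each = nrow(off)), , drop = FALSE] +
      off[rep(seq_len(nrow(off)), times = nrow(ijk)), , drop = FALSE]
    ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
          nb[, 2] >= 1 & nb[, 2] <= shape[2] &
          nb[, 3] >= 1 & nb[, 3] <= shape[3]
    vox <- unique(c(vox, ijk_to_linear(nb[ok, , drop = FALSE], shape)))
  }
  network_mask(vox, mask$geometry, name = mask$name)
}
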