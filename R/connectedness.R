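## Step 1: per-run network connectedness maps and hotspot detection.

## frames x voxels matrix of a run's data at the given linear indices,
## restricted to non-censored frames
run_matrix <- function(run, voxels, frames = valid_frames(run)) {
  d <- dim(run$data)
  M <- matrix(run$data, prod(d[1:3]), d[4])
  t(M[voxels, frames, drop = FALSE])
}

## unit-norm centered columns; constant columns returned as NA with a
## count so callers can warn
unit_columns <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  nrm <- sqrt(colSums(Xc^2))
  const <- nrm == 0
  nrm[const] <- 1
  Z <- sweep(Xc, 2, nrm, "/")
  Z[, const] <- NA_real_
  list(Z = Z, const = const)
}

#' Network connectedness map for one run
#'
#' For every network voxel `v`, computes the mean Pearson correlation of
#' `v`'s time series with every other network voxel (self-correlation
#' excluded by default), over non-censored frames, then applies Fisher's
#' z — the per-voxel "connectedness" statistic. The computation uses the
#' identity `rowSums(R) = Z' (Z 1)` for unit-norm centered data `Z`, so
#' cost is linear in network size rather than quadratic.
#'
#' @param run a [bold_run()] with at least 3 non-censored frames.
#' @param network a [network_mask()] with at least 2 voxels.
#' @param include_self include each voxel's self-correlation (r = 1) in
#'   its mean, reproducing tools whose row mean keeps the diagonal.
#' @param z_first apply Fisher z to each pairwise r before averaging
#'   (sensitivity-analysis variant; forms the dense correlation matrix,
#'   so memory is quadratic in network size).
#' @return An object of class `connectedness_map`: 3D `values` array
#'   (`NA` off-mask, `NaN` at constant voxels), `geometry`,
#'   `subject_id`, `condition`, `network_name`.
#' @export
connectedness_map <- function(run, network, include_self = FALSE,
                              z_first = FALSE) {
  stopifnot(inherits(run, "bold_run"), inherits(network, "network_mask"),
            geometry_compatible(run$geometry, network$geometry))
  V <- length(network$voxels)
  if (V < 2) stop("network must have at least 2 voxels")
  if (length(valid_frames(run)) < 3)
    stop("need at least 3 non-censored frames")
  X <- run_matrix(run, network$voxels)
  u <- unit_columns(X)
  nconst <- sum(u$const)
  if (nconst > 0)
    warning(nconst, " constant voxel series; their pairs dropped from ",
            "the remaining voxels' means")
  Z <- u$Z[, !u$const, drop = FALSE]
  Vv <- ncol(Z)
  vals <- rep(NaN, V)
  if (Vv >= 2) {
    if (z_first) {
      R <- crossprod(Z)
      diag(R) <- NA
      ## self-correlation is always excluded here: atanh(1) is not finite,
      ## so an include_self mean is undefined on the z-first path
      zz <- suppressWarnings(fisher_z(R))
      vals[!u$const] <- rowMeans(zz, na.rm = TRUE)
    } else {
      tot <- as.vector(crossprod(Z, rowSums(Z)))   # row sums of R, incl self
      mr <- if (include_self) tot / Vv else (tot - 1) / (Vv - 1)
      vals[!u$const] <- fisher_z(mr)
    }
  }
  out <- array(NA_real_, network$geometry$shape)
  out[network$voxels] <- vals
  structure(list(values = out, geometry = network$geometry,
                 subject_id = run$subject_id, condition = run$condition,
                 network_name = network$name),
            class = "connectedness_map")
}

#' @export
print.connectedness_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat("connectedness_map [", x$network_name, "] ",
      if (!is.na(x$subject_id)) paste0(x$subject_id, "/", x$condition, " "),
      length(v), " voxels, mean z ", round(mean(v, na.rm = TRUE), 4),
      "\n", sep = "")
  invisible(x)
}

## connectedness maps for a list of runs -> subjects x voxels matrix
connectedness_matrix <- function(runs, network, include_self = FALSE) {
  do.call(rbind, lapply(runs, function(r)
    connectedness_map(r, network, include_self)$values[network$voxels]))
}

## observed voxelwise paired z map (3D, NA off-mask)
observed_z_map <- function(A, B, mask) {
  z <- signflip_z_matrix(A - B, matrix(1, 1, nrow(A)))[1, ]
  out <- array(NA_real_, mask$geometry$shape)
  out[mask$voxels] <- z
  out
}

check_contrast <- function(runs_a, runs_b, contrast) {
  ca <- unique(unlist(lapply(runs_a, function(r)
    as.character(r$condition))))
  cb <- unique(unlist(lapply(runs_b, function(r)
    as.character(r$condition))))
  got <- c(if (length(ca) == 1) ca else NA, if (length(cb) == 1) cb else NA)
  if (is.null(contrast)) {
    if (!anyNA(got)) return(got)
    return(c("A", "B"))
  }
  if (!anyNA(got) && !all(is.na(got)) && !identical(got, contrast))
    stop("runs belong to conditions (", paste(got, collapse = ", "),
         ") but the requested contrast is (",
         paste(contrast, collapse = ", "), ")")
  contrast
}

#' Find connectedness hotspots for a paired contrast
#'
#' Step 1 of the two-step analysis: per-subject connectedness maps in
#' both conditions, voxelwise paired t standardized to z, a sign-flip
#' permutation null of the maximum cluster size to calibrate the
#' cluster-size threshold, then cluster labeling at `voxel_z` and size
#' filtering. Positive sign means condition A > condition B.
#'
#' @param runs_a,runs_b subject-aligned lists of [bold_run()]s for the
#'   two conditions.
#' @param network a [network_mask()].
#' @param voxel_z cluster-forming threshold (default 1.96, two-tailed
#'   p < 0.05).
#' @param n_perm,alpha permutation settings for the cluster-size null.
#' @param adjacency cluster connectivity (6/18/26).
#' @param include_self see [connectedness_map()].
#' @param contrast optional `c(label_a, label_b)`; checked against the
#'   runs' condition labels when both are present.
#' @param seed optional integer for the permutation draw.
#' @return A `cluster_set` of hotspot records, with attributes `z_map`
#'   (3D observed z), `perm` (the [perm_cluster_threshold()] result),
#'   `contrast`, `network_name`, `n_subjects`, and `maps_a`/`maps_b`
#'   (subjects x voxels connectedness matrices, reused by
#'   [find_drivers()] checks).
#' @export
find_hotspots <- function(runs_a, runs_b, network, voxel_z = 1.96,
                          n_perm = 100, alpha = 0.05, adjacency = 6,
                          include_self = FALSE, contrast = NULL,
                          seed = NULL) {
  stopifnot(length(runs_a) == length(runs_b), length(runs_a) >= 2)
  contrast <- check_contrast(runs_a, runs_b, contrast)
  A <- connectedness_matrix(runs_a, network, include_self)
  B <- connectedness_matrix(runs_b, network, include_self)
  perm <- perm_cluster_threshold(A, B, network, voxel_z, n_perm = n_perm,
                                 alpha = alpha, adjacency = adjacency,
                                 seed = seed)
  zmap <- observed_z_map(A, B, network)
  cl <- label_clusters(zmap, network, voxel_z, adjacency, role = "hotspot")
  cl <- apply_cluster_threshold(cl, perm$threshold_voxels)
  attr(cl, "z_map") <- zmap
  attr(cl, "perm") <- perm
  attr(cl, "contrast") <- contrast
  attr(cl, "network_name") <- network$name
  attr(cl, "n_subjects") <- length(runs_a)
  cl
}
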