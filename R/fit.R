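#' Fit the two-step connectedness contrast
#'
#' The package's front-end model fit: given a study (real or from
#' [generate_study()]), a pairwise condition contrast and a network,
#' runs Step 1 (hotspot detection on connectedness maps, with a
#' sign-flip permutation cluster-size threshold) and Step 2 (per-hotspot
#' seed-based driver detection under the conservative size floor), and
#' returns a classed object with the usual methods.
#'
#' @param study a `study_dataset`, or a list with elements `runs_a` and
#'   `runs_b` (subject-aligned lists of [bold_run()]s).
#' @param contrast `c(condition_a, condition_b)`; positive effects mean
#'   A > B.
#' @param network a [network_mask()], or the name of a mask in
#'   `study$masks`.
#' @param voxel_z Step-1 cluster-forming threshold (default 1.96).
#' @param driver_voxel_z Step-2 threshold (default 3.291).
#' @param n_perm,alpha permutation settings for both steps.
#' @param adjacency cluster connectivity (6/18/26).
#' @param floor_voxels driver size floor (default 20).
#' @param drivers run Step 2 (default `TRUE`).
#' @param include_self see [connectedness_map()].
#' @param seed optional integer governing all permutation draws.
#' @return An object of class `connectedness_fit`.
#' @export
fit_connectedness <- function(study, contrast, network,
                              voxel_z = 1.96, driver_voxel_z = 3.291,
                              n_perm = 100, alpha = 0.05, adjacency = 6,
                              floor_voxels = 20, drivers = TRUE,
                              include_self = FALSE, seed = NULL) {
  if (inherits(study, "study_dataset")) {
    stopifnot(all(contrast %in% names(study$runs)))
    runs_a <- study$runs[[contrast[1]]]
    runs_b <- study$runs[[contrast[2]]]
    if (is.character(network)) network <- study$masks[[network]]
  } else {
    runs_a <- study$runs_a
    runs_b <- study$runs_b
  }
  stopifnot(inherits(network, "network_mask"))
  hs <- find_hotspots(runs_a, runs_b, network, voxel_z = voxel_z,
                      n_perm = n_perm, alpha = alpha,
                      adjacency = adjacency, include_self = include_self,
                      contrast = contrast, seed = child_seed(seed, 0))
  dr <- NULL
  if (drivers && nrow(hs))
    dr <- find_drivers(hs, runs_a, runs_b, network,
                       voxel_z = driver_voxel_z, n_perm = n_perm,
                       alpha = alpha, floor_voxels = floor_voxels,
                       adjacency = adjacency, seed = child_seed(seed, 1))
  structure(list(hotspots = hs, drivers = dr,
                 network_name = network$name, contrast = contrast,
                 n_subjects = length(runs_a),
                 settings = list(voxel_z = voxel_z,
                                 driver_voxel_z = driver_voxel_z,
                                 n_perm = n_perm, alpha = alpha,
                                 adjacency = adjacency,
                                 floor_voxels = floor_voxels,
                                 include_self = include_self,
                                 seed = seed),
                 hotspot_threshold =
                   attr(hs, "perm")$threshold_voxels,
                 driver_thresholds = if (!is.null(dr))
                   vapply(attr(dr, "perms"),
                          function(p) p$threshold_voxels, 0L)
                 else integer(0)),
            class = "connectedness_fit")
}

#' @export
print.connectedness_fit <- function(x, ...) {
  cat("Two-step network connectedness contrast\n")
  cat("  network:  ", x$network_name, "\n", sep = "")
  cat("  contrast: ", x$contrast[1], " versus ", x$contrast[2],
      "  (n = ", x$n_subjects, " subjects, paired)\n", sep = "")
  cat("  step 1: |z| > ", x$settings$voxel_z,
      ", permutation cluster-size threshold ", x$hotspot_threshold,
      " voxels -> ", nrow(x$hotspots), " hotspot(s)\n", sep = "")
  if (!is.null(x$drivers))
    cat("  step 2: |z| > ", x$settings$driver_voxel_z,
        ", thresholds ", paste(x$driver_thresholds, collapse = "/"),
        " voxels (floor ", x$settings$floor_voxels, ") -> ",
        nrow(x$drivers), " driver(s)\n", sep = "")
  invisible(x)
}

#' @export
summary.connectedness_fit <- function(object, ...) {
  print(object)
  tab <- as.data.frame(object)
  if (nrow(tab)) {
    cat("\n")
    print.data.frame(tab, digits = 3, row.names = FALSE)
  } else cat("  no clusters survive thresholding\n")
  invisible(tab)
}

#' @export
as.data.frame.connectedness_fit <- function(x, ...) {
  cols <- c("id", "role", "parent_id", "sign", "x", "y", "z",
            "n_voxels", "volume_mm3", "peak_z")
  hs <- as.data.frame(unclass(x$hotspots),
                      stringsAsFactors = FALSE)[, cols, drop = FALSE]
  dr <- if (!is.null(x$drivers) && nrow(x$drivers))
    as.data.frame(unclass(x$drivers),
                  stringsAsFactors = FALSE)[, cols, drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(hs))) {
    rows[[length(rows) + 1L]] <- hs[i, , drop = FALSE]
    if (!is.null(dr)) {
      kids <- dr[!is.na(dr$parent_id) & dr$parent_id == hs$id[i], ,
                 drop = FALSE]
      if (nrow(kids)) rows[[length(rows) + 1L]] <- kids
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else hs
  rownames(out) <- NULL
  out
}

#' @export
plot.connectedness_fit <- function(x, ...) {
  perm <- attr(x$hotspots, "perm")
  sizes <- perm$max_cluster_sizes
  graphics::hist(sizes, breaks = seq(-0.5, max(sizes, perm$threshold_voxels) + 1.5),
                 main = paste0("Permutation null of max cluster size\n",
                               x$contrast[1], " vs ", x$contrast[2],
                               " [", x$network_name, "]"),
                 xlab = "max cluster size (voxels)", ...)
  graphics::abline(v = perm$threshold_voxels, lty = 2)
  if (nrow(x$hotspots))
    graphics::points(x$hotspots$n_voxels,
                     rep(0, nrow(x$hotspots)), pch = 17)
  invisible(x)
}
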