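## Synthetic multi-subject BOLD study generator. Each network carries a
## shared latent signal; a voxel's series is the sum, over networks that
## contain it, of (loading + condition-specific delta) * latent, plus
## temporally autocorrelated, spatially smoothed Gaussian noise.
## Condition effects (coupling deltas confined to known voxel blocks) are
## the recoverable ground truth for the hotspot/driver analyses.

#' Rectangular voxel block as linear indices
#'
#' Convenience constructor for regions in simulation configs and tests.
#'
#' @param x_range,y_range,z_range integer index ranges (1-based).
#' @param shape grid shape `(nx, ny, nz)`.
#' @return Integer vector of linear voxel indices.
#' @export
block_region <- function(x_range, y_range, z_range, shape) {
  g <- as.matrix(expand.grid(i = x_range, j = y_range, k = z_range))
  sort(ijk_to_linear(g, as.integer(shape)))
}

#' Network specification for the generator
#'
#' @param name network label.
#' @param region linear voxel indices of the network's true extent.
#' @param base_loading loading of member voxels on the network's latent
#'   signal (> 0).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(name, region, base_loading = 0.55) {
  stopifnot(base_loading > 0, length(region) >= 1)
  structure(list(name = name, region = sort(as.integer(region)),
                 base_loading = base_loading),
            class = "network_spec")
}

#' Ground-truth effect specification
#'
#' A condition-dependent perturbation of the coupling between a voxel
#' block and one network's latent signal: inside `region`, for the
#' affected conditions, the loading on `network`'s latent changes by
#' `coupling_delta` (negative values weaken coupling; `-0.8 *
#' base_loading` removes 80% of it).
#'
#' @param region linear voxel indices (must lie inside `network`'s
#'   region).
#' @param conditions_affected character vector of condition labels.
#' @param coupling_delta finite real, change in latent loading.
#' @param network name of the network whose latent is affected.
#' @param description free-text note.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(region, conditions_affected, coupling_delta,
                        network, description = "") {
  stopifnot(is.finite(coupling_delta), length(region) >= 1)
  structure(list(region = sort(as.integer(region)),
                 conditions_affected = as.character(conditions_affected),
                 coupling_delta = coupling_delta,
                 network = network, description = description),
            class = "effect_spec")
}

default_network_specs <- function(grid_shape) {
  ## two overlapping blocks, mimicking the hippocampal-cortical /
  ## parietal network overlap situation
  list(network_spec("HCN", block_region(3:12, 3:12, 3:8, grid_shape), 0.55),
       network_spec("PN",  block_region(9:18, 9:18, 5:10, grid_shape), 0.55))
}

#' Simulation configuration
#'
#' Defaults give a desk-scale study: 12 subjects, 300 frames, a
#' 20 x 20 x 12 grid of 2-mm voxels, two overlapping networks. The
#' full-study scale of the emulated design (24 subjects, 550 frames, TR
#' 0.555 s) is available by argument.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param n_frames frames per run (>= 20).
#' @param tr_s repetition time in seconds.
#' @param grid_shape voxel grid `(nx, ny, nz)`.
#' @param voxel_size_mm voxel edge lengths in mm.
#' @param conditions condition labels; every subject gets one run per
#'   condition.
#' @param network_specs list of [network_spec()]s.
#' @param effects list of [effect_spec()]s (ground truth).
#' @param noise_sd per-voxel noise standard deviation (> 0).
#' @param ar1_phi lag-1 autocorrelation of latents and noise, in [0, 1).
#' @param smooth_fwhm_mm spatial smoothing applied to the noise field
#'   (noise is rescaled back to `noise_sd` per voxel afterwards, so the
#'   smoothing sets spatial correlation, not amplitude).
#' @param censor_fraction fraction of frames zero-filled per run, in
#'   [0, 1).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 12, n_frames = 300, tr_s = 0.555,
                       grid_shape = c(20, 20, 12),
                       voxel_size_mm = c(2, 2, 2),
                       conditions = c("sham", "cTBS", "iTBS"),
                       network_specs = default_network_specs(grid_shape),
                       effects = list(),
                       noise_sd = 1, ar1_phi = 0.3, smooth_fwhm_mm = 4,
                       censor_fraction = 0.05) {
  stopifnot(n_subjects >= 2, n_frames >= 20, noise_sd > 0,
            ar1_phi >= 0, ar1_phi < 1,
            censor_fraction >= 0, censor_fraction < 1,
            length(conditions) >= 1)
  net_names <- vapply(network_specs, `[[`, "", "name")
  for (ef in effects) {
    if (!ef$network %in% net_names)
      stop("effect refers to unknown network '", ef$network, "'")
    net <- network_specs[[match(ef$network, net_names)]]
    if (!all(ef$region %in% net$region))
      stop("effect region extends outside network '", ef$network, "'")
    if (!all(ef$conditions_affected %in% conditions))
      stop("effect refers to unknown condition")
  }
  structure(list(n_subjects = n_subjects, n_frames = n_frames, tr_s = tr_s,
                 grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm, conditions = conditions,
                 network_specs = network_specs, effects = effects,
                 noise_sd = noise_sd, ar1_phi = ar1_phi,
                 smooth_fwhm_mm = smooth_fwhm_mm,
                 censor_fraction = censor_fraction),
            class = "sim_config")
}

## unit-variance AR(1) columns: T x m matrix
ar1_series <- function(n, m, phi) {
  E <- matrix(stats::rnorm(n * m), n, m)
  if (phi == 0) return(E)
  E <- E * sqrt(1 - phi^2)
  E[1, ] <- E[1, ] / sqrt(1 - phi^2)        # stationary start, unit sd
  for (t in 2:n) E[t, ] <- phi * E[t - 1, ] + E[t, ]
  E
}

## unit-variance AR(1) rows: nvox x nt matrix. The recursion is unrolled
## into one triangular moving-average operator B (X = Z B, with
## B[1, t] = phi^(t-1) for the stationary start and
## B[s, t] = sqrt(1 - phi^2) phi^(t-s) for s >= 2), so the whole draw is
## a single matrix product instead of a per-frame loop.
ar1_rows <- function(nvox, nt, phi) {
  Z <- stats::rnorm(nvox * nt)
  dim(Z) <- c(nvox, nt)
  if (phi == 0) return(Z)
  pow <- phi^(0:(nt - 1))
  B <- matrix(0, nt, nt)
  for (s in seq_len(nt)) {
    B[s, s:nt] <- pow[1:(nt - s + 1)]
    if (s >= 2) B[s, s:nt] <- B[s, s:nt] * sqrt(1 - phi^2)
  }
  Z %*% B
}

## variance shrink factor of the separable smoothing kernel (interior
## voxels): product over axes of sum(k^2)
smooth_var_factor <- function(fwhm_mm, voxel_size_mm) {
  if (fwhm_mm == 0) return(1)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  prod(vapply(1:3, function(ax) {
    sum(gaussian_kernel_1d(sigma_mm / voxel_size_mm[ax])^2)
  }, 0))
}

#' Generate a synthetic study
#'
#' Draws, for every subject and condition, one residual-like BOLD run:
#' voxel `v`'s series is `sum over networks containing v of
#' (base_loading + delta_v(condition)) * g_net + noise`, where `g_net` is
#' the network's unit-variance AR(1) latent (drawn independently per
#' run), `delta` comes from the config's [effect_spec()]s, and the noise
#' is AR(1) in time, spatially smoothed, and rescaled to `noise_sd` per
#' voxel. A `censor_fraction` of frames per run is zero-filled and
#' flagged. Deterministic given `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (optional but recommended).
#' @return An object of class `study_dataset`: `runs` (per condition, a
#'   list of [bold_run()]s over subjects), `masks` (true
#'   [network_mask()]s), `truth` (the effect specs), `config`,
#'   `geometry`.
#' @export
generate_study <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(seed)
  shape <- config$grid_shape
  nvox <- prod(shape)
  nt <- config$n_frames
  geom <- vol_geometry(shape, config$voxel_size_mm)
  masks <- lapply(config$network_specs, function(ns)
    network_mask(ns$region, geom, name = ns$name))
  names(masks) <- vapply(config$network_specs, `[[`, "", "name")
  vf <- smooth_var_factor(config$smooth_fwhm_mm, config$voxel_size_mm)
  ncens <- floor(config$censor_fraction * nt)
  subjects <- sprintf("sub%02d", seq_len(config$n_subjects))

  ## per-network loading vectors by condition (shared across subjects)
  loadings <- lapply(config$conditions, function(cond) {
    lapply(config$network_specs, function(ns) {
      lam <- numeric(nvox)
      lam[ns$region] <- ns$base_loading
      for (ef in config$effects)
        if (ef$network == ns$name && cond %in% ef$conditions_affected)
          lam[ef$region] <- lam[ef$region] + ef$coupling_delta
      lam
    })
  })
  names(loadings) <- config$conditions

  runs <- lapply(config$conditions, function(cond) {
    lapply(subjects, function(sub) {
      ## noise: AR(1) in time, smoothed in space, rescaled to noise_sd
      ## per voxel (the 1/sqrt(vf) undoes the kernel's variance shrink)
      dat <- ar1_rows(nvox, nt, config$ar1_phi) *
        (config$noise_sd / sqrt(vf))
      dim(dat) <- c(shape, nt)
      if (config$smooth_fwhm_mm > 0)
        dat <- smooth_volume(dat, config$smooth_fwhm_mm,
                             config$voxel_size_mm)
      dim(dat) <- c(nvox, nt)
      lam_c <- loadings[[cond]]
      for (ni in seq_along(config$network_specs)) {
        g <- ar1_series(nt, 1, config$ar1_phi)[, 1]
        ## unit SAMPLE variance: realized latent power is identical
        ## across runs, so coupling (the loadings), not latent power
        ## realizations, drives between-condition connectedness change
        g <- (g - mean(g)) / stats::sd(g)
        lam <- lam_c[[ni]]
        on <- which(lam != 0)
        if (length(on))
          dat[on, ] <- dat[on, ] + outer(lam[on], g)
      }
      cens <- if (ncens > 0) sort(sample.int(nt, ncens)) else integer(0)
      if (length(cens)) dat[, cens] <- 0    # zero-fill while unshared
      dim(dat) <- c(shape, nt)
      bold_run(dat, geom, tr_s = config$tr_s, censored_frames = cens,
               subject_id = sub, condition = cond)
    })
  })
  names(runs) <- config$conditions
  structure(list(runs = runs, masks = masks, truth = config$effects,
                 config = config, geometry = geom),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("study_dataset: ", x$config$n_subjects, " subjects x ",
      length(x$config$conditions), " conditions (",
      paste(x$config$conditions, collapse = ", "), "), grid ",
      paste(x$config$grid_shape, collapse = "x"), ", ",
      x$config$n_frames, " frames; ", length(x$truth),
      " ground-truth effect(s)\n", sep = "")
  invisible(x)
}

#' Dice overlap between a detected voxel set and ground truth
#'
#' `Dice = 2 |A intersect B| / (|A| + |B|)`. Two empty sets give 0 with a
#' warning.
#'
#' @param detected integer linear voxel indices (or a `cluster_set` row's
#'   `voxels` entry).
#' @param truth integer linear voxel indices, an [effect_spec()], or a
#'   [network_mask()].
#' @return Dice coefficient in [0, 1].
#' @export
truth_overlap <- function(detected, truth) {
  a <- unique(as.integer(unlist(detected)))
  b <- if (inherits(truth, "effect_spec")) truth$region
       else if (inherits(truth, "network_mask")) truth$voxels
       else unique(as.integer(truth))
  if (!length(a) && !length(b)) {
    warning("both sets empty; Dice defined as 0")
    return(0)
  }
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Write a study to disk
#'
#' One NIfTI per run (`<subject>_<condition>.nii.gz`), one per mask
#' (`mask_<name>.nii.gz`), and a JSON manifest with the config, censor
#' flags and ground-truth effect geometry.
#'
#' @param study a `study_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  censor <- list()
  for (cond in names(study$runs))
    for (run in study$runs[[cond]]) {
      fn <- paste0(run$subject_id, "_", cond, ".nii.gz")
      write_volume(run, file.path(dir, fn))
      censor[[fn]] <- run$censored_frames
    }
  for (m in study$masks)
    write_volume(m, file.path(dir, paste0("mask_", m$name, ".nii.gz")))
  manifest <- list(
    conditions = study$config$conditions,
    subjects = sprintf("sub%02d", seq_len(study$config$n_subjects)),
    tr_s = study$config$tr_s,
    grid_shape = study$config$grid_shape,
    voxel_size_mm = study$config$voxel_size_mm,
    censored_frames = censor,
    truth = lapply(study$truth, function(ef)
      list(network = ef$network, region = ef$region,
           conditions_affected = ef$conditions_affected,
           coupling_delta = ef$coupling_delta,
           description = ef$description)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
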