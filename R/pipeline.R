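## End-to-end pipeline driver: simulate (or load) a study, optionally
## residualize, define or adopt network masks, run the two-step contrast
## for every requested condition pair and network, and write tables,
## permutation distributions and a reproducibility manifest.

#' Serialize a cluster table as TSV text
#'
#' One row per cluster, hotspots each followed by their drivers
#' (`parent_id` links a driver to its hotspot). Columns: id, role,
#' parent_id, sign, x, y, z, n_voxels, volume_mm3, peak_z; peak z is
#' printed with one decimal, coordinates with up to 10 significant
#' digits.
#'
#' @param hotspots a `cluster_set` (or a [fit_connectedness()] result,
#'   in which case `drivers` is taken from it).
#' @param drivers optional driver `cluster_set`.
#' @return Character scalar of TSV text (header always present).
#' @export
cluster_table <- function(hotspots, drivers = NULL) {
  if (inherits(hotspots, "connectedness_fit")) {
    tab <- as.data.frame(hotspots)
  } else {
    fake <- list(hotspots = hotspots, drivers = drivers)
    class(fake) <- "connectedness_fit"
    tab <- as.data.frame(fake)
  }
  num <- function(v) vapply(v, function(x)
    if (is.na(x)) "NA" else sprintf("%.10g", x), "")
  lines <- c(paste(c("id", "role", "parent_id", "sign", "x", "y", "z",
                     "n_voxels", "volume_mm3", "peak_z"),
                   collapse = "\t"))
  if (nrow(tab))
    lines <- c(lines, paste(tab$id, tab$role,
                            ifelse(is.na(tab$parent_id), "NA",
                                   tab$parent_id),
                            tab$sign, num(tab$x), num(tab$y), num(tab$z),
                            tab$n_voxels, num(tab$volume_mm3),
                            sprintf("%.1f", tab$peak_z), sep = "\t"))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Parse a cluster TSV back into a data frame
#'
#' @param x a file path or TSV text (anything with a newline is treated
#'   as text).
#' @return Data frame with the numeric columns restored.
#' @export
parse_cluster_table <- function(x) {
  con <- if (grepl("\n", x)) textConnection(x) else x
  utils::read.delim(con, stringsAsFactors = FALSE)
}

effects_from_config <- function(effects, grid_shape) {
  lapply(effects, function(e) {
    region <- if (!is.null(e$block)) {
      b <- e$block
      block_region(b[[1]][1]:b[[1]][2], b[[2]][1]:b[[2]][2],
                   b[[3]][1]:b[[3]][2], grid_shape)
    } else as.integer(unlist(e$region))
    effect_spec(region, e$conditions, e$coupling_delta, e$network,
                description = if (is.null(e$description)) "" else
                  e$description)
  })
}

#' Run the full pipeline from a config
#'
#' Stages: simulate a study per `config$simulate`; optionally
#' residualize each run (`config$preprocess`); adopt the generator's
#' network masks (`networks: truth`) or re-define them from
#' sham-condition seed connectivity (`networks: estimate`); run the
#' two-step contrast for every pair in `config$contrasts` and every
#' network; write cluster TSV tables, permutation distributions, masks
#' and a JSON manifest (seeds, thresholds actually applied, package
#' version) to `out_dir`. Deterministic given `config$seed`.
#'
#' @param config a list, or path to a YAML/JSON config file. Recognized
#'   fields: `seed`, `simulate` (arguments of [sim_config()], with
#'   effects given as blocks), `preprocess` (logical), `networks`
#'   (`"truth"` or `"estimate"`), `contrasts` (list of pairs),
#'   `settings` (arguments of [fit_connectedness()]), `write_maps`,
#'   `write_runs` (logicals).
#' @param out_dir output directory; overrides `config$out_dir`.
#' @return Invisibly, a list with the study, fits and manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
    else yaml::read_yaml(config)
  }
  if (is.null(out_dir)) out_dir <- config$out_dir
  stopifnot(!is.null(out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  ## --- simulate ---------------------------------------------------
  simargs <- config$simulate
  if (is.null(simargs)) simargs <- list()
  if (!is.null(simargs$effects))
    simargs$effects <- effects_from_config(
      simargs$effects,
      if (!is.null(simargs$grid_shape)) unlist(simargs$grid_shape)
      else c(20, 20, 12))
  for (nm in c("grid_shape", "voxel_size_mm", "conditions"))
    if (!is.null(simargs[[nm]])) simargs[[nm]] <- unlist(simargs[[nm]])
  cfg <- do.call(sim_config, simargs)
  study <- generate_study(cfg, seed = child_seed(seed, 100))
  if (isTRUE(config$write_runs)) write_study(study, file.path(out_dir, "study"))

  ## --- preprocess -------------------------------------------------
  if (isTRUE(config$preprocess)) {
    band <- c(0.01, 0.1)
    for (cond in names(study$runs))
      study$runs[[cond]] <- lapply(study$runs[[cond]], residualize,
                                   band = band)
  }

  ## --- network masks ----------------------------------------------
  masks <- study$masks
  net_mode <- if (is.null(config$networks)) "truth" else config$networks
  if (net_mode == "estimate") {
    sham <- study$runs[["sham"]]
    if (is.null(sham)) stop("networks: estimate requires a sham condition")
    masks <- lapply(study$masks, function(truth_mask) {
      ## seed: the central third of the true network, mimicking a
      ## compact anatomical seed inside it
      ijk <- mask_ijk(truth_mask)
      ctr <- round(colMeans(ijk))
      d <- abs(sweep(ijk, 2, ctr))
      seed_vox <- truth_mask$voxels[rowSums(d) <=
                                      stats::quantile(rowSums(d), 0.1)]
      gm <- group_seed_map(sham, network_mask(seed_vox, truth_mask$geometry,
                                              "seed"))
      thr <- noise_cluster_threshold(gm$mask,
                                     cfg$smooth_fwhm_mm,
                                     voxel_p = 1e-8, n_sim = 100,
                                     alpha = 0.01,
                                     seed = child_seed(seed, 200))
      define_network(gm, voxel_p = 1e-8, cluster_threshold = thr,
                     dilate_iters = 1, name = truth_mask$name)
    })
  }
  for (m in masks)
    write_volume(m, file.path(out_dir, paste0("mask_", m$name, ".nii.gz")))
  overlap <- if (length(masks) >= 2)
    mask_overlap(masks[[1]], masks[[2]]) else NA

  ## --- contrasts --------------------------------------------------
  contrasts <- config$contrasts
  if (is.null(contrasts)) {
    cs <- cfg$conditions
    contrasts <- if (length(cs) >= 2) list(c(cs[2], cs[1])) else list()
  }
  settings <- if (is.null(config$settings)) list() else config$settings
  fits <- list()
  applied <- list()
  k <- 0
  for (m in masks) for (ct in contrasts) {
    ct <- unlist(ct)
    k <- k + 1
    tag <- paste0(m$name, "_", ct[1], "_versus_", ct[2])
    fit <- do.call(fit_connectedness,
                   c(list(study = study, contrast = ct, network = m,
                          seed = child_seed(seed, 300 + k)), settings))
    fits[[tag]] <- fit
    writeLines(cluster_table(fit),
               file.path(out_dir, paste0("clusters_", tag, ".tsv")))
    perm <- attr(fit$hotspots, "perm")
    utils::write.table(
      data.frame(perm = seq_along(perm$max_cluster_sizes),
                 max_cluster_size = perm$max_cluster_sizes),
      file.path(out_dir, paste0("perm_", tag, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (isTRUE(config$write_maps)) {
      for (cond in ct) for (run in study$runs[[cond]]) {
        cm <- connectedness_map(run, m)
        vals <- cm$values
        vals[is.na(vals)] <- 0
        write_volume(vals, file.path(out_dir,
          paste0("conn_", m$name, "_", run$subject_id, "_", cond,
                 ".nii.gz")), geometry = m$geometry)
      }
    }
    applied[[tag]] <- list(
      contrast = ct, network = m$name,
      voxel_z = fit$settings$voxel_z,
      driver_voxel_z = fit$settings$driver_voxel_z,
      hotspot_cluster_threshold = fit$hotspot_threshold,
      driver_cluster_thresholds = fit$driver_thresholds,
      floor_voxels = fit$settings$floor_voxels,
      n_hotspots = nrow(fit$hotspots),
      n_drivers = if (is.null(fit$drivers)) 0L else nrow(fit$drivers))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("conmap")),
    seed = seed,
    sim = list(n_subjects = cfg$n_subjects, n_frames = cfg$n_frames,
               tr_s = cfg$tr_s, grid_shape = cfg$grid_shape,
               conditions = cfg$conditions, noise_sd = cfg$noise_sd,
               ar1_phi = cfg$ar1_phi, smooth_fwhm_mm = cfg$smooth_fwhm_mm,
               censor_fraction = cfg$censor_fraction,
               n_effects = length(cfg$effects)),
    networks = net_mode,
    mask_sizes = lapply(masks, function(m) length(m$voxels)),
    mask_overlap_voxels = overlap,
    thresholds_applied = applied)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(study = study, masks = masks, fits = fits,
                 manifest = manifest))
}
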