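## Individualized seed selection from a baseline run: a hippocampal
## target (the most interconnected voxels of an anatomical hippocampus
## mask) and a parietal stimulation site (the parietal voxel most
## connected to that target).

#' Select an individualized hippocampal target
#'
#' Ranks the voxels of an anatomical mask by within-mask connectedness
#' (Fisher-z mean correlation with every other mask voxel) and returns
#' the top fraction as the subject's target. Both the score and the
#' selection are invariant to per-voxel affine rescaling of the data.
#'
#' @param baseline a [bold_run()] (baseline session).
#' @param hippo_mask anatomical [network_mask()] with >= 2 voxels.
#' @param top_fraction fraction of mask voxels to keep, in (0, 1];
#'   default 0.05. At least one voxel is always returned.
#' @return A [network_mask()] named `"<mask>_target"`.
#' @export
hippocampal_target <- function(baseline, hippo_mask, top_fraction = 0.05) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  if (length(hippo_mask$voxels) < 2)
    stop("hippocampus mask must have at least 2 voxels")
  cm <- connectedness_map(baseline, hippo_mask)
  score <- cm$values[hippo_mask$voxels]
  k <- max(1L, ceiling(top_fraction * length(hippo_mask$voxels)))
  ## ties broken toward the lower linear index for determinism
  o <- order(-score, hippo_mask$voxels, na.last = TRUE)
  network_mask(hippo_mask$voxels[o[seq_len(k)]], hippo_mask$geometry,
               name = paste0(hippo_mask$name, "_target"))
}

#' Select the parietal stimulation site
#'
#' Correlates the spatial mean series of the target with every voxel of
#' the parietal search mask (non-censored frames, Fisher z) and returns
#' the argmax voxel; ties go to the lowest linear index.
#'
#' @param baseline a [bold_run()].
#' @param target a [network_mask()] (e.g. from [hippocampal_target()]).
#' @param parietal_mask non-empty search [network_mask()].
#' @return List with `linear` (index), `ijk`, `world` (mm), and `z` (the
#'   winning Fisher-z connectivity).
#' @export
parietal_site <- function(baseline, target, parietal_mask) {
  if (!length(parietal_mask$voxels)) stop("empty parietal mask")
  if (!length(target$voxels)) stop("empty target mask")
  z <- seed_z_values(baseline, target$voxels, parietal_mask$voxels)
  if (all(is.nan(z))) stop("no usable parietal voxel series")
  best <- which(z == max(z, na.rm = TRUE))[1]
  lin <- parietal_mask$voxels[best]
  ijk <- drop(linear_to_ijk(lin, parietal_mask$geometry$shape))
  list(linear = lin, ijk = ijk,
       world = world_coords(ijk, parietal_mask$geometry),
       z = z[best])
}
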