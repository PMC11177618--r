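#' BOLD run container
#'
#' A `bold_run` bundles one subject-by-condition 4D residual time series
#' with its grid geometry, repetition time and motion-censoring flags.
#' Censored frames are carried both as metadata (`censored_frames`) and as
#' literal zeros in `data` (the zero-fill convention of the source
#' pipeline); correlation code downstream drops them via the flags.
#'
#' @param data 4D numeric array `(x, y, z, t)`.
#' @param geometry a [vol_geometry()]; defaults to unit voxels.
#' @param tr_s repetition time in seconds.
#' @param censored_frames integer vector of frame indices (1-based) that
#'   are zero-filled; the constructor enforces the zero-fill.
#' @param subject_id,condition identifier strings.
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, geometry = NULL, tr_s = 1,
                     censored_frames = integer(0),
                     subject_id = NA_character_, condition = NA_character_) {
  stopifnot(length(dim(data)) == 4L, tr_s > 0)
  if (is.null(geometry))
    geometry <- vol_geometry(dim(data)[1:3])
  stopifnot(identical(geometry$shape, as.integer(dim(data)[1:3])))
  censored_frames <- sort(unique(as.integer(censored_frames)))
  if (length(censored_frames)) {
    stopifnot(all(censored_frames >= 1L),
              all(censored_frames <= dim(data)[4]))
    ## avoid duplicating the (possibly large) array when the caller
    ## already zero-filled
    if (any(data[, , , censored_frames] != 0))
      data[, , , censored_frames] <- 0
  }
  structure(list(data = data, geometry = geometry, tr_s = tr_s,
                 censored_frames = censored_frames,
                 subject_id = subject_id, condition = condition),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat("bold_run: ", paste(d[1:3], collapse = "x"), " voxels, ", d[4],
      " frames (", length(x$censored_frames), " censored), TR ",
      x$tr_s, " s", sep = "")
  if (!is.na(x$subject_id))
    cat(" [", x$subject_id, "/", x$condition, "]", sep = "")
  cat("\n")
  invisible(x)
}

n_frames <- function(run) dim(run$data)[4]

valid_frames <- function(run) {
  setdiff(seq_len(n_frames(run)), run$censored_frames)
}

#' Network mask container
#'
#' A labeled set of voxels on a grid, stored as 1-based linear indices.
#'
#' @param voxels integer vector of linear voxel indices, or an n x 3
#'   matrix of `(i, j, k)` indices.
#' @param geometry a [vol_geometry()].
#' @param name identifier string.
#' @return An object of class `network_mask`.
#' @export
network_mask <- function(voxels, geometry, name = "mask") {
  if (is.matrix(voxels)) {
    stopifnot(all(voxels >= 1L), all(t(voxels) <= geometry$shape))
    voxels <- ijk_to_linear(voxels, geometry$shape)
  }
  voxels <- sort(unique(as.integer(voxels)))
  stopifnot(all(voxels >= 1L), all(voxels <= prod(geometry$shape)))
  structure(list(geometry = geometry, voxels = voxels, name = name),
            class = "network_mask")
}

#' @export
print.network_mask <- function(x, ...) {
  cat("network_mask '", x$name, "': ", length(x$voxels), " voxels on ",
      paste(x$geometry$shape, collapse = "x"), " grid\n", sep = "")
  invisible(x)
}

#' @export
length.network_mask <- function(x) length(x$voxels)

mask_ijk <- function(mask) linear_to_ijk(mask$voxels, mask$geometry$shape)

#' Indicator volume for a mask
#'
#' @param mask a [network_mask()].
#' @return 3D 0/1 array on the mask's grid.
#' @export
mask_to_volume <- function(mask) {
  v <- array(0, dim = mask$geometry$shape)
  v[mask$voxels] <- 1
  v
}

#' Threshold a volume into a mask
#'
#' Voxels with value strictly greater than `threshold` become mask
#' members. An empty result is legal (warning only), since intermediate
#' thresholding steps may legitimately select nothing.
#'
#' @param vol 3D numeric array.
#' @param threshold numeric cutoff.
#' @param geometry a [vol_geometry()] for the volume; defaults to unit
#'   voxels.
#' @param name mask identifier.
#' @return A [network_mask()].
#' @export
mask_from_volume <- function(vol, threshold = 0.5, geometry = NULL,
                             name = "mask") {
  stopifnot(length(dim(vol)) == 3L)
  if (is.null(geometry)) geometry <- vol_geometry(dim(vol))
  stopifnot(identical(geometry$shape, as.integer(dim(vol))))
  idx <- which(vol > threshold)
  if (!length(idx)) warning("mask '", name, "' is empty")
  network_mask(idx, geometry, name = name)
}

geometry_from_nifti <- function(img,
                                world_convention = "right_negative_x") {
  d <- dim(img)
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  aff <- unname(structure(RNifti::xform(img), code = NULL))
  aff <- matrix(as.numeric(aff), 4, 4)
  if (abs(det(aff[1:3, 1:3])) < 1e-12)       # unset qform: fall back to pixdim
    aff <- diag(c(abs(pd[1:3]), 1))
  vol_geometry(d[1:3], abs(pd[1:3]), affine = aff,
               world_convention = world_convention)
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/2 file. 4D images are returned as a [bold_run()] (with
#' TR taken from the time-axis pixdim unless overridden); 3D images are
#' returned as a plain array with a `geometry` attribute.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param expect `"any"`, `"4d"` or `"3d"`; mismatches are errors.
#' @param tr_s optional TR override in seconds.
#' @param censored_frames optional censor flags for 4D reads.
#' @param world_convention hemisphere reporting convention for the
#'   geometry.
#' @return A `bold_run` or a 3D array with attribute `geometry`.
#' @export
read_volume <- function(path, expect = c("any", "4d", "3d"), tr_s = NULL,
                        censored_frames = integer(0),
                        world_convention = "right_negative_x") {
  expect <- match.arg(expect)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (expect == "4d" && nd != 4L) stop("expected 4D image, got ", nd, "D")
  if (expect == "3d" && nd != 3L) stop("expected 3D image, got ", nd, "D")
  geom <- geometry_from_nifti(img, world_convention)
  if (nd == 4L) {
    if (is.null(tr_s)) {
      pd <- RNifti::pixdim(img)
      tr_s <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
    }
    bold_run(array(as.numeric(img), dim(img)), geom, tr_s = tr_s,
             censored_frames = censored_frames)
  } else if (nd == 3L) {
    v <- array(as.numeric(img), dim(img))
    attr(v, "geometry") <- geom
    v
  } else stop("expected a 3D or 4D image, got ", nd, "D")
}

#' Write a volume, run or mask as NIfTI
#'
#' `bold_run`s are written as 4D with TR in the time pixdim; masks as
#' uint8 indicator volumes; arrays as given. Data are stored as float64
#' so that write-read round trips are lossless.
#'
#' @param x a [bold_run()], [network_mask()], or 3/4D array (optionally
#'   carrying a `geometry` attribute).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param geometry geometry to use when `x` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, geometry = NULL) {
  if (inherits(x, "network_mask")) {
    arr <- mask_to_volume(x)
    geometry <- x$geometry
    dt <- "uint8"
    tdim <- NULL
  } else if (inherits(x, "bold_run")) {
    arr <- x$data
    geometry <- x$geometry
    dt <- "double"
    tdim <- x$tr_s
  } else {
    arr <- x
    if (is.null(geometry)) geometry <- attr(x, "geometry")
    if (is.null(geometry)) geometry <- vol_geometry(dim(arr)[1:3])
    dt <- "double"
    tdim <- NULL
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(geometry$voxel_size_mm,
                           if (!is.null(tdim)) tdim)
  RNifti::qform(img) <- structure(geometry$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}
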