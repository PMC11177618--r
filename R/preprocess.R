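## Minimal residualization chain: simultaneous bandpass + nuisance
## regression (one OLS per voxel), Gaussian spatial smoothing, and
## per-voxel intensity normalization.

## sine/cosine regressors for all DFT frequencies OUTSIDE [low, high];
## projecting them out is the bandpass
fourier_outside_band <- function(n, tr_s, low_hz, high_hz) {
  kmax <- floor(n / 2)
  cols <- list()
  tt <- seq_len(n) - 1
  for (k in seq_len(kmax)) {
    f <- k / (n * tr_s)
    if (f >= low_hz && f <= high_hz) next
    ang <- 2 * pi * k * tt / n
    cols[[length(cols) + 1L]] <- cos(ang)
    if (k < n / 2) cols[[length(cols) + 1L]] <- sin(ang)
  }
  if (length(cols)) do.call(cbind, cols) else matrix(0, n, 0)
}

#' Nuisance regressor set
#'
#' @param regressors numeric matrix, one row per frame, one column per
#'   regressor (e.g. motion estimates and their derivatives).
#' @param names optional column names.
#' @return An object of class `nuisance_set`.
#' @export
nuisance_set <- function(regressors, names = colnames(regressors)) {
  regressors <- as.matrix(regressors)
  stopifnot(all(is.finite(regressors)))
  if (is.null(names)) names <- paste0("nuis", seq_len(ncol(regressors)))
  structure(list(regressors = regressors, names = names),
            class = "nuisance_set")
}

#' Read whitespace-delimited nuisance regressors
#'
#' One row per frame, one column per regressor.
#'
#' @param path text file path.
#' @return A [nuisance_set()].
#' @export
read_nuisance <- function(path) {
  nuisance_set(as.matrix(utils::read.table(path, header = FALSE)))
}

#' Residualize a BOLD run
#'
#' Fits, per voxel, a single ordinary-least-squares model whose columns
#' are an intercept, an optional linear trend, the nuisance regressors,
#' and sine/cosine terms at every DFT frequency outside `band` — so that
#' bandpass filtering and nuisance removal happen in one simultaneous
#' linear model. The fit uses non-censored frames only; censored frames
#' are zero-filled in the output and recorded in `censored_frames`.
#'
#' @param run a [bold_run()].
#' @param nuisance a [nuisance_set()] or `NULL`.
#' @param band `c(low_hz, high_hz)` passband, or `NULL` to skip the
#'   Fourier columns. Must satisfy `0 <= low < high < 1/(2 tr_s)`.
#' @param censored frame indices to censor (default: the run's flags).
#' @param trend include a linear-trend column (default `TRUE`).
#' @return A residualized [bold_run()].
#' @export
residualize <- function(run, nuisance = NULL, band = NULL,
                        censored = run$censored_frames, trend = TRUE) {
  nt <- n_frames(run)
  censored <- sort(unique(as.integer(censored)))
  keep <- setdiff(seq_len(nt), censored)
  X <- matrix(1, nt, 1)
  if (trend) X <- cbind(X, seq_len(nt) - (nt + 1) / 2)
  if (!is.null(nuisance)) {
    stopifnot(inherits(nuisance, "nuisance_set"),
              nrow(nuisance$regressors) == nt)
    X <- cbind(X, nuisance$regressors)
  }
  if (!is.null(band)) {
    low <- band[1]; high <- band[2]
    nyq <- 1 / (2 * run$tr_s)
    if (!(low >= 0 && low < high && high < nyq))
      stop("band must satisfy 0 <= low < high < Nyquist (", round(nyq, 4),
           " Hz)")
    if (low > 0 && nt * run$tr_s < 2 / low)
      warning("run shorter than two cycles of the low cutoff")
    X <- cbind(X, fourier_outside_band(nt, run$tr_s, low, high))
  }
  if (ncol(X) >= length(keep))
    stop("design has as many columns as usable frames")
  dat <- run$data
  d <- dim(dat)
  Y <- matrix(dat, prod(d[1:3]), d[4])
  qx <- qr(X[keep, , drop = FALSE])
  if (qx$rank < ncol(X))
    warning("rank-deficient design: ", ncol(X) - qx$rank,
            " collinear column(s) dropped")
  res <- t(qr.resid(qx, t(Y[, keep, drop = FALSE])))
  out <- matrix(0, nrow(Y), d[4])
  out[, keep] <- res
  bold_run(array(out, d), run$geometry, tr_s = run$tr_s,
           censored_frames = censored, subject_id = run$subject_id,
           condition = run$condition)
}

#' Bandpass filter a run by frequency-regressor projection
#'
#' Removes all DFT frequency components outside `[low_hz, high_hz]`
#' (including DC) by projecting out the corresponding sine/cosine
#' regressors; equivalent to [residualize()] with no nuisance set and no
#' trend column.
#'
#' @param run a [bold_run()].
#' @param low_hz,high_hz passband edges in Hz.
#' @return A filtered [bold_run()].
#' @export
bandpass <- function(run, low_hz = 0.01, high_hz = 0.1) {
  residualize(run, nuisance = NULL, band = c(low_hz, high_hz),
              trend = FALSE)
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3.5 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

## banded convolution matrix with zero-padding at the edges
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  C <- matrix(0, n, n)
  for (off in -r:r) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1 & j <= n
    C[cbind(i[ok], j[ok])] <- kernel[off + r + 1L]
  }
  C
}

#' Gaussian spatial smoothing
#'
#' Separable per-frame 3D Gaussian convolution with
#' `sigma = fwhm / (2 sqrt(2 log 2))` converted to voxels on each axis,
#' zero-padded at the volume edges. `fwhm_mm = 0` is the identity.
#' Internally the x-axis convolution is one matrix product and the y/z
#' convolutions are fused into a single Kronecker-product operator, so
#' long 4D series smooth without a per-frame loop.
#'
#' @param x a [bold_run()], 4D array, or 3D array.
#' @param fwhm_mm kernel full-width at half-maximum in mm.
#' @param voxel_size_mm voxel size per axis (taken from the run's
#'   geometry when `x` is a `bold_run`).
#' @return Same type as `x`, smoothed.
#' @export
smooth_volume <- function(x, fwhm_mm, voxel_size_mm = c(1, 1, 1)) {
  stopifnot(fwhm_mm >= 0)
  if (inherits(x, "bold_run")) {
    out <- x
    out$data <- smooth_volume(x$data, fwhm_mm, x$geometry$voxel_size_mm)
    return(out)
  }
  if (fwhm_mm == 0) return(x)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d <- dim(x)
  stopifnot(length(d) %in% 3:4)
  ks <- lapply(1:3, function(ax)
    gaussian_kernel_1d(sigma_mm / voxel_size_mm[ax]))
  C1 <- conv_matrix(d[1], ks[[1]])
  ## operator on the combined (y, z) index, y varying fastest
  C23 <- kronecker(conv_matrix(d[3], ks[[3]]), conv_matrix(d[2], ks[[2]]))
  nyz <- d[2] * d[3]
  if (length(d) == 3L) {
    dim(x) <- c(d[1], nyz)
    out <- C1 %*% x %*% t(C23)
    dim(out) <- d
    return(out)
  }
  nt <- d[4]
  dim(x) <- c(d[1], nyz * nt)
  x <- C1 %*% x
  dim(x) <- c(d[1], nyz, nt)
  x <- aperm(x, c(2, 1, 3))
  dim(x) <- c(nyz, d[1] * nt)
  x <- C23 %*% x
  dim(x) <- c(nyz, d[1], nt)
  x <- aperm(x, c(2, 1, 3))
  dim(x) <- d
  x
}

#' Scale each voxel's series to mean 100
#'
#' Per-voxel multiplicative rescaling so the mean over non-censored
#' frames is 100; voxels whose mean is 0 (e.g. all-zero voxels) are left
#' untouched. Pearson correlations downstream are invariant to this.
#'
#' @param run a [bold_run()].
#' @return A rescaled [bold_run()].
#' @export
normalize_intensity <- function(run) {
  keep <- valid_frames(run)
  d <- dim(run$data)
  Y <- matrix(run$data, prod(d[1:3]), d[4])
  m <- rowMeans(Y[, keep, drop = FALSE])
  scale <- ifelse(m == 0, 1, 100 / m)
  run$data <- array(Y * scale, d)
  run
}
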