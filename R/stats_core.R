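## Scalar statistical primitives shared by every pipeline stage:
## Pearson correlation on valid frames, Fisher z, paired t, and the
## t -> standardized-normal ("z(t)") conversion used for voxel thresholds.

#' Pearson correlation over valid frames
#'
#' Computes Pearson's r between two series restricted to `valid` frames
#' (typically the non-censored frames of a run). A constant series yields
#' `NaN` with a warning rather than an error, since masked-out voxels can
#' legitimately be flat.
#'
#' @param x,y numeric series of equal length.
#' @param valid integer indices (or logical vector) of frames to use;
#'   default all.
#' @return Correlation in `[-1, 1]`, or `NaN` for degenerate input.
#' @export
pearson_r <- function(x, y, valid = NULL) {
  stopifnot(length(x) == length(y))
  if (!is.null(valid)) {
    x <- x[valid]
    y <- y[valid]
  }
  if (length(x) < 3L) stop("need at least 3 valid frames")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant series: correlation undefined")
    return(NaN)
  }
  stats::cor(x, y)
}

#' Fisher's z transform
#'
#' `z = arctanh(r)`, the variance-stabilizing transform applied to
#' correlations throughout the pipeline. Values within floating-point
#' reach of `+/-1` (|r| >= 1 - 1e-7, which arise from numerically
#' identical series) are clipped to `+/-(1 - 1e-7)` with a warning, so
#' degenerate pairs yield a large finite z instead of overflowing.
#'
#' @param r numeric vector of correlations.
#' @return Fisher z values, same shape as `r`.
#' @export
fisher_z <- function(r) {
  bad <- is.finite(r) & abs(r) >= 1 - 1e-7
  if (any(bad)) {
    warning("correlation at or beyond +/-1 clipped before Fisher z")
    r[bad] <- sign(r[bad]) * (1 - 1e-7)
  }
  atanh(r)
}

#' Paired t statistic
#'
#' Two-tailed paired t on subject-aligned values: `d = a - b`,
#' `t = mean(d) / (sd(d)/sqrt(n))`, `df = n - 1` (sample sd, n-1
#' denominator). Degenerate case `sd(d) = 0`: t is 0 when the mean
#' difference is also 0, otherwise a signed infinity sentinel.
#'
#' @param a,b numeric vectors of per-subject values, equal length >= 2.
#' @return List with elements `t` and `df`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  t <- if (s == 0) {
    if (m == 0) 0 else sign(m) * Inf
  } else m / (s / sqrt(n))
  list(t = t, df = n - 1L)
}

## cap for the standardized-z sentinel: beyond the range where the
## normal quantile is representable
.z_cap <- 38

#' Standardize a t statistic to the normal scale
#'
#' `z(t) = qnorm(pt(t, df))`, computed tail-symmetrically in log space
#' (the smaller tail is evaluated and the sign restored) so that very
#' large `|t|` maps to a large finite z instead of overflowing. This is
#' the scale on which voxelwise cluster-forming thresholds are applied
#' (z = 1.96 for two-tailed p < 0.05, z = 3.291 for p < 0.001).
#'
#' @param t numeric vector of t statistics (may contain `+/-Inf`).
#' @param df degrees of freedom (>= 1), scalar or vector.
#' @return Standardized z, monotone and odd in `t`.
#' @export
t_to_z <- function(t, df) {
  stopifnot(all(df >= 1))
  z <- rep(NA_real_, length(t))
  fin <- is.finite(t)
  if (any(fin)) {
    lp <- stats::pt(abs(t[fin]), df = if (length(df) > 1) df[fin] else df,
                    lower.tail = FALSE, log.p = TRUE)
    zz <- stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
    z[fin] <- sign(t[fin]) * pmin(zz, .z_cap)
  }
  inf <- is.infinite(t)
  z[inf] <- sign(t[inf]) * .z_cap
  z
}
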