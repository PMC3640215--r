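#' Masked voxel time-series matrix
#'
#' The working container for one subject's fMRI run: a time-by-voxel real
#' matrix together with its sampling interval and the mapping from voxel
#' columns back to 3D grid coordinates.
#'
#' @param data numeric matrix, rows are time points, columns in-mask voxels.
#' @param tr_seconds sampling interval in seconds (> 0).
#' @param voxel_index V x 3 integer matrix of 1-based grid coordinates, one
#'   row per column of `data`, in mask scan order (first axis fastest).
#' @param subject_id character label.
#' @return object of class `voxel_ts`.
#' @export
voxel_ts <- function(data, tr_seconds, voxel_index = NULL,
                     subject_id = "sub-01") {
  data <- as.matrix(data)
  .stop_if(!all(is.finite(data)), "voxel time series contain non-finite values")
  stopifnot(tr_seconds > 0)
  if (!is.null(voxel_index)) {
    voxel_index <- as.matrix(voxel_index)
    stopifnot(nrow(voxel_index) == ncol(data), ncol(voxel_index) == 3)
  }
  structure(list(data = data, tr_seconds = tr_seconds,
                 voxel_index = voxel_index, subject_id = subject_id),
            class = "voxel_ts")
}

#' @export
print.voxel_ts <- function(x, ...) {
  cat("<voxel_ts>", x$subject_id, ":", nrow(x$data), "volumes x",
      ncol(x$data), "voxels @ TR", x$tr_seconds, "s\n")
  invisible(x)
}

#' @export
dim.voxel_ts <- function(x) dim(x$data)

#' High-pass filter specification
#'
#' @param cutoff_hz lower frequency bound retained, in Hz. Frequencies
#'   strictly below the cutoff are removed; the bin exactly at the cutoff is
#'   kept.
#' @param zero_dc whether the DC (mean) bin is also zeroed.
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(cutoff_hz = 0.25, zero_dc = TRUE) {
  stopifnot(cutoff_hz > 0)
  structure(list(cutoff_hz = cutoff_hz, zero_dc = isTRUE(zero_dc)),
            class = "filter_spec")
}

#' Discard initial volumes
#'
#' Drops the first `n_discard` time points of a run to remove the T1
#' saturation transient at the start of an EPI acquisition.
#'
#' @param m a [voxel_ts()].
#' @param n_discard number of initial rows to remove (must leave >= 1 row).
#' @return the shortened [voxel_ts()].
#' @export
discard_initial_volumes <- function(m, n_discard) {
  stopifnot(inherits(m, "voxel_ts"), n_discard >= 0)
  .stop_if(n_discard >= nrow(m$data),
           "cannot discard ", n_discard, " of ", nrow(m$data), " volumes")
  if (n_discard == 0) return(m)
  m$data <- m$data[-seq_len(n_discard), , drop = FALSE]
  m
}

#' Regress motion parameters out of every voxel
#'
#' Least-squares residuals of each voxel time course on an intercept plus the
#' six rigid-body motion parameters (3 translations, 3 rotations). A
#' rank-deficient design (e.g. a constant motion column) is handled through
#' the pivoted QR solve, with a warning.
#'
#' @param m a [voxel_ts()].
#' @param motion numeric time-by-6 matrix or data frame, rows matching
#'   `m$data`.
#' @return [voxel_ts()] of residuals.
#' @export
regress_motion <- function(m, motion) {
  stopifnot(inherits(m, "voxel_ts"))
  motion <- as.matrix(motion)
  .stop_if(nrow(motion) != nrow(m$data),
           "motion table has ", nrow(motion), " rows but data has ",
           nrow(m$data))
  .stop_if(ncol(motion) != 6, "motion table must have 6 columns")
  X <- cbind(1, motion)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    warning("motion design is rank deficient (rank ", qr_x$rank, " of ",
            ncol(X), "); using pivoted least squares")
  }
  m$data <- qr.resid(qr_x, m$data)
  m
}

#' Scale every voxel to mean 0, SD 1
#'
#' Constant columns cannot be standardized; they are set to all-zero and their
#' count recorded in the `n_constant` attribute of the result.
#'
#' @param m a [voxel_ts()].
#' @return standardized [voxel_ts()] with attribute `n_constant`.
#' @export
standardize_voxels <- function(m) {
  stopifnot(inherits(m, "voxel_ts"))
  mu <- colMeans(m$data)
  ctr <- sweep(m$data, 2, mu)
  s <- sqrt(colSums(ctr^2) / (nrow(ctr) - 1))
  const <- s == 0
  s[const] <- 1
  out <- sweep(ctr, 2, s, "/")
  out[, const] <- 0
  m$data <- out
  attr(m, "n_constant") <- sum(const)
  m
}

#' Exact DFT high-pass filter
#'
#' Transforms each voxel time course with the discrete Fourier transform,
#' zeroes every coefficient whose frequency is strictly below the cutoff
#' (plus DC when `zero_dc`), and transforms back. Positive- and
#' negative-frequency bins are zeroed symmetrically so the output is exactly
#' real; bins at or above the cutoff are untouched, making the filter exact on
#' the DFT grid and idempotent.
#'
#' @param m a [voxel_ts()].
#' @param spec a [filter_spec()]; the cutoff must lie below the Nyquist
#'   frequency `1 / (2 * tr)`.
#' @return filtered [voxel_ts()].
#' @export
highpass_fourier <- function(m, spec = filter_spec()) {
  stopifnot(inherits(m, "voxel_ts"), inherits(spec, "filter_spec"))
  nyq <- 1 / (2 * m$tr_seconds)
  .stop_if(spec$cutoff_hz >= nyq,
           "cutoff (", spec$cutoff_hz, " Hz) must be below Nyquist (",
           round(nyq, 4), " Hz)")
  n <- nrow(m$data)
  f <- (0:(n - 1)) / (n * m$tr_seconds)
  f_folded <- pmin(f, 1 / m$tr_seconds - f)
  keep <- f_folded >= spec$cutoff_hz
  if (spec$zero_dc) keep[1] <- FALSE else keep[1] <- TRUE
  m$data <- Re(mvfft(mvfft(m$data) * keep, inverse = TRUE)) / n
  m
}

# 1D Gaussian kernel matrix with renormalization handled by the caller
.gauss_kernel <- function(fwhm) {
  sigma <- fwhm / 2.3548
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k / sum(k)
}

# convolve a 3D array along one axis with kernel k, treating NA as outside
.conv_axis <- function(a, k, axis) {
  d <- dim(a)
  perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  mat <- matrix(ap, dp[1], dp[2] * dp[3])
  half <- (length(k) - 1) / 2
  out <- matrix(0, dp[1], ncol(mat))
  for (i in seq_along(k)) {
    off <- i - 1 - half
    src <- seq_len(dp[1]) + off
    ok <- src >= 1 & src <= dp[1]
    out[ok, ] <- out[ok, ] + k[i] * mat[src[ok], ]
  }
  arr <- array(out, dp)
  aperm(arr, order(perm))
}

#' Gaussian spatial smoothing on the masked grid
#'
#' Separable Gaussian convolution (`sigma = fwhm / 2.3548` per axis) applied
#' volume by volume, restricted to in-mask voxels: values outside the mask are
#' treated as absent and the kernel is renormalized at mask edges by dividing
#' through the smoothed mask indicator, so no signal is diluted into the
#' exterior. `fwhm = 0` is the identity.
#'
#' @param m a [voxel_ts()] with a `voxel_index`.
#' @param fwhm_voxels full width at half maximum per axis, in voxels
#'   (length 1 or 3, >= 0).
#' @return smoothed [voxel_ts()].
#' @export
smooth_gaussian <- function(m, fwhm_voxels) {
  stopifnot(inherits(m, "voxel_ts"), all(fwhm_voxels >= 0))
  fwhm <- rep_len(fwhm_voxels, 3)
  if (all(fwhm == 0)) return(m)
  .stop_if(is.null(m$voxel_index), "smoothing needs a voxel_index")
  grid <- apply(m$voxel_index, 2, max)
  kern <- lapply(fwhm, function(f) if (f > 0) .gauss_kernel(f) else 1)
  mask_arr <- array(0, grid)
  mask_arr[m$voxel_index] <- 1
  w <- mask_arr
  for (ax in 1:3) if (fwhm[ax] > 0) w <- .conv_axis(w, kern[[ax]], ax)
  wv <- w[m$voxel_index]
  out <- m$data
  vol <- array(0, grid)
  for (t in seq_len(nrow(m$data))) {
    vol[m$voxel_index] <- m$data[t, ]
    sm <- vol
    for (ax in 1:3) if (fwhm[ax] > 0) sm <- .conv_axis(sm, kern[[ax]], ax)
    out[t, ] <- sm[m$voxel_index] / wv
  }
  m$data <- out
  m
}

#' Temporal preprocessing pipeline for one subject
#'
#' Fixed order: discard initial volumes, regress motion, standardize voxels,
#' optional Gaussian smoothing, DFT high-pass filter. Each step and its
#' parameters are recorded in the `provenance` attribute of the result.
#'
#' @param m a [voxel_ts()].
#' @param motion time-by-6 motion table aligned with the *undiscarded* run
#'   (its first `n_discard` rows are dropped alongside the data), or `NULL`
#'   to skip motion regression.
#' @param n_discard initial volumes to drop (default 24).
#' @param cutoff_hz high-pass cutoff in Hz; `NA` disables the filter (the
#'   unfiltered reference analysis).
#' @param fwhm_voxels smoothing FWHM in voxels (0 = off).
#' @return preprocessed [voxel_ts()] with a `provenance` attribute.
#' @export
preprocess <- function(m, motion = NULL, n_discard = 24, cutoff_hz = 0.25,
                       fwhm_voxels = 0) {
  steps <- list(discard = n_discard)
  m <- discard_initial_volumes(m, n_discard)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (n_discard > 0) {
      .stop_if(nrow(motion) <= n_discard,
               "motion table shorter than the discard count")
      motion <- motion[-seq_len(n_discard), , drop = FALSE]
    }
    m <- regress_motion(m, motion)
    steps$motion_regression <- TRUE
  }
  m <- standardize_voxels(m)
  steps$n_constant_voxels <- attr(m, "n_constant")
  if (any(fwhm_voxels > 0)) {
    m <- smooth_gaussian(m, fwhm_voxels)
    steps$smooth_fwhm_voxels <- fwhm_voxels
  }
  if (!is.na(cutoff_hz)) {
    m <- highpass_fourier(m, filter_spec(cutoff_hz = cutoff_hz))
    steps$highpass_cutoff_hz <- cutoff_hz
  }
  attr(m, "provenance") <- steps
  m
}
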