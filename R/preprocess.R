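#' Cleaning configuration
#'
#' @param fd_threshold censoring threshold on framewise displacement, mm
#'   (default 0.15).
#' @param rotation_radius radius converting rotation increments to arc
#'   displacement, mm (default 5, rodent head scale).
#' @param band passband in Hz (default 0.01--0.10).
#' @param fwhm spatial smoothing kernel full-width at half-maximum, mm
#'   (default 0.7).
#' @param n_discard leading volumes removed before any cleaning (default 10).
#' @param censor_mode `"interpolate"` (default; keeps the regular temporal
#'   grid that windowed analyses need) or `"drop"`.
#' @param TR repetition time, seconds (default 1).
#' @return A `cleaning_config` list.
#' @export
cleaning_config <- function(fd_threshold = 0.15, rotation_radius = 5,
                            band = c(0.01, 0.10), fwhm = 0.7,
                            n_discard = 10,
                            censor_mode = c("interpolate", "drop"),
                            TR = 1) {
  censor_mode <- match.arg(censor_mode)
  nyq <- 1 / (2 * TR)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < nyq)) {
    stop("band must satisfy 0 < low < high < Nyquist")
  }
  if (fwhm < 0) stop("fwhm must be >= 0")
  structure(list(fd_threshold = fd_threshold,
                 rotation_radius = rotation_radius, band = band, fwhm = fwhm,
                 n_discard = n_discard, censor_mode = censor_mode, TR = TR),
            class = "cleaning_config")
}

#' Framewise displacement from a six-parameter motion table
#'
#' FD(t) is the sum of absolute backward differences of the three
#' translations (mm) plus `radius` times those of the three rotations
#' (radians), with FD(1) = 0.
#'
#' @param motion T x 6 matrix: translations (mm) then rotations (radians).
#' @param radius rotation-to-displacement radius in mm (default 5).
#' @return Numeric vector of length T, non-negative.
#' @export
framewise_displacement <- function(motion, radius = 5) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion table must have exactly 6 columns")
  if (nrow(motion) < 2) stop("need at least 2 frames")
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            radius * rowSums(d[, 4:6, drop = FALSE]))
  fd
}

#' Censor high-motion frames
#'
#' @param series T x V numeric matrix (columns are regions or voxels).
#' @param fd framewise displacement aligned to `series`.
#' @param threshold censoring threshold in mm (default 0.15).
#' @param mode `"drop"` removes offending rows; `"interpolate"` (default)
#'   replaces them by linear interpolation over surviving frames, keeping T
#'   constant.
#' @return List: `series` (cleaned), `kept` (row indices of surviving
#'   frames), `censored` (indices flagged).
#' @export
censor_frames <- function(series, fd, threshold = 0.15,
                          mode = c("interpolate", "drop")) {
  mode <- match.arg(mode)
  series <- as.matrix(series)
  if (length(fd) != nrow(series)) stop("fd not aligned to series")
  bad <- which(fd > threshold)
  if (length(bad) > 0.5 * nrow(series)) {
    warning(sprintf("%d/%d frames censored (>50%%): flag subject for exclusion",
                    length(bad), nrow(series)))
  }
  if (length(bad) == 0) {
    return(list(series = series, kept = seq_len(nrow(series)),
                censored = integer(0)))
  }
  keep <- setdiff(seq_len(nrow(series)), bad)
  if (mode == "drop") {
    return(list(series = series[keep, , drop = FALSE], kept = keep,
                censored = bad))
  }
  out <- series
  for (j in seq_len(ncol(series))) {
    out[bad, j] <- stats::approx(keep, series[keep, j], xout = bad,
                                 rule = 2)$y
  }
  list(series = out, kept = seq_len(nrow(series)), censored = bad)
}

#' Hard frequency-domain band-pass filter
#'
#' Zeroes all Fourier amplitudes with frequency outside `band` (the DC and,
#' when outside the band, Nyquist bins included) and inverts the transform.
#' Idempotent by construction. Columns are filtered independently.
#'
#' @param x numeric vector or T x V matrix.
#' @param TR sampling interval in seconds.
#' @param band passband `c(low, high)` in Hz.
#' @return Filtered object of the same shape.
#' @export
bandpass_fft <- function(x, TR = 1, band = c(0.01, 0.10)) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  T <- nrow(x)
  freq <- pmin(seq_len(T) - 1, T - (seq_len(T) - 1)) / (T * TR)
  keep <- freq >= band[1] & freq <= band[2]
  out <- apply(x, 2, function(col) {
    f <- stats::fft(col)
    f[!keep] <- 0
    Re(stats::fft(f, inverse = TRUE)) / T
  })
  out <- matrix(out, nrow = T)
  dimnames(out) <- dimnames(x)
  if (vec) drop(out) else out
}

#' Detrend, regress nuisance signals, and band-pass filter
#'
#' Per column: ordinary-least-squares residualization against an intercept,
#' a linear trend, and the supplied confound columns (WM mean, CSF mean, six
#' motion parameters), followed by the hard band-pass of [bandpass_fft()].
#' The global mean signal is deliberately not a regressor. Constant confound
#' columns are dropped with a warning. Regression precedes filtering; the
#' sequential ordering can reintroduce a small out-of-band component of the
#' confounds into the residual band, a known property that is documented
#' rather than altered.
#'
#' @param series T x V matrix, leading discard frames already removed.
#' @param confounds T x C matrix (typically C = 8) aligned to `series`; may
#'   be NULL for trend-only cleaning.
#' @param config a [cleaning_config()].
#' @return Cleaned T x V matrix.
#' @export
clean_timeseries <- function(series, confounds = NULL,
                             config = cleaning_config()) {
  series <- as.matrix(series)
  T <- nrow(series)
  X <- cbind(intercept = 1, trend = seq_len(T) - (T + 1) / 2)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != T) stop("confounds not aligned to series")
    keep <- apply(confounds, 2, function(c) stats::sd(c) > 0)
    if (!all(keep)) {
      warning(sprintf("dropping %d constant confound column(s)",
                      sum(!keep)))
      confounds <- confounds[, keep, drop = FALSE]
    }
    X <- cbind(X, confounds)
  }
  resid <- stats::lm.fit(X, series)$residuals
  resid <- matrix(resid, nrow = T, dimnames = dimnames(series))
  bandpass_fft(resid, TR = config$TR, band = config$band)
}

# 1-D Gaussian kernel for a FWHM given in voxel units, truncated at 3 sigma.
.gauss_kernel <- function(fwhm_vox) {
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  if (sigma < 1e-8) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable 3-D convolution with zero padding at the grid edges.
.conv3_sep <- function(vol, kernel) {
  if (length(kernel) == 1) return(vol)
  d <- dim(vol)
  r <- (length(kernel) - 1) / 2
  for (ax in 1:3) {
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    v <- aperm(vol, perm)
    dm <- dim(v)
    m <- matrix(v, nrow = dm[1])
    padded <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
    out <- matrix(0, dm[1], ncol(m))
    for (i in seq_along(kernel)) {
      out <- out + kernel[i] * padded[i:(i + dm[1] - 1), , drop = FALSE]
    }
    vol <- aperm(array(out, dm), order(perm))
  }
  vol
}

#' Mask-normalized spatial Gaussian smoothing
#'
#' Per-frame separable 3-D Gaussian convolution with
#' sigma = fwhm / (2 sqrt(2 ln 2)) per axis. Kernel weights are renormalized
#' over in-mask voxels (smooth(x*m)/smooth(m)) so values near the mask border
#' are not darkened; out-of-mask voxels are left untouched. A constant
#' in-mask field is exactly preserved; the in-mask mean is preserved only
#' approximately near mask borders (the renormalized operator is row- but
#' not column-stochastic there).
#'
#' @param bold 4-D array (x, y, z, t) or a `voxel_scan`.
#' @param fwhm kernel FWHM in mm.
#' @param voxel_size voxel edge in mm (taken from the scan if one is given).
#' @param mask logical 3-D array; smoothing confined to it (defaults to the
#'   scan's brain mask, or all-TRUE for a bare array).
#' @return Object of the same type with smoothed BOLD.
#' @export
gaussian_smooth <- function(bold, fwhm, voxel_size = NULL, mask = NULL) {
  scan <- NULL
  if (inherits(bold, "voxel_scan")) {
    scan <- bold
    if (is.null(voxel_size)) voxel_size <- scan$voxel_size
    if (is.null(mask)) mask <- scan$brain_mask
    bold <- scan$bold
  }
  stopifnot(length(dim(bold)) == 4, !is.null(voxel_size))
  if (is.null(mask)) mask <- array(TRUE, dim(bold)[1:3])
  if (fwhm > 0 && fwhm < voxel_size / 2) {
    warning("fwhm below half the voxel size: smoothing is a near-no-op")
  }
  kernel <- .gauss_kernel(fwhm / voxel_size)
  if (length(kernel) == 1) {
    out <- bold
  } else {
    m <- array(as.numeric(mask), dim(mask))
    sm_mask <- .conv3_sep(m, kernel)
    sm_mask[sm_mask < 1e-12] <- 1
    out <- bold
    for (t in seq_len(dim(bold)[4])) {
      frame <- bold[, , , t]
      sm <- .conv3_sep(frame * m, kernel) / sm_mask
      frame[mask] <- sm[mask]
      out[, , , t] <- frame
    }
  }
  if (!is.null(scan)) {
    scan$bold <- out
    scan
  } else out
}

#' Full cleaning of a region-level simulated subject
#'
#' Applies the pipeline's owned steps in order: discard leading frames,
#' censor by framewise displacement, detrend + nuisance regression (WM, CSF,
#' six motion parameters), band-pass.
#'
#' @param subject one element of a `roi_sim`'s `subjects` list (or any list
#'   with `series`, `motion`, `wm`, `csf`).
#' @param config a [cleaning_config()].
#' @return List: `series` (cleaned), `fd`, `censored`, `kept`.
#' @export
clean_roi_subject <- function(subject, config = cleaning_config()) {
  keep <- (config$n_discard + 1):nrow(subject$series)
  series <- subject$series[keep, , drop = FALSE]
  motion <- subject$motion[keep, , drop = FALSE]
  conf <- cbind(wm = subject$wm[keep], csf = subject$csf[keep], motion)
  fd <- framewise_displacement(motion, config$rotation_radius)
  cens <- censor_frames(series, fd, config$fd_threshold, config$censor_mode)
  conf <- conf[cens$kept, , drop = FALSE]
  cleaned <- clean_timeseries(cens$series, conf, config)
  list(series = cleaned, fd = fd, censored = cens$censored,
       kept = cens$kept)
}
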