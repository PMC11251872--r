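#' Kendall's coefficient of concordance (W)
#'
#' Agreement among m raters ranking n objects. Each rater's scores are
#' ranked with average ranks for ties; with rank sums R_j,
#' S = sum_j (R_j - mean R)^2 and
#' W = 12 S / (m^2 (n^3 - n) - m * sum_i T_i), where T_i = sum over the tie
#' groups of rater i of (t^3 - t). Without ties the denominator reduces to
#' m^2 (n^3 - n). W is invariant to rater order and to monotone per-rater
#' transforms.
#'
#' @param scores m x n matrix: rows are raters, columns objects.
#' @param tie_correction apply the tie term (default TRUE). With it off, a
#'   rater with all-equal scores makes W undefined (NA).
#' @return W in [0, 1]; NA when undefined (all raters constant, or a
#'   constant rater with `tie_correction = FALSE`).
#' @export
kendalls_w <- function(scores, tie_correction = TRUE) {
  scores <- as.matrix(scores)
  m <- nrow(scores); n <- ncol(scores)
  if (m < 2 || n < 2) stop("need at least 2 raters and 2 objects")
  const <- apply(scores, 1, function(r) length(unique(r)) == 1)
  if (all(const)) return(NA_real_)
  if (!tie_correction && any(const)) return(NA_real_)
  ranks <- t(apply(scores, 1, rank))
  Tsum <- if (tie_correction) sum(apply(ranks, 1, .tie_term)) else 0
  Rj <- colSums(ranks)
  S <- sum((Rj - mean(Rj))^2)
  denom <- m^2 * (n^3 - n) - m * Tsum
  if (denom <= 0) return(NA_real_)
  12 * S / denom
}

.tie_term <- function(r) {
  if (!anyDuplicated(r)) return(0)
  tt <- table(r)
  sum(tt^3 - tt)
}

# W from precomputed per-object rank sums, rater count m, object count n and
# total tie term. Shared by ReHo/stability fast paths.
.w_from_ranksums <- function(Rj, m, n, Tsum) {
  S <- sum((Rj - m * (n + 1) / 2)^2)
  denom <- m^2 * (n^3 - n) - m * Tsum
  if (denom <= 0) return(NA_real_)
  12 * S / denom
}

# In-mask 26-neighborhoods (including the center voxel) for every in-mask
# voxel; returned as positions into the vector of in-mask voxels.
.neighborhoods26 <- function(mask) {
  dims <- dim(mask)
  idx <- which(mask)
  pos <- array(0L, dims)
  pos[idx] <- seq_along(idx)
  coords <- which(mask, arr.ind = TRUE)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  lapply(seq_along(idx), function(i) {
    nb <- sweep(offs, 2, coords[i, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nb <- nb[ok, , drop = FALSE]
    p <- pos[nb]
    p[p > 0L]
  })
}

#' Fractional amplitude of low-frequency fluctuations
#'
#' Ratio of summed Fourier amplitudes inside the band to the summed
#' amplitude over all positive frequencies (DC excluded), per column.
#'
#' @param x T-vector or T x V matrix.
#' @param TR sampling interval, seconds.
#' @param band passband in Hz.
#' @return fALFF per column, in [0, 1].
#' @export
falff <- function(x, TR = 1, band = c(0.01, 0.10)) {
  x <- as.matrix(x)
  T <- nrow(x)
  amp <- Mod(stats::mvfft(x))
  kmax <- floor(T / 2)
  pos <- 2:(kmax + 1)
  freq <- (pos - 1) / (T * TR)
  inband <- freq >= band[1] & freq <= band[2]
  tot <- colSums(amp[pos, , drop = FALSE])
  out <- colSums(amp[pos[inband], , drop = FALSE]) / tot
  out[tot == 0] <- NA_real_
  drop(out)
}

# Flatten a 4-D scan to a T x V matrix of the voxels in `which_idx`.
.flat_series <- function(bold, which_idx) {
  d <- dim(bold)
  m <- matrix(bold, prod(d[1:3]), d[4])
  t(m[which_idx, , drop = FALSE])
}

#' Windowed voxel-level intrinsic-activity indices
#'
#' For every sliding window, five maps over the gray-matter mask:
#' \describe{
#'   \item{fALFF}{band amplitude fraction of the window spectrum;}
#'   \item{ReHo}{Kendall's W of the voxel and its in-mask 26-neighborhood
#'     (raters) over timepoints (objects), computed on *unsmoothed* data
#'     (smoothing order enforced);}
#'   \item{VMHC}{Fisher-z correlation with the homotopic mirror voxel;}
#'   \item{DC}{sum of positive correlations r with all other gray-matter
#'     voxels where r > 0.25 and p < 0.05 (t transform, df = window - 2);}
#'   \item{GScorr}{Fisher-z correlation with the whole-brain-mask mean
#'     series.}
#' }
#'
#' @param scan a cleaned `voxel_scan`.
#' @param width,step window parameters in TR units.
#' @param fwhm smoothing FWHM in mm applied (mask-normalized) before every
#'   index except ReHo; 0 disables (default 0.7).
#' @param dc_r_min DC correlation floor (default 0.25, strict).
#' @param alpha_dc DC significance level (default 0.05, strict).
#' @return A `windowed_voxel_maps` object: list with `maps` (named list of
#'   windows x V_gm matrices), `gm_index`, `windows`, `dims`.
#' @export
windowed_indices <- function(scan, width = 50, step = 5, fwhm = 0.7,
                             dc_r_min = 0.25, alpha_dc = 0.05) {
  stopifnot(inherits(scan, "voxel_scan"))
  dims <- dim(scan$bold)[1:3]
  T <- dim(scan$bold)[4]
  wins <- sliding_windows(T, width, step)
  if (width < 2 / 0.01) {
    # window shorter than two cycles of the low band edge
    warning("window too short to resolve the 0.01 Hz band edge for fALFF")
  }
  gm_idx <- which(scan$gm_mask)
  brain_idx <- which(scan$brain_mask)
  smoothed <- if (fwhm > 0) {
    gaussian_smooth(scan$bold, fwhm, scan$voxel_size, scan$brain_mask)
  } else scan$bold
  raw_gm <- .flat_series(scan$bold, gm_idx)
  sm_gm <- .flat_series(smoothed, gm_idx)
  sm_brain_mean <- rowMeans(.flat_series(smoothed, brain_idx))
  mir <- mirror_index(dims, scan$mirror_axis)[gm_idx]
  mir_pos <- match(mir, gm_idx)
  sm_mirror <- .flat_series(smoothed, mir)
  nbrs <- .neighborhoods26(scan$gm_mask)
  V <- length(gm_idx)
  nw <- nrow(wins)
  maps <- lapply(c("fALFF", "ReHo", "VMHC", "DC", "GScorr"),
                 function(x) matrix(NA_real_, nw, V))
  names(maps) <- c("fALFF", "ReHo", "VMHC", "DC", "GScorr")
  tcrit <- stats::qt(1 - alpha_dc / 2, df = width - 2)
  rcrit <- max(dc_r_min, tcrit / sqrt(tcrit^2 + width - 2))
  for (w in seq_len(nw)) {
    rows <- wins[w, 1]:wins[w, 2]
    sl_sm <- sm_gm[rows, , drop = FALSE]
    sl_raw <- raw_gm[rows, , drop = FALSE]
    maps$fALFF[w, ] <- falff(sl_sm, TR = scan$TR)
    # ReHo: shared per-voxel ranks, neighborhood rank sums
    ranks <- apply(sl_raw, 2, rank)
    ties <- vapply(seq_len(V), function(v) .tie_term(ranks[, v]), numeric(1))
    maps$ReHo[w, ] <- vapply(seq_len(V), function(v) {
      nb <- nbrs[[v]]
      .w_from_ranksums(rowSums(ranks[, nb, drop = FALSE]),
                       m = length(nb), n = width, Tsum = sum(ties[nb]))
    }, numeric(1))
    cs <- scale(sl_sm, center = TRUE, scale = FALSE)
    nrm <- sqrt(colSums(cs^2))
    okv <- nrm > 0
    # VMHC
    vm <- rep(NA_real_, V)
    ok_m <- okv & !is.na(mir_pos) & okv[ifelse(is.na(mir_pos), 1, mir_pos)]
    sl_mir <- cs[, mir_pos[ok_m], drop = FALSE]
    vm[ok_m] <- colSums(cs[, ok_m, drop = FALSE] * sl_mir) /
      (nrm[ok_m] * nrm[mir_pos[ok_m]])
    maps$VMHC[w, ] <- fisher_z(vm)
    # DC over gray-matter voxels
    cn <- sweep(cs[, okv, drop = FALSE], 2, nrm[okv], "/")
    R <- crossprod(cn)
    diag(R) <- 0
    keep <- R > rcrit
    dcv <- rep(NA_real_, V)
    dcv[okv] <- colSums(R * keep)
    maps$DC[w, ] <- dcv
    # GScorr vs the whole-brain mean
    g <- sm_brain_mean[rows] - mean(sm_brain_mean[rows])
    gn <- sqrt(sum(g^2))
    gs <- rep(NA_real_, V)
    if (gn > 0) gs[okv] <- colSums(cs[, okv, drop = FALSE] * g) /
        (nrm[okv] * gn)
    maps$GScorr[w, ] <- fisher_z(gs)
  }
  structure(list(maps = maps, gm_index = gm_idx, windows = wins,
                 dims = dims, width = width, step = step),
            class = "windowed_voxel_maps")
}

#' Concordance of the five intrinsic indices
#'
#' Voxel-wise: per voxel, Kendall's W with the five indices as raters and
#' windows as objects. Volume-wise: per window, W with indices as raters and
#' in-mask voxels as objects, averaged over windows per subject. Because W
#' is rank-based, both are invariant to monotone per-index transforms.
#'
#' @param wvm a `windowed_voxel_maps`.
#' @param fisher_transform also return atanh-transformed copies for group
#'   statistics (default TRUE).
#' @return List of class `concordance_maps`: `voxelwise` (W per gm voxel),
#'   `volumewise_series` (W per window), `volumewise` (their mean), plus
#'   `voxelwise_z` / `volumewise_z` when requested.
#' @export
concordance_maps <- function(wvm, fisher_transform = TRUE) {
  maps <- wvm$maps
  V <- ncol(maps[[1]]); nw <- nrow(maps[[1]])
  voxelwise <- vapply(seq_len(V), function(v) {
    scores <- t(vapply(maps, function(m) m[, v], numeric(nw)))
    scores <- scores[stats::complete.cases(scores), , drop = FALSE]
    if (nrow(scores) < 2) return(NA_real_)
    kendalls_w(scores)
  }, numeric(1))
  volumewise_series <- vapply(seq_len(nw), function(w) {
    scores <- t(vapply(maps, function(m) m[w, ], numeric(V)))
    ok <- !apply(is.na(scores), 2, any)
    if (sum(ok) < 2) return(NA_real_)
    kendalls_w(scores[, ok, drop = FALSE])
  }, numeric(1))
  out <- list(voxelwise = voxelwise,
              volumewise_series = volumewise_series,
              volumewise = mean(volumewise_series, na.rm = TRUE),
              gm_index = wvm$gm_index, dims = wvm$dims)
  if (fisher_transform) {
    out$voxelwise_z <- fisher_z(voxelwise)
    out$volumewise_z <- fisher_z(out$volumewise)
  }
  structure(out, class = "concordance_maps")
}

#' Dynamic FC-architecture stability map
#'
#' For each gray-matter voxel, the windows x (V-1) matrix of Fisher-z FC
#' between the voxel and every other in-mask voxel is summarized by
#' Kendall's W with windows as raters and connections as objects: 1 means
#' the voxel keeps the same whole-brain connectivity profile in every
#' window. Rank ties (e.g. from constant-in-window voxels) are handled by
#' the tie correction. Since ranks are invariant under atanh, W is computed
#' directly on the r profiles.
#'
#' @param scan a cleaned `voxel_scan`.
#' @param width,step window parameters in TR units.
#' @param mask logical 3-D mask (default the scan's gray-matter mask; must
#'   hold at least 10 voxels).
#' @param fisher_transform also return the atanh-transformed map.
#' @return List of class `stability_map`: `stability` (W per mask voxel),
#'   `mask_index`, optionally `stability_z`.
#' @export
stability_map <- function(scan, width = 50, step = 5, mask = NULL,
                          fisher_transform = TRUE) {
  stopifnot(inherits(scan, "voxel_scan"))
  if (is.null(mask)) mask <- scan$gm_mask
  idx <- which(mask)
  V <- length(idx)
  if (V < 10) stop("mask must contain at least 10 voxels")
  T <- dim(scan$bold)[4]
  wins <- sliding_windows(T, width, step)
  nw <- nrow(wins)
  x <- .flat_series(scan$bold, idx)
  ranksums <- matrix(0, V, V - 1)
  tiesums <- numeric(V)
  for (w in seq_len(nw)) {
    sl <- x[wins[w, 1]:wins[w, 2], , drop = FALSE]
    cs <- scale(sl, center = TRUE, scale = FALSE)
    nrm <- sqrt(colSums(cs^2))
    nrm[nrm == 0] <- Inf   # constant voxel: all its r values 0, full ties
    cn <- sweep(cs, 2, nrm, "/")
    R <- crossprod(cn)
    for (v in seq_len(V)) {
      rk <- rank(R[v, -v])
      ranksums[v, ] <- ranksums[v, ] + rk
      tiesums[v] <- tiesums[v] + .tie_term(rk)
    }
  }
  W <- vapply(seq_len(V), function(v) {
    .w_from_ranksums(ranksums[v, ], m = nw, n = V - 1, Tsum = tiesums[v])
  }, numeric(1))
  out <- list(stability = W, mask_index = idx, dims = dim(mask),
              n_windows = nw)
  if (fisher_transform) out$stability_z <- fisher_z(W)
  structure(out, class = "stability_map")
}

#' Voxel-wise two-group test with BH-FDR correction
#'
#' Per in-mask voxel, an independent-samples t-test (equal variance;
#' `paired = TRUE` switches to a paired test) with Benjamini-Hochberg
#' correction across voxels and a signed significance mask.
#'
#' @param maps_a,maps_b subjects x V matrices of per-voxel values on the
#'   same lattice (V must agree).
#' @param alpha level on adjusted p-values (default 0.05).
#' @param paired paired test (default FALSE; the default fits distinct
#'   cohorts per condition).
#' @return Data frame per voxel: `t`, `p`, `p_adj`, `mask` (-1, 0, +1 for
#'   significant decrease/none/increase in group A relative to B).
#' @export
voxelwise_group_test <- function(maps_a, maps_b, alpha = 0.05,
                                 paired = FALSE) {
  maps_a <- as.matrix(maps_a); maps_b <- as.matrix(maps_b)
  if (ncol(maps_a) != ncol(maps_b)) stop("non-matching lattices")
  if (nrow(maps_a) < 2 || nrow(maps_b) < 2) {
    stop("need at least 2 subjects per group")
  }
  if (paired && nrow(maps_a) != nrow(maps_b)) {
    stop("paired test needs equal group sizes")
  }
  if (paired) {
    d <- maps_a - maps_b
    n <- nrow(d)
    mu <- colMeans(d)
    se <- apply(d, 2, stats::sd) / sqrt(n)
    tval <- mu / se
    df <- n - 1
  } else {
    na <- nrow(maps_a); nb <- nrow(maps_b)
    mu <- colMeans(maps_a) - colMeans(maps_b)
    sa2 <- apply(maps_a, 2, stats::var)
    sb2 <- apply(maps_b, 2, stats::var)
    sp2 <- ((na - 1) * sa2 + (nb - 1) * sb2) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    tval <- mu / se
    df <- na + nb - 2
  }
  p <- 2 * stats::pt(-abs(tval), df)
  p[se == 0] <- 1
  tval[se == 0] <- 0
  padj <- stats::p.adjust(p, method = "BH")
  mask <- integer(length(p))
  mask[padj < alpha] <- sign(tval[padj < alpha])
  data.frame(t = tval, p = p, p_adj = padj, mask = mask)
}

#' Clean a voxel scan
#'
#' Discard leading frames, censor by framewise displacement (interpolation
#' keeps the temporal grid), then detrend + regress WM/CSF means and the six
#' motion parameters and band-pass every brain voxel.
#'
#' @param scan a `voxel_scan` from the generator.
#' @param config a [cleaning_config()].
#' @return The scan with cleaned `bold` (T reduced by `n_discard`), plus
#'   `fd` and `censored` bookkeeping.
#' @export
clean_voxel_scan <- function(scan, config = cleaning_config()) {
  keep_t <- (config$n_discard + 1):dim(scan$bold)[4]
  bold <- scan$bold[, , , keep_t, drop = FALSE]
  motion <- scan$motion[keep_t, , drop = FALSE]
  dims <- dim(bold)[1:3]
  T <- length(keep_t)
  flatmat <- matrix(bold, prod(dims), T)
  brain <- which(scan$brain_mask)
  wm_mean <- colMeans(flatmat[which(scan$wm_mask), , drop = FALSE])
  csf_mean <- colMeans(flatmat[which(scan$csf_mask), , drop = FALSE])
  fd <- framewise_displacement(motion, config$rotation_radius)
  series <- t(flatmat[brain, , drop = FALSE])
  cens <- censor_frames(series, fd, config$fd_threshold, "interpolate")
  conf <- cbind(wm = wm_mean, csf = csf_mean, motion)
  cleaned <- clean_timeseries(cens$series, conf, config)
  flatmat[brain, ] <- t(cleaned)
  scan$bold <- array(flatmat, dim = c(dims, T))
  scan$motion <- motion
  scan$states <- scan$states[keep_t]
  scan$fd <- fd
  scan$censored <- cens$censored
  scan
}
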