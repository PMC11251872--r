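#' Repair a symmetric matrix to a positive-definite correlation matrix
#'
#' Eigenvalues are floored at `floor_ev` and the result rescaled to unit
#' diagonal.
#'
#' @param m symmetric matrix.
#' @param floor_ev minimum eigenvalue after repair.
#' @return A positive-definite correlation matrix.
#' @export
pd_repair <- function(m, floor_ev = 1e-6) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, floor_ev)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- stats::cov2cor(out)
  (out + t(out)) / 2
}

.state_spec <- function(id, covariance, mean_dwell, weight) {
  stopifnot(mean_dwell >= 1, isSymmetric(covariance))
  structure(list(id = id, covariance = covariance,
                 mean_dwell = mean_dwell, weight = weight),
            class = "state_spec")
}

.known_profiles <- c("awake", "PRO", "ISO", "KET", "DEX", "ISO-DEX")

#' Build the brain-state covariance library for a condition
#'
#' Four canonical windowed-FC regimes are modeled:
#' \describe{
#'   \item{rich}{awake-like, strong coupling in every block (the
#'     cortico-subcortical block averages `awake_cs_mean`);}
#'   \item{cortical}{anesthetic-like, cortico-cortical block identical to the
#'     rich state, subcortical block scaled by `suppression`,
#'     cortico-subcortical block flattened to `suppression` times its rich
#'     mean;}
#'   \item{weak}{globally weak coupling (`weak_factor` scaling);}
#'   \item{complex}{suppressed but structured: cortico-cortical scaled by
#'     `dex_cc_factor`, a sign-alternating cortico-subcortical pattern
#'     distinct from the awake one (dexmedetomidine-like).}
#' }
#' Each condition's library is a weighted subset: the awake profile is
#' dominated by the rich state; volatile/intravenous anesthetic profiles mix
#' the cortical-preserved and weak states; the DEX profile adds the complex
#' state. Anesthetic libraries never contain the rich state, so every one of
#' their states has a strictly lower mean cortico-subcortical |r| than the
#' awake-dominant state.
#'
#' Flattening (rather than scaling) the cortico-subcortical block under
#' anesthesia is deliberate: scaling preserves the Pearson pattern similarity
#' of the block, whereas the suppressed regime is meant to lose its
#' cortico-subcortical structure while the subcortical block keeps its
#' pattern at reduced strength.
#'
#' @param rois a `roi_set` (needs both classes present).
#' @param profile condition name, one of
#'   `r paste0('"', c("awake","PRO","ISO","KET","DEX","ISO-DEX"), '"', collapse = ", ")`.
#' @param awake_cs_mean target mean correlation of the rich state's
#'   cortico-subcortical block (default 0.5).
#' @param suppression scaling of subcortical and (flattened)
#'   cortico-subcortical coupling in anesthetic states (default 0.3).
#' @param dex_cc_factor cortico-cortical scaling in the complex state
#'   (default 0.6).
#' @param weak_factor global scaling of the weak state (default 0.1; the
#'   weak regime is near-zero coupling everywhere).
#' @param mean_dwell expected consecutive volumes per state, TR units
#'   (default 200; regime transitions are rare).
#' @param weights optional mixing-weight override: a named numeric vector
#'   over state ids (`rich`, `cortical`, `weak`, `complex`), or a list of
#'   such vectors keyed by profile name. Overriding lets tests plant
#'   single-state or custom-mixture conditions.
#' @return List of `state_spec` objects; weights sum to 1.
#' @export
build_state_library <- function(rois, profile,
                                awake_cs_mean = 0.5,
                                suppression = 0.3,
                                dex_cc_factor = 0.6,
                                weak_factor = 0.1,
                                mean_dwell = 200,
                                weights = NULL) {
  if (!profile %in% .known_profiles) {
    stop(sprintf("unknown condition profile '%s'", profile))
  }
  n <- rois$n
  sub <- roi_indices(rois, "subcortical")
  ctx <- roi_indices(rois, "cortical")

  # Rich (awake-like) state: a three-factor Gram construction. A global
  # factor couples every region (it alone generates the cortico-subcortical
  # block, scaled so that block averages awake_cs_mean), while a cortical
  # and a subcortical factor add strong within-class coherence on top, as in
  # the awake brain. Deterministic stride patterns make every loading
  # heterogeneous; Gram + positive residual diagonal keeps the matrix PD.
  stride_pat <- function(stride, m, spread = 0.05) {
    1 - spread + 2 * spread * (stride * (seq_len(m) - 1) %% m) / (m - 1)
  }
  within_target <- 0.90   # awake within-class block mean (cc and ss)
  g <- stride_pat(7, n)
  cl <- numeric(n); sl <- numeric(n)
  cl[ctx] <- stride_pat(3, length(ctx))
  sl[sub] <- stride_pat(9, length(sub))
  utb <- upper.tri(diag(length(ctx)))
  # calibrate factor scales so the block means hit their targets after the
  # unit-variance cap (fixed-point iteration; converges in a few passes)
  for (iter in 1:6) {
    g <- g * sqrt(awake_cs_mean / mean(outer(g[sub], g[ctx])))
    cc_extra <- within_target - mean(outer(g[ctx], g[ctx])[utb])
    ss_extra <- within_target - mean(outer(g[sub], g[sub])[utb])
    cl[ctx] <- cl[ctx] * sqrt(cc_extra /
                                mean(outer(cl[ctx], cl[ctx])[utb]))
    sl[sub] <- sl[sub] * sqrt(ss_extra /
                                mean(outer(sl[sub], sl[sub])[utb]))
    shrink <- sqrt(pmin(1, 0.98 / (g^2 + cl^2 + sl^2)))
    g <- g * shrink; cl <- cl * shrink; sl <- sl * shrink
  }
  rich <- outer(g, g) + outer(cl, cl) + outer(sl, sl)
  cs_flat_rich <- mean(rich[sub, ctx])

  blockset <- function(m, rows, cols, value) {
    m[rows, cols] <- value
    m[cols, rows] <- t(m[rows, cols])
    m
  }

  cortical <- rich
  cortical <- blockset(cortical, sub, sub, suppression * rich[sub, sub])
  cortical <- blockset(cortical, sub, ctx, suppression * cs_flat_rich)

  weak <- weak_factor * rich
  weak <- blockset(weak, sub, ctx, weak_factor * cs_flat_rich)

  # Complex state: its own signed rank-one loading pattern (positive
  # definite by construction): reversed global loadings, subcortical signs
  # alternating, cortico-cortical level dex_cc_factor of the rich state.
  # Coupling is suppressed on average (signed cortico-subcortical entries
  # cancel) yet highly structured, unlike the flat suppression of the other
  # states.
  mu <- rev(stride_pat(7, n))
  sgn <- rep(1, n)
  sgn[sub] <- (-1)^seq_along(sub)
  utc <- upper.tri(diag(length(ctx)))
  mu <- mu * sqrt(dex_cc_factor * mean(rich[ctx, ctx][utc]) /
                    mean(outer(mu[ctx], mu[ctx])[utc]))
  complexst <- outer(sgn * mu, sgn * mu)
  # damp every subcortical-involving entry so this regime is "suppressed",
  # keeping all four regimes at comparable mutual separations in edge space
  damp <- matrix(1, n, n)
  damp[sub, ] <- 0.85
  damp[, sub] <- 0.85
  damp[sub, sub] <- 0.85
  complexst <- complexst * damp

  finish <- function(m) {
    diag(m) <- 1
    pd_repair(m)
  }
  states <- list(rich = finish(rich), cortical = finish(cortical),
                 weak = finish(weak), complex = finish(complexst))

  if (is.list(weights)) weights <- weights[[profile]]
  if (is.null(weights)) {
    weights <- switch(profile,
      "awake"   = c(rich = 0.85, cortical = 0.12, weak = 0.03),
      "PRO"     = c(cortical = 0.55, weak = 0.45),
      "ISO"     = c(cortical = 0.65, weak = 0.35),
      "KET"     = c(cortical = 0.50, weak = 0.50),
      "DEX"     = c(complex = 0.50, weak = 0.30, cortical = 0.20),
      "ISO-DEX" = c(cortical = 0.70, weak = 0.30))
  }
  stopifnot(all(names(weights) %in% names(states)), all(weights > 0))
  weights <- weights / sum(weights)

  lapply(names(weights), function(id) {
    .state_spec(id, states[[id]], mean_dwell, unname(weights[id]))
  })
}

#' Generator configuration
#'
#' Defaults state the simulated world: 500 volumes per scan at TR = 1 s (the
#' first 10 discarded in preprocessing), band-limited signal in
#' 0.01--0.10 Hz, group sizes 13/12/13/11/10/11
#' (awake/PRO/ISO/KET/DEX/ISO-DEX), rare regime switches (mean dwell 200 TR),
#' and a 12 x 12 x 6 voxel lattice at 0.5 mm mirrored about the first axis.
#'
#' @param seed integer seed; mandatory (every simulation stream derives from
#'   it).
#' @param groups condition names; each must be a known profile of
#'   [build_state_library()].
#' @param n_subjects_per_group single count or named vector over `groups`.
#' @param T_volumes volumes per scan (default 500).
#' @param n_discard leading volumes the cleaning step will drop (default 10).
#' @param TR repetition time in seconds (default 1).
#' @param band passband in Hz for the simulated hemodynamic signal.
#' @param noise_sd white (broadband) measurement noise on ROI series, signal
#'   units (default 0.005, calibrated so that >90% of spectral amplitude
#'   stays inside the passband; realistic measurement noise is modeled at
#'   the voxel level via `voxel_noise_sd`, and the dominant stochasticity
#'   downstream is finite-window sampling error).
#' @param confound_leak coefficient with which WM and CSF confound series
#'   leak into every ROI series (default 0.1).
#' @param spike_prob per-frame probability of a motion spike (default 0.02).
#' @param spike_amp translation step of a spike in mm (default 0.3, i.e.
#'   framewise displacement well above the 0.15 mm censoring threshold).
#' @param motion_jitter per-frame SD of baseline motion increments in mm
#'   (default 2e-4; baseline FD stays far below threshold).
#' @param lattice_shape voxel-mode grid dims; must be even along
#'   `mirror_axis`.
#' @param mirror_axis dimension index of the mid-sagittal mirror (default 1).
#' @param voxel_size voxel edge in mm (default 0.5).
#' @param voxel_noise_sd independent voxel noise SD relative to unit regional
#'   signal (default 1; homotopic voxel pairs then correlate near 0.5).
#' @param ... overrides passed to [build_state_library()]
#'   (`awake_cs_mean`, `suppression`, `dex_cc_factor`, `weak_factor`,
#'   `mean_dwell`).
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed,
                             groups = .known_profiles,
                             n_subjects_per_group = c(awake = 13, PRO = 12,
                                                      ISO = 13, KET = 11,
                                                      DEX = 10, `ISO-DEX` = 11),
                             T_volumes = 500, n_discard = 10, TR = 1,
                             band = c(0.01, 0.10),
                             noise_sd = 0.005, confound_leak = 0.1,
                             spike_prob = 0.02, spike_amp = 0.3,
                             motion_jitter = 2e-4,
                             lattice_shape = c(12, 12, 6), mirror_axis = 1,
                             voxel_size = 0.5, voxel_noise_sd = 1,
                             ...) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("generator_config: 'seed' is required for reproducibility")
  }
  if (T_volumes <= n_discard + 50) {
    stop("T_volumes must exceed n_discard + 50")
  }
  if (lattice_shape[mirror_axis] %% 2 != 0) {
    stop("lattice_shape must be even along the mirror axis")
  }
  if (spike_prob < 0 || spike_prob > 1) stop("spike_prob must be in [0,1]")
  if (is.null(names(n_subjects_per_group))) {
    n_subjects_per_group <- stats::setNames(
      rep_len(n_subjects_per_group, length(groups)), groups)
  }
  n_subjects_per_group <- n_subjects_per_group[groups]
  if (anyNA(n_subjects_per_group)) stop("n_subjects_per_group must cover all groups")
  structure(list(seed = as.integer(seed), groups = groups,
                 n_subjects_per_group = n_subjects_per_group,
                 T_volumes = T_volumes, n_discard = n_discard, TR = TR,
                 band = band, noise_sd = noise_sd,
                 confound_leak = confound_leak,
                 spike_prob = spike_prob, spike_amp = spike_amp,
                 motion_jitter = motion_jitter,
                 lattice_shape = lattice_shape, mirror_axis = mirror_axis,
                 voxel_size = voxel_size, voxel_noise_sd = voxel_noise_sd,
                 state_args = list(...)),
            class = "generator_config")
}

# Combine the master seed with stream labels into a reproducible sub-seed
# (kept below 2^31).
.substream <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 1009 + as.numeric(p)) %% 2147483629
  as.integer(h)
}

# First-order Markov state sequence with stationary weights w and per-state
# mean dwell d. Each visit has a refractory minimum of d/8 frames followed
# by geometric departures calibrated so the expected dwell equals d exactly;
# the floor prevents implausibly brief state flickers (which would also
# bleed broadband energy into the colored signal).
.markov_states <- function(T, weights, dwell) {
  k <- length(weights)
  if (k == 1) return(rep(1L, T))
  min_dwell <- pmax(1, floor(dwell / 8))
  p_leave <- 1 / (dwell - min_dwell + 1)
  s <- integer(T)
  s[1] <- sample.int(k, 1, prob = weights)
  age <- 1L
  for (t in 2:T) {
    i <- s[t - 1]
    if (age >= min_dwell[i] && stats::runif(1) < p_leave[i]) {
      pj <- weights[-i] / sum(weights[-i])
      s[t] <- which(seq_len(k) != i)[sample.int(k - 1, 1, prob = pj)]
      age <- 1L
    } else {
      s[t] <- i
      age <- age + 1L
    }
  }
  s
}

# Band-limited unit-variance innovation columns: white noise, hard
# frequency-domain mask, rescale to SD 1. Filtering precedes covariance
# coloring so the target cross-correlation is preserved.
.band_innovations <- function(T, n, band, TR) {
  e <- matrix(stats::rnorm(T * n), T, n)
  e <- bandpass_fft(e, TR = TR, band = band)
  sds <- sqrt(colMeans(e^2))
  sweep(e, 2, pmax(sds, 1e-12), "/")
}

# One subject's regime-switching ROI signal; returns T x n matrix + labels.
.simulate_subject_signal <- function(config, library, rois) {
  T <- config$T_volumes
  n <- rois$n
  weights <- vapply(library, `[[`, numeric(1), "weight")
  dwell <- vapply(library, `[[`, numeric(1), "mean_dwell")
  states <- .markov_states(T, weights, dwell)
  innov <- .band_innovations(T, n, config$band, config$TR)
  chols <- lapply(library, function(s) chol(s$covariance))
  # Crossfade the state colorings over a short triangular ramp: regime
  # changes are not instantaneous, and a hard switch would inject broadband
  # energy that breaks the band-limitation of the emitted series. The label
  # sequence stays the crisp Markov chain.
  k <- length(library)
  w <- matrix(0, T, k)
  w[cbind(seq_len(T), states)] <- 1
  if (k > 1 && length(unique(states)) > 1) {
    ramp <- 11L
    pad <- ramp %/% 2
    kern <- (pad + 1) - abs(seq_len(ramp) - (pad + 1))
    kern <- kern / sum(kern)
    wp <- rbind(w[rep(1, pad), , drop = FALSE], w,
                w[rep(T, pad), , drop = FALSE])
    w <- apply(wp, 2, function(col) {
      as.numeric(stats::filter(col, kern, sides = 2))
    })[(pad + 1):(pad + T), , drop = FALSE]
    w <- w / rowSums(w)   # partition of unity, exact after padding
  }
  x <- matrix(0, T, n)
  switching <- k > 1 && length(unique(states)) > 1
  for (s in seq_len(k)) {
    active <- w[, s] > 0
    if (!any(active)) next
    xs <- innov %*% chols[[s]]
    x <- x + w[, s] * xs
  }
  if (switching) {
    # the crossfade's amplitude modulation leaks a little energy past the
    # band edges; re-masking enforces the stated spectral support (shared
    # linear filter: within-regime correlation structure is preserved)
    x <- bandpass_fft(x, TR = config$TR, band = config$band)
  }
  wm <- drop(.band_innovations(T, 1, config$band, config$TR))
  csf <- drop(.band_innovations(T, 1, config$band, config$TR))
  x <- x + config$confound_leak * (wm + csf)
  if (config$noise_sd > 0) {
    x <- x + config$noise_sd * matrix(stats::rnorm(T * n), T, n)
  }
  colnames(x) <- rois$names
  list(series = x, states = states,
       state_ids = vapply(library, `[[`, character(1), "id"),
       wm = wm, csf = csf)
}

# Six-column motion table (mm, mm, mm, rad, rad, rad) with step spikes.
.simulate_motion <- function(config) {
  T <- config$T_volumes
  j <- config$motion_jitter
  inc <- cbind(matrix(stats::rnorm(T * 3, sd = j), T, 3),
               matrix(stats::rnorm(T * 3, sd = j / 10), T, 3))
  inc[1, ] <- 0
  spikes <- which(stats::runif(T) < config$spike_prob)
  spikes <- setdiff(spikes, 1L)
  for (f in spikes) {
    axis <- sample.int(3, 1)
    inc[f, axis] <- inc[f, axis] + sample(c(-1, 1), 1) * config$spike_amp
  }
  motion <- apply(inc, 2, cumsum)
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  list(motion = motion, spike_frames = spikes)
}

#' Simulate region-level BOLD for every group
#'
#' Each subject's signal is a first-order Markov mixture of the condition's
#' state library: band-limited Gaussian innovations colored by the Cholesky
#' factor of the active state's covariance, plus WM/CSF confound leakage and
#' white measurement noise. Identical configuration (including seed) gives
#' bit-identical output.
#'
#' @param config a [generator_config()].
#' @param rois a `roi_set` (default [default_roi_set()]).
#' @return A `roi_sim` object: list with `subjects` (each having `id`,
#'   `group`, `series` (T x N), `states`, `state_ids`, `motion`,
#'   `spike_frames`, `wm`, `csf`), `design` data frame, `libraries`, and the
#'   `config`.
#' @export
simulate_roi_timeseries <- function(config, rois = default_roi_set()) {
  stopifnot(inherits(config, "generator_config"))
  libraries <- lapply(config$groups, function(g) {
    do.call(build_state_library, c(list(rois = rois, profile = g),
                                   config$state_args))
  })
  names(libraries) <- config$groups
  subjects <- list()
  for (gi in seq_along(config$groups)) {
    g <- config$groups[gi]
    ns <- config$n_subjects_per_group[[g]]
    if (ns < 2) warning(sprintf("group '%s' has fewer than 2 subjects", g))
    for (si in seq_len(ns)) {
      set.seed(.substream(config$seed, 1L, gi, si))
      sig <- .simulate_subject_signal(config, libraries[[g]], rois)
      mot <- .simulate_motion(config)
      subjects[[length(subjects) + 1]] <- c(
        list(id = sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", g), si),
             group = g),
        sig, mot)
    }
  }
  design <- data.frame(
    subject_id = vapply(subjects, `[[`, character(1), "id"),
    group = vapply(subjects, `[[`, character(1), "group"),
    stringsAsFactors = FALSE)
  structure(list(subjects = subjects, design = design,
                 libraries = libraries, rois = rois, config = config),
            class = "roi_sim")
}

# Mirror-symmetric lattice layout: labels 1..n for ROI parcels, plus WM, CSF
# and background compartments. Left half filled in raster order, then
# reflected.
.build_lattice <- function(config, rois) {
  dims <- config$lattice_shape
  ax <- config$mirror_axis
  half <- dims
  half[ax] <- dims[ax] / 2
  n_half <- prod(half)
  per_roi <- (n_half * 5) %/% (6 * rois$n)   # ~5/6 of the half-lattice is GM
  n_gm <- per_roi * rois$n
  rest <- n_half - n_gm
  n_wm <- ceiling(rest * 2 / 3)
  n_csf <- floor(rest / 4)
  lab_half <- integer(n_half)
  lab_half[seq_len(n_gm)] <- rep(seq_len(rois$n), each = per_roi)
  lab_half[n_gm + seq_len(n_wm)] <- -1L          # WM
  lab_half[n_gm + n_wm + seq_len(n_csf)] <- -2L  # CSF
  labels <- array(0L, dims)
  coords <- as.matrix(expand.grid(lapply(half, seq_len)))
  mirror <- coords
  mirror[, ax] <- dims[ax] + 1 - coords[, ax]
  labels[coords] <- lab_half
  labels[mirror] <- lab_half
  labels
}

#' Simulate a voxel-level scan for one subject
#'
#' Builds a left/right mirror-symmetric lattice in which every gray-matter
#' voxel carries its region's ROI signal plus independent voxel noise,
#' WM and CSF compartments carry their confound series, and the motion table
#' contains step spikes whose framewise displacement exceeds the censoring
#' threshold at known frames.
#'
#' @param config a [generator_config()].
#' @param rois a `roi_set`.
#' @param condition which group to simulate (default first configured group).
#' @param subject subject index within the group (default 1); the voxel scan
#'   of subject s reuses the ROI-level stream of that subject, so ROI and
#'   voxel analyses see the same underlying signal.
#' @return A `voxel_scan`: list with `bold` (4-D array x,y,z,t), `labels`
#'   (3-D int; 1..N regions, -1 WM, -2 CSF, 0 background), logical masks
#'   `gm_mask`, `wm_mask`, `csf_mask`, `brain_mask`, `motion` (T x 6),
#'   `spike_frames`, ROI ground truth (`states`, `roi_series`), `voxel_size`,
#'   `mirror_axis`, `rois`.
#' @export
simulate_voxel_scan <- function(config, rois = default_roi_set(),
                                condition = config$groups[1], subject = 1L) {
  stopifnot(inherits(config, "generator_config"))
  gi <- match(condition, config$groups)
  if (is.na(gi)) stop(sprintf("unknown condition '%s'", condition))
  library <- do.call(build_state_library,
                     c(list(rois = rois, profile = condition),
                       config$state_args))
  set.seed(.substream(config$seed, 1L, gi, subject))
  sig <- .simulate_subject_signal(config, library, rois)
  mot <- .simulate_motion(config)

  labels <- .build_lattice(config, rois)
  .check_lattice_symmetry(labels, config$mirror_axis)
  dims <- dim(labels)
  T <- config$T_volumes
  nvox <- prod(dims)
  flat <- as.vector(labels)
  bold <- matrix(0, nvox, T)
  vn <- config$voxel_noise_sd
  for (r in seq_len(rois$n)) {
    vox <- which(flat == r)
    base <- matrix(sig$series[, r], length(vox), T, byrow = TRUE)
    bold[vox, ] <- base
  }
  bold[flat == -1L, ] <- matrix(sig$wm, sum(flat == -1L), T, byrow = TRUE)
  bold[flat == -2L, ] <- matrix(sig$csf, sum(flat == -2L), T, byrow = TRUE)
  if (vn > 0) bold <- bold + vn * matrix(stats::rnorm(nvox * T), nvox, T)
  bold4d <- array(bold, dim = c(dims, T))
  structure(list(bold = bold4d, labels = labels,
                 gm_mask = labels > 0L, wm_mask = labels == -1L,
                 csf_mask = labels == -2L, brain_mask = labels != 0L,
                 motion = mot$motion, spike_frames = mot$spike_frames,
                 states = sig$states, state_ids = sig$state_ids,
                 roi_series = sig$series, wm = sig$wm, csf = sig$csf,
                 voxel_size = config$voxel_size,
                 mirror_axis = config$mirror_axis,
                 condition = condition, subject = subject, rois = rois,
                 TR = config$TR),
            class = "voxel_scan")
}

.check_lattice_symmetry <- function(labels, axis) {
  idx <- lapply(dim(labels), seq_len)
  idx[[axis]] <- rev(idx[[axis]])
  mirrored <- do.call(`[`, c(list(labels), idx))
  bad <- which(mirrored != labels, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("ROI layout not mirror-symmetric at %d voxel(s), e.g. (%s)",
                 nrow(bad), paste(bad[1, ], collapse = ",")))
  }
  invisible(TRUE)
}

#' Mirror-voxel index map across the symmetry axis
#'
#' @param dims lattice dims.
#' @param axis mirror axis.
#' @return Integer vector: for each voxel (column-major order), the flat
#'   index of its homotopic partner.
#' @export
mirror_index <- function(dims, axis) {
  coords <- as.matrix(expand.grid(lapply(dims, seq_len)))
  m <- coords
  m[, axis] <- dims[axis] + 1 - coords[, axis]
  as.integer(m[, 1] + (m[, 2] - 1) * dims[1] +
               (m[, 3] - 1) * dims[1] * dims[2])
}

#' @export
print.voxel_scan <- function(x, ...) {
  d <- dim(x$bold)
  cat(sprintf("<voxel_scan> %s lattice, %d volumes, condition %s (%d GM voxels)\n",
              paste(d[1:3], collapse = "x"), d[4], x$condition,
              sum(x$gm_mask)))
  invisible(x)
}

#' Majority-vote ground-truth state label per sliding window
#'
#' @param states per-volume state labels (after discarding leading frames if
#'   the windows are on the discarded grid).
#' @param windows window index matrix from [sliding_windows()].
#' @return Integer label per window.
#' @export
window_true_labels <- function(states, windows) {
  apply(windows, 1, function(w) {
    tab <- tabulate(states[w[1]:w[2]])
    which.max(tab)
  })
}
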