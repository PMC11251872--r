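# Toy scan: every voxel is a deterministic mixture of two sinusoids with an
# integer number of cycles per window, so windowed FC is exactly constant
# across windows.
toy_scan <- function(dims = c(4, 4, 2), T = 100, mix = NULL, seed = 1) {
  set.seed(seed)
  nv <- prod(dims)
  t <- seq_len(T)
  s1 <- sin(2 * pi * 2 * t / 50)
  s2 <- sin(2 * pi * 4 * t / 50)
  if (is.null(mix)) mix <- cbind(a = runif(nv, 0.5, 2), b = runif(nv, -1, 1))
  flat <- mix[, 1] %o% s1 + mix[, 2] %o% s2
  labels <- array(rep(c(1L, 2L), each = nv / 2), dims)
  structure(list(bold = array(flat, dim = c(dims, T)),
                 labels = labels,
                 gm_mask = array(TRUE, dims),
                 wm_mask = array(FALSE, dims),
                 csf_mask = array(FALSE, dims),
                 brain_mask = array(TRUE, dims),
                 motion = matrix(0, T, 6),
                 spike_frames = integer(0),
                 voxel_size = 0.5, mirror_axis = 1,
                 condition = "toy", subject = 1L, TR = 1,
                 rois = default_roi_set()),
            class = "voxel_scan")
}

test_that("Kendall's W hits its anchors and matches the definition", {
  # identical rankings
  base <- matrix(rep(c(3, 1, 4, 1.5, 9), 4), 4, 5, byrow = TRUE)
  expect_equal(kendalls_w(base), 1)
  # two exactly reversed rankings
  rev2 <- rbind(1:6, 6:1)
  expect_equal(kendalls_w(rev2), 0)

  set.seed(40)
  for (rep in 1:150) {
    m <- sample(2:8, 1); n <- sample(3:12, 1)
    scores <- matrix(rnorm(m * n), m, n)
    if (rep %% 2 == 0) scores <- round(scores)   # force ties
    w <- kendalls_w(scores)
    expect_equal(w, kendalls_w_definition(scores), tolerance = 1e-12)
    expect_true(w >= 0 && w <= 1 + 1e-12)
    # rater-order invariance
    expect_equal(kendalls_w(scores[sample(m), ]), w, tolerance = 1e-12)
    # monotone per-rater transform invariance
    tr <- scores
    tr[1, ] <- exp(tr[1, ])
    tr[m, ] <- 3 * tr[m, ] - 2
    expect_equal(kendalls_w(tr), w, tolerance = 1e-12)
  }

  const <- rbind(rep(1, 5), rnorm(5))
  expect_true(is.na(kendalls_w(const, tie_correction = FALSE)))
  expect_true(is.na(kendalls_w(rbind(rep(1, 5), rep(2, 5)))))
  expect_error(kendalls_w(matrix(1:5, 1)), "2 raters")
})

test_that("fALFF matches a direct spectral ratio and scales correctly", {
  T <- 100
  x <- sin(2 * pi * 0.05 * seq_len(T))
  got <- falff(x, TR = 1)
  amp <- Mod(stats::fft(x))[2:(T / 2 + 1)]
  freq <- seq_len(T / 2) / T
  oracle <- sum(amp[freq >= 0.01 & freq <= 0.10]) / sum(amp)
  expect_equal(got, oracle, tolerance = 1e-10)
  expect_gt(got, 0.9)
  expect_equal(falff(42 * x), got, tolerance = 1e-12)  # amplitude invariance
  xo <- sin(2 * pi * 0.2 * seq_len(T))
  expect_lt(falff(xo), 0.1)
})

test_that("windowed indices are exact on a degenerate uniform scan", {
  dims <- c(4, 4, 2)
  T <- 50
  scan <- toy_scan(dims, T, mix = cbind(rep(1, prod(dims)), rep(0.2, prod(dims))))
  wvm <- suppressWarnings(windowed_indices(scan, width = 50, step = 5, fwhm = 0))
  expect_length(wvm$maps, 5)
  expect_equal(nrow(wvm$maps$ReHo), 1)
  v <- prod(dims)
  # identical series everywhere: perfect homogeneity, homotopy, coupling
  expect_equal(unname(wvm$maps$ReHo[1, ]), rep(1, v))
  expect_equal(unname(wvm$maps$VMHC[1, ]), rep(fisher_z(1), v))
  expect_equal(unname(wvm$maps$GScorr[1, ]), rep(fisher_z(1), v))
  expect_equal(unname(wvm$maps$DC[1, ]), rep(v - 1, v))
  expect_true(all(wvm$maps$fALFF[1, ] > 0.9))
})

test_that("VMHC is symmetric under mirroring", {
  rois <- tiny_rois()
  cfg <- generator_config(seed = 41, groups = "awake",
                          n_subjects_per_group = 1, T_volumes = 70)
  scan <- simulate_voxel_scan(cfg, rois)
  wvm <- suppressWarnings(windowed_indices(scan, 50, 20, fwhm = 0))
  mir <- mirror_index(dim(scan$labels), scan$mirror_axis)
  pos <- match(mir[wvm$gm_index], wvm$gm_index)
  expect_equal(wvm$maps$VMHC[1, ], wvm$maps$VMHC[1, pos])
})

test_that("concordance is 1 for monotone-equivalent indices, null otherwise", {
  set.seed(42)
  nw <- 30; V <- 120
  M <- matrix(rnorm(nw * V), nw, V)
  wvm <- structure(list(
    maps = list(fALFF = M, ReHo = exp(M), VMHC = M^3 + M,
                DC = atan(M), GScorr = 2 * M - 5),
    gm_index = seq_len(V), windows = sliding_windows(nw, 1, 1),
    dims = c(V, 1, 1)), class = "windowed_voxel_maps")
  conc <- concordance_maps(wvm)
  expect_equal(conc$voxelwise, rep(1, V))
  expect_equal(conc$volumewise, 1)
  expect_equal(conc$voxelwise_z, rep(fisher_z(1), V))

  # independent indices: mean voxel-wise W matches a permutation-null oracle
  maps0 <- replicate(5, matrix(rnorm(nw * V), nw, V), simplify = FALSE)
  names(maps0) <- names(wvm$maps)
  wvm0 <- wvm; wvm0$maps <- maps0
  got <- mean(concordance_maps(wvm0)$voxelwise)
  perm <- lapply(maps0, function(m) m[sample(nw), ])
  wvmp <- wvm; wvmp$maps <- perm
  null_mean <- mean(concordance_maps(wvmp)$voxelwise)
  expect_lt(abs(got - null_mean), 0.02)
})

test_that("stability is exact for frozen FC architecture, lower when switching", {
  scan <- toy_scan(T = 100)
  st <- stability_map(scan, width = 50, step = 10)
  expect_equal(st$stability, rep(1, prod(dim(scan$labels))))

  # switching between regimes destabilizes the FC profile
  rois <- tiny_rois()
  lower <- logical(0)
  for (sd in 1:3) {
    cfg_sw <- generator_config(seed = sd, groups = "ISO",
                               n_subjects_per_group = 1, T_volumes = 210,
                               mean_dwell = 40,
                               weights = c(cortical = 0.5, weak = 0.5))
    cfg_st <- generator_config(seed = sd, groups = "ISO",
                               n_subjects_per_group = 1, T_volumes = 210,
                               weights = c(cortical = 1))
    s_sw <- stability_map(simulate_voxel_scan(cfg_sw, rois), 50, 10)
    s_st <- stability_map(simulate_voxel_scan(cfg_st, rois), 50, 10)
    lower <- c(lower, mean(s_sw$stability) < mean(s_st$stability))
  }
  expect_true(all(lower))
})

test_that("voxel-wise group test controls errors and finds planted effects", {
  set.seed(43)
  V <- 400; n <- 10
  a0 <- matrix(rnorm(n * V), n, V)
  expect_false(any(voxelwise_group_test(a0, a0 + 0 * a0)$mask != 0))

  # planted d = 1.5 decrease in most of group B's map (e.g. the subcortical
  # compartment); sensitivity averaged over replicates
  affected <- 1:300
  sens <- fp <- numeric(5)
  for (r in 1:5) {
    a <- matrix(rnorm(n * V), n, V)
    b <- matrix(rnorm(n * V), n, V)
    b[, affected] <- b[, affected] - 1.5
    res <- voxelwise_group_test(a, b)
    sens[r] <- mean(res$mask[affected] == 1)     # A > B detected
    fp[r] <- mean(res$mask[-affected] != 0)
    expect_identical(res$p_adj < 0.05, bh_brute_force(res$p, 0.05))
  }
  expect_gt(mean(sens), 0.8)
  expect_lt(mean(fp), 0.05)

  b1 <- matrix(rnorm(n * V), n, V)
  expect_error(voxelwise_group_test(a0, b1[, 1:10]), "lattice")
  pr <- voxelwise_group_test(a0, b1, paired = TRUE)
  expect_true(all(pr$p >= 0 & pr$p <= 1))
})
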