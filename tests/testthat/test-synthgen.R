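test_that("state libraries satisfy their structural contracts", {
  rois <- tiny_rois()
  sub <- roi_indices(rois, "subcortical")
  ctx <- roi_indices(rois, "cortical")

  expect_error(build_state_library(rois, "halothane"), "unknown condition")

  aw <- build_state_library(rois, "awake")
  expect_true(all(vapply(aw, function(s) s$id, character(1)) %in%
                    c("rich", "cortical", "weak", "complex")))
  expect_equal(sum(vapply(aw, `[[`, numeric(1), "weight")), 1)

  rich <- aw[[1]]$covariance
  # dominant awake state hits the configured cortico-subcortical mean
  expect_lt(abs(mean(rich[sub, ctx]) - 0.5), 0.02)

  for (profile in c("awake", "ISO", "DEX")) {
    for (s in build_state_library(rois, profile)) {
      ev <- eigen(s$covariance, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), 0)                       # PD repair contract
      expect_equal(unname(diag(s$covariance)), rep(1, rois$n))
    }
  }

  # every anesthetic-library state is strictly weaker cortico-subcortically
  awake_cs <- mean(abs(rich[sub, ctx]))
  for (s in build_state_library(rois, "ISO")) {
    expect_lt(mean(abs(s$covariance[sub, ctx])), awake_cs)
  }

  # cortical-preserved state shares the awake cortico-cortical block
  cort <- aw[[which(vapply(aw, `[[`, character(1), "id") == "cortical")]]
  expect_lt(max(abs(cort$covariance[ctx, ctx] - rich[ctx, ctx])), 0.02)

  # weight override: single-state library
  lib1 <- build_state_library(rois, "ISO", weights = c(weak = 1))
  expect_length(lib1, 1)
  expect_identical(lib1[[1]]$id, "weak")
})

test_that("generator config validates its invariants", {
  expect_error(generator_config(), "seed")
  expect_error(generator_config(seed = 1, T_volumes = 55), "T_volumes")
  expect_error(generator_config(seed = 1, lattice_shape = c(11, 12, 6)),
               "even")
  expect_error(generator_config(seed = 1, spike_prob = 1.5), "spike_prob")
})

test_that("identical config reproduces ROI simulations bit-identically", {
  cfg <- generator_config(seed = 7, groups = "ISO",
                          n_subjects_per_group = 2, T_volumes = 150)
  a <- quiet_sim(cfg)
  b <- quiet_sim(cfg)
  expect_identical(a$subjects[[1]]$series, b$subjects[[1]]$series)
  expect_identical(a$subjects[[2]]$states, b$subjects[[2]]$states)
  expect_identical(a$subjects[[1]]$motion, b$subjects[[1]]$motion)
})

test_that("noise-free single-state data recover the planted covariance", {
  rois <- tiny_rois()
  cfg <- generator_config(seed = 5, groups = "awake", n_subjects_per_group = 1,
                          T_volumes = 10000, noise_sd = 0, confound_leak = 0,
                          weights = c(rich = 1))
  s <- quiet_sim(cfg, rois)$subjects[[1]]
  expect_identical(unique(s$states), 1L)
  truth <- build_state_library(rois, "awake", weights = c(rich = 1))[[1]]$covariance
  expect_lt(max(abs(stats::cor(s$series) - truth)), 0.05)
  expect_equal(nrow(s$series), 10000)
})

test_that("Markov switching matches the requested dwell time", {
  cfg <- generator_config(seed = 9, groups = "ISO", n_subjects_per_group = 1,
                          T_volumes = 10000, mean_dwell = 100)
  st <- quiet_sim(cfg)$subjects[[1]]$states
  runs <- rle(st)$lengths
  expect_gt(length(runs), 10)
  expect_lt(abs(mean(runs) - 100) / 100, 0.2)
})

test_that("default configurations emit band-limited series", {
  rois <- tiny_rois()
  for (g in c("awake", "DEX")) {
    cfg <- generator_config(seed = 3, groups = g, n_subjects_per_group = 3)
    fracs <- vapply(quiet_sim(cfg, rois)$subjects, function(s) {
      x <- s$series
      T <- nrow(x)
      amp <- Mod(stats::mvfft(x))
      pos <- 2:(floor(T / 2) + 1)
      freq <- (pos - 1) / T
      inband <- freq >= 0.01 & freq <= 0.10
      mean(colSums(amp[pos, ][inband, ]) / colSums(amp[pos, ]))
    }, numeric(1))
    expect_true(all(fracs > 0.9))
  }
})

test_that("voxel scans tie voxels to regional signals and plant motion truth", {
  rois <- tiny_rois()
  # noise-free: every voxel correlates 1 with its region's series
  cfg0 <- generator_config(seed = 11, groups = "awake",
                           n_subjects_per_group = 1, T_volumes = 120,
                           voxel_noise_sd = 0, spike_prob = 0)
  scan0 <- simulate_voxel_scan(cfg0, rois)
  expect_length(scan0$spike_frames, 0)     # no spikes planted
  flat <- matrix(scan0$bold, prod(dim(scan0$labels)), 120)
  for (r in c(1L, 15L)) {
    vox <- which(scan0$labels == r)[1]
    expect_equal(stats::cor(flat[vox, ], scan0$roi_series[, r]), 1)
  }
  # homotopic pairs share the regional signal: with voxel noise sd equal to
  # the (unit) signal sd the expected correlation is ~ 1/(1+1) = 0.5
  cfg1 <- generator_config(seed = 12, groups = "awake",
                           n_subjects_per_group = 1, voxel_noise_sd = 1)
  scan1 <- simulate_voxel_scan(cfg1, rois)
  dims <- dim(scan1$labels)
  mir <- mirror_index(dims, scan1$mirror_axis)
  flat1 <- matrix(scan1$bold, prod(dims), dim(scan1$bold)[4])
  gm <- which(scan1$gm_mask)
  rs <- vapply(gm[seq(1, length(gm), by = 37)], function(v) {
    stats::cor(flat1[v, ], flat1[mir[v], ])
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.5), 0.1)
  # label lattice is mirror-symmetric
  idx <- lapply(dims, seq_len)
  idx[[scan1$mirror_axis]] <- rev(idx[[scan1$mirror_axis]])
  expect_identical(do.call(`[`, c(list(scan1$labels), idx)), scan1$labels)
  # mirror involution
  expect_identical(mir[mir], seq_len(prod(dims)))
})

test_that("window-majority ground-truth labels follow the state sequence", {
  states <- rep(c(1L, 2L), each = 50)
  w <- sliding_windows(100, 20, 20)
  # the straddling middle window is a 10/10 tie, resolved to the lower label
  expect_identical(window_true_labels(states, w), c(1L, 1L, 1L, 2L, 2L))
})
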