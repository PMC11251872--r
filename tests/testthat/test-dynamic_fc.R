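test_that("sliding-window arithmetic is exact", {
  expect_equal(nrow(sliding_windows(490, 50, 5)), 89)
  expect_equal(nrow(sliding_windows(50, 50, 5)), 1)
  expect_equal(nrow(sliding_windows(100, 50, 10)), 6)
  w <- sliding_windows(100, 50, 10)
  expect_equal(w[, "start"], seq(1, 51, 10))
  expect_true(all(w[, "end"] <= 100))
  expect_true(all(w[, "end"] - w[, "start"] + 1 == 50))
  expect_error(sliding_windows(40, 50, 5), "shorter")
  expect_error(sliding_windows(100, 50, 0), "step")
})

test_that("windowed FC reduces to static FC and flags degenerate windows", {
  set.seed(20)
  x <- matrix(rnorm(120 * 5), 120, 5)
  w <- windowed_fc(x, width = 120, step = 120)
  expect_length(w$windows, 1)
  expect_equal(w$windows[[1]], fc_matrix(x))

  xc <- x; xc[1:50, 2] <- 1   # constant inside the first window only
  expect_warning(wc <- windowed_fc(xc, width = 50, step = 70),
                 "constant column")
  expect_true(all(wc$windows[[1]][2, -2] == 0))
})

test_that("windows of stationary data fluctuate around the static matrix", {
  rois <- tiny_rois()
  cfg <- generator_config(seed = 22, groups = "awake",
                          n_subjects_per_group = 1, T_volumes = 2000,
                          weights = c(rich = 1))
  s <- quiet_sim(cfg, rois)$subjects[[1]]
  wfc <- windowed_fc(s$series)
  mean_win <- apply(simplify2array(wfc$windows), c(1, 2), mean)
  stat <- fc_matrix(s$series)
  off <- upper.tri(stat)
  expect_lt(mean(abs(mean_win[off] - stat[off])), 0.06)
})

test_that("clustering recovers planted two-state structure deterministically", {
  rois <- tiny_rois()
  cfg <- generator_config(seed = 23, groups = c("awake", "ISO"),
                          n_subjects_per_group = 2,
                          weights = list(awake = c(rich = 1),
                                         ISO = c(weak = 1)))
  sim <- quiet_sim(cfg, rois)
  wfc <- lapply(sim$subjects, function(s)
    windowed_fc(clean_roi_subject(s)$series))
  names(wfc) <- sim$design$subject_id

  m <- cluster_states(wfc, sim$design, k_fixed = 2, seed = 1, n_init = 10,
                      rois = rois)
  truth <- rep(match(sim$design$group, c("awake", "ISO")), each = 89)
  expect_equal(adjusted_rand_index(m$labels, truth), 1)

  m2 <- cluster_states(wfc, sim$design, k_fixed = 2, seed = 1, n_init = 10,
                       rois = rois)
  expect_identical(m$labels, m2$labels)          # determinism given seed
  expect_identical(m$centroids, m2$centroids)

  # centroids reshape back to symmetric matrices over the ROI set
  expect_equal(dim(m$centroid_matrices[[1]]), c(20, 20))
  expect_equal(m$centroid_matrices[[1]], t(m$centroid_matrices[[1]]))

  # model bookkeeping invariants
  expect_equal(unname(rowSums(m$frequencies)), rep(1, 4))
  for (tm in m$transition$per_subject) {
    defined <- !is.na(tm[, 1])
    if (any(defined)) {
      expect_equal(unname(rowSums(tm[defined, , drop = FALSE])),
                   rep(1, sum(defined)), tolerance = 1e-12)
    }
  }
})

test_that("davies_bouldin prefers the true number of separated blobs", {
  set.seed(24)
  x <- rbind(matrix(rnorm(200, 0), 100, 2),
             matrix(rnorm(200, 8), 100, 2),
             matrix(rnorm(200, c(0, 16)), 100, 2))
  truth <- rep(1:3, each = 100)
  dbis <- vapply(2:5, function(k) {
    set.seed(k)
    km <- stats::kmeans(x, k, nstart = 10)
    davies_bouldin(x, km$cluster, km$centers)
  }, numeric(1))
  expect_equal((2:5)[which.min(dbis)], 3)
  expect_true(is.na(davies_bouldin(x, rep(1, 300), matrix(0, 1, 2))))
})

test_that("frequencies and transitions count hand-checkable sequences", {
  m <- fake_model(labels = c(1L, 1L, 2L, 2L), subject = rep("s1", 4), k = 2)
  expect_equal(unname(m$frequencies["s1", ]), c(0.5, 0.5))
  tm <- m$transition$per_subject$s1
  expect_equal(tm[1, ], c(0.5, 0.5))
  expect_equal(tm[2, ], c(0, 1))

  cm <- fake_model(labels = rep(2L, 6), subject = rep("s1", 6), k = 2)
  expect_equal(unname(cm$frequencies["s1", ]), c(0, 1))
  tmc <- cm$transition$per_subject$s1
  expect_true(all(is.na(tmc[1, ])))              # no departures observed
  expect_equal(tmc[2, ], c(0, 1))

  # transitions never counted across subject boundaries
  two <- fake_model(labels = c(1L, 1L, 2L, 2L),
                    subject = c("a", "a", "b", "b"), k = 2)
  expect_equal(two$transition$counts[1, 2], 0)
})

test_that("defined transition rows sum to one on random sequences", {
  set.seed(25)
  for (rep in 1:20) {
    labs <- sample.int(4, 60, replace = TRUE)
    m <- fake_model(labs, rep(c("a", "b", "c"), each = 20), 4)
    for (tm in m$transition$per_subject) {
      defined <- !is.na(tm[, 1])
      expect_equal(unname(rowSums(tm[defined, , drop = FALSE])),
                   rep(1, sum(defined)), tolerance = 1e-12)
    }
    expect_equal(unname(rowSums(m$frequencies)), rep(1, 3))
  }
})

test_that("state ANOVA stays at chance under the null", {
  set.seed(26)
  groups <- rep(c("awake", "PRO", "ISO", "KET", "DEX", "ISO-DEX"), each = 2)
  nsig <- replicate(100, {
    labels <- unlist(lapply(seq_along(groups), function(i) {
      sample.int(4, 89, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
    }))
    m <- fake_model(labels, rep(sprintf("s%02d", seq_along(groups)), each = 89), 4)
    design <- data.frame(subject_id = sprintf("s%02d", seq_along(groups)),
                         group = groups)
    st <- state_statistics(m, design)
    sum(st$anova$significant)
  })
  expect_lte(mean(nsig), 1)   # <= 1 of k = 4 states significant on average
  # diagnostics come back in the expected shape
  st4 <- state_statistics(
    fake_model(sample.int(3, 4 * 89, TRUE),
               rep(c("w", "x", "y", "z"), each = 89), 3),
    data.frame(subject_id = c("w", "x", "y", "z"),
               group = c("awake", "awake", "ISO", "ISO")))
  expect_true(all(c("state", "F", "p") %in% colnames(st4$anova)))
  expect_true(all(c("state", "bartlett_p") %in% colnames(st4$diagnostics)))
})

test_that("adjusted Rand index behaves at its anchors", {
  expect_equal(adjusted_rand_index(1:4, c(2L, 1L, 4L, 3L)), 1)  # relabeling
  expect_equal(adjusted_rand_index(rep(1, 6), rep(1, 6)), 1)
  a <- rep(1:2, each = 50)
  set.seed(27)
  expect_lt(abs(adjusted_rand_index(a, sample(a))), 0.15)       # ~ chance
})
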