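#' Sliding-window index pairs
#'
#' Windows of `width` TRs advanced by `step`, covering a T-length series:
#' count = floor((T - width)/step) + 1. Returned as 1-based inclusive
#' [start, end] rows; the last window ends at or before T.
#'
#' @param T number of timepoints.
#' @param width window width in TR units (default 50).
#' @param step step length in TR units (default 5).
#' @return Integer matrix with columns `start`, `end`.
#' @export
sliding_windows <- function(T, width = 50, step = 5) {
  if (T < width) stop("series shorter than window width")
  if (step < 1) stop("step must be >= 1")
  starts <- as.integer(seq.int(1L, T - width + 1L, by = step))
  cbind(start = starts, end = starts + as.integer(width) - 1L)
}

#' Sliding-window functional connectivity
#'
#' Each window's matrix is computed exactly as the static [fc_matrix()] on
#' the window slice. A column constant within some window degenerates that
#' window's edges to z = 0 with a warning (short-window edge case) rather
#' than erroring.
#'
#' @param series cleaned T x N matrix on a regular temporal grid.
#' @param width,step window parameters in TR units.
#' @return A `windowed_fc` object: list with `windows` (list of z matrices),
#'   `index` (window bounds), `width`, `step`.
#' @export
windowed_fc <- function(series, width = 50, step = 5) {
  series <- as.matrix(series)
  idx <- sliding_windows(nrow(series), width, step)
  wins <- lapply(seq_len(nrow(idx)), function(w) {
    slice <- series[idx[w, 1]:idx[w, 2], , drop = FALSE]
    sds <- apply(slice, 2, stats::sd)
    if (any(sds == 0)) {
      warning(sprintf("window %d: constant column, its edges set to z = 0", w))
      r <- suppressWarnings(stats::cor(slice))
      r[is.na(r)] <- 0
      z <- fisher_z(r)
      diag(z) <- NA_real_
      z
    } else {
      fc_matrix(slice)
    }
  })
  structure(list(windows = wins, index = idx, width = width, step = step),
            class = "windowed_fc")
}

# Stack a list of windowed_fc objects into a pooled window x edge matrix,
# with bookkeeping of subject/condition per row.
.pool_windows <- function(wfc_list, design = NULL, use_z = TRUE,
                          rois = default_roi_set()) {
  ids <- names(wfc_list)
  if (is.null(ids)) ids <- sprintf("subj%03d", seq_along(wfc_list))
  mats <- list(); subj <- character(0)
  for (i in seq_along(wfc_list)) {
    v <- vapply(wfc_list[[i]]$windows, vectorize_fc,
                numeric(rois$n * (rois$n - 1) / 2),
                scope = "all", rois = rois)
    mats[[i]] <- t(v)
    subj <- c(subj, rep(ids[i], ncol(v)))
  }
  x <- do.call(rbind, mats)
  if (!use_z) x <- tanh(x)
  group <- if (!is.null(design)) {
    design$group[match(subj, design$subject_id)]
  } else rep(NA_character_, length(subj))
  list(x = x, subject = subj, group = group)
}

#' Davies-Bouldin index of a partition
#'
#' Centroid (Euclidean) formulation: per-cluster dispersion is the mean
#' distance of members to their centroid; the index is the mean over
#' clusters of the worst (max) ratio (S_i + S_j) / d(c_i, c_j).
#'
#' @param x points x features matrix.
#' @param labels integer cluster labels, 1..k.
#' @param centers k x features centroid matrix.
#' @return The DBI (lower is better); NA for k < 2.
#' @export
davies_bouldin <- function(x, labels, centers) {
  k <- nrow(centers)
  if (k < 2) return(NA_real_)
  S <- vapply(seq_len(k), function(i) {
    d <- sweep(x[labels == i, , drop = FALSE], 2, centers[i, ])
    mean(sqrt(rowSums(d^2)))
  }, numeric(1))
  M <- as.matrix(stats::dist(centers))
  r <- vapply(seq_len(k), function(i) {
    max((S[i] + S[-i]) / M[i, -i])
  }, numeric(1))
  mean(r)
}

#' Cluster pooled windowed FC into brain states
#'
#' k-means (squared Euclidean, `n_init` restarts, fixed seed) on the pooled
#' window x edge matrix from all subjects and conditions. If `k_fixed` is
#' absent, k is chosen to minimize the Davies-Bouldin index over `k_range`.
#' An empty cluster triggers a restart with an offset seed (up to 10
#' attempts). Clustering operates on Fisher-z vectors by default.
#'
#' @param wfc_list named list of `windowed_fc` objects (names = subject
#'   ids).
#' @param design data frame with `subject_id`, `group`.
#' @param k_range candidate state counts (default 2:8).
#' @param k_fixed fix k instead of selecting by DBI.
#' @param seed RNG seed for the k-means restarts (default 42).
#' @param n_init random restarts (default 50).
#' @param use_z cluster Fisher-z (TRUE, default) or r values.
#' @param rois `roi_set`.
#' @return A `state_model`: list with `k`, `centroids` (k x edges),
#'   `centroid_matrices` (list of N x N), `labels` (per pooled window),
#'   `subject`, `group`, `frequencies` (subject x k), `transition` (per
#'   subject k x k + pooled), `dbi_curve`.
#' @export
cluster_states <- function(wfc_list, design = NULL, k_range = 2:8,
                           k_fixed = NULL, seed = 42, n_init = 50,
                           use_z = TRUE, rois = default_roi_set()) {
  pool <- .pool_windows(wfc_list, design, use_z, rois)
  x <- pool$x
  if (!is.null(design) && !all(design$group %in% pool$group)) {
    warning("some design conditions contribute no windows to the pool")
  }
  run_k <- function(k, seed_offset = 0) {
    for (attempt in 0:9) {
      set.seed(seed + seed_offset + attempt)
      km <- tryCatch(
        suppressWarnings(
          stats::kmeans(x, centers = k, nstart = n_init, iter.max = 200)),
        error = function(e) NULL)
      if (!is.null(km) && length(unique(km$cluster)) == k) return(km)
    }
    stop(sprintf("k-means failed to produce %d non-empty clusters", k))
  }
  if (is.null(k_fixed)) {
    k_range <- k_range[k_range >= 2]
    fits <- lapply(k_range, run_k)
    dbi <- vapply(seq_along(k_range), function(i) {
      davies_bouldin(x, fits[[i]]$cluster, fits[[i]]$centers)
    }, numeric(1))
    names(dbi) <- k_range
    best <- which.min(dbi)
    km <- fits[[best]]
    k <- k_range[best]
  } else {
    k <- k_fixed
    km <- run_k(k)
    dbi <- stats::setNames(davies_bouldin(x, km$cluster, km$centers),
                           as.character(k))
  }
  centroid_matrices <- lapply(seq_len(k), function(i) {
    .edge_vector_to_matrix(km$centers[i, ], rois)
  })
  model <- structure(list(k = k, centroids = km$centers,
                          centroid_matrices = centroid_matrices,
                          labels = km$cluster, subject = pool$subject,
                          group = pool$group, dbi_curve = dbi,
                          use_z = use_z, rois = rois),
                     class = "state_model")
  model$frequencies <- state_frequencies(model)
  model$transition <- transition_matrices(model)
  model
}

.edge_vector_to_matrix <- function(v, rois) {
  n <- rois$n
  m <- matrix(NA_real_, n, n, dimnames = list(rois$names, rois$names))
  m[upper.tri(m)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Per-subject state occupancy fractions
#'
#' @param model a `state_model`.
#' @return subjects x k matrix of fractions (rows sum to 1).
#' @export
state_frequencies <- function(model) {
  ids <- unique(model$subject)
  f <- t(vapply(ids, function(s) {
    as.numeric(tabulate(model$labels[model$subject == s], model$k))
  }, numeric(model$k)))
  f <- f / rowSums(f)
  rownames(f) <- ids
  colnames(f) <- paste0("state", seq_len(model$k))
  f
}

#' Per-subject and pooled state transition matrices
#'
#' Transitions are counted only between consecutive windows of the same
#' subject. Rows are normalized by observed departures; rows with no
#' departure are NA (undefined), never zero. Two poolings are provided:
#' `subject_mean` averages per-subject rows over subjects where the row is
#' defined; `pooled` normalizes the summed counts.
#'
#' @param model a `state_model`.
#' @return List: `per_subject` (list of k x k matrices), `subject_mean`,
#'   `pooled`, `counts`.
#' @export
transition_matrices <- function(model) {
  k <- model$k
  ids <- unique(model$subject)
  count1 <- function(lab) {
    m <- matrix(0, k, k)
    if (length(lab) > 1) {
      for (t in seq_len(length(lab) - 1)) {
        m[lab[t], lab[t + 1]] <- m[lab[t], lab[t + 1]] + 1
      }
    }
    m
  }
  norm_rows <- function(m) {
    out <- m / rowSums(m)
    out[rowSums(m) == 0, ] <- NA_real_
    out
  }
  counts <- lapply(ids, function(s) count1(model$labels[model$subject == s]))
  names(counts) <- ids
  per_subject <- lapply(counts, norm_rows)
  total <- Reduce(`+`, counts)
  arr <- simplify2array(per_subject)
  subject_mean <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  subject_mean[is.nan(subject_mean)] <- NA_real_
  list(per_subject = per_subject, subject_mean = subject_mean,
       pooled = norm_rows(total), counts = total)
}

#' Group statistics on state frequencies and transitions
#'
#' Per state: one-way ANOVA of occupancy fraction across conditions with
#' Tukey-Kramer pairwise contrasts, plus Shapiro-Wilk (per condition) and
#' Bartlett (across conditions) diagnostics. Diagnostics are reported, not
#' used to gate the parametric tests.
#'
#' @param model a `state_model`.
#' @param design data frame with `subject_id`, `group`.
#' @param alpha significance level (default 0.05).
#' @return List of class `state_stats`: `frequencies`, `anova` (per-state
#'   data frame with F, p), `tukey` (list of pairwise tables),
#'   `diagnostics` (Shapiro/Bartlett p-values), `transition`.
#' @export
state_statistics <- function(model, design, alpha = 0.05) {
  freq <- model$frequencies
  group <- factor(design$group[match(rownames(freq), design$subject_id)])
  anova_rows <- list(); tukey <- list(); diag_rows <- list()
  for (s in seq_len(model$k)) {
    y <- freq[, s]
    fit <- stats::aov(y ~ group)
    an <- summary(fit)[[1]]
    Fv <- an$`F value`[1]
    pv <- an$`Pr(>F)`[1]
    if (is.null(pv) || length(pv) == 0) { Fv <- NA_real_; pv <- NA_real_ }
    anova_rows[[s]] <- data.frame(
      state = s, F = Fv, p = pv,
      significant = isTRUE(pv < alpha))
    tk <- stats::TukeyHSD(fit)$group
    tukey[[s]] <- data.frame(contrast = rownames(tk), tk,
                             row.names = NULL, check.names = FALSE)
    sw <- vapply(levels(group), function(g) {
      yy <- y[group == g]
      if (length(unique(yy)) < 3 || stats::sd(yy) == 0) return(NA_real_)
      stats::shapiro.test(yy)$p.value
    }, numeric(1))
    bt <- tryCatch(stats::bartlett.test(y, group)$p.value,
                   error = function(e) NA_real_)
    diag_rows[[s]] <- data.frame(state = s, t(sw), bartlett_p = bt,
                                 check.names = FALSE)
  }
  structure(list(frequencies = freq,
                 group = group,
                 anova = do.call(rbind, anova_rows),
                 tukey = tukey,
                 diagnostics = do.call(rbind, diag_rows),
                 transition = model$transition,
                 alpha = alpha),
            class = "state_stats")
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement of two partitions of the same items; 1 means
#' identical partitions (up to relabeling).
#'
#' @param a,b integer label vectors of equal length.
#' @return The ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
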