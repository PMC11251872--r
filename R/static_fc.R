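#' Fisher-z transform with clipping
#'
#' atanh(r) with |r| clipped to 1 - `clip` so perfectly correlated pairs stay
#' finite.
#'
#' @param r correlations.
#' @param clip clipping margin (default 1e-7).
#' @return Fisher-z values.
#' @export
fisher_z <- function(r, clip = 1e-7) {
  atanh(pmax(pmin(r, 1 - clip), -1 + clip))
}

#' Static functional connectivity matrix
#'
#' Pearson correlations between all region pairs, Fisher-z transformed.
#' The diagonal is set to NA: self-correlations carry no information and are
#' excluded from every downstream statistic.
#'
#' @param series T x N matrix of cleaned BOLD (T >= 3).
#' @param clip Fisher-z clipping margin.
#' @return N x N symmetric matrix of z values with NA diagonal.
#' @export
fc_matrix <- function(series, clip = 1e-7) {
  series <- as.matrix(series)
  if (nrow(series) < 3) stop("need at least 3 timepoints")
  sds <- apply(series, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(series)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop(sprintf("constant column(s): %s", paste(bad, collapse = ", ")))
  }
  z <- fisher_z(stats::cor(series), clip)
  diag(z) <- NA_real_
  z
}

#' Vectorize an FC matrix over a region scope
#'
#' Fixed, documented ordering: triangle scopes use the upper triangle in
#' column-major order (diagonal excluded); the cortico-subcortical scope is
#' the full subcortical-rows x cortical-columns block in column-major order.
#'
#' @param z N x N FC matrix.
#' @param scope one of `"all"`, `"cortical"`, `"subcortical"`,
#'   `"cortico_subcortical"`.
#' @param rois the `roi_set` the matrix is defined over.
#' @return Numeric vector (lengths 190 / 45 / 45 / 100 for N = 20).
#' @export
vectorize_fc <- function(z, scope = c("all", "cortical", "subcortical",
                                      "cortico_subcortical"),
                         rois = default_roi_set()) {
  scope <- match.arg(scope)
  sub <- roi_indices(rois, "subcortical")
  ctx <- roi_indices(rois, "cortical")
  switch(scope,
    all = z[upper.tri(z)],
    cortical = {
      b <- z[ctx, ctx]
      b[upper.tri(b)]
    },
    subcortical = {
      b <- z[sub, sub]
      b[upper.tri(b)]
    },
    cortico_subcortical = as.vector(z[sub, ctx]))
}

#' Edge-wise two-sample test with BH-FDR correction
#'
#' Each upper-triangle edge is compared between groups with an
#' independent-samples t-test (equal-variance by default, Welch by flag);
#' p-values are Benjamini-Hochberg adjusted across edges.
#'
#' @param group_a,group_b lists of FC matrices (one per subject).
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @param welch use the Welch (unequal-variance) form (default FALSE).
#' @param rois `roi_set` for edge labels.
#' @return Data frame with one row per edge: `roi_i`, `roi_j`, `t`, `p`,
#'   `p_adj`, `significant`.
#' @export
edgewise_group_test <- function(group_a, group_b, alpha = 0.05,
                                welch = FALSE, rois = default_roi_set()) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("need at least 2 subjects per group")
  }
  va <- t(vapply(group_a, vectorize_fc, numeric(sum(upper.tri(group_a[[1]]))),
                 scope = "all", rois = rois))
  vb <- t(vapply(group_b, vectorize_fc, numeric(ncol(va)),
                 scope = "all", rois = rois))
  na <- nrow(va); nb <- nrow(vb)
  ma <- colMeans(va); mb <- colMeans(vb)
  sa2 <- apply(va, 2, stats::var); sb2 <- apply(vb, 2, stats::var)
  if (welch) {
    se <- sqrt(sa2 / na + sb2 / nb)
    df <- (sa2 / na + sb2 / nb)^2 /
      ((sa2 / na)^2 / (na - 1) + (sb2 / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * sa2 + (nb - 1) * sb2) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(se))
  }
  tval <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(tval), df)
  zerovar <- se == 0
  if (any(zerovar)) {
    warning(sprintf("%d edge(s) with zero variance in both groups: p set to 1",
                    sum(zerovar)))
    tval[zerovar] <- 0
    p[zerovar] <- 1
  }
  padj <- stats::p.adjust(p, method = "BH")
  ut <- which(upper.tri(diag(rois$n)), arr.ind = TRUE)
  data.frame(roi_i = rois$names[ut[, 1]], roi_j = rois$names[ut[, 2]],
             t = tval, p = p, p_adj = padj,
             significant = padj < alpha,
             stringsAsFactors = FALSE)
}

#' FC-matrix similarity analysis
#'
#' Pairwise Pearson correlation between vectorized FC matrices over a scope,
#' at the individual level (one matrix per subject) or group level (one mean
#' matrix per condition). When a design is supplied, a summary of Fisher-z
#' transformed mean similarities within and between conditions is attached.
#'
#' @param matrices named list of FC matrices.
#' @param scope vectorization scope, see [vectorize_fc()].
#' @param rois `roi_set`.
#' @param design optional data frame with `subject_id`, `group` matching
#'   `names(matrices)`.
#' @return List of class `fc_similarity`: `values` (M x M correlation
#'   matrix), `scope`, and (with a design) `summary` — a data frame of mean
#'   z(r) for every condition pair.
#' @export
similarity_analysis <- function(matrices, scope = "all",
                                rois = default_roi_set(), design = NULL) {
  if (length(matrices) < 2) stop("need at least 2 matrices")
  vecs <- vapply(matrices,
                 vectorize_fc, numeric(length(
                   vectorize_fc(matrices[[1]], scope, rois))),
                 scope = scope, rois = rois)
  sds <- apply(vecs, 2, stats::sd)
  sim <- suppressWarnings(stats::cor(vecs))
  sim[sds == 0, ] <- NA_real_
  sim[, sds == 0] <- NA_real_
  diag(sim) <- 1
  out <- list(values = sim, scope = scope)
  if (!is.null(design)) {
    design <- design[match(names(matrices), design$subject_id), ]
    groups <- unique(design$group)
    rows <- list()
    for (a in seq_along(groups)) for (b in a:length(groups)) {
      ia <- which(design$group == groups[a])
      ib <- which(design$group == groups[b])
      block <- sim[ia, ib, drop = FALSE]
      if (a == b) block <- block[upper.tri(block)]
      rows[[length(rows) + 1]] <- data.frame(
        group_a = groups[a], group_b = groups[b],
        mean_zr = mean(fisher_z(block), na.rm = TRUE),
        n_pairs = sum(!is.na(block)), stringsAsFactors = FALSE)
    }
    out$summary <- do.call(rbind, rows)
  }
  structure(out, class = "fc_similarity")
}

#' Mean cross-condition similarity for one scope
#'
#' Convenience extractor: mean Fisher-z similarity over all subject pairs
#' whose conditions differ.
#'
#' @param sim an `fc_similarity` with a summary.
#' @return Single number (mean z(r) over between-condition group pairs,
#'   weighted by pair counts).
#' @export
cross_condition_similarity <- function(sim) {
  s <- sim$summary
  s <- s[s$group_a != s$group_b, ]
  sum(s$mean_zr * s$n_pairs) / sum(s$n_pairs)
}
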