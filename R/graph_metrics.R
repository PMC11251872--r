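#' Binarize an FC matrix at a sparsity threshold
#'
#' Upper-triangle |z| values are ranked descending and the strongest
#' floor(sparsity * N(N-1)/2) connections retained as edges; ties at the
#' cutoff are broken by lexicographic (row, column) order so repeated runs
#' agree. Negative correlations enter by absolute value.
#'
#' @param z N x N Fisher-z FC matrix (diagonal ignored).
#' @param sparsity retained-edge fraction in (0, 1] (default 0.2).
#' @return Symmetric 0/1 adjacency matrix with zero diagonal and attribute
#'   `sparsity`.
#' @export
binarize_by_sparsity <- function(z, sparsity = 0.2) {
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must be in (0, 1]")
  n <- nrow(z)
  ut <- which(upper.tri(z), arr.ind = TRUE)
  w <- abs(z[upper.tri(z)])
  n_keep <- floor(sparsity * nrow(ut))
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- ord[seq_len(n_keep)]
  adj <- matrix(0L, n, n, dimnames = dimnames(z))
  adj[ut[keep, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  attr(adj, "sparsity") <- sparsity
  adj
}

# All-pairs BFS distances on a binary undirected graph; Inf if unreachable.
.bfs_distances <- function(adj) {
  n <- nrow(adj)
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ] > 0))
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier) > 0) {
      depth <- depth + 1
      nxt <- unique(unlist(nbrs[frontier]))
      nxt <- nxt[is.infinite(d[s, nxt])]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

#' Nodal graph metrics on a binary network
#'
#' \describe{
#'   \item{efficiency}{mean inverse geodesic distance to the other N-1 nodes,
#'     harmonic convention 1/Inf = 0 for unreachable pairs; in [0, 1];}
#'   \item{clustering}{fraction of a node's neighbor pairs that are
#'     connected, 0 when degree < 2;}
#'   \item{shortest_path}{mean geodesic distance over *reachable* other
#'     nodes, NA for isolated nodes.}
#' }
#'
#' @param adj symmetric binary adjacency with zero diagonal.
#' @return Data frame with columns `node`, `degree`, `efficiency`,
#'   `clustering`, `shortest_path`.
#' @export
nodal_metrics <- function(adj) {
  n <- nrow(adj)
  d <- .bfs_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  eff <- rowSums(inv) / (n - 1)
  deg <- rowSums(adj)
  clust <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    sub <- adj[nb, nb]
    sum(sub) / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  spath <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (length(di) == 0) NA_real_ else mean(di)
  }, numeric(1))
  nodes <- rownames(adj)
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  data.frame(node = nodes, degree = deg, efficiency = eff,
             clustering = clust, shortest_path = spath,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Time-resolved nodal metrics and their coefficient of variation
#'
#' Per-window binarization at `sparsity` followed by [nodal_metrics()];
#' the CV of each node is the population standard deviation over windows
#' divided by the mean, computed over windows where the metric is defined.
#' Nodes whose mean metric is below 1e-9 get NA CV.
#'
#' @param wfc a `windowed_fc` (>= 2 windows).
#' @param sparsity retained-edge fraction (default 0.2).
#' @param sample_sd use the n-1 (sample) SD instead of the population SD
#'   (default FALSE).
#' @return List of class `nodal_metric_series`: per metric a windows x N
#'   matrix, plus `cv` (metric x node data frame) and `sparsity`.
#' @export
time_resolved_metrics <- function(wfc, sparsity = 0.2, sample_sd = FALSE) {
  stopifnot(inherits(wfc, "windowed_fc"), length(wfc$windows) >= 2)
  per_win <- lapply(wfc$windows, function(z) {
    nodal_metrics(binarize_by_sparsity(z, sparsity))
  })
  metrics <- c("efficiency", "clustering", "shortest_path")
  series <- lapply(metrics, function(m) {
    t(vapply(per_win, function(df) df[[m]], numeric(nrow(per_win[[1]]))))
  })
  names(series) <- metrics
  nodes <- per_win[[1]]$node
  for (m in metrics) colnames(series[[m]]) <- nodes
  cv_of <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    mu <- mean(v)
    if (abs(mu) < 1e-9) return(NA_real_)
    if (sample_sd) stats::sd(v) / mu
    else sqrt(mean((v - mu)^2)) / mu
  }
  cv <- vapply(series, function(mat) apply(mat, 2, cv_of),
               numeric(length(nodes)))
  structure(list(series = series,
                 cv = as.data.frame(cv),
                 nodes = nodes, sparsity = sparsity),
            class = "nodal_metric_series")
}
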