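# Sparse moving-average operator: n cells -> n - window + 1 windows of the
# stated size, stride 1, trailing partial windows excluded.
smoothing_operator <- function(n, window) {
  k <- n - window + 1
  Matrix::sparseMatrix(i = rep(seq_len(k), each = window) +
                         rep(seq_len(window) - 1L, times = k),
                       j = rep(seq_len(k), each = window),
                       x = 1 / window, dims = c(n, k))
}

apply_profile_scaling <- function(v, scaling) {
  switch(scaling,
         none = v,
         zscore = if (stats::sd(v) == 0) rep(0, length(v)) else
           (v - mean(v)) / stats::sd(v),
         minmax01 = if (max(v) == min(v)) rep(0, length(v)) else
           (v - min(v)) / (max(v) - min(v)),
         maxscale = {
           if (max(v) <= 0) stop("maxscale needs a positive maximum",
                                 call. = FALSE)
           v / max(v)
         },
         stop("unknown scaling '", scaling, "'", call. = FALSE))
}

#' Smooth per-cell values along pseudotime with a sliding window
#'
#' Cells are sorted by pseudotime (ties broken by cell id) and a stride-1
#' moving average of the stated window size is taken; trailing partial
#' windows are excluded, so the output has n - window + 1 positions. An
#' optional scaling is applied after smoothing: \code{"minmax01"} maps to
#' [0, 1] (the surface-marker display convention; a constant profile maps to
#' 0), \code{"zscore"} standardises, \code{"maxscale"} divides by the
#' profile maximum.
#'
#' @param values numeric vector, one value per cell in \code{pt$cell_ids}
#'   order (or named by cell id).
#' @param pt a \code{\link{pseudotime_ordering}}.
#' @param window window size (default 20).
#' @param scaling one of \code{"none"}, \code{"zscore"}, \code{"minmax01"},
#'   \code{"maxscale"}.
#' @return A list of class \code{"SmoothedProfile"}: \code{values} (length
#'   n - window + 1), \code{window}, \code{scaling}, \code{cell_order}.
#' @export
sliding_window_smooth <- function(values, pt, window = 20,
                                  scaling = c("none", "zscore", "minmax01",
                                              "maxscale")) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(pt, "PseudotimeOrdering"))
  n <- length(pt$cell_ids)
  if (window < 1 || window > n)
    stop("window must lie in [1, n_cells]", call. = FALSE)
  if (!is.null(names(values))) values <- values[pt$cell_ids]
  stopifnot(length(values) == n)
  ord <- pseudotime_order(pt)
  sm <- as.numeric(values[ord] %*% smoothing_operator(n, window))
  structure(list(values = apply_profile_scaling(sm, scaling),
                 window = window, scaling = scaling,
                 cell_order = pt$cell_ids[ord]),
            class = "SmoothedProfile")
}

#' Phenotype composition of each sliding window
#'
#' Uses the same windowing as \code{\link{sliding_window_smooth}} and returns,
#' for each window position, the proportion of cells carrying each label —
#' the data behind the phenotype colorbar drawn above pseudotime heatmaps.
#'
#' @param labels character vector of per-cell labels, in \code{pt$cell_ids}
#'   order (or named by cell id).
#' @param pt a \code{\link{pseudotime_ordering}}.
#' @param window window size (default 20).
#' @return Matrix of window positions x label levels; rows sum to 1.
#' @export
window_composition <- function(labels, pt, window = 20) {
  stopifnot(inherits(pt, "PseudotimeOrdering"))
  n <- length(pt$cell_ids)
  if (window < 1 || window > n)
    stop("window must lie in [1, n_cells]", call. = FALSE)
  if (!is.null(names(labels))) labels <- labels[pt$cell_ids]
  stopifnot(length(labels) == n)
  lev <- sort(unique(labels))
  ind <- sapply(lev, function(l) as.numeric(labels[pseudotime_order(pt)] == l))
  if (n == 1L) ind <- matrix(ind, nrow = 1, dimnames = list(NULL, lev))
  out <- as.matrix(Matrix::crossprod(smoothing_operator(n, window), ind))
  colnames(out) <- lev
  out
}

#' Pearson correlation of a marker with pseudotime
#'
#' Computed on the raw (unsmoothed) per-cell values — the number reported
#' next to each smoothed marker trace. Markers from index-sort tables should
#' be log-transformed before calling.
#'
#' @param marker numeric per-cell values, in \code{pt$cell_ids} order (or
#'   named by cell id).
#' @param pt a \code{\link{pseudotime_ordering}}.
#' @return Pearson correlation coefficient.
#' @export
marker_pseudotime_correlation <- function(marker, pt) {
  stopifnot(inherits(pt, "PseudotimeOrdering"))
  if (!is.null(names(marker))) marker <- marker[pt$cell_ids]
  if (length(marker) < 3) stop("need at least 3 cells", call. = FALSE)
  if (stats::sd(marker) == 0) stop("marker has zero variance", call. = FALSE)
  stats::cor(marker, pt$pseudotime)
}

#' Permutation test for genes dynamically expressed along pseudotime
#'
#' Per gene, the statistic is the variance of the window-smoothed expression
#' profile along pseudotime: genes with any reproducible trend have smooth
#' profiles of high variance, while exchangeable (non-dynamic) genes do not.
#' The null distribution is obtained by permuting the cell ordering; the same
#' permutations are shared across genes. The permutation p-value uses the
#' add-one convention (never exactly 0), is BH-adjusted across genes, and
#' genes are flagged dynamic at adjusted p below \code{alpha}.
#'
#' @param x an \code{ExpressionMatrix}, lognorm layer.
#' @param pt a \code{\link{pseudotime_ordering}} over the same cells.
#' @param window smoothing window (default 20).
#' @param n_perm number of permutations (default 1000, minimum 100).
#' @param alpha adjusted-p threshold for the dynamic flag (default 0.01).
#' @param seed integer seed for the permutation draw.
#' @return A data frame, one row per gene: \code{gene_id}, \code{statistic},
#'   \code{p_perm}, \code{p_adj}, \code{is_dynamic}, \code{cluster_id}
#'   (NA until \code{\link{cluster_dynamic_genes}} is run).
#' @export
dynamic_gene_test <- function(x, pt, window = 20, n_perm = 1000,
                              alpha = 0.01, seed = 1L) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(pt, "PseudotimeOrdering"))
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  if (!setequal(x$cell_ids, pt$cell_ids))
    stop("expression matrix and pseudotime cover different cells", call. = FALSE)
  n <- length(x$cell_ids)
  if (window > n) stop("window exceeds number of cells", call. = FALSE)
  v <- x$values[, pt$cell_ids[pseudotime_order(pt)], drop = FALSE]
  W <- smoothing_operator(n, window)
  k <- ncol(W)
  prof_var <- function(m) {
    s <- as.matrix(m %*% W)
    (rowSums(s^2) - k * rowMeans(s)^2) / (k - 1)
  }
  obs <- prof_var(v)
  exceed <- integer(nrow(v))
  with_seed(seed, {
    for (r in seq_len(n_perm)) {
      null_stat <- prof_var(v[, sample.int(n), drop = FALSE])
      exceed <- exceed + (null_stat >= obs)
    }
  })
  p_perm <- (1 + exceed) / (1 + n_perm)
  p_adj <- bh_adjust(p_perm)
  data.frame(gene_id = x$gene_ids, statistic = obs, p_perm = p_perm,
             p_adj = p_adj, is_dynamic = p_adj < alpha,
             cluster_id = NA_integer_, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Smoothed pseudotime profiles for a set of genes
#'
#' Convenience wrapper returning a genes x windows matrix of smoothed
#' (optionally scaled) profiles — the rows of the pseudotime heatmaps.
#'
#' @param x an \code{ExpressionMatrix}, lognorm layer.
#' @param pt a \code{\link{pseudotime_ordering}}.
#' @param genes gene ids (default: all).
#' @param window window size (default 20).
#' @param scaling per-gene scaling applied after smoothing (default
#'   \code{"zscore"}, the heatmap convention).
#' @return Numeric matrix, genes x window positions.
#' @export
smoothed_profiles <- function(x, pt, genes = NULL, window = 20,
                              scaling = "zscore") {
  stopifnot(inherits(x, "ExpressionMatrix"))
  genes <- genes %||% x$gene_ids
  t(sapply(genes, function(g)
    sliding_window_smooth(stats::setNames(x$values[g, ], x$cell_ids), pt,
                          window = window, scaling = scaling)$values))
}

#' Louvain clustering of dynamic-gene profiles
#'
#' Builds a k-nearest-neighbor graph over genes (Euclidean distance between
#' their z-scored smoothed profiles) and partitions it with Louvain community
#' detection. Clusters are relabelled by descending size, so cluster 1 is
#' always the largest. The default resolution (0.3) is deliberately coarse:
#' the stage exists to separate broad dynamic modes (increasing vs
#' decreasing programs), and modularity at resolution 1 over-partitions
#' coherent monotone profile groups.
#'
#' @param profiles genes x windows matrix of z-scored smoothed profiles
#'   (e.g. from \code{\link{smoothed_profiles}} restricted to dynamic genes).
#' @param n_neighbors kNN graph size (default 15, capped at n - 1).
#' @param resolution Louvain resolution (default 0.3).
#' @param seed integer seed.
#' @return Named integer vector of cluster ids, one per input gene.
#' @export
cluster_dynamic_genes <- function(profiles, n_neighbors = 15,
                                  resolution = 0.3, seed = 1L) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n < 2) {
    warning("fewer than 2 genes: returning a single cluster")
    return(stats::setNames(rep(1L, n), rownames(profiles)))
  }
  k <- min(n_neighbors, n - 1)
  d <- as.matrix(stats::dist(profiles))
  nn <- apply(d, 1, function(r) order(r)[2:(k + 1)])
  adj <- matrix(FALSE, n, n)
  adj[cbind(rep(seq_len(n), each = k), as.vector(nn))] <- TRUE
  adj <- adj | t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- with_seed(seed,
    igraph::membership(igraph::cluster_louvain(g, resolution = resolution)))
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  stats::setNames(as.integer(relab[as.character(memb)]), rownames(profiles))
}

#' Scale profiles to their per-gene maximum
#'
#' Divides each profile by its maximum, so every gene peaks at 1. Unlike
#' z-scoring, this preserves where along pseudotime each gene reaches its
#' maximum, which is what reveals staged induction (e.g. of protease genes).
#'
#' @param profiles genes x positions numeric matrix with positive per-gene
#'   maxima.
#' @return The row-rescaled matrix.
#' @export
max_scale_profiles <- function(profiles) {
  profiles <- as.matrix(profiles)
  mx <- apply(profiles, 1, max)
  if (any(mx <= 0))
    stop("nonpositive profile maximum for: ",
         paste(rownames(profiles)[mx <= 0] %||%
                 which(mx <= 0), collapse = ", "), call. = FALSE)
  profiles / mx
}
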