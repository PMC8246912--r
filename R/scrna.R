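#' Depth-normalise and log-transform a counts matrix
#'
#' Scales every cell to the same total (\code{target_sum}), then applies a
#' natural log after adding a pseudocount. The defaults (1e6, pseudocount 1)
#' give log-CPM, the usual choice for deep plate-based single-cell counts.
#'
#' @param x an \code{ExpressionMatrix}, counts layer.
#' @param target_sum per-cell total after scaling (default 1e6).
#' @param pseudocount added before the log (default 1).
#' @return An \code{ExpressionMatrix} with layer \code{"lognorm"}.
#' @export
normalize_log <- function(x, target_sum = 1e6, pseudocount = 1) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$layer != "counts") stop("normalize_log expects a counts layer",
                                call. = FALSE)
  totals <- colSums(x$values)
  if (any(totals == 0))
    stop("cell(s) with zero total counts: ",
         paste(x$cell_ids[totals == 0], collapse = ", "), call. = FALSE)
  v <- sweep(x$values, 2, target_sum / totals, `*`)
  expression_matrix(log(v + pseudocount), x$gene_ids, x$cell_ids,
                    cell_labels = x$cell_labels, layer = "lognorm")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' returned in the original order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Per-gene Welch two-sample differential expression
#'
#' Welch's unequal-variance t-test per gene on log-normalised values, two
#' sided, with BH adjustment across all tested genes. Direction is reported
#' relative to the second-named group: \code{"up"} means higher in group b.
#' Genes with zero variance in both groups get p = 1 by convention.
#'
#' @param x an \code{ExpressionMatrix}, lognorm layer.
#' @param group_a,group_b labels (matched against \code{cell_labels}) or
#'   logical/integer cell selections defining the two groups.
#' @param alpha adjusted-p threshold at which a direction is called
#'   (default 0.01).
#' @return A data frame with one row per gene: \code{gene_id}, \code{mean_a},
#'   \code{mean_b}, \code{t_stat}, \code{p}, \code{p_adj}, \code{direction}
#'   (\code{"up"}/\code{"down"}, NA above the threshold).
#' @export
differential_expression <- function(x, group_a, group_b, alpha = 0.01) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$layer != "lognorm")
    stop("differential_expression expects a lognorm layer", call. = FALSE)
  sel <- function(g) {
    if (is.character(g) && length(g) <= length(unique(x$cell_labels))) {
      if (is.null(x$cell_labels)) stop("matrix has no cell labels", call. = FALSE)
      which(x$cell_labels %in% g)
    } else if (is.logical(g)) which(g) else as.integer(g)
  }
  ia <- sel(group_a); ib <- sel(group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("need at least 2 cells per group", call. = FALSE)
  a <- x$values[, ia, drop = FALSE]
  b <- x$values[, ib, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tt <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  degenerate <- va == 0 & vb == 0
  if (any(degenerate)) {
    tt[degenerate] <- 0
    p[degenerate] <- 1
    message(sum(degenerate), " gene(s) with zero variance in both groups: p = 1")
  }
  p_adj <- bh_adjust(p)
  direction <- ifelse(p_adj < alpha, ifelse(mb > ma, "up", "down"),
                      NA_character_)
  data.frame(gene_id = x$gene_ids, mean_a = ma, mean_b = mb, t_stat = tt,
             p = p, p_adj = p_adj, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bin-matched gene-set score per cell
#'
#' Mean expression of the signature genes minus the mean of a control set
#' drawn from expression-matched bins: genes are ranked by mean expression
#' and cut into \code{n_bins} equal-frequency bins; for each signature gene,
#' \code{ctrl_size} control genes are sampled from its bin (signature genes
#' excluded), and the union of these draws forms the control set. This
#' removes the depth/expression-level component of the raw signature mean.
#'
#' @param x an \code{ExpressionMatrix}, lognorm layer.
#' @param signature a \code{SignatureList}.
#' @param n_bins number of expression bins (default 25).
#' @param ctrl_size control genes drawn per signature gene (default 50).
#' @param seed integer seed for the control draw.
#' @return Named numeric vector: one score per cell.
#' @export
score_gene_set <- function(x, signature, n_bins = 25, ctrl_size = 50,
                           seed = 1L) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(signature, "SignatureList"))
  present <- intersect(signature$genes, x$gene_ids)
  if (!length(present))
    stop("no signature gene found in matrix; missing: ",
         paste(signature$genes, collapse = ", "), call. = FALSE)
  gm <- rowMeans(x$values)
  bins <- cut(rank(gm, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  names(bins) <- x$gene_ids
  ctrl <- with_seed(seed, {
    unique(unlist(lapply(present, function(g) {
      pool <- setdiff(x$gene_ids[bins == bins[g]], present)
      if (!length(pool)) return(character(0))
      sample(pool, min(ctrl_size, length(pool)))
    })))
  })
  sig_mean <- colMeans(x$values[present, , drop = FALSE])
  ctrl_mean <- if (length(ctrl))
    colMeans(x$values[ctrl, , drop = FALSE]) else 0
  stats::setNames(sig_mean - ctrl_mean, x$cell_ids)
}

#' Assign cells to cell-cycle phases from S and G2M scores
#'
#' A cell is in G1 when both scores are negative; otherwise it takes the
#' phase of the larger score, with exact ties between positive scores broken
#' toward G2M.
#'
#' @param s_score,g2m_score numeric vectors of per-cell phase scores (e.g.
#'   from \code{\link{score_gene_set}} with the S and G2M gene lists).
#' @return A list of class \code{"CellCycleResult"}: \code{s_score},
#'   \code{g2m_score}, \code{phase} (\code{"G1"}, \code{"S"}, \code{"G2M"}).
#' @export
assign_cell_cycle <- function(s_score, g2m_score) {
  stopifnot(length(s_score) == length(g2m_score))
  phase <- ifelse(s_score < 0 & g2m_score < 0, "G1",
                  ifelse(s_score > g2m_score, "S", "G2M"))
  structure(list(s_score = s_score, g2m_score = g2m_score, phase = phase),
            class = "CellCycleResult")
}

#' @export
print.CellCycleResult <- function(x, ...) {
  tab <- table(factor(x$phase, c("G1", "S", "G2M")))
  cat("CellCycleResult:",
      paste(sprintf("%s %.1f%%", names(tab), 100 * tab / length(x$phase)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Bundled mouse cell-cycle phase gene lists
#'
#' The widely used S-phase and G2M-phase marker lists (Tirosh-derived) in
#' mouse symbol casing, shipped as plain-text files under
#' \code{inst/extdata}. Users may substitute their own lists anywhere a
#' \code{SignatureList} is accepted.
#'
#' @return A list with \code{SignatureList} elements \code{s} and \code{g2m}.
#' @export
default_cell_cycle_genes <- function() {
  list(s = read_signature(system.file("extdata", "mouse_s_genes.txt",
                                      package = "lineagetrace"),
                          name = "S"),
       g2m = read_signature(system.file("extdata", "mouse_g2m_genes.txt",
                                        package = "lineagetrace"),
                            name = "G2M"))
}
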