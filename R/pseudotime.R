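#' Per-cell pseudotime ordering
#'
#' @param cell_ids character vector of cell ids.
#' @param pseudotime finite numeric vector, one value per cell. Only the
#'   ordering (and relative spacing) is meaningful; adding a constant changes
#'   nothing downstream.
#' @param method \code{"pc1"} or \code{"dpt"}.
#' @param root_cell root cell id (diffusion pseudotime) or NULL.
#' @param orientation_markers genes whose downregulation fixed the direction
#'   (PC1 pseudotime) or NULL.
#' @return A list of class \code{"PseudotimeOrdering"}.
#' @export
pseudotime_ordering <- function(cell_ids, pseudotime, method = c("pc1", "dpt"),
                                root_cell = NULL, orientation_markers = NULL) {
  method <- match.arg(method)
  cell_ids <- as.character(cell_ids)
  stopifnot(length(cell_ids) == length(pseudotime), all(is.finite(pseudotime)))
  structure(list(cell_ids = cell_ids,
                 pseudotime = stats::setNames(as.numeric(pseudotime), cell_ids),
                 method = method, root_cell = root_cell,
                 orientation_markers = orientation_markers),
            class = "PseudotimeOrdering")
}

#' @export
print.PseudotimeOrdering <- function(x, ...) {
  cat(sprintf("PseudotimeOrdering (%s): %d cells, range [%.3g, %.3g]\n",
              x$method, length(x$cell_ids), min(x$pseudotime),
              max(x$pseudotime)))
  invisible(x)
}

# cell order along pseudotime; ties broken by cell id
pseudotime_order <- function(pt) order(pt$pseudotime, pt$cell_ids)

#' PC1 pseudotime oriented by progenitor marker loss
#'
#' Cells are ordered by their score on the first principal component of the
#' standardised cells x genes matrix over the most variable genes. The sign
#' of PC1 is arbitrary, so the direction is anchored biologically: the mean
#' Pearson correlation of the supplied progenitor markers (genes known to be
#' lost during differentiation, e.g. Cd34 and Kit) with pseudotime is made
#' negative.
#'
#' @param x an \code{ExpressionMatrix}, lognorm layer.
#' @param orientation_genes_down gene ids whose expression must decrease
#'   along pseudotime.
#' @param n_hvg number of highly variable genes (dispersion-ranked) entering
#'   the PCA; default 2000, capped at the matrix size.
#' @return A \code{\link{pseudotime_ordering}} with method \code{"pc1"}.
#' @export
pc1_pseudotime <- function(x, orientation_genes_down, n_hvg = 2000) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$layer != "lognorm") stop("pc1_pseudotime expects a lognorm layer",
                                 call. = FALSE)
  miss <- setdiff(orientation_genes_down, x$gene_ids)
  if (length(miss))
    stop("orientation gene(s) not in matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  v <- x$values
  gv <- apply(v, 1, stats::var)
  gm <- rowMeans(v)
  disp <- ifelse(gm > 0, gv / gm, 0)
  keep <- which(gv > 0)
  keep <- keep[order(disp[keep], decreasing = TRUE)]
  keep <- keep[seq_len(min(n_hvg, length(keep)))]
  pc <- fit_pca(t(v[keep, , drop = FALSE]), n_components = 1)
  pt <- as.numeric(pc$scores[, 1])
  r <- sapply(orientation_genes_down, function(g)
    stats::cor(v[g, ], pt))
  if (all(abs(r) < 1e-6))
    stop("orientation genes are uncorrelated with PC1; direction undefined",
         call. = FALSE)
  if (mean(r) > 0) pt <- -pt
  pseudotime_ordering(x$cell_ids, pt, method = "pc1",
                      orientation_markers = orientation_genes_down)
}

#' Diffusion pseudotime from a fitted diffusion map
#'
#' Distance of every cell from a root cell in the rescaled eigencomponent
#' space: \deqn{dpt(x) = \sqrt{\sum_i (\lambda_i/(1-\lambda_i))^2
#' (\psi_i(x)-\psi_i(root))^2}} over the retained nontrivial eigenpairs.
#' The root scores 0 and the induced pairwise distance is symmetric.
#'
#' @param model a \code{DiffusionModel}.
#' @param root_cell cell id (or row index) of the root.
#' @return A \code{\link{pseudotime_ordering}} with method \code{"dpt"}.
#' @export
diffusion_pseudotime <- function(model, root_cell) {
  stopifnot(inherits(model, "DiffusionModel"))
  ids <- model$cell_ids %||% as.character(seq_len(nrow(model$components)))
  ri <- if (is.character(root_cell)) match(root_cell, ids) else
    as.integer(root_cell)
  if (is.na(ri) || ri < 1 || ri > nrow(model$components))
    stop("root cell not among embedded cells", call. = FALSE)
  lam <- model$eigenvalues
  if (any(lam == 1))
    stop("retained eigenvalue equal to 1: non-decaying component", call. = FALSE)
  # components are psi * lambda, so rescale by 1/(1 - lambda)
  w <- sweep(model$components, 2, 1 - lam, `/`)
  diff2 <- sweep(w, 2, w[ri, ], `-`)^2
  pseudotime_ordering(ids, sqrt(rowSums(diff2)), method = "dpt",
                      root_cell = ids[ri])
}

#' Select a pseudotime root cell by maximising a score
#'
#' Picks the candidate with the highest score — by default the projection
#' frequency score of \code{\link{knn_frequency_score}}, i.e. the cell most
#' similar to the reference progenitor population. Ties are broken toward the
#' lexicographically smallest cell id, so the choice is deterministic.
#'
#' @param candidates character vector of candidate cell ids.
#' @param scores numeric vector of scores, parallel to \code{candidates} or
#'   named by cell id.
#' @return The selected root cell id.
#' @export
select_root <- function(candidates, scores) {
  if (!length(candidates)) stop("no root candidates", call. = FALSE)
  if (!is.null(names(scores))) scores <- scores[candidates]
  stopifnot(length(scores) == length(candidates))
  best <- which(scores == max(scores))
  sort(candidates[best])[1]
}
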