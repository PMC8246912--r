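#' Gene-by-cell expression matrix with identifiers and phenotype labels
#'
#' The central expression container of the package: a dense non-negative
#' numeric matrix (genes in rows, cells in columns) together with unique gene
#' and cell identifiers, an optional per-cell phenotype label (e.g. sorting
#' gate: \code{"BaP"}, \code{"Ba"}, \code{"P1"}, \code{"MC"}) and a layer tag
#' saying whether the values are raw counts or log-normalised expression.
#'
#' @param values numeric matrix, genes x cells, all entries >= 0. For the
#'   \code{"counts"} layer all entries must be integer-valued.
#' @param gene_ids character vector of unique gene identifiers, one per row.
#'   Identifiers are opaque, case-sensitive strings; no symbol mapping is done.
#' @param cell_ids character vector of unique cell identifiers, one per column.
#' @param cell_labels optional character vector of per-cell phenotype labels.
#' @param layer one of \code{"counts"} or \code{"lognorm"}.
#'
#' @return An object of class \code{"ExpressionMatrix"}: a list with elements
#'   \code{values}, \code{gene_ids}, \code{cell_ids}, \code{cell_labels},
#'   \code{layer}.
#' @export
expression_matrix <- function(values, gene_ids, cell_ids, cell_labels = NULL,
                              layer = c("counts", "lognorm")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(values) != length(gene_ids))
    stop("expression matrix has ", nrow(values), " rows but ", length(gene_ids),
         " gene ids", call. = FALSE)
  if (ncol(values) != length(cell_ids))
    stop("expression matrix has ", ncol(values), " columns but ",
         length(cell_ids), " cell ids", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("duplicate cell ids: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(values)))
    stop("expression values must be finite", call. = FALSE)
  if (any(values < 0))
    stop("expression values must be non-negative", call. = FALSE)
  if (layer == "counts" && any(values != round(values)))
    stop("counts layer must be integer-valued", call. = FALSE)
  if (!is.null(cell_labels)) {
    cell_labels <- as.character(cell_labels)
    if (length(cell_labels) != length(cell_ids))
      stop("cell_labels length must match number of cells", call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_labels = cell_labels, layer = layer),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s]: %d genes x %d cells\n",
              x$layer, length(x$gene_ids), length(x$cell_ids)))
  if (!is.null(x$cell_labels)) {
    tab <- table(x$cell_labels)
    cat("cell labels:", paste(sprintf("%s (%d)", names(tab), tab),
                              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an ExpressionMatrix by gene and/or cell
#'
#' @param x an \code{ExpressionMatrix}.
#' @param genes gene ids or row indices (default: all).
#' @param cells cell ids or column indices (default: all).
#' @return An \code{ExpressionMatrix} restricted to the requested rows/columns,
#'   in the requested order.
#' @export
subset_expression <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  gi <- if (is.null(genes)) seq_along(x$gene_ids) else {
    if (is.character(genes)) {
      miss <- setdiff(genes, x$gene_ids)
      if (length(miss))
        stop("unknown gene ids: ", paste(miss, collapse = ", "), call. = FALSE)
      match(genes, x$gene_ids)
    } else genes
  }
  ci <- if (is.null(cells)) seq_along(x$cell_ids) else {
    if (is.character(cells)) {
      miss <- setdiff(cells, x$cell_ids)
      if (length(miss))
        stop("unknown cell ids: ", paste(miss, collapse = ", "), call. = FALSE)
      match(cells, x$cell_ids)
    } else cells
  }
  expression_matrix(x$values[gi, ci, drop = FALSE],
                    x$gene_ids[gi], x$cell_ids[ci],
                    cell_labels = if (!is.null(x$cell_labels)) x$cell_labels[ci],
                    layer = x$layer)
}
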