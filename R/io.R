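#' Read an expression matrix from disk
#'
#' Accepts either a MatrixMarket coordinate file (\code{.mtx}) accompanied by
#' gene and cell id files (one id per line), or a dense tab-separated matrix
#' (genes in rows, no header). Row/column order on disk is preserved exactly.
#'
#' @param path_matrix path to the \code{.mtx} or dense TSV matrix file.
#' @param path_genes path to the gene id file, one id per line.
#' @param path_cells path to the cell id file, one id per line.
#' @param labels optional per-cell phenotype labels: either a character vector
#'   (in cell-file order) or a path to a two-column TSV (cell_id, label).
#' @param layer layer tag of the stored values (\code{"counts"} or
#'   \code{"lognorm"}).
#' @return An \code{\link{expression_matrix}}.
#' @export
read_expression <- function(path_matrix, path_genes, path_cells,
                            labels = NULL, layer = "counts") {
  gene_ids <- read_id_file(path_genes)
  cell_ids <- read_id_file(path_cells)
  first <- readLines(path_matrix, n = 1L)
  if (startsWith(first, "%%MatrixMarket")) {
    m <- as.matrix(Matrix::readMM(path_matrix))
  } else {
    m <- as.matrix(utils::read.table(path_matrix, sep = "\t", header = FALSE))
    colnames(m) <- NULL
  }
  if (nrow(m) != length(gene_ids) || ncol(m) != length(cell_ids))
    stop(sprintf("matrix is %d x %d but id files declare %d genes and %d cells",
                 nrow(m), ncol(m), length(gene_ids), length(cell_ids)),
         call. = FALSE)
  if (!is.null(labels) && length(labels) == 1L && file.exists(labels)) {
    lab_df <- utils::read.table(labels, sep = "\t", header = FALSE,
                                col.names = c("cell_id", "label"),
                                colClasses = "character")
    miss <- setdiff(cell_ids, lab_df$cell_id)
    if (length(miss))
      stop("label file missing cells: ", paste(miss, collapse = ", "),
           call. = FALSE)
    labels <- lab_df$label[match(cell_ids, lab_df$cell_id)]
  }
  expression_matrix(m, gene_ids, cell_ids, cell_labels = labels, layer = layer)
}

read_id_file <- function(path) {
  ids <- readLines(path)
  ids <- ids[nzchar(ids)]
  if (anyDuplicated(ids))
    stop("duplicate ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  ids
}

#' Write an expression matrix to disk
#'
#' Counts layers round-trip exactly; log-normalised values round-trip to the
#' printed precision of the MatrixMarket writer.
#'
#' @param x an \code{ExpressionMatrix}.
#' @param path_matrix output \code{.mtx} path.
#' @param path_genes,path_cells output id file paths.
#' @param path_labels optional output path for a two-column cell/label TSV;
#'   ignored when the matrix carries no labels.
#' @return Invisibly, \code{x}.
#' @export
write_expression <- function(x, path_matrix, path_genes, path_cells,
                             path_labels = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  Matrix::writeMM(Matrix::Matrix(x$values, sparse = TRUE), path_matrix)
  writeLines(x$gene_ids, path_genes)
  writeLines(x$cell_ids, path_cells)
  if (!is.null(path_labels) && !is.null(x$cell_labels))
    utils::write.table(data.frame(cell_id = x$cell_ids, label = x$cell_labels),
                       path_labels, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(x)
}

#' Read a flow-cytometry event table
#'
#' Delimited text with a header row naming the parameters; comma-separated for
#' \code{.csv}, tab-separated otherwise. Rows are kept in file order. The
#' schema declares which header columns are instrument parameters and their
#' kind; columns not named in the schema, the population column or the cell id
#' column are rejected if referenced and ignored otherwise.
#'
#' @param path input CSV/TSV path.
#' @param kinds named character vector mapping parameter columns to
#'   \code{"fluorescent"} or \code{"scatter"}.
#' @param population_col name of the population label column.
#' @param cell_id_col optional name of a cell id column (index-sorted tables).
#' @return An \code{\link{event_table}}.
#' @export
read_events <- function(path, kinds, population_col = "population",
                        cell_id_col = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character")
  need <- c(names(kinds), population_col, cell_id_col)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("columns declared in schema but absent from header: ",
         paste(miss, collapse = ", "), call. = FALSE)
  rows <- sapply(names(kinds), function(p) {
    v <- suppressWarnings(as.numeric(df[[p]]))
    if (anyNA(v))
      stop("non-numeric value in parameter column '", p, "'", call. = FALSE)
    v
  })
  if (nrow(df) == 1L) rows <- matrix(rows, nrow = 1L,
                                     dimnames = list(NULL, names(kinds)))
  event_table(rows, kinds, population = df[[population_col]],
              cell_ids = if (!is.null(cell_id_col)) df[[cell_id_col]])
}

#' Write a flow-cytometry event table
#'
#' Column order is stable: cell id (if present), parameters in table order,
#' then the population column.
#'
#' @param x an \code{EventTable}.
#' @param path output path; comma-separated for \code{.csv}, tab otherwise.
#' @return Invisibly, \code{x}.
#' @export
write_events <- function(x, path) {
  stopifnot(inherits(x, "EventTable"))
  df <- as.data.frame(x$rows, check.names = FALSE)
  df$population <- x$population
  if (!is.null(x$cell_ids)) df <- cbind(cell_id = x$cell_ids, df)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Read a gene signature list
#'
#' Plain text, one gene per line; \code{#} starts a comment; duplicates are
#' collapsed. The result is an order-free set.
#'
#' @param path input path.
#' @param name signature name; defaults to the file name without extension.
#' @return A \code{\link{signature_list}}.
#' @export
read_signature <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    stop("signature file ", path, " contains no genes after comment stripping",
         call. = FALSE)
  signature_list(name, lines)
}

#' Write a gene signature list
#'
#' @param x a \code{SignatureList}.
#' @param path output path.
#' @return Invisibly, \code{x}.
#' @export
write_signature <- function(x, path) {
  stopifnot(inherits(x, "SignatureList"))
  writeLines(c(paste("#", x$name), x$genes), path)
  invisible(x)
}
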