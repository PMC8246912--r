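#' Flow-cytometry event table
#'
#' One row per recorded event (or index-sorted cell), one column per
#' instrument parameter. Every parameter carries a kind flag distinguishing
#' fluorescence channels (log-transformed during preprocessing) from light
#' scatter channels (kept linear). Each event belongs to a named population;
#' index-sorted tables additionally carry per-row cell identifiers that link
#' events to transcriptomes or colony outcomes.
#'
#' @param rows numeric matrix of events x parameters; column names are the
#'   parameter names.
#' @param kinds named character vector mapping every parameter name to
#'   \code{"fluorescent"} or \code{"scatter"}.
#' @param population character vector of population labels, one per event.
#' @param cell_ids optional character vector of unique per-event cell ids
#'   (index-sorted tables).
#'
#' @return An object of class \code{"EventTable"}.
#' @export
event_table <- function(rows, kinds, population, cell_ids = NULL) {
  rows <- as.matrix(rows)
  storage.mode(rows) <- "double"
  pn <- colnames(rows)
  if (is.null(pn)) stop("event rows must have parameter column names", call. = FALSE)
  if (anyDuplicated(pn)) stop("duplicate parameter names", call. = FALSE)
  if (is.null(names(kinds)) || !setequal(names(kinds), pn))
    stop("kinds must be a named vector covering exactly the parameters: ",
         paste(pn, collapse = ", "), call. = FALSE)
  kinds <- kinds[pn]
  if (!all(kinds %in% c("fluorescent", "scatter")))
    stop("parameter kinds must be 'fluorescent' or 'scatter'", call. = FALSE)
  population <- as.character(population)
  if (length(population) != nrow(rows))
    stop("population labels must have one entry per event", call. = FALSE)
  if (!is.null(cell_ids)) {
    cell_ids <- as.character(cell_ids)
    if (length(cell_ids) != nrow(rows))
      stop("cell_ids must have one entry per event", call. = FALSE)
    if (anyDuplicated(cell_ids))
      stop("duplicate cell ids in event table", call. = FALSE)
  }
  structure(list(rows = rows, parameter_names = pn, kinds = kinds,
                 population = population, cell_ids = cell_ids),
            class = "EventTable")
}

#' @export
print.EventTable <- function(x, ...) {
  cat(sprintf("EventTable: %d events x %d parameters (%d fluorescent, %d scatter)\n",
              nrow(x$rows), ncol(x$rows),
              sum(x$kinds == "fluorescent"), sum(x$kinds == "scatter")))
  tab <- table(x$population)
  cat("populations:", paste(sprintf("%s (%d)", names(tab), tab),
                            collapse = ", "), "\n")
  if (!is.null(x$cell_ids)) cat("index-sorted: per-event cell ids present\n")
  invisible(x)
}

#' @export
dim.EventTable <- function(x) dim(x$rows)

#' Subset an EventTable by event rows
#'
#' @param x an \code{EventTable}.
#' @param i integer or logical row index.
#' @return The \code{EventTable} restricted to the selected events, order
#'   preserved as given by \code{i}.
#' @export
subset_events <- function(x, i) {
  stopifnot(inherits(x, "EventTable"))
  event_table(x$rows[i, , drop = FALSE], x$kinds, x$population[i],
              cell_ids = if (!is.null(x$cell_ids)) x$cell_ids[i])
}

#' Gene signature list
#'
#' A named, duplicate-free set of gene identifiers, e.g. basophil or mast-cell
#' signature genes, or the S/G2M phase marker lists used for cell-cycle
#' scoring.
#'
#' @param name signature name.
#' @param genes character vector of gene ids; duplicates are removed.
#' @return An object of class \code{"SignatureList"}.
#' @export
signature_list <- function(name, genes) {
  genes <- unique(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("signature '", name, "' is empty", call. = FALSE)
  structure(list(name = as.character(name), genes = genes),
            class = "SignatureList")
}

#' @export
print.SignatureList <- function(x, ...) {
  cat(sprintf("SignatureList '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}
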