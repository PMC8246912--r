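#' Neighbor frequency score of reference cells for a projected query set
#'
#' For every query cell (projected into the reference PCA space with
#' \code{\link{project_pca}}), its k nearest reference cells are found by
#' Euclidean distance in component space, with ties broken by reference cell
#' id. Each reference cell's score is the number of query cells listing it
#' among their k nearest, normalised by the number of query cells. High
#' scores mark the reference cells most similar to the query population —
#' e.g. the cells of a tissue dataset closest to projected bone-marrow
#' progenitors.
#'
#' @param reference matrix of reference scores (cells x components), row
#'   names = reference cell ids.
#' @param query matrix of projected query scores in the same component space.
#' @param k neighborhood size (default 10).
#' @return A data frame: \code{reference_cell_id}, \code{count} (raw
#'   appearances; sums to k x n_query), \code{score} (count / n_query),
#'   with attribute \code{k}.
#' @export
knn_frequency_score <- function(reference, query, k = 10) {
  reference <- as.matrix(reference)
  query <- as.matrix(query)
  n_ref <- nrow(reference)
  if (k > n_ref) stop("k exceeds the number of reference cells", call. = FALSE)
  ref_ids <- rownames(reference) %||% as.character(seq_len(n_ref))
  count <- integer(n_ref)
  for (i in seq_len(nrow(query))) {
    d <- sqrt(colSums((t(reference) - query[i, ])^2))
    nn <- order(d, ref_ids)[seq_len(k)]
    count[nn] <- count[nn] + 1L
  }
  out <- data.frame(reference_cell_id = ref_ids, count = count,
                    score = count / nrow(query), stringsAsFactors = FALSE)
  attr(out, "k") <- k
  out
}

#' Hypergeometric test for the overlap of two gene lists
#'
#' Upper-tail exact test: the probability of observing at least the given
#' overlap when \code{length(list_a)} genes are drawn without replacement
#' from a universe containing \code{length(list_b)} "successes". Computed in
#' log space via the hypergeometric distribution function, so extreme
#' enrichments (p below 1e-300 on large universes) are handled.
#'
#' @param list_a,list_b character vectors of gene ids; must be subsets of
#'   \code{universe}.
#' @param universe character vector defining the gene universe (typically the
#'   genes expressed in the analysed matrix).
#' @return A list of class \code{"OverlapResult"}: \code{n_universe},
#'   \code{n_list_a}, \code{n_list_b}, \code{n_overlap}, \code{p}.
#' @export
hypergeometric_overlap <- function(list_a, list_b, universe) {
  universe <- unique(as.character(universe))
  list_a <- unique(as.character(list_a))
  list_b <- unique(as.character(list_b))
  bad <- c(setdiff(list_a, universe), setdiff(list_b, universe))
  if (length(bad))
    stop("gene(s) outside the universe: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  n_u <- length(universe)
  n_a <- length(list_a)
  n_b <- length(list_b)
  n_ov <- length(intersect(list_a, list_b))
  p <- if (n_ov == 0) 1 else
    exp(stats::phyper(n_ov - 1, n_b, n_u - n_b, n_a, lower.tail = FALSE,
                      log.p = TRUE))
  structure(list(n_universe = n_u, n_list_a = n_a, n_list_b = n_b,
                 n_overlap = n_ov, p = p),
            class = "OverlapResult")
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat(sprintf(
    "OverlapResult: %d/%d vs %d in universe %d; overlap %d; p = %.3g\n",
    x$n_list_a, x$n_universe, x$n_list_b, x$n_universe, x$n_overlap, x$p))
  invisible(x)
}
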