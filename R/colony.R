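#' Default basophil / mast-cell flow gates
#'
#' Axis-aligned regions over the c-Kit, FceRI and CD49b intensities: the
#' basophil gate is c-Kit low, FceRI high, CD49b high; the mast-cell gate is
#' c-Kit high, FceRI high. Intensities are on instrument scale.
#'
#' @return A named list of gates, each a named list of \code{c(lo, hi)}
#'   ranges per parameter.
#' @export
colony_gates <- function() {
  list(Ba = list(cKit = c(0, 100), FceRI = c(1000, Inf), CD49b = c(1000, Inf)),
       MC = list(cKit = c(1000, Inf), FceRI = c(1000, Inf)))
}

#' Classify one cultured colony from its flow events
#'
#' Applies the colony rules: a colony is classified only when it yields at
#' least \code{min_events} live events, and a lineage is called only when at
#' least \code{min_gate_events} live events fall inside that lineage's gate.
#' Colonies with both lineages called are mixed. Colony size defaults to the
#' live event count and is set to 1 when no live cells were observed.
#'
#' @param events the colony's \code{\link{event_table}}; events with
#'   population \code{"dead"} are excluded as non-viable.
#' @param gates gate definitions as in \code{\link{colony_gates}}.
#' @param min_events minimum live events for classification (default 20).
#' @param min_gate_events minimum in-gate events for a lineage call
#'   (default 5).
#' @param colony_id colony identifier.
#' @param origin_cell_id optional id of the index-sorted founding cell.
#' @param size optional visually determined colony size; defaults to the
#'   live event count (minimum 1).
#' @return A list of class \code{"ColonyRecord"}: \code{colony_id},
#'   \code{origin_cell_id}, \code{size}, \code{n_live_events},
#'   \code{gate_counts}, \code{lineage_calls}, \code{classified},
#'   \code{type} (\code{"Ba"}, \code{"MC"}, \code{"mixed"}, \code{"none"},
#'   or NA when unclassified).
#' @export
classify_colony <- function(events, gates = colony_gates(), min_events = 20,
                            min_gate_events = 5, colony_id = "colony",
                            origin_cell_id = NULL, size = NULL) {
  stopifnot(inherits(events, "EventTable"))
  for (g in names(gates)) {
    bad <- setdiff(names(gates[[g]]), events$parameter_names)
    if (length(bad))
      stop("gate '", g, "' references unknown parameter(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  live <- events$population != "dead"
  n_live <- sum(live)
  rows <- events$rows[live, , drop = FALSE]
  gate_counts <- vapply(gates, function(gate) {
    inside <- rep(TRUE, nrow(rows))
    for (p in names(gate))
      inside <- inside & rows[, p] >= gate[[p]][1] & rows[, p] <= gate[[p]][2]
    sum(inside)
  }, integer(1))
  classified <- n_live >= min_events
  calls <- if (classified) names(gates)[gate_counts >= min_gate_events]
           else character(0)
  type <- if (!classified) NA_character_
          else if (length(calls) >= 2) "mixed"
          else if (length(calls) == 1) calls
          else "none"
  size <- as.integer(size %||% max(n_live, 1L))
  if (size < 1) stop("colony size must be at least 1", call. = FALSE)
  structure(list(colony_id = colony_id, origin_cell_id = origin_cell_id,
                 size = size, n_live_events = n_live,
                 gate_counts = gate_counts, lineage_calls = calls,
                 classified = classified, type = type),
            class = "ColonyRecord")
}

#' @export
print.ColonyRecord <- function(x, ...) {
  cat(sprintf("ColonyRecord %s: size %d, %d live events, %s\n",
              x$colony_id, x$size, x$n_live_events,
              if (!x$classified) "unclassified" else paste("type", x$type)))
  invisible(x)
}

#' Summarise colony type output per founding population
#'
#' Among classified colonies, computes the fraction of each colony type
#' (Ba-only, MC-only, mixed, none) per founding population within each
#' experiment replicate, then the mean and SEM of those fractions across
#' replicates. Populations without any classified colony are omitted (missing,
#' not zero).
#'
#' @param records list of \code{ColonyRecord}s.
#' @param populations character vector: founding population per record.
#' @param experiments character/integer vector: replicate id per record
#'   (default: one experiment).
#' @return A data frame: \code{population}, \code{type}, \code{mean_fraction},
#'   \code{sem} (NA with a single replicate), \code{n_experiments}.
#' @export
summarize_colony_output <- function(records, populations,
                                    experiments = NULL) {
  stopifnot(length(records) == length(populations))
  experiments <- experiments %||% rep("expt1", length(records))
  cls <- vapply(records, `[[`, logical(1), "classified")
  if (!any(cls)) stop("no classified colony", call. = FALSE)
  type <- vapply(records, function(r) r$type %||% NA_character_,
                 character(1))
  df <- data.frame(population = populations, experiment = experiments,
                   type = type, stringsAsFactors = FALSE)[cls, ]
  types <- c("Ba", "MC", "mixed", "none")
  out <- do.call(rbind, lapply(split(df, df$population), function(d) {
    frac <- t(sapply(split(d$type, d$experiment), function(tt)
      vapply(types, function(ty) mean(tt == ty), numeric(1))))
    n <- nrow(frac)
    data.frame(population = d$population[1], type = types,
               mean_fraction = colMeans(frac),
               sem = if (n > 1) apply(frac, 2, stats::sd) / sqrt(n)
                     else NA_real_,
               n_experiments = n, row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Overlay colony outcomes on a reference PCA embedding
#'
#' Projects the index-sorted founding cells of the colonies into a fitted
#' reference PCA space and joins each projected cell with its colony outcome
#' and log10 colony size — the data behind overlay plots of colony fate on
#' the reference landscape.
#'
#' @param model a \code{PCAModel} fitted on the reference events.
#' @param index_events index-sorted \code{\link{event_table}} (with cell ids)
#'   of the founding cells.
#' @param records list of \code{ColonyRecord}s whose \code{origin_cell_id}s
#'   match \code{index_events} cell ids.
#' @return A data frame: \code{colony_id}, the PC score columns,
#'   \code{log10_size}, \code{type}, \code{classified}; one row per colony.
#' @export
overlay_colonies <- function(model, index_events, records) {
  stopifnot(inherits(index_events, "EventTable"))
  if (is.null(index_events$cell_ids))
    stop("index event table lacks cell ids", call. = FALSE)
  origins <- vapply(records, function(r) r$origin_cell_id %||% NA_character_,
                    character(1))
  miss <- setdiff(origins, index_events$cell_ids)
  if (length(miss) || anyNA(origins))
    stop("colony origin cell(s) not in index table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  scores <- project_pca(model, index_events)
  idx <- match(origins, index_events$cell_ids)
  data.frame(colony_id = vapply(records, `[[`, character(1), "colony_id"),
             scores[idx, , drop = FALSE],
             log10_size = log10(vapply(records, function(r)
               as.numeric(r$size), numeric(1))),
             type = vapply(records, function(r) r$type %||% NA_character_,
                           character(1)),
             classified = vapply(records, `[[`, logical(1), "classified"),
             row.names = NULL, stringsAsFactors = FALSE)
}
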