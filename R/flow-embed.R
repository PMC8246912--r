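#' Preprocess flow-cytometry events for embedding
#'
#' Applies the standard event-table preprocessing chain, in this order:
#' down-sample every population without replacement to the size of the
#' smallest population; remove exact duplicate rows; log10(x + 1)-transform
#' fluorescent parameters (scatter parameters stay linear); z-score every
#' column to mean 0, sd 1.
#'
#' @param events an \code{\link{event_table}} with at least 2 populations.
#' @param seed integer seed used for the down-sampling draw.
#' @return A list: \code{matrix} (retained events x parameters, transformed
#'   and z-scored), \code{kept} (row indices into \code{events}, ascending),
#'   \code{events} (the retained subset of the input table, untransformed).
#' @export
preprocess_events <- function(events, seed = 1L) {
  stopifnot(inherits(events, "EventTable"))
  tab <- table(events$population)
  if (length(tab) < 2) stop("need at least 2 populations", call. = FALSE)
  if (any(tab == 0)) stop("population with 0 events", call. = FALSE)
  n_min <- min(tab)
  kept <- with_seed(seed, {
    unlist(lapply(names(tab), function(p) {
      idx <- which(events$population == p)
      if (length(idx) > n_min) sort(sample(idx, n_min)) else idx
    }))
  })
  kept <- sort(kept)
  rows <- events$rows[kept, , drop = FALSE]
  dup <- duplicated(rows)
  kept <- kept[!dup]
  rows <- rows[!dup, , drop = FALSE]
  m <- transform_event_rows(rows, events$kinds)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s) after deduplication: ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  m <- scale(m)
  attr(m, "scaled:center") <- NULL
  attr(m, "scaled:scale") <- NULL
  list(matrix = m, kept = kept, events = subset_events(events, kept))
}

# log10(x+1) on fluorescent columns, linear on scatter
transform_event_rows <- function(rows, kinds) {
  fl <- names(kinds)[kinds == "fluorescent"]
  fl <- intersect(fl, colnames(rows))
  rows[, fl] <- log10(rows[, fl, drop = FALSE] + 1)
  rows
}

#' Fit a centered-and-scaled PCA
#'
#' PCA of the column-standardised data (correlation-matrix PCA), with a fixed
#' sign convention — the largest-magnitude entry of each loading column is
#' positive — so embeddings are reproducible across runs and platforms. When
#' given an \code{EventTable}, fluorescent parameters are log10(x + 1)
#' transformed first and the transform is remembered by the model, so that
#' \code{\link{project_pca}} can map raw query events into the fitted space.
#'
#' @param x numeric matrix (observations x variables) or an
#'   \code{\link{event_table}}.
#' @param n_components number of components to retain (default: full rank).
#' @return A list of class \code{"PCAModel"} (\code{parameter_means},
#'   \code{parameter_sds}, \code{loadings}, \code{explained_variance},
#'   \code{log_transform}, \code{kinds}) with the training \code{scores}
#'   attached.
#' @export
fit_pca <- function(x, n_components = NULL) {
  kinds <- NULL
  if (inherits(x, "EventTable")) {
    kinds <- x$kinds
    x <- transform_event_rows(x$rows, kinds)
  }
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 observations", call. = FALSE)
  full <- min(nrow(x) - 1, ncol(x))
  if (is.null(n_components)) n_components <- full
  if (n_components > full)
    stop("n_components exceeds min(rows - 1, columns) = ", full, call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  load <- pc$rotation[, seq_len(n_components), drop = FALSE]
  # sign convention: largest-magnitude loading entry positive
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  load <- sweep(load, 2, flip, `*`)
  z <- scale(x, center = pc$center, scale = pc$scale)
  scores <- z %*% load
  colnames(scores) <- colnames(load) <- paste0("PC", seq_len(n_components))
  model <- structure(list(parameter_means = pc$center,
                          parameter_sds = pc$scale,
                          loadings = load,
                          explained_variance = pc$sdev[seq_len(n_components)]^2,
                          log_transform = !is.null(kinds),
                          kinds = kinds,
                          scores = scores),
                     class = "PCAModel")
  model
}

#' @export
print.PCAModel <- function(x, ...) {
  ev <- x$explained_variance
  cat(sprintf("PCAModel: %d parameters, %d components\n",
              nrow(x$loadings), ncol(x$loadings)))
  cat("variance explained:",
      paste(sprintf("%.1f%%", 100 * ev / length(x$parameter_means)),
            collapse = " "), "\n")
  invisible(x)
}

#' Project new observations into a fitted PCA space
#'
#' Query rows are run through the model's stored transform — the training log
#' rules (for event tables), training means and training sds — and multiplied
#' by the loadings. Projecting the training data reproduces the training
#' scores exactly.
#'
#' @param model a \code{PCAModel} from \code{\link{fit_pca}}.
#' @param query an \code{\link{event_table}}, or a matrix / data frame whose
#'   columns include the model's training parameters.
#' @return Score matrix (query rows x components).
#' @export
project_pca <- function(model, query) {
  stopifnot(inherits(model, "PCAModel"))
  if (inherits(query, "EventTable")) {
    rows <- query$rows
    if (model$log_transform) rows <- transform_event_rows(rows, query$kinds)
  } else {
    rows <- as.matrix(query)
    if (model$log_transform && !is.null(model$kinds))
      rows <- transform_event_rows(rows, model$kinds)
  }
  pars <- names(model$parameter_means)
  miss <- setdiff(pars, colnames(rows))
  if (length(miss))
    stop("query missing parameter column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  z <- scale(rows[, pars, drop = FALSE], center = model$parameter_means,
             scale = model$parameter_sds)
  s <- z %*% model$loadings
  rownames(s) <- rownames(rows)
  s
}

#' Fit a diffusion map with an adaptive Gaussian kernel
#'
#' Spectral embedding of the k-nearest-neighbor graph: per-point bandwidths
#' equal to the distance to the \code{n_neighbors}-th neighbor; Gaussian
#' kernel \eqn{\exp(-d_{ij}^2 / (\sigma_i \sigma_j))} on the symmetrised kNN
#' graph; anisotropic (alpha = 1) density normalisation, removing sampling-
#' density effects; row-normalisation to a Markov transition matrix; and
#' eigendecomposition via the symmetric conjugate. The trivial constant
#' eigenvector (eigenvalue 1) is dropped and the remaining eigenvectors,
#' scaled by their eigenvalues, form the diffusion components. Each
#' component's largest-magnitude entry is made positive.
#'
#' @param x numeric matrix (observations x variables), typically the output
#'   of \code{\link{preprocess_events}} or a standardised expression matrix.
#' @param n_dcs number of diffusion components to retain (default 10).
#' @param n_neighbors kNN graph size / bandwidth rank (default 30).
#' @return A list of class \code{"DiffusionModel"}: \code{kernel_bandwidths},
#'   \code{eigenvalues} (magnitude-sorted, trivial pair dropped),
#'   \code{components} (observations x n_dcs), \code{stationary} (the Markov
#'   chain's stationary weights), \code{cell_ids}.
#' @export
fit_diffusion_map <- function(x, n_dcs = 10, n_neighbors = 30) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n <= n_neighbors)
    stop("need more observations than n_neighbors", call. = FALSE)
  d2 <- as.matrix(stats::dist(x))^2
  # bandwidth = distance to the n_neighbors-th neighbor
  sigma <- apply(d2, 1, function(r) sqrt(sort(r[-which.min(r)])[n_neighbors]))
  sigma <- pmax(sigma, .Machine$double.eps)
  nn <- apply(d2, 1, function(r) order(r)[2:(n_neighbors + 1)])
  adj <- matrix(FALSE, n, n)
  adj[cbind(rep(seq_len(n), each = n_neighbors), as.vector(nn))] <- TRUE
  adj <- adj | t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  if (igraph::components(g)$no > 1)
    stop("kNN graph is disconnected; raise n_neighbors", call. = FALSE)
  K <- exp(-d2 / outer(sigma, sigma))
  K[!adj] <- 0
  diag(K) <- 1
  q <- rowSums(K)
  W <- K / outer(q, q)          # alpha = 1 density normalisation
  dd <- rowSums(W)
  S <- W / sqrt(outer(dd, dd))  # symmetric conjugate of the Markov matrix
  es <- eigen(S, symmetric = TRUE)
  ord <- order(abs(es$values), decreasing = TRUE)
  vals <- es$values[ord]
  vecs <- es$vectors[, ord, drop = FALSE]
  if (n_dcs > n - 1) stop("n_dcs must be below the number of observations",
                          call. = FALSE)
  keep <- 2:(n_dcs + 1)
  psi <- vecs[, keep, drop = FALSE] / sqrt(dd)
  comps <- sweep(psi, 2, vals[keep], `*`)
  flip <- apply(comps, 2, function(v) sign(v[which.max(abs(v))]))
  comps <- sweep(comps, 2, flip, `*`)
  colnames(comps) <- paste0("DC", seq_len(n_dcs))
  rownames(comps) <- rownames(x)
  structure(list(kernel_bandwidths = sigma,
                 eigenvalues = vals[keep],
                 components = comps,
                 stationary = dd / sum(dd),
                 trivial_eigenvalue = vals[1],
                 n_neighbors = n_neighbors,
                 cell_ids = rownames(x)),
            class = "DiffusionModel")
}

#' @export
print.DiffusionModel <- function(x, ...) {
  cat(sprintf("DiffusionModel: %d observations, %d components, eigenvalues %s\n",
              nrow(x$components), ncol(x$components),
              paste(sprintf("%.3f", utils::head(x$eigenvalues, 4)),
                    collapse = " ")))
  invisible(x)
}
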