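# Small in-code fixtures shared across test files.

tiny_expression <- function(layer = "counts") {
  m <- matrix(c(4, 0, 1, 0,
                0, 2, 0, 3,
                1, 1, 1, 1), nrow = 3, byrow = TRUE)
  expression_matrix(m, paste0("g", 1:3), paste0("c", 1:4),
                    cell_labels = c("A", "A", "B", "B"), layer = layer)
}

tiny_events <- function(n = 6) {
  rows <- cbind(FL1 = 10^seq(1, 2, length.out = n),
                FL2 = 10^seq(2, 1, length.out = n),
                SC1 = seq(100, 200, length.out = n))
  event_table(rows,
              kinds = c(FL1 = "fluorescent", FL2 = "fluorescent",
                        SC1 = "scatter"),
              population = rep(c("P", "Q"), length.out = n),
              cell_ids = sprintf("ev%02d", seq_len(n)))
}

# deterministic pseudotime over n cells, ids in scrambled order
tiny_pt <- function(n = 10) {
  ids <- sprintf("c%02d", seq_len(n))
  pseudotime_ordering(ids, seq_len(n), method = "pc1",
                      orientation_markers = "g1")
}

# default-parameter simulation restricted to one trajectory, normalised;
# cached per seed so several test files can share it cheaply
sim_trajectory <- local({
  cache <- list()
  function(seed = 7) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      sim <- simulate_bifurcating_expression(sim_params(seed = seed))
      sel <- trajectory_cells(sim$truth, "A")
      ln <- normalize_log(subset_expression(sim$expression,
                                            cells = which(sel)))
      cache[[key]] <<- list(sim = sim, sel = sel, lognorm = ln,
                            latent = sim$truth$latent_time[sel])
    }
    cache[[key]]
  }
})

orientation_genes_of <- function(sim, n = 5) {
  sim$truth$gene_ids[sim$truth$gene_class == "down"][seq_len(n)]
}

# compact simulation for end-to-end pipeline tests: small enough to run the
# full permutation machinery in seconds, large enough that the BH threshold
# is attainable (60 planted monotone genes among 400)
sim_small <- function(seed = 5) {
  simulate_bifurcating_expression(
    sim_params(n_cells = 150, n_genes = 400, frac_dynamic = 0.15,
               seed = seed))
}

# restrict an index-sort table to the cells of an expression matrix
index_for <- function(truth, em, seed = 1) {
  idx <- simulate_index_sort(truth, seed = seed)
  subset_events(idx, match(em$cell_ids, idx$cell_ids))
}

dir_bytes <- function(dir) {
  fs <- sort(list.files(dir, recursive = TRUE))
  setNames(lapply(fs, function(f)
    readBin(file.path(dir, f), "raw", file.size(file.path(dir, f)))), fs)
}
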