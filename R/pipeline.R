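#' Resolved parameter set for the analysis pipelines
#'
#' Collects every stage parameter with the analysis defaults: smoothing
#' window 20, dynamic-gene threshold adjusted p < 0.01, 10-nearest-neighbor
#' projection scoring, and the colony rules (20 live events to classify,
#' 5 in-gate events to call a lineage). The resolved configuration is written
#' next to every pipeline's outputs.
#'
#' @param window sliding-window size (default 20).
#' @param alpha BH-adjusted p threshold for dynamic genes and DE calls
#'   (default 0.01).
#' @param k projection neighborhood size (default 10).
#' @param n_perm permutations for the dynamic-gene test (default 1000).
#' @param n_dcs diffusion components (default 10).
#' @param n_neighbors kNN size for the diffusion kernel (default 30).
#' @param n_pcs PCA components for expression embeddings (default 10).
#' @param n_hvg highly variable genes entering PCA (default 2000).
#' @param min_events,min_gate_events colony classification rules
#'   (defaults 20 and 5).
#' @param seed global integer seed; stage sub-seeds derive from it.
#' @param out_dir output directory, or NULL to skip writing.
#' @return A list of class \code{"PipelineConfig"}.
#' @export
pipeline_config <- function(window = 20, alpha = 0.01, k = 10, n_perm = 1000,
                            n_dcs = 10, n_neighbors = 30, n_pcs = 10,
                            n_hvg = 2000, min_events = 20,
                            min_gate_events = 5, seed = 1L, out_dir = NULL) {
  structure(list(window = window, alpha = alpha, k = k, n_perm = n_perm,
                 n_dcs = n_dcs, n_neighbors = n_neighbors, n_pcs = n_pcs,
                 n_hvg = n_hvg, min_events = min_events,
                 min_gate_events = min_gate_events, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "PipelineConfig")
}

write_tsv_out <- function(df, dir, name, manifest) {
  if (is.null(dir)) return(manifest)
  path <- file.path(dir, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  c(manifest, name)
}

finish_manifest <- function(cfg, files, pipeline) {
  if (is.null(cfg$out_dir)) return(invisible(NULL))
  meta <- list(pipeline = pipeline,
               package_version = as.character(utils::packageVersion("lineagetrace")),
               seed = cfg$seed,
               parameters = cfg[setdiff(names(cfg), "out_dir")],
               files = files)
  jsonlite::write_json(meta, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

stage_msg <- function(stage, ...) message("[", stage, "] ", ...)

# z-scored cells x genes matrix over dispersion-ranked variable genes,
# shared by the expression PCA stages
hvg_cell_matrix <- function(lognorm, n_hvg) {
  v <- lognorm$values
  gv <- apply(v, 1, stats::var)
  gm <- rowMeans(v)
  disp <- ifelse(gm > 0, gv / gm, 0)
  keep <- which(gv > 0)
  keep <- keep[order(disp[keep], decreasing = TRUE)]
  keep <- keep[seq_len(min(n_hvg, length(keep)))]
  t(v[keep, , drop = FALSE])
}

cluster_direction <- function(profiles, clusters) {
  vapply(sort(unique(clusters)), function(cl) {
    m <- colMeans(profiles[clusters == cl, , drop = FALSE])
    if (stats::cor(m, seq_along(m)) > 0) "increasing" else "decreasing"
  }, character(1))
}

#' Run the bone-marrow basophil differentiation analysis
#'
#' The full progenitor-to-basophil sequence on one expression dataset:
#' normalisation; Welch + BH differential expression between the two sorting
#' phenotypes; optional cell-cycle scoring and phase assignment; PC1
#' pseudotime oriented by progenitor-marker loss; surface-marker/pseudotime
#' correlations from the index-sort table; the sliding-window permutation
#' test for dynamic genes with Louvain clustering of their profiles; and
#' hypergeometric overlaps of the dynamic clusters with supplied signatures.
#'
#' @param expression counts-layer \code{ExpressionMatrix} with cell labels.
#' @param groups length-2 character vector naming the two phenotypes to
#'   contrast (a, b); DE direction is relative to the second.
#' @param orientation_genes genes whose expression must decrease along
#'   pseudotime (progenitor markers).
#' @param index optional index-sorted \code{EventTable}; marker stages are
#'   skipped gracefully when absent.
#' @param cc_signatures optional list with \code{SignatureList}s \code{s} and
#'   \code{g2m}; cell-cycle stages are skipped when NULL.
#' @param signatures optional named list of \code{SignatureList}s to test for
#'   overlap against each dynamic-gene cluster.
#' @param config a \code{\link{pipeline_config}}.
#' @return Invisibly, a list with \code{de}, \code{cell_cycle},
#'   \code{pseudotime}, \code{marker_correlations}, \code{dynamic_genes},
#'   \code{profiles}, \code{composition}, \code{overlaps},
#'   \code{cluster_direction}. TSV artifacts and a manifest are written to
#'   \code{config$out_dir} when set.
#' @export
run_basophil_pipeline <- function(expression, groups, orientation_genes,
                                  index = NULL, cc_signatures = NULL,
                                  signatures = NULL,
                                  config = pipeline_config()) {
  cfg <- config
  if (!is.null(cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  stage_msg("normalize", length(expression$gene_ids), " genes x ",
            length(expression$cell_ids), " cells")
  ln <- normalize_log(expression)

  stage_msg("de", "contrast ", groups[1], " vs ", groups[2])
  de <- differential_expression(ln, groups[1], groups[2], alpha = cfg$alpha)
  files <- write_tsv_out(de, cfg$out_dir, "de.tsv", files)

  cc <- NULL
  if (!is.null(cc_signatures)) {
    stage_msg("cell_cycle", "scoring S and G2M programs")
    s <- score_gene_set(ln, cc_signatures$s, seed = derive_seed(cfg$seed, 1))
    g2m <- score_gene_set(ln, cc_signatures$g2m, seed = derive_seed(cfg$seed, 2))
    cc <- assign_cell_cycle(s, g2m)
    files <- write_tsv_out(
      data.frame(cell_id = ln$cell_ids, label = ln$cell_labels,
                 s_score = s, g2m_score = g2m, phase = cc$phase),
      cfg$out_dir, "cell_cycle.tsv", files)
  }

  stage_msg("pseudotime", "PC1 over ", cfg$n_hvg, " variable genes")
  pt <- pc1_pseudotime(ln, orientation_genes, n_hvg = cfg$n_hvg)
  files <- write_tsv_out(
    data.frame(cell_id = pt$cell_ids, pseudotime = pt$pseudotime,
               method = pt$method),
    cfg$out_dir, "pseudotime.tsv", files)

  marker_cor <- NULL
  if (!is.null(index)) {
    stage_msg("markers", ncol(index$rows), " index parameters")
    lg <- transform_event_rows(index$rows, index$kinds)
    rownames(lg) <- index$cell_ids
    marker_cor <- data.frame(
      marker = colnames(lg),
      pearson_r = apply(lg[pt$cell_ids, , drop = FALSE], 2,
                        marker_pseudotime_correlation, pt = pt),
      row.names = NULL)
    files <- write_tsv_out(marker_cor, cfg$out_dir,
                           "marker_correlations.tsv", files)
  } else stage_msg("markers", "no index table; marker stages skipped")

  stage_msg("dynamics", "permutation test, n_perm = ", cfg$n_perm)
  dyn <- dynamic_gene_test(ln, pt, window = cfg$window, n_perm = cfg$n_perm,
                           alpha = cfg$alpha, seed = derive_seed(cfg$seed, 3))
  dyn_genes <- dyn$gene_id[dyn$is_dynamic]
  stage_msg("dynamics", length(dyn_genes), " dynamic genes at adjusted p < ",
            cfg$alpha)
  prof <- NULL
  dir_lab <- NULL
  if (length(dyn_genes) >= 2) {
    prof <- smoothed_profiles(ln, pt, genes = dyn_genes, window = cfg$window,
                              scaling = "zscore")
    cl <- cluster_dynamic_genes(prof, seed = derive_seed(cfg$seed, 4))
    dyn$cluster_id[match(names(cl), dyn$gene_id)] <- as.integer(cl)
    dir_lab <- cluster_direction(prof, cl)
    files <- write_tsv_out(
      data.frame(gene_id = rownames(prof), prof, check.names = FALSE),
      cfg$out_dir, "profiles.tsv", files)
  }
  files <- write_tsv_out(dyn, cfg$out_dir, "dynamic_genes.tsv", files)

  comp <- window_composition(stats::setNames(ln$cell_labels, ln$cell_ids),
                             pt, window = cfg$window)
  files <- write_tsv_out(data.frame(window = seq_len(nrow(comp)), comp,
                                    check.names = FALSE),
                         cfg$out_dir, "window_composition.tsv", files)

  overlaps <- NULL
  if (!is.null(signatures) && length(dyn_genes) >= 2) {
    universe <- ln$gene_ids[rowSums(ln$values > 0) >= 1]
    overlaps <- do.call(rbind, lapply(names(signatures), function(sn) {
      sig <- intersect(signatures[[sn]]$genes, universe)
      do.call(rbind, lapply(sort(unique(dyn$cluster_id[!is.na(dyn$cluster_id)])),
        function(cl) {
          ov <- hypergeometric_overlap(
            dyn$gene_id[!is.na(dyn$cluster_id) & dyn$cluster_id == cl],
            sig, universe)
          data.frame(signature = sn, cluster = cl,
                     direction = dir_lab[cl], n_overlap = ov$n_overlap,
                     p = ov$p, stringsAsFactors = FALSE)
        }))
    }))
    files <- write_tsv_out(overlaps, cfg$out_dir, "overlaps.tsv", files)
  }

  finish_manifest(cfg, files, "basophil")
  invisible(list(de = de, cell_cycle = cc, pseudotime = pt,
                 marker_correlations = marker_cor, dynamic_genes = dyn,
                 profiles = prof, composition = comp, overlaps = overlaps,
                 cluster_direction = dir_lab))
}

#' Run the peritoneal mast-cell differentiation analysis
#'
#' PCA of the tissue dataset; projection of a reference progenitor dataset
#' into that space with k-nearest-neighbor frequency scoring; root selection
#' at the most progenitor-like cell; diffusion map and diffusion pseudotime;
#' marker correlations; dynamic-gene detection and clustering; and max-scaled
#' profiles of requested genes (e.g. proteases) to read staged induction.
#'
#' @param expression counts-layer \code{ExpressionMatrix} of the tissue
#'   (e.g. peritoneal) cells, with labels.
#' @param query_expression counts-layer \code{ExpressionMatrix} of the
#'   reference progenitors to project (gene set must cover the tissue HVGs).
#' @param index optional index-sorted \code{EventTable}.
#' @param stage_genes optional gene ids whose max-scaled profiles are
#'   reported.
#' @param signatures optional named list of \code{SignatureList}s for
#'   cluster overlap tests.
#' @param config a \code{\link{pipeline_config}}.
#' @return Invisibly, a list with \code{pca}, \code{neighbor_scores},
#'   \code{root}, \code{pseudotime}, \code{marker_correlations},
#'   \code{dynamic_genes}, \code{profiles}, \code{staged_profiles},
#'   \code{overlaps}, \code{cluster_direction}.
#' @export
run_mastcell_pipeline <- function(expression, query_expression, index = NULL,
                                  stage_genes = NULL, signatures = NULL,
                                  config = pipeline_config()) {
  cfg <- config
  if (!is.null(cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  ln <- normalize_log(expression)
  cm <- hvg_cell_matrix(ln, cfg$n_hvg)
  stage_msg("pca", ncol(cm), " variable genes, ", cfg$n_pcs, " components")
  pca <- fit_pca(cm, n_components = min(cfg$n_pcs, ncol(cm),
                                        nrow(cm) - 1))

  qln <- normalize_log(query_expression)
  qmat <- t(qln$values[colnames(cm), , drop = FALSE])
  qscores <- project_pca(pca, qmat)
  stage_msg("projection", nrow(qscores), " query cells, k = ", cfg$k)
  nbs <- knn_frequency_score(pca$scores, qscores, k = cfg$k)
  files <- write_tsv_out(nbs, cfg$out_dir, "neighbor_scores.tsv", files)

  root <- select_root(ln$cell_ids,
                      stats::setNames(nbs$score, nbs$reference_cell_id))
  stage_msg("root", root)

  dm <- fit_diffusion_map(pca$scores, n_dcs = min(cfg$n_dcs, nrow(cm) - 2),
                          n_neighbors = cfg$n_neighbors)
  pt <- diffusion_pseudotime(dm, root)
  files <- write_tsv_out(
    data.frame(cell_id = pt$cell_ids, pseudotime = pt$pseudotime,
               method = pt$method, root = root),
    cfg$out_dir, "pseudotime.tsv", files)

  marker_cor <- NULL
  if (!is.null(index)) {
    lg <- transform_event_rows(index$rows, index$kinds)
    rownames(lg) <- index$cell_ids
    marker_cor <- data.frame(
      marker = colnames(lg),
      pearson_r = apply(lg[pt$cell_ids, , drop = FALSE], 2,
                        marker_pseudotime_correlation, pt = pt),
      row.names = NULL)
    files <- write_tsv_out(marker_cor, cfg$out_dir,
                           "marker_correlations.tsv", files)
  }

  dyn <- dynamic_gene_test(ln, pt, window = cfg$window, n_perm = cfg$n_perm,
                           alpha = cfg$alpha, seed = derive_seed(cfg$seed, 3))
  dyn_genes <- dyn$gene_id[dyn$is_dynamic]
  stage_msg("dynamics", length(dyn_genes), " dynamic genes")
  prof <- NULL
  dir_lab <- NULL
  if (length(dyn_genes) >= 2) {
    prof <- smoothed_profiles(ln, pt, genes = dyn_genes, window = cfg$window,
                              scaling = "zscore")
    cl <- cluster_dynamic_genes(prof, seed = derive_seed(cfg$seed, 4))
    dyn$cluster_id[match(names(cl), dyn$gene_id)] <- as.integer(cl)
    dir_lab <- cluster_direction(prof, cl)
  }
  files <- write_tsv_out(dyn, cfg$out_dir, "dynamic_genes.tsv", files)

  staged <- NULL
  if (!is.null(stage_genes)) {
    raw <- smoothed_profiles(ln, pt, genes = stage_genes, window = cfg$window,
                             scaling = "none")
    staged <- max_scale_profiles(raw)
    files <- write_tsv_out(
      data.frame(gene_id = rownames(staged), staged, check.names = FALSE),
      cfg$out_dir, "staged_profiles.tsv", files)
  }

  overlaps <- NULL
  if (!is.null(signatures) && length(dyn_genes) >= 2) {
    universe <- ln$gene_ids[rowSums(ln$values > 0) >= 1]
    overlaps <- do.call(rbind, lapply(names(signatures), function(sn) {
      sig <- intersect(signatures[[sn]]$genes, universe)
      do.call(rbind, lapply(sort(unique(dyn$cluster_id[!is.na(dyn$cluster_id)])),
        function(cl) {
          ov <- hypergeometric_overlap(
            dyn$gene_id[!is.na(dyn$cluster_id) & dyn$cluster_id == cl],
            sig, universe)
          data.frame(signature = sn, cluster = cl, direction = dir_lab[cl],
                     n_overlap = ov$n_overlap, p = ov$p,
                     stringsAsFactors = FALSE)
        }))
    }))
    files <- write_tsv_out(overlaps, cfg$out_dir, "overlaps.tsv", files)
  }

  finish_manifest(cfg, files, "mastcell")
  invisible(list(pca = pca, neighbor_scores = nbs, root = root,
                 pseudotime = pt, marker_correlations = marker_cor,
                 dynamic_genes = dyn, profiles = prof,
                 staged_profiles = staged, overlaps = overlaps,
                 cluster_direction = dir_lab))
}

#' Run the flow-cytometry embedding and colony-fate analysis
#'
#' Preprocesses the multi-population reference events, fits the diffusion map
#' and PCA embeddings, projects index-sorted colony founders into the PCA
#' space, classifies colonies under the 20/5 rules and joins outcomes with
#' the projected coordinates.
#'
#' @param events reference \code{EventTable} (>= 2 populations).
#' @param index optional index-sorted \code{EventTable} of colony founders.
#' @param colonies optional named list of per-colony \code{EventTable}s; the
#'   names are colony ids and must match \code{index} cell ids when both are
#'   given.
#' @param gates colony gate definitions (default \code{\link{colony_gates}}).
#' @param colony_populations optional founding population per colony for the
#'   output summary.
#' @param config a \code{\link{pipeline_config}}.
#' @return Invisibly, a list with \code{preprocessed}, \code{diffusion},
#'   \code{pca}, \code{index_scores}, \code{colony_records},
#'   \code{colony_summary}, \code{overlay}.
#' @export
run_flow_pipeline <- function(events, index = NULL, colonies = NULL,
                              gates = colony_gates(),
                              colony_populations = NULL,
                              config = pipeline_config()) {
  cfg <- config
  if (!is.null(cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  prep <- preprocess_events(events, seed = derive_seed(cfg$seed, 1))
  stage_msg("preprocess", nrow(prep$matrix), " events retained of ",
            nrow(events$rows))
  dm <- fit_diffusion_map(prep$matrix,
                          n_dcs = min(cfg$n_dcs, nrow(prep$matrix) - 2),
                          n_neighbors = cfg$n_neighbors)
  files <- write_tsv_out(
    data.frame(population = prep$events$population, dm$components,
               check.names = FALSE),
    cfg$out_dir, "dc.tsv", files)
  pca <- fit_pca(prep$events)
  files <- write_tsv_out(
    data.frame(population = prep$events$population, pca$scores,
               check.names = FALSE),
    cfg$out_dir, "pca.tsv", files)

  index_scores <- NULL
  if (!is.null(index)) {
    index_scores <- project_pca(pca, index)
    rownames(index_scores) <- index$cell_ids
    files <- write_tsv_out(
      data.frame(cell_id = index$cell_ids, index_scores, check.names = FALSE),
      cfg$out_dir, "index_projection.tsv", files)
  }

  records <- NULL
  summary <- NULL
  overlay <- NULL
  if (!is.null(colonies)) {
    records <- lapply(names(colonies), function(id)
      classify_colony(colonies[[id]], gates = gates,
                      min_events = cfg$min_events,
                      min_gate_events = cfg$min_gate_events,
                      colony_id = id,
                      origin_cell_id = if (!is.null(index)) id))
    stage_msg("colonies", sum(vapply(records, `[[`, logical(1), "classified")),
              " of ", length(records), " colonies classified")
    rec_df <- data.frame(
      colony_id = vapply(records, `[[`, character(1), "colony_id"),
      size = vapply(records, function(r) as.numeric(r$size), numeric(1)),
      n_live_events = vapply(records, function(r)
        as.numeric(r$n_live_events), numeric(1)),
      classified = vapply(records, `[[`, logical(1), "classified"),
      type = vapply(records, function(r) r$type, character(1)),
      stringsAsFactors = FALSE)
    files <- write_tsv_out(rec_df, cfg$out_dir, "colonies.tsv", files)
    if (!is.null(colony_populations)) {
      summary <- summarize_colony_output(records, colony_populations)
      files <- write_tsv_out(summary, cfg$out_dir, "colony_summary.tsv", files)
    }
    if (!is.null(index)) {
      overlay <- overlay_colonies(pca, index, records)
      files <- write_tsv_out(overlay, cfg$out_dir, "overlay.tsv", files)
    }
  }

  finish_manifest(cfg, files, "flow")
  invisible(list(preprocessed = prep, diffusion = dm, pca = pca,
                 index_scores = index_scores, colony_records = records,
                 colony_summary = summary, overlay = overlay))
}
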