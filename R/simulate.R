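#' Parameters of the bifurcating-trajectory simulator
#'
#' Bundles every knob of \code{\link{simulate_bifurcating_expression}} with
#' defaults chosen to emulate a plate-based (Smart-Seq2-like) single-cell
#' experiment over a progenitor bifurcation: hundreds of cells, thousands of
#' genes, overdispersed negative-binomial counts, a tenth of the genes
#' monotonically up- or downregulated along the trajectory, and a small set of
#' cell-cycle-driven genes tied to a proliferative early-time subset.
#'
#' @param n_cells number of cells (default 300).
#' @param n_genes number of genes (default 2000).
#' @param branch_point latent time at which the trunk splits (default 0.3).
#' @param frac_dynamic fraction of genes with monotone up/down dynamics along
#'   the trajectory (default 0.1; split equally between up and down).
#' @param frac_cycle_s,frac_cycle_g2m fractions of genes driven by the S and
#'   G2M programs of proliferative cells (default 0.02 each).
#' @param nb_dispersion negative-binomial dispersion phi (variance =
#'   mu + phi mu^2); default 0.3, typical plate-protocol overdispersion.
#' @param library_size_mean expected total counts per cell (default 2e4, a
#'   deep plate-protocol depth scaled to the simulated gene count).
#' @param library_size_cv coefficient of variation of the log-normal per-cell
#'   size factors (default 0.3).
#' @param effect_range range (natural-log units) from which each dynamic
#'   gene's log-fold span is drawn uniformly (default c(1, 3)).
#' @param branch_specific_frac fraction of dynamic genes restricted to one
#'   branch (flat on the other); default 0 — dynamic genes model the shared
#'   maturation program that changes monotonically along both lineages.
#' @param loc_range,steep_range uniform ranges for each dynamic gene's
#'   logistic midpoint and steepness in latent-time units (defaults
#'   c(0.35, 0.65) and c(0.08, 0.15)): transitions concentrate around
#'   mid-differentiation, giving the two coherent profile groups (one
#'   increasing, one decreasing) that real trajectory heatmaps show.
#' @param cycle_effect log-fold elevation of cycle genes in cells of the
#'   matching phase (default 2).
#' @param marker_spec data frame with columns \code{marker}, \code{branch}
#'   (\code{"A"} or \code{"B"}), \code{sign} (+1/-1), \code{strength}, used by
#'   \code{\link{simulate_index_sort}}. Defaults mirror a progenitor panel:
#'   CD34 and cKit lost along the basophil branch, CD49b gained; ST2 gained
#'   and integrin-beta7 lost along the mast-cell branch.
#' @param seed integer seed; identical seeds give identical output.
#' @return A list of class \code{"SimParams"}.
#' @export
sim_params <- function(n_cells = 300, n_genes = 2000, branch_point = 0.3,
                       frac_dynamic = 0.1, frac_cycle_s = 0.02,
                       frac_cycle_g2m = 0.02, nb_dispersion = 0.3,
                       library_size_mean = 2e4, library_size_cv = 0.3,
                       effect_range = c(1, 3), branch_specific_frac = 0,
                       loc_range = c(0.35, 0.65), steep_range = c(0.08, 0.15),
                       cycle_effect = 2,
                       marker_spec = default_marker_spec(), seed = 1L) {
  stopifnot(n_cells >= 2, n_genes >= 1,
            branch_point > 0, branch_point < 1,
            frac_dynamic > 0, frac_dynamic < 1,
            frac_cycle_s >= 0, frac_cycle_g2m >= 0,
            frac_dynamic + frac_cycle_s + frac_cycle_g2m < 1,
            nb_dispersion > 0, library_size_mean > 0, library_size_cv >= 0,
            length(effect_range) == 2, effect_range[1] <= effect_range[2],
            branch_specific_frac >= 0, branch_specific_frac <= 1)
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 branch_point = branch_point, frac_dynamic = frac_dynamic,
                 frac_cycle_s = frac_cycle_s, frac_cycle_g2m = frac_cycle_g2m,
                 nb_dispersion = nb_dispersion,
                 library_size_mean = library_size_mean,
                 library_size_cv = library_size_cv,
                 effect_range = effect_range,
                 branch_specific_frac = branch_specific_frac,
                 loc_range = loc_range, steep_range = steep_range,
                 cycle_effect = cycle_effect,
                 marker_spec = marker_spec, seed = as.integer(seed)),
            class = "SimParams")
}

#' @rdname sim_params
#' @export
default_marker_spec <- function() {
  data.frame(marker = c("CD34", "cKit", "CD49b", "ST2", "Itgb7"),
             branch = c("A", "A", "A", "B", "B"),
             sign = c(-1, -1, 1, 1, -1),
             strength = c(0.9, 0.7, 0.8, 0.8, 0.8),
             stringsAsFactors = FALSE)
}

#' Simulate a bifurcating single-cell expression matrix with ground truth
#'
#' Cells carry a latent differentiation time uniform on [0, 1]; cells before
#' the branch point form the trunk (the bipotent progenitor pool), later cells
#' are split evenly between two branches. Dynamic genes follow a scaled
#' logistic of latent time — by default along both branches (a shared
#' maturation program); branch-specific genes are held at their branch-point
#' value on the other branch. Cell-cycle genes are elevated
#' in a proliferative subset whose frequency decays with latent time; all
#' remaining genes are flat. Counts are negative binomial around these means
#' with log-normal per-cell size factors.
#'
#' @param params a \code{\link{sim_params}} object.
#' @return A list with elements \code{expression} (an
#'   \code{\link{expression_matrix}}, counts layer, cells labelled by branch)
#'   and \code{truth} (a \code{TrajectoryTruth}: per-cell \code{branch},
#'   \code{latent_time}, \code{phase}; per-gene \code{gene_class},
#'   \code{gene_branch}, \code{effect_size} and profile parameters).
#' @export
simulate_bifurcating_expression <- function(params) {
  stopifnot(inherits(params, "SimParams"))
  p <- params
  n_dyn <- round(p$frac_dynamic * p$n_genes)
  if (n_dyn < 2)
    stop("frac_dynamic * n_genes must be at least 2", call. = FALSE)
  if (p$n_cells < 40)
    warning("fewer than 40 cells: downstream window-20 smoothing will be short")
  n_s <- round(p$frac_cycle_s * p$n_genes)
  n_g2m <- round(p$frac_cycle_g2m * p$n_genes)

  with_seed(p$seed, {
    t <- stats::runif(p$n_cells)
    branch <- ifelse(t < p$branch_point, "trunk",
                     ifelse(stats::runif(p$n_cells) < 0.5, "branchA", "branchB"))
    # proliferative fraction decays with maturation
    prolif <- stats::runif(p$n_cells) < stats::plogis((0.4 - t) / 0.1)
    phase <- ifelse(!prolif, "none",
                    ifelse(stats::runif(p$n_cells) < 0.5, "S", "G2M"))

    gene_class <- rep("flat", p$n_genes)
    n_up <- ceiling(n_dyn / 2)
    gene_class[seq_len(n_up)] <- "up"
    gene_class[n_up + seq_len(n_dyn - n_up)] <- "down"
    if (n_s > 0) gene_class[n_dyn + seq_len(n_s)] <- "cycle_S"
    if (n_g2m > 0) gene_class[n_dyn + n_s + seq_len(n_g2m)] <- "cycle_G2M"
    dyn <- gene_class %in% c("up", "down")
    gene_branch <- rep(NA_character_, p$n_genes)
    n_spec <- round(p$branch_specific_frac * n_dyn)
    gene_branch[dyn] <- c(rep_len(c("A", "B"), n_spec),
                          rep("both", n_dyn - n_spec))
    effect <- numeric(p$n_genes)
    effect[dyn] <- stats::runif(n_dyn, p$effect_range[1], p$effect_range[2])
    loc <- stats::runif(p$n_genes, p$loc_range[1], p$loc_range[2])
    steep <- stats::runif(p$n_genes, p$steep_range[1], p$steep_range[2])
    base_log <- ifelse(dyn | gene_class %in% c("cycle_S", "cycle_G2M"),
                       stats::rnorm(p$n_genes, log(2), 0.5),
                       stats::rnorm(p$n_genes, log(1), 1.5))

    # gene x cell log-mean matrix
    logmu <- matrix(base_log, p$n_genes, p$n_cells)
    on_branch <- function(b) {
      if (b == "both") rep(TRUE, p$n_cells)
      else branch == "trunk" | branch == paste0("branch", b)
    }
    for (g in which(dyn)) {
      tg <- ifelse(on_branch(gene_branch[g]), t, p$branch_point)
      shape <- stats::plogis((tg - loc[g]) / steep[g])
      if (gene_class[g] == "down") shape <- 1 - shape
      logmu[g, ] <- base_log[g] + effect[g] * shape
    }
    if (n_s > 0)
      logmu[gene_class == "cycle_S", phase == "S"] <-
        logmu[gene_class == "cycle_S", phase == "S"] + p$cycle_effect
    if (n_g2m > 0)
      logmu[gene_class == "cycle_G2M", phase == "G2M"] <-
        logmu[gene_class == "cycle_G2M", phase == "G2M"] + p$cycle_effect

    sdlog <- sqrt(log(1 + p$library_size_cv^2))
    sf <- stats::rlnorm(p$n_cells, -sdlog^2 / 2, sdlog)
    mu <- exp(logmu)
    mu <- mu * (p$library_size_mean / mean(colSums(mu)))
    mu <- sweep(mu, 2, sf, `*`)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / p$nb_dispersion),
                     p$n_genes, p$n_cells)

    gene_ids <- sprintf("gene%04d", seq_len(p$n_genes))
    cell_ids <- sprintf("cell%04d", seq_len(p$n_cells))
    truth <- structure(list(
      cell_ids = cell_ids, branch = branch, latent_time = t, phase = phase,
      gene_ids = gene_ids, gene_class = gene_class, gene_branch = gene_branch,
      effect_size = effect, location = loc, steepness = steep,
      base_log_mean = base_log, branch_point = p$branch_point),
      class = "TrajectoryTruth")
    list(expression = expression_matrix(counts, gene_ids, cell_ids,
                                        cell_labels = branch,
                                        layer = "counts"),
         truth = truth)
  })
}

#' Cells belonging to one trajectory of the simulated bifurcation
#'
#' @param truth a \code{TrajectoryTruth}.
#' @param branch \code{"A"} or \code{"B"}.
#' @return Logical vector selecting trunk cells plus cells on the requested
#'   branch.
#' @export
trajectory_cells <- function(truth, branch = c("A", "B")) {
  branch <- match.arg(branch)
  truth$branch %in% c("trunk", paste0("branch", branch))
}

#' Simulate an index-sort table coupled to a simulated trajectory
#'
#' Each marker's log10 intensity is a linear ramp in latent time along its
#' assigned branch (held at the branch-point value elsewhere) with the given
#' sign and strength, plus Gaussian noise, then placed on instrument scale by
#' exponentiation. With default noise (sd 0.2 in log10 units) a marker of
#' strength > 0.5 has the specified correlation sign with latent time with
#' near certainty for 100 or more cells.
#'
#' @param truth a \code{TrajectoryTruth}.
#' @param marker_spec data frame as in \code{\link{sim_params}}.
#' @param seed integer seed.
#' @param noise_sd Gaussian noise sd on the log10 scale (default 0.2).
#' @param base_log10 baseline log10 intensity (default 2).
#' @return An index-sorted \code{\link{event_table}} (all markers fluorescent,
#'   population = simulated branch, cell ids from the truth).
#' @export
simulate_index_sort <- function(truth, marker_spec = default_marker_spec(),
                                seed = 1L, noise_sd = 0.2, base_log10 = 2) {
  stopifnot(inherits(truth, "TrajectoryTruth"))
  bad <- setdiff(marker_spec$branch, c("A", "B"))
  if (length(bad))
    stop("unknown branch in marker_spec: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!all(marker_spec$sign %in% c(-1, 1)))
    stop("marker signs must be +1 or -1", call. = FALSE)
  n <- length(truth$cell_ids)
  with_seed(seed, {
    rows <- sapply(seq_len(nrow(marker_spec)), function(i) {
      on_b <- truth$branch %in% c("trunk", paste0("branch", marker_spec$branch[i]))
      tt <- ifelse(on_b, truth$latent_time, truth$branch_point)
      lg <- base_log10 + marker_spec$sign[i] * marker_spec$strength[i] * tt +
        stats::rnorm(n, 0, noise_sd)
      10^lg
    })
    colnames(rows) <- marker_spec$marker
    kinds <- stats::setNames(rep("fluorescent", nrow(marker_spec)),
                             marker_spec$marker)
    event_table(rows, kinds, population = truth$branch,
                cell_ids = truth$cell_ids)
  })
}

#' Simulate multi-population flow-cytometry events on a branching manifold
#'
#' Populations are Gaussian clusters centred along a one-dimensional branching
#' latent curve mapped into parameter space through a random smooth (linear
#' plus quadratic) embedding, mimicking contiguous sorting gates along a
#' differentiation continuum. Fluorescent parameters are exponentiated to
#' instrument scale; scatter parameters stay linear. A fraction of rows can be
#' duplicated verbatim to exercise deduplication.
#'
#' @param populations character vector of population names (>= 2).
#' @param n_per_pop integer vector of events per population (recycled).
#' @param n_fluor,n_scatter numbers of fluorescent and scatter parameters
#'   (defaults 9 and 2, a typical panel).
#' @param manifold_spec optional data frame with columns \code{population},
#'   \code{branch} (\code{"trunk"}, \code{"A"}, \code{"B"}) and \code{t}
#'   (position along the curve in [0,1]); by default the first two populations
#'   sit on the trunk and the rest alternate between the branches at
#'   increasing positions.
#' @param dup_rate fraction of rows to duplicate verbatim (default 0).
#' @param noise_sd cluster spread in latent units (default 0.08).
#' @param seed integer seed.
#' @return An \code{\link{event_table}} (no cell ids).
#' @export
simulate_flow_events <- function(populations, n_per_pop, n_fluor = 9,
                                 n_scatter = 2, manifold_spec = NULL,
                                 dup_rate = 0, noise_sd = 0.08, seed = 1L) {
  populations <- as.character(populations)
  if (length(populations) < 2) stop("need at least 2 populations", call. = FALSE)
  n_per_pop <- rep_len(as.integer(n_per_pop), length(populations))
  stopifnot(all(n_per_pop > 0), dup_rate >= 0, dup_rate < 1,
            n_fluor >= 1, n_scatter >= 0)
  if (is.null(manifold_spec)) {
    k <- length(populations)
    # contiguous gates along a continuum: centers close enough that
    # neighboring populations overlap through their tails
    manifold_spec <- data.frame(
      population = populations,
      branch = c("trunk", "trunk", rep_len(c("A", "B"), max(0, k - 2)))[seq_len(k)],
      t = c(0.15, 0.4, seq(0.55, 0.85,
                           length.out = max(1, k - 2)))[seq_len(k)],
      stringsAsFactors = FALSE)
  }
  miss <- setdiff(populations, manifold_spec$population)
  if (length(miss))
    stop("manifold_spec missing populations: ", paste(miss, collapse = ", "),
         call. = FALSE)
  n_par <- n_fluor + n_scatter
  pn <- c(sprintf("FL%d", seq_len(n_fluor)),
          if (n_scatter > 0) sprintf("SC%d", seq_len(n_scatter)))
  kinds <- stats::setNames(rep(c("fluorescent", "scatter"),
                               c(n_fluor, n_scatter)), pn)
  with_seed(seed, {
    # random smooth embedding of the branching curve into parameter space
    a <- stats::rnorm(n_par, 0, 1.2)
    b <- stats::rnorm(n_par, 0, 0.8)
    cA <- stats::rnorm(n_par, 0, 1.5)
    cB <- stats::rnorm(n_par, 0, 1.5)
    bp <- 0.5
    embed <- function(t, branch) {
      off <- switch(branch, trunk = 0 * t,
                    A = pmax(0, t - bp), B = -pmax(0, t - bp))
      outer(t, a) + outer(t^2, b) +
        outer(off, if (branch == "B") cB else cA) * (branch != "trunk")
    }
    rows <- do.call(rbind, lapply(seq_along(populations), function(i) {
      ms <- manifold_spec[manifold_spec$population == populations[i], ][1, ]
      n <- n_per_pop[i]
      t <- ms$t + stats::rnorm(n, 0, noise_sd)
      lat <- embed(t, ms$branch) + matrix(stats::rnorm(n * n_par, 0, noise_sd),
                                          n, n_par)
      out <- lat
      fl <- seq_len(n_fluor)
      out[, fl] <- 10^(2.5 + 0.6 * lat[, fl])
      if (n_scatter > 0)
        out[, -fl] <- 5e4 * (2 + 0.5 * lat[, -fl, drop = FALSE])
      out
    }))
    colnames(rows) <- pn
    population <- rep(populations, n_per_pop)
    n_dup <- round(dup_rate * nrow(rows))
    if (n_dup > 0) {
      idx <- sample.int(nrow(rows), n_dup)
      rows <- rbind(rows, rows[idx, , drop = FALSE])
      population <- c(population, population[idx])
    }
    event_table(rows, kinds, population = population)
  })
}

#' Simulate the flow events of one cultured colony
#'
#' Events fall into four categories — dead, basophil-gate (c-Kit low, FceRI
#' and CD49b high), mast-gate (c-Kit and FceRI high), and other live — drawn
#' per event from the stated fractions. Dead events carry population
#' \code{"dead"}, live events \code{"live"}; gate membership is encoded in the
#' c-Kit / FceRI / CD49b intensities so that the default
#' \code{\link{colony_gates}} recover the drawn category.
#'
#' @param n_cells number of events (>= 0).
#' @param frac_ba_gate,frac_mc_gate,frac_dead expected category fractions;
#'   must sum to at most 1.
#' @param seed integer seed.
#' @return An \code{\link{event_table}} with parameters cKit, FceRI, CD49b.
#' @export
simulate_colony_events <- function(n_cells, frac_ba_gate = 0.2,
                                   frac_mc_gate = 0.2, frac_dead = 0.1,
                                   seed = 1L) {
  if (n_cells < 0) stop("n_cells must be non-negative", call. = FALSE)
  stopifnot(frac_ba_gate >= 0, frac_mc_gate >= 0, frac_dead >= 0,
            frac_ba_gate + frac_mc_gate + frac_dead <= 1)
  pn <- c("cKit", "FceRI", "CD49b")
  kinds <- stats::setNames(rep("fluorescent", 3), pn)
  if (n_cells == 0)
    return(event_table(matrix(numeric(0), 0, 3, dimnames = list(NULL, pn)),
                       kinds, population = character(0)))
  with_seed(seed, {
    cat_ <- sample(c("dead", "ba", "mc", "other"), n_cells, replace = TRUE,
                   prob = c(frac_dead, frac_ba_gate, frac_mc_gate,
                            1 - frac_dead - frac_ba_gate - frac_mc_gate))
    lo <- function(n) 10^stats::rnorm(n, 1.5, 0.1)
    hi <- function(n) 10^stats::rnorm(n, 3.5, 0.1)
    n <- n_cells
    rows <- cbind(cKit = lo(n), FceRI = lo(n), CD49b = lo(n))
    rows[cat_ == "ba", ] <- cbind(lo(sum(cat_ == "ba")),
                                  hi(sum(cat_ == "ba")),
                                  hi(sum(cat_ == "ba")))
    rows[cat_ == "mc", ] <- cbind(hi(sum(cat_ == "mc")),
                                  hi(sum(cat_ == "mc")),
                                  lo(sum(cat_ == "mc")))
    colnames(rows) <- pn
    event_table(rows, kinds,
                population = ifelse(cat_ == "dead", "dead", "live"))
  })
}
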