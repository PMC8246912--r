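test_that("normalisation scales cells to the target and logs", {
  em <- expression_matrix(matrix(c(2, 2, 1, 3), 2, 2), c("g1", "g2"),
                          c("c1", "c2"))
  ln <- normalize_log(em, target_sum = 4, pseudocount = 1)
  expect_equal(ln$values[, "c1"], c(g1 = log(3), g2 = log(3)))
  # expm1 of the output re-sums to target_sum per cell
  expect_equal(unname(colSums(expm1(ln$values))), c(4, 4), tolerance = 1e-8)
  expect_equal(ln$layer, "lognorm")

  same <- expression_matrix(matrix(c(1, 2, 1, 2), 2, 2), c("g1", "g2"),
                            c("c1", "c2"))
  lns <- normalize_log(same)
  expect_equal(lns$values[, 1], lns$values[, 2])

  zero <- expression_matrix(matrix(c(1, 0, 0, 0), 2, 2), c("g1", "g2"),
                            c("c1", "c2"))
  expect_error(normalize_log(zero), "c2")
})

test_that("Welch DE matches t.test and behaves on degenerate input", {
  set.seed(4)
  m <- matrix(rexp(50 * 12), 50, 12)
  em <- expression_matrix(m, sprintf("g%02d", 1:50), sprintf("c%02d", 1:12),
                          cell_labels = rep(c("A", "B"), c(5, 7)),
                          layer = "lognorm")
  de <- differential_expression(em, "A", "B")
  for (g in c(1, 17, 50)) {
    ref <- t.test(m[g, 6:12], m[g, 1:5])
    expect_equal(de$t_stat[g], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(de$p[g], ref$p.value, tolerance = 1e-10)
  }
  expect_equal(de$p_adj, p.adjust(de$p, "BH"))

  # identical groups: t = 0, p = 1 everywhere
  dup <- expression_matrix(cbind(m[, 1:5], m[, 1:5]), sprintf("g%02d", 1:50),
                           sprintf("c%02d", 1:10),
                           cell_labels = rep(c("A", "B"), each = 5),
                           layer = "lognorm")
  de0 <- suppressMessages(differential_expression(dup, "A", "B"))
  expect_true(all(de0$t_stat == 0))
  expect_true(all(de0$p == 1))
})

test_that("a planted near-separated gene attains the smallest adjusted p", {
  set.seed(5)
  m <- matrix(rnorm(30 * 8, 5, 1), 30, 8)
  m[1, ] <- c(0, 0, 0, 0, 1, 1, 1, 1) + seq(-2e-3, 2e-3, length.out = 8)
  em <- expression_matrix(m - min(m), sprintf("g%02d", 1:30),
                          sprintf("c%02d", 1:8),
                          cell_labels = rep(c("A", "B"), each = 4),
                          layer = "lognorm")
  de <- differential_expression(em, "A", "B")
  expect_equal(which.min(de$p_adj), 1)
  expect_equal(de$direction[1], "up")
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(.01, .02, .03)), c(.03, .03, .03))
  expect_equal(bh_adjust(c(.04, .04)), c(.04, .04))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(6)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("DE on label-permuted null data stays within the BH level", {
  frac <- sapply(1:20, function(s) {
    set.seed(100 + s)
    m <- matrix(rnorm(300 * 30), 300, 30)
    em <- expression_matrix(m - min(m), sprintf("g%03d", 1:300),
                            sprintf("c%02d", 1:30),
                            cell_labels = sample(rep(c("A", "B"), 15)),
                            layer = "lognorm")
    de <- differential_expression(em, "A", "B")
    mean(de$p_adj < 0.01)
  })
  expect_lte(mean(frac), 0.015)
})

test_that("gene-set scoring is bin-matched, shift-recovering and seeded", {
  set.seed(7)
  n_genes <- 200; n_cells <- 40
  base <- matrix(rnorm(n_genes * n_cells, 3, 0.2), n_genes, n_cells)
  sig_idx <- 1:10
  cshift <- 1.5
  base[sig_idx, ] <- base[sig_idx, ] + cshift
  # put signature genes in the same expression bins as controls by adding
  # matching high-mean controls (40 elevated genes fill 2 of the 10 bins)
  base[11:40, ] <- base[11:40, ] + cshift
  em <- expression_matrix(base - min(base), sprintf("g%03d", 1:n_genes),
                          sprintf("c%02d", 1:n_cells), layer = "lognorm")
  sig <- signature_list("test", sprintf("g%03d", sig_idx))
  sc <- score_gene_set(em, sig, n_bins = 10, ctrl_size = 20, seed = 3)
  expect_equal(unname(mean(sc)), 0, tolerance = 0.3)

  sc2 <- score_gene_set(em, sig, n_bins = 10, ctrl_size = 20, seed = 3)
  expect_identical(sc, sc2)

  # constant shift between signature and its expression-matched controls
  shifted <- base
  shifted[sig_idx, ] <- shifted[sig_idx, ] + 0.7
  em2 <- expression_matrix(shifted - min(shifted), em$gene_ids, em$cell_ids,
                           layer = "lognorm")
  sc3 <- score_gene_set(em2, sig, n_bins = 10, ctrl_size = 20, seed = 3)
  expect_equal(unname(mean(sc3)), 0.7, tolerance = 0.25)

  expect_error(score_gene_set(em, signature_list("none", "nope")), "nope")
})

test_that("phase assignment follows the score rule", {
  cc <- assign_cell_cycle(c(-0.2, 0.5, 0.1, 0.3), c(-0.1, 0.1, 0.4, 0.3))
  expect_equal(cc$phase, c("G1", "S", "G2M", "G2M"))
})

test_that("planted proliferative cells are recovered as S or G2M", {
  sim <- simulate_bifurcating_expression(sim_params(seed = 41))
  ln <- normalize_log(sim$expression)
  s_sig <- signature_list("S", sim$truth$gene_ids[
    sim$truth$gene_class == "cycle_S"])
  g2m_sig <- signature_list("G2M", sim$truth$gene_ids[
    sim$truth$gene_class == "cycle_G2M"])
  s <- score_gene_set(ln, s_sig, seed = 1)
  g2m <- score_gene_set(ln, g2m_sig, seed = 2)
  cc <- assign_cell_cycle(s, g2m)
  prolif <- sim$truth$phase != "none"
  expect_gte(mean(cc$phase[prolif] %in% c("S", "G2M")), 0.95)
  # and the assigned phase matches the planted one for most proliferative cells
  expect_gte(mean(cc$phase[prolif] == sim$truth$phase[prolif]), 0.8)
})
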