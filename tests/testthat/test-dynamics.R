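test_that("sliding-window smoothing matches hand arithmetic", {
  pt <- tiny_pt(10)
  v <- setNames(1:10, pt$cell_ids)
  # window 1, no scaling: identity in pseudotime order
  s1 <- sliding_window_smooth(v, pt, window = 1, scaling = "none")
  expect_equal(s1$values, 1:10)
  # ramp 1..10, window 3 -> 2..9
  s3 <- sliding_window_smooth(v, pt, window = 3, scaling = "none")
  expect_equal(s3$values, as.numeric(2:9))
  expect_error(sliding_window_smooth(v, pt, window = 11), "window")
})

test_that("profile scalings honor their range contracts", {
  pt <- tiny_pt(10)
  v <- setNames(c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3), pt$cell_ids)
  mm <- sliding_window_smooth(v, pt, window = 2, scaling = "minmax01")
  expect_gte(min(mm$values), 0)
  expect_lte(max(mm$values), 1)
  zs <- sliding_window_smooth(v, pt, window = 2, scaling = "zscore")
  expect_equal(mean(zs$values), 0, tolerance = 1e-8)
  ms <- sliding_window_smooth(v, pt, window = 2, scaling = "maxscale")
  expect_equal(max(ms$values), 1)
  # constant input with minmax01 degenerates to zero
  const <- sliding_window_smooth(setNames(rep(2, 10), pt$cell_ids), pt,
                                 window = 2, scaling = "minmax01")
  expect_equal(const$values, rep(0, 9))
})

test_that("window composition tracks label proportions", {
  pt <- tiny_pt(10)
  lab <- setNames(rep(c("A", "B"), each = 5), pt$cell_ids)
  comp <- window_composition(lab, pt, window = 2)
  expect_equal(unname(rowSums(comp)), rep(1, 9), tolerance = 1e-12)
  # A proportion decreases monotonically from 1 to 0
  expect_true(all(diff(comp[, "A"]) <= 0))
  expect_equal(unname(comp[1, "A"]), 1)
  expect_equal(unname(comp[9, "A"]), 0)
  one <- window_composition(setNames(rep("X", 10), pt$cell_ids), pt, 3)
  expect_true(all(one[, "X"] == 1))
})

test_that("marker correlation uses unsmoothed values", {
  pt <- tiny_pt(30)
  set.seed(2)
  marker <- setNames(as.numeric(1:30) + rnorm(30, 0, 3), pt$cell_ids)
  r <- marker_pseudotime_correlation(marker, pt)
  expect_equal(r, cor(marker, 1:30))
  # perfectly aligned and anti-aligned markers
  expect_equal(marker_pseudotime_correlation(
    setNames(as.numeric(1:30), pt$cell_ids), pt), 1)
  expect_equal(marker_pseudotime_correlation(
    setNames(-as.numeric(1:30), pt$cell_ids), pt), -1)
  # smoothing the marker would change r, the reported value does not
  sm <- sliding_window_smooth(marker, pt, window = 5, scaling = "none")
  r_sm <- cor(sm$values, seq_along(sm$values))
  expect_false(isTRUE(all.equal(r, r_sm)))
  expect_error(marker_pseudotime_correlation(
    setNames(rep(1, 30), pt$cell_ids), pt), "zero variance")
  # hand-computed 5-point case
  pt5 <- tiny_pt(5)
  m5 <- setNames(c(2, 4, 5, 4, 10), pt5$cell_ids)
  num <- sum((m5 - mean(m5)) * (1:5 - 3))
  den <- sqrt(sum((m5 - mean(m5))^2) * sum((1:5 - 3)^2))
  expect_equal(marker_pseudotime_correlation(m5, pt5), num / den)
})

test_that("a constant gene is never called dynamic", {
  traj <- sim_trajectory(7)
  ln <- traj$lognorm
  small <- subset_expression(ln, genes = 1:20)
  small$values[3, ] <- 5
  pt <- pc1_pseudotime(ln, orientation_genes_of(traj$sim))
  dyn <- dynamic_gene_test(small, pt, n_perm = 100, seed = 1)
  expect_equal(dyn$statistic[3], 0)
  expect_equal(dyn$p_perm[3], 1)
  expect_false(dyn$is_dynamic[3])
})

test_that("dynamic genes are recovered and cluster into the two planted groups", {
  for (seed in c(7, 8)) {
    traj <- sim_trajectory(seed)
    sim <- traj$sim
    pt <- pc1_pseudotime(traj$lognorm, orientation_genes_of(sim))
    dyn <- dynamic_gene_test(traj$lognorm, pt, n_perm = 1000, seed = 2)
    mono <- sim$truth$gene_class %in% c("up", "down")
    expect_gte(mean(dyn$is_dynamic[mono]), 0.9)

    prof <- smoothed_profiles(traj$lognorm, pt,
                              genes = dyn$gene_id[dyn$is_dynamic])
    cl <- cluster_dynamic_genes(prof, seed = 3)
    expect_equal(length(unique(cl)), 2)
    expect_length(cl, sum(dyn$is_dynamic))
    # purity of the increasing/decreasing split: cycle genes fade with
    # maturation, so they belong with the decreasing program
    truth_dir <- ifelse(sim$truth$gene_class == "up", "inc", "dec")
    tc <- truth_dir[match(names(cl), sim$truth$gene_ids)]
    purity <- sum(sapply(split(tc, cl), function(z) max(table(z)))) /
      length(cl)
    expect_gte(purity, 0.95)
  }
})

test_that("profile clustering covers every gene exactly once", {
  set.seed(4)
  prof <- rbind(matrix(rep(sin(seq(0, 3, length.out = 50)), 6), 6,
                       byrow = TRUE),
                matrix(rep(cos(seq(0, 3, length.out = 50)), 6), 6,
                       byrow = TRUE))
  rownames(prof) <- paste0("g", 1:12)
  cl <- cluster_dynamic_genes(prof + rnorm(600, 0, 0.01), seed = 1)
  expect_setequal(names(cl), rownames(prof))
  expect_false(any(is.na(cl)))
  # two identical profiles form one cluster
  two <- matrix(rep(1:20, 2), 2, byrow = TRUE) + rnorm(40, 0, 1e-6)
  rownames(two) <- c("a", "b")
  expect_equal(unname(cluster_dynamic_genes(two, seed = 1)), c(1L, 1L))
  expect_warning(one <- cluster_dynamic_genes(two[1, , drop = FALSE]),
                 "single cluster")
  expect_equal(unname(one), 1L)
})

test_that("max-scaling preserves peak positions and rejects flat-zero input", {
  prof <- rbind(a = c(2, 4), b = c(1, 0.5))
  ms <- max_scale_profiles(prof)
  expect_equal(ms["a", ], c(2, 4) / 4)
  expect_equal(unname(apply(ms, 1, max)), c(1, 1))
  # already max-1 rows are unchanged
  expect_equal(max_scale_profiles(ms), ms)
  # argmax ordering (staging) is invariant under the scaling
  set.seed(5)
  stages <- t(sapply(c(10, 25, 40), function(pk)
    dnorm(1:50, pk, 6) + runif(50, 0, 1e-3)))
  expect_equal(apply(max_scale_profiles(stages), 1, which.max),
               apply(stages, 1, which.max))
  expect_error(max_scale_profiles(rbind(c(-1, 0))), "nonpositive")
})
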