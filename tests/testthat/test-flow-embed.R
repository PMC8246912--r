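test_that("preprocessing downsamples, deduplicates and z-scores", {
  et <- simulate_flow_events(paste0("p", 1:5), c(100, 250, 80, 300, 120),
                             seed = 3)
  prep <- preprocess_events(et, seed = 1)
  kept_pop <- et$population[prep$kept]
  expect_true(all(table(kept_pop) <= 80))
  expect_equal(max(table(kept_pop)), 80)
  expect_false(any(duplicated(prep$matrix)))
  expect_true(all(abs(colMeans(prep$matrix)) < 1e-10))
  expect_true(all(abs(apply(prep$matrix, 2, sd) - 1) < 1e-10))
  expect_identical(prep$kept, sort(prep$kept))

  # an exact duplicate row is dropped, one copy kept
  dup <- simulate_flow_events(c("a", "b"), 40, dup_rate = 0.5, seed = 3)
  pdup <- preprocess_events(dup, seed = 1)
  expect_false(any(duplicated(pdup$matrix)))

  one <- subset_events(et, et$population == "p1")
  expect_error(preprocess_events(one), "at least 2 populations")
})

test_that("re-preprocessing its own output is a z-scoring fixed point", {
  et <- simulate_flow_events(c("a", "b", "c"), c(60, 60, 60), seed = 4)
  prep <- preprocess_events(et, seed = 1)
  # population sizes already equal and rows unique: only z-scoring remains,
  # and z-scored columns are its fixed point
  again <- scale(prep$matrix)
  expect_equal(unname(again[, ]), unname(prep$matrix), tolerance = 1e-10)
})

test_that("PCA matches a direct covariance eigendecomposition", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- matrix(rnorm(50 * 10), 50, 10) %*% diag(sqrt(seq(1, 4, length.out = 10)))
    fit <- fit_pca(x)
    ev <- eigen(cov(scale(x)), symmetric = TRUE)
    expect_equal(fit$explained_variance, ev$values[1:ncol(fit$loadings)],
                 tolerance = 1e-8)
    for (j in seq_len(ncol(fit$loadings))) {
      v <- ev$vectors[, j]
      v <- v * sign(v[which.max(abs(v))])
      expect_equal(unname(fit$loadings[, j]), v, tolerance = 1e-8)
    }
  }
  # trace identity at full rank
  set.seed(9); x <- matrix(rnorm(40 * 6), 40, 6)
  expect_equal(sum(fit_pca(x)$explained_variance), 6, tolerance = 1e-8)
})

test_that("two-point PCA geometry and component-count validation", {
  x <- rbind(c(0, 0), c(3, 4))
  fit <- fit_pca(x, n_components = 1)
  expect_equal(abs(diff(fit$scores[, 1])), sqrt(2) * sqrt(2), tolerance = 1e-8)
  expect_equal(sum(fit$scores[, 1]), 0, tolerance = 1e-10)
  expect_error(fit_pca(x, n_components = 2), "n_components")
})

test_that("projection reproduces training scores and a hand-computed case", {
  et <- simulate_flow_events(c("a", "b"), c(50, 50), n_fluor = 3,
                             n_scatter = 1, seed = 6)
  fit <- fit_pca(et)
  self <- project_pca(fit, et)
  expect_equal(unname(self), unname(fit$scores), tolerance = 1e-10)

  # the training mean maps to the origin (plain-matrix model, no log rule)
  xm <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("u", "v")))
  fitm <- fit_pca(xm)
  expect_equal(as.numeric(project_pca(fitm, t(as.matrix(colMeans(xm))))),
               c(0, 0), tolerance = 1e-10)

  # explicit arithmetic: z-score then multiply by loadings
  q <- matrix(c(1.5, -0.5), 1, 2, dimnames = list(NULL, c("u", "v")))
  zq <- (q - colMeans(xm)) / apply(xm, 2, sd)
  expect_equal(unname(project_pca(fitm, q)),
               unname(zq %*% fitm$loadings), tolerance = 1e-12)

  expect_error(project_pca(fitm, matrix(1, 1, 1, dimnames = list(NULL, "u"))),
               "missing parameter")
})

test_that("diffusion map agrees with a dense brute-force eigendecomposition", {
  set.seed(2)
  x <- cbind(seq(0, 1, length.out = 60), rnorm(60, 0, 0.01))
  dm <- fit_diffusion_map(x, n_dcs = 3, n_neighbors = 8)
  or <- dense_diffusion_oracle(x, n_dcs = 3, n_neighbors = 8)
  expect_equal(or$values[1], 1, tolerance = 1e-8)
  expect_equal(dm$eigenvalues, or$values[2:4], tolerance = 1e-8)
  for (j in 1:3) {
    got <- dm$components[, j] / dm$eigenvalues[j]
    got <- got * sign(got[which.max(abs(got))])
    expect_equal(got, or$psi[, j], tolerance = 1e-6)
  }
})

test_that("diffusion map orders a 1-D ramp and is order-equivariant", {
  set.seed(3)
  pos <- sort(runif(200))
  x <- cbind(pos, 0)
  dm <- fit_diffusion_map(x, n_dcs = 2, n_neighbors = 10)
  expect_equal(abs(cor(dm$components[, 1], pos, method = "spearman")), 1)
  expect_true(all(abs(dm$eigenvalues) <= 1))
  expect_equal(dm$trivial_eigenvalue, 1, tolerance = 1e-10)

  perm <- sample(200)
  dmp <- fit_diffusion_map(x[perm, , drop = FALSE], n_dcs = 2,
                           n_neighbors = 10)
  expect_equal(abs(dmp$components[, 1]), abs(dm$components[perm, 1]),
               tolerance = 1e-8)

  far <- rbind(x, cbind(pos + 100, 0))
  expect_error(fit_diffusion_map(far, n_dcs = 2, n_neighbors = 10),
               "disconnected")
})

test_that("diffusion embedding separates simulated populations (silhouette > 0)", {
  et <- simulate_flow_events(paste0("p", 1:5), 80, seed = 8)
  prep <- preprocess_events(et, seed = 1)
  dm <- fit_diffusion_map(prep$matrix, n_dcs = 2, n_neighbors = 30)
  sil <- cluster::silhouette(as.integer(factor(prep$events$population)),
                             dist(dm$components[, 1:2]))
  expect_gt(mean(sil[, "sil_width"]), 0)
})
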