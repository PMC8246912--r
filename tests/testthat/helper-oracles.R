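# Independent brute-force oracles used by both the unit and acceptance tests.

# BH step-up by its definition: adj_i = min_{j >= i} m * p_(j) / j, capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[o[i]] <- min(vapply(i:m, function(j) m * p[o[j]] / j, numeric(1)), 1)
  adj
}

# upper-tail hypergeometric by full enumeration of all possible draws
hyper_enum_oracle <- function(a, b, universe) {
  obs <- length(intersect(a, b))
  draws <- utils::combn(length(universe), length(a))
  mean(apply(draws, 2, function(idx)
    length(intersect(universe[idx], b)) >= obs))
}

# diffusion map recomputed naively: explicit-loop dense kernel, plain
# (non-symmetric) eigendecomposition of the Markov matrix, eigenvectors
# renormalised under the degree inner product
dense_diffusion_oracle <- function(x, n_dcs, n_neighbors) {
  n <- nrow(x)
  d2 <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) d2[i, j] <- sum((x[i, ] - x[j, ])^2)
  sigma <- numeric(n)
  nnl <- vector("list", n)
  for (i in 1:n) {
    o <- order(d2[i, ])
    o <- o[o != i]
    sigma[i] <- sqrt(d2[i, o[n_neighbors]])
    nnl[[i]] <- o[1:n_neighbors]
  }
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    if (i == j || j %in% nnl[[i]] || i %in% nnl[[j]])
      K[i, j] <- exp(-d2[i, j] / (sigma[i] * sigma[j]))
  q <- rowSums(K)
  W <- K / outer(q, q)
  dd <- rowSums(W)
  P <- W / dd
  e <- eigen(P)
  ord <- order(abs(Re(e$values)), decreasing = TRUE)
  vals <- Re(e$values)[ord]
  vecs <- Re(e$vectors)[, ord, drop = FALSE]
  psi <- sapply(2:(n_dcs + 1), function(k) {
    v <- vecs[, k]
    v <- v / sqrt(sum(dd * v^2))
    v * sign(v[which.max(abs(v))])
  })
  list(values = vals, psi = psi, dd = dd)
}
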