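# Independent oracles used across the suite. They deliberately avoid the
# package's own code paths: Floyd-Warshall instead of Dijkstra, triple
# loops instead of matrix products, exhaustive enumeration instead of
# union-find Kruskal, and igraph where an external reference exists.

# Floyd-Warshall all-pairs shortest paths on distances 1/w.
fw_oracle <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[W > 0] <- 1 / W[W > 0]
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# Brute-force weighted clustering (geometric-mean triangles, global-max
# normalization), explicit triple loop.
brute_clustering <- function(W) {
  n <- nrow(W)
  Wn <- W / max(W)
  C_i <- numeric(n)
  for (i in seq_len(n)) {
    k_i <- sum(W[i, ] > 0)
    if (k_i < 2) next
    t_i <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h) {
          t_i <- t_i + (Wn[i, j] * Wn[i, h] * Wn[j, h])^(1 / 3)
        }
      }
    }
    t_i <- t_i / 2
    C_i[i] <- 2 * t_i / (k_i * (k_i - 1))
  }
  list(C = mean(C_i), C_i = C_i)
}

# Exhaustive minimum spanning tree: enumerate all (n-1)-edge subsets,
# keep spanning ones, minimize total distance 1/w. Only for tiny graphs.
brute_mst <- function(W) {
  n <- nrow(W)
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  m <- nrow(idx)
  combos <- utils::combn(m, n - 1)
  best <- NULL
  best_d <- Inf
  for (c_ in seq_len(ncol(combos))) {
    rows <- combos[, c_]
    g <- igraph::graph_from_edgelist(idx[rows, , drop = FALSE],
                                     directed = FALSE)
    if (igraph::vcount(g) < n) {
      g <- igraph::add_vertices(g, n - igraph::vcount(g))
    }
    if (igraph::components(g)$no != 1L) next
    d <- sum(1 / W[idx[rows, , drop = FALSE]])
    if (d < best_d) {
      best_d <- d
      best <- idx[rows, , drop = FALSE]
    }
  }
  list(edges = best, total_distance = best_d)
}

# ICC(3,1) through R's own ANOVA table rather than closed-form mean squares.
aov_icc_oracle <- function(M) {
  d <- data.frame(
    value = as.vector(M),
    subject = factor(rep(seq_len(nrow(M)), ncol(M))),
    session = factor(rep(seq_len(ncol(M)), each = nrow(M))))
  tab <- summary(stats::aov(value ~ subject + session, data = d))[[1]]
  bms <- tab["subject", "Mean Sq"]
  ems <- tab["Residuals", "Mean Sq"]
  k <- ncol(M)
  (bms - ems) / (bms + (k - 1) * ems)
}

# Random connected symmetric weight matrix (dense enough to be connected
# with probability ~1; regenerated if not).
rand_connected_W <- function(n, density = 0.5, seed = 1) {
  set.seed(seed)
  repeat {
    W <- matrix(0, n, n)
    ut <- upper.tri(W)
    w <- ifelse(runif(sum(ut)) < density, runif(sum(ut), 0.05, 0.95), 0)
    W[ut] <- w
    W <- W + t(W)
    g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
    if (igraph::components(g)$no == 1L) return(W)
  }
}

# Minimal deterministic cohort covariates for statistical tests.
rand_design <- function(n, seed = 1) {
  set.seed(seed)
  cohort <- tibble::tibble(
    age = runif(n, 20, 60), sex = rbinom(n, 1, 0.5),
    handedness = rbinom(n, 1, 0.85),
    total_brain_volume = rnorm(n, 1.2e6, 1e5),
    head_motion = abs(rnorm(n, 0.2, 0.05)))
  covariate_design(cohort)
}
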