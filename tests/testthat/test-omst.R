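# OMST filtering: Kruskal trees, global cost efficiency, the iterative
# filter and its contracts.

test_that("the MST of a triangle keeps the two strongest edges", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.9
  W[2, 3] <- W[3, 2] <- 0.8
  W[1, 3] <- W[3, 1] <- 0.1
  tree <- kruskal_mst(W)
  got <- sort(paste(tree$i, tree$j))
  # brute force over all three spanning trees
  oracle <- brute_mst(W)
  expect_identical(got, sort(paste(oracle$edges[, 1], oracle$edges[, 2])))
  expect_identical(got, c("1 2", "2 3"))
})

test_that("Kruskal matches exhaustive enumeration on complete 4-node graphs", {
  for (s in 1:5) {
    set.seed(s)
    W <- matrix(0, 4, 4)
    W[upper.tri(W)] <- runif(6, 0.05, 0.95)
    W <- W + t(W)
    tree <- kruskal_mst(W)
    oracle <- brute_mst(W)
    expect_equal(sum(1 / tree$w), oracle$total_distance, tolerance = 1e-12)
  }
})

test_that("a path graph is its own spanning tree", {
  W <- matrix(0, 5, 5)
  for (i in 1:4) W[i, i + 1] <- W[i + 1, i] <- 0.5
  tree <- kruskal_mst(W)
  expect_identical(nrow(tree), 4L)
  expect_identical(paste(tree$i, tree$j), paste(1:4, 2:5))
})

test_that("MST total weight agrees with igraph on random graphs", {
  for (s in 1:5) {
    W <- rand_connected_W(10, density = 0.6, seed = 100 + s)
    tree <- kruskal_mst(W)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    mst <- igraph::mst(g, weights = 1 / igraph::E(g)$weight)
    expect_equal(sum(1 / tree$w),
                 sum(1 / igraph::E(mst)$weight), tolerance = 1e-10)
  }
})

test_that("excluded edges are honored and exhaustion signals no-spanning-tree", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.9
  W[2, 3] <- W[3, 2] <- 0.8
  W[1, 3] <- W[3, 1] <- 0.1
  tree <- kruskal_mst(W, excluded_edges = cbind(1, 2))
  expect_identical(sort(paste(tree$i, tree$j)), c("1 3", "2 3"))
  expect_error(kruskal_mst(W, excluded_edges = rbind(c(1, 2), c(1, 3))),
               class = "omstnet_no_spanning_tree")
})

test_that("selecting the full graph gives zero global cost efficiency", {
  W <- rand_connected_W(8, density = 0.8, seed = 7)
  expect_equal(global_cost_efficiency(W, W), 0, tolerance = 1e-12)
})

test_that("GCE of a toy selection matches a Floyd-Warshall hand computation", {
  W <- rand_connected_W(5, density = 0.9, seed = 8)
  tree <- kruskal_mst(W)
  sel <- matrix(0, 5, 5)
  for (r in seq_len(nrow(tree))) {
    sel[tree$i[r], tree$j[r]] <- sel[tree$j[r], tree$i[r]] <- tree$w[r]
  }
  eff_from_fw <- function(M) {
    D <- fw_oracle(M)
    mean(1 / D[row(D) != col(D)])
  }
  oracle <- eff_from_fw(sel) / eff_from_fw(W) - sum(sel) / sum(W)
  expect_equal(global_cost_efficiency(sel, W), oracle, tolerance = 1e-12)
})

test_that("a tree input passes through OMST unchanged", {
  W <- matrix(0, 6, 6)
  for (i in 1:5) W[i, i + 1] <- W[i + 1, i] <- runif(1, 0.3, 0.9)
  pr <- omst_filter(W)
  expect_identical(pr$n_trees, 1L)
  expect_equal(pr$network, W, ignore_attr = TRUE)
  expect_equal(pr$wiring_cost, 1)
})

test_that("OMST output matches an independent exhaustive-round oracle", {
  # oracle: igraph MST per round (distinct weights, so ties are immaterial),
  # no early stopping, GCE via Floyd-Warshall efficiencies
  omst_oracle <- function(W) {
    n <- nrow(W)
    eff <- function(M) {
      D <- fw_oracle(M)
      mean(1 / D[row(D) != col(D)])
    }
    e0 <- eff(W)
    residual <- W
    union_sel <- matrix(0, n, n)
    best <- NULL
    repeat {
      g <- igraph::graph_from_adjacency_matrix(residual, mode = "undirected",
                                               weighted = TRUE)
      if (igraph::components(g)$no > 1) break
      mst <- igraph::mst(g, weights = 1 / igraph::E(g)$weight)
      el <- igraph::as_edgelist(mst, names = FALSE)
      if (nrow(el) < n - 1) break
      for (r in seq_len(nrow(el))) {
        i <- el[r, 1]; j <- el[r, 2]
        union_sel[i, j] <- union_sel[j, i] <- W[i, j]
        residual[i, j] <- residual[j, i] <- 0
      }
      gce <- eff(union_sel) / e0 - sum(union_sel) / sum(W)
      if (is.null(best) || gce > best$gce) {
        best <- list(network = union_sel, gce = gce)
      }
    }
    best
  }
  set.seed(30)
  W <- matrix(0, 20, 20)
  W[upper.tri(W)] <- runif(190, 0.05, 0.95)
  W <- W + t(W)
  pr <- omst_filter(W)
  oracle <- omst_oracle(W)
  expect_equal(pr$network, oracle$network, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(pr$gce, oracle$gce, tolerance = 1e-10)
})

test_that("OMST satisfies its structural contracts on random matrices", {
  for (s in 1:8) {
    W <- rand_connected_W(25, density = 0.7, seed = 200 + s)
    pr <- omst_filter(W)
    net <- pr$network
    n <- nrow(net)
    # connected
    g <- igraph::graph_from_adjacency_matrix(net > 0, mode = "undirected")
    expect_equal(igraph::components(g)$no, 1)
    # edge count within [n-1, n_trees * (n-1)] (edge-disjoint union)
    ec <- sum(net > 0) / 2
    expect_gte(ec, n - 1)
    expect_lte(ec, pr$n_trees * (n - 1))
    # wiring cost is the selected-to-total weight ratio
    expect_equal(pr$wiring_cost, sum(net) / sum(W), tolerance = 1e-12)
    # cost strictly increases along the curve
    expect_true(all(diff(pr$gce_curve$wiring_cost) > 0))
    # argmax beats the single-MST solution
    expect_gte(pr$gce, pr$gce_curve$gce[1] - 1e-12)
    # selected weights carried over from the input
    expect_true(all(net[net > 0] == W[net > 0]))
  }
})

test_that("OMST is deterministic and rejects disconnected input", {
  W <- rand_connected_W(15, density = 0.5, seed = 33)
  expect_identical(omst_filter(W), omst_filter(W))
  Wd <- matrix(0, 4, 4)
  Wd[1, 2] <- Wd[2, 1] <- 0.5
  Wd[3, 4] <- Wd[4, 3] <- 0.5
  expect_error(omst_filter(Wd), class = "omstnet_data_error")
})
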