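# Synthetic cohort generator: network structure, planted effects, BOLD
# simulation.

test_that("single-module spec yields a complete graph with weights near the block mean", {
  spec <- ground_truth_spec(n_nodes = 4, n_modules = 1,
                            within_weight_mean = 0.5,
                            between_weight_mean = 0.1, seed = 3)
  W <- generate_ground_truth_network(spec)
  off <- W[upper.tri(W)]
  expect_true(all(off > 0))
  expect_true(all(abs(off - 0.5) < 0.25))
  expect_equal(diag(W), rep(0, 4))
})

test_that("ground-truth generation is deterministic given the seed", {
  spec <- ground_truth_spec(n_nodes = 25, n_modules = 3, seed = 42)
  expect_identical(generate_ground_truth_network(spec),
                   generate_ground_truth_network(spec))
})

test_that("disconnected block structure is bridged minimally", {
  spec <- ground_truth_spec(n_nodes = 10, n_modules = 2,
                            within_weight_mean = 0.5,
                            between_weight_mean = 0, rewiring_prob = 0,
                            seed = 5)
  W <- generate_ground_truth_network(spec)
  mods <- attr(W, "modules")
  between_edges <- which(W > 0 & outer(mods, mods, "!=") & upper.tri(W))
  expect_identical(length(between_edges), 1L)
  expect_identical(attr(W, "bridges"), 1L)
  # union-find style component oracle via igraph
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  expect_equal(igraph::components(g)$no, 1)
  # removing the bridge splits the graph into exactly the two modules
  W2 <- W
  W2[W > 0 & outer(mods, mods, "!=")] <- 0
  g2 <- igraph::graph_from_adjacency_matrix(W2 > 0, mode = "undirected")
  expect_equal(igraph::components(g2)$no, 2)
})

test_that("generated matrices are symmetric, nonnegative and connected across specs", {
  for (s in 1:5) {
    spec <- ground_truth_spec(n_nodes = 20 + 5 * s, n_modules = s,
                              rewiring_prob = 0.1, seed = s)
    W <- generate_ground_truth_network(spec)
    expect_lt(max(abs(W - t(W))), 1e-12)
    expect_gte(min(W), 0)
    g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
    expect_equal(igraph::components(g)$no, 1)
  }
})

test_that("invalid generator parameters are rejected", {
  expect_error(ground_truth_spec(n_nodes = 5, n_modules = 9),
               class = "omstnet_parameter_error")
  expect_error(ground_truth_spec(within_weight_mean = 0.2,
                                 between_weight_mean = 0.4),
               class = "omstnet_parameter_error")
  expect_error(effect_spec(true_r = 1.4), class = "omstnet_parameter_error")
  expect_error(effect_spec("nodal_efficiency", target_nodes = integer()),
               class = "omstnet_parameter_error")
})

test_that("null effect cohorts show no g-metric correlation beyond sampling noise", {
  gspec <- ground_truth_spec(n_nodes = 30, n_modules = 3, seed = 2)
  espec <- effect_spec("global_clustering", true_r = 0)
  syn <- generate_cohort(200, gspec, espec, seed = 8)
  cvals <- vapply(syn$networks, function(w) clustering(w)$C, numeric(1))
  expect_lt(abs(cor(syn$cohort$g, cvals)), 3 / sqrt(200))
})

test_that("planted g-clustering correlations are recovered in expectation", {
  gspec <- ground_truth_spec(n_nodes = 40, n_modules = 4, seed = 7)
  for (r in c(0, 0.3)) {
    espec <- effect_spec("global_clustering", true_r = r)
    recovered <- vapply(1:8, function(k) {
      syn <- generate_cohort(300, gspec, espec, seed = 500 + k)
      cvals <- vapply(syn$networks, function(w) clustering(w)$C, numeric(1))
      cor(syn$cohort$g, cvals)
    }, numeric(1))
    expect_lt(abs(mean(recovered) - r), 0.05)
  }
})

test_that("efficiency-targeted effects land on efficiency, not clustering", {
  gspec <- ground_truth_spec(n_nodes = 30, n_modules = 3, seed = 4)
  espec <- effect_spec("global_efficiency", true_r = 0.5)
  syn <- generate_cohort(150, gspec, espec, seed = 21)
  evals <- vapply(syn$networks, function(w) efficiency(w)$E, numeric(1))
  cvals <- vapply(syn$networks, function(w) clustering(w)$C, numeric(1))
  expect_gt(cor(syn$driver, evals), 0.95)
  # max-normalized clustering is invariant to the uniform scaling
  expect_lt(abs(cor(syn$driver, cvals)), 0.3)
})

test_that("a two-subject cohort is valid and complete", {
  gspec <- ground_truth_spec(n_nodes = 12, n_modules = 2, seed = 1)
  syn <- generate_cohort(2, gspec, effect_spec(true_r = 0.1), seed = 1)
  expect_identical(nrow(syn$cohort), 2L)
  expect_false(anyNA(syn$cohort))
  expect_length(syn$networks, 2L)
})

test_that("cohort demographics respect their documented ranges and codings", {
  gspec <- ground_truth_spec(n_nodes = 15, n_modules = 3, seed = 9)
  syn <- generate_cohort(300, gspec, effect_spec(true_r = 0), seed = 33)
  co <- syn$cohort
  expect_true(all(co$age >= 18 & co$age <= 75))
  expect_true(all(co$sex %in% 0:1))
  expect_true(all(co$LQ >= -100 & co$LQ <= 100))
  expect_identical(co$handedness, as.integer(co$LQ >= 60))
  expect_true(all(co$head_motion > 0))
  # negative g-motion association is planted by default
  expect_lt(cor(co$g, co$head_motion), 0)
})

test_that("simulated series reproduce the target correlation structure", {
  # independence case: empty network
  W0 <- matrix(0, 6, 6)
  ts0 <- simulate_bold(W0, n_volumes = 5000, seed = 2)
  R0 <- cor(t(ts0$node_series))
  expect_lt(mean(abs(R0[upper.tri(R0)])), 0.05)

  # single-pair case at rho = 0.6
  W1 <- matrix(0, 2, 2)
  W1[1, 2] <- W1[2, 1] <- 0.6
  ts1 <- simulate_bold(W1, n_volumes = 50000, seed = 3)
  expect_lt(abs(cor(ts1$node_series[1, ], ts1$node_series[2, ]) - 0.6), 0.02)

  # seed determinism
  ts_a <- simulate_bold(W1, n_volumes = 100, seed = 11)
  ts_b <- simulate_bold(W1, n_volumes = 100, seed = 11)
  expect_identical(ts_a$node_series, ts_b$node_series)
})

test_that("empirical covariance converges to the repaired target", {
  spec <- ground_truth_spec(n_nodes = 8, n_modules = 2,
                            within_weight_mean = 0.45,
                            between_weight_mean = 0.15, seed = 6)
  W <- generate_ground_truth_network(spec)
  ts <- simulate_bold(W, n_volumes = 50000, seed = 4)
  R_emp <- cor(t(ts$node_series))
  R_target <- W
  diag(R_target) <- 1
  R_target <- as.matrix(Matrix::nearPD(R_target, corr = TRUE)$mat)
  expect_lt(max(abs(R_emp - R_target)), 0.03)
})

test_that("confound signals and motion noise enter the node series", {
  W <- matrix(0, 5, 5)
  ts_conf <- simulate_bold(W, n_volumes = 2000, n_confounds = 2, seed = 5)
  expect_identical(nrow(ts_conf$confound_series), 2L)
  # confounds induce shared variance: uncontrolled correlations exceed
  # the confound-free ones on average
  ts_free <- simulate_bold(W, n_volumes = 2000, n_confounds = 0, seed = 5)
  m_conf <- mean(abs(cor(t(ts_conf$node_series))[upper.tri(W)]))
  m_free <- mean(abs(cor(t(ts_free$node_series))[upper.tri(W)]))
  expect_gt(m_conf, m_free)
  # motion noise raises series variance
  v0 <- var(as.numeric(simulate_bold(W, 1000, seed = 6)$node_series))
  v1 <- var(as.numeric(simulate_bold(W, 1000, motion_scale = 1,
                                     seed = 6)$node_series))
  expect_gt(v1, v0)
})
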