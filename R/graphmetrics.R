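# Weighted graph metrics on pruned networks: shortest paths and efficiency
# on inverse-weight distances, Onnela-style weighted clustering with
# global-max weight normalization, characteristic path length, and
# small-world propensity against lattice and random nulls.

#' All-pairs shortest path lengths on inverse-weight distances
#'
#' Edge weights are connection strengths; path search runs on distances
#' d = 1/w (Dijkstra from every source, compiled), so strong connections
#' are short.
#'
#' @param W Connected symmetric nonnegative weight matrix, zero diagonal.
#' @return An n x n matrix of shortest path lengths, zero diagonal.
#' @export
shortest_path_lengths <- function(W) {
  check_network(W)
  D <- apsp_inverse_weight(W)
  if (any(!is.finite(D))) {
    stop_omstnet("graph is disconnected: infinite shortest path lengths",
                 "omstnet_data_error")
  }
  D
}

#' Global and nodal efficiency
#'
#' Nodal efficiency of node i is the mean inverse shortest path length from
#' i to every other node; global efficiency is the mean nodal efficiency:
#' E = (1/n) * sum_i sum_{j != i} (d_ij^w)^{-1} / (n - 1).
#'
#' @param W Connected weight matrix.
#' @return List with `E` (global) and `E_i` (nodal vector).
#' @export
efficiency <- function(W) {
  check_network(W)
  n <- nrow(W)
  if (n < 2L) stop_omstnet("efficiency needs at least 2 nodes",
                           "omstnet_data_error")
  D <- shortest_path_lengths(W)
  inv <- 1 / D
  diag(inv) <- 0
  E_i <- rowSums(inv) / (n - 1)
  list(E = mean(E_i), E_i = E_i)
}

#' Global and local weighted clustering
#'
#' Weights are first normalized by the global maximum, ŵ = w / max(w).
#' The weighted triangle intensity around node i uses the geometric-mean
#' form t_i = (1/2) * sum_{j,h} (ŵ_ij ŵ_ih ŵ_jh)^{1/3}; with k_i the number
#' of nonzero neighbors, C_i = 2 t_i / (k_i (k_i - 1)) (zero when
#' k_i < 2) and C is the node average.
#'
#' @param W Symmetric nonnegative weight matrix.
#' @return List with `C` (global) and `C_i` (local vector).
#' @export
clustering <- function(W) {
  check_network(W)
  n <- nrow(W)
  mx <- max(W)
  if (mx == 0) return(list(C = 0, C_i = rep(0, n)))
  Wn <- W / mx
  W3 <- Wn^(1 / 3)
  t_i <- diag(W3 %*% W3 %*% W3) / 2
  k_i <- rowSums(W > 0)
  C_i <- ifelse(k_i >= 2, 2 * t_i / (k_i * (k_i - 1)), 0)
  list(C = mean(C_i), C_i = C_i)
}

#' Characteristic path length
#'
#' Mean shortest path length over all ordered pairs of distinct nodes, on
#' inverse-weight distances.
#'
#' @param W Connected weight matrix.
#' @return A single number.
#' @export
characteristic_path_length <- function(W) {
  D <- shortest_path_lengths(W)
  mean(offdiag(D))
}

# Ring-lattice null: same n and edge count; observed weights sorted
# descending are assigned to node pairs in order of increasing ring
# distance (ties broken by (i, j)).
lattice_null <- function(W) {
  n <- nrow(W)
  w <- sort(W[upper.tri(W)][W[upper.tri(W)] > 0], decreasing = TRUE)
  idx <- which(upper.tri(W), arr.ind = TRUE)
  ring <- pmin(abs(idx[, 1] - idx[, 2]), n - abs(idx[, 1] - idx[, 2]))
  ord <- order(ring, idx[, 1], idx[, 2])
  L <- matrix(0, n, n)
  take <- ord[seq_along(w)]
  L[idx[take, , drop = FALSE]] <- w
  L + t(L)
}

# Random null: same n and edge count, uniformly random placement, weights
# randomly permuted; disconnected draws rejected (cap attempts).
random_null <- function(W, max_attempts = 100L) {
  n <- nrow(W)
  w <- W[upper.tri(W)][W[upper.tri(W)] > 0]
  m <- length(w)
  pairs <- which(upper.tri(W))
  for (a in seq_len(max_attempts)) {
    R <- matrix(0, n, n)
    R[sample(pairs, m)] <- sample(w)
    R <- R + t(R)
    if (is_connected_graph(R)) return(R)
  }
  stop_omstnet(sprintf(
    "no connected random null in %d attempts; graph too sparse", max_attempts),
    "omstnet_data_error")
}

#' Small-world propensity
#'
#' Locates the observed clustering coefficient and characteristic path
#' length between matched lattice and random null networks:
#' Δ_C = (C_latt - C_obs) / (C_latt - C_rand),
#' Δ_L = (L_obs - L_rand) / (L_latt - L_rand), each clamped to \[0, 1\],
#' and φ = 1 - sqrt((Δ_C² + Δ_L²) / 2).
#'
#' The lattice null reassigns the observed weights, sorted descending, to
#' node pairs in order of increasing ring distance; random nulls place the
#' same number of edges uniformly at random with randomly permuted weights
#' (disconnected draws are rejected and redrawn). Random-null statistics
#' are averaged over `n_null` realizations.
#'
#' @param W Connected weight matrix with at least 4 nodes.
#' @param n_null Number of random null networks (default 10).
#' @param seed Integer seed for the random nulls.
#' @return A list of class `swp_result`: `phi`, `delta_c`, `delta_l`,
#'   `c_obs`, `c_latt`, `c_rand`, `l_obs`, `l_latt`, `l_rand`, `n_null`,
#'   `seed`.
#' @export
small_world_propensity <- function(W, n_null = 10L, seed = 1L) {
  check_network(W)
  if (nrow(W) < 4L) stop_omstnet("need at least 4 nodes", "omstnet_data_error")
  check_scalar(n_null, "n_null", lower = 1, integer = TRUE)
  if (!is_connected_graph(W)) {
    stop_omstnet("graph must be connected", "omstnet_data_error")
  }
  c_obs <- clustering(W)$C
  l_obs <- characteristic_path_length(W)
  latt <- lattice_null(W)
  if (!is_connected_graph(latt)) {
    # Very sparse graphs can yield a disconnected ring assignment; fall
    # back to closing the ring with the smallest weights.
    stop_omstnet("lattice null disconnected; graph too sparse for SWP",
                 "omstnet_data_error")
  }
  c_latt <- clustering(latt)$C
  l_latt <- characteristic_path_length(latt)
  stats_rand <- with_seed(seed, {
    vapply(seq_len(n_null), function(k) {
      R <- random_null(W)
      c(clustering(R)$C, characteristic_path_length(R))
    }, numeric(2))
  })
  c_rand <- mean(stats_rand[1, ])
  l_rand <- mean(stats_rand[2, ])

  clamp01 <- function(x) min(max(x, 0), 1)
  dc_den <- c_latt - c_rand
  dl_den <- l_latt - l_rand
  delta_c <- if (abs(dc_den) < 1e-12) 0 else clamp01((c_latt - c_obs) / dc_den)
  delta_l <- if (abs(dl_den) < 1e-12) 0 else clamp01((l_obs - l_rand) / dl_den)
  phi <- 1 - sqrt((delta_c^2 + delta_l^2) / 2)
  phi <- min(max(phi, 0), 1)
  structure(
    list(phi = phi, delta_c = delta_c, delta_l = delta_l,
         c_obs = c_obs, c_latt = c_latt, c_rand = c_rand,
         l_obs = l_obs, l_latt = l_latt, l_rand = l_rand,
         n_null = as.integer(n_null), seed = as.integer(seed)),
    class = "swp_result"
  )
}

#' @export
print.swp_result <- function(x, ...) {
  cat(sprintf(
    "<swp_result> phi = %.4f (delta_C = %.3f, delta_L = %.3f; %d random nulls)\n",
    x$phi, x$delta_c, x$delta_l, x$n_null))
  invisible(x)
}

#' Full metric set of one network
#'
#' Computes global and nodal efficiency, global and local clustering,
#' characteristic path length, and optionally small-world propensity.
#'
#' @param W Connected weight matrix (typically an OMST-pruned network).
#' @param swp Also compute small-world propensity (slower)?
#' @param n_null,seed Passed to [small_world_propensity()].
#' @return A list of class `graph_metric_set` with `E`, `E_i`, `C`, `C_i`,
#'   `L_obs`, and `swp` (an `swp_result` or NULL).
#' @export
graph_metrics <- function(W, swp = FALSE, n_null = 10L, seed = 1L) {
  eff <- efficiency(W)
  clu <- clustering(W)
  D <- shortest_path_lengths(W)
  res <- list(E = eff$E, E_i = eff$E_i, C = clu$C, C_i = clu$C_i,
              L_obs = mean(offdiag(D)),
              swp = if (swp) small_world_propensity(W, n_null, seed))
  class(res) <- "graph_metric_set"
  res
}

#' @export
print.graph_metric_set <- function(x, ...) {
  cat(sprintf("<graph_metric_set> E = %.4f, C = %.4f, L_obs = %.4f%s\n",
              x$E, x$C, x$L_obs,
              if (!is.null(x$swp)) sprintf(", phi = %.4f", x$swp$phi) else ""))
  invisible(x)
}

#' Tidy a metric set into a long tibble
#'
#' @param x A `graph_metric_set`.
#' @param ... Unused.
#' @return A tibble with columns `metric`, `node` (NA for global values)
#'   and `value`.
#' @method tidy graph_metric_set
#' @export
tidy.graph_metric_set <- function(x, ...) {
  n <- length(x$E_i)
  out <- dplyr::bind_rows(
    tibble::tibble(metric = "global_efficiency", node = NA_integer_,
                   value = x$E),
    tibble::tibble(metric = "global_clustering", node = NA_integer_,
                   value = x$C),
    tibble::tibble(metric = "characteristic_path_length",
                   node = NA_integer_, value = x$L_obs),
    tibble::tibble(metric = "nodal_efficiency", node = seq_len(n),
                   value = x$E_i),
    tibble::tibble(metric = "local_clustering", node = seq_len(n),
                   value = x$C_i)
  )
  if (!is.null(x$swp)) {
    out <- dplyr::bind_rows(
      out,
      tibble::tibble(metric = "small_world_propensity", node = NA_integer_,
                     value = x$swp$phi))
  }
  out
}
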