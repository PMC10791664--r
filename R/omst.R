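# Orthogonal minimum spanning tree (OMST) topological filtering.
#
# Edge weights are connection strengths; spanning trees are minimal in the
# distance d = 1/w, so each tree keeps the strongest available backbone.
# Trees are extracted iteratively, each orthogonal (edge-disjoint) to all
# previous ones, and the aggregate union is scored by Global Cost
# Efficiency = normalized global efficiency - wiring cost; the aggregate
# maximizing GCE is returned.

#' Minimum spanning tree by Kruskal's algorithm
#'
#' Runs Kruskal's algorithm on the positive-weight edges of `W` not listed
#' in `excluded_edges`, with distance `1/w` so the strongest connections
#' are kept. Ties are broken deterministically by (distance, smaller node
#' index, larger node index).
#'
#' @param W Symmetric nonnegative weight matrix with zero diagonal.
#' @param excluded_edges Optional two-column matrix of node index pairs to
#'   ignore (both orientations are excluded).
#' @return A tibble with columns `i`, `j`, `w` holding the n-1 tree edges.
#'   If no spanning tree exists a condition of class
#'   `omstnet_no_spanning_tree` is signalled.
#' @export
kruskal_mst <- function(W, excluded_edges = NULL) {
  check_network(W)
  n <- nrow(W)
  ed <- edge_table(W)
  if (!is.null(excluded_edges) && nrow(excluded_edges) > 0) {
    key <- paste(pmin(excluded_edges[, 1L], excluded_edges[, 2L]),
                 pmax(excluded_edges[, 1L], excluded_edges[, 2L]))
    ed <- ed[!(paste(ed$i, ed$j) %in% key), , drop = FALSE]
  }
  ed <- ed[order(1 / ed$w, ed$i, ed$j), , drop = FALSE]
  sel <- kruskal_select(ed$i, ed$j, n)
  if (length(sel) < n - 1L) {
    stop_omstnet("no spanning tree exists on the admissible edges",
                 "omstnet_no_spanning_tree")
  }
  ed[sel, , drop = FALSE]
}

# Global efficiency of a weight matrix (inverse-distance shortest paths);
# mean over ordered pairs of inverse distance equals E. Validation is the
# caller's job: this sits in the inner OMST loop.
global_efficiency_value <- function(W) {
  D <- apsp_inverse_weight(W)
  mean(1 / offdiag(D))
}

#' Global cost efficiency of a selected subgraph
#'
#' GCE = E(selected) / E(original) - wiring cost, where the wiring cost is
#' the ratio of total selected edge weight to the total weight of the
#' original graph. Normalizing efficiency by the original graph's
#' efficiency puts both terms on a common \[0, 1\] scale.
#'
#' @param selected Weight matrix of the selected subgraph (connected).
#' @param original Weight matrix of the unfiltered graph.
#' @return A single number in (-1, 1).
#' @export
global_cost_efficiency <- function(selected, original) {
  check_network(selected, "selected")
  check_network(original, "original")
  tot <- sum(original) / 2
  if (tot <= 0) {
    stop_omstnet("original graph has no edges", "omstnet_data_error")
  }
  if (any(selected > 0 & original == 0)) {
    stop_omstnet("selected edges must be a subset of the original edges",
                 "omstnet_data_error")
  }
  e_norm <- global_efficiency_value(selected) / global_efficiency_value(original)
  cost <- (sum(selected) / 2) / tot
  e_norm - cost
}

#' OMST topological filtering of a connectivity matrix
#'
#' Iteratively extracts edge-disjoint minimum spanning trees (each tree's
#' edges are zeroed out before the next extraction, keeping the trees
#' orthogonal), aggregates them, and scores every aggregate by Global Cost
#' Efficiency. The aggregate with maximal GCE over all rounds is returned;
#' the result is always connected because it contains at least the first
#' spanning tree.
#'
#' @param C A `connectivity_matrix` at stage `"fisher_z"`, or any
#'   symmetric nonnegative weight matrix whose positive subgraph is
#'   connected.
#' @param max_trees Maximum number of trees to extract (default 50).
#' @return An object of class `pruned_graph`: `network` (selected weights,
#'   0 elsewhere), `n_trees`, `wiring_cost`, `gce`, and `gce_curve`, a
#'   tibble of (round, gce, wiring_cost) evaluated at every round.
#' @export
omst_filter <- function(C, max_trees = 50L) {
  W <- matrix(as.numeric(C), nrow(C), ncol(C), dimnames = dimnames(C))
  check_network(W, "C")
  check_scalar(max_trees, "max_trees", lower = 1, integer = TRUE)
  if (!is_connected_graph(W)) {
    stop_omstnet("positive-weight subgraph is disconnected; OMST needs a connected input",
                 "omstnet_data_error")
  }
  n <- nrow(W)
  e_orig <- global_efficiency_value(W)
  tot <- sum(W) / 2

  # The distance order 1/w (ties by node indices) never changes across
  # rounds, so the edge list is sorted once; each round runs union-find
  # Kruskal over the edges not yet claimed by an earlier tree.
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  ei <- idx[, 1L]
  ej <- idx[, 2L]
  ew <- W[idx]
  ord <- order(1 / ew, ei, ej)
  ei <- ei[ord]; ej <- ej[ord]; ew <- ew[ord]
  avail <- rep(TRUE, length(ei))

  union_sel <- matrix(0, n, n)
  rounds <- integer(0)
  gces <- costs <- numeric(0)
  best <- NULL
  m <- 0L
  while (m < max_trees) {
    cand <- which(avail)
    sel <- kruskal_select(ei[cand], ej[cand], n)
    if (length(sel) < n - 1L) break
    m <- m + 1L
    take <- cand[sel]
    avail[take] <- FALSE
    tree_idx <- cbind(ei[take], ej[take])
    union_sel[tree_idx] <- ew[take]
    union_sel[tree_idx[, 2:1, drop = FALSE]] <- ew[take]
    cost <- (sum(union_sel) / 2) / tot
    gce <- global_efficiency_value(union_sel) / e_orig - cost
    rounds[m] <- m; gces[m] <- gce; costs[m] <- cost
    if (is.null(best) || gce > best$gce) {
      best <- list(network = union_sel, n_trees = m, wiring_cost = cost,
                   gce = gce)
    }
  }
  if (is.null(best)) {
    stop_omstnet("no spanning tree could be extracted", "omstnet_data_error")
  }
  dimnames(best$network) <- dimnames(W)
  structure(
    c(best, list(gce_curve = tibble::tibble(round = rounds, gce = gces,
                                            wiring_cost = costs))),
    class = "pruned_graph"
  )
}

#' @export
print.pruned_graph <- function(x, ...) {
  cat(sprintf(
    "<pruned_graph> %d nodes, %d edges from %d orthogonal MSTs; GCE = %.4f, wiring cost = %.4f\n",
    nrow(x$network), sum(x$network > 0) / 2, x$n_trees, x$gce,
    x$wiring_cost))
  invisible(x)
}

#' GCE curve of an OMST filtering run
#'
#' @param object A `pruned_graph`.
#' @param ... Unused.
#' @return A ggplot of global cost efficiency against OMST round, with the
#'   selected round highlighted.
#' @method autoplot pruned_graph
#' @export
autoplot.pruned_graph <- function(object, ...) {
  ggplot2::ggplot(object$gce_curve,
                  ggplot2::aes(x = .data$round, y = .data$gce)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$n_trees, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "OMST round (trees aggregated)",
                  y = "Global cost efficiency",
                  title = "OMST global cost efficiency curve") +
    ggplot2::theme_minimal()
}
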