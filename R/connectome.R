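# Connectome construction: partial correlations controlling confound series,
# negative clipping, Fisher z. The stage tag enforces the fixed pipeline
# order raw_r -> clipped -> fisher_z.

new_connectivity_matrix <- function(values, stage) {
  stopifnot(stage %in% c("raw_r", "clipped", "fisher_z"))
  structure(values, class = c("connectivity_matrix", "matrix", "array"),
            stage = stage)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d x %d, stage = %s\n",
              nrow(x), ncol(x), attr(x, "stage")))
  invisible(x)
}

conn_stage <- function(C) attr(C, "stage")

#' Pairwise partial correlations controlling confound series
#'
#' Computes the functional connectivity matrix of a time-series bundle:
#' every node series is residualized on the confound series (with
#' intercept), and entry (i, j) is the Pearson correlation of the
#' residualized series of nodes i and j. With zero confounds this reduces
#' to the plain correlation matrix. The diagonal is forced to zero.
#'
#' Controls are the confound series only, not the remaining nodes, so the
#' estimate is well defined even when the number of nodes exceeds the
#' number of volumes.
#'
#' @param ts A `ts_bundle` (see [simulate_bold()]) or a list with elements
#'   `node_series` (n_nodes x T) and `confound_series` (n_conf x T).
#' @return A `connectivity_matrix` at stage `"raw_r"`.
#' @export
partial_correlation_matrix <- function(ts) {
  X <- ts$node_series
  Z <- ts$confound_series
  if (!is.matrix(X) || !is.numeric(X)) {
    stop_omstnet("`node_series` must be a numeric matrix", "omstnet_data_error")
  }
  n <- nrow(X)
  T_ <- ncol(X)
  n_conf <- if (is.null(Z)) 0L else nrow(Z)
  if (T_ <= n_conf + 2L) {
    stop_omstnet(sprintf(
      "need more volumes than confounds + 2 (T = %d, confounds = %d)",
      T_, n_conf), "omstnet_data_error")
  }
  sds <- apply(X, 1L, sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    stop_omstnet(sprintf("constant node series: %s",
                         paste(bad, collapse = ", ")),
                 "omstnet_data_error")
  }
  R <- if (n_conf > 0L) {
    design <- cbind(1, t(Z))
    resid <- t(X) - design %*% qr.coef(qr(design), t(X))
    rs <- apply(resid, 2L, sd)
    if (any(rs < 1e-12)) {
      stop_omstnet(sprintf("zero-variance residual series for node(s): %s",
                           paste(which(rs < 1e-12), collapse = ", ")),
                   "omstnet_data_error")
    }
    cor(resid)
  } else {
    cor(t(X))
  }
  R <- (R + t(R)) / 2
  diag(R) <- 0
  dimnames(R) <- list(rownames(X), rownames(X))
  new_connectivity_matrix(R, "raw_r")
}

#' Replace negative correlations with zeros
#'
#' @param C A `connectivity_matrix` at stage `"raw_r"`.
#' @return A `connectivity_matrix` at stage `"clipped"`.
#' @export
clip_negatives <- function(C) {
  if (!inherits(C, "connectivity_matrix") || conn_stage(C) != "raw_r") {
    stop_omstnet("`C` must be a connectivity_matrix at stage raw_r",
                 "omstnet_data_error")
  }
  new_connectivity_matrix(pmax(unclass(C), 0), "clipped")
}

#' Fisher z-transform of clipped correlations
#'
#' Applies artanh entrywise. Entries equal to 1 (perfectly correlated
#' nodes) are first capped at 1 - 1e-7 so all edge weights stay finite,
#' as required by downstream spanning-tree filtering.
#'
#' @param C A `connectivity_matrix` at stage `"clipped"`.
#' @return A `connectivity_matrix` at stage `"fisher_z"`.
#' @export
fisher_z <- function(C) {
  if (!inherits(C, "connectivity_matrix") || conn_stage(C) != "clipped") {
    stop_omstnet("`C` must be a connectivity_matrix at stage clipped",
                 "omstnet_data_error")
  }
  V <- unclass(C)
  if (max(V) > 1) {
    stop_omstnet("correlation entries > 1 are not valid", "omstnet_data_error")
  }
  V <- pmin(V, 1 - 1e-7)
  new_connectivity_matrix(atanh(V), "fisher_z")
}

#' Concatenate sessions of one subject
#'
#' Joins node (and confound) series along time after z-standardizing each
#' series within session, removing inter-session scale and offset
#' differences before correlations are computed on the concatenated data.
#'
#' @param bundles A list of `ts_bundle` objects with identical node and
#'   confound counts.
#' @param standardize Standardize each series per session first (default
#'   TRUE).
#' @return A single `ts_bundle` with total T equal to the summed session
#'   lengths.
#' @export
concatenate_sessions <- function(bundles, standardize = TRUE) {
  if (!length(bundles)) {
    stop_omstnet("`bundles` must be a non-empty list", "omstnet_data_error")
  }
  n_nodes <- vapply(bundles, function(b) nrow(b$node_series), integer(1))
  n_conf <- vapply(bundles, function(b) nrow(b$confound_series), integer(1))
  if (length(unique(n_nodes)) != 1L || length(unique(n_conf)) != 1L) {
    stop_omstnet("sessions differ in node or confound count",
                 "omstnet_data_error")
  }
  std <- function(M) {
    if (!standardize || nrow(M) == 0L) return(M)
    t(apply(M, 1L, function(x) (x - mean(x)) / sd(x)))
  }
  node <- do.call(cbind, lapply(bundles, function(b) std(b$node_series)))
  conf <- do.call(cbind, lapply(bundles, function(b) std(b$confound_series)))
  out <- bundles[[1L]]
  out$node_series <- node
  out$confound_series <- conf
  out$session_id <- paste(vapply(bundles, function(b) b$session_id,
                                 character(1)), collapse = "+")
  out
}

# Networks -> fisher_z connectivity shortcut used when a cohort supplies
# precomputed symmetric matrices instead of time series.
network_to_connectivity <- function(W) {
  check_network(W)
  C <- new_connectivity_matrix(unclass(W), "raw_r")
  fisher_z(clip_negatives(C))
}
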