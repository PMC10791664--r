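# Reliability: ICC(3,1) test-retest consistency and split-half reliability
# with the Spearman-Brown correction.

#' ICC(3,1): two-way mixed-effects, single-measurement consistency
#'
#' Computes the intraclass correlation from the two-way subjects x sessions
#' ANOVA decomposition: ICC = (BMS - EMS) / (BMS + (k - 1) * EMS), where
#' BMS is the between-subjects mean square and EMS the residual mean
#' square after removing subject and session effects.
#'
#' @param measurements Complete subjects x sessions numeric matrix with at
#'   least 3 subjects and 2 sessions.
#' @return A single number (<= 1).
#' @export
icc_3_1 <- function(measurements) {
  M <- as.matrix(measurements)
  if (anyNA(M)) stop_omstnet("missing cells are not supported",
                             "omstnet_data_error")
  n <- nrow(M)
  k <- ncol(M)
  if (n < 3L || k < 2L) {
    stop_omstnet("need >= 3 subjects and >= 2 sessions", "omstnet_data_error")
  }
  grand <- mean(M)
  row_m <- rowMeans(M)
  col_m <- colMeans(M)
  bms <- k * sum((row_m - grand)^2) / (n - 1)
  resid <- M - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand
  ems <- sum(resid^2) / ((n - 1) * (k - 1))
  (bms - ems) / (bms + (k - 1) * ems)
}

#' Spearman-Brown correction of a split-half correlation
#'
#' SB = 2r / (1 + r), adjusting a half-length correlation to full test
#' length.
#'
#' @param r Split-half Pearson correlation(s).
#' @return Corrected coefficient(s).
#' @export
spearman_brown <- function(r) 2 * r / (1 + r)

# Run one bundle through connectome -> OMST -> metrics.
bundle_to_metrics <- function(ts, max_trees = 50L) {
  C <- fisher_z(clip_negatives(partial_correlation_matrix(ts)))
  pruned <- omst_filter(C, max_trees = max_trees)
  graph_metrics(pruned$network)
}

#' Split-half reliability of graph metrics
#'
#' Splits every subject's time series into odd- and even-indexed volumes,
#' pushes both halves independently through the full pipeline (partial
#' correlations, clipping, Fisher z, OMST, graph metrics), correlates each
#' metric across subjects between the halves, and applies the
#' Spearman-Brown correction SB = 2r / (1 + r).
#'
#' @param bundles List of `ts_bundle` objects, one per subject, each with
#'   at least 20 volumes.
#' @param metrics Global metrics to report.
#' @param max_trees OMST round cap.
#' @return A tibble of class `reliability_result`: `metric`, `r`
#'   (uncorrected) and `sb`.
#' @export
split_half_reliability <- function(bundles,
                                   metrics = c("global_efficiency",
                                               "global_clustering"),
                                   max_trees = 50L) {
  if (length(bundles) < 3L) {
    stop_omstnet("need at least 3 subjects", "omstnet_data_error")
  }
  Ts <- vapply(bundles, function(b) ncol(b$node_series), integer(1))
  if (any(Ts < 20L)) {
    stop_omstnet("every subject needs at least 20 volumes",
                 "omstnet_data_error")
  }
  half <- function(b, idx) {
    b$node_series <- b$node_series[, idx, drop = FALSE]
    if (nrow(b$confound_series)) {
      b$confound_series <- b$confound_series[, idx, drop = FALSE]
    }
    b
  }
  vals <- purrr::map(bundles, function(b) {
    T_ <- ncol(b$node_series)
    odd <- bundle_to_metrics(half(b, seq(1L, T_, by = 2L)), max_trees)
    even <- bundle_to_metrics(half(b, seq(2L, T_, by = 2L)), max_trees)
    pick <- function(ms) c(global_efficiency = ms$E,
                           global_clustering = ms$C,
                           characteristic_path_length = ms$L_obs)
    list(odd = pick(odd), even = pick(even))
  })
  out <- dplyr::bind_rows(lapply(metrics, function(m) {
    o <- vapply(vals, function(v) v$odd[[m]], numeric(1))
    e <- vapply(vals, function(v) v$even[[m]], numeric(1))
    r <- cor(o, e)
    tibble::tibble(metric = m, r = r, sb = spearman_brown(r))
  }))
  class(out) <- c("reliability_result", class(out))
  out
}

#' Test-retest reliability of metrics across sessions
#'
#' Convenience wrapper computing ICC(3,1) per metric from a long tibble of
#' per-subject, per-session metric values.
#'
#' @param df Tibble with columns `subject`, `session`, `metric`, `value`.
#' @return A tibble of class `reliability_result`: `metric`, `icc`.
#' @export
test_retest_reliability <- function(df) {
  need <- c("subject", "session", "metric", "value")
  if (!all(need %in% names(df))) {
    stop_omstnet("df needs columns subject, session, metric, value",
                 "omstnet_data_error")
  }
  out <- df |>
    dplyr::group_by(.data$metric) |>
    dplyr::group_modify(function(d, key) {
      M <- tidyr::pivot_wider(d, id_cols = "subject",
                              names_from = "session",
                              values_from = "value")
      tibble::tibble(icc = icc_3_1(as.matrix(M[, -1L])))
    }) |>
    dplyr::ungroup()
  class(out) <- c("reliability_result", class(out))
  out
}
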