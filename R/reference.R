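# Reference bookkeeping quantities of the multi-center study design the
# package re-implements, and the published global association table shipped
# with the package for reproduction checks.

#' Number of unique edges of the whole-brain parcellation network
#'
#' A network on `n_cortical + n_subcortical` nodes in which every region
#' can connect to every other region has one matrix triangle of
#' n * (n - 1) / 2 unique edges (no self-connections).
#'
#' @param n_cortical Number of cortical areas (default 360: 180 per
#'   hemisphere in the multi-modal parcellation).
#' @param n_subcortical Number of subcortical areas (default 16: 8 per
#'   hemisphere).
#' @return Integer edge count.
#' @export
parcellation_edge_count <- function(n_cortical = 360L, n_subcortical = 16L) {
  check_scalar(n_cortical, "n_cortical", lower = 0, integer = TRUE)
  check_scalar(n_subcortical, "n_subcortical", lower = 0, integer = TRUE)
  n <- n_cortical + n_subcortical
  as.integer(n * (n - 1) / 2)
}

#' Bonferroni-corrected per-test threshold
#'
#' @param alpha Family-wise error level (default 0.05).
#' @param m Number of tests in the family (default 16, the 4 x 4
#'   source-by-target prediction grid including self-prediction).
#' @return The per-test cutoff `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 16L) {
  check_scalar(alpha, "alpha", lower = 0, upper = 1)
  check_scalar(m, "m", lower = 1, integer = TRUE)
  alpha / m
}

#' Reference multi-center global association table
#'
#' Partial correlations between g and the three global metrics (global
#' efficiency, global clustering, small-world propensity) reported for the
#' ten multi-center resting-state data sets, shipped with the package as a
#' plain-text fixture; `significant` flags the entries below the 0.05
#' level.
#'
#' @return A tibble with columns `dataset`, `metric`, `r`, `p`,
#'   `significant`.
#' @export
reference_global_associations <- function() {
  path <- system.file("extdata", "global_association_reference.csv",
                      package = "omstnet", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "numeric",
                                       "numeric", "integer"))
  tibble::as_tibble(df)
}

#' Summary of the significant reference associations
#'
#' Mean and standard deviation of the reference partial correlations that
#' reached significance, the headline effect-size summary of the global
#' analysis.
#'
#' @return A tibble with `n_significant`, `mean_r`, `sd_r`.
#' @export
summarize_significant_associations <- function() {
  ref <- reference_global_associations()
  sig <- ref[ref$significant == 1L, ]
  tibble::tibble(n_significant = nrow(sig), mean_r = mean(sig$r),
                 sd_r = sd(sig$r))
}
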