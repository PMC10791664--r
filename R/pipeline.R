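# End-to-end orchestration: simulate (or ingest) cohorts, build
# connectomes, prune with OMST, compute metrics, run the association
# battery, and assemble a reproducible report.

pipeline_defaults <- function() {
  list(
    n_cohorts = 2L,
    n_subjects = 60L,
    n_nodes = 40L,
    n_modules = 4L,
    within_weight_mean = 0.5,
    between_weight_mean = 0.2,
    rewiring_prob = 0.05,
    target_metric = "global_clustering",
    target_nodes = integer(),
    true_r = 0.3,
    noise_sd = 0.005,
    effect_strength = 0.2,
    simulate_series = FALSE,
    n_volumes = 200L,
    n_confounds = 3L,
    max_trees = 50L,
    swp = FALSE,
    n_null = 10L,
    lambda_rule = "min",
    m_bonferroni = NULL,
    nodal_metrics = c("nodal_efficiency", "local_clustering"),
    seed = 1L
  )
}

#' Build and validate a pipeline configuration
#'
#' All tunables of the individual stages live here: synthetic-cohort shape
#' and planted effect, whether BOLD-like series are simulated or subject
#' networks are used as connectivity directly, OMST round cap, small-world
#' propensity settings, elastic-net penalty rule, Bonferroni family size
#' (defaults to the squared number of cohorts) and the master seed.
#' Unknown keys are rejected before any computation.
#'
#' @param ... Named overrides of the defaults.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  overrides <- list(...)
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop_omstnet(paste("unknown configuration key(s):",
                       paste(unknown, collapse = ", ")),
                 "omstnet_config_error")
  }
  cfg <- utils::modifyList(defaults, overrides)
  check_scalar(cfg$n_cohorts, "n_cohorts", lower = 1, integer = TRUE)
  check_scalar(cfg$n_subjects, "n_subjects", lower = 2, integer = TRUE)
  check_scalar(cfg$n_volumes, "n_volumes", lower = 10, integer = TRUE)
  if (!is.logical(cfg$simulate_series) || !is.logical(cfg$swp)) {
    stop_omstnet("`simulate_series` and `swp` must be logical",
                 "omstnet_config_error")
  }
  if (!cfg$lambda_rule %in% c("min", "1se")) {
    stop_omstnet("`lambda_rule` must be 'min' or '1se'",
                 "omstnet_config_error")
  }
  if (is.null(cfg$m_bonferroni)) cfg$m_bonferroni <- cfg$n_cohorts^2
  structure(cfg, class = "pipeline_config")
}

# Metrics of every subject in one cohort; returns global tibble + nodal
# matrices + OMST diagnostics.
cohort_metrics <- function(syn, cfg, cohort_seed) {
  n_sub <- nrow(syn$cohort)
  glob <- vector("list", n_sub)
  E_i <- C_i <- matrix(NA_real_, n_sub, cfg$n_nodes)
  diag_rows <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    C <- if (cfg$simulate_series) {
      ts <- simulate_bold(syn$networks[[s]], n_volumes = cfg$n_volumes,
                          n_confounds = cfg$n_confounds,
                          motion_scale = syn$cohort$head_motion[s],
                          seed = split_seed(cohort_seed, 100 + s),
                          subject_id = syn$cohort$id[s])
      fisher_z(clip_negatives(partial_correlation_matrix(ts)))
    } else {
      network_to_connectivity(syn$networks[[s]])
    }
    pruned <- omst_filter(C, max_trees = cfg$max_trees)
    ms <- graph_metrics(pruned$network, swp = cfg$swp, n_null = cfg$n_null,
                        seed = split_seed(cohort_seed, 200 + s))
    glob[[s]] <- tibble::tibble(
      id = syn$cohort$id[s], g = syn$cohort$g[s],
      global_efficiency = ms$E, global_clustering = ms$C,
      characteristic_path_length = ms$L_obs,
      small_world_propensity = if (cfg$swp) ms$swp$phi else NA_real_)
    E_i[s, ] <- ms$E_i
    C_i[s, ] <- ms$C_i
    diag_rows[[s]] <- tibble::tibble(
      id = syn$cohort$id[s], n_trees = pruned$n_trees,
      wiring_cost = pruned$wiring_cost, gce = pruned$gce)
  }
  colnames(E_i) <- colnames(C_i) <- sprintf("node%03d", seq_len(cfg$n_nodes))
  list(global = dplyr::bind_rows(glob),
       nodal = list(nodal_efficiency = E_i, local_clustering = C_i),
       omst_diagnostics = dplyr::bind_rows(diag_rows))
}

#' Run the full analysis pipeline on synthetic cohorts
#'
#' Executes the stages in fixed order: cohort generation, connectivity
#' (simulated series + partial correlations, or subject networks taken as
#' raw correlations), negative clipping, Fisher z, OMST pruning, graph
#' metrics, winsorized Holm-corrected partial correlations of g with the
#' global metrics, elastic-net selection of nodal predictors, cross-sample
#' prediction with Bonferroni correction, and predictor-set overlap.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `analysis_report`: `associations` (tibble with a
#'   `cohort` column), `predictions` (source x target grid per nodal
#'   metric), `overlap` (per nodal metric), `enet` (per cohort and metric),
#'   `omst_diagnostics`, `metrics` (per-cohort global metric tibbles),
#'   `config`, `seed_registry`, `version`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    stop_omstnet("`config` must be a pipeline_config", "omstnet_config_error")
  }
  cfg <- config
  gspec <- ground_truth_spec(
    n_nodes = cfg$n_nodes, n_modules = cfg$n_modules,
    within_weight_mean = cfg$within_weight_mean,
    between_weight_mean = cfg$between_weight_mean,
    rewiring_prob = cfg$rewiring_prob, seed = split_seed(cfg$seed, 0L))
  espec <- effect_spec(target_metric = cfg$target_metric,
                       target_nodes = cfg$target_nodes,
                       true_r = cfg$true_r, noise_sd = cfg$noise_sd,
                       effect_strength = cfg$effect_strength)

  cohort_names <- sprintf("cohort%d", seq_len(cfg$n_cohorts))
  seed_registry <- list(master = cfg$seed)
  cohorts <- list()
  metrics <- list()
  for (k in seq_len(cfg$n_cohorts)) {
    cohort_seed <- split_seed(cfg$seed, k)
    seed_registry[[cohort_names[k]]] <- cohort_seed
    syn <- generate_cohort(cfg$n_subjects, gspec, espec, seed = cohort_seed)
    cohorts[[k]] <- syn
    metrics[[k]] <- cohort_metrics(syn, cfg, cohort_seed)
  }
  names(metrics) <- cohort_names

  assoc_metrics <- c("global_efficiency", "global_clustering",
                     if (cfg$swp) "small_world_propensity")
  associations <- dplyr::bind_rows(lapply(seq_len(cfg$n_cohorts), function(k) {
    at <- association_table(metrics[[k]]$global, cohorts[[k]]$cohort,
                            metrics = assoc_metrics)
    dplyr::mutate(tibble::as_tibble(at), cohort = cohort_names[k],
                  .before = 1L)
  }))

  enet <- list()
  for (k in seq_len(cfg$n_cohorts)) {
    design <- covariate_design(cohorts[[k]]$cohort)
    enet[[cohort_names[k]]] <- lapply(cfg$nodal_metrics, function(m) {
      elastic_net_select(metrics[[k]]$nodal[[m]],
                         metrics[[k]]$global$g, design,
                         seed = split_seed(cfg$seed, 300 + k),
                         lambda_rule = cfg$lambda_rule)
    })
    names(enet[[cohort_names[k]]]) <- cfg$nodal_metrics
  }

  predictions <- dplyr::bind_rows(lapply(cfg$nodal_metrics, function(m) {
    dplyr::bind_rows(lapply(seq_len(cfg$n_cohorts), function(src) {
      dplyr::bind_rows(lapply(seq_len(cfg$n_cohorts), function(tgt) {
        res <- cross_sample_predict(
          enet[[cohort_names[src]]][[m]]$selected,
          metrics[[tgt]]$nodal[[m]], metrics[[tgt]]$global$g,
          covariate_design(cohorts[[tgt]]$cohort),
          source = cohort_names[src], target = cohort_names[tgt],
          m_bonferroni = cfg$m_bonferroni)
        dplyr::mutate(tibble::as_tibble(res), metric = m, .before = 1L)
      }))
    }))
  }))

  overlap <- lapply(cfg$nodal_metrics, function(m) {
    supports <- lapply(cohort_names, function(cn) enet[[cn]][[m]]$selected)
    names(supports) <- cohort_names
    effects <- lapply(cohort_names, function(cn) enet[[cn]][[m]]$beta)
    names(effects) <- cohort_names
    if (cfg$n_cohorts >= 2L) predictor_overlap(supports, effects) else NULL
  })
  names(overlap) <- cfg$nodal_metrics

  structure(
    list(associations = associations, predictions = predictions,
         overlap = overlap, enet = enet,
         omst_diagnostics = dplyr::bind_rows(lapply(seq_len(cfg$n_cohorts),
           function(k) dplyr::mutate(metrics[[k]]$omst_diagnostics,
                                     cohort = cohort_names[k], .before = 1L))),
         metrics = lapply(metrics, function(m) m$global),
         cohorts = lapply(cohorts, function(x) x$cohort),
         config = unclass(cfg), seed_registry = seed_registry,
         version = as.character(utils::packageVersion("omstnet"))),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d cohort(s) x %d subjects, %d nodes (omstnet %s)\n",
              x$config$n_cohorts, x$config$n_subjects, x$config$n_nodes,
              x$version))
  cat("\nAssociations (partial r of g with global metrics):\n")
  print(x$associations)
  cat("\nCross-sample prediction grid:\n")
  print(x$predictions)
  invisible(x)
}

#' Write an analysis report to JSON
#'
#' Serializes all report tables, the configuration echo and the seed
#' registry; rerunning the pipeline with the same configuration reproduces
#' the file bit for bit.
#'
#' @param report An `analysis_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  payload <- list(
    associations = report$associations,
    predictions = report$predictions,
    overlap = lapply(report$overlap, function(o) {
      if (is.null(o)) return(NULL)
      list(all_way = o$all_way, overlap_pct = o$overlap_pct)
    }),
    omst_diagnostics = report$omst_diagnostics,
    config = report$config, seed_registry = report$seed_registry,
    version = report$version)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
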