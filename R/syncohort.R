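#' Specify a ground-truth modular network
#'
#' Describes the group-level "true" functional network from which synthetic
#' subject networks are perturbed: a weighted stochastic block structure with
#' `n_modules` communities, strong within-module weights, weaker
#' between-module weights, and optional long-range rewiring that gives the
#' graph a small-world flavour.
#'
#' @param n_nodes Number of network nodes. Defaults to 376, the size of a
#'   whole-brain parcellation with 360 cortical and 16 subcortical regions.
#' @param n_modules Number of modules (communities).
#' @param within_weight_mean Mean edge weight inside modules, on the
#'   correlation scale, in (0, 1).
#' @param between_weight_mean Mean edge weight between modules; must be
#'   strictly smaller than `within_weight_mean` and may be 0.
#' @param rewiring_prob Probability that a within-module edge swaps its
#'   weight with a between-module pair, creating a long-range shortcut.
#' @param weight_jitter_sd SD of the Gaussian jitter applied to edge weights
#'   around their block mean.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return An object of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(n_nodes = 376L, n_modules = 4L,
                              within_weight_mean = 0.5,
                              between_weight_mean = 0.2,
                              rewiring_prob = 0.05,
                              weight_jitter_sd = 0.05,
                              seed = 1L) {
  check_scalar(n_nodes, "n_nodes", lower = 2, integer = TRUE)
  check_scalar(n_modules, "n_modules", lower = 1, upper = n_nodes,
               integer = TRUE)
  check_scalar(within_weight_mean, "within_weight_mean", lower = 1e-6,
               upper = 1 - 1e-6)
  check_scalar(between_weight_mean, "between_weight_mean", lower = 0,
               upper = 1 - 1e-6)
  if (within_weight_mean <= between_weight_mean) {
    stop_omstnet("`within_weight_mean` must exceed `between_weight_mean`",
                 "omstnet_parameter_error")
  }
  check_scalar(rewiring_prob, "rewiring_prob", lower = 0, upper = 1)
  check_scalar(weight_jitter_sd, "weight_jitter_sd", lower = 0)
  check_scalar(seed, "seed", integer = TRUE)
  structure(
    list(n_nodes = as.integer(n_nodes), n_modules = as.integer(n_modules),
         within_weight_mean = within_weight_mean,
         between_weight_mean = between_weight_mean,
         rewiring_prob = rewiring_prob,
         weight_jitter_sd = weight_jitter_sd,
         seed = as.integer(seed)),
    class = "ground_truth_spec"
  )
}

#' Specify a planted association between g and a graph metric
#'
#' Controls how subject networks are modulated by a latent driver variable
#' that correlates with the general-intelligence factor g at `true_r`, so
#' that downstream association statistics can be checked against a known
#' effect size.
#'
#' @param target_metric One of `"global_efficiency"`, `"global_clustering"`,
#'   `"nodal_efficiency"`, `"local_clustering"`.
#' @param target_nodes Node indices carrying the effect for nodal targets;
#'   must be empty for global targets.
#' @param true_r Planted correlation between g and the subject-level metric
#'   driver, in \[-1, 1\].
#' @param noise_sd SD of the multiplicative log-normal edge jitter applied
#'   independently per subject (network-level measurement noise).
#' @param effect_strength Relative modulation of the targeted weights per
#'   driver SD.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(target_metric = c("global_clustering",
                                          "global_efficiency",
                                          "nodal_efficiency",
                                          "local_clustering"),
                        target_nodes = integer(),
                        true_r = 0.3, noise_sd = 0.005,
                        effect_strength = 0.2) {
  target_metric <- match.arg(target_metric)
  if (!is.numeric(true_r) || length(true_r) != 1L || !is.finite(true_r) ||
      abs(true_r) > 1) {
    stop_omstnet("`true_r` must be a single number in [-1, 1]",
                 "omstnet_parameter_error")
  }
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(effect_strength, "effect_strength", lower = 0, upper = 0.3)
  global <- target_metric %in% c("global_efficiency", "global_clustering")
  if (global && length(target_nodes) > 0) {
    stop_omstnet("`target_nodes` must be empty for global targets",
                 "omstnet_parameter_error")
  }
  if (!global && length(target_nodes) == 0) {
    stop_omstnet("nodal targets need at least one entry in `target_nodes`",
                 "omstnet_parameter_error")
  }
  structure(
    list(target_metric = target_metric,
         target_nodes = as.integer(target_nodes),
         true_r = true_r, noise_sd = noise_sd,
         effect_strength = effect_strength),
    class = "effect_spec"
  )
}

module_assignment <- function(spec) {
  sort(rep_len(seq_len(spec$n_modules), spec$n_nodes))
}

#' Generate the ground-truth network of a synthetic study
#'
#' Draws a symmetric, zero-diagonal, nonnegative weighted adjacency matrix
#' with modular block structure and optional long-range rewired edges. The
#' positive-weight subgraph is always returned connected: if the block
#' structure leaves modules disconnected (e.g. `between_weight_mean = 0`),
#' a minimal chain of single bridge edges is added between components.
#'
#' @param spec A [ground_truth_spec()].
#' @return A `n_nodes` x `n_nodes` weight matrix with a `modules` attribute
#'   (integer module label per node) and a `bridges` attribute counting the
#'   bridge edges added to restore connectivity.
#' @export
generate_ground_truth_network <- function(spec) {
  if (!inherits(spec, "ground_truth_spec")) {
    stop_omstnet("`spec` must be a ground_truth_spec", "omstnet_parameter_error")
  }
  n <- spec$n_nodes
  mods <- module_assignment(spec)
  with_seed(spec$seed, {
    same <- outer(mods, mods, "==")
    mu <- ifelse(same, spec$within_weight_mean, spec$between_weight_mean)
    W <- matrix(0, n, n)
    ut <- upper.tri(W)
    w <- mu[ut]
    jitter <- rnorm(sum(ut), 0, spec$weight_jitter_sd)
    w <- ifelse(w > 0, pmin(pmax(w + jitter, 1e-4), 1 - 1e-4), 0)
    W[ut] <- w

    # Long-range rewiring: swap selected within-module weights with
    # between-module pairs, preserving the overall weight multiset.
    if (spec$rewiring_prob > 0 && spec$n_modules > 1L) {
      within_idx <- which(ut & same)
      between_idx <- which(ut & !same)
      pick <- within_idx[runif(length(within_idx)) < spec$rewiring_prob]
      if (length(pick) > 0 && length(between_idx) > 0) {
        swap <- sample(between_idx, min(length(pick), length(between_idx)))
        pick <- pick[seq_along(swap)]
        tmp <- W[pick]
        W[pick] <- W[swap]
        W[swap] <- tmp
      }
    }
    W <- W + t(W)

    # Restore connectivity with a minimal set of bridges between components.
    n_bridges <- 0L
    repeat {
      comp <- graph_components(W)
      if (max(comp) == 1L) break
      a <- which(comp == 1L)[1L]
      b <- which(comp == 2L)[1L]
      W[a, b] <- W[b, a] <- spec$within_weight_mean
      n_bridges <- n_bridges + 1L
    }
    attr(W, "modules") <- mods
    attr(W, "bridges") <- n_bridges
    W
  })
}

# Connected-component labels of the positive subgraph (BFS).
graph_components <- function(W) {
  n <- nrow(W)
  comp <- integer(n)
  label <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    label <- label + 1L
    frontier <- s
    comp[s] <- label
    while (length(frontier)) {
      nb <- which(colSums(W[frontier, , drop = FALSE] > 0) > 0 & comp == 0L)
      comp[nb] <- label
      frontier <- nb
    }
  }
  comp
}

# Apply the planted-effect modulation for one subject's standardized driver d.
#
# Efficiency targets scale the relevant weights uniformly: on inverse-weight
# distances E is exactly linear in the scale, while the max-normalized
# clustering coefficient is scale-invariant, so the effect stays confined.
# Clustering targets blend the relevant weights toward the graph maximum
# (s > 0 compresses weight ratios toward 1, raising the geometric-mean
# triangle intensity); the caller then rescales the whole matrix so global
# efficiency is unchanged, confining the effect to clustering.
apply_effect <- function(W, espec, mods, d) {
  s <- espec$effect_strength * d
  switch(espec$target_metric,
    global_efficiency = W * max(1 + s, 0.05),
    nodal_efficiency = {
      f <- max(1 + s, 0.05)
      idx <- espec$target_nodes
      M <- matrix(1, nrow(W), ncol(W))
      M[idx, ] <- f
      M[, idx] <- f
      W * M
    },
    global_clustering = blend_to_max(W, s, outer(mods, mods, "==")),
    local_clustering = {
      mask <- matrix(FALSE, nrow(W), ncol(W))
      for (i in espec$target_nodes) {
        nb <- setdiff(which(W[i, ] > 0), i)
        mask[nb, nb] <- TRUE
      }
      diag(mask) <- FALSE
      blend_to_max(W, s, mask)
    }
  )
}

# Calibrate the clustering-effect transform for one ground truth.
#
# A driver-dependent blend toward the maximum raises the clustering
# coefficient but also (a) drags pruned-network efficiency along and
# (b) responds nonlinearly. Both are corrected on a noise-free grid of
# driver values: for each grid point the blended matrix is rescaled on the
# Fisher-z scale by gamma = Ep0 / Ep so the OMST-pruned efficiency equals
# the ground truth's (the z-rescale is exactly invisible to the OMST
# selection and to max-normalized clustering), and the resulting net
# clustering response curve is inverted so that the planted response is
# linear in the driver. Returns the blend closure, the interpolated gamma
# and the driver reparametrization h.
calibrate_clustering_effect <- function(W0, espec, mods) {
  mask <- if (espec$target_metric == "global_clustering") {
    outer(mods, mods, "==")
  } else {
    m <- matrix(FALSE, nrow(W0), ncol(W0))
    for (i in espec$target_nodes) {
      nb <- setdiff(which(W0[i, ] > 0), i)
      m[nb, nb] <- TRUE
    }
    diag(m) <- FALSE
    m
  }
  blend <- function(s) blend_to_max(W0, s, mask)
  pruned_ez <- function(w) {
    efficiency(omst_filter(atanh(pmin(w, 1 - 1e-6)))$network)$E
  }
  ep0 <- pruned_ez(W0)
  dgrid <- seq(-4, 4, by = 0.25)
  comp <- vapply(dgrid, function(dd) {
    B <- blend(espec$effect_strength * dd)
    g <- ep0 / pruned_ez(B)
    c(clustering(tanh(g * atanh(pmin(B, 1 - 1e-6))))$C, g)
  }, numeric(2))
  c_comp <- comp[1, ]
  gamma_grid <- comp[2, ]
  if (any(diff(c_comp) <= 0)) {
    # Non-monotone net response (degenerate spec); fall back to the raw
    # driver scale rather than inverting an ambiguous curve.
    h <- function(dd) pmin(pmax(dd, -4), 4)
  } else {
    c0 <- c_comp[dgrid == 0]
    slope <- (stats::approx(dgrid, c_comp, 1.5)$y -
                stats::approx(dgrid, c_comp, -1.5)$y) / 3
    h <- function(dd) {
      target <- pmin(pmax(c0 + slope * dd, min(c_comp)), max(c_comp))
      stats::approx(c_comp, dgrid, target)$y
    }
  }
  list(blend = blend,
       gamma = stats::approxfun(dgrid, gamma_grid, rule = 2),
       h = h)
}

# Convex blend of positive weights toward the graph maximum: w' =
# w + s * (max - w), floored at a small positive value so no edge vanishes.
blend_to_max <- function(W, s, mask = NULL) {
  mx <- max(W)
  pos <- W > 0
  if (!is.null(mask)) pos <- pos & mask
  out <- W
  out[pos] <- pmax(W[pos] + s * (mx - W[pos]), 1e-4)
  out
}

#' Generate a synthetic cohort with a planted g-metric association
#'
#' Draws per-subject networks as perturbations of a common ground truth,
#' together with a subject table carrying the latent general-intelligence
#' factor g, demographics, handedness, total brain volume and a head-motion
#' covariate. A latent driver correlated with g at `true_r` modulates the
#' weights relevant to the chosen target metric, so the empirical g-metric
#' correlation recovers `true_r` in expectation.
#'
#' Head motion is generated with a negative correlation with g
#' (`motion_g_r`, default -0.2), emulating the motion-cognition association
#' reported in large resting-state samples, and scales the noise of
#' simulated series downstream.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param gspec A [ground_truth_spec()].
#' @param espec An [effect_spec()].
#' @param seed Integer master seed.
#' @param motion_g_r Correlation between g and the latent motion driver.
#' @return A list of class `synthetic_cohort` with elements `cohort`
#'   (tibble: id, g, age, sex, LQ, handedness, total_brain_volume,
#'   head_motion), `networks` (list of subject weight matrices), `driver`
#'   (the latent standardized driver), `ground_truth`, `gspec`, `espec`,
#'   `seed`.
#' @export
generate_cohort <- function(n_subjects, gspec, espec, seed = 1L,
                            motion_g_r = -0.2) {
  check_scalar(n_subjects, "n_subjects", lower = 2, integer = TRUE)
  if (!inherits(espec, "effect_spec")) {
    stop_omstnet("`espec` must be an effect_spec", "omstnet_parameter_error")
  }
  check_scalar(motion_g_r, "motion_g_r", lower = -1, upper = 1)
  n_subjects <- as.integer(n_subjects)
  W0 <- generate_ground_truth_network(gspec)
  mods <- attr(W0, "modules")
  n <- gspec$n_nodes

  with_seed(split_seed(seed, 1L), {
    g <- as.numeric(scale(rnorm(n_subjects)))
    d <- espec$true_r * g +
      sqrt(max(0, 1 - espec$true_r^2)) * rnorm(n_subjects)
    d <- as.numeric(scale(d))

    m_lat <- motion_g_r * g +
      sqrt(max(0, 1 - motion_g_r^2)) * rnorm(n_subjects)
    head_motion <- 0.15 * exp(0.4 * m_lat)

    age <- pmin(pmax(rnorm(n_subjects, 28, 8), 18), 75)
    sex <- as.integer(runif(n_subjects) < 0.5)
    # ~85% right-handers, LQ clustered near 100 for them.
    right <- runif(n_subjects) < 0.85
    LQ <- ifelse(right, pmin(100, rnorm(n_subjects, 85, 15)),
                 pmax(-100, pmin(100, rnorm(n_subjects, -10, 45))))
    handedness <- as.integer(LQ >= 60)
    tbv <- rnorm(n_subjects, 1.2e6, 1e5)

    ut <- upper.tri(W0)
    clustering_target <- espec$target_metric %in%
      c("global_clustering", "local_clustering")
    cal <- if (clustering_target) {
      calibrate_clustering_effect(W0, espec, mods)
    }
    networks <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      Ws <- if (clustering_target) {
        # Calibrated transform: blend toward the max along the driver,
        # rescale on the Fisher-z scale so the pruned-network efficiency is
        # unaffected (OMST selection and max-normalized clustering are
        # scale-invariant there), and reparametrize the driver so the net
        # clustering response is linear; see calibrate_clustering_effect().
        de <- cal$h(d[s])
        B <- cal$blend(espec$effect_strength * de)
        tanh(cal$gamma(de) * atanh(pmin(B, 1 - 1e-6)))
      } else {
        apply_effect(W0, espec, mods, d[s])
      }
      eps <- matrix(0, n, n)
      eps[ut] <- rnorm(sum(ut), 0, espec$noise_sd)
      eps <- eps + t(eps)
      Ws <- Ws * exp(eps)
      if (clustering_target) {
        # Uniform amplitude factor: invisible to max-normalized clustering,
        # it supplies natural driver-independent efficiency variation.
        Ws <- Ws * exp(0.03 * rnorm(1))
      }
      Ws <- pmin(Ws, 1 - 1e-4)
      diag(Ws) <- 0
      attr(Ws, "modules") <- mods
      networks[[s]] <- Ws
    }

    cohort <- tibble::tibble(
      id = sprintf("S%04d", seq_len(n_subjects)),
      g = g, age = age, sex = sex, LQ = LQ, handedness = handedness,
      total_brain_volume = tbv, head_motion = head_motion
    )
    structure(
      list(cohort = cohort, networks = networks, driver = d,
           ground_truth = W0, gspec = gspec, espec = espec,
           seed = as.integer(seed)),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d subjects, %d nodes, target %s, true_r = %.2f\n",
    nrow(x$cohort), x$gspec$n_nodes, x$espec$target_metric, x$espec$true_r))
  print(x$cohort, n = 5)
  invisible(x)
}

#' Simulate BOLD-like node time series from a network
#'
#' Treats the network weights as target correlations, repairs the implied
#' matrix to the nearest positive-definite correlation matrix (Higham
#' iteration via [Matrix::nearPD()], tolerance 1e-8), and draws a zero-mean
#' multivariate Gaussian series. Optional AR(1) confound signals
#' (autoregression 0.3) are added to every node with loadings drawn
#' U(0.1, 0.3); the same signals are returned as the nuisance regressors,
#' playing the role of white-matter/ventricle series. `motion_scale` adds
#' white framewise noise, emulating motion-related corruption.
#'
#' @param network Symmetric nonnegative weight matrix with zero diagonal.
#' @param n_volumes Number of time points (>= 10).
#' @param tr_seconds Repetition time in seconds.
#' @param n_confounds Number of confound signals (>= 0).
#' @param motion_scale Nonnegative SD multiplier of added white noise.
#' @param seed Integer seed.
#' @param subject_id,session_id Identifiers carried in the bundle.
#' @return A list of class `ts_bundle`: `node_series` (n_nodes x T),
#'   `confound_series` (n_confounds x T), `tr_seconds`, `subject_id`,
#'   `session_id`, `seed`.
#' @export
simulate_bold <- function(network, n_volumes, tr_seconds = 2,
                          n_confounds = 0L, motion_scale = 0,
                          seed = 1L, subject_id = "S0001",
                          session_id = "ses1") {
  check_network(network, "network")
  check_scalar(n_volumes, "n_volumes", lower = 10, integer = TRUE)
  check_scalar(tr_seconds, "tr_seconds", lower = 1e-6)
  check_scalar(n_confounds, "n_confounds", lower = 0, integer = TRUE)
  check_scalar(motion_scale, "motion_scale", lower = 0)
  n <- nrow(network)
  n_volumes <- as.integer(n_volumes)
  n_confounds <- as.integer(n_confounds)

  R <- network
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE, conv.tol = 1e-8,
                                  maxit = 200)$mat)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop_omstnet(sprintf(
      "target correlation matrix not positive definite after repair (min eigenvalue %.3e)",
      min(ev)), "omstnet_internal_error")
  }
  L <- chol(R)

  with_seed(seed, {
    X <- matrix(rnorm(n_volumes * n), n_volumes, n) %*% L
    node_series <- t(X)
    confound_series <- matrix(numeric(0), 0L, n_volumes)
    if (n_confounds > 0L) {
      confound_series <- t(vapply(
        seq_len(n_confounds),
        function(k) as.numeric(stats::filter(rnorm(n_volumes), 0.3,
                                             method = "recursive")),
        numeric(n_volumes)))
      loadings <- matrix(runif(n * n_confounds, 0.1, 0.3), n, n_confounds)
      node_series <- node_series + loadings %*% confound_series
    }
    if (motion_scale > 0) {
      node_series <- node_series + motion_scale *
        matrix(rnorm(n * n_volumes), n, n_volumes)
    }
    rownames(node_series) <- sprintf("node%03d", seq_len(n))
    structure(
      list(node_series = node_series, confound_series = confound_series,
           tr_seconds = tr_seconds, subject_id = subject_id,
           session_id = session_id, seed = as.integer(seed)),
      class = "ts_bundle"
    )
  })
}

#' @export
print.ts_bundle <- function(x, ...) {
  cat(sprintf("<ts_bundle> %s/%s: %d nodes x %d volumes, %d confounds, TR %gs\n",
              x$subject_id, x$session_id, nrow(x$node_series),
              ncol(x$node_series), nrow(x$confound_series), x$tr_seconds))
  invisible(x)
}
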