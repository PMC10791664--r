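# Nodal analysis: elastic-net selection of nodal predictors of g,
# cross-sample prediction with Bonferroni correction, predictor-set
# overlap.

#' Elastic-net selection of nodal predictors of g
#'
#' Standardizes and residualizes g and every nodal-metric column on the
#' covariate design, then fits an elastic net with mixing parameter
#' `alpha = 0.5` over a grid of 100 log-spaced penalties from
#' `lambda_max = max|X'y| / (n * alpha)` down to `1e-4 * lambda_max`,
#' selecting the penalty by 10-fold cross-validated mean squared error
#' with a seeded fold assignment. Nodes with non-zero coefficients at the
#' selected penalty form the support.
#'
#' @param X Subjects x nodes matrix of one nodal metric.
#' @param g General-intelligence scores.
#' @param design Covariate matrix (see [covariate_design()]).
#' @param seed Integer seed for the fold assignment.
#' @param alpha Elastic-net mixing parameter (default 0.5).
#' @param nfolds Number of CV folds (default 10).
#' @param lambda_rule `"min"` (CV-MSE minimizer, default) or `"1se"`.
#' @return An object of class `enet_model`: `alpha`, `lambda_grid`,
#'   `lambda_selected`, `beta` (named coefficient vector at the selected
#'   penalty), `selected` (indices of the support), `cv_folds`,
#'   `lambda_rule`, `seed`, and the underlying `cv.glmnet` fit.
#' @export
elastic_net_select <- function(X, g, design, seed = 1L, alpha = 0.5,
                               nfolds = 10L, lambda_rule = c("min", "1se")) {
  lambda_rule <- match.arg(lambda_rule)
  X <- as.matrix(X)
  n <- nrow(X)
  if (anyNA(X) || anyNA(g) || any(!is.finite(X)) || any(!is.finite(g))) {
    stop_omstnet("non-finite entries in predictors or response",
                 "omstnet_data_error")
  }
  if (n < 20L) stop_omstnet("need at least 20 subjects", "omstnet_data_error")
  if (n < nfolds) stop_omstnet("fewer subjects than folds",
                               "omstnet_data_error")
  if (is.null(colnames(X))) colnames(X) <- sprintf("node%03d", seq_len(ncol(X)))

  y <- as.numeric(scale(residualize(g, design)))
  Xr <- apply(X, 2L, function(col) {
    r <- residualize(col, design)
    s <- sd(r)
    if (s < 1e-12) rep(0, length(r)) else (r - mean(r)) / s
  })
  colnames(Xr) <- colnames(X)

  lambda_max <- max(abs(crossprod(Xr, y))) / (n * alpha)
  lambda_grid <- exp(seq(log(lambda_max), log(1e-4 * lambda_max),
                         length.out = 100))
  foldid <- with_seed(seed, sample(rep_len(seq_len(nfolds), n)))
  fit <- glmnet::cv.glmnet(Xr, y, alpha = alpha, lambda = lambda_grid,
                           foldid = foldid, standardize = FALSE,
                           intercept = TRUE)
  lambda_selected <- if (lambda_rule == "min") fit$lambda.min else fit$lambda.1se
  beta <- as.numeric(stats::coef(fit, s = lambda_selected))[-1L]
  names(beta) <- colnames(Xr)
  structure(
    list(alpha = alpha, lambda_grid = lambda_grid,
         lambda_selected = lambda_selected, beta = beta,
         selected = unname(which(beta != 0)), cv_folds = as.integer(nfolds),
         lambda_rule = lambda_rule, seed = as.integer(seed), fit = fit),
    class = "enet_model"
  )
}

#' @export
print.enet_model <- function(x, ...) {
  cat(sprintf(
    "<enet_model> alpha = %.2f, %d-fold CV (%s rule): lambda = %.4g, %d non-zero of %d predictors\n",
    x$alpha, x$cv_folds, x$lambda_rule, x$lambda_selected,
    length(x$selected), length(x$beta)))
  invisible(x)
}

#' @method tidy enet_model
#' @export
tidy.enet_model <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = x$beta,
                 selected = x$beta != 0)
}

#' @method glance enet_model
#' @export
glance.enet_model <- function(x, ...) {
  i <- match(x$lambda_selected, x$fit$lambda)
  tibble::tibble(alpha = x$alpha, lambda = x$lambda_selected,
                 lambda_rule = x$lambda_rule, n_selected = length(x$selected),
                 cv_mse = x$fit$cvm[i], cv_folds = x$cv_folds)
}

#' Cross-sample prediction from a selected predictor set
#'
#' Fits an ordinary least-squares regression of residualized g on the
#' residualized selected nodal metrics in a target sample and reports the
#' coefficient of determination with its overall F-test p-value,
#' Bonferroni-thresholded at `0.05 / m_bonferroni`.
#'
#' An empty predictor set returns a result flagged `no_predictors` (the
#' "-" rows of a prediction grid) rather than an error.
#'
#' @param selected Node indices selected in the source sample.
#' @param X_target Subjects x nodes metric matrix of the target sample.
#' @param g_target g scores of the target sample.
#' @param design_target Covariate matrix of the target sample.
#' @param source,target Sample labels carried into the result.
#' @param m_bonferroni Size of the Bonferroni family (default 16, a 4 x 4
#'   source-by-target grid including self-prediction).
#' @param include_controls Fit controls as regressors instead of
#'   residualizing first (alternative reading of the control convention).
#' @return A tibble of class `prediction_result`: `source`, `target`,
#'   `n_predictors`, `r_squared`, `p_raw`, `significant_bonferroni`,
#'   `no_predictors`.
#' @export
cross_sample_predict <- function(selected, X_target, g_target, design_target,
                                 source = "source", target = "target",
                                 m_bonferroni = 16L,
                                 include_controls = FALSE) {
  check_scalar(m_bonferroni, "m_bonferroni", lower = 1, integer = TRUE)
  if (length(selected) == 0L) {
    out <- tibble::tibble(source = source, target = target,
                          n_predictors = 0L, r_squared = NA_real_,
                          p_raw = NA_real_, significant_bonferroni = FALSE,
                          no_predictors = TRUE)
    class(out) <- c("prediction_result", class(out))
    return(out)
  }
  X_target <- as.matrix(X_target)
  if (max(selected) > ncol(X_target)) {
    stop_omstnet("target sample lacks some selected node metrics",
                 "omstnet_data_error")
  }
  Xs <- X_target[, selected, drop = FALSE]
  if (include_controls) {
    df <- data.frame(g = g_target, Xs, as.data.frame(design_target))
    fit <- lm(g ~ ., data = df)
  } else {
    y <- residualize(g_target, design_target)
    Xr <- apply(Xs, 2L, residualize, design = design_target)
    fit <- lm(y ~ Xr)
  }
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- unname(pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE))
  out <- tibble::tibble(source = source, target = target,
                        n_predictors = length(selected),
                        r_squared = sm$r.squared, p_raw = p,
                        significant_bonferroni = p < 0.05 / m_bonferroni,
                        no_predictors = FALSE)
  class(out) <- c("prediction_result", class(out))
  out
}

#' Overlap among predictor sets
#'
#' Given the elastic-net supports of several samples (and optionally their
#' coefficient vectors), reports all pairwise intersections, the all-way
#' intersection, the overlap percentage relative to the union, and the
#' per-node effect size averaged over the samples selecting it.
#'
#' @param supports Named list (>= 2) of node-index vectors.
#' @param effects Optional named list of coefficient vectors (full length,
#'   zeros for unselected nodes) matching `supports`.
#' @return A list of class `overlap_report`: `pairwise` (tibble: pair,
#'   intersection size, overlap of the pairwise union), `all_way`
#'   (indices), `overlap_pct` (all-way intersection relative to the
#'   union), and `averaged_effects` (tibble per overlapping node).
#' @export
predictor_overlap <- function(supports, effects = NULL) {
  if (length(supports) < 2L) {
    stop_omstnet("need at least 2 supports", "omstnet_data_error")
  }
  if (is.null(names(supports))) {
    names(supports) <- sprintf("sample%d", seq_along(supports))
  }
  nm <- names(supports)
  pairs <- utils::combn(nm, 2L, simplify = FALSE)
  pairwise <- dplyr::bind_rows(lapply(pairs, function(p) {
    a <- supports[[p[1]]]; b <- supports[[p[2]]]
    inter <- intersect(a, b)
    uni <- union(a, b)
    tibble::tibble(sample_a = p[1], sample_b = p[2],
                   n_intersect = length(inter),
                   overlap_pct = if (length(uni)) 100 * length(inter) /
                     length(uni) else 0,
                   nodes = list(sort(inter)))
  }))
  all_way <- Reduce(intersect, supports)
  uni <- Reduce(union, supports)
  averaged <- NULL
  if (!is.null(effects) && length(all_way)) {
    averaged <- tibble::tibble(
      node = sort(all_way),
      mean_effect = vapply(sort(all_way), function(i) {
        mean(vapply(effects, function(e) e[i], numeric(1)))
      }, numeric(1)))
  }
  structure(
    list(pairwise = pairwise, all_way = sort(all_way),
         overlap_pct = if (length(uni)) 100 * length(all_way) / length(uni)
                       else 0,
         averaged_effects = averaged),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> all-way intersection: %d node(s) (%.1f%% of union)\n",
              length(x$all_way), x$overlap_pct))
  print(x$pairwise)
  invisible(x)
}
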