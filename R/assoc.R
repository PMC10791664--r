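# Association battery: winsorization, covariate design, residualization,
# partial correlations with Holm correction, handedness coding.

#' Winsorize outliers at mean +/- 3 IQR
#'
#' Values deviating more than three interquartile ranges from the mean are
#' replaced by the nearer bound; all other values are untouched. Quantiles
#' use linear interpolation (type 7).
#'
#' @param values Numeric vector with at least 4 finite values.
#' @param k Number of IQRs defining the bounds (default 3).
#' @return The winsorized vector.
#' @export
winsorize <- function(values, k = 3) {
  if (!is.numeric(values) || sum(is.finite(values)) < 4L) {
    stop_omstnet("`values` needs at least 4 finite entries",
                 "omstnet_data_error")
  }
  q <- quantile(values, c(0.25, 0.75), na.rm = TRUE, type = 7)
  iqr <- q[2] - q[1]
  m <- mean(values, na.rm = TRUE)
  pmin(pmax(values, m - k * iqr), m + k * iqr)
}

#' Build the standard covariate design matrix
#'
#' Columns, in fixed order: age, sex, age*sex, age^2, age^2*sex,
#' handedness, total_brain_volume, head_motion. Age is mean-centered before
#' forming powers and interactions to limit collinearity; the condition
#' number of the design is attached as an attribute.
#'
#' @param cohort A cohort tibble with columns `age`, `sex`, `handedness`,
#'   `total_brain_volume`, `head_motion`.
#' @return A numeric matrix with attribute `condition_number`.
#' @export
covariate_design <- function(cohort) {
  need <- c("age", "sex", "handedness", "total_brain_volume", "head_motion")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop_omstnet(paste("cohort is missing columns:",
                       paste(miss, collapse = ", ")),
                 "omstnet_data_error")
  }
  age_c <- cohort$age - mean(cohort$age)
  X <- cbind(
    age = age_c,
    sex = cohort$sex,
    age_sex = age_c * cohort$sex,
    age2 = age_c^2,
    age2_sex = age_c^2 * cohort$sex,
    handedness = cohort$handedness,
    total_brain_volume = cohort$total_brain_volume,
    head_motion = cohort$head_motion
  )
  sds <- apply(X, 2L, sd)
  Z <- scale(X[, sds > 0, drop = FALSE])
  attr(X, "condition_number") <- if (ncol(Z)) kappa(Z, exact = TRUE) else NA_real_
  X
}

#' OLS residuals of a variable on a covariate design
#'
#' Residualizes `y` on the design columns plus an intercept; the residuals
#' are orthogonal to every column within numerical precision.
#'
#' @param y Numeric response vector.
#' @param design Covariate matrix (see [covariate_design()]).
#' @return Numeric residual vector.
#' @export
residualize <- function(y, design) {
  design <- as.matrix(design)
  n <- length(y)
  if (n != nrow(design)) {
    stop_omstnet("`y` and `design` have different lengths",
                 "omstnet_data_error")
  }
  if (n <= ncol(design) + 1L) {
    stop_omstnet("need more observations than design columns + 1",
                 "omstnet_data_error")
  }
  X <- cbind(`(Intercept)` = 1, design)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop_omstnet(paste("rank-deficient design; dependent columns:",
                       paste(dep, collapse = ", ")),
                 "omstnet_data_error")
  }
  as.numeric(qr.resid(qrX, y))
}

#' Partial correlation between g and a metric, net of covariates
#'
#' Both variables are residualized on the design (with intercept); the
#' partial correlation is the Pearson correlation of the residuals, tested
#' two-sided with t = r * sqrt(df / (1 - r^2)) on df = n - 2 - n_controls
#' degrees of freedom.
#'
#' @param g General-intelligence scores.
#' @param metric Graph-metric values, same length.
#' @param design Covariate matrix.
#' @return A list with `r`, `p_raw`, `df`, `n`.
#' @export
partial_correlation_test <- function(g, metric, design) {
  design <- as.matrix(design)
  n <- length(g)
  df <- n - 2L - ncol(design)
  if (df <= 0) stop_omstnet("nonpositive degrees of freedom",
                            "omstnet_data_error")
  r <- cor(residualize(g, design), residualize(metric, design))
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(tval), df)
  list(r = r, p_raw = p, df = df, n = n)
}

#' Holm step-down adjustment of p-values
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @return Adjusted p-values (elementwise >= raw).
#' @export
holm_adjust <- function(p_values) {
  if (!is.numeric(p_values) || any(!is.finite(p_values)) ||
      any(p_values < 0 | p_values > 1)) {
    stop_omstnet("p-values must be finite and in [0, 1]",
                 "omstnet_data_error")
  }
  stats::p.adjust(p_values, method = "holm")
}

#' Table of partial correlations between g and global metrics
#'
#' Winsorizes g and each metric at mean +/- 3 IQR, computes partial
#' correlations controlling the standard covariate set, and applies Holm's
#' correction across the metrics of the table (the multiple-comparison
#' family is the set of global metrics tested within one data set).
#'
#' @param metrics_df Tibble with one row per subject: a `g` column plus one
#'   column per global metric.
#' @param cohort Cohort tibble providing the covariates.
#' @param metrics Names of the metric columns to test.
#' @return A tibble of class `association_table`: `metric`, `r`, `p_raw`,
#'   `p_holm`, `df`, `n`.
#' @export
association_table <- function(metrics_df, cohort,
                              metrics = c("global_efficiency",
                                          "global_clustering",
                                          "small_world_propensity")) {
  design <- covariate_design(cohort)
  g <- winsorize(metrics_df$g)
  rows <- purrr::map(metrics, function(m) {
    if (!m %in% names(metrics_df)) {
      stop_omstnet(sprintf("metric column `%s` not found", m),
                   "omstnet_data_error")
    }
    v <- winsorize(metrics_df[[m]])
    res <- partial_correlation_test(g, v, design)
    tibble::tibble(metric = m, r = res$r, p_raw = res$p_raw,
                   df = res$df, n = res$n)
  })
  out <- dplyr::bind_rows(rows)
  out$p_holm <- holm_adjust(out$p_raw)
  out <- out[, c("metric", "r", "p_raw", "p_holm", "df", "n")]
  class(out) <- c("association_table", class(out))
  out
}

#' Plot an association table
#'
#' @param object An `association_table`.
#' @param alpha Significance level marked on the plot.
#' @param ... Unused.
#' @return A ggplot showing partial correlations with Holm-significance.
#' @method autoplot association_table
#' @export
autoplot.association_table <- function(object, alpha = 0.05, ...) {
  df <- tibble::as_tibble(object)
  df$significant <- df$p_holm < alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$r,
                                   fill = .data$significant)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick"),
                               name = sprintf("Holm p < %.2f", alpha)) +
    ggplot2::labs(x = NULL, y = "partial r with g") +
    ggplot2::theme_minimal()
}

#' Lateralization quotient and handedness coding
#'
#' LQ = (R - L) / (R + L) * 100 from right- and left-hand response counts;
#' handedness is coded 1 (right-handed) when LQ >= 60 and 0 otherwise.
#'
#' @param R Right-hand response count(s).
#' @param L Left-hand response count(s).
#' @return A tibble with columns `LQ` and `handedness`.
#' @export
lateralization_quotient <- function(R, L) {
  if (length(R) != length(L)) {
    stop_omstnet("`R` and `L` must have the same length", "omstnet_data_error")
  }
  if (any(R < 0 | L < 0) || any(R + L == 0)) {
    stop_omstnet("counts must be nonnegative with R + L > 0",
                 "omstnet_data_error")
  }
  LQ <- (R - L) / (R + L) * 100
  tibble::tibble(LQ = LQ, handedness = as.integer(LQ >= 60))
}
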