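# Plain-text I/O: square TSV for matrices, CSV for cohort tables, JSON for
# manifests and reports.

#' Write a weight or connectivity matrix as square TSV
#'
#' @param M Square numeric matrix; row/column labels are taken from
#'   dimnames or generated as node001, node002, ...
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(M, path) {
  M <- as.matrix(unclass(M))
  if (is.null(colnames(M))) {
    colnames(M) <- rownames(M) <- sprintf("node%03d", seq_len(ncol(M)))
  }
  df <- data.frame(label = rownames(M), M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square TSV matrix
#'
#' Validates squareness, finite entries, matching row/column labels and
#' symmetry (asymmetries above 1e-8 are rejected); values are symmetrized
#' to remove writeout rounding and returned with zero verified diagonal.
#'
#' @param path TSV file written by [write_matrix()].
#' @param asym_tol Largest tolerated absolute asymmetry (default 1e-8).
#' @return A labelled symmetric matrix.
#' @export
read_matrix <- function(path, asym_tol = 1e-8) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = NA)
  labels <- as.character(df[[1L]])
  M <- as.matrix(df[, -1L, drop = FALSE])
  if (nrow(M) != ncol(M)) {
    stop_omstnet(sprintf("matrix in %s is %d x %d, not square", path,
                         nrow(M), ncol(M)), "omstnet_format_error")
  }
  if (!identical(labels, colnames(M))) {
    stop_omstnet(sprintf("row/column label mismatch in %s", path),
                 "omstnet_format_error")
  }
  bad <- which(!is.finite(M), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_omstnet(sprintf("non-finite value in %s at row %d (%s), column %s",
                         path, bad[1, 1], labels[bad[1, 1]],
                         colnames(M)[bad[1, 2]]),
                 "omstnet_format_error")
  }
  storage.mode(M) <- "double"
  asym <- max(abs(M - t(M)))
  if (asym > asym_tol) {
    stop_omstnet(sprintf("matrix in %s asymmetric by %.3g (tolerance %.3g)",
                         path, asym, asym_tol), "omstnet_format_error")
  }
  M <- (M + t(M)) / 2
  rownames(M) <- labels
  M
}

cohort_header <- c("id", "g", "age", "sex", "LQ", "handedness",
                   "total_brain_volume", "head_motion")

#' Write a cohort table as CSV
#'
#' @param cohort Cohort tibble with the documented columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  miss <- setdiff(cohort_header, names(cohort))
  if (length(miss)) {
    stop_omstnet(paste("cohort is missing columns:",
                       paste(miss, collapse = ", ")),
                 "omstnet_format_error")
  }
  utils::write.csv(cohort[, cohort_header], path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Validates the documented header and checks that the handedness coding
#' is consistent with the LQ >= 60 rule, warning with the offending row
#' ids otherwise.
#'
#' @param path CSV file written by [write_cohort()].
#' @return A cohort tibble.
#' @export
read_cohort <- function(path) {
  if (file.size(path) == 0) {
    stop_omstnet(sprintf("%s is empty", path), "omstnet_format_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(cohort_header, names(df))
  if (length(miss)) {
    stop_omstnet(paste("cohort file is missing columns:",
                       paste(miss, collapse = ", ")),
                 "omstnet_format_error")
  }
  expected <- as.integer(df$LQ >= 60)
  bad <- which(df$handedness != expected)
  if (length(bad)) {
    warning(sprintf(
      "handedness coding inconsistent with the LQ >= 60 rule for row(s): %s",
      paste(df$id[bad], collapse = ", ")), call. = FALSE)
  }
  tibble::as_tibble(df[, cohort_header])
}

#' Write a synthetic cohort to disk
#'
#' Writes the subject table as CSV, every subject network as square TSV,
#' and a JSON manifest recording paths, the master seed and an echo of the
#' generator specifications.
#'
#' @param x A `synthetic_cohort` (see [generate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_synthetic_cohort <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort_path <- file.path(dir, "cohort.csv")
  write_cohort(x$cohort, cohort_path)
  net_paths <- vapply(seq_along(x$networks), function(s) {
    p <- file.path(dir, sprintf("network_%s.tsv", x$cohort$id[s]))
    write_matrix(x$networks[[s]], p)
    p
  }, character(1))
  manifest <- list(
    cohort = cohort_path, networks = net_paths, seed = x$seed,
    gspec = unclass(x$gspec), espec = unclass(x$espec))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}
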