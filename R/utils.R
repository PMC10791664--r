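# Internal helpers shared across modules.

# All randomness in the package flows from one integer master seed through
# this splitting scheme: stream k of seed s is s + k * 10007, folded into
# [0, 2^31) so it stays a valid R integer.
split_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((as.numeric(seed) + k * 10007) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

stop_omstnet <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "omstnet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_omstnet(sprintf("`%s` must be a single finite number", name),
                 "omstnet_parameter_error")
  }
  if (integer && x != round(x)) {
    stop_omstnet(sprintf("`%s` must be an integer", name),
                 "omstnet_parameter_error")
  }
  if (x < lower || x > upper) {
    stop_omstnet(sprintf("`%s` must be in [%s, %s]", name, lower, upper),
                 "omstnet_parameter_error")
  }
  invisible(x)
}

# Validate a weighted network: symmetric, zero diagonal, nonnegative.
check_network <- function(W, name = "W", tol = 1e-12) {
  if (!is.matrix(W) || !is.numeric(W) || nrow(W) != ncol(W)) {
    stop_omstnet(sprintf("`%s` must be a square numeric matrix", name),
                 "omstnet_data_error")
  }
  if (anyNA(W)) {
    stop_omstnet(sprintf("`%s` contains missing values", name),
                 "omstnet_data_error")
  }
  if (max(abs(W - t(W))) > tol) {
    stop_omstnet(sprintf("`%s` is not symmetric within %g", name, tol),
                 "omstnet_data_error")
  }
  if (any(diag(W) != 0)) {
    stop_omstnet(sprintf("`%s` must have a zero diagonal", name),
                 "omstnet_data_error")
  }
  if (min(W) < 0) {
    stop_omstnet(sprintf("`%s` has negative weights", name),
                 "omstnet_data_error")
  }
  invisible(W)
}

# Connectivity of the positive-weight subgraph.
is_connected_graph <- function(W) {
  n <- nrow(W)
  if (n <= 1L) return(TRUE)
  reached <- logical(n)
  frontier <- 1L
  reached[1L] <- TRUE
  while (length(frontier)) {
    nb <- which(colSums(W[frontier, , drop = FALSE] > 0) > 0 & !reached)
    reached[nb] <- TRUE
    frontier <- nb
  }
  all(reached)
}

# Upper-triangle edge list of positive weights as a tibble.
edge_table <- function(W) {
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  tibble::tibble(i = idx[, 1L], j = idx[, 2L], w = W[idx])
}

offdiag <- function(M) M[row(M) != col(M)]
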