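#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rlnorm runif rnorm setNames
#' @importFrom utils combn head
NULL

#' Derive a stream of child seeds from one master seed
#'
#' All stochastic functions in the package draw their randomness from a single
#' integer seed. When a procedure has several independent random stages (base
#' graph, per-subject jitter, per-variant jitter, ...), the master seed is
#' split into child seeds by seeding R's RNG once with the master and drawing
#' `n` integers uniformly from `1:(2^31 - 2)`. Stage `k` then reseeds with
#' child `k`, so adding stages never perturbs the draws of earlier ones.
#'
#' @param seed Integer master seed.
#' @param n Number of child seeds to derive.
#' @return Integer vector of length `n`.
#' @export
#' @examples
#' split_seed(42, 3)
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(n), n >= 1)
  withr::with_seed(as.integer(seed), sample.int(2147483646L, as.integer(n)))
}

# run code under a local seed without disturbing the caller's RNG state;
# seed = NULL uses the ambient RNG stream
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

#' Validate a connectivity matrix
#'
#' Checks that `w` is a square numeric matrix, symmetric (within `tol`),
#' nonnegative, with a zero diagonal. Called by every function that consumes
#' a connectome; returns the matrix invisibly so it can be used in pipes.
#'
#' @param w Square numeric matrix of arc weights.
#' @param tol Absolute tolerance for the symmetry check.
#' @return `w`, invisibly.
#' @export
validate_network <- function(w, tol = 1e-9) {
  if (!is.matrix(w) || !is.numeric(w)) {
    abort("`w` must be a numeric matrix.")
  }
  if (nrow(w) != ncol(w)) {
    abort(sprintf("`w` must be square; got %d x %d.", nrow(w), ncol(w)))
  }
  asym <- abs(w - t(w))
  if (any(asym > tol)) {
    idx <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "`w` is not symmetric: |w[%d,%d] - w[%d,%d]| = %.3g exceeds tol = %g.",
      idx[1L], idx[2L], idx[2L], idx[1L], max(asym), tol
    ))
  }
  if (any(w < 0)) abort("`w` has negative weights.")
  if (any(diag(w) != 0)) abort("`w` must have a zero diagonal.")
  invisible(w)
}

# default node labels n1..nN when a matrix has no dimnames
node_labels <- function(w) {
  if (!is.null(rownames(w))) rownames(w) else paste0("n", seq_len(nrow(w)))
}

# matrix -> igraph (undirected, weighted), dropping zero entries
as_igraph <- function(w) {
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g
}

# upper-triangle edge list of a symmetric matrix as a three-column tibble
edge_table <- function(w) {
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  tibble(i = idx[, 1L], j = idx[, 2L], weight = w[idx])
}
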