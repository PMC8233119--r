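#' Canonical edge ordering
#'
#' Connectivity matrices are vectorized by their lower triangle in a fixed
#' canonical order: node pairs (i, j) with i > j, row-major over i, i.e.
#' (2,1), (3,1), (3,2), (4,1), ... Node indices are 1-based. This order is
#' used everywhere an edge vector or a subjects-by-edges table appears.
#'
#' @param i,j Node indices with `i > j >= 1` (vectorized).
#' @param n Number of nodes.
#' @return `edge_index()`: the 1-based position(s) of edge (i, j) in the
#'   canonical order, in `1..n(n-1)/2`.
#' @examples
#' edge_index(2, 1, 3)          # 1
#' edge_index(3, 2, 3)          # 3
#' n_edges(268)                 # 35778
#' @export
edge_index <- function(i, j, n) {
  if (length(n) != 1L || n < 2) stop("`n` must be a single node count >= 2")
  bad <- !(j >= 1 & i > j & i <= n)
  if (any(bad)) {
    stop(sprintf("invalid edge (i=%s, j=%s) for n=%d: need 1 <= j < i <= n",
                 paste(i[bad], collapse = ","), paste(j[bad], collapse = ","), n))
  }
  as.integer((i - 1) * (i - 2) / 2 + j)
}

#' @rdname edge_index
#' @param k Canonical edge position(s), in `1..n(n-1)/2`.
#' @return `edge_index_inverse()`: a two-column matrix of node pairs
#'   `(node_i, node_j)` with `node_i > node_j`.
#' @export
edge_index_inverse <- function(k, n) {
  E <- n_edges(n)
  if (any(k < 1 | k > E)) stop(sprintf("edge position out of range 1..%d", E))
  t0 <- k - 1                                # 0-based position
  i0 <- floor((1 + sqrt(1 + 8 * t0)) / 2)    # 0-based i; guard rounding
  i0 <- ifelse(i0 * (i0 - 1) / 2 > t0, i0 - 1, i0)
  i0 <- ifelse((i0 + 1) * i0 / 2 <= t0, i0 + 1, i0)
  j0 <- t0 - i0 * (i0 - 1) / 2
  cbind(node_i = as.integer(i0 + 1), node_j = as.integer(j0 + 1))
}

#' @rdname edge_index
#' @return `n_edges()`: the number of lower-triangle edges, n(n-1)/2.
#' @export
n_edges <- function(n) as.integer(n * (n - 1) / 2)

#' All node pairs in canonical order
#'
#' @param n Number of nodes.
#' @return A data.frame with integer columns `node_i`, `node_j` (`node_i >
#'   node_j`), one row per edge, in canonical order.
#' @export
edge_node_pairs <- function(n) {
  as.data.frame(edge_index_inverse(seq_len(n_edges(n)), n))
}

edge_labels <- function(edges) paste0(edges$node_i, "_", edges$node_j)

parse_edge_labels <- function(labels) {
  parts <- strsplit(labels, "_", fixed = TRUE)
  ok <- lengths(parts) == 2L
  if (!all(ok)) stop("malformed edge label(s): ", paste(labels[!ok], collapse = ", "))
  m <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE)
  data.frame(node_i = m[, 1], node_j = m[, 2])
}

#' Vectorize a connectivity matrix
#'
#' Extracts the lower triangle of a symmetric matrix in canonical edge order
#' (see [edge_index()]). Asymmetry up to `tol` is absorbed by averaging
#' `m` with its transpose; larger asymmetry is an error.
#'
#' @param m A symmetric numeric matrix (unit diagonal, entries in `[-1, 1]`
#'   for correlation matrices; only symmetry is enforced here).
#' @param tol Largest tolerated absolute asymmetry.
#' @return Numeric vector of length `n(n-1)/2`.
#' @export
vectorize <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || nrow(m) < 2)
    stop("`m` must be a square matrix with at least 2 nodes")
  asym <- max(abs(m - t(m)))
  if (asym > tol)
    stop(sprintf("matrix is not symmetric: max |m - t(m)| = %.3g > tol = %.3g", asym, tol))
  m <- (m + t(m)) / 2
  m[upper.tri(m)]   # column-major upper triangle == row-major lower triangle
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize()]: fills the off-diagonal of an `n x n` symmetric
#' matrix from a canonical edge vector.
#'
#' @param v Edge vector of length `n(n-1)/2`.
#' @param diag Value placed on the diagonal (1 for correlation matrices).
#' @return Symmetric `n x n` matrix.
#' @export
unvectorize <- function(v, diag = 1) {
  E <- length(v)
  n <- (1 + sqrt(1 + 8 * E)) / 2
  if (abs(n - round(n)) > 1e-8)
    stop(sprintf("length %d is not n(n-1)/2 for any integer n", E))
  n <- as.integer(round(n))
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  base::diag(m) <- diag
  m
}
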