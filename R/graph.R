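#' Build the spatial K-nearest-neighbour graph
#'
#' Each spot selects its `k` nearest neighbours by Euclidean distance in
#' coordinate space; the adjacency is then symmetrized by union, so
#' `a_ij = a_ji = 1` whenever either spot selected the other. Distance ties
#' are broken deterministically by the smaller spot index.
#'
#' @param coords N x 2 numeric matrix of spot positions.
#' @param k number of neighbours each spot selects (default 6).
#' @return An object of class `spatial_graph` with elements `A` (0/1
#'   symmetric adjacency, zero diagonal), `A_hat_norm` (the self-loop
#'   normalized adjacency \eqn{\hat D^{-1/2}(A+I)\hat D^{-1/2}}), `L` (the
#'   combinatorial Laplacian \eqn{D - A}) and `k`.
#' @export
build_knn_graph <- function(coords, k = 6L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L)
    stop_sducl("need at least two spots to build a graph", "sducl_parameter_error")
  k <- as.integer(k)
  if (k < 1L || k >= n)
    stop_sducl(sprintf("k must satisfy 1 <= k < N (got k = %d, N = %d)", k, n),
               "sducl_parameter_error")
  d <- as.matrix(stats::dist(coords))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d[i, ]
    di[i] <- Inf
    # order() is a stable sort, so equal distances resolve to smaller index
    nn <- order(di)[seq_len(k)]
    A[i, nn] <- 1
  }
  A <- pmax(A, t(A))          # union symmetrization
  graph_from_adjacency(A, k = k)
}

#' Assemble a spatial_graph from a 0/1 adjacency matrix
#'
#' @param A symmetric 0/1 matrix with zero diagonal.
#' @param k neighbour count recorded on the object (informational).
#' @export
graph_from_adjacency <- function(A, k = NA_integer_) {
  A <- as.matrix(A)
  if (!isSymmetric(unname(A), tol = 0))
    stop_sducl("adjacency matrix must be symmetric", "sducl_precondition_error")
  if (any(diag(A) != 0))
    stop_sducl("adjacency matrix must have a zero diagonal", "sducl_precondition_error")
  structure(list(A = A,
                 A_hat_norm = normalized_adjacency(A),
                 L = laplacian(A),
                 k = k),
            class = "spatial_graph")
}

#' Self-loop symmetric normalization of an adjacency matrix
#'
#' Computes \eqn{\hat D^{-1/2} (A + I) \hat D^{-1/2}} where \eqn{\hat D} is
#' the degree matrix of \eqn{A + I}. Isolated nodes get degree 1 from their
#' self-loop, so the result is always finite.
#'
#' @param A symmetric 0/1 adjacency, zero diagonal.
#' @export
normalized_adjacency <- function(A) {
  A_hat <- A + diag(nrow(A))
  d <- rowSums(A_hat)
  inv_sqrt <- 1 / sqrt(d)
  A_hat * tcrossprod(inv_sqrt)
}

#' Combinatorial graph Laplacian
#'
#' \eqn{L = D - A} with \eqn{D} the diagonal degree matrix; rows sum to zero,
#' which is what makes heat diffusion on the graph mass-conserving.
#'
#' @param A symmetric 0/1 adjacency, zero diagonal.
#' @export
laplacian <- function(A) {
  diag(rowSums(A), nrow(A)) - A
}

#' @export
print.spatial_graph <- function(x, ...) {
  n <- nrow(x$A)
  cat(sprintf("spatial_graph: %d nodes, %d edges (k = %s)\n",
              n, sum(x$A) / 2, x$k))
  invisible(x)
}

#' Export the edge list of a spatial graph
#'
#' @param graph a `spatial_graph`.
#' @param path optional TSV output path; when `NULL` the edge list data.frame
#'   is returned instead of written.
#' @return data.frame with 0-based `from`/`to` columns (each edge once,
#'   `from < to`), invisibly when written.
#' @export
edge_list <- function(graph, path = NULL) {
  idx <- which(upper.tri(graph$A) & graph$A > 0, arr.ind = TRUE)
  df <- data.frame(from = idx[, 1] - 1L, to = idx[, 2] - 1L)
  df <- df[order(df$from, df$to), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
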