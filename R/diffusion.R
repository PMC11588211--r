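#' Heat-kernel of a graph Laplacian
#'
#' Computes the matrix exponential `exp(-alpha * L)` through the symmetric
#' eigendecomposition of `L`. Because `L 1 = 0`, the kernel is doubly
#' stochastic: entrywise nonnegative, symmetric, and every row/column sums to
#' one, so diffusion conserves total signal mass.
#'
#' @param L combinatorial Laplacian (symmetric).
#' @param alpha diffusion rate (time), nonnegative.
#' @return N x N dense kernel matrix.
#' @export
heat_kernel <- function(L, alpha = 0.1) {
  L <- as.matrix(L)
  if (!isSymmetric(unname(L), tol = 1e-8))
    stop_sducl("Laplacian must be symmetric", "sducl_precondition_error")
  if (alpha < 0)
    stop_sducl("alpha must be nonnegative", "sducl_parameter_error")
  eig <- eigen(L, symmetric = TRUE)
  eig$vectors %*% (exp(-alpha * eig$values) * t(eig$vectors))
}

#' Diffuse a signal over a graph
#'
#' Simulates biological signal diffusion from a source: `m = exp(-alpha L) s`.
#' Signal spreads from the source along edges; total mass is conserved
#' (`sum(m) == sum(s)`), and at `alpha = 0` the signal is returned unchanged.
#'
#' @param L combinatorial Laplacian (symmetric) or a `spatial_graph`.
#' @param s nonnegative source vector, not all zero.
#' @param alpha diffusion rate (default 0.1).
#' @return diffused signal vector `m`.
#' @export
diffuse <- function(L, s, alpha = 0.1) {
  if (inherits(L, "spatial_graph")) L <- L$L
  s <- as.numeric(s)
  if (length(s) != nrow(as.matrix(L)))
    stop_sducl("source vector length does not match the Laplacian", "sducl_alignment_error")
  if (any(s < 0) || all(s == 0))
    stop_sducl("source signal must be nonnegative and not all zero",
               "sducl_precondition_error")
  as.numeric(heat_kernel(L, alpha) %*% s)
}

#' Discover per-node diffusion microenvironments
#'
#' For every node i, a unit signal is planted at i and diffused with the
#' graph heat kernel; the nodes are then ranked by accumulated signal
#' strength and the top `n_sub` form node i's microenvironment — the
#' subnetwork most relevant to the source. All N diffusions share one kernel
#' computation: row i of `exp(-alpha L)` is exactly the diffused signal from
#' source i.
#'
#' @param graph a `spatial_graph` (or a Laplacian matrix).
#' @param alpha signal diffusion rate (default 0.1).
#' @param n_sub microenvironment size (default 20); capped at N.
#' @return object of class `microenvironment_map` with `members` (list of
#'   sorted member index vectors, strongest signal first, ties by ascending
#'   index), `signal` (the N x N kernel; row i is source i's diffused
#'   signal), `alpha` and `n_sub`.
#' @export
discover_microenvironments <- function(graph, alpha = 0.1, n_sub = 20L) {
  L <- if (inherits(graph, "spatial_graph")) graph$L else as.matrix(graph)
  n_sub <- as.integer(n_sub)
  if (n_sub < 1L)
    stop_sducl("n_sub must be at least 1", "sducl_parameter_error")
  E <- heat_kernel(L, alpha)
  n <- nrow(E)
  size <- min(n_sub, n)
  members <- lapply(seq_len(n), function(i) {
    # stable order(): descending signal, equal signals resolve to smaller index
    order(E[i, ], decreasing = TRUE)[seq_len(size)]
  })
  structure(list(members = members, signal = E, alpha = alpha, n_sub = n_sub),
            class = "microenvironment_map")
}

#' @export
print.microenvironment_map <- function(x, ...) {
  cat(sprintf("microenvironment_map: %d nodes, size %d, alpha = %g\n",
              length(x$members), length(x$members[[1]]), x$alpha))
  invisible(x)
}

# Row-normalized membership matrix M (N x N): M[i, j] = 1/|members(i)| for
# j in members(i). readout(H) = sigmoid(M %*% H).
membership_matrix <- function(me) {
  n <- length(me$members)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) M[i, me$members[[i]]] <- 1 / length(me$members[[i]])
  M
}
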