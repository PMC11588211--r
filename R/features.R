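#' Preprocess gene expression counts
#'
#' Standard expression preprocessing ahead of representation learning:
#' library-size normalization to the median depth, `log1p`, selection of the
#' `n_hvg` most variable genes, and per-gene z-scoring.
#'
#' @param ds a [spatial_dataset()] with raw counts.
#' @param n_hvg number of highly variable genes to keep (all genes when
#'   `n_hvg >= N_gene`).
#' @return N x min(n_hvg, N_gene) numeric matrix of expression features; the
#'   selected gene names are kept as column names.
#' @export
preprocess_genes <- function(ds, n_hvg = 3000L) {
  counts <- ds$counts
  depth <- rowSums(counts)
  if (any(depth == 0)) {
    warning(sprintf("%d spot(s) have zero total counts; left as zero vectors",
                    sum(depth == 0)))
    depth[depth == 0] <- 1
  }
  sf <- depth / stats::median(depth)
  x <- log1p(counts / sf)
  v <- apply(x, 2L, stats::var)
  n_keep <- min(as.integer(n_hvg), ncol(x))
  keep <- order(v, decreasing = TRUE)[seq_len(n_keep)]
  keep <- sort(keep)                       # preserve gene order
  standardize_columns(x[, keep, drop = FALSE])
}

# z-score columns; zero-variance columns map to 0.
standardize_columns <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2L, stats::sd)
  s[s == 0 | is.na(s)] <- 1
  scale(x, center = mu, scale = s)[, , drop = FALSE]
}

#' Extract per-spot image features from histology patches
#'
#' The default `"patchstats"` backbone is a deterministic descriptor that
#' needs no pretrained weights: per colour channel it records the patch mean,
#' variance and an 8-bin intensity histogram (30 features). Any pretrained
#' network can be plugged in by passing a function that maps the
#' `N x p x p x 3` patch stack to an `N x d` matrix.
#'
#' @param patches patch stack from [crop_patches()].
#' @param backbone `"patchstats"` or a function `(patches) -> matrix`.
#' @param d_i when a function backbone returns more than `d_i` columns, the
#'   features are compressed to `d_i` dimensions by truncated SVD.
#' @return N x d matrix of column-standardized image features.
#' @export
extract_image_features <- function(patches, backbone = "patchstats", d_i = 50L) {
  if (is.function(backbone)) {
    feats <- backbone(patches)
    feats <- as.matrix(feats)
    if (ncol(feats) > d_i) {
      sv <- svd(scale(feats, scale = FALSE), nu = d_i, nv = 0L)
      feats <- sv$u %*% diag(sv$d[seq_len(d_i)], d_i)
    }
  } else if (identical(backbone, "patchstats")) {
    feats <- patchstats_features(patches)
  } else {
    stop_sducl(sprintf("unknown image backbone '%s' (use \"patchstats\" or pass a function)",
                       backbone), "sducl_parameter_error")
  }
  standardize_columns(feats)
}

patchstats_features <- function(patches) {
  n <- dim(patches)[1]
  feats <- matrix(0, n, 30L)
  breaks <- seq(0, 255, length.out = 9L)
  for (i in seq_len(n)) {
    row <- numeric(0)
    for (ch in 1:3) {
      v <- as.vector(patches[i, , , ch])
      h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                                 all.inside = TRUE), nbins = 8L) / length(v)
      row <- c(row, mean(v) / 255, stats::var(v) / 255^2, h)
    }
    feats[i, ] <- row
  }
  colnames(feats) <- as.vector(t(outer(c("R", "G", "B"),
                                       c("mean", "var", paste0("hist", 1:8)),
                                       paste, sep = "_")))
  feats
}

#' Katz index matrix of a graph
#'
#' The Katz index scores every node pair by the attenuated count of all
#' connecting paths, \eqn{K = \sum_{l\ge1} \beta^l A^l}; short paths dominate
#' and influence decays with path length. The closed form
#' \eqn{(I-\beta A)^{-1} - I} is used by default; a truncated sum over path
#' lengths `1..l_max` is available as an alternative route.
#'
#' @param graph a `spatial_graph` (or plain symmetric 0/1 adjacency matrix).
#' @param beta attenuation factor; must be positive and below the reciprocal
#'   spectral radius of `A` for the series to converge. Values at or above
#'   the bound are shrunk to `0.9 / rho(A)` with a warning.
#' @param l_max `"closed_form"` or a positive integer truncation length.
#' @return list of class `katz_matrix` with `K`, the `beta` actually used,
#'   and `l_max`.
#' @export
katz_matrix <- function(graph, beta = 0.1, l_max = "closed_form") {
  A <- if (inherits(graph, "spatial_graph")) graph$A else as.matrix(graph)
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop_sducl("beta must be a positive number", "sducl_parameter_error")
  n <- nrow(A)
  rho <- if (any(A != 0))
    max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values)) else 0
  if (rho > 0 && beta >= 1 / rho) {
    beta_new <- 0.9 / rho
    warning(sprintf("beta = %.4g >= 1/rho(A) = %.4g; shrunk to %.4g for convergence",
                    beta, 1 / rho, beta_new))
    beta <- beta_new
  }
  if (identical(l_max, "closed_form")) {
    K <- solve(diag(n) - beta * A) - diag(n)
  } else {
    l_max <- as.integer(l_max)
    if (l_max < 1L) stop_sducl("l_max must be >= 1", "sducl_parameter_error")
    term <- beta * A
    K <- term
    for (l in seq_len(l_max - 1L)) {
      term <- beta * (term %*% A)
      K <- K + term
    }
  }
  structure(list(K = K, beta = beta, l_max = l_max), class = "katz_matrix")
}

#' Per-node spatial topology features from the Katz matrix
#'
#' Compresses the N x N Katz index matrix into a fixed-width per-node
#' feature block: row i of the output is node i's loading on the `d_s`
#' dominant left singular vectors of `K`, scaled by the singular values.
#'
#' @inheritParams katz_matrix
#' @param d_s number of topology feature dimensions (default 32; capped at N).
#' @return list with `katz` (the `katz_matrix`) and `Es` (N x d_s matrix).
#' @export
katz_features <- function(graph, beta = 0.1, l_max = "closed_form", d_s = 32L) {
  km <- katz_matrix(graph, beta = beta, l_max = l_max)
  n <- nrow(km$K)
  d_s <- min(as.integer(d_s), n)
  sv <- svd(km$K, nu = d_s, nv = 0L)
  Es <- sv$u %*% diag(sv$d[seq_len(d_s)], d_s)
  colnames(Es) <- sprintf("katz_sv%d", seq_len(d_s))
  list(katz = km, Es = Es)
}

#' Fuse feature blocks into the augmented feature matrix
#'
#' Column-wise concatenation `F = Eg (+) Ei (+) Es` of the gene, image and
#' spatial-topology blocks, each z-standardized per column first so that no
#' modality dominates by scale. Missing blocks are simply skipped, which is
#' how the image-free and topology-free model variants are expressed.
#'
#' @param Eg gene expression feature block (required).
#' @param Ei optional image feature block.
#' @param Es optional spatial topology feature block.
#' @return object of class `augmented_features` with elements `F` (the fused
#'   N x d matrix), `block_slices` (named list of column index vectors) and
#'   `dims` (named block widths).
#' @export
fuse_features <- function(Eg, Ei = NULL, Es = NULL) {
  blocks <- list(Eg = Eg, Ei = Ei, Es = Es)
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  n <- nrow(blocks[[1]])
  for (nm in names(blocks)) {
    if (nrow(blocks[[nm]]) != n)
      stop_sducl(sprintf("block %s has %d rows, expected %d",
                         nm, nrow(blocks[[nm]]), n), "sducl_alignment_error")
    blocks[[nm]] <- standardize_columns(as.matrix(blocks[[nm]]))
  }
  Fmat <- do.call(cbind, unname(blocks))
  widths <- vapply(blocks, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  slices <- Map(function(s, e) s:e, starts, ends)
  structure(list(F = Fmat, block_slices = slices, dims = widths),
            class = "augmented_features")
}

#' @export
print.augmented_features <- function(x, ...) {
  cat(sprintf("augmented_features: %d spots x %d dims [%s]\n",
              nrow(x$F), ncol(x$F),
              paste(sprintf("%s=%d", names(x$dims), x$dims), collapse = ", ")))
  invisible(x)
}
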