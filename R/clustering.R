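#' Cluster learned embeddings
#'
#' @param H N x d embedding matrix (or a fitted [sducl()] object, whose
#'   embeddings are used).
#' @param n_clusters number of clusters (k-means / GMM); ignored by Leiden.
#' @param method `"kmeans"` (default, 20 restarts), `"gmm"` (Gaussian
#'   mixture via `mclust`) or `"leiden"` (community detection on a shared
#'   k-nearest-neighbour graph of the embeddings; needs `igraph`).
#' @param seed RNG seed making the result deterministic.
#' @param resolution Leiden resolution parameter.
#' @return integer factor of predicted cluster labels.
#' @export
cluster_embeddings <- function(H, n_clusters, method = c("kmeans", "gmm", "leiden"),
                               seed = 0L, resolution = 1) {
  if (inherits(H, "sducl")) H <- H$H
  H <- as.matrix(H)
  method <- match.arg(method)
  n <- nrow(H)
  if (method %in% c("kmeans", "gmm")) {
    if (n_clusters < 2L)
      stop_sducl("n_clusters must be at least 2", "sducl_parameter_error")
    if (n_clusters > n)
      stop_sducl(sprintf("n_clusters = %d exceeds the %d spots", n_clusters, n),
                 "sducl_parameter_error")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (method %in% c("kmeans", "gmm") && n_clusters == n)
    return(factor(seq_len(n)))        # every spot its own cluster
  labels <- switch(method,
    kmeans = {
      # drop constant columns; kmeans handles them, but they waste distance
      keep <- apply(H, 2L, stats::sd) > 0
      Hk <- if (any(keep)) H[, keep, drop = FALSE] else H
      stats::kmeans(Hk, centers = n_clusters, nstart = 20L, iter.max = 100L)$cluster
    },
    gmm = {
      # Mclust() re-evaluates mclustBIC() in the caller's frame, which fails
      # when mclust is not attached; go through the BIC summary instead
      bic <- mclust::mclustBIC(H, G = n_clusters, verbose = FALSE)
      summ <- utils::getFromNamespace("summaryMclustBIC", "mclust")
      summ(bic, data = H, G = n_clusters)$classification
    },
    leiden = {
      if (!requireNamespace("igraph", quietly = TRUE))
        stop_sducl("method 'leiden' requires the igraph package", "sducl_parameter_error")
      g <- snn_graph(H, k = min(15L, n - 1L))
      cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                   resolution = resolution)
      igraph::membership(cl)
    })
  factor(as.integer(labels))
}

snn_graph <- function(H, k) {
  d <- as.matrix(stats::dist(H))
  n <- nrow(d)
  nn <- t(vapply(seq_len(n), function(i) {
    di <- d[i, ]; di[i] <- Inf
    order(di)[seq_len(k)]
  }, integer(k)))
  edges <- do.call(rbind, lapply(seq_len(n), function(i) cbind(i, nn[i, ])))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# contingency table of two label vectors
label_contingency <- function(a, b) {
  table(factor(a), factor(b))
}

#' External clustering agreement metrics
#'
#' Computes the four label-agreement metrics between a ground-truth and a
#' predicted partition:
#' * **ARI** — adjusted Rand index by the pair-counting contingency formula;
#' * **NMI** — mutual information normalized by the *arithmetic mean* of the
#'   two label entropies;
#' * **V-measure** — harmonic mean of homogeneity and completeness;
#' * **Purity** — fraction of spots assigned to their cluster's majority
#'   class.
#' All four are invariant to relabeling of either partition.
#'
#' @param labels_true,labels_pred label vectors of equal length.
#' @return named list with `ARI`, `NMI`, `V_measure`, `Purity`.
#' @export
external_metrics <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred))
    stop_sducl("label vectors differ in length", "sducl_alignment_error")
  ct <- label_contingency(labels_true, labels_pred)
  n <- sum(ct)
  # ARI (pair counting)
  sum_ij <- sum(choose(ct, 2))
  a <- rowSums(ct); b <- colSums(ct)
  sum_a <- sum(choose(a, 2)); sum_b <- sum(choose(b, 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  ari <- if (max_idx == exp_idx) 1 else (sum_ij - exp_idx) / (max_idx - exp_idx)
  # entropies and mutual information (natural log)
  p <- ct / n
  pa <- a / n; pb <- b / n
  h_true <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  h_pred <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
  denom <- (h_true + h_pred) / 2
  nmi <- if (denom == 0) 1 else mi / denom
  # V-measure
  homogeneity <- if (h_true == 0) 1 else mi / h_true
  completeness <- if (h_pred == 0) 1 else mi / h_pred
  v <- if (homogeneity + completeness == 0) 0 else
    2 * homogeneity * completeness / (homogeneity + completeness)
  purity <- sum(apply(ct, 2L, max)) / n
  list(ARI = ari, NMI = nmi, V_measure = v, Purity = purity)
}

#' Internal clustering quality metrics
#'
#' * **SC** — mean silhouette width over all spots (Euclidean distances; via
#'   the `cluster` package); `NA` when fewer than two clusters.
#' * **DBI** — Davies-Bouldin index: for clusters with centroids `c_i` and
#'   mean within-cluster centroid distance `s_i`,
#'   `DBI = mean_i max_{j != i} (s_i + s_j) / d(c_i, c_j)`; lower is better.
#'
#' @param H N x d embedding matrix.
#' @param labels_pred predicted cluster labels.
#' @return named list with `SC` and `DBI`.
#' @export
internal_metrics <- function(H, labels_pred) {
  H <- as.matrix(H)
  labels_pred <- as.integer(factor(labels_pred))
  ks <- sort(unique(labels_pred))
  if (length(ks) < 2L) return(list(SC = NA_real_, DBI = NA_real_))
  sil <- cluster::silhouette(labels_pred, stats::dist(H))
  sc <- mean(sil[, "sil_width"])
  centroids <- t(vapply(ks, function(k) colMeans(H[labels_pred == k, , drop = FALSE]),
                        numeric(ncol(H))))
  s <- vapply(seq_along(ks), function(i) {
    rows <- H[labels_pred == ks[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(rows, 2L, centroids[i, ])^2)))
  }, numeric(1))
  cd <- as.matrix(stats::dist(centroids))
  db <- mean(vapply(seq_along(ks), function(i) {
    r <- (s[i] + s[-i]) / cd[i, -i]
    max(r)
  }, numeric(1)))
  list(SC = sc, DBI = db)
}

#' Full clustering report
#'
#' Clusters the embeddings and assembles the evaluation metrics: external
#' agreement metrics when ground truth is available, internal metrics always.
#'
#' @inheritParams cluster_embeddings
#' @param labels_true optional ground-truth labels.
#' @return object of class `clustering_report` with `labels_pred`, `metrics`,
#'   `n_clusters`, `method` and `seed`.
#' @export
clustering_report <- function(H, n_clusters, labels_true = NULL,
                              method = "kmeans", seed = 0L) {
  if (inherits(H, "sducl")) {
    if (is.null(labels_true)) labels_true <- H$labels
    H <- H$H
  }
  labels_pred <- cluster_embeddings(H, n_clusters, method = method, seed = seed)
  metrics <- internal_metrics(H, labels_pred)
  if (!is.null(labels_true))
    metrics <- c(external_metrics(labels_true, labels_pred), metrics)
  structure(list(labels_pred = labels_pred, metrics = metrics,
                 n_clusters = length(unique(labels_pred)),
                 method = method, seed = seed),
            class = "clustering_report")
}

#' @export
print.clustering_report <- function(x, ...) {
  cat(sprintf("clustering_report: %d clusters (%s, seed %d)\n",
              x$n_clusters, x$method, x$seed))
  for (nm in names(x$metrics))
    cat(sprintf("  %-10s %.4f\n", nm, x$metrics[[nm]]))
  invisible(x)
}
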