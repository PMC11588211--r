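#' Fit the signal-diffusion contrastive representation model
#'
#' The main entry point. Starting from a [spatial_dataset()], the pipeline
#' is: (1) build the spatial K-nearest-neighbour graph from the coordinates;
#' (2) assemble the augmented feature matrix `F = Eg (+) Ei (+) Es` from
#' preprocessed expression, histology patch features and Katz topology
#' features; (3) discover each spot's diffusion microenvironment with the
#' graph heat kernel `exp(-alpha * L)`; (4) train a GCN autoencoder jointly
#' with a symmetric contrastive objective that discriminates each spot's
#' embedding against its microenvironment summary, using feature shuffling
#' as the corruption. The learned embedding matrix `H` is the
#' representation used for downstream clustering and visualization.
#'
#' @param ds a [spatial_dataset()].
#' @param k spatial graph neighbour count (default 6).
#' @param n_hvg highly variable genes kept in the expression block.
#' @param use_image include the histology feature block (only when the
#'   dataset carries an image).
#' @param use_katz include the Katz spatial-topology feature block.
#' @param use_fusion when `FALSE`, the model runs on the expression block
#'   alone (the "no tensor fusion" variant).
#' @param backbone image feature backbone passed to
#'   [extract_image_features()].
#' @param patch_px histology patch size; `NULL` for the dataset default.
#' @param d_i,d_s image / topology feature widths.
#' @param beta_katz Katz attenuation factor (default 0.1).
#' @param l_max Katz computation route: `"closed_form"` or a truncation
#'   length.
#' @param alpha_diffusion signal diffusion rate of the microenvironment
#'   discovery (default 0.1).
#' @param n_sub microenvironment size (default 20).
#' @param use_signal when `FALSE`, microenvironments are replaced by one
#'   whole-graph summary (`n_sub = N`), i.e. the plain DGI readout.
#' @param epochs,lr,weight_decay,alpha_rec,beta_con,hidden,embed,reduction
#'   training hyperparameters, see [train_sducl()].
#' @param seed integer seed controlling weight init, corruption permutations
#'   and every other stochastic step.
#' @param verbose print progress.
#' @return An object of class `sducl`: a list with `H` (N x embed
#'   embeddings, rows named by barcode), `S` (microenvironment summaries),
#'   `losses` (per-epoch loss table), `params` (trained weights), `graph`,
#'   `features` (the `augmented_features`), `microenv`, `labels` (copied
#'   from the dataset, may be `NULL`) and `config` (the full effective
#'   configuration). Methods: `print`, `summary`, `coef`, `fitted`,
#'   `residuals`, `predict`, `plot`.
#' @examples
#' spec <- synthetic_spec(grid_shape = c(6, 10), n_genes = 60, seed = 1)
#' ds <- generate_synthetic(spec)
#' fit <- sducl(ds, epochs = 20, n_sub = 10, seed = 1)
#' rep <- clustering_report(fit, n_clusters = 3)
#' @export
sducl <- function(ds, k = 6L, n_hvg = 3000L,
                  use_image = !is.null(ds$image), use_katz = TRUE,
                  use_fusion = TRUE, backbone = "patchstats", patch_px = NULL,
                  d_i = 50L, d_s = 32L, beta_katz = 0.1, l_max = "closed_form",
                  alpha_diffusion = 0.1, n_sub = 20L, use_signal = TRUE,
                  epochs = 500L, lr = 1e-3, weight_decay = 1e-4,
                  alpha_rec = 1, beta_con = 1, hidden = 512L, embed = 64L,
                  reduction = "mean", seed = 0L, verbose = FALSE) {
  stopifnot(inherits(ds, "spatial_dataset"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  graph <- build_knn_graph(ds$coords, k = k)
  n <- nrow(ds$counts)

  Eg <- preprocess_genes(ds, n_hvg = n_hvg)
  Ei <- NULL; Es <- NULL; katz <- NULL
  if (use_fusion && use_image && !is.null(ds$image)) {
    patches <- crop_patches(ds, patch_px = patch_px)
    Ei <- extract_image_features(patches, backbone = backbone, d_i = d_i)
  }
  if (use_fusion && use_katz) {
    kf <- katz_features(graph, beta = beta_katz, l_max = l_max, d_s = d_s)
    Es <- kf$Es; katz <- kf$katz
  }
  feats <- fuse_features(Eg, Ei, Es)
  rownames(feats$F) <- ds$spot_ids

  n_sub_eff <- if (use_signal) min(as.integer(n_sub), n) else n
  me <- discover_microenvironments(graph, alpha = alpha_diffusion,
                                   n_sub = n_sub_eff)

  fit <- train_sducl(feats$F, graph$A_hat_norm, me, epochs = epochs, lr = lr,
                     weight_decay = weight_decay, alpha_rec = alpha_rec,
                     beta_con = beta_con, hidden = hidden, embed = embed,
                     reduction = reduction, verbose = verbose)

  config <- list(k = k, n_hvg = n_hvg, use_image = use_image,
                 use_katz = use_katz, use_fusion = use_fusion,
                 backbone = if (is.function(backbone)) "custom" else backbone,
                 patch_px = patch_px, d_i = d_i, d_s = d_s,
                 beta_katz = beta_katz, l_max = l_max,
                 alpha_diffusion = alpha_diffusion, n_sub = n_sub,
                 use_signal = use_signal, epochs = epochs, lr = lr,
                 weight_decay = weight_decay, alpha_rec = alpha_rec,
                 beta_con = beta_con, hidden = hidden, embed = embed,
                 reduction = reduction, seed = seed)
  structure(list(H = fit$H, S = fit$S, X_rec = fit$X_rec, losses = fit$losses,
                 params = fit$params, graph = graph, features = feats,
                 katz = katz, microenv = me, labels = ds$labels,
                 spot_ids = ds$spot_ids, coords = ds$coords, config = config),
            class = "sducl")
}

#' @export
print.sducl <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("sducl fit: %d spots -> %d-dim embeddings\n",
              nrow(x$H), ncol(x$H)))
  cat(sprintf("  blocks: %s (d = %d)\n",
              paste(sprintf("%s=%d", names(x$features$dims), x$features$dims),
                    collapse = " "),
              ncol(x$features$F)))
  cat(sprintf("  graph: k = %d; diffusion alpha = %g, n_sub = %s\n",
              cfg$k, cfg$alpha_diffusion,
              if (cfg$use_signal) cfg$n_sub else "N (whole graph)"))
  last <- x$losses[nrow(x$losses), ]
  cat(sprintf("  after %d epochs: L_rec %.4f, L_con %.4f, L_con' %.4f\n",
              cfg$epochs, last$L_rec, last$L_con, last$L_con_sym))
  invisible(x)
}

#' @export
summary.sducl <- function(object, ...) {
  print(object)
  l <- object$losses
  cat(sprintf("  loss: epoch 1 L = %.4f -> epoch %d L = %.4f\n",
              l$L[1], nrow(l), l$L[nrow(l)]))
  cat(sprintf("  embedding: %d active dims of %d (nonzero variance)\n",
              sum(apply(object$H, 2, stats::sd) > 0), ncol(object$H)))
  invisible(object)
}

#' @export
coef.sducl <- function(object, ...) object$params

#' Extract embeddings from a fitted model
#'
#' `predict()` returns the learned per-spot embeddings; the model is
#' transductive, so `newdata` is not supported.
#' @param object a fitted `sducl` object.
#' @param ... unused.
#' @export
predict.sducl <- function(object, ...) {
  args <- list(...)
  if (!is.null(args$newdata))
    stop_sducl("sducl is transductive: embeddings exist only for the fitted spots",
               "sducl_parameter_error")
  object$H
}

#' @export
fitted.sducl <- function(object, ...) object$X_rec

#' @export
residuals.sducl <- function(object, ...) object$features$F - object$X_rec

#' Plot training losses or the embedding
#'
#' @param x fitted `sducl` object.
#' @param which `"loss"` (per-epoch loss curves) or `"embedding"` (first two
#'   principal components of `H`, coloured by labels when available).
#' @param ... passed to the underlying plot call.
#' @export
plot.sducl <- function(x, which = c("loss", "embedding"), ...) {
  which <- match.arg(which)
  if (which == "loss") {
    l <- x$losses
    plot(l$epoch, l$L, type = "l", xlab = "epoch", ylab = "loss",
         main = "training loss", ...)
    lines(l$epoch, l$L_rec, lty = 2)
    lines(l$epoch, l$L_con + l$L_con_sym, lty = 3)
    legend("topright", c("total", "reconstruction", "contrastive"),
           lty = 1:3, bty = "n")
  } else {
    pc <- stats::prcomp(x$H, rank. = 2)$x
    col <- if (!is.null(x$labels)) as.integer(x$labels) else 1L
    plot(pc, col = col, pch = 16, main = "embedding (PC1/PC2)", ...)
  }
  invisible(x)
}
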