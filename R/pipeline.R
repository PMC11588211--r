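#' Assemble a full run configuration
#'
#' Collects every tunable of the pipeline with its default, validates the
#' combination, and returns a config list that [sducl_run()] consumes and
#' echoes verbatim next to its outputs, so a run is reproducible from the
#' echoed config alone.
#'
#' @param input path to the input data (directory or file), or `NULL` when a
#'   dataset object is passed to [sducl_run()] directly.
#' @param format one of `"visium"`, `"h5ad"`, `"csv"`, `"synthetic"`.
#' @param coords_path,labels_path companion files for `format = "csv"`.
#' @param n_clusters number of clusters for the final clustering; `NULL`
#'   uses the number of ground-truth classes when labels are present.
#' @param out output directory.
#' @param ... any tunable accepted by [sducl()] (e.g. `k`,
#'   `alpha_diffusion`, `n_sub`, `beta_katz`, `epochs`, `seed`) plus the
#'   ablation switches `use_image`, `use_katz`, `use_fusion`, `use_signal`,
#'   and `alpha_rec` / `beta_con`.
#' @return list of class `sducl_config`.
#' @export
run_config <- function(input = NULL, format = c("visium", "h5ad", "csv", "synthetic"),
                       coords_path = NULL, labels_path = NULL,
                       n_clusters = NULL, out = tempfile("sducl_run_"), ...) {
  format <- match.arg(format)
  cfg <- list(k = 6L, n_hvg = 3000L, use_image = TRUE, use_katz = TRUE,
              use_fusion = TRUE, backbone = "patchstats", patch_px = NULL,
              d_i = 50L, d_s = 32L, beta_katz = 0.1, l_max = "closed_form",
              alpha_diffusion = 0.1, n_sub = 20L, use_signal = TRUE,
              epochs = 500L, lr = 1e-3, weight_decay = 1e-4,
              alpha_rec = 1, beta_con = 1, hidden = 512L, embed = 64L,
              reduction = "mean", seed = 0L, method = "kmeans")
  extra <- list(...)
  unknown <- setdiff(names(extra), names(cfg))
  if (length(unknown) > 0L)
    stop_sducl(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
               "sducl_parameter_error")
  cfg <- utils::modifyList(cfg, extra)
  if (cfg$alpha_rec == 0 && cfg$beta_con == 0)
    stop_sducl("alpha_rec = 0 and beta_con = 0 leaves no training signal",
               "sducl_parameter_error")
  cfg$input <- input; cfg$format <- format
  cfg$coords_path <- coords_path; cfg$labels_path <- labels_path
  cfg$n_clusters <- n_clusters; cfg$out <- out
  structure(cfg, class = "sducl_config")
}

#' Run the full pipeline
#'
#' read -> graph -> feature augmentation -> microenvironments -> training ->
#' clustering -> report, writing five artifacts to the output directory:
#' `embeddings.tsv`, `clusters.tsv`, `losses.csv`, `metrics.json` and
#' `config.json`.
#'
#' @param config a [run_config()].
#' @param ds optional [spatial_dataset()]; when given, `input`/`format` in
#'   the config are ignored.
#' @return list with `fit` (the [sducl()] object), `report` (the
#'   [clustering_report()]) and `out` (the output directory), invisibly.
#' @export
sducl_run <- function(config, ds = NULL) {
  stopifnot(inherits(config, "sducl_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_sducl(sprintf("[stage %s] %s", name, conditionMessage(e)),
                 "sducl_pipeline_error")
    })
  }
  if (is.null(ds)) {
    ds <- stage("read", switch(config$format,
      visium = read_visium(config$input),
      h5ad = read_h5ad(config$input),
      csv = read_csv_pair(config$input, config$coords_path, config$labels_path),
      synthetic = generate_synthetic(synthetic_spec(seed = config$seed))))
  }
  fit <- stage("fit", sducl(
    ds, k = config$k, n_hvg = config$n_hvg,
    use_image = config$use_image && !is.null(ds$image),
    use_katz = config$use_katz, use_fusion = config$use_fusion,
    backbone = config$backbone, patch_px = config$patch_px,
    d_i = config$d_i, d_s = config$d_s, beta_katz = config$beta_katz,
    l_max = config$l_max, alpha_diffusion = config$alpha_diffusion,
    n_sub = config$n_sub, use_signal = config$use_signal,
    epochs = config$epochs, lr = config$lr,
    weight_decay = config$weight_decay, alpha_rec = config$alpha_rec,
    beta_con = config$beta_con, hidden = config$hidden, embed = config$embed,
    reduction = config$reduction, seed = config$seed))

  n_clusters <- config$n_clusters %||%
    (if (!is.null(ds$labels)) nlevels(droplevels(ds$labels)) else
       stop_sducl("n_clusters not given and dataset has no labels to infer it from",
                  "sducl_parameter_error"))
  report <- stage("cluster",
                  clustering_report(fit$H, n_clusters, labels_true = ds$labels,
                                    method = config$method, seed = config$seed))

  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage("write", {
    emb <- data.frame(barcode = rownames(fit$H), fit$H, check.names = FALSE)
    write.table(emb, file.path(out, "embeddings.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(barcode = rownames(fit$H),
                           cluster = report$labels_pred),
                file.path(out, "clusters.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.csv(fit$losses, file.path(out, "losses.csv"), row.names = FALSE)
    jsonlite::write_json(report$metrics, file.path(out, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    cfg <- unclass(config)
    cfg$out <- NULL
    jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                         file.path(out, "config.json"), auto_unbox = TRUE,
                         digits = NA)
  })
  invisible(list(fit = fit, report = report, out = out))
}
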