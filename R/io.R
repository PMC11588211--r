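#' Read a 10x Visium (spaceranger-style) directory
#'
#' Expects an MTX feature-barcode triplet (`matrix.mtx[.gz]`,
#' `barcodes.tsv[.gz]`, `features.tsv[.gz]` or `genes.tsv`) plus a tissue
#' positions table (`tissue_positions_list.csv`, old headerless 6-column
#' dialect, or `tissue_positions.csv`, new headered dialect — auto-detected).
#' Files are searched in `dir_path` and in the conventional
#' `filtered_feature_bc_matrix/` and `spatial/` subdirectories. Spots flagged
#' `in_tissue = 0` are dropped and coordinates are taken from the
#' full-resolution pixel columns. A `labels.tsv` (barcode, label) companion
#' file, as written by [write_visium()], is read back into `labels`.
#'
#' @param dir_path directory containing the run.
#' @param image_path optional path to a PNG/TIFF histology raster; when
#'   `NULL`, `image.png` / `spatial/tissue_hires_image.png` are tried.
#' @return a [spatial_dataset()].
#' @export
read_visium <- function(dir_path, image_path = NULL) {
  if (!dir.exists(dir_path))
    stop_sducl(sprintf("directory not found: %s", dir_path), "sducl_format_error")
  find1 <- function(names) {
    for (sub in c(".", "filtered_feature_bc_matrix", "spatial"))
      for (nm in names) {
        p <- file.path(dir_path, sub, nm)
        if (file.exists(p)) return(p)
      }
    NULL
  }
  mtx <- find1(c("matrix.mtx", "matrix.mtx.gz"))
  if (is.null(mtx))
    stop_sducl("no matrix.mtx[.gz] found: not a Visium matrix directory",
               "sducl_format_error")
  barcodes <- find1(c("barcodes.tsv", "barcodes.tsv.gz"))
  features <- find1(c("features.tsv", "features.tsv.gz", "genes.tsv", "genes.tsv.gz"))
  if (is.null(barcodes) || is.null(features))
    stop_sducl("matrix.mtx present but barcodes/features file is missing",
               "sducl_format_error")
  pos <- find1(c("tissue_positions_list.csv", "tissue_positions.csv"))
  if (is.null(pos))
    stop_sducl("no tissue positions CSV found", "sducl_format_error")

  m <- Matrix::readMM(mtx)                     # genes x barcodes (10x layout)
  bc <- readLines(barcodes)
  ft <- read.table(features, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  genes <- ft[[min(2L, ncol(ft))]]
  if (nrow(m) != length(genes) || ncol(m) != length(bc))
    stop_sducl("matrix dimensions do not match barcodes/features files",
               "sducl_format_error")
  counts <- t(as.matrix(m))
  rownames(counts) <- bc
  colnames(counts) <- make.unique(genes)

  positions <- read_tissue_positions(pos)
  unmatched <- sum(!positions$barcode %in% bc)
  keep <- positions[positions$barcode %in% bc & positions$in_tissue == 1L, , drop = FALSE]
  missing_pos <- sum(!bc %in% positions$barcode)
  if (missing_pos > 0L)
    stop_sducl(sprintf("%d barcodes in the matrix have no entry in the positions file (and %d position rows are unmatched)",
                       missing_pos, unmatched), "sducl_alignment_error")
  counts <- counts[keep$barcode, , drop = FALSE]

  image <- NULL
  if (is.null(image_path))
    image_path <- find1(c("image.png", "tissue_hires_image.png"))
  if (!is.null(image_path)) image <- read_raster(image_path)

  spot_diameter <- NULL
  sf <- find1(c("scalefactors_json.json"))
  if (!is.null(sf)) {
    sj <- jsonlite::read_json(sf)
    spot_diameter <- sj$spot_diameter_fullres %||% NULL
  }

  labels <- NULL
  lab_file <- find1("labels.tsv")
  if (!is.null(lab_file)) {
    lt <- read.table(lab_file, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    labels <- lt[[2]][match(keep$barcode, as.character(lt[[1]]))]
  }

  spatial_dataset(
    counts = counts,
    coords = cbind(keep$pxl_col, keep$pxl_row),
    spot_ids = keep$barcode,
    image = image,
    pixel_coords = if (!is.null(image)) cbind(keep$pxl_row, keep$pxl_col) else NULL,
    spot_diameter_px = if (!is.null(image)) spot_diameter else NULL,
    labels = labels)
}

# Both spaceranger dialects: old = headerless 6 columns, new = headered.
read_tissue_positions <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("barcode", first, fixed = TRUE)
  tab <- read.csv(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(tab) != 6L)
      stop_sducl("headerless tissue positions file must have 6 columns",
                 "sducl_format_error")
    names(tab) <- c("barcode", "in_tissue", "array_row", "array_col",
                    "pxl_row_in_fullres", "pxl_col_in_fullres")
  }
  need <- c("barcode", "in_tissue", "pxl_row_in_fullres", "pxl_col_in_fullres")
  if (!all(need %in% names(tab)))
    stop_sducl(sprintf("tissue positions file lacks columns: %s",
                       paste(setdiff(need, names(tab)), collapse = ", ")),
               "sducl_format_error")
  data.frame(barcode = as.character(tab$barcode),
             in_tissue = as.integer(tab$in_tissue),
             pxl_row = as.numeric(tab$pxl_row_in_fullres),
             pxl_col = as.numeric(tab$pxl_col_in_fullres),
             stringsAsFactors = FALSE)
}

read_raster <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop_sducl("the 'tiff' package is required to read TIFF rasters",
                 "sducl_format_error")
    img <- tiff::readTIFF(path)
  } else {
    stop_sducl(sprintf("unsupported raster format: %s", path), "sducl_format_error")
  }
  raster_to_array(img)
}

#' Read a counts/coordinates CSV pair
#'
#' Both files must carry the spot barcode in their first column; rows are
#' aligned on it (order taken from the counts file).
#'
#' @param counts_path CSV/TSV of spots x genes with a barcode first column and
#'   gene names in the header.
#' @param coords_path CSV/TSV with barcode, x, y columns.
#' @param labels_path optional CSV/TSV with barcode and a label column.
#' @return a [spatial_dataset()].
#' @export
read_csv_pair <- function(counts_path, coords_path, labels_path = NULL) {
  read_any <- function(p) {
    sep <- if (grepl("\\.tsv$", p, ignore.case = TRUE)) "\t" else ","
    read.table(p, header = TRUE, sep = sep, stringsAsFactors = FALSE,
               check.names = FALSE)
  }
  ct <- read_any(counts_path)
  co <- read_any(coords_path)
  ids <- as.character(ct[[1]])
  co_ids <- as.character(co[[1]])
  common <- intersect(ids, co_ids)
  if (length(common) == 0L)
    stop_sducl("counts and coords files share no barcodes", "sducl_alignment_error")
  if (length(common) < length(ids) || length(common) < length(co_ids))
    stop_sducl(sprintf("%d barcodes are present in only one of the two files",
                       length(union(ids, co_ids)) - length(common)),
               "sducl_alignment_error")
  counts <- as.matrix(ct[, -1, drop = FALSE])
  rownames(counts) <- ids
  co <- co[match(ids, co_ids), , drop = FALSE]
  labels <- NULL
  if (!is.null(labels_path)) {
    lb <- read_any(labels_path)
    labels <- lb[[2]][match(ids, as.character(lb[[1]]))]
  }
  spatial_dataset(counts, cbind(as.numeric(co[[2]]), as.numeric(co[[3]])),
                  spot_ids = ids, labels = labels)
}

#' Read / write AnnData `.h5ad` containers
#'
#' Bridges to the Python `anndata` library (invoked through the `python`
#' executable on the PATH) and exchanges plain-text tables with it, so the R
#' side needs no HDF5 bindings. The container must carry spot coordinates in
#' `obsm["spatial"]`.
#'
#' @param path `.h5ad` file.
#' @param labels_col name of the `obs` column holding ground-truth labels;
#'   when `NULL` the columns `label`, `ground_truth`, `layer`, `domain` are
#'   tried in that order.
#' @return a [spatial_dataset()].
#' @export
read_h5ad <- function(path, labels_col = NULL) {
  if (!file.exists(path))
    stop_sducl(sprintf("file not found: %s", path), "sducl_format_error")
  helper <- system.file("python", "h5ad_bridge.py", package = "sducl")
  tmp <- tempfile("h5ad_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  status <- system2(find_python(), c(helper, "export", shQuote(path), shQuote(tmp)),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status") %||% 0L
  if (code != 0L)
    stop_sducl(paste(c(sprintf("reading %s failed:", path), status), collapse = "\n"),
               "sducl_format_error")
  if (!file.exists(file.path(tmp, "spatial.csv")))
    stop_sducl("h5ad container has no obsm['spatial'] coordinate slot",
               "sducl_format_error")
  counts <- as.matrix(read.csv(file.path(tmp, "X.csv"), row.names = 1,
                               check.names = FALSE))
  coords <- as.matrix(read.csv(file.path(tmp, "spatial.csv"), row.names = 1))
  obs <- read.csv(file.path(tmp, "obs.csv"), row.names = 1, check.names = FALSE,
                  stringsAsFactors = FALSE)
  labels <- NULL
  cand <- labels_col %||% c("label", "ground_truth", "layer", "domain")
  hit <- intersect(cand, colnames(obs))
  if (length(hit) > 0L) {
    labels <- obs[[hit[1]]]
    lv <- readLines(file.path(tmp, paste0("levels_", hit[1], ".txt")))
    if (length(lv) > 0L) labels <- factor(labels, levels = lv)
  } else if (!is.null(labels_col)) {
    stop_sducl(sprintf("obs column '%s' not found in %s", labels_col, path),
               "sducl_format_error")
  }
  spatial_dataset(counts, coords[rownames(counts), , drop = FALSE],
                  spot_ids = rownames(counts), labels = labels)
}

#' @rdname read_h5ad
#' @param ds a [spatial_dataset()] to serialize.
#' @param labels_name `obs` column name used for `ds$labels` when present.
#' @export
write_h5ad <- function(ds, path, labels_name = "label") {
  helper <- system.file("python", "h5ad_bridge.py", package = "sducl")
  tmp <- tempfile("h5ad_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  write.csv(data.frame(ds$counts, row.names = ds$spot_ids, check.names = FALSE),
            file.path(tmp, "X.csv"))
  write.csv(data.frame(x = ds$coords[, 1], y = ds$coords[, 2],
                       row.names = ds$spot_ids),
            file.path(tmp, "spatial.csv"))
  if (!is.null(ds$labels)) {
    write.csv(data.frame(barcode = ds$spot_ids, label = as.character(ds$labels)),
              file.path(tmp, "labels.csv"), row.names = FALSE)
    writeLines(levels(ds$labels), file.path(tmp, "levels.txt"))
    writeLines(labels_name, file.path(tmp, "labels_name.txt"))
  }
  status <- system2(find_python(), c(helper, "import", shQuote(tmp), shQuote(path)),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status") %||% 0L
  if (code != 0L)
    stop_sducl(paste(c("writing h5ad failed:", status), collapse = "\n"),
               "sducl_format_error")
  invisible(path)
}

find_python <- function() {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    stop_sducl("no python executable found on the PATH (needed for .h5ad I/O)",
               "sducl_format_error")
  py
}

#' Write a spatial dataset as a minimal Visium-style directory
#'
#' Emits the MTX triplet, a tissue positions CSV (either dialect), an
#' `image.png` when the dataset has one, and a `scalefactors_json.json`.
#' The output round-trips through [read_visium()].
#'
#' @param ds a [spatial_dataset()].
#' @param dir output directory (created if needed).
#' @param positions_dialect `"old"` (headerless `tissue_positions_list.csv`)
#'   or `"new"` (headered `tissue_positions.csv`).
#' @return `dir`, invisibly.
#' @export
write_visium <- function(ds, dir, positions_dialect = c("old", "new")) {
  positions_dialect <- match.arg(positions_dialect)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::Matrix(t(ds$counts), sparse = TRUE)   # genes x barcodes
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(ds$spot_ids, file.path(dir, "barcodes.tsv"))
  write.table(data.frame(id = ds$gene_ids, name = ds$gene_ids,
                         type = "Gene Expression"),
              file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  px <- ds$pixel_coords
  if (is.null(px)) px <- cbind(ds$coords[, 2], ds$coords[, 1])
  pos <- data.frame(barcode = ds$spot_ids, in_tissue = 1L,
                    array_row = 0L, array_col = 0L,
                    pxl_row_in_fullres = px[, 1], pxl_col_in_fullres = px[, 2])
  if (positions_dialect == "old") {
    write.table(pos, file.path(dir, "tissue_positions_list.csv"), sep = ",",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    write.csv(pos, file.path(dir, "tissue_positions.csv"), quote = FALSE,
              row.names = FALSE)
  }
  if (!is.null(ds$image))
    png::writePNG(ds$image / 255, file.path(dir, "image.png"))
  if (!is.null(ds$spot_diameter_px))
    jsonlite::write_json(list(spot_diameter_fullres = ds$spot_diameter_px),
                         file.path(dir, "scalefactors_json.json"),
                         auto_unbox = TRUE)
  if (!is.null(ds$labels))
    write.table(data.frame(barcode = ds$spot_ids, label = as.character(ds$labels)),
                file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(dir)
}
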