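#' Construct a spatial transcriptomics dataset
#'
#' The in-memory container used throughout the package: a spot-by-gene count
#' (or expression) matrix, 2-D spatial coordinates per spot, and optionally a
#' full-slide histology raster with per-spot pixel positions and ground-truth
#' domain labels.
#'
#' Coordinates are stored as floating point in a metric (pixel or micron)
#' system; Euclidean distances between rows of `coords` define the spatial
#' neighbour graph, so array row/column indices should not be used here.
#'
#' @param counts numeric matrix, spots in rows, genes in columns; no negative
#'   entries.
#' @param coords numeric matrix/data.frame with one (x, y) row per spot.
#' @param spot_ids character vector of unique barcodes (default: rownames of
#'   `counts` or `spot-1..N`).
#' @param gene_ids character vector of gene names (default: colnames of
#'   `counts` or `gene-1..M`).
#' @param image optional `H x W x 3` numeric array with values in `[0, 255]`.
#' @param pixel_coords optional matrix of per-spot (row, col) pixel positions
#'   into `image`; required when `image` is given.
#' @param spot_diameter_px optional positive scalar, spot diameter in pixels.
#' @param labels optional per-spot ground-truth labels (coerced to factor).
#' @return An object of class `spatial_dataset`.
#' @export
spatial_dataset <- function(counts, coords, spot_ids = NULL, gene_ids = NULL,
                            image = NULL, pixel_coords = NULL,
                            spot_diameter_px = NULL, labels = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  n <- nrow(counts)
  if (n < 1L) stop_sducl("dataset must contain at least one spot", "sducl_format_error")
  if (any(counts < 0)) stop_sducl("counts contain negative entries", "sducl_format_error")

  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 2L)
    stop_sducl("coords must be a numeric N x 2 matrix", "sducl_format_error")
  if (nrow(coords) != n)
    stop_sducl(sprintf("coords has %d rows but counts has %d spots", nrow(coords), n),
               "sducl_alignment_error")
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y")

  spot_ids <- spot_ids %||% rownames(counts) %||% sprintf("spot-%d", seq_len(n))
  spot_ids <- as.character(spot_ids)
  if (anyDuplicated(spot_ids))
    stop_sducl("spot_ids are not unique", "sducl_format_error")
  if (length(spot_ids) != n)
    stop_sducl("spot_ids length does not match number of spots", "sducl_alignment_error")
  gene_ids <- gene_ids %||% colnames(counts) %||% sprintf("gene-%d", seq_len(ncol(counts)))
  gene_ids <- as.character(gene_ids)
  rownames(counts) <- spot_ids
  colnames(counts) <- gene_ids
  rownames(coords) <- spot_ids

  if (!is.null(labels)) {
    if (length(labels) != n)
      stop_sducl("labels length does not match number of spots", "sducl_alignment_error")
    labels <- as.factor(labels)
  }

  if (!is.null(image)) {
    image <- raster_to_array(image)
    if (is.null(pixel_coords))
      stop_sducl("an image requires pixel_coords", "sducl_format_error")
    pixel_coords <- as.matrix(pixel_coords)
    if (nrow(pixel_coords) != n || ncol(pixel_coords) != 2L)
      stop_sducl("pixel_coords must be an N x 2 matrix of (row, col) positions",
                 "sducl_alignment_error")
    storage.mode(pixel_coords) <- "double"
    colnames(pixel_coords) <- c("row", "col")
    if (is.null(spot_diameter_px)) spot_diameter_px <- NULL
  } else {
    pixel_coords <- NULL
  }
  if (!is.null(spot_diameter_px) && (!is.numeric(spot_diameter_px) || spot_diameter_px <= 0))
    stop_sducl("spot_diameter_px must be a positive number", "sducl_parameter_error")

  structure(
    list(counts = counts, coords = coords, spot_ids = spot_ids,
         gene_ids = gene_ids, image = image, pixel_coords = pixel_coords,
         spot_diameter_px = spot_diameter_px, labels = labels),
    class = "spatial_dataset")
}

# Accept H x W (grey), H x W x 3 arrays on 0..1 or 0..255 scale; return
# H x W x 3 double array on the 0..255 scale.
raster_to_array <- function(image) {
  if (length(dim(image)) == 2L) image <- array(rep(image, 3L), c(dim(image), 3L))
  if (length(dim(image)) != 3L || dim(image)[3] < 3L)
    stop_sducl("image must be an H x W x 3 array", "sducl_format_error")
  image <- image[, , 1:3, drop = FALSE]
  storage.mode(image) <- "double"
  if (max(image) <= 1) image <- image * 255
  image
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("spatial_dataset: %d spots x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  coords range: x [%.1f, %.1f], y [%.1f, %.1f]\n",
              min(x$coords[, 1]), max(x$coords[, 1]),
              min(x$coords[, 2]), max(x$coords[, 2])))
  if (!is.null(x$image))
    cat(sprintf("  image: %d x %d px (spot diameter %s px)\n",
                dim(x$image)[1], dim(x$image)[2],
                x$spot_diameter_px %||% "unknown"))
  if (!is.null(x$labels))
    cat(sprintf("  labels: %d classes (%s)\n", nlevels(x$labels),
                paste(utils::head(levels(x$labels), 5), collapse = ", ")))
  invisible(x)
}

#' @export
dim.spatial_dataset <- function(x) dim(x$counts)

#' Crop per-spot histology patches
#'
#' Extracts one square patch per spot, centred on the spot's pixel
#' coordinate. Windows that would overrun the raster are shifted inward so
#' every patch has exactly `patch_px` x `patch_px` pixels.
#'
#' @param ds a [spatial_dataset()] carrying an image and pixel coordinates.
#' @param patch_px patch side length in pixels; defaults to the rounded spot
#'   diameter when known, else 32.
#' @return numeric array `N x patch_px x patch_px x 3` on the 0..255 scale.
#' @export
crop_patches <- function(ds, patch_px = NULL) {
  if (is.null(ds$image))
    stop_sducl("dataset has no image to crop patches from", "sducl_precondition_error")
  patch_px <- patch_px %||%
    (if (!is.null(ds$spot_diameter_px)) max(1L, round(ds$spot_diameter_px)) else 32L)
  patch_px <- as.integer(patch_px)
  h <- dim(ds$image)[1]; w <- dim(ds$image)[2]
  if (patch_px > h || patch_px > w)
    stop_sducl(sprintf("patch_px = %d exceeds image size %d x %d", patch_px, h, w),
               "sducl_parameter_error")
  n <- nrow(ds$pixel_coords)
  out <- array(0, c(n, patch_px, patch_px, 3L))
  half <- patch_px %/% 2L
  for (i in seq_len(n)) {
    r0 <- min(max(round(ds$pixel_coords[i, 1]) - half, 0L), h - patch_px)
    c0 <- min(max(round(ds$pixel_coords[i, 2]) - half, 0L), w - patch_px)
    out[i, , , ] <- ds$image[(r0 + 1L):(r0 + patch_px), (c0 + 1L):(c0 + patch_px), ]
  }
  out
}
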