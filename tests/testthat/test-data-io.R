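test_that("visium directory round-trips counts, coords and spot ids", {
  ds <- make_tiny_ds()
  dir <- withr::local_tempdir()
  write_visium(ds, dir)
  back <- read_visium(dir)
  expect_identical(unname(back$counts), unname(ds$counts))
  expect_equal(back$spot_ids, ds$spot_ids)
  # read_visium reconstructs coords from the pixel columns (x = col, y = row)
  expect_equal(unname(back$coords),
               unname(cbind(ds$pixel_coords[, 2], ds$pixel_coords[, 1])))
  expect_false(is.null(back$image))
  expect_equal(back$spot_diameter_px, 8)
})

test_that("positions dialects are auto-detected and in_tissue = 0 rows drop", {
  ds <- make_tiny_ds()
  for (dialect in c("old", "new")) {
    dir <- withr::local_tempdir()
    write_visium(ds, dir, positions_dialect = dialect)
    # flag one spot as out-of-tissue by editing the positions file
    f <- file.path(dir, c(old = "tissue_positions_list.csv",
                          new = "tissue_positions.csv")[[dialect]])
    lines <- readLines(f)
    target <- if (dialect == "old") 1L else 2L
    lines[target] <- sub(",1,", ",0,", lines[target], fixed = TRUE)
    writeLines(lines, f)
    back <- read_visium(dir)
    expect_equal(nrow(back$counts), nrow(ds$counts) - 1L)
  }
})

test_that("malformed visium directories raise named format errors", {
  dir <- withr::local_tempdir()
  expect_error(read_visium(dir), "matrix.mtx", class = "sducl_format_error")
  ds <- make_tiny_ds()
  write_visium(ds, dir)
  file.remove(file.path(dir, "tissue_positions_list.csv"))
  expect_error(read_visium(dir), "positions", class = "sducl_format_error")
})

test_that("barcode mismatch between matrix and positions is an alignment error", {
  ds <- make_tiny_ds()
  dir <- withr::local_tempdir()
  write_visium(ds, dir)
  f <- file.path(dir, "tissue_positions_list.csv")
  lines <- readLines(f)
  lines[1] <- sub("^BC-01", "BC-XX", lines[1])
  writeLines(lines, f)
  expect_error(read_visium(dir), "1 barcodes", class = "sducl_alignment_error")
})

test_that("csv pair reader aligns on barcodes and rejects disjoint keys", {
  ds <- make_tiny_ds()
  dir <- withr::local_tempdir()
  cpath <- file.path(dir, "counts.csv")
  xpath <- file.path(dir, "coords.csv")
  write.csv(data.frame(barcode = ds$spot_ids, ds$counts, check.names = FALSE),
            cpath, row.names = FALSE)
  # coords deliberately in reversed order: reader must align on the key
  write.csv(data.frame(barcode = rev(ds$spot_ids), x = rev(ds$coords[, 1]),
                       y = rev(ds$coords[, 2])), xpath, row.names = FALSE)
  back <- read_csv_pair(cpath, xpath)
  expect_equal(unname(back$counts), unname(ds$counts))
  expect_equal(unname(back$coords), unname(ds$coords))

  write.csv(data.frame(barcode = paste0("other-", seq_len(9)), x = 1:9, y = 1:9),
            xpath, row.names = FALSE)
  expect_error(read_csv_pair(cpath, xpath), class = "sducl_alignment_error")
})

test_that("h5ad bridge round-trips counts, coords and label categories", {
  ds <- make_tiny_ds()
  path <- withr::local_tempfile(fileext = ".h5ad")
  write_h5ad(ds, path)
  back <- read_h5ad(path)
  expect_equal(unname(back$counts), unname(ds$counts))
  expect_equal(unname(back$coords), unname(ds$coords))
  expect_equal(as.character(back$labels), as.character(ds$labels))
  expect_equal(levels(back$labels), levels(ds$labels))
  expect_error(read_h5ad(file.path(tempdir(), "nope.h5ad")),
               class = "sducl_format_error")
})

test_that("patch cropping slices, clamps at borders and keeps shape", {
  img <- array(seq_len(100 * 100 * 3), c(100, 100, 3))
  mk <- function(px_rowcol) spatial_dataset(
    counts = matrix(1, nrow(px_rowcol), 2), coords = px_rowcol,
    image = img, pixel_coords = px_rowcol, spot_diameter_px = 32)
  ds <- mk(rbind(c(50, 50)))
  p <- crop_patches(ds, 32)
  expect_equal(dim(p), c(1L, 32L, 32L, 3L))
  expect_equal(p[1, , , ], img[35:66, 35:66, ])      # 0-based rows/cols 34..65

  ds0 <- mk(rbind(c(0, 0)))
  p0 <- crop_patches(ds0, 32)
  expect_equal(p0[1, , , ], img[1:32, 1:32, ])        # clamped into the raster

  ds7 <- mk(cbind(seq(20, 80, length.out = 7), seq(20, 80, length.out = 7)))
  expect_equal(dim(crop_patches(ds7, 32)), c(7L, 32L, 32L, 3L))

  expect_error(crop_patches(ds, 128), class = "sducl_parameter_error")
  no_img <- spatial_dataset(matrix(1, 2, 2), cbind(1:2, 1:2))
  expect_error(crop_patches(no_img), class = "sducl_precondition_error")
})

test_that("patch extraction is translation-consistent away from borders", {
  set.seed(7)
  img <- array(runif(60 * 60 * 3, 0, 255), c(60, 60, 3))
  shift <- 5L
  img_shifted <- array(0, c(65, 65, 3))
  img_shifted[6:65, 6:65, ] <- img
  px <- rbind(c(30, 30), c(25, 40))
  ds1 <- spatial_dataset(matrix(1, 2, 2), px, image = img, pixel_coords = px)
  ds2 <- spatial_dataset(matrix(1, 2, 2), px, image = img_shifted,
                         pixel_coords = px + shift)
  expect_equal(crop_patches(ds1, 16), crop_patches(ds2, 16))
})

test_that("dataset invariants are enforced at construction", {
  expect_error(spatial_dataset(matrix(-1, 2, 2), cbind(1:2, 1:2)),
               class = "sducl_format_error")
  expect_error(spatial_dataset(matrix(1, 2, 2), cbind(1:3, 1:3)),
               class = "sducl_alignment_error")
  expect_error(spatial_dataset(matrix(1, 2, 2), cbind(1:2, 1:2),
                               spot_ids = c("a", "a")),
               class = "sducl_format_error")
  expect_error(spatial_dataset(matrix(1, 2, 2), cbind(1:2, 1:2),
                               image = array(0, c(5, 5, 3))),
               class = "sducl_format_error")  # image without pixel_coords
})
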