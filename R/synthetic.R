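#' Specify a synthetic spatial transcriptomics dataset
#'
#' Describes a slide of spots on a regular grid partitioned into spatial
#' domains with distinct expression programs, mimicking the structure of
#' annotated Visium slides (layered cortex-like bands, or Voronoi mosaics
#' for tumour-like tissue). Counts are negative-binomial with lognormal
#' per-spot depth; each domain has a dedicated set of marker genes whose
#' mean is multiplied by `exp(marker_log_fc)` inside the domain; the
#' histology image tints each spot's pixel block with a domain base colour
#' plus Gaussian noise, so image patches also carry domain signal.
#' `marker_log_fc` acts as the single domain effect-size knob: the colour
#' contrast between domain tints scales linearly with it (reaching the full
#' palette at 1.5), and at 0 the slide is null in every modality.
#'
#' @param grid_shape integer `(rows, cols)` of the spot grid.
#' @param n_domains number of spatial domains.
#' @param n_genes total genes.
#' @param n_markers_per_domain marker genes per domain.
#' @param marker_log_fc natural-log fold change of markers inside their
#'   domain (0 gives a null slide with no domain signal).
#' @param nb_dispersion negative-binomial dispersion (`size = 1/dispersion`);
#'   larger means more overdispersed.
#' @param depth_mean expected total counts per spot.
#' @param image_noise_sd pixel noise s.d. on the 0..255 scale.
#' @param layout `"layers"` (contiguous bands across rows) or `"mosaic"`
#'   (Voronoi patches around random seed spots).
#' @param seed RNG seed; the dataset is a deterministic function of the spec.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(grid_shape = c(10L, 30L), n_domains = 3L,
                           n_genes = 300L, n_markers_per_domain = 30L,
                           marker_log_fc = 1.5, nb_dispersion = 0.3,
                           depth_mean = 5000, image_noise_sd = 10,
                           layout = c("layers", "mosaic"), seed = 0L) {
  layout <- match.arg(layout)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 1L))
    stop_sducl("grid_shape must be two positive integers", "sducl_parameter_error")
  if (n_domains < 1L || n_domains > prod(grid_shape))
    stop_sducl("n_domains must be between 1 and the number of spots",
               "sducl_parameter_error")
  if (n_markers_per_domain * n_domains > n_genes)
    stop_sducl("not enough genes for the requested marker sets", "sducl_parameter_error")
  if (marker_log_fc < 0 || nb_dispersion <= 0 || depth_mean <= 0 || image_noise_sd < 0)
    stop_sducl("effect sizes, dispersion and depth must be nonnegative/positive",
               "sducl_parameter_error")
  structure(list(grid_shape = grid_shape, n_domains = as.integer(n_domains),
                 n_genes = as.integer(n_genes),
                 n_markers_per_domain = as.integer(n_markers_per_domain),
                 marker_log_fc = marker_log_fc, nb_dispersion = nb_dispersion,
                 depth_mean = depth_mean, image_noise_sd = image_noise_sd,
                 layout = layout, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# fixed palette of well-separated domain base colours (RGB, 0..255)
domain_palette <- function(n) {
  base <- rbind(c(200, 80, 80), c(80, 160, 200), c(120, 200, 100),
                c(220, 180, 60), c(170, 90, 200), c(90, 200, 180),
                c(230, 120, 170), c(140, 140, 140))
  base[((seq_len(n) - 1L) %% nrow(base)) + 1L, , drop = FALSE]
}

#' Generate a synthetic spatial dataset
#'
#' @param spec a [synthetic_spec()].
#' @return a [spatial_dataset()] with ground-truth `labels`, a tinted
#'   histology image and per-spot pixel coordinates. Identical specs (same
#'   seed) produce bit-identical datasets.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  rows <- spec$grid_shape[1]; cols <- spec$grid_shape[2]
  n <- rows * cols
  grid <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  spacing <- 100
  coords <- cbind(x = grid$col * spacing, y = grid$row * spacing)

  domains <- switch(spec$layout,
    layers = {
      # contiguous bands across rows (cortical-layer-like)
      cut(grid$row, breaks = spec$n_domains, labels = FALSE)
    },
    mosaic = {
      seeds <- sample.int(n, spec$n_domains)
      d2 <- outer(coords[, 1], coords[seeds, 1], "-")^2 +
        outer(coords[, 2], coords[seeds, 2], "-")^2
      max.col(-d2, ties.method = "first")
    })
  labels <- factor(paste0("D", domains), levels = paste0("D", seq_len(spec$n_domains)))

  # gene programs: relative abundances + domain marker boosts
  q <- rgamma(spec$n_genes, shape = 2, rate = 2)
  q <- q / sum(q)
  markers <- matrix(seq_len(spec$n_markers_per_domain * spec$n_domains),
                    nrow = spec$n_markers_per_domain)
  boost <- matrix(1, spec$n_domains, spec$n_genes)
  for (d in seq_len(spec$n_domains))
    boost[d, markers[, d]] <- exp(spec$marker_log_fc)

  depth_factor <- rlnorm(n, meanlog = -0.3^2 / 2, sdlog = 0.3)
  mu <- (depth_factor * spec$depth_mean) * (boost[domains, , drop = FALSE] *
                                              rep(q, each = n))
  counts <- matrix(rnbinom(n * spec$n_genes, mu = mu,
                           size = 1 / spec$nb_dispersion),
                   n, spec$n_genes)
  colnames(counts) <- sprintf("gene-%d", seq_len(spec$n_genes))

  # histology raster: one 16 px block per spot, tinted by domain colour.
  # marker_log_fc is the single domain effect-size knob: the colour contrast
  # between domains scales with it (full palette at the reference effect of
  # 1.5), so a null slide (marker_log_fc = 0) carries no domain signal in
  # any modality.
  ppu <- 16L
  img <- array(0, c(rows * ppu, cols * ppu, 3L))
  tint <- min(1, spec$marker_log_fc / 1.5)
  pal <- 150 + (domain_palette(spec$n_domains) - 150) * tint
  for (i in seq_len(n)) {
    r0 <- (grid$row[i] - 1L) * ppu
    c0 <- (grid$col[i] - 1L) * ppu
    block <- array(rep(pal[domains[i], ], each = ppu * ppu), c(ppu, ppu, 3L))
    img[(r0 + 1L):(r0 + ppu), (c0 + 1L):(c0 + ppu), ] <- block
  }
  img <- img + array(rnorm(length(img), 0, spec$image_noise_sd), dim(img))
  img <- pmin(pmax(img, 0), 255)
  pixel_coords <- cbind(row = (grid$row - 0.5) * ppu, col = (grid$col - 0.5) * ppu)

  spatial_dataset(counts = counts, coords = coords,
                  spot_ids = sprintf("SYN-%04d", seq_len(n)),
                  image = img, pixel_coords = pixel_coords,
                  spot_diameter_px = ppu - 2, labels = labels)
}
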