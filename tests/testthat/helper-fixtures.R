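# Shared fixtures and independent oracles. Everything here is deliberately
# naive (brute force / direct series summation) so the tests compare the
# package against an implementation-independent route.

# brute-force KNN neighbour sets (ties by smaller index), no symmetrization
brute_knn <- function(coords, k) {
  n <- nrow(coords)
  lapply(seq_len(n), function(i) {
    d <- sqrt(rowSums(sweep(coords, 2L, coords[i, ])^2))
    d[i] <- Inf
    order(d)[seq_len(k)]
  })
}

# random symmetric 0/1 adjacency with no isolated guarantee
random_adjacency <- function(n, p = 0.2) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up] <- rbinom(length(up), 1L, p)
  A + t(A)
}

# direct truncated series for the matrix exponential exp(X), k = 0..k_max
series_expm <- function(X, k_max = 30L) {
  n <- nrow(X)
  acc <- diag(n)
  term <- diag(n)
  for (k in seq_len(k_max)) {
    term <- term %*% X / k
    acc <- acc + term
  }
  acc
}

# small dataset with an image, used across the I/O tests
make_tiny_ds <- function(n_side = 3L, n_genes = 8L, seed = 42L) {
  set.seed(seed)
  n <- n_side^2
  counts <- matrix(rpois(n * n_genes, 5), n, n_genes)
  grid <- expand.grid(row = seq_len(n_side), col = seq_len(n_side))
  img <- array(runif(40 * 40 * 3, 0, 255), c(40, 40, 3))
  spatial_dataset(
    counts = counts,
    coords = cbind(grid$col * 10, grid$row * 10),
    spot_ids = sprintf("BC-%02d", seq_len(n)),
    image = img,
    pixel_coords = cbind(grid$row * 10, grid$col * 10),
    spot_diameter_px = 8,
    labels = rep(c("a", "b", "c"), length.out = n))
}

# fast, tiny training configuration for model-level tests
fit_tiny <- function(ds, epochs = 15L, seed = 1L, ...) {
  sducl(ds, epochs = epochs, seed = seed, hidden = 32L, embed = 8L,
        n_sub = 5L, d_s = 8L, ...)
}

expect_error_class <- function(expr, class) {
  expect_error(expr, class = class)
}
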