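test_that("gene preprocessing normalizes, selects HVGs and z-scores", {
  # constant counts: zero variance everywhere -> all-zero features
  ds <- spatial_dataset(matrix(5, 4, 3), cbind(1:4, 1:4))
  expect_true(all(preprocess_genes(ds) == 0))

  # n_hvg >= N_gene keeps all genes
  set.seed(2)
  ds <- spatial_dataset(matrix(rpois(40, 6), 5, 8), cbind(1:5, 1:5))
  expect_equal(ncol(preprocess_genes(ds, n_hvg = 100)), 8L)

  # HVG set equals brute-force top-variance genes on the same normalized data
  counts <- matrix(rpois(24, 10), 6, 4)
  counts[, 2] <- counts[, 2] * c(1, 8, 1, 8, 1, 8)      # one clearly variable gene
  ds <- spatial_dataset(counts, cbind(1:6, 1:6))
  eg <- preprocess_genes(ds, n_hvg = 2)
  depth <- rowSums(counts)
  x <- log1p(counts / (depth / median(depth)))
  top2 <- sort(order(apply(x, 2, var), decreasing = TRUE)[1:2])
  expect_equal(colnames(eg), sprintf("gene-%d", top2))

  # zero-depth spot warns and stays a zero vector pre-scaling
  counts0 <- rbind(c(0, 0, 0), matrix(rpois(9, 5), 3, 3))
  ds0 <- spatial_dataset(counts0, cbind(1:4, 1:4))
  expect_warning(preprocess_genes(ds0), "zero total counts")
})

test_that("patchstats image features are deterministic and shape-correct", {
  set.seed(9)
  patches <- array(runif(5 * 8 * 8 * 3, 0, 255), c(5, 8, 8, 3))
  f1 <- extract_image_features(patches)
  f2 <- extract_image_features(patches)
  expect_identical(f1, f2)
  expect_equal(dim(f1), c(5L, 30L))

  # identical patches give identical rows
  patches[2, , , ] <- patches[1, , , ]
  f <- extract_image_features(patches)
  expect_equal(f[1, ], f[2, ])

  # all-black vs all-white: means differ, within-patch variances are zero
  bw <- array(0, c(2, 4, 4, 3))
  bw[2, , , ] <- 255
  raw <- sducl:::patchstats_features(bw)
  expect_equal(raw[, "R_mean"], c(0, 1))
  expect_equal(raw[, "R_var"], c(0, 0))

  expect_error(extract_image_features(patches, backbone = "resnet51"),
               class = "sducl_parameter_error")

  # pluggable backbone: any function patches -> matrix works
  fn <- function(p) cbind(apply(p, 1, mean), apply(p, 1, max))
  expect_equal(dim(extract_image_features(patches, backbone = fn)), c(5L, 2L))
})

test_that("Katz matrix matches the geometric closed form on a single edge", {
  A <- rbind(c(0, 1), c(1, 0))
  km <- katz_matrix(A, beta = 0.5)
  # paths alternate: K12 = b + b^3 + ... = b/(1-b^2) = 2/3; K11 = b^2/(1-b^2) = 1/3
  expect_equal(km$K, rbind(c(1 / 3, 2 / 3), c(2 / 3, 1 / 3)), tolerance = 1e-12)
  expect_equal(katz_matrix(matrix(0, 3, 3), beta = 0.3)$K, matrix(0, 3, 3))
  expect_error(katz_matrix(A, beta = -1), class = "sducl_parameter_error")
})

test_that("truncated Katz series converges to the closed form", {
  # path graph P4
  A <- matrix(0, 4, 4)
  A[cbind(1:3, 2:4)] <- 1
  A <- A + t(A)
  closed <- katz_matrix(A, beta = 0.1)$K
  trunc <- katz_matrix(A, beta = 0.1, l_max = 8)$K
  expect_lt(max(abs(closed - trunc)), 1e-6)
  # oracle route: direct inverse
  expect_equal(closed, solve(diag(4) - 0.1 * A) - diag(4), tolerance = 1e-12)
})

test_that("beta at or above 1/rho(A) is shrunk with a warning", {
  A <- 1 - diag(4)           # rho = 3
  expect_warning(km <- katz_matrix(A, beta = 0.5), "shrunk")
  expect_equal(km$beta, 0.9 / 3)
  expect_true(all(is.finite(km$K)))
})

test_that("adding an edge never decreases any Katz entry", {
  set.seed(13)
  for (rep in 1:5) {
    A <- random_adjacency(8, 0.25)
    zeros <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
    if (nrow(zeros) == 0) next
    e <- zeros[sample.int(nrow(zeros), 1), ]
    A2 <- A
    A2[e[1], e[2]] <- A2[e[2], e[1]] <- 1
    beta <- 0.5 / max(abs(eigen(A2, symmetric = TRUE, only.values = TRUE)$values))
    K1 <- katz_matrix(A, beta = beta)$K
    K2 <- katz_matrix(A2, beta = beta)$K
    expect_gte(min(K2 - K1), -1e-10)
  }
})

test_that("Katz topology features have fixed width and capture structure", {
  g <- build_knn_graph(as.matrix(expand.grid(1:5, 1:5)), k = 4)
  kf <- katz_features(g, d_s = 8)
  expect_equal(dim(kf$Es), c(25L, 8L))
  # reconstruction from d_s = N singular vectors is exact
  kf_full <- katz_features(g, d_s = 25)
  sv <- svd(kf$katz$K)
  expect_equal(abs(kf_full$Es), abs(sv$u %*% diag(sv$d)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("fusion concatenates standardized blocks and records slices", {
  set.seed(4)
  Eg <- matrix(rnorm(50), 10, 5)
  Ei <- matrix(rnorm(30) * 100, 10, 3)
  Es <- matrix(rnorm(20) + 7, 10, 2)
  af <- fuse_features(Eg, Ei, Es)
  expect_equal(ncol(af$F), 10L)
  expect_equal(unname(af$dims), c(5L, 3L, 2L))
  # every column standardized regardless of original scale
  expect_equal(unname(colMeans(af$F)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(af$F, 2, sd)), rep(1, 10), tolerance = 1e-12)
  # slices reconstruct the standardized blocks exactly
  expect_equal(af$F[, af$block_slices$Ei],
               unname(sducl:::standardize_columns(Ei)), ignore_attr = TRUE)

  # single-block fusion is the identity up to standardization
  af1 <- fuse_features(Eg)
  expect_equal(names(af1$dims), "Eg")
  expect_equal(af1$F, sducl:::standardize_columns(Eg), ignore_attr = TRUE)

  expect_error(fuse_features(Eg, Ei[1:5, ]), class = "sducl_alignment_error")
})

test_that("permuting spots permutes all fused feature rows identically", {
  set.seed(8)
  Eg <- matrix(rnorm(40), 8, 5)
  Es <- matrix(rnorm(24), 8, 3)
  perm <- sample.int(8)
  a <- fuse_features(Eg, Es = Es)$F
  b <- fuse_features(Eg[perm, ], Es = Es[perm, ])$F
  expect_equal(b, a[perm, ], ignore_attr = TRUE)
})
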