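test_that("gcn layer applies normalized aggregation, weights and activation", {
  # single isolated node: A_hat_norm = [1]
  out <- gcn_layer(matrix(c(2, -3), 1), matrix(1, 1, 1), diag(2), c(0, 0))
  expect_equal(out, matrix(c(2, 0), 1))
  # equal input rows on a symmetric two-node graph stay equal
  A2n <- normalized_adjacency(rbind(c(0, 1), c(1, 0)))
  H <- rbind(c(1, 2), c(1, 2))
  W <- matrix(rnorm(4), 2)
  out <- gcn_layer(H, A2n, W, c(0.5, -0.5))
  expect_equal(out[1, ], out[2, ])
  # zero weights and bias give zero output
  expect_true(all(gcn_layer(H, A2n, matrix(0, 2, 2), c(0, 0)) == 0))
  expect_error(gcn_layer(H, A2n, matrix(0, 3, 2), c(0, 0)),
               class = "sducl_alignment_error")
})

test_that("corruption permutes rows, preserves the multiset and is seeded", {
  set.seed(99)
  Fm <- matrix(rnorm(50), 10, 5)
  set.seed(1); c1 <- corrupt_features(Fm)
  set.seed(1); c2 <- corrupt_features(Fm)
  expect_identical(c1$perm, c2$perm)
  expect_equal(c1$F_prime, Fm[c1$perm, ])
  # undoing the permutation recovers the original rows exactly
  expect_equal(c1$F_prime[order(c1$perm), ], Fm)
  # N = 1 is the identity
  expect_equal(corrupt_features(Fm[1, , drop = FALSE])$F_prime,
               Fm[1, , drop = FALSE])
})

test_that("readout averages microenvironment members through a sigmoid", {
  g <- graph_from_adjacency(1 - diag(4))
  me <- discover_microenvironments(g, n_sub = 4)
  h <- c(1, -2, 0.5)
  H <- matrix(rep(h, each = 4), 4)
  S <- readout(H, me)
  expect_equal(unname(S), matrix(rep(1 / (1 + exp(-h)), each = 4), 4))
  # H = 0 -> all entries sigmoid(0) = 0.5
  expect_true(all(readout(matrix(0, 4, 3), me) == 0.5))
  # singleton microenvironments: S[i] = sigmoid(H[i])
  me1 <- discover_microenvironments(g, n_sub = 1)
  H <- matrix(rnorm(12), 4)
  expect_equal(unname(readout(H, me1)), 1 / (1 + exp(-H)))
})

test_that("bilinear discriminator matches closed forms", {
  expect_equal(discriminate(rnorm(4), rnorm(4), matrix(0, 4, 4)), 0.5)
  e1 <- c(1, 0, 0)
  expect_equal(discriminate(e1, e1, diag(3)), 1 / (1 + exp(-1)))
  # transpose identity: D(h, s; W) = D(s, h; W')
  h <- rnorm(5); s <- rnorm(5); W <- matrix(rnorm(25), 5)
  expect_equal(discriminate(h, s, W), discriminate(s, h, t(W)))
  # logits mode exposes the pre-sigmoid bilinear form
  expect_equal(discriminate(h, s, W, logits = TRUE),
               as.numeric(t(h) %*% W %*% s))
})

test_that("contrastive loss equals log 2 at a zero discriminator", {
  set.seed(6)
  H <- matrix(rnorm(40), 8); Hp <- matrix(rnorm(40), 8)
  S <- matrix(runif(40), 8); Sp <- matrix(runif(40), 8)
  l <- contrastive_loss(H, Hp, S, Sp, matrix(0, 5, 5))
  expect_equal(l$L_con, log(2), tolerance = 1e-12)
  expect_equal(l$L_con_sym, log(2), tolerance = 1e-12)

  # perfect discrimination drives the loss to zero
  Wbig <- diag(5) * 50
  lp <- contrastive_loss(S * 10, -S * 10, S, -S, Wbig)
  expect_lt(lp$L_con, 1e-3)

  # gradient at W = 0 vanishes when H = H' (positives = negatives)
  g0 <- sducl:::contrastive_grad_wdisc(H, H, S, Sp, matrix(0, 5, 5))
  expect_equal(max(abs(g0)), 0)
})

test_that("analytic discriminator gradient matches finite differences", {
  set.seed(12)
  n <- 5; d <- 4
  H <- matrix(rnorm(n * d), n); Hp <- matrix(rnorm(n * d), n)
  S <- matrix(runif(n * d), n); Sp <- matrix(runif(n * d), n)
  W <- matrix(rnorm(d * d, sd = 0.3), d)
  g <- sducl:::contrastive_grad_wdisc(H, Hp, S, Sp, W)
  loss_at <- function(W) {
    l <- contrastive_loss(H, Hp, S, Sp, W)
    l$L_con + l$L_con_sym
  }
  eps <- 1e-6
  g_num <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in seq_len(d)) {
    Wp <- W; Wp[i, j] <- W[i, j] + eps
    Wm <- W; Wm[i, j] <- W[i, j] - eps
    g_num[i, j] <- (loss_at(Wp) - loss_at(Wm)) / (2 * eps)
  }
  expect_lt(max(abs(g - g_num)), 1e-4)
})

test_that("reconstruction loss is quadratic with the documented reductions", {
  Fm <- rbind(c(1, 0))
  expect_equal(reconstruction_loss(Fm, Fm), 0)
  expect_equal(reconstruction_loss(Fm, rbind(c(0, 0))), 1)
  Fm <- matrix(rnorm(20), 5)
  X <- matrix(rnorm(20), 5)
  l1 <- reconstruction_loss(Fm, X)
  expect_equal(reconstruction_loss(Fm, Fm + 2 * (X - Fm)), 4 * l1)
  expect_equal(reconstruction_loss(Fm, X, reduction = "sum"), 5 * l1)
})

test_that("training runs, losses stay finite and reconstruction improves", {
  ds <- generate_synthetic(synthetic_spec(grid_shape = c(5, 8), n_genes = 60,
                                          n_markers_per_domain = 10, seed = 3))
  fit <- fit_tiny(ds, epochs = 60, seed = 3)
  expect_true(all(is.finite(as.matrix(fit$losses[, -1]))))
  expect_lt(fit$losses$L_rec[60], fit$losses$L_rec[1])
  expect_equal(dim(fit$H), c(40L, 8L))
  expect_equal(rownames(fit$H), ds$spot_ids)
  # summaries live in (0, 1)
  expect_true(all(fit$S > 0 & fit$S < 1))
})

test_that("loss-weight switches express the model variants", {
  ds <- generate_synthetic(synthetic_spec(grid_shape = c(4, 6), n_genes = 40,
                                          n_markers_per_domain = 8, seed = 5))
  # contrastive-only and reconstruction-only both train
  f_rec <- fit_tiny(ds, epochs = 5, beta_con = 0)
  f_con <- fit_tiny(ds, epochs = 5, alpha_rec = 0)
  expect_true(all(is.finite(f_rec$losses$L)))
  expect_true(all(is.finite(f_con$losses$L)))
  expect_error(fit_tiny(ds, alpha_rec = 0, beta_con = 0),
               class = "sducl_parameter_error")
  # whole-graph readout (n_sub = N): all summary rows identical
  f_dgi <- fit_tiny(ds, epochs = 5, use_signal = FALSE)
  expect_equal(f_dgi$S, f_dgi$S[rep(1, nrow(f_dgi$S)), ], ignore_attr = TRUE)
  # image-free / topology-free ablations shrink the feature blocks
  f_noimg <- fit_tiny(ds, epochs = 2, use_image = FALSE)
  expect_false("Ei" %in% names(f_noimg$features$dims))
  f_eg <- fit_tiny(ds, epochs = 2, use_fusion = FALSE)
  expect_equal(names(f_eg$features$dims), "Eg")
})

test_that("encoder forward pass is permutation-equivariant", {
  set.seed(44)
  n <- 12
  Fm <- matrix(rnorm(n * 6), n)
  g <- build_knn_graph(matrix(runif(n * 2), n), k = 3)
  p <- sducl:::init_params(6, 10, 4)
  H <- sducl:::encoder_forward(Fm, g$A_hat_norm, p)$H
  perm <- sample.int(n)
  A_perm <- g$A[perm, perm]
  Hp <- sducl:::encoder_forward(Fm[perm, ], normalized_adjacency(A_perm), p)$H
  expect_equal(Hp, H[perm, ], tolerance = 1e-12)
})

test_that("fits are bit-reproducible under the same seed", {
  ds <- generate_synthetic(synthetic_spec(grid_shape = c(4, 6), n_genes = 40,
                                          n_markers_per_domain = 8, seed = 7))
  f1 <- fit_tiny(ds, epochs = 10, seed = 123)
  f2 <- fit_tiny(ds, epochs = 10, seed = 123)
  expect_identical(f1$H, f2$H)
  expect_identical(f1$losses, f2$losses)
  f3 <- fit_tiny(ds, epochs = 10, seed = 124)
  expect_false(identical(f1$H, f3$H))
})
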