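# GCN autoencoder + microenvironment-contrastive objective, trained
# full-batch with hand-written backpropagation and Adam. All randomness
# (weight init, per-epoch corruption permutation) is drawn from R's RNG so a
# single set.seed() makes a run reproducible.

sigmoid <- function(x) 1 / (1 + exp(-x))
# log(1 + exp(x)) without overflow
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
relu <- function(x) pmax(x, 0)

#' One graph-convolution layer
#'
#' `H_out = act(A_hat_norm %*% H_in %*% W + b)` — the layer aggregates each
#' node's neighbourhood (including itself, via the self-loop in the
#' normalized adjacency) and applies a linear map plus activation.
#'
#' @param H_in N x d_in input features.
#' @param A_hat_norm self-loop normalized adjacency from
#'   [normalized_adjacency()].
#' @param W d_in x d_out weight matrix.
#' @param b length-d_out bias vector.
#' @param activation `"relu"` or `"linear"`.
#' @return N x d_out matrix.
#' @export
gcn_layer <- function(H_in, A_hat_norm, W, b, activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  H_in <- as.matrix(H_in)
  if (ncol(H_in) != nrow(W))
    stop_sducl("gcn_layer: feature width does not match weight matrix", "sducl_alignment_error")
  Z <- A_hat_norm %*% H_in %*% W
  Z <- sweep(Z, 2L, b, "+")
  if (activation == "relu") relu(Z) else Z
}

#' Corrupt features by row shuffling
#'
#' The corruption step of the contrastive objective: the feature vectors are
#' permuted across spots while the graph topology is left untouched, so every
#' node keeps its neighbourhood but receives another node's features. The
#' permutation is drawn from the current RNG state.
#'
#' @param F_mat N x d feature matrix.
#' @return list with `F_prime` (the shuffled matrix) and `perm` (the
#'   permutation used).
#' @export
corrupt_features <- function(F_mat) {
  n <- nrow(F_mat)
  perm <- if (n > 1L) sample.int(n) else 1L
  list(F_prime = F_mat[perm, , drop = FALSE], perm = perm)
}

#' Microenvironment readout
#'
#' Aggregates each node's microenvironment into a global summary vector:
#' `S[i] = sigmoid(mean of H rows over members(i))`. The logistic squashing
#' keeps summaries in (0, 1), as in the Deep-Graph-Infomax readout this
#' generalizes; with `n_sub = N` every microenvironment is the whole graph
#' and all rows of `S` coincide (the plain DGI readout).
#'
#' @param H N x d embedding matrix.
#' @param me a `microenvironment_map` (or a precomputed membership matrix).
#' @return N x d matrix of summaries with entries in (0, 1).
#' @export
readout <- function(H, me) {
  M <- if (inherits(me, "microenvironment_map")) membership_matrix(me) else me
  sigmoid(M %*% H)
}

#' Bilinear discriminator score
#'
#' Scores a (local embedding, microenvironment summary) pair with the
#' logistic of a bilinear form: `D(h, s) = sigmoid(h' W s)`.
#'
#' @param h embedding vector or N x d matrix (rows scored against matching
#'   rows of `s`).
#' @param s summary vector or N x d matrix.
#' @param W_disc d x d bilinear weight matrix.
#' @param logits return the pre-sigmoid bilinear form instead of the
#'   probability (numerically safer for loss computation).
#' @return numeric vector of scores in (0, 1) (or logits).
#' @export
discriminate <- function(h, s, W_disc, logits = FALSE) {
  h <- unname(rbind(h)); s <- unname(rbind(s))
  z <- rowSums((h %*% W_disc) * s)
  if (logits) z else sigmoid(z)
}

#' Symmetric contrastive loss
#'
#' Binary cross-entropy over (embedding, summary) pairs. The forward term
#' treats `(H[i], S[i])` as positive and `(H_prime[i], S[i])` as negative;
#' the mirrored term swaps the roles of the original and corrupted branches,
#' with positives `(H_prime[i], S_prime[i])` and negatives
#' `(H[i], S_prime[i])`. Both are computed in the logit-stable form; with a
#' zero discriminator every score is 1/2 and each term equals `log(2)`.
#'
#' @param H,H_prime N x d embeddings of the original and corrupted branches.
#' @param S,S_prime N x d microenvironment summaries of the two branches.
#' @param W_disc d x d bilinear discriminator matrix.
#' @return list with `L_con` (forward term), `L_con_sym` (mirrored term).
#' @export
contrastive_loss <- function(H, H_prime, S, S_prime, W_disc) {
  stopifnot(all(dim(H) == dim(H_prime)), all(dim(H) == dim(S)))
  if (!all(is.finite(H)) || !all(is.finite(H_prime)))
    stop_sducl("non-finite embeddings in contrastive loss", "sducl_numeric_error")
  HW <- H %*% W_disc
  HpW <- H_prime %*% W_disc
  pos1 <- rowSums(HW * S);  neg1 <- rowSums(HpW * S)
  pos2 <- rowSums(HpW * S_prime); neg2 <- rowSums(HW * S_prime)
  list(L_con = mean(softplus(-pos1) + softplus(neg1)) / 2,
       L_con_sym = mean(softplus(-pos2) + softplus(neg2)) / 2)
}

# Gradient of L_con + L_con_sym w.r.t. W_disc (embeddings and summaries held
# fixed); used by the finite-difference gradient check.
contrastive_grad_wdisc <- function(H, H_prime, S, S_prime, W_disc) {
  n <- nrow(H)
  HW <- H %*% W_disc
  HpW <- H_prime %*% W_disc
  g_pos1 <- -sigmoid(-rowSums(HW * S)) / (2 * n)
  g_neg1 <- sigmoid(rowSums(HpW * S)) / (2 * n)
  g_pos2 <- -sigmoid(-rowSums(HpW * S_prime)) / (2 * n)
  g_neg2 <- sigmoid(rowSums(HW * S_prime)) / (2 * n)
  crossprod(H, g_pos1 * S) + crossprod(H_prime, g_neg1 * S) +
    crossprod(H_prime, g_pos2 * S_prime) + crossprod(H, g_neg2 * S_prime)
}

#' Reconstruction loss
#'
#' Squared Euclidean distance between input and reconstructed features,
#' summed over feature dimensions. `reduction = "mean"` (default) averages
#' over spots so the loss scale does not grow with N; `"sum"` is the plain
#' summed form.
#'
#' @param F_mat original feature matrix.
#' @param X_rec reconstructed feature matrix.
#' @param reduction `"mean"` or `"sum"` over spots.
#' @export
reconstruction_loss <- function(F_mat, X_rec, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  sq <- sum((F_mat - X_rec)^2)
  if (reduction == "mean") sq / nrow(F_mat) else sq
}

# ---- parameter initialization and Adam ------------------------------------

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

init_params <- function(d, hidden, embed) {
  list(W1 = glorot(d, hidden),     b1 = numeric(hidden),
       W2 = glorot(hidden, embed), b2 = numeric(embed),
       W3 = glorot(embed, hidden), b3 = numeric(hidden),
       W4 = glorot(hidden, d),     b4 = numeric(d),
       Wd = glorot(embed, embed))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (weight_decay > 0 && grepl("^W", nm)) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    m_hat <- state$m[[nm]] / (1 - beta1^state$t)
    v_hat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * m_hat / (sqrt(v_hat) + eps)
  }
  list(params = params, state = state)
}

# ---- forward / backward ----------------------------------------------------

encoder_forward <- function(Fm, A, p) {
  Z1 <- sweep(A %*% Fm %*% p$W1, 2L, p$b1, "+"); H1 <- relu(Z1)
  Z2 <- sweep(A %*% H1 %*% p$W2, 2L, p$b2, "+"); H <- relu(Z2)
  list(Z1 = Z1, H1 = H1, Z2 = Z2, H = H)
}

decoder_forward <- function(H, A, p) {
  Z3 <- sweep(A %*% H %*% p$W3, 2L, p$b3, "+"); D1 <- relu(Z3)
  X <- sweep(A %*% D1 %*% p$W4, 2L, p$b4, "+")   # final layer linear
  list(Z3 = Z3, D1 = D1, X = X)
}

# Backprop through one encoder; returns weight grads and nothing else (input
# features are constants). dH is the upstream gradient at the embedding.
encoder_backward <- function(dH, fw, Fm, A, p) {
  dZ2 <- dH * (fw$Z2 > 0)
  AdZ2 <- A %*% dZ2
  dW2 <- crossprod(fw$H1, AdZ2); db2 <- colSums(dZ2)
  dH1 <- AdZ2 %*% t(p$W2)
  dZ1 <- dH1 * (fw$Z1 > 0)
  AdZ1 <- A %*% dZ1
  dW1 <- crossprod(Fm, AdZ1); db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

#' Train the signal-diffusion contrastive model
#'
#' Low-level training loop on prepared inputs; most users should call
#' [sducl()] instead. Each epoch: draw a fresh corruption permutation,
#' encode the original and corrupted features on the same topology, read out
#' per-node microenvironment summaries for both branches (memberships come
#' from the original topology, which corruption does not alter), decode the
#' original embedding, and take one Adam step on
#' `alpha_rec * L_rec + beta_con * (L_con + L_con')`.
#'
#' @param F_mat N x d fused feature matrix.
#' @param A_hat_norm normalized adjacency of the spatial graph.
#' @param me `microenvironment_map` for the readout.
#' @param epochs number of full-batch epochs (default 500).
#' @param lr Adam learning rate (default 1e-3).
#' @param weight_decay L2 penalty coefficient on weight matrices (default 1e-4).
#' @param alpha_rec,beta_con loss weights (defaults 1 and 1); setting one to
#'   zero yields the reconstruction-only / contrastive-only model variants.
#' @param hidden,embed layer widths of the encoder d -> hidden -> embed
#'   (defaults 512 and 64); the decoder mirrors them.
#' @param reduction reconstruction-loss reduction, `"mean"` or `"sum"`.
#' @param verbose print the loss every 100 epochs.
#' @return list with `params` (trained weights incl. the discriminator
#'   `Wd`), `H` (final N x embed embeddings), `S` (final summaries), `X_rec`
#'   (final reconstruction) and `losses` (per-epoch data.frame with columns
#'   `epoch, L_rec, L_con, L_con_sym, L`).
#' @export
train_sducl <- function(F_mat, A_hat_norm, me, epochs = 500L, lr = 1e-3,
                        weight_decay = 1e-4, alpha_rec = 1, beta_con = 1,
                        hidden = 512L, embed = 64L,
                        reduction = c("mean", "sum"), verbose = FALSE) {
  reduction <- match.arg(reduction)
  if (alpha_rec == 0 && beta_con == 0)
    stop_sducl("alpha_rec and beta_con cannot both be zero: no training signal",
               "sducl_parameter_error")
  Fm <- as.matrix(F_mat)
  n <- nrow(Fm); d <- ncol(Fm)
  A <- as.matrix(A_hat_norm)
  M <- membership_matrix(me)
  tM <- t(M)
  p <- init_params(d, hidden, embed)
  opt <- adam_init(p)
  losses <- data.frame(epoch = seq_len(epochs), L_rec = NA_real_,
                       L_con = NA_real_, L_con_sym = NA_real_, L = NA_real_)
  fw <- NULL; S <- NULL; dec <- NULL

  for (ep in seq_len(epochs)) {
    cor <- corrupt_features(Fm)
    Fp <- cor$F_prime
    fw <- encoder_forward(Fm, A, p)
    fwp <- encoder_forward(Fp, A, p)
    H <- fw$H; Hp <- fwp$H
    ZS <- M %*% H; S <- sigmoid(ZS)
    ZSp <- M %*% Hp; Sp <- sigmoid(ZSp)
    dec <- decoder_forward(H, A, p)

    HW <- H %*% p$Wd
    HpW <- Hp %*% p$Wd
    pos1 <- rowSums(HW * S);   neg1 <- rowSums(HpW * S)
    pos2 <- rowSums(HpW * Sp); neg2 <- rowSums(HW * Sp)
    L_con <- mean(softplus(-pos1) + softplus(neg1)) / 2
    L_con_sym <- mean(softplus(-pos2) + softplus(neg2)) / 2
    L_rec <- reconstruction_loss(Fm, dec$X, reduction)
    L_tot <- alpha_rec * L_rec + beta_con * (L_con + L_con_sym)
    losses[ep, 2:5] <- c(L_rec, L_con, L_con_sym, L_tot)
    if (!is.finite(L_tot)) {
      bad <- c(L_rec = L_rec, L_con = L_con, L_con_sym = L_con_sym)
      stop_sducl(sprintf("non-finite loss at epoch %d (%s diverged)", ep,
                         paste(names(bad)[!is.finite(bad)], collapse = ", ")),
                 "sducl_numeric_error")
    }
    if (verbose && (ep == 1L || ep %% 100L == 0L))
      message(sprintf("epoch %4d  L_rec %.4f  L_con %.4f  L_con' %.4f  L %.4f",
                      ep, L_rec, L_con, L_con_sym, L_tot))

    # ---- backward ----
    g_pos1 <- beta_con * -sigmoid(-pos1) / (2 * n)
    g_neg1 <- beta_con * sigmoid(neg1) / (2 * n)
    g_pos2 <- beta_con * -sigmoid(-pos2) / (2 * n)
    g_neg2 <- beta_con * sigmoid(neg2) / (2 * n)

    dWd <- crossprod(H, g_pos1 * S) + crossprod(Hp, g_neg1 * S) +
      crossprod(Hp, g_pos2 * Sp) + crossprod(H, g_neg2 * Sp)
    dH <- (g_pos1 * S + g_neg2 * Sp) %*% t(p$Wd)
    dHp <- (g_neg1 * S + g_pos2 * Sp) %*% t(p$Wd)
    dS <- (g_pos1 * H + g_neg1 * Hp) %*% p$Wd
    dSp <- (g_pos2 * Hp + g_neg2 * H) %*% p$Wd
    dH <- dH + tM %*% (dS * S * (1 - S))
    dHp <- dHp + tM %*% (dSp * Sp * (1 - Sp))

    # reconstruction path (original branch only)
    scale_rec <- if (reduction == "mean") 1 / n else 1
    dX <- alpha_rec * 2 * (dec$X - Fm) * scale_rec
    AdX <- A %*% dX
    dW4 <- crossprod(dec$D1, AdX); db4 <- colSums(dX)
    dD1 <- AdX %*% t(p$W4)
    dZ3 <- dD1 * (dec$Z3 > 0)
    AdZ3 <- A %*% dZ3
    dW3 <- crossprod(H, AdZ3); db3 <- colSums(dZ3)
    dH <- dH + AdZ3 %*% t(p$W3)

    g_enc <- encoder_backward(dH, fw, Fm, A, p)
    g_encp <- encoder_backward(dHp, fwp, Fp, A, p)
    grads <- list(W1 = g_enc$W1 + g_encp$W1, b1 = g_enc$b1 + g_encp$b1,
                  W2 = g_enc$W2 + g_encp$W2, b2 = g_enc$b2 + g_encp$b2,
                  W3 = dW3, b3 = db3, W4 = dW4, b4 = db4, Wd = dWd)
    st <- adam_step(p, grads, opt, lr, weight_decay)
    p <- st$params; opt <- st$state
    if (!all(vapply(p, function(w) all(is.finite(w)), logical(1))))
      stop_sducl(sprintf("non-finite weights after epoch %d", ep),
                 "sducl_numeric_error")
  }

  # final forward pass with the trained weights (no corruption needed)
  fw <- encoder_forward(Fm, A, p)
  dec <- decoder_forward(fw$H, A, p)
  S <- sigmoid(M %*% fw$H)
  rownames(fw$H) <- rownames(Fm)
  list(params = p, H = fw$H, S = S, X_rec = dec$X, losses = losses)
}
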