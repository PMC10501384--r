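# Gated local-global fusion: convex mixing weights computed from a local
# (1-D convolutional) and a global (average-pooled) view of the summed
# embeddings. Two stages: branch fusion (similarity vs structure), then
# fusion with the raw 3-mer representation.

BN_EPS <- 1e-8

# 1-D convolution along rows, kernel size 3, zero padding, one channel.
conv_rows <- function(X, w, b) {
  d <- ncol(X)
  Xm1 <- if (d > 1) cbind(0, X[, -d, drop = FALSE]) else 0 * X
  Xp1 <- if (d > 1) cbind(X[, -1, drop = FALSE], 0) else 0 * X
  w[1] * Xm1 + w[2] * X + w[3] * Xp1 + b
}

conv_back_input <- function(dY, w) {
  d <- ncol(dY)
  Dp1 <- if (d > 1) cbind(dY[, -1, drop = FALSE], 0) else 0 * dY
  Dm1 <- if (d > 1) cbind(0, dY[, -d, drop = FALSE]) else 0 * dY
  w[1] * Dp1 + w[2] * dY + w[3] * Dm1
}

conv_back_w <- function(X, dY) {
  d <- ncol(X)
  Xm1 <- if (d > 1) cbind(0, X[, -d, drop = FALSE]) else 0 * X
  Xp1 <- if (d > 1) cbind(X[, -1, drop = FALSE], 0) else 0 * X
  c(sum(Xm1 * dY), sum(X * dY), sum(Xp1 * dY))
}

bn_forward <- function(Y) {
  mu <- colMeans(Y)
  v <- colMeans(sweep(Y, 2L, mu)^2)
  sd <- sqrt(v + BN_EPS)
  Z <- sweep(sweep(Y, 2L, mu), 2L, sd, `/`)
  list(Z = Z, sd = sd)
}

bn_backward <- function(dZ, bn) {
  Z <- bn$Z
  t1 <- sweep(dZ, 2L, colMeans(dZ))
  t2 <- sweep(Z, 2L, colMeans(dZ * Z), `*`)
  sweep(t1 - t2, 2L, bn$sd, `/`)
}

#' Create a local-global fusion block
#'
#' A fusion block holds two shared kernel-3 one-dimensional convolutions:
#' the first (`f'`) is followed by batch standardization and ReLU, the
#' second (`f`) closes each path. The local path convolves the input
#' vector directly; the global path first collapses it by global average
#' pooling, so its output is a per-sample scalar broadcast across
#' positions.
#'
#' @param seed integer seed for the (small random) kernel initialization.
#' @param init `"small"` (default, N(0, 0.1) kernels) or `"zero"`.
#' @return List of class `fusion_block` with kernels `w1`, `w2` and
#'   biases `b1`, `b2`.
#' @export
fusion_block <- function(seed = 1L, init = c("small", "zero")) {
  init <- match.arg(init)
  p <- if (init == "zero") {
    list(w1 = numeric(3), b1 = 0, w2 = numeric(3), b2 = 0)
  } else {
    with_seed(seed, list(w1 = stats::rnorm(3, sd = 0.1), b1 = 0,
                         w2 = stats::rnorm(3, sd = 0.1), b2 = 0))
  }
  structure(p, class = "fusion_block")
}

# Forward through one block on a batch (rows = samples). Returns the
# pre-sigmoid activation (local + broadcast global) and a cache.
block_forward <- function(Ea, blk, cache = FALSE) {
  Ea <- rbind(Ea)
  c1 <- conv_rows(Ea, blk$w1, blk$b1)
  bn1 <- bn_forward(c1)
  r1 <- pmax(bn1$Z, 0)
  lo <- conv_rows(r1, blk$w2, blk$b2)
  ga <- matrix(rowMeans(Ea), ncol = 1L)
  c1g <- conv_rows(ga, blk$w1, blk$b1)
  bng <- bn_forward(c1g)
  r1g <- pmax(bng$Z, 0)
  gl <- conv_rows(r1g, blk$w2, blk$b2)
  act <- sweep(lo, 1L, gl, `+`)
  if (!cache) return(act)
  list(act = act,
       cc = list(Ea = Ea, bn1 = bn1, r1 = r1, ga = ga, bng = bng, r1g = r1g))
}

# Backward through one block: dAct is d(loss)/d(pre-sigmoid activation).
block_backward <- function(dAct, fw, blk) {
  cc <- fw$cc
  d <- ncol(cc$Ea)
  g <- list(w1 = numeric(3), b1 = 0, w2 = numeric(3), b2 = 0)
  # local path
  dr1 <- conv_back_input(dAct, blk$w2)
  g$w2 <- g$w2 + conv_back_w(cc$r1, dAct)
  g$b2 <- g$b2 + sum(dAct)
  dz1 <- dr1 * (cc$bn1$Z > 0)
  dc1 <- bn_backward(dz1, cc$bn1)
  dEa <- conv_back_input(dc1, blk$w1)
  g$w1 <- g$w1 + conv_back_w(cc$Ea, dc1)
  g$b1 <- g$b1 + sum(dc1)
  # global path (per-sample scalar broadcast over positions)
  dgl <- matrix(rowSums(dAct), ncol = 1L)
  dr1g <- conv_back_input(dgl, blk$w2)
  g$w2 <- g$w2 + conv_back_w(cc$r1g, dgl)
  g$b2 <- g$b2 + sum(dgl)
  dz1g <- dr1g * (cc$bng$Z > 0)
  dc1g <- bn_backward(dz1g, cc$bng)
  dga <- conv_back_input(dc1g, blk$w1)
  g$w1 <- g$w1 + conv_back_w(cc$ga, dc1g)
  g$b1 <- g$b1 + sum(dc1g)
  dEa <- dEa + matrix(dga, nrow(dEa), d) / d
  list(grads = g, dEa = dEa)
}

#' Gating weights of a fusion block
#'
#' `w = sigmoid(local(e) + global(e))`; every entry lies strictly in
#' (0, 1). Accepts a single vector or a batch matrix (rows = samples);
#' batch standardization uses the statistics of the batch passed in.
#'
#' @param e_a numeric vector or matrix (the summed embeddings).
#' @param block a [fusion_block()].
#' @return Gating weights with the same shape as `e_a`.
#' @export
fusion_weight <- function(e_a, block) {
  vec <- is.null(dim(e_a))
  if (!all(is.finite(e_a))) stop("non-finite input")
  W <- 1 / (1 + exp(-block_forward(rbind(e_a), block)))
  if (vec) drop(W) else W
}

#' Fuse the two branch embeddings
#'
#' `e_ss = w * e_sm + (1 - w) * e_st`, with the elementwise gate
#' `w = ` [fusion_weight()] of `e_sm + e_st`. The output is an entrywise
#' convex combination of the inputs.
#'
#' @param e_sm,e_st similarity-branch and structure-branch embeddings
#'   (vectors or conformable matrices).
#' @param block a [fusion_block()].
#' @param w optional forced gate (test hook); scalar or conformable.
#' @return Fused embedding of the same shape.
#' @export
fuse_branches <- function(e_sm, e_st, block, w = NULL) {
  if (length(e_sm) != length(e_st)) stop("dimension mismatch")
  if (is.null(w)) w <- fusion_weight(e_sm + e_st, block)
  w * e_sm + (1 - w) * e_st
}

#' Fuse the branch representation with the raw 3-mer representation
#'
#' `e_fi = w' * e_ss + (1 - w') * e_km`, with the gate computed by a
#' second fusion block on `e_ss + e_km`. `e_km` must already be projected
#' to the width of `e_ss` (the default embedding width equals the 64-dim
#' 3-mer encoding, so the projection is the identity).
#'
#' @param e_ss fused branch embedding.
#' @param e_km (projected) 3-mer representation.
#' @param block a [fusion_block()].
#' @param w optional forced gate (test hook).
#' @return Final fused embedding.
#' @export
fuse_with_kmer <- function(e_ss, e_km, block, w = NULL) {
  if (length(e_ss) != length(e_km)) stop("dimension mismatch")
  if (is.null(w)) w <- fusion_weight(e_ss + e_km, block)
  w * e_ss + (1 - w) * e_km
}

#' Initialize the two-stage fusion model
#'
#' @param d_emb branch embedding width.
#' @param d_km raw k-mer width (64 for 3-mers). When it differs from
#'   `d_emb` a learnable linear projection is added.
#' @param seed integer seed.
#' @return List of class `fusion_model` with `block1`, `block2` and an
#'   optional `proj` matrix.
#' @export
fusion_init <- function(d_emb, d_km = 64L, seed = 1L) {
  proj <- if (d_km != d_emb) with_seed(seed + 1L, glorot(d_km, d_emb))
  structure(list(block1 = fusion_block(seed), block2 = fusion_block(seed + 2L),
                 proj = proj, d_emb = d_emb, d_km = d_km),
            class = "fusion_model")
}

project_kmer <- function(E_km, model) {
  if (is.null(model$proj)) E_km else E_km %*% model$proj
}

# Per-feature batch standardization applied to every representation
# entering the fusion stage: the gates mix entrywise, which presumes
# commensurate scales, and the branch embeddings, structure embeddings
# and k-mer frequencies live on very different ones.
fusion_standardize <- function(M) {
  mu <- colMeans(M)
  sd <- sqrt(colMeans(sweep(M, 2L, mu)^2))
  sd[sd < 1e-12] <- 1
  sweep(sweep(M, 2L, mu), 2L, sd, `/`)
}

#' Fused feature matrix under an ablation mode
#'
#' @param e_sm,e_st branch embedding matrices (m rows).
#' @param e_km raw 3-mer frequency matrix (m x 64).
#' @param model a [fusion_model()].
#' @param mode `"full"` (two-stage gated fusion), `"drop-raw"` (structure
#'   branch + k-mer only), `"drop-trans"` (similarity branch + k-mer
#'   only), or `"weighted-only"` (fixed 0.5/0.5 averaging, no blocks).
#' @details All three representations are standardized per feature before
#'   mixing (the gates combine entrywise, which presumes commensurate
#'   scales), in every mode.
#' @return m-row feature matrix fed to the classifier.
#' @export
fused_features <- function(e_sm, e_st, e_km, model,
                           mode = c("full", "drop-raw", "drop-trans",
                                    "weighted-only")) {
  mode <- match.arg(mode)
  e_sm <- fusion_standardize(e_sm)
  e_st <- fusion_standardize(e_st)
  Ekm <- project_kmer(fusion_standardize(e_km), model)
  e_ss <- switch(mode,
    "full" = fuse_branches(e_sm, e_st, model$block1),
    "drop-raw" = e_st,
    "drop-trans" = e_sm,
    "weighted-only" = 0.5 * e_sm + 0.5 * e_st)
  out <- if (mode == "weighted-only") {
    0.5 * e_ss + 0.5 * Ekm
  } else {
    fuse_with_kmer(e_ss, Ekm, model$block2)
  }
  rownames(out) <- rownames(e_km)
  out
}

# Forward + full backward of the auxiliary reconstruction objective
# BCE(sigmoid(E_fi E_fi^T), S_target). Returns loss and parameter grads.
fusion_aux_grads <- function(model, e_sm, e_st, e_km, S_target) {
  m <- nrow(e_sm)
  e_sm <- fusion_standardize(e_sm)
  e_st <- fusion_standardize(e_st)
  e_km_z <- fusion_standardize(e_km)
  Ekm <- project_kmer(e_km_z, model)
  fw1 <- block_forward(e_sm + e_st, model$block1, cache = TRUE)
  W1 <- 1 / (1 + exp(-fw1$act))
  E_ss <- W1 * e_sm + (1 - W1) * e_st
  Eb <- E_ss + Ekm
  fw2 <- block_forward(Eb, model$block2, cache = TRUE)
  W2 <- 1 / (1 + exp(-fw2$act))
  E_fi <- W2 * E_ss + (1 - W2) * Ekm
  logits <- tcrossprod(E_fi)
  loss <- bce_from_logits(logits, S_target)
  dlogits <- (1 / (1 + exp(-logits)) - S_target) / length(logits)
  dE_fi <- (dlogits + t(dlogits)) %*% E_fi
  dW2 <- dE_fi * (E_ss - Ekm)
  dE_ss <- dE_fi * W2
  dEkm <- dE_fi * (1 - W2)
  bk2 <- block_backward(dW2 * W2 * (1 - W2), fw2, model$block2)
  dE_ss <- dE_ss + bk2$dEa
  dEkm <- dEkm + bk2$dEa
  dW1 <- dE_ss * (e_sm - e_st)
  bk1 <- block_backward(dW1 * W1 * (1 - W1), fw1, model$block1)
  dproj <- if (!is.null(model$proj)) crossprod(e_km_z, dEkm)
  list(loss = loss, g1 = bk1$grads, g2 = bk2$grads, dproj = dproj)
}

#' Train the fusion blocks on the auxiliary reconstruction objective
#'
#' With the branch embeddings frozen, the fusion parameters are updated
#' by Adam to minimize the BCE between `sigmoid(E_fi E_fi^T)` and the
#' similarity target, keeping the whole representation pipeline
#' label-free. `epochs = 0` leaves the blocks at their seeded random
#' initialization (fixed-mixer reading).
#'
#' @param model a [fusion_model()].
#' @param e_sm,e_st,e_km embedding and k-mer matrices (m rows each).
#' @param S_target similarity target in `[0, 1]`.
#' @param epochs number of Adam steps (default 50).
#' @param lr learning rate (default 1e-3).
#' @return The model with updated parameters and a `loss` attribute
#'   (per-epoch trace).
#' @export
train_fusion <- function(model, e_sm, e_st, e_km, S_target,
                         epochs = 50L, lr = 1e-3) {
  if (epochs <= 0) return(model)
  pars <- list(w1a = model$block1$w1, b1a = model$block1$b1,
               w2a = model$block1$w2, b2a = model$block1$b2,
               w1b = model$block2$w1, b1b = model$block2$b1,
               w2b = model$block2$w2, b2b = model$block2$b2)
  if (!is.null(model$proj)) pars$proj <- model$proj
  st <- adam_init(pars)
  trace <- numeric(epochs)
  for (e in seq_len(epochs)) {
    gg <- fusion_aux_grads(model, e_sm, e_st, e_km, S_target)
    trace[e] <- gg$loss
    grads <- list(w1a = gg$g1$w1, b1a = gg$g1$b1, w2a = gg$g1$w2,
                  b2a = gg$g1$b2, w1b = gg$g2$w1, b1b = gg$g2$b1,
                  w2b = gg$g2$w2, b2b = gg$g2$b2)
    if (!is.null(model$proj)) grads$proj <- gg$dproj
    up <- adam_step(pars, grads, st, lr)
    pars <- up$pars; st <- up$state
    model$block1$w1 <- pars$w1a; model$block1$b1 <- pars$b1a
    model$block1$w2 <- pars$w2a; model$block1$b2 <- pars$b2a
    model$block2$w1 <- pars$w1b; model$block2$b1 <- pars$b1b
    model$block2$w2 <- pars$w2b; model$block2$b2 <- pars$b2b
    if (!is.null(model$proj)) model$proj <- pars$proj
  }
  attr(model, "loss") <- trace
  model
}
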