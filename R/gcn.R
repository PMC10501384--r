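# Self-correlation graph convolutional autoencoder: a learnable initial
# node matrix (no prior node annotations), scaled residual graph
# convolution layers, and a dual adjacency-reconstruction BCE loss.

#' Residual scaling schedule of the graph convolution stack
#'
#' Layer `i` (1-based) of an `n_layers` stack contributes with weight
#' `i / (n_layers + 1)`, preventing the accumulated representation from
#' shrinking as depth grows. For three layers the weights are 0.25, 0.5,
#' 0.75.
#'
#' @param layer 1-based layer index.
#' @param n_layers total number of layers.
#' @return Scalar weight in (0, 1).
#' @export
alpha_schedule <- function(layer, n_layers) {
  if (layer < 1 || layer > n_layers) {
    stop("layer index ", layer, " outside 1..", n_layers)
  }
  layer / (n_layers + 1)
}

# Symmetric-normalized operator N = D^{-1/2} ((A + A^T)/2 + I) D^{-1/2};
# "laplacian" variant uses the degree-normalized D - A form instead.
normalize_adjacency <- function(A, variant = c("sym_norm", "laplacian")) {
  variant <- match.arg(variant)
  A <- unclass(as.matrix(A))
  attributes(A)[setdiff(names(attributes(A)), "dim")] <- NULL
  Ah <- (A + t(A)) / 2
  if (variant == "sym_norm") {
    Ah <- Ah + diag(nrow(A))
    dg <- rowSums(Ah)
    Ah * outer(1 / sqrt(dg), 1 / sqrt(dg))
  } else {
    dg <- pmax(rowSums(Ah), .Machine$double.eps)
    (diag(dg) - Ah) * outer(1 / sqrt(dg), 1 / sqrt(dg))
  }
}

#' One graph convolution layer
#'
#' Computes `ReLU(N H W)` where `N` is the symmetric-normalized adjacency
#' with self-loops, `D^{-1/2}((A + A^T)/2 + I)D^{-1/2}` (`D` the degree
#' matrix of the symmetrized, self-looped adjacency). The `"laplacian"`
#' variant replaces the normalized adjacency with the degree-normalized
#' Laplacian `D^{-1/2}(diag(deg) - (A + A^T)/2)D^{-1/2}`.
#'
#' @param H node feature matrix (m rows).
#' @param A square adjacency (similarity or binary structure graph).
#' @param W weight matrix conformable with `H`.
#' @param variant `"sym_norm"` (default) or `"laplacian"`.
#' @return Activated node feature matrix `ReLU(N H W)`.
#' @export
gcn_layer <- function(H, A, W, variant = c("sym_norm", "laplacian")) {
  H <- as.matrix(H); W <- as.matrix(W)
  if (!all(is.finite(H)) || !all(is.finite(W))) stop("non-finite input")
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (nrow(H) != nrow(A)) stop("H must have one row per node")
  if (ncol(H) != nrow(W)) stop("H and W are not conformable")
  N <- normalize_adjacency(A, variant)
  pmax(N %*% (H %*% W), 0)
}

#' Initialize the self-correlation GCN
#'
#' Creates the learnable initial node matrix `Er` (m x m, Glorot-uniform)
#' and, per branch, the convolution weights and the residual-stream
#' projection matrices that align the accumulated representation with
#' each layer's width.
#'
#' @param m number of nodes (sequences).
#' @param hidden integer vector of per-layer output widths
#'   (default `c(128, 64, 64)`).
#' @param branches names of the adjacency branches sharing `Er`.
#' @param seed integer seed.
#' @return List with `Er`, per-branch `W` and `P` weight lists, `hidden`,
#'   and `alphas`.
#' @export
selfcorr_init <- function(m, hidden = c(128L, 64L, 64L),
                          branches = c("sim", "st"), seed = 1L) {
  stopifnot(m >= 2, length(hidden) >= 1)
  dims <- c(m, hidden)
  with_seed(seed, {
    br <- lapply(branches, function(b) {
      list(W = lapply(seq_along(hidden),
                      function(i) glorot(dims[i], dims[i + 1L])),
           P = lapply(seq_along(hidden),
                      function(i) glorot(dims[i], dims[i + 1L])))
    })
    names(br) <- branches
    list(Er = glorot(m, m), branches = br, hidden = as.integer(hidden),
         alphas = vapply(seq_along(hidden), alpha_schedule,
                         numeric(1), n_layers = length(hidden)))
  })
}

#' Forward pass of one self-correlation branch
#'
#' Starting from the learnable node matrix (`H0 = R0 = Er`), each layer
#' computes a graph convolution of the running hidden state and adds it,
#' scaled by [alpha_schedule()], to the residual stream, which is first
#' projected to the layer's width: `R_i = R_{i-1} P_i + alpha_i H_i` with
#' `H_i = ReLU(N H_{i-1} W_i)`. The final residual stream is the branch
#' embedding.
#'
#' @param A adjacency matrix (similarity or structure graph), or a
#'   pre-normalized operator via `N`.
#' @param Er learnable initial node matrix.
#' @param weights list with elements `W` and `P` as in [selfcorr_init()].
#' @param alphas per-layer residual scales.
#' @param variant convolution variant, see [gcn_layer()].
#' @param N optional precomputed normalized operator (overrides `A`).
#' @param cache return intermediates for backpropagation.
#' @return Embedding matrix (m x last hidden width), or a list with
#'   intermediates when `cache = TRUE`.
#' @export
selfcorr_forward <- function(A, Er, weights, alphas,
                             variant = "sym_norm", N = NULL, cache = FALSE) {
  if (is.null(N)) N <- normalize_adjacency(A, variant)
  nl <- length(weights$W)
  stopifnot(length(alphas) == nl, length(weights$P) == nl)
  H <- Er; R <- Er
  Hs <- vector("list", nl); Rs <- vector("list", nl + 1L)
  pre <- vector("list", nl)
  Rs[[1L]] <- R
  for (i in seq_len(nl)) {
    pre[[i]] <- N %*% (H %*% weights$W[[i]])
    Hn <- pmax(pre[[i]], 0)
    R <- R %*% weights$P[[i]] + alphas[i] * Hn
    Hs[[i]] <- H <- Hn
    Rs[[i + 1L]] <- R
  }
  if (!all(is.finite(R))) stop("non-finite embedding")
  if (cache) list(out = R, H = Hs, R = Rs, pre = pre, N = N) else R
}

# Gradients of one branch given dOut = dL/d(embedding). Returns dEr, dW, dP.
selfcorr_backward <- function(fw, Er, weights, alphas, dOut) {
  nl <- length(weights$W)
  N <- fw$N
  dW <- vector("list", nl); dP <- vector("list", nl)
  dR <- dOut
  dH_next <- NULL          # gradient flowing into H_i from layer i+1's conv
  dEr <- matrix(0, nrow(Er), ncol(Er))
  for (i in rev(seq_len(nl))) {
    Rprev <- fw$R[[i]]
    Hprev <- if (i == 1L) Er else fw$H[[i - 1L]]
    dP[[i]] <- crossprod(Rprev, dR)
    dHi <- alphas[i] * dR
    if (!is.null(dH_next)) dHi <- dHi + dH_next
    dpre <- dHi * (fw$pre[[i]] > 0)
    Nd <- N %*% dpre
    dW[[i]] <- crossprod(Hprev, Nd)
    dH_next <- Nd %*% t(weights$W[[i]])
    dR <- dR %*% t(weights$P[[i]])
    if (i == 1L) dEr <- dR + dH_next
  }
  list(dEr = dEr, dW = dW, dP = dP)
}

softplus <- function(z) ifelse(z > 30, z, log1p(exp(pmin(z, 30))))

# Mean BCE between sigmoid(logits) and targets in [0,1], numerically stable.
bce_from_logits <- function(logits, target) {
  mean(softplus(-logits) + (1 - target) * logits)
}

#' Dual adjacency-reconstruction loss
#'
#' Mean binary cross-entropy between the reconstructed similarity matrix
#' and its `[0, 1]` target plus the same term for the structure graph.
#' Reconstructions are probabilities (typically `sigmoid(E %*% t(E))`
#' from the branch embeddings).
#'
#' @param S_hat,G_hat reconstructed matrices with entries in (0, 1).
#' @param S_target similarity target in `[0, 1]`.
#' @param G_target binary structure-graph target.
#' @return Nonnegative scalar: the sum of the two mean-BCE terms.
#' @export
reconstruction_loss <- function(S_hat, S_target, G_hat, G_target) {
  for (tg in list(S_target, G_target)) {
    if (any(tg < 0 | tg > 1)) stop("targets must lie in [0, 1]")
  }
  eps <- 1e-12
  bce <- function(p, t) {
    p <- pmin(pmax(p, eps), 1 - eps)
    mean(-t * log(p) - (1 - t) * log(1 - p))
  }
  bce(S_hat, S_target) + bce(G_hat, G_target)
}
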