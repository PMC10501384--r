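# Hand-rolled Transformer encoder over 3-mer token streams. Kept in plain
# matrix algebra so the gradient path (used by the joint training loop) is
# explicit and finite-difference checkable.

#' Transformer encoder configuration
#'
#' Defaults follow the method's reported setting (embedding size 32,
#' feed-forward width 128, six encoder blocks) except for the head count:
#' 32 is not divisible by 6, so the default is 4 heads (per-head width 8);
#' any `heads` that divides `d_model` is accepted.
#'
#' @param d_model embedding width (default 32).
#' @param heads number of attention heads; must divide `d_model`.
#' @param ff_dim feed-forward hidden width (default 128).
#' @param blocks number of encoder blocks (default 6; 0 is a valid
#'   pass-through used as a closed-form test hook).
#' @param dropout dropout rate in `[0, 1)` applied during gradient passes.
#' @param pooling `"mean"` (default) or `"max"` pooling over positions.
#' @param seed integer seed for weight initialization.
#' @return A list of class `transformer_config`.
#' @export
transformer_config <- function(d_model = 32L, heads = 4L, ff_dim = 128L,
                               blocks = 6L, dropout = 0.1,
                               pooling = c("mean", "max"), seed = 1L) {
  pooling <- match.arg(pooling)
  stopifnot(d_model >= 2, ff_dim >= 1, blocks >= 0,
            dropout >= 0, dropout < 1)
  if (d_model %% 2L != 0L) stop("d_model must be even (sin/cos pairing)")
  if (d_model %% heads != 0L) {
    stop("d_model (", d_model, ") must be divisible by heads (", heads,
         "); e.g. use heads = 4 at d_model = 32, or raise d_model to a ",
         "multiple of the requested head count")
  }
  structure(list(d_model = as.integer(d_model), heads = as.integer(heads),
                 ff_dim = as.integer(ff_dim), blocks = as.integer(blocks),
                 dropout = dropout, pooling = pooling,
                 seed = as.integer(seed)),
            class = "transformer_config")
}

#' Sinusoidal positional encoding table
#'
#' Row `t + 1` (positions are 0-based) holds the functional encoding of
#' position `t`: column pairs `(2k, 2k+1)` (0-based) are
#' `sin(t / 10000^(2k/d))` and `cos(t / 10000^(2k/d))`. Row 0 is therefore
#' `(0, 1, 0, 1, ...)` and every entry lies in `[-1, 1]`.
#'
#' @param L number of positions (rows).
#' @param d encoding width; must be even.
#' @return `L` x `d` numeric matrix.
#' @export
positional_encoding <- function(L, d) {
  stopifnot(L >= 1)
  if (d < 2 || d %% 2L != 0L) stop("d must be even and >= 2")
  t <- 0:(L - 1)
  k <- 0:(d / 2 - 1)
  w <- 10000^(-2 * k / d)
  ang <- outer(t, w)                      # L x d/2
  P <- matrix(0, L, d)
  P[, 2 * k + 1] <- sin(ang)
  P[, 2 * k + 2] <- cos(ang)
  P
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Initialize Transformer encoder parameters
#'
#' @param cfg a [transformer_config()].
#' @param vocab_size token vocabulary size (64 for 3-mers).
#' @return Named list with the token embedding table and per-block
#'   attention / feed-forward weights.
#' @export
transformer_init <- function(cfg, vocab_size = 64L) {
  d <- cfg$d_model; ff <- cfg$ff_dim
  with_seed(cfg$seed, {
    list(
      embed = matrix(stats::rnorm(vocab_size * d, sd = 0.5), vocab_size, d),
      blocks = lapply(seq_len(cfg$blocks), function(b) {
        list(Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d),
             Wo = glorot(d, d),
             W1 = glorot(d, ff), b1 = numeric(ff),
             W2 = glorot(ff, d), b2 = numeric(d))
      })
    )
  })
}

row_softmax <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

# Forward pass for one token stream. Returns the pooled vector; with
# cache = TRUE also all intermediates needed for backpropagation.
tf_forward_one <- function(tok, params, cfg, PE, cache = FALSE,
                           drop_masks = NULL) {
  d <- cfg$d_model; nh <- cfg$heads; dh <- d %/% nh
  X <- params$embed[tok + 1L, , drop = FALSE] + PE
  L <- nrow(X)
  cc <- if (cache) list(X0 = X, blocks = vector("list", cfg$blocks))
  for (b in seq_len(cfg$blocks)) {
    P <- params$blocks[[b]]
    Qf <- X %*% P$Wq; Kf <- X %*% P$Wk; Vf <- X %*% P$Wv
    O <- matrix(0, L, d)
    As <- if (cache) vector("list", nh)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- row_softmax(Qf[, cols, drop = FALSE] %*%
                         t(Kf[, cols, drop = FALSE]) / sqrt(dh))
      O[, cols] <- A %*% Vf[, cols, drop = FALSE]
      if (cache) As[[h]] <- A
    }
    MH <- O %*% P$Wo
    if (!is.null(drop_masks)) MH <- MH * drop_masks[[b]]$m1
    Y <- X + MH
    F1 <- sweep(Y %*% P$W1, 2L, P$b1, `+`)
    Fr <- pmax(F1, 0)
    F2 <- sweep(Fr %*% P$W2, 2L, P$b2, `+`)
    if (!is.null(drop_masks)) F2 <- F2 * drop_masks[[b]]$m2
    Xn <- Y + F2
    if (cache) cc$blocks[[b]] <- list(X = X, Qf = Qf, Kf = Kf, Vf = Vf,
                                      As = As, O = O, Y = Y, Fr = Fr)
    X <- Xn
  }
  pooled <- if (cfg$pooling == "mean") colMeans(X) else apply(X, 2L, max)
  if (!all(is.finite(pooled))) stop("non-finite activations in encoder")
  if (cache) list(pooled = pooled, X = X, cache = cc) else pooled
}

#' Encode token streams into per-sequence embeddings
#'
#' Each stream receives the learned token embedding plus the sinusoidal
#' positional encoding, passes through the configured number of encoder
#' blocks (multi-head scaled dot-product attention and a ReLU feed-forward
#' sublayer, each with a residual connection), and is pooled over
#' positions. With `blocks = 0` the output is exactly the pooled sum of
#' token embedding and positional encoding (closed-form test hook).
#'
#' @param tokens integer matrix of 0-based token streams (rows =
#'   sequences), as produced by [tokenize()].
#' @param params parameters from [transformer_init()]; created from
#'   `cfg$seed` when `NULL`.
#' @param cfg a [transformer_config()].
#' @return Numeric matrix, one `d_model`-length row per sequence.
#' @export
encode_sequences <- function(tokens, params = NULL, cfg = transformer_config()) {
  tokens <- rbind(tokens)
  if (nrow(tokens) == 0L) stop("empty input")
  if (is.null(params)) params <- transformer_init(cfg)
  PE <- positional_encoding(ncol(tokens), cfg$d_model)
  U <- t(vapply(seq_len(nrow(tokens)),
                function(i) tf_forward_one(tokens[i, ], params, cfg, PE),
                numeric(cfg$d_model)))
  rownames(U) <- rownames(tokens)
  U
}

# Backward pass through the encoder stack: given d(loss)/d(pooled) rows dU,
# accumulate parameter gradients. Recomputes each sequence's forward with a
# cache so peak memory stays per-sequence. Mean pooling only.
transformer_backward <- function(tokens, params, cfg, dU, drop_masks = NULL) {
  stopifnot(cfg$pooling == "mean")
  tokens <- rbind(tokens)
  d <- cfg$d_model; nh <- cfg$heads; dh <- d %/% nh
  PE <- positional_encoding(ncol(tokens), cfg$d_model)
  L <- ncol(tokens)
  g <- list(embed = matrix(0, nrow(params$embed), d),
            blocks = lapply(params$blocks, function(P) {
              lapply(P, function(w) if (is.matrix(w)) 0 * w else 0 * w)
            }))
  for (i in seq_len(nrow(tokens))) {
    tok <- tokens[i, ]
    dm <- if (!is.null(drop_masks)) {
      drop_masks[[i]]
    } else if (cfg$dropout > 0) {
      # inverted-dropout masks on the attention and feed-forward outputs,
      # drawn per gradient pass
      lapply(seq_len(cfg$blocks), function(b) {
        list(m1 = matrix(stats::rbinom(L * d, 1L, 1 - cfg$dropout),
                         L, d) / (1 - cfg$dropout),
             m2 = matrix(stats::rbinom(L * d, 1L, 1 - cfg$dropout),
                         L, d) / (1 - cfg$dropout))
      })
    }
    fw <- tf_forward_one(tok, params, cfg, PE, cache = TRUE, drop_masks = dm)
    dX <- matrix(dU[i, ] / L, L, d, byrow = TRUE)
    for (b in rev(seq_len(cfg$blocks))) {
      P <- params$blocks[[b]]; C <- fw$cache$blocks[[b]]
      dF2 <- dX
      if (!is.null(dm)) dF2 <- dF2 * dm[[b]]$m2
      dFr <- dF2 %*% t(P$W2)
      g$blocks[[b]]$W2 <- g$blocks[[b]]$W2 + t(C$Fr) %*% dF2
      g$blocks[[b]]$b2 <- g$blocks[[b]]$b2 + colSums(dF2)
      dF1 <- dFr * (C$Fr > 0)
      g$blocks[[b]]$W1 <- g$blocks[[b]]$W1 + t(C$Y) %*% dF1
      g$blocks[[b]]$b1 <- g$blocks[[b]]$b1 + colSums(dF1)
      dY <- dX + dF1 %*% t(P$W1)
      dMH <- dY
      if (!is.null(dm)) dMH <- dMH * dm[[b]]$m1
      dO <- dMH %*% t(P$Wo)
      g$blocks[[b]]$Wo <- g$blocks[[b]]$Wo + t(C$O) %*% dMH
      dQf <- matrix(0, L, d); dKf <- matrix(0, L, d); dVf <- matrix(0, L, d)
      for (h in seq_len(nh)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        A <- C$As[[h]]
        dOh <- dO[, cols, drop = FALSE]
        dA <- dOh %*% t(C$Vf[, cols, drop = FALSE])
        dVf[, cols] <- t(A) %*% dOh
        dS <- A * (dA - rowSums(dA * A))
        dQf[, cols] <- dS %*% C$Kf[, cols, drop = FALSE] / sqrt(dh)
        dKf[, cols] <- t(dS) %*% C$Qf[, cols, drop = FALSE] / sqrt(dh)
      }
      g$blocks[[b]]$Wq <- g$blocks[[b]]$Wq + t(C$X) %*% dQf
      g$blocks[[b]]$Wk <- g$blocks[[b]]$Wk + t(C$X) %*% dKf
      g$blocks[[b]]$Wv <- g$blocks[[b]]$Wv + t(C$X) %*% dVf
      dX <- dY + dQf %*% t(P$Wq) + dKf %*% t(P$Wk) + dVf %*% t(P$Wv)
    }
    for (p in seq_len(L)) {
      r <- tok[p] + 1L
      g$embed[r, ] <- g$embed[r, ] + dX[p, ]
    }
  }
  g
}

#' Binary structure graph from sequence embeddings
#'
#' Pairwise Manhattan distances between embedding rows are min-max
#' normalized over the off-diagonal entries and converted to a proximity
#' `g = 1 - normalized distance`; entries with `g > threshold` become 1,
#' others 0, and the diagonal is forced to 1. The min-max normalization
#' makes the graph invariant to uniform scaling of the embeddings. When
#' all embeddings coincide the graph degenerates to all ones with a
#' warning.
#'
#' @param E numeric matrix of per-sequence embeddings (>= 2 rows).
#' @param threshold proximity cutoff in (0, 1), default 0.5.
#' @return Binary symmetric m x m matrix of class `structure_graph`, with
#'   the continuous proximity matrix attached as attribute `"proximity"`.
#' @export
build_structure_graph <- function(E, threshold = 0.5) {
  E <- as.matrix(E)
  if (nrow(E) < 2L) stop("need at least 2 embeddings")
  D <- as.matrix(stats::dist(E, method = "manhattan"))
  off <- D[upper.tri(D)]
  mn <- min(off); mx <- max(off)
  if (mx == mn) {
    warning("all embeddings are equidistant; structure graph is all ones")
    G <- matrix(1, nrow(D), ncol(D))
    prox <- G
  } else {
    prox <- 1 - (D - mn) / (mx - mn)
    diag(prox) <- 1
    G <- (prox > threshold) * 1
    diag(G) <- 1
  }
  dimnames(G) <- dimnames(D)
  structure(G, proximity = prox, threshold = threshold,
            range = c(mn, mx), class = c("structure_graph", class(G)))
}
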