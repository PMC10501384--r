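# Independent brute-force oracles used to pin down every numerical
# operation. Deliberately written as scalar loops / direct formulas,
# sharing no code with the implementation.

rand_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

oracle_kmer <- function(s, K = 3) {
  voc <- kmer_vocab(K)
  n <- nchar(s)
  counts <- setNames(numeric(length(voc)), voc)
  for (l in 1:(n - K + 1)) {
    w <- substr(s, l, l + K - 1)
    counts[w] <- counts[w] + 1
  }
  counts / (n - K + 1)
}

oracle_manhattan <- function(u, v) {
  acc <- 0
  for (j in seq_along(u)) acc <- acc + abs(u[j] - v[j])
  acc
}

oracle_distance_matrix <- function(X) {
  m <- nrow(X)
  D <- matrix(0, m, m)
  for (i in 1:m) for (j in 1:m) D[i, j] <- oracle_manhattan(X[i, ], X[j, ])
  D
}

oracle_pe <- function(L, d) {
  P <- matrix(0, L, d)
  for (t in 0:(L - 1)) {
    for (i in 0:(d - 1)) {
      k <- i %/% 2
      w <- 1 / 10000^(2 * k / d)
      P[t + 1, i + 1] <- if (i %% 2 == 0) sin(w * t) else cos(w * t)
    }
  }
  P
}

oracle_gcn_layer <- function(H, A, W) {
  m <- nrow(A)
  Ah <- (A + t(A)) / 2 + diag(m)
  D <- diag(rowSums(Ah))
  N <- solve(sqrt(D)) %*% Ah %*% solve(sqrt(D))
  Z <- N %*% H %*% W
  Z[Z < 0] <- 0
  Z
}

oracle_bce <- function(p, t) {
  acc <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      acc <- acc - t[i, j] * log(p[i, j]) - (1 - t[i, j]) * log(1 - p[i, j])
    }
  }
  acc / length(p)
}

oracle_metrics <- function(tp, fp, tn, fn) {
  prec <- tp / (tp + fp)
  sn <- tp / (tp + fn)
  c(Acc = (tp + tn) / (tp + fp + tn + fn),
    F1 = 2 * prec * sn / (prec + sn),
    Prec = prec, Sn = sn, Sp = tn / (tn + fp),
    MCC = (tp * tn - fp * fn) /
      sqrt((tp + fp)) / sqrt((tp + fn)) / sqrt((tn + fp)) / sqrt((tn + fn)))
}

# Rank-statistic AUC (Mann-Whitney with midranks for ties).
oracle_auc_mw <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  acc <- 0
  for (p in pos) for (q in neg) {
    acc <- acc + (p > q) + 0.5 * (p == q)
  }
  acc / (length(pos) * length(neg))
}

fd_grad <- function(f, x, h = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}
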