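test_that("alpha schedule follows i/(I+1) and sums to I/2", {
  expect_equal(alpha_schedule(1, 3), 0.25)
  expect_equal(alpha_schedule(3, 3), 0.75)
  expect_equal(alpha_schedule(1, 1), 0.5)
  expect_error(alpha_schedule(0, 3), "outside")
  expect_error(alpha_schedule(4, 3), "outside")
  for (I in 1:6) {
    expect_equal(sum(vapply(1:I, alpha_schedule, numeric(1), n_layers = I)),
                 I / 2)
  }
})

test_that("gcn layer matches the symmetric-normalized closed form", {
  # identity graph, identity features/weights: self-loops double, normalize
  # back to the identity
  expect_equal(gcn_layer(diag(2), diag(2), diag(2)), diag(2))
  # 3-node path graph, hand-checkable against the dense oracle
  A <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  H <- diag(3); W <- diag(3)
  expect_equal(gcn_layer(H, A, W), oracle_gcn_layer(H, A, W),
               tolerance = 1e-12)
  set.seed(31)
  for (r in 1:100) {
    m <- sample(2:6, 1); dh <- sample(1:5, 1); dout <- sample(1:4, 1)
    A <- matrix(runif(m * m), m, m)
    H <- matrix(rnorm(m * dh), m, dh)
    W <- matrix(rnorm(dh * dout), dh, dout)
    Z <- gcn_layer(H, A, W)
    expect_equal(Z, oracle_gcn_layer(H, A, W), tolerance = 1e-9)
    expect_true(all(Z >= 0) && all(is.finite(Z)))
  }
  expect_error(gcn_layer(matrix(NA_real_, 2, 2), diag(2), diag(2)),
               "non-finite")
})

test_that("selfcorr forward unrolls the scaled residual recursion", {
  set.seed(32)
  m <- 5
  A <- matrix(runif(m * m), m, m)
  gcn <- selfcorr_init(m, hidden = 4L, seed = 2)
  # one layer: R1 = Er P1 + 0.5 * relu(N Er W1)
  out <- selfcorr_forward(A, gcn$Er, gcn$branches$sim, gcn$alphas)
  N <- m6arec:::normalize_adjacency(A)
  manual <- gcn$Er %*% gcn$branches$sim$P[[1]] +
    0.5 * pmax(N %*% gcn$Er %*% gcn$branches$sim$W[[1]], 0)
  expect_equal(out, manual, tolerance = 1e-12)

  # three layers on a 4-node toy graph: straight-line unrolled script
  m <- 4
  A <- matrix(runif(m * m), m, m)
  gcn <- selfcorr_init(m, hidden = c(3L, 2L, 2L), seed = 3)
  w <- gcn$branches$st
  N <- m6arec:::normalize_adjacency(A)
  H0 <- gcn$Er; R <- gcn$Er
  H1 <- pmax(N %*% H0 %*% w$W[[1]], 0); R <- R %*% w$P[[1]] + 0.25 * H1
  H2 <- pmax(N %*% H1 %*% w$W[[2]], 0); R <- R %*% w$P[[2]] + 0.50 * H2
  H3 <- pmax(N %*% H2 %*% w$W[[3]], 0); R <- R %*% w$P[[3]] + 0.75 * H3
  expect_equal(selfcorr_forward(A, gcn$Er, w, gcn$alphas), R,
               tolerance = 1e-12)
  # deterministic under fixed seed
  gcn2 <- selfcorr_init(m, hidden = c(3L, 2L, 2L), seed = 3)
  expect_identical(gcn$Er, gcn2$Er)
})

test_that("with Er frozen, the embedding depends only on the adjacency", {
  set.seed(33)
  m <- 6
  gcn <- selfcorr_init(m, hidden = c(4L, 3L), seed = 7)
  A1 <- matrix(runif(m * m), m, m)
  A2 <- matrix(runif(m * m), m, m)
  e1 <- selfcorr_forward(A1, gcn$Er, gcn$branches$sim, gcn$alphas)
  e1b <- selfcorr_forward(A1, gcn$Er, gcn$branches$sim, gcn$alphas)
  e2 <- selfcorr_forward(A2, gcn$Er, gcn$branches$sim, gcn$alphas)
  expect_identical(e1, e1b)
  expect_false(isTRUE(all.equal(e1, e2)))
})

test_that("reconstruction loss matches closed forms and the scalar oracle", {
  h <- matrix(0.5, 2, 2)
  expect_equal(reconstruction_loss(h, h, h, h), 2 * log(2))
  # near-perfect probabilities on binary targets drive the loss to 0
  t1 <- matrix(c(1, 0, 0, 1), 2, 2)
  p <- abs(t1 - 1e-12)
  expect_lt(reconstruction_loss(p, t1, p, t1), 1e-10)
  expect_error(reconstruction_loss(h, h * 3, h, h), "\\[0, 1\\]")
  set.seed(34)
  for (r in 1:100) {
    p1 <- matrix(runif(9, 0.01, 0.99), 3, 3)
    p2 <- matrix(runif(9, 0.01, 0.99), 3, 3)
    t1 <- matrix(runif(9), 3, 3)
    t2 <- matrix(rbinom(9, 1, 0.5), 3, 3)
    expect_equal(reconstruction_loss(p1, t1, p2, t2),
                 oracle_bce(p1, t1) + oracle_bce(p2, t2), tolerance = 1e-9)
  }
})

test_that("branch backward matches finite differences of the loss", {
  set.seed(35)
  m <- 5
  A <- matrix(runif(m * m), m, m)
  S_t <- matrix(runif(m * m), m, m); S_t <- (S_t + t(S_t)) / 2
  gcn <- selfcorr_init(m, hidden = c(4L, 3L), seed = 8)
  w <- gcn$branches$sim
  N <- m6arec:::normalize_adjacency(A)

  loss_fn <- function(Er, w) {
    E <- selfcorr_forward(NULL, Er, w, gcn$alphas, N = N)
    m6arec:::bce_from_logits(tcrossprod(E), S_t)
  }
  fw <- selfcorr_forward(NULL, gcn$Er, w, gcn$alphas, N = N, cache = TRUE)
  dl <- (plogis(tcrossprod(fw$out)) - S_t) / m^2
  bk <- m6arec:::selfcorr_backward(fw, gcn$Er, w, gcn$alphas,
                                   (dl + t(dl)) %*% fw$out)

  fd_Er <- matrix(fd_grad(function(v) {
    loss_fn(matrix(v, m, m), w)
  }, as.numeric(gcn$Er)), m, m)
  expect_equal(bk$dEr, fd_Er, tolerance = 1e-6)
  for (i in 1:2) {
    fd_W <- matrix(fd_grad(function(v) {
      w2 <- w; w2$W[[i]] <- matrix(v, nrow(w$W[[i]]))
      loss_fn(gcn$Er, w2)
    }, as.numeric(w$W[[i]])), nrow(w$W[[i]]))
    expect_equal(bk$dW[[i]], fd_W, tolerance = 1e-6)
    fd_P <- matrix(fd_grad(function(v) {
      w2 <- w; w2$P[[i]] <- matrix(v, nrow(w$P[[i]]))
      loss_fn(gcn$Er, w2)
    }, as.numeric(w$P[[i]])), nrow(w$P[[i]]))
    expect_equal(bk$dP[[i]], fd_P, tolerance = 1e-6)
  }
})

test_that("training a two-cluster toy graph recovers the block structure", {
  set.seed(36)
  m <- 30
  blocks <- rep(c(1, 2), each = m / 2)
  A <- outer(blocks, blocks, function(a, b) ifelse(a == b, 0.9, 0.05))
  diag(A) <- 1
  toks <- matrix(sample(0:63, m * 20, replace = TRUE), m, 20)
  cfg <- transformer_config(d_model = 4, heads = 2, ff_dim = 8, blocks = 1,
                            dropout = 0, seed = 1)
  fit <- suppressWarnings(
    train_embeddings(A, toks, tf_cfg = cfg, hidden = c(16L, 8L),
                     epochs = 300, lr = 5e-3, refresh_every = Inf, seed = 4))
  P <- plogis(tcrossprod(fit$e_sm))
  within <- mean(P[outer(blocks, blocks, `==`) & row(P) != col(P)])
  between <- mean(P[outer(blocks, blocks, `!=`)])
  expect_gt(within, between)
})
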