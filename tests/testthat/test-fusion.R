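test_that("fusion gates lie strictly in (0,1) and are deterministic", {
  set.seed(41)
  blk <- fusion_block(seed = 5)
  for (r in 1:20) {
    e <- rnorm(16)
    w <- fusion_weight(e, blk)
    expect_true(all(w > 0 & w < 1))
    expect_identical(w, fusion_weight(e, blk))
  }
  # zero input through a zero-initialized block gives exactly 0.5
  z <- fusion_weight(numeric(8), fusion_block(init = "zero"))
  expect_equal(z, rep(0.5, 8))
  expect_error(fusion_weight(c(1, NA), blk), "non-finite")
})

test_that("branch fusion is an entrywise convex combination", {
  set.seed(42)
  blk <- fusion_block(seed = 6)
  v <- rnorm(12)
  expect_equal(fuse_branches(v, v, blk), v)
  a <- rnorm(12); b <- rnorm(12)
  expect_equal(fuse_branches(a, b, blk, w = 1), a)
  expect_equal(fuse_branches(a, b, blk, w = 0), b)
  for (r in 1:50) {
    a <- rnorm(12); b <- rnorm(12)
    f <- fuse_branches(a, b, blk)
    expect_true(all(f >= pmin(a, b) - 1e-12 & f <= pmax(a, b) + 1e-12))
  }
  expect_error(fuse_branches(1:3, 1:4, blk), "dimension")
})

test_that("kmer fusion matches a frozen-weight scalar recomputation", {
  set.seed(43)
  blk <- fusion_block(seed = 7)
  # single vector: batch standardization collapses to zero, so with zero
  # biases the gate is exactly sigmoid(0) = 0.5
  e_ss <- rnorm(8); e_km <- runif(8)
  expect_equal(fuse_with_kmer(e_ss, e_km, blk), 0.5 * e_ss + 0.5 * e_km)
  expect_equal(fuse_with_kmer(e_km, e_km, blk), e_km)

  # two-sample batch: straight-line recomputation of the whole block
  d <- 8
  E_ss <- matrix(rnorm(2 * d), 2, d)
  E_km <- matrix(runif(2 * d), 2, d)
  got <- fuse_with_kmer(E_ss, E_km, blk)
  conv <- function(x, w, b) {
    n <- length(x)
    vapply(seq_len(n), function(j) {
      xm <- if (j > 1) x[j - 1] else 0
      xp <- if (j < n) x[j + 1] else 0
      w[1] * xm + w[2] * x[j] + w[3] * xp + b
    }, numeric(1))
  }
  X <- E_ss + E_km
  C1 <- t(apply(X, 1, conv, w = blk$w1, b = blk$b1))
  Z1 <- apply(C1, 2, function(col) {
    (col - mean(col)) / sqrt(mean((col - mean(col))^2) + 1e-8)
  })
  LO <- t(apply(pmax(Z1, 0), 1, conv, w = blk$w2, b = blk$b2))
  ga <- rowMeans(X)
  c1g <- blk$w1[2] * ga + blk$b1
  z1g <- (c1g - mean(c1g)) / sqrt(mean((c1g - mean(c1g))^2) + 1e-8)
  gl <- blk$w2[2] * pmax(z1g, 0) + blk$b2
  W <- 1 / (1 + exp(-(LO + gl)))
  expect_equal(got, W * E_ss + (1 - W) * E_km, tolerance = 1e-9)
})

test_that("ablation modes emit distinct m-row matrices", {
  set.seed(44)
  m <- 15; d <- 10
  e_sm <- matrix(rnorm(m * d), m, d)
  e_st <- matrix(rnorm(m * d), m, d)
  e_km <- matrix(runif(m * d), m, d)
  model <- fusion_init(d, d, seed = 3)
  mats <- lapply(c("full", "drop-raw", "drop-trans", "weighted-only"),
                 function(md) fused_features(e_sm, e_st, e_km, model, md))
  for (M in mats) expect_equal(nrow(M), m)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_false(isTRUE(all.equal(mats[[i]], mats[[j]])))
  }
  expect_error(fused_features(e_sm, e_st, e_km, model, "nope"))
  # weighted-only on identical inputs returns the standardized input
  same <- fused_features(e_km, e_km, e_km, model, "weighted-only")
  expect_equal(same, m6arec:::fusion_standardize(e_km), ignore_attr = TRUE)
  # drop-raw excludes the similarity branch entirely
  e_sm2 <- matrix(rnorm(m * d), m, d)
  expect_equal(fused_features(e_sm, e_st, e_km, model, "drop-raw"),
               fused_features(e_sm2, e_st, e_km, model, "drop-raw"))
})

test_that("fusion gradients flow end-to-end (finite differences, 4-dim toy)", {
  set.seed(45)
  m <- 3; d <- 4
  e_sm <- matrix(rnorm(m * d), m, d)
  e_st <- matrix(rnorm(m * d), m, d)
  e_km <- matrix(runif(m * d), m, d)
  S_t <- matrix(runif(m * m), m, m); S_t <- (S_t + t(S_t)) / 2
  model <- fusion_init(d, d, seed = 9)
  gg <- m6arec:::fusion_aux_grads(model, e_sm, e_st, e_km, S_t)

  loss_with <- function(model) {
    m6arec:::fusion_aux_grads(model, e_sm, e_st, e_km, S_t)$loss
  }
  for (bn in c("block1", "block2")) {
    for (pn in c("w1", "w2")) {
      fd <- fd_grad(function(v) {
        mo <- model; mo[[bn]][[pn]] <- v; loss_with(mo)
      }, model[[bn]][[pn]])
      ana <- if (bn == "block1") gg$g1[[pn]] else gg$g2[[pn]]
      expect_equal(ana, fd, tolerance = 1e-4)
    }
    for (pn in c("b1", "b2")) {
      fd <- fd_grad(function(v) {
        mo <- model; mo[[bn]][[pn]] <- v; loss_with(mo)
      }, model[[bn]][[pn]])
      ana <- if (bn == "block1") gg$g1[[pn]] else gg$g2[[pn]]
      expect_equal(ana, fd, tolerance = 1e-4)
    }
  }
  expect_true(all(abs(c(gg$g1$w1, gg$g2$w1)) > 0))
})

test_that("auxiliary fusion training reduces its reconstruction loss", {
  set.seed(46)
  m <- 25; d <- 8
  e_sm <- matrix(rnorm(m * d), m, d)
  e_st <- matrix(rnorm(m * d), m, d)
  e_km <- matrix(runif(m * d), m, d)
  S_t <- plogis(tcrossprod(matrix(rnorm(m * 2), m, 2)))
  model <- fusion_init(d, d, seed = 10)
  trained <- train_fusion(model, e_sm, e_st, e_km, S_t,
                          epochs = 80, lr = 5e-3)
  tr <- attr(trained, "loss")
  expect_lt(tail(tr, 1), tr[1])
  expect_identical(train_fusion(model, e_sm, e_st, e_km, S_t, epochs = 0),
                   model)
})
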