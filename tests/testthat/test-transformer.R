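test_that("positional encoding matches the scalar closed form", {
  P <- positional_encoding(5, 8)
  expect_equal(P[1, ], rep(c(0, 1), 4))
  expect_equal(positional_encoding(2, 2)[2, ], c(sin(1), cos(1)))
  expect_error(positional_encoding(4, 7), "even")
  set.seed(4)
  for (r in 1:100) {
    L <- sample(1:20, 1); d <- 2 * sample(1:8, 1)
    P <- positional_encoding(L, d)
    expect_equal(P, oracle_pe(L, d), tolerance = 1e-12)
    expect_true(all(abs(P) <= 1 + 1e-12))
  }
})

test_that("head count must divide the embedding width", {
  expect_error(transformer_config(d_model = 32, heads = 6), "divisible")
  cfg <- transformer_config(d_model = 36, heads = 6)
  expect_equal(cfg$heads, 6L)
})

test_that("encoder is deterministic, batch-equivariant, and reduces to the
           pooled embedding table at blocks = 0", {
  cfg <- transformer_config(d_model = 8, heads = 2, ff_dim = 16, blocks = 2,
                            dropout = 0, seed = 9)
  set.seed(10)
  toks <- matrix(sample(0:63, 5 * 12, replace = TRUE), 5, 12)
  params <- transformer_init(cfg)
  U1 <- encode_sequences(toks, params, cfg)
  U2 <- encode_sequences(toks, params, cfg)
  expect_identical(U1, U2)
  # identical streams give identical rows
  U3 <- encode_sequences(toks[c(1, 1, 2), ], params, cfg)
  expect_equal(U3[1, ], U3[2, ])
  # permuting the batch permutes outputs
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(encode_sequences(toks[perm, ], params, cfg), U1[perm, ])
  expect_error(encode_sequences(toks[0, , drop = FALSE], params, cfg),
               "empty")

  cfg0 <- transformer_config(d_model = 8, heads = 2, blocks = 0,
                             dropout = 0, seed = 9)
  p0 <- transformer_init(cfg0)
  U0 <- encode_sequences(toks, p0, cfg0)
  PE <- positional_encoding(12, 8)
  for (i in 1:5) {
    expect_equal(U0[i, ], colMeans(p0$embed[toks[i, ] + 1, ] + PE),
                 tolerance = 1e-12)
  }
})

test_that("structure graph is binary, symmetric, threshold-consistent and
           scale-invariant", {
  set.seed(11)
  for (r in 1:20) {
    E <- matrix(rnorm(10 * 6), 10, 6)
    G <- build_structure_graph(E)
    expect_true(all(G %in% c(0, 1)))
    expect_equal(unclass(G), t(unclass(G)), ignore_attr = TRUE)
    expect_equal(unname(diag(G)), rep(1, 10))
    prox <- attr(G, "proximity")
    off <- row(prox) != col(prox)
    expect_equal(unclass(G)[off], as.numeric(prox[off] > 0.5))
    # invariant to uniform scaling
    G2 <- build_structure_graph(3.7 * E)
    expect_equal(unclass(G), unclass(G2), ignore_attr = TRUE)
  }
  # the pair realizing the max distance is disconnected; zero distance pairs
  # are connected
  E <- rbind(c(0, 0), c(0, 0), c(10, 10), c(1, 1))
  G <- build_structure_graph(E)
  expect_equal(unclass(G)[1, 2], 1)
  expect_equal(unclass(G)[1, 3], 0)
  expect_warning(build_structure_graph(matrix(1, 3, 2)), "all ones")
})

test_that("encoder backward matches finite differences of a pooled
           functional", {
  cfg <- transformer_config(d_model = 4, heads = 2, ff_dim = 6, blocks = 2,
                            dropout = 0, seed = 21)
  set.seed(22)
  toks <- matrix(sample(0:63, 3 * 7, replace = TRUE), 3, 7)
  params <- transformer_init(cfg)
  Cmat <- matrix(rnorm(3 * 4), 3, 4)   # random linear functional of pooled U
  loss_of <- function(p) sum(encode_sequences(toks, p, cfg) * Cmat)
  g <- transformer_backward(toks, params, cfg, Cmat)

  flat <- function(p) c(as.numeric(p$embed),
                        unlist(lapply(p$blocks, function(b)
                          lapply(b, as.numeric))))
  unflat <- function(v, proto) {
    out <- proto
    n <- length(proto$embed)
    out$embed <- matrix(v[1:n], nrow(proto$embed))
    pos <- n
    for (b in seq_along(proto$blocks)) {
      for (w in names(proto$blocks[[b]])) {
        k <- length(proto$blocks[[b]][[w]])
        val <- v[(pos + 1):(pos + k)]
        out$blocks[[b]][[w]] <- if (is.matrix(proto$blocks[[b]][[w]])) {
          matrix(val, nrow(proto$blocks[[b]][[w]]))
        } else val
        pos <- pos + k
      }
    }
    out
  }
  v0 <- flat(params)
  # spot-check a deterministic subset of coordinates (full FD is O(npar) slow)
  set.seed(23)
  idx <- sort(sample(seq_along(v0), 60))
  fd <- vapply(idx, function(i) {
    vp <- v0; vp[i] <- vp[i] + 1e-5
    vm <- v0; vm[i] <- vm[i] - 1e-5
    (loss_of(unflat(vp, params)) - loss_of(unflat(vm, params))) / 2e-5
  }, numeric(1))
  expect_equal(unname(flat(g)[idx]), fd, tolerance = 1e-5)
})
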