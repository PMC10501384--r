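# Joint training loop: the similarity and structure branches of the
# self-correlation GCN are optimized under the dual reconstruction loss;
# the structure graph is periodically refreshed from the Transformer,
# whose weights receive gradient through the refresh (straight-through
# past the thresholding).

#' Train the graph autoencoder with iterative structure-graph refresh
#'
#' Each epoch runs both self-correlation branches (one on the `[0, 1]`
#' similarity matrix, one on the binary structure graph), computes the
#' dual adjacency-reconstruction BCE loss, and takes one Adam step over
#' the learnable node matrix and the convolution weights. Every
#' `refresh_every` epochs the structure graph is rebuilt from the
#' Transformer embeddings, and the Transformer parameters are updated
#' through the pre-threshold proximity (the thresholding itself blocks
#' gradients; the min-max normalization constants are treated as fixed).
#' `refresh_every = Inf` freezes the structure graph after its initial
#' construction (static-graph autoencoder).
#'
#' @param S_target m x m similarity matrix in `[0, 1]`
#'   (see [distance_to_similarity()]).
#' @param tokens integer token-stream matrix from [tokenize()], m rows.
#' @param tf_cfg a [transformer_config()].
#' @param hidden per-layer GCN output widths (default `c(128, 64, 64)`).
#' @param epochs number of training epochs (default 200).
#' @param lr Adam learning rate (default 1e-4).
#' @param refresh_every structure-graph refresh period (default 10).
#' @param threshold structure-graph proximity cutoff (default 0.5).
#' @param variant graph convolution variant, see [gcn_layer()].
#' @param seed integer seed for all parameter initialization.
#' @param verbose print the loss every 10 epochs.
#' @return Object of class `m6a_embeddings`: list with branch embeddings
#'   `e_sm` and `e_st` (m rows each), the final structure graph `G_st`,
#'   trained parameters, and a training `log` (epoch, loss, loss_sim,
#'   loss_st).
#' @export
train_embeddings <- function(S_target, tokens, tf_cfg = transformer_config(),
                             hidden = c(128L, 64L, 64L), epochs = 200L,
                             lr = 1e-4, refresh_every = 10L, threshold = 0.5,
                             variant = "sym_norm", seed = 1L,
                             verbose = FALSE) {
  S_target <- as.matrix(S_target)
  m <- nrow(S_target)
  tokens <- rbind(tokens)
  if (nrow(tokens) != m) stop("tokens and similarity matrix disagree on m")
  if (any(S_target < 0 | S_target > 1)) {
    stop("similarity target must lie in [0, 1]; apply distance_to_similarity()")
  }
  N_sim <- normalize_adjacency(S_target, variant)
  params_tf <- transformer_init(tf_cfg)
  gcn <- selfcorr_init(m, hidden, seed = seed)
  gcn_pars <- list(Er = gcn$Er,
                   sim = gcn$branches$sim, st = gcn$branches$st)
  st_gcn <- adam_init(gcn_pars)
  st_tf <- adam_init(params_tf)

  refresh <- function() {
    U <- encode_sequences(tokens, params_tf, tf_cfg)
    sg <- suppressWarnings(build_structure_graph(U, threshold))
    list(U = U, G = unclass(sg)[seq_len(m), seq_len(m)],
         prox = attr(sg, "proximity"), rng = attr(sg, "range"),
         N = normalize_adjacency(unclass(sg)[seq_len(m), seq_len(m)], variant))
  }
  sg <- refresh()
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    loss_sim = numeric(0), loss_st = numeric(0))

  for (e in seq_len(epochs)) {
    refresh_now <- e == 1L ||
      (is.finite(refresh_every) && (e - 1L) %% refresh_every == 0L)
    if (refresh_now && e > 1L) sg <- refresh()

    fw_s <- selfcorr_forward(NULL, gcn_pars$Er, gcn_pars$sim, gcn$alphas,
                             N = N_sim, cache = TRUE)
    fw_g <- selfcorr_forward(NULL, gcn_pars$Er, gcn_pars$st, gcn$alphas,
                             N = sg$N, cache = TRUE)
    logit_s <- tcrossprod(fw_s$out)
    logit_g <- tcrossprod(fw_g$out)
    loss_s <- bce_from_logits(logit_s, S_target)
    loss_g <- bce_from_logits(logit_g, sg$G)
    loss <- loss_s + loss_g
    if (!is.finite(loss)) {
      stop("NaN/Inf loss at epoch ", e, " (loss_sim = ", loss_s,
           ", loss_st = ", loss_g, ")")
    }
    log[e, ] <- list(e, loss, loss_s, loss_g)
    if (verbose && (e == 1L || e %% 10L == 0L)) {
      message(sprintf("epoch %d: loss %.5f (sim %.5f, st %.5f)", e,
                      loss, loss_s, loss_g))
    }

    dl_s <- (stats::plogis(logit_s) - S_target) / m^2
    dl_g <- (stats::plogis(logit_g) - sg$G) / m^2
    bk_s <- selfcorr_backward(fw_s, gcn_pars$Er, gcn_pars$sim, gcn$alphas,
                              (dl_s + t(dl_s)) %*% fw_s$out)
    bk_g <- selfcorr_backward(fw_g, gcn_pars$Er, gcn_pars$st, gcn$alphas,
                              (dl_g + t(dl_g)) %*% fw_g$out)
    grads <- list(Er = bk_s$dEr + bk_g$dEr,
                  sim = list(W = bk_s$dW, P = bk_s$dP),
                  st = list(W = bk_g$dW, P = bk_g$dP))
    up <- adam_step(gcn_pars, grads, st_gcn, lr)
    gcn_pars <- up$pars; st_gcn <- up$state

    if (refresh_now && diff(sg$rng) > 0) {
      # straight-through: d(loss)/d(binary target) evaluated at the target,
      # passed to the continuous proximity, then to the pooled embeddings.
      dT <- -logit_g / m^2
      diag(dT) <- 0
      dD <- -dT / diff(sg$rng)
      dDsym <- dD + t(dD)
      dU <- matrix(0, m, tf_cfg$d_model)
      U <- sg$U
      for (i in seq_len(m)) {
        Sg <- sign(sweep(U, 2L, U[i, ], `-`))   # sign(u_j - u_i), m x d
        dU[i, ] <- -colSums(dDsym[i, ] * Sg)
      }
      g_tf <- transformer_backward(tokens, params_tf, tf_cfg, dU)
      up <- adam_step(params_tf, g_tf, st_tf, lr)
      params_tf <- up$pars; st_tf <- up$state
    }
  }

  if (epochs >= 20L) {
    k <- min(10L, epochs %/% 2L)
    if (mean(utils::tail(log$loss, k)) >= mean(utils::head(log$loss, k))) {
      warning("reconstruction loss did not decrease over training")
    }
  }

  structure(list(e_sm = fw_s$out, e_st = fw_g$out, G_st = sg$G,
                 Er = gcn_pars$Er,
                 gcn = list(branches = list(sim = gcn_pars$sim,
                                            st = gcn_pars$st),
                            alphas = gcn$alphas, hidden = hidden),
                 params_tf = params_tf, tf_cfg = tf_cfg,
                 threshold = threshold, variant = variant,
                 log = log),
            class = "m6a_embeddings")
}

#' @export
print.m6a_embeddings <- function(x, ...) {
  cat("m6a_embeddings:", nrow(x$e_sm), "sequences, width", ncol(x$e_sm),
      "\n  final loss:", signif(utils::tail(x$log$loss, 1), 6),
      "over", nrow(x$log), "epochs\n")
  invisible(x)
}
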