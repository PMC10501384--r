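# End-to-end orchestration: encoding -> similarity graph -> structure
# graph -> graph autoencoder -> fusion -> cross-validated classification.

#' Pipeline configuration
#'
#' Collects every tunable of the representation pipeline. Defaults follow
#' the method's reported setting (3-mers, three GCN layers, learning rate
#' 1e-4, transformer embedding 32 / feed-forward 128 / six blocks).
#'
#' @param K k-mer length (default 3).
#' @param similarity distance-to-affinity transform,
#'   `"rbf"` or `"max_complement"`.
#' @param threshold structure-graph proximity cutoff (default 0.5).
#' @param hidden GCN layer widths (default `c(128, 64, 64)`).
#' @param epochs autoencoder training epochs (default 200).
#' @param lr Adam learning rate (default 1e-4).
#' @param refresh_every structure-graph refresh period (default 10).
#' @param variant graph convolution variant (see [gcn_layer()]).
#' @param fusion_epochs auxiliary fusion-training epochs (default 50;
#'   0 leaves the blocks as seeded fixed mixers).
#' @param fusion_lr fusion learning rate (default 1e-3).
#' @param tf a [transformer_config()].
#' @param seed master seed for all parameter initialization.
#' @return List of class `m6a_config`.
#' @export
m6a_config <- function(K = 3L, similarity = c("rbf", "max_complement"),
                       threshold = 0.5, hidden = c(128L, 64L, 64L),
                       epochs = 200L, lr = 1e-4, refresh_every = 10L,
                       variant = "sym_norm", fusion_epochs = 50L,
                       fusion_lr = 1e-3, tf = transformer_config(),
                       seed = 1L) {
  similarity <- match.arg(similarity)
  structure(list(K = as.integer(K), similarity = similarity,
                 threshold = threshold, hidden = as.integer(hidden),
                 epochs = as.integer(epochs), lr = lr,
                 refresh_every = refresh_every, variant = variant,
                 fusion_epochs = as.integer(fusion_epochs),
                 fusion_lr = fusion_lr, tf = tf, seed = as.integer(seed)),
            class = "m6a_config")
}

#' Learn the full sequence representation
#'
#' Runs the label-free representation stack on a window set: 3-mer
#' encoding, Manhattan distance matrix, `[0, 1]` similarity transform,
#' transformer token encoding with structure-graph extraction, joint
#' graph-autoencoder training, and (optionally) auxiliary training of the
#' fusion blocks. Labels, if present, are never seen by this stage.
#'
#' @param x an [rna_set].
#' @param config an [m6a_config()].
#' @param verbose print training progress.
#' @return Object of class `m6a_representation`: list with the k-mer
#'   matrix `e_km`, distance matrix `D`, similarity `S`, trained
#'   autoencoder `fit` (see [train_embeddings()]), fusion `model`, and
#'   the input `set`.
#' @export
m6a_represent <- function(x, config = m6a_config(), verbose = FALSE) {
  stopifnot(inherits(x, "rna_set"))
  e_km <- kmer_encode(x, config$K)
  D <- kmer_distance_matrix(e_km)
  S <- distance_to_similarity(D, config$similarity)
  tokens <- tokenize(x)
  fit <- train_embeddings(S, tokens, tf_cfg = config$tf,
                          hidden = config$hidden, epochs = config$epochs,
                          lr = config$lr,
                          refresh_every = config$refresh_every,
                          threshold = config$threshold,
                          variant = config$variant, seed = config$seed,
                          verbose = verbose)
  model <- fusion_init(utils::tail(config$hidden, 1L), ncol(e_km),
                       seed = config$seed)
  model <- train_fusion(model, fit$e_sm, fit$e_st, e_km, S,
                        epochs = config$fusion_epochs,
                        lr = config$fusion_lr)
  structure(list(set = x, e_km = e_km, D = D, S = S, fit = fit,
                 model = model, config = config),
            class = "m6a_representation")
}

#' @export
print.m6a_representation <- function(x, ...) {
  cat("m6a_representation:", x$set$m, "sequences\n")
  print(x$fit)
  invisible(x)
}

#' Extract classifier features from a learned representation
#'
#' @param rep an [m6a_represent()] result.
#' @param mode ablation mode, see [fused_features()].
#' @return m-row feature matrix.
#' @export
m6a_feature_matrix <- function(rep, mode = "full") {
  stopifnot(inherits(rep, "m6a_representation"))
  fused_features(rep$fit$e_sm, rep$fit$e_st, rep$e_km, rep$model, mode)
}

# Inductive variant: representation learned on training indices only;
# held-out sequences adopt the branch embeddings of their nearest
# training neighbor (k-mer L1), keeping their own k-mer vector.
inductive_features <- function(x, train_idx, config, mode = "full") {
  rep_tr <- m6a_represent(x[train_idx], config)
  e_km_all <- kmer_encode(x, config$K)
  te <- setdiff(seq_len(x$m), train_idx)
  nn <- vapply(te, function(i) {
    dists <- colSums(abs(t(rep_tr$e_km) - e_km_all[i, ]))
    which.min(dists)
  }, integer(1))
  e_sm <- matrix(NA_real_, x$m, ncol(rep_tr$fit$e_sm))
  e_st <- e_sm
  e_sm[train_idx, ] <- rep_tr$fit$e_sm
  e_st[train_idx, ] <- rep_tr$fit$e_st
  e_sm[te, ] <- rep_tr$fit$e_sm[nn, , drop = FALSE]
  e_st[te, ] <- rep_tr$fit$e_st[nn, , drop = FALSE]
  fused_features(e_sm, e_st, e_km_all, rep_tr$model, mode)
}

#' Run the full recognition pipeline with cross-validation
#'
#' Learns the representation, extracts fused features and evaluates them
#' by stratified k-fold cross-validation. The default evaluation is
#' transductive: the similarity matrix and embeddings are built over the
#' full (unlabelled) sequence set before the folds are scored, matching
#' how graph-based site recognizers are usually evaluated. The
#' `"inductive"` mode instead restricts representation learning to each
#' training fold and attaches test sequences to their nearest training
#' neighbor; it is slower but leak-free.
#'
#' @param x a labelled [rna_set].
#' @param config an [m6a_config()].
#' @param classifier downstream classifier (default `"rf"`).
#' @param folds number of CV folds (default 10).
#' @param mode feature ablation mode (default `"full"`).
#' @param evaluation `"transductive"` (default) or `"inductive"`.
#' @param verbose print progress.
#' @return Object of class `m6a_result`: list with the `representation`
#'   (transductive only), feature matrix `X`, the `plan`, the fold-wise
#'   `report` (see [cross_validate()]), and the settings used.
#' @export
m6a_run <- function(x, config = m6a_config(), classifier = "rf",
                    folds = 10L, mode = "full",
                    evaluation = c("transductive", "inductive"),
                    verbose = FALSE) {
  evaluation <- match.arg(evaluation)
  if (anyNA(x$label)) stop("classification requires a label for every record")
  plan <- cv_plan(x$label, folds, seed = config$seed)
  if (evaluation == "transductive") {
    rep <- m6a_represent(x, config, verbose = verbose)
    X <- m6a_feature_matrix(rep, mode)
    report <- cross_validate(X, x$label, plan, classifier,
                             seed = config$seed)
  } else {
    rep <- NULL
    rows <- vector("list", plan$folds)
    X <- NULL
    for (k in seq_len(plan$folds)) {
      tr <- which(plan$assignment != k)
      Xk <- inductive_features(x, tr, config, mode)
      te <- plan$assignment == k
      scores <- fit_predict(classifier, Xk[tr, , drop = FALSE],
                            x$label[tr], Xk[te, , drop = FALSE],
                            seed = config$seed + k)
      rows[[k]] <- fold_metric_row(scores, x$label[te])
    }
    M <- do.call(rbind, rows)
    report <- as.data.frame(rbind(M, colMeans(M)))
    report <- cbind(Fold = c(as.character(seq_len(plan$folds) - 1L), "Mean"),
                    report)
  }
  structure(list(representation = rep, X = X, plan = plan, report = report,
                 classifier = classifier, mode = mode,
                 evaluation = evaluation, config = config),
            class = "m6a_result")
}

#' @export
print.m6a_result <- function(x, ...) {
  cat("m6a_result (", x$evaluation, ", ", x$classifier, ", mode ",
      x$mode, ")\n", sep = "")
  print(x$report, row.names = FALSE, digits = 4)
  invisible(x)
}
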