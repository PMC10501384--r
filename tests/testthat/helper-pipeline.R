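# Shared benchmark fixtures for the end-to-end tests. Representations are
# expensive, so they are computed once per difficulty level and cached
# for the whole test run. The benchmark profile (reduced encoder,
# converging learning rate; see the methods vignette) and the seeds are
# fixed study conditions.

BENCH_SEED <- 101L      # generator
PROFILE_SEED <- 11L     # parameter initialization / folds

profile_config <- function(seed = PROFILE_SEED) {
  m6a_config(epochs = 100L, lr = 5e-3, refresh_every = 20L,
             fusion_epochs = 100L, fusion_lr = 1e-2,
             tf = transformer_config(d_model = 16L, heads = 2L,
                                     ff_dim = 64L, blocks = 2L,
                                     seed = seed),
             seed = seed)
}

.bench_cache <- new.env(parent = emptyenv())

bench_representation <- function(eps, m = 1000L) {
  key <- sprintf("rep_%g_%d", eps, m)
  if (is.null(.bench_cache[[key]])) {
    d <- synth_generate(synth_config(m = m, eps = eps, seed = BENCH_SEED))
    .bench_cache[[key]] <- list(
      rep = m6a_represent(d$sequences, profile_config()),
      y = d$sequences$label,
      plan = cv_plan(d$sequences$label, 10L, seed = PROFILE_SEED))
  }
  .bench_cache[[key]]
}

bench_cv_auc <- function(eps, mode = "full", m = 1000L) {
  key <- sprintf("auc_%g_%s_%d", eps, mode, m)
  if (is.null(.bench_cache[[key]])) {
    b <- bench_representation(eps, m)
    X <- m6a_feature_matrix(b$rep, mode)
    rep <- cross_validate(X, b$y, b$plan, "rf", seed = PROFILE_SEED)
    .bench_cache[[key]] <- rep$AUC[rep$Fold == "Mean"]
  }
  .bench_cache[[key]]
}
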