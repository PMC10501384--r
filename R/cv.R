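# Stratified cross-validation, classifier wrappers and the fold-wise
# metric report.

#' Stratified cross-validation plan
#'
#' Partitions sample indices into `folds` non-overlapping test sets of
#' (near-)equal size. With `stratified = TRUE` (default) each class is
#' distributed round-robin after a seeded shuffle, so every fold keeps
#' the class balance and no training fold can lose a class.
#'
#' @param y binary 0/1 label vector.
#' @param folds number of folds (default 10).
#' @param seed integer seed.
#' @param stratified stratify by class (default TRUE).
#' @return Object of class `cv_plan`: list with `folds`, `assignment`
#'   (fold id per sample), `seed`, `stratified`.
#' @export
cv_plan <- function(y, folds = 10L, seed = 1L, stratified = TRUE) {
  y <- as.integer(y)
  stopifnot(folds >= 2, length(y) >= folds)
  assignment <- integer(length(y))
  with_seed(seed, {
    if (stratified) {
      for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        assignment[idx] <- rep_len(seq_len(folds), length(idx))
      }
    } else {
      assignment[sample(seq_along(y))] <- rep_len(seq_len(folds), length(y))
    }
  })
  structure(list(folds = as.integer(folds), assignment = assignment,
                 seed = as.integer(seed), stratified = stratified),
            class = "cv_plan")
}

classifier_backends <- c(rf = "randomForest", lr = "stats",
                         xgboost = "xgboost", svm = "e1071",
                         lightgbm = "lightgbm", catboost = "catboost")

classifier_available <- function(method) {
  pkg <- classifier_backends[[method]]
  !is.null(pkg) && requireNamespace(pkg, quietly = TRUE)
}

# Train one classifier and return positive-class probabilities on Xte.
fit_predict <- function(method, Xtr, ytr, Xte, seed = 1L) {
  f <- factor(ytr, levels = c(0, 1))
  with_seed(seed, switch(method,
    rf = {
      fit <- randomForest::randomForest(x = Xtr, y = f, ntree = 500L)
      unname(stats::predict(fit, Xte, type = "prob")[, "1"])
    },
    lr = {
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, Xtr), ytr, family = stats::binomial()))
      beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      unname(stats::plogis(drop(cbind(1, Xte) %*% beta)))
    },
    xgboost = {
      dtr <- xgboost::xgb.DMatrix(Xtr, label = ytr)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 4L,
                      eta = 0.3, nthread = 1L, seed = seed),
        data = dtr, nrounds = 100L, verbose = 0)
      unname(stats::predict(fit, xgboost::xgb.DMatrix(Xte)))
    },
    svm = {
      fit <- e1071::svm(x = Xtr, y = f, probability = TRUE,
                        kernel = "radial")
      pr <- stats::predict(fit, Xte, probability = TRUE)
      unname(attr(pr, "probabilities")[, "1"])
    },
    stop("unknown classifier: ", method)
  ))
}

fold_metric_row <- function(scores, ytest, threshold = 0.5) {
  cm <- compute_metrics(confusion_counts(as.integer(scores > threshold),
                                         ytest))
  cv <- roc_pr(scores, ytest)
  c(MCC = unname(cm["MCC"]), Acc = unname(cm["Acc"]), Sn = unname(cm["Sn"]),
    Sp = unname(cm["Sp"]), Prec = unname(cm["Prec"]), F1 = unname(cm["F1"]),
    AUC = cv$auc, AUPR = cv$aupr)
}

#' Cross-validated metric report
#'
#' Trains the classifier on nine folds and evaluates on the tenth, for
#' every fold of the plan, then appends the arithmetic mean row. Class
#' labels are predicted at probability 0.5; AUC/AUPR use the
#' positive-class scores.
#'
#' @param X feature matrix (m rows).
#' @param y binary 0/1 labels.
#' @param plan a [cv_plan()] (default: stratified 10-fold, seed 1).
#' @param classifier one of `"rf"`, `"lr"`, `"xgboost"`, `"svm"`.
#' @param seed seed for classifier training.
#' @return Data frame with a `Fold` column (`"0"`..`"k-1"`, then
#'   `"Mean"`) and columns MCC, Acc, Sn, Sp, Prec, F1, AUC, AUPR.
#' @export
cross_validate <- function(X, y, plan = cv_plan(y), classifier = "rf",
                           seed = 1L) {
  X <- as.matrix(X); y <- as.integer(y)
  stopifnot(nrow(X) == length(y), length(plan$assignment) == length(y))
  if (anyNA(y)) stop("labels required for cross-validation")
  rows <- matrix(NA_real_, plan$folds, 8L)
  for (k in seq_len(plan$folds)) {
    te <- plan$assignment == k
    if (length(unique(y[!te])) < 2L || length(unique(y[te])) < 2L) {
      stop("fold ", k, " has a single class; use a stratified cv_plan()")
    }
    scores <- fit_predict(classifier, X[!te, , drop = FALSE], y[!te],
                          X[te, , drop = FALSE], seed = seed + k)
    rows[k, ] <- fold_metric_row(scores, y[te])
  }
  out <- as.data.frame(rbind(rows, colMeans(rows)))
  names(out) <- c("MCC", "Acc", "Sn", "Sp", "Prec", "F1", "AUC", "AUPR")
  cbind(Fold = c(as.character(seq_len(plan$folds) - 1L), "Mean"), out)
}

#' Paired classifier sweep
#'
#' Runs [cross_validate()] for several classifiers on the *same* folds
#' (paired design) and tabulates per-fold AUC, one column per classifier.
#' Classifiers whose backend package is not installed are skipped with a
#' warning; the random-forest column is always produced.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param plan a [cv_plan()].
#' @param classifiers classifier names to try.
#' @param seed seed for classifier training.
#' @return Data frame with `Fold` (`"Fold1"`...) rows and one AUC column
#'   per available classifier.
#' @export
classifier_sweep <- function(X, y, plan = cv_plan(y),
                             classifiers = c("rf", "lr", "xgboost", "svm",
                                             "lightgbm", "catboost"),
                             seed = 1L) {
  classifiers <- unique(c("rf", classifiers))
  out <- data.frame(Fold = paste0("Fold", seq_len(plan$folds)))
  for (cl in classifiers) {
    if (!classifier_available(cl)) {
      warning("classifier backend for '", cl, "' is not installed; skipping")
      next
    }
    rep <- cross_validate(X, y, plan, classifier = cl, seed = seed)
    out[[cl]] <- rep$AUC[seq_len(plan$folds)]
  }
  out
}
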