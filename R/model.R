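# Classifier families, hyperparameter grids, cross-validated grid search,
# metric suite and the repeated stratified split protocol.

#' Default hyperparameter grid for a model family
#'
#' SVM (RBF kernel, balanced class weights): penalty
#' `C in {0.1, 1, 10, 100, 1000, 10000}` crossed with kernel coefficient
#' `gamma in (1/n_features) * {1, 10, 100, 1000}`.  kNN:
#' `n_neighbors in 3..9` crossed with Minkowski `p in {1, 2}` (the
#' tree-index `leaf_size` is recorded as a constant -- it cannot change
#' predictions).  RF (Gini split criterion):
#' `max_depth in {3, 10, unbounded}`, `min_samples_split in
#' {10, 30, 50, 70, 90}`, `max_features in {sqrt, log2}`,
#' `n_estimators in {100, 300, 500}`.  GBT is a fixed configuration:
#' learning rate 0.1, depth 10, 1000 trees.
#'
#' @param family `"svm"`, `"knn"`, `"rf"` or `"gbt"`.
#' @param n_features feature count after any selection/reduction (sets the
#'   SVM gamma grid base `1/n_features`).
#' @return data frame, one row per configuration.
#' @export
default_grid <- function(family = c("svm", "knn", "rf", "gbt"),
                         n_features = NULL) {
  family <- match.arg(family)
  switch(family,
    svm = {
      if (is.null(n_features) || n_features < 1)
        stop("validation error: n_features required for the svm grid")
      expand.grid(cost = c(0.1, 1, 10, 100, 1000, 10000),
                  gamma = (1 / n_features) * c(1, 10, 100, 1000))
    },
    knn = {
      g <- expand.grid(n_neighbors = 3:9, p = c(1, 2))
      g$leaf_size <- 30L
      g
    },
    rf = expand.grid(max_depth = c(3, 10, 0),     # 0 = unbounded
                     min_samples_split = c(10, 30, 50, 70, 90),
                     max_features = c("sqrt", "log2"),
                     n_estimators = c(100, 300, 500),
                     stringsAsFactors = FALSE),
    gbt = data.frame(eta = 0.1, max_depth = 10, nrounds = 1000))
}

# crude check that a matrix has been through standardize()/pca_reduce()
looks_scaled <- function(X) {
  isTRUE(attr(X, "standardized")) || all(abs(colMeans(X)) < 0.5)
}

# stratified fold assignment
make_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# stratified train/test split preserving class proportions within 1 sample
stratified_split <- function(y, test_fraction, seed) {
  set.seed(seed)
  test <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_test <- round(length(idx) * test_fraction)
    test <- c(test, sample(idx, n_test))
  }
  sort(test)
}

fit_one <- function(X, y, family, par, seed) {
  yf <- factor(y, levels = c(0, 1))
  fit <- switch(family,
    svm = {
      tab <- table(yf)
      cw <- sum(tab) / (2 * tab)   # "balanced" class weighting
      e1071::svm(x = X, y = yf, kernel = "radial", cost = par$cost,
                 gamma = par$gamma, class.weights = cw, scale = FALSE)
    },
    knn = list(Xtr = X, ytr = as.integer(as.character(yf)),
               k = par$n_neighbors, p = par$p),
    rf = {
      p <- ncol(X)
      mtry <- if (par$max_features == "sqrt") max(1, floor(sqrt(p)))
              else max(1, floor(log2(p)))
      ranger::ranger(x = X, y = yf, num.trees = par$n_estimators,
                     mtry = mtry, min.node.size = par$min_samples_split,
                     max.depth = par$max_depth, splitrule = "gini",
                     probability = TRUE, seed = seed, num.threads = 1)
    },
    gbt = {
      set.seed(seed)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = par$eta,
                      max_depth = par$max_depth, nthread = 1),
        data = xgboost::xgb.DMatrix(X, label = as.integer(as.character(yf))),
        nrounds = par$nrounds, verbose = 0)
    })
  structure(list(family = family, params = par, fit = fit),
            class = "pf_model")
}

#' Continuous class-1 score of a fitted model
#'
#' SVM: signed decision value oriented towards class 1.  kNN: fraction of
#' the k nearest training neighbours labeled 1 (Minkowski distance of order
#' `p`).  RF: out-of-bag-free predicted class-1 probability.  GBT: predicted
#' probability.
#'
#' @param model a `pf_model` from [fit_one()]/[grid_search_fit()].
#' @param X feature matrix to score.
#' @return numeric score vector (higher means more class-1-like).
#' @export
predict_score <- function(model, X) {
  X <- as.matrix(X)
  switch(model$family,
    svm = {
      p <- predict(model$fit, X, decision.values = TRUE)
      dv <- attr(p, "decision.values")
      s <- as.numeric(dv[, 1])
      # libsvm orients the value towards the class named first in the
      # column label "a/b": positive means class a
      if (startsWith(colnames(dv)[1], "0/")) s <- -s
      s
    },
    knn = {
      m <- model$fit
      apply(X, 1, function(x) {
        d <- if (m$p == 2) sqrt(colSums((t(m$Xtr) - x)^2))
             else colSums(abs(t(m$Xtr) - x))
        mean(m$ytr[order(d)[seq_len(m$k)]])
      })
    },
    rf = predict(model$fit, X, num.threads = 1)$predictions[, "1"],
    gbt = predict(model$fit, xgboost::xgb.DMatrix(X)))
}

predict_class <- function(model, X) {
  s <- predict_score(model, X)
  thr <- if (model$family == "svm") 0 else 0.5
  as.integer(s > thr)
}

#' Exhaustive grid search with stratified k-fold cross-validation
#'
#' Evaluates every configuration of the family's grid by mean
#' cross-validation accuracy over stratified folds, refits the best
#' configuration (first in enumeration order on ties) on the full training
#' set and returns the fitted model.  SVM and kNN refuse input that does not
#' look standardized unless `allow_unscaled = TRUE`; tree families accept
#' raw features.
#'
#' @param X training feature matrix.
#' @param y binary 0/1 labels.
#' @param family model family.
#' @param grid hyperparameter grid (default [default_grid()] with the gamma
#'   base computed from `ncol(X)`).
#' @param folds number of cross-validation folds.
#' @param seed integer seed (fold assignment and tree models).
#' @param allow_unscaled override the scaling guard for SVM/kNN.
#' @return a `pf_model` with elements `cv_accuracy`, `cv_table` (accuracy per
#'   configuration) and `params` (the winning row).
#' @export
grid_search_fit <- function(X, y, family = c("svm", "knn", "rf", "gbt"),
                            grid = NULL, folds = 5, seed = 1L,
                            allow_unscaled = FALSE) {
  family <- match.arg(family)
  X <- as.matrix(X)
  y <- as.integer(as.character(y))
  if (family %in% c("svm", "knn") && !allow_unscaled && !looks_scaled(X))
    stop("validation error: ", family, " requires standardized input ",
         "(use standardize(); override with allow_unscaled = TRUE)")
  if (is.null(grid)) grid <- default_grid(family, n_features = ncol(X))
  fold <- make_folds(y, folds, seed)
  if (any(tapply(y, fold, function(z) length(unique(z))) < 2))
    stop("validation error: degenerate fold without both classes")

  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    par <- grid[g, , drop = FALSE]
    hits <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f
      m <- fit_one(X[tr, , drop = FALSE], y[tr], family, par, seed)
      hits <- hits + sum(predict_class(m, X[!tr, , drop = FALSE]) == y[!tr])
    }
    acc[g] <- hits / length(y)
  }
  best <- which.max(acc)          # first maximum wins on ties
  model <- fit_one(X, y, family, grid[best, , drop = FALSE], seed)
  model$cv_accuracy <- acc[best]
  model$cv_table <- cbind(grid, cv_accuracy = acc)
  model
}

#' Evaluate a fitted model on a test set
#'
#' Computes the confusion counts (class 1 positive) and precision, recall,
#' F1, accuracy, sensitivity (= recall), specificity and ROC AUC (from the
#' continuous score ranking; `NA` with a flag when the test set has a single
#' class).
#'
#' @param model a `pf_model`.
#' @param X test feature matrix.
#' @param y test labels.
#' @return object of class `eval_report` (named list of counts and metrics).
#' @export
evaluate_model <- function(model, X, y) {
  y <- as.integer(as.character(y))
  score <- predict_score(model, X)
  pred <- predict_class(model, X)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (is.finite(precision) && is.finite(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  accuracy <- (tp + tn) / length(y)
  specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  auc <- NA_real_
  if (length(unique(y)) == 2) {
    if (length(unique(score)) == 1) {
      auc <- 0.5                       # uninformative constant score
    } else {
      auc <- as.numeric(pROC::auc(pROC::roc(
        response = y, predictor = score, levels = c(0, 1),
        direction = "<", quiet = TRUE)))
    }
  }
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 precision = precision, recall = recall, f1 = f1,
                 accuracy = accuracy, sensitivity = recall,
                 specificity = specificity, roc_auc = auc,
                 auc_defined = length(unique(y)) == 2,
                 params = model$params, family = model$family),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s: acc %.3f, F1 %.3f, ROC AUC %s\n",
              x$family, x$accuracy,
              ifelse(is.na(x$f1), NA, x$f1),
              ifelse(is.na(x$roc_auc), "NA", sprintf("%.3f", x$roc_auc))))
  invisible(x)
}

#' Repeated stratified split protocol
#'
#' For each of `rounds` iterations: stratified 70/30 train/test split,
#' optional in-fold balancing, scaling (automatic for SVM/kNN), optional PCA
#' or top-k feature selection (all fit on the training subset only),
#' exhaustive grid search with stratified cross-validation on the training
#' subset, evaluation of the refit best model on the test subset.  Reports
#' per-round metrics and their means.
#'
#' @param dataset a `labeled_dataset` or a list with `X` and `y`.
#' @param family model family.
#' @param rounds number of repeated splits.
#' @param test_fraction held-out fraction per round.
#' @param seed integer seed; round `r` derives `seed + r`.
#' @param n_components optional PCA dimension.
#' @param rank_method,top_k optional feature selection (mutually exclusive
#'   with `n_components`).
#' @param grid optional explicit hyperparameter grid.
#' @param folds cross-validation folds inside the grid search.
#' @param balance optional [balance_config()] applied inside each round's
#'   training subset (the default `NULL` assumes the dataset was balanced
#'   beforehand, matching the reference protocol).
#' @return object of class `protocol_report`: list with `rounds` (data
#'   frame of per-round metrics), `mean` (named metric means), `family`,
#'   `best_params` (per round).
#' @export
repeated_protocol <- function(dataset, family = c("svm", "knn", "rf", "gbt"),
                              rounds = 10, test_fraction = 0.3, seed = 1L,
                              n_components = NULL, rank_method = NULL,
                              top_k = NULL, grid = NULL, folds = 5,
                              balance = NULL) {
  family <- match.arg(family)
  if (!is.null(n_components) && !is.null(rank_method))
    stop("validation error: choose PCA or feature selection, not both")
  X <- if (inherits(dataset, "labeled_dataset")) dataset$X else dataset$X
  y <- as.integer(as.character(dataset$y))
  needs_scale <- family %in% c("svm", "knn")

  metric_names <- c("precision", "recall", "f1", "accuracy", "sensitivity",
                    "specificity", "roc_auc")
  out <- vector("list", rounds)
  best <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    rs <- seed + r
    te <- stratified_split(y, test_fraction, rs)
    Xtr <- X[-te, , drop = FALSE]; ytr <- y[-te]
    Xte <- X[te, , drop = FALSE];  yte <- y[te]
    if (!is.null(balance)) {
      cfg <- balance
      cfg$seed <- cfg$seed + rs
      b <- balance_classes(Xtr, ytr, cfg)
      Xtr <- b$X; ytr <- b$y
    }
    if (needs_scale) {
      s <- standardize(Xtr, Xte)
      Xtr <- s$train; Xte <- s$test
    }
    if (!is.null(n_components)) {
      p <- pca_reduce(Xtr, n_components, Xte)
      Xtr <- p$train; Xte <- p$test
    }
    if (!is.null(rank_method)) {
      keep <- rank_features(Xtr, ytr, rank_method, k = top_k, seed = rs)
      Xtr <- Xtr[, keep, drop = FALSE]
      Xte <- Xte[, keep, drop = FALSE]
      attr(Xtr, "standardized") <- needs_scale
    }
    model <- grid_search_fit(Xtr, ytr, family, grid = grid, folds = folds,
                             seed = rs, allow_unscaled = !needs_scale)
    rep_r <- evaluate_model(model, Xte, yte)
    out[[r]] <- unlist(rep_r[metric_names])
    best[[r]] <- model$params
  }
  rounds_df <- as.data.frame(do.call(rbind, out))
  rounds_df$round <- seq_len(rounds)
  structure(list(rounds = rounds_df,
                 mean = colMeans(rounds_df[metric_names], na.rm = TRUE),
                 family = family, best_params = best),
            class = "protocol_report")
}

#' @export
print.protocol_report <- function(x, ...) {
  cat(sprintf("<protocol_report> %s over %d rounds\n", x$family,
              nrow(x$rounds)))
  print(round(x$mean, 4))
  invisible(x)
}
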