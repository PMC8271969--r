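# Feature-ranking methods for top-k selection.

#' Rank features by relevance to the label
#'
#' Methods: `pearson` ranks by the absolute Pearson correlation between
#' feature and label; `l1` by order of entry along an L1-penalised logistic
#' regularisation path (ties by final coefficient magnitude); `tree_importance`
#' by random-forest impurity importance; `gradient_importance` by
#' gradient-boosting gain; `rfe` by recursive feature elimination (step 1)
#' with a ranking model refit after each removal.
#'
#' @param X feature matrix with column names.
#' @param y binary 0/1 label vector.
#' @param method ranking method.
#' @param k how many top features to return.
#' @param seed integer seed (tree and boosting methods).
#' @param rfe_model model family used inside `rfe`: `"svm"` (linear-kernel
#'   weight magnitudes) or `"rf"` (impurity importance).
#' @return character vector of the top-`k` column names, best first.
#' @export
rank_features <- function(X, y,
                          method = c("pearson", "l1", "tree_importance",
                                     "gradient_importance", "rfe"),
                          k = ncol(X), seed = 1L,
                          rfe_model = c("svm", "rf")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (k > ncol(X)) stop("validation error: k exceeds the number of features")
  y <- as.integer(as.character(y))

  ranking <- switch(
    method,
    pearson = {
      r <- suppressWarnings(abs(cor(X, y)))[, 1]
      r[!is.finite(r)] <- 0
      colnames(X)[order(-r)]
    },
    l1 = {
      Z <- scale(X)
      Z[!is.finite(Z)] <- 0
      fit <- glmnet::glmnet(Z, factor(y), family = "binomial", alpha = 1,
                            standardize = FALSE)
      B <- as.matrix(fit$beta)
      entry <- apply(B != 0, 1, function(z) {
        w <- which(z)
        if (length(w)) w[1] else ncol(B) + 1L
      })
      final <- abs(B[, ncol(B)])
      colnames(X)[order(entry, -final)]
    },
    tree_importance = {
      set.seed(seed)
      fit <- ranger::ranger(x = X, y = factor(y), num.trees = 500,
                            importance = "impurity", seed = seed,
                            num.threads = 1)
      colnames(X)[order(-fit$variable.importance)]
    },
    gradient_importance = {
      set.seed(seed)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = 0.3,
                      max_depth = 6, nthread = 1),
        data = xgboost::xgb.DMatrix(X, label = y), nrounds = 100,
        verbose = 0)
      imp <- xgboost::xgb.importance(model = fit)
      sc <- setNames(rep(0, ncol(X)), colnames(X))
      sc[imp$Feature] <- imp$Gain
      colnames(X)[order(-sc)]
    },
    rfe = {
      rfe_model <- match.arg(rfe_model)
      remaining <- colnames(X)
      eliminated <- character(0)
      while (length(remaining) > 1) {
        imp <- rfe_importance(X[, remaining, drop = FALSE], y,
                              rfe_model, seed)
        worst <- remaining[which.min(imp)]
        eliminated <- c(worst, eliminated)
        remaining <- setdiff(remaining, worst)
      }
      c(remaining, eliminated)
    })
  head(ranking, k)
}

# Per-feature importance used inside RFE.
rfe_importance <- function(X, y, model, seed) {
  if (model == "svm") {
    s <- standardize(X)
    fit <- e1071::svm(x = s$train, y = factor(y, levels = c(0, 1)),
                      kernel = "linear", scale = FALSE)
    w <- t(fit$coefs) %*% fit$SV
    abs(as.numeric(w))
  } else {
    fit <- ranger::ranger(x = X, y = factor(y), num.trees = 200,
                          importance = "impurity", seed = seed,
                          num.threads = 1)
    as.numeric(fit$variable.importance)
  }
}
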