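# Scaling, PCA, feature ranking, grid search, metrics and the repeated
# protocol.

sep_data <- function(n = 120, p = 6, gap = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * p), ncol = p)
  X[, 1] <- X[, 1] + gap * y
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = y)
}

test_that("standardization uses training statistics only", {
  d <- sep_data()
  Xte <- matrix(rnorm(30 * 6, mean = 5), ncol = 6)
  s <- standardize(d$X, Xte)
  expect_equal(unname(colMeans(s$train)), rep(0, 6), tolerance = 1e-9)
  expect_equal(unname(apply(s$train, 2, sd)), rep(1, 6), tolerance = 1e-9)
  # test matrix scaled with train statistics, not its own
  expect_equal(unname(s$test[1, 1]),
               unname((Xte[1, 1] - s$center[1]) / s$scale[1]))
  expect_gt(abs(mean(s$test[, 1])), 1)
  # constant column passes through centred
  Xc <- cbind(d$X, konst = 7)
  expect_message(s2 <- standardize(Xc), "zero-variance")
  expect_equal(unname(s2$train[, 7]), rep(0, nrow(Xc)))
})

test_that("PCA projects on training axes with non-increasing reconstruction error", {
  d <- sep_data(n = 80, p = 10)
  err <- vapply(c(2, 5, 9), function(k) {
    p <- pca_reduce(d$X, k)
    rec <- p$train %*% t(p$fit$rotation[, 1:k]) +
      matrix(p$fit$center, nrow(d$X), 10, byrow = TRUE)
    sum((rec - d$X)^2)
  }, numeric(1))
  expect_true(all(diff(err) <= 1e-8))
  expect_equal(ncol(pca_reduce(d$X, 3)$train), 3L)
  expect_error(pca_reduce(d$X, 50), "validation error")
})

test_that("feature ranking finds planted signals", {
  d <- sep_data(n = 100, p = 8)
  # a copy of the label is perfectly correlated and must rank first
  X2 <- cbind(d$X, lab = as.numeric(d$y))
  expect_equal(rank_features(X2, d$y, "pearson", k = 1), "lab")
  # planted effect beats pure noise in >= 95% of seeded repeats
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    y <- rep(c(0L, 1L), each = 250)
    X <- matrix(rnorm(500 * 10), ncol = 10,
                dimnames = list(NULL, paste0("v", 1:10)))
    X[, 4] <- X[, 4] + 1.2 * y
    r <- rank_features(X, y, "pearson", k = 1, seed = s)
    r == "v4"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # full-k returns a permutation of the columns
  perm <- rank_features(d$X, d$y, "l1", k = ncol(d$X))
  expect_setequal(perm, colnames(d$X))
  for (m in c("l1", "tree_importance", "gradient_importance", "rfe"))
    expect_equal(rank_features(d$X, d$y, m, k = 1, seed = 2), "f1", label = m)
  expect_error(rank_features(d$X, d$y, "magic"), "arg")
  expect_error(rank_features(d$X, d$y, "pearson", k = 99), "validation error")
})

test_that("the SVM gamma grid follows 1/n_features times powers of ten", {
  g120 <- default_grid("svm", 120)
  expect_equal(sort(unique(g120$gamma)),
               (1 / 120) * c(1, 10, 100, 1000), tolerance = 1e-12)
  expect_true(any(abs(g120$gamma - 0.0833) < 1e-3))
  g40 <- default_grid("svm", 40)
  expect_true(0.25 %in% g40$gamma)
  expect_equal(sort(unique(g120$cost)), c(0.1, 1, 10, 100, 1000, 10000))
  expect_equal(nrow(default_grid("knn")), 14L)   # 7 neighbour counts x 2 p
  expect_equal(nrow(default_grid("rf")), 90L)
  expect_equal(default_grid("gbt"),
               data.frame(eta = 0.1, max_depth = 10, nrounds = 1000))
})

test_that("metrics match the printed formulas on a constructed confusion", {
  # 1-NN on 1-D points reproduces any confusion table we like
  model <- structure(list(family = "knn",
                          params = data.frame(n_neighbors = 1, p = 2),
                          fit = list(Xtr = matrix(c(0, 1)),
                                     ytr = c(0L, 1L), k = 1, p = 2)),
                     class = "pf_model")
  Xte <- matrix(c(rep(1, 40), rep(0, 10), rep(0, 45), rep(1, 5)))
  yte <- rep(c(1L, 1L, 0L, 0L), c(40, 10, 45, 5))
  r <- evaluate_model(model, Xte, yte)
  expect_equal(c(r$TP, r$FN, r$TN, r$FP), c(40, 10, 45, 5))
  expect_equal(r$precision, 8 / 9, tolerance = 1e-12)
  expect_equal(r$recall, 0.8, tolerance = 1e-12)
  expect_equal(r$accuracy, 0.85, tolerance = 1e-12)
  expect_equal(r$specificity, 0.9, tolerance = 1e-12)
  expect_equal(r$f1, 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8), tolerance = 1e-12)
  # identities
  expect_identical(r$recall, r$sensitivity)
  expect_equal(r$f1, 2 * r$precision * r$recall / (r$precision + r$recall),
               tolerance = 1e-12)
})

test_that("perfect and chance classifiers bracket the metric range", {
  model <- structure(list(family = "knn",
                          params = data.frame(n_neighbors = 1, p = 2),
                          fit = list(Xtr = matrix(c(0, 1)),
                                     ytr = c(0L, 1L), k = 1, p = 2)),
                     class = "pf_model")
  Xte <- matrix(rep(c(0, 1), each = 20))
  yte <- rep(c(0L, 1L), each = 20)
  r <- evaluate_model(model, Xte, yte)
  expect_equal(c(r$precision, r$recall, r$f1, r$accuracy, r$specificity,
                 r$roc_auc), rep(1, 6))
  # constant-score classifier: AUC 0.5
  const <- structure(list(family = "knn",
                          params = data.frame(n_neighbors = 1, p = 2),
                          fit = list(Xtr = matrix(c(0, 0.001)),
                                     ytr = c(1L, 1L), k = 2, p = 2)),
                     class = "pf_model")
  rc <- evaluate_model(const, Xte, yte)
  expect_equal(rc$roc_auc, 0.5)
  # single-class test set: AUC flagged missing
  r1 <- evaluate_model(model, Xte[1:20, , drop = FALSE], yte[1:20])
  expect_true(is.na(r1$roc_auc))
  expect_false(r1$auc_defined)
})

test_that("grid search refuses unscaled input for distance models only", {
  d <- sep_data(n = 60)
  Xraw <- d$X + 100                      # blatantly uncentred
  expect_error(grid_search_fit(Xraw, d$y, "svm",
                               grid = data.frame(cost = 1, gamma = 0.1)),
               "standardized")
  s <- standardize(Xraw)
  fit <- grid_search_fit(s$train, d$y, "svm",
                         grid = data.frame(cost = 1, gamma = 0.1), seed = 2)
  expect_s3_class(fit, "pf_model")
  expect_equal(fit$params$cost, 1)
  # singleton grid returns that configuration; trees accept raw features
  fit_rf <- grid_search_fit(Xraw, d$y, "rf",
                            grid = data.frame(max_depth = 3,
                                              min_samples_split = 10,
                                              max_features = "sqrt",
                                              n_estimators = 50),
                            seed = 2)
  expect_equal(fit_rf$params$n_estimators, 50)
  expect_true(all(fit_rf$cv_table$cv_accuracy >= 0.9))
  # boosted trees run with their fixed-parameter style configuration
  fit_gbt <- grid_search_fit(Xraw, d$y, "gbt",
                             grid = data.frame(eta = 0.3, max_depth = 3,
                                               nrounds = 25),
                             seed = 2)
  sc <- predict_score(fit_gbt, Xraw)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_gt(evaluate_model(fit_gbt, Xraw, d$y)$accuracy, 0.9)
})

test_that("fitted statistics never depend on test rows", {
  d <- sep_data(n = 80)
  teA <- matrix(rnorm(20 * 6), ncol = 6)
  teB <- matrix(rnorm(20 * 6, mean = 50), ncol = 6)
  sA <- standardize(d$X, teA); sB <- standardize(d$X, teB)
  expect_identical(sA$center, sB$center)
  expect_identical(sA$scale, sB$scale)
  expect_identical(sA$train, sB$train)
  pA <- pca_reduce(d$X, 3, teA); pB <- pca_reduce(d$X, 3, teB)
  expect_identical(pA$fit$rotation, pB$fit$rotation)
  expect_identical(pA$train, pB$train)
})

test_that("the repeated protocol stratifies splits and averages its rounds", {
  d <- sep_data(n = 200, gap = 4)
  ds <- list(X = d$X, y = d$y)
  pr <- repeated_protocol(ds, "knn", rounds = 4, seed = 3,
                          grid = data.frame(n_neighbors = 5, p = 2))
  expect_equal(nrow(pr$rounds), 4L)
  expect_named(pr$mean, c("precision", "recall", "f1", "accuracy",
                          "sensitivity", "specificity", "roc_auc"))
  expect_gt(pr$mean[["accuracy"]], 0.9)
  # stratification: per-round test class counts match 30% within 1 sample
  te <- physiofear:::stratified_split(d$y, 0.3, seed = 44)
  expect_lte(abs(sum(d$y[te] == 1) - 0.3 * sum(d$y == 1)), 1)
  expect_lte(abs(sum(d$y[te] == 0) - 0.3 * sum(d$y == 0)), 1)
  expect_error(repeated_protocol(ds, "svm", rounds = 2, n_components = 2,
                                 rank_method = "pearson", top_k = 2),
               "not both")
})
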