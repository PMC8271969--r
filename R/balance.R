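# Two-stage class balancing: random undersampling of the majority class to
# a minority:majority ratio, then SMOTE oversampling of the minority class
# to a fraction of the (reduced) majority.  With the default ratios a
# 992/166 dataset becomes 830/664 and a 4960/830 dataset becomes 4150/3320:
# the class counts depend only on the input counts and the configuration,
# never on the data values or the seed.

#' Balancing configuration
#'
#' @param undersample_ratio target minority:majority ratio after the random
#'   undersampling stage (majority reduced to
#'   `floor(n_minority / undersample_ratio)`).
#' @param smote_ratio target minority:majority ratio after SMOTE (minority
#'   grown to `floor(smote_ratio * n_majority)`).
#' @param k_neighbors number of nearest minority neighbours SMOTE
#'   interpolates between.
#' @param seed integer seed.
#' @return object of class `balance_config`.
#' @export
balance_config <- function(undersample_ratio = 0.2, smote_ratio = 0.8,
                           k_neighbors = 5, seed = 1L) {
  if (!(undersample_ratio > 0) || undersample_ratio > smote_ratio ||
      smote_ratio > 1)
    stop("configuration error: need 0 < undersample_ratio <= smote_ratio <= 1")
  if (k_neighbors < 1)
    stop("configuration error: k_neighbors must be >= 1")
  structure(list(undersample_ratio = undersample_ratio,
                 smote_ratio = smote_ratio,
                 k_neighbors = as.integer(k_neighbors),
                 seed = as.integer(seed)),
            class = "balance_config")
}

split_classes <- function(y) {
  tab <- table(y)
  if (length(tab) != 2)
    stop("validation error: need exactly two classes, found ", length(tab))
  minority <- names(tab)[which.min(tab)]
  majority <- names(tab)[which.max(tab)]
  if (tab[1] == tab[2]) { minority <- names(tab)[2]; majority <- names(tab)[1] }
  list(minority = minority, majority = majority,
       n_min = min(tab), n_maj = max(tab))
}

#' Randomly undersample the majority class
#'
#' Minority rows pass through untouched; majority rows are sampled without
#' replacement down to `floor(n_minority / undersample_ratio)` (no-op when
#' already at or below the target).
#'
#' @param X feature matrix (rows = samples).
#' @param y binary label vector.
#' @param config a [balance_config()].
#' @return list with `X`, `y` and `kept` (row indices of the input retained).
#' @export
random_undersample <- function(X, y, config = balance_config()) {
  X <- as.matrix(X)
  cl <- split_classes(y)
  target <- floor(cl$n_min / config$undersample_ratio)
  maj_idx <- which(y == cl$majority)
  min_idx <- which(y == cl$minority)
  if (length(maj_idx) > target) {
    set.seed(config$seed)
    maj_idx <- sort(sample(maj_idx, target))
  }
  kept <- sort(c(min_idx, maj_idx))
  list(X = X[kept, , drop = FALSE], y = y[kept], kept = kept)
}

#' SMOTE-oversample the minority class
#'
#' Grows the minority class to `floor(smote_ratio * n_majority)` by
#' synthesising points `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)` and
#' `x_nn` one of the `k_neighbors` nearest minority neighbours (Euclidean)
#' of a randomly chosen minority point `x`.  Original rows are retained;
#' synthetic rows are appended.
#'
#' @inheritParams random_undersample
#' @return list with `X`, `y` and `n_synthetic`.
#' @export
smote_oversample <- function(X, y, config = balance_config()) {
  X <- as.matrix(X)
  cl <- split_classes(y)
  if (cl$n_min <= config$k_neighbors)
    stop("validation error: minority class (", cl$n_min,
         ") must exceed k_neighbors (", config$k_neighbors,
         "); use a smaller k")
  target <- floor(config$smote_ratio * cl$n_maj)
  n_synth <- target - cl$n_min
  if (n_synth <= 0)
    return(list(X = X, y = y, n_synthetic = 0L))

  min_idx <- which(y == cl$minority)
  M <- X[min_idx, , drop = FALSE]
  d <- as.matrix(dist(M))
  diag(d) <- Inf
  k <- config$k_neighbors
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))

  set.seed(config$seed)
  base <- sample.int(nrow(M), n_synth, replace = TRUE)
  pick <- sample.int(k, n_synth, replace = TRUE)
  u <- runif(n_synth)
  synth <- M[base, , drop = FALSE] +
    u * (M[nn[cbind(base, pick)], , drop = FALSE] - M[base, , drop = FALSE])
  lab <- y[min_idx[1]]
  y_new <- c(y, rep(lab, n_synth))
  list(X = rbind(X, synth), y = y_new, n_synthetic = n_synth)
}

#' Balance a binary dataset (undersample then SMOTE)
#'
#' Runs [random_undersample()] followed by [smote_oversample()] and shuffles
#' the row order with the seed.  Accepts either a `labeled_dataset` or an
#' explicit `X`/`y` pair.
#'
#' @param X feature matrix or a `labeled_dataset`.
#' @param y binary label vector (ignored when `X` is a `labeled_dataset`).
#' @param config a [balance_config()].
#' @return same shape as the input: a `labeled_dataset`, or a list with `X`
#'   and `y`.
#' @export
balance_classes <- function(X, y = NULL, config = balance_config()) {
  as_dataset <- inherits(X, "labeled_dataset")
  if (as_dataset) { ds <- X; X <- ds$X; y <- ds$y }
  u <- random_undersample(X, y, config)
  s <- smote_oversample(u$X, u$y, config)
  set.seed(config$seed + 1L)
  ord <- sample.int(length(s$y))
  X_out <- s$X[ord, , drop = FALSE]
  y_out <- s$y[ord]
  if (as_dataset) {
    ds$X <- X_out; ds$y <- y_out
    ds$meta <- data.frame(row = seq_along(y_out))
    return(ds)
  }
  list(X = X_out, y = y_out)
}
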