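# Scaling and dimensionality reduction, always fit on training rows only.

#' Standardize features with training statistics
#'
#' Per-column `(x - mean_train) / sd_train`, applied to the training matrix
#' and (with the same statistics) to an optional test matrix.  Zero-variance
#' columns are centred and passed through with the divisor treated as 1
#' (reported via a message).
#'
#' @param train training feature matrix.
#' @param test optional test feature matrix (same columns).
#' @return list with `train`, `test`, `center`, `scale`; both matrices carry
#'   attribute `standardized = TRUE`.
#' @export
standardize <- function(train, test = NULL) {
  train <- as.matrix(train)
  ctr <- colMeans(train)
  scl <- apply(train, 2, sd)
  flat <- !is.finite(scl) | scl == 0
  if (any(flat)) {
    message("standardize: ", sum(flat),
            " zero-variance column(s) centred without scaling")
    scl[flat] <- 1
  }
  tr <- sweep(sweep(train, 2, ctr), 2, scl, "/")
  attr(tr, "standardized") <- TRUE
  te <- NULL
  if (!is.null(test)) {
    te <- sweep(sweep(as.matrix(test), 2, ctr), 2, scl, "/")
    attr(te, "standardized") <- TRUE
  }
  list(train = tr, test = te, center = ctr, scale = scl)
}

#' Project onto leading principal components
#'
#' Fits the rotation on the training rows only and applies it to both
#' matrices.
#'
#' @param train training feature matrix.
#' @param n_components number of components (`<= min(rows, cols)`); the
#'   conventional defaults downstream are 100 for the 120-column
#'   non-overlapping layout and 20 for the 40-column overlapping layout.
#' @param test optional test matrix.
#' @return list with `train`, `test` (scores matrices) and the `prcomp`
#'   object as `fit`.
#' @export
pca_reduce <- function(train, n_components, test = NULL) {
  train <- as.matrix(train)
  if (n_components < 1 || n_components > min(dim(train)))
    stop("validation error: n_components must lie in [1, min(rows, cols)]")
  if (is.null(colnames(train)))
    colnames(train) <- paste0("V", seq_len(ncol(train)))
  if (!is.null(test)) {
    test <- as.matrix(test)
    colnames(test) <- colnames(train)
  }
  fit <- prcomp(train, center = TRUE, scale. = FALSE)
  tr <- fit$x[, seq_len(n_components), drop = FALSE]
  attr(tr, "standardized") <- TRUE   # centred scores; scale-ready for SVM/kNN
  te <- NULL
  if (!is.null(test))
    te <- predict(fit, test)[, seq_len(n_components), drop = FALSE]
  if (!is.null(te)) attr(te, "standardized") <- TRUE
  list(train = tr, test = te, fit = fit)
}
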