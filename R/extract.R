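# Per-trial feature extraction and labeled dataset assembly.

#' Extract the 40-feature rows of one trial
#'
#' Decomposes the trial's conductance (baseline and stimulus jointly, so the
#' tonic estimate is continuous across the boundary) and evaluates every
#' feature in each analysis window of the scheme.  Baseline-referenced
#' features (`mar`, `str`) use the trial's own 5 s baseline for every
#' window; SCR events belong to the window containing their onset; beats
#' are assigned to a window when they fall inside it.  A failing window
#' yields an `NA` row rather than aborting the trial.
#'
#' @param trial a `trial_record`.
#' @param scheme a [window_scheme()].
#' @param components optional precomputed [decompose_eda()] result for the
#'   concatenated baseline+stimulus trace.
#' @param amp_min minimum SCR amplitude, microsiemens.
#' @param wl_squared waveform-length variant, see [eda_time_features()].
#' @return data frame: one row per window with the 40 features plus
#'   `label`, `subject_id`, `trial_index`, `window_index`.
#' @export
extract_trial <- function(trial, scheme = window_scheme(),
                          components = NULL, amp_min = 0.05,
                          wl_squared = TRUE) {
  stopifnot(inherits(trial, "trial_record"), inherits(scheme, "window_scheme"))
  fs <- trial$fs
  nb <- length(trial$baseline_gsr)
  baseline_s <- nb / fs
  full <- c(trial$baseline_gsr, trial$trial_gsr)
  if (is.null(components)) components <- decompose_eda(full, fs, amp_min)
  sig <- list(GSR = trial$trial_gsr,
              SCL = components$scl[-seq_len(nb)],
              SCR = components$scr[-seq_len(nb)])
  base <- list(GSR = trial$baseline_gsr,
               SCL = components$scl[seq_len(nb)],
               SCR = components$scr[seq_len(nb)])
  # events in stimulus-relative time
  ev <- components$events
  ev$onset <- ev$onset - baseline_s
  ev <- ev[ev$onset >= 0, , drop = FALSE]

  wins <- make_windows(length(trial$trial_gsr) / fs, scheme)
  rows <- vector("list", nrow(wins))
  for (w in seq_len(nrow(wins))) {
    s <- wins$start_s[w]; e <- wins$end_s[w]
    feats <- setNames(rep(NA_real_, length(feature_names())), feature_names())
    ok <- tryCatch({
      idx <- (round(s * fs) + 1L):round(e * fs)
      for (nm in names(sig)) {
        x <- sig[[nm]][idx]
        tf <- eda_time_features(x, base[[nm]], wl_squared = wl_squared)
        feats[paste(nm, names(tf), sep = "_")] <- tf
        sf <- spectral_features(power_spectrum(x, fs = fs))
        feats[paste(nm, names(sf), sep = "_")] <- sf
      }
      evf <- event_features(ev, s, e)
      feats[c("GSR_nimp", "GSR_avimp", "GSR_maximp")] <- evf
      bt <- trial$beat_times
      inw <- bt[bt >= baseline_s + s & bt < baseline_s + e]
      hf <- hrv_features(diff(inw), beat_times = inw[-1])
      feats[c("HR_std", "HRV_std", "HRV_NN50", "HRV_pNN50", "HRV_NN20",
              "HRV_pNN20", "HRV_hlr")] <- hf
      TRUE
    }, error = function(err) FALSE)
    if (!ok) feats[] <- NA_real_
    rows[[w]] <- c(as.list(feats),
                   list(label = trial$fear, subject_id = trial$subject_id,
                        trial_index = trial$trial_index, window_index = w))
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
}

#' Assemble a labeled dataset from trial records
#'
#' Non-overlapping scheme: one row per trial with 120 columns (the 40
#' features of each window, suffixed `[W1]`, `[W2]`, `[W3]`).  Overlapping
#' scheme: one row per window (five per trial) with 40 columns, every row
#' carrying the trial's fear label.  Missing values are imputed with the
#' column median (reported via the `n_imputed` attribute and a message).
#'
#' @param trials list of `trial_record` objects.
#' @param scheme a [window_scheme()].
#' @param impute impute missing values with column medians.
#' @param ... passed to [extract_trial()].
#' @return object of class `labeled_dataset`: list with `X` (numeric
#'   matrix), `y` (integer 0/1), `scheme` and `meta` (data frame of subject,
#'   trial and window indices).
#' @export
assemble_dataset <- function(trials, scheme = window_scheme(),
                             impute = TRUE, ...) {
  if (length(trials) == 0) stop("validation error: empty trial list")
  per_trial <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    per_trial[[i]] <- tryCatch(extract_trial(trials[[i]], scheme, ...),
                               error = function(err) {
                                 warning("assemble_dataset: dropping trial ",
                                         i, ": ", conditionMessage(err))
                                 NULL
                               })
  }
  per_trial <- per_trial[!vapply(per_trial, is.null, logical(1))]
  if (length(per_trial) == 0) stop("validation error: no extractable trials")
  fn <- feature_names()

  if (scheme$mode == "overlapping") {
    all_rows <- do.call(rbind, per_trial)
    X <- as.matrix(all_rows[, fn])
    y <- as.integer(all_rows$label)
    meta <- all_rows[, c("subject_id", "trial_index", "window_index")]
  } else {
    n_win <- nrow(make_windows(scheme = scheme))
    cols <- as.vector(vapply(seq_len(n_win),
                             function(w) paste0(fn, "[W", w, "]"),
                             character(length(fn))))
    X <- matrix(NA_real_, length(per_trial), length(cols),
                dimnames = list(NULL, cols))
    y <- integer(length(per_trial))
    meta <- data.frame(subject_id = character(length(per_trial)),
                       trial_index = integer(length(per_trial)))
    for (i in seq_along(per_trial)) {
      tr <- per_trial[[i]]
      X[i, ] <- as.vector(vapply(seq_len(nrow(tr)),
                                 function(w) as.numeric(tr[w, fn]),
                                 numeric(length(fn))))
      y[i] <- as.integer(tr$label[1])
      meta$subject_id[i] <- tr$subject_id[1]
      meta$trial_index[i] <- tr$trial_index[1]
    }
  }
  rownames(meta) <- NULL

  n_imputed <- 0L
  if (impute && anyNA(X)) {
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      if (any(nas)) {
        X[nas, j] <- median(X[, j], na.rm = TRUE)
        n_imputed <- n_imputed + sum(nas)
      }
    }
    message("assemble_dataset: imputed ", n_imputed,
            " missing values with column medians")
  }
  structure(list(X = X, y = y, scheme = scheme, meta = meta),
            class = "labeled_dataset", n_imputed = n_imputed)
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d x %d (%s), classes: %s\n",
              nrow(x$X), ncol(x$X), x$scheme$mode,
              paste(sprintf("%d=%d", as.integer(names(table(x$y))),
                            as.integer(table(x$y))), collapse = ", ")))
  invisible(x)
}

#' Write / read a labeled dataset as CSV
#'
#' The header carries the feature names (including the `[W*]` window
#' suffixes of the non-overlapping layout) plus a `label` column.
#'
#' @param dataset a `labeled_dataset`.
#' @param path file path.
#' @return `path` invisibly (write); a `labeled_dataset` (read).
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  df <- as.data.frame(dataset$X, check.names = FALSE)
  df$label <- dataset$y
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @param mode windowing mode of the stored dataset.
#' @export
read_dataset_csv <- function(path, mode = c("non_overlapping",
                                            "overlapping")) {
  mode <- match.arg(mode)
  df <- as.data.frame(data.table::fread(path, header = TRUE),
                      check.names = FALSE)
  if (!"label" %in% names(df))
    stop("parse error: dataset file lacks a label column")
  y <- as.integer(df$label)
  X <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
  structure(list(X = X, y = y, scheme = window_scheme(mode),
                 meta = data.frame(row = seq_len(nrow(X)))),
            class = "labeled_dataset")
}
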