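# Session and ratings CSV dialect.
#
# A session file holds three numeric columns -- gsr_uS, ppg, status -- one
# row per raw sample, with a header line.  A ratings file holds one row per
# trial with columns subject, trial, valence, arousal, dominance.

#' Write a session recording to CSV
#'
#' @param recording a `session_recording`.
#' @param path output file path.
#' @param digits significant digits written for the numeric channels; the
#'   declared text-float precision of the dialect.
#' @return `path`, invisibly.
#' @export
write_session_csv <- function(recording, path, digits = 10) {
  stopifnot(inherits(recording, "session_recording"))
  df <- data.frame(gsr_uS = signif(recording$gsr, digits),
                   ppg = signif(recording$ppg, digits),
                   status = recording$status)
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read a session recording from CSV
#'
#' Validates the three-column dialect; malformed files (wrong column count,
#' non-numeric entries, empty file) raise a parse error naming the offending
#' row where one exists.
#'
#' @param path file path.
#' @param fs sampling rate to attach, samples/s.
#' @param subject_id identifier to attach.
#' @return a `session_recording`.
#' @export
read_session_csv <- function(path, fs = 512, subject_id = "S01") {
  if (!file.size(path) > 0) stop("parse error: empty session file: ", path)
  dt <- data.table::fread(path, colClasses = "character", header = TRUE)
  if (ncol(dt) != 3)
    stop("parse error: expected 3 columns (gsr_uS, ppg, status), found ",
         ncol(dt))
  if (nrow(dt) == 0) stop("parse error: session file has a header but no rows")
  mat <- suppressWarnings(vapply(dt, as.numeric, numeric(nrow(dt))))
  mat <- matrix(mat, nrow = nrow(dt))
  bad <- which(!complete.cases(mat) |
                 !complete.cases(vapply(dt, function(z) !is.na(z) & nzchar(z),
                                        logical(nrow(dt)))))
  if (length(bad) > 0)
    stop("parse error: non-numeric or missing value at data row ", bad[1])
  structure(list(gsr = mat[, 1], ppg = mat[, 2],
                 status = as.integer(mat[, 3]), fs = fs,
                 subject_id = subject_id),
            class = "session_recording")
}

#' Write a per-trial ratings table to CSV
#'
#' @param ground_truth a `ground_truth` object (or any data frame with
#'   columns `trial`, `valence`, `arousal`, `dominance`).
#' @param path output file path.
#' @param subject subject identifier for the `subject` column.
#' @return `path`, invisibly.
#' @export
write_ratings_csv <- function(ground_truth, path, subject = "S01") {
  tr <- if (inherits(ground_truth, "ground_truth")) ground_truth$trials
        else ground_truth
  df <- data.frame(subject = subject, trial = tr$trial,
                   valence = tr$valence, arousal = tr$arousal,
                   dominance = tr$dominance)
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read a per-trial ratings table from CSV
#'
#' @param path file path.
#' @return data frame with columns `subject`, `trial`, `valence`, `arousal`,
#'   `dominance`.
#' @export
read_ratings_csv <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  need <- c("subject", "trial", "valence", "arousal", "dominance")
  if (!all(need %in% names(df)))
    stop("parse error: ratings file must have columns ",
         paste(need, collapse = ", "))
  df[, need]
}
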