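# Preprocessing: FIR low-pass design, zero-phase-aligned decimation,
# status-driven trial segmentation and PPG beat detection.

#' FIR low-pass filter specification
#'
#' @param cutoff_hz cutoff frequency, Hz.
#' @param order filter order (number of taps minus one); must be even so the
#'   group delay `order/2` is an integer number of samples.
#' @param window taper name; currently `"hamming"`.
#' @param fs sampling rate the filter is designed for, samples/s.
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(cutoff_hz = 5, order = 512, window = "hamming",
                        fs = 512) {
  if (!(cutoff_hz > 0) || cutoff_hz >= fs / 2)
    stop("configuration error: cutoff must lie in (0, fs/2)")
  if (order %% 2 != 0)
    stop("configuration error: order must be even for integer group delay")
  structure(list(cutoff_hz = cutoff_hz, order = as.integer(order),
                 window = match.arg(window, "hamming"), fs = fs),
            class = "filter_spec")
}

#' Design a linear-phase FIR low-pass filter by the window method
#'
#' Returns `order + 1` symmetric coefficients with unity DC gain.
#'
#' @param spec a [filter_spec()].
#' @return numeric coefficient vector.
#' @export
design_lowpass <- function(spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  b <- as.numeric(signal::fir1(spec$order, spec$cutoff_hz / (spec$fs / 2),
                               type = "low",
                               window = signal::hamming(spec$order + 1)))
  b / sum(b)   # exact unity DC gain
}

#' Low-pass filter and decimate a signal
#'
#' Applies the FIR filter with edge-replication padding and compensates the
#' `order/2`-sample group delay so that the filtered trace stays aligned with
#' the input, then keeps every `fs/fs_out`-th sample starting from the first.
#' Output sample `i` (counting from 0) therefore corresponds to input time
#' `i * (fs/fs_out) / fs` seconds.
#'
#' @param x numeric signal at `spec$fs`.
#' @param spec a [filter_spec()].
#' @param fs_out output rate, samples/s; `spec$fs` must be an integer
#'   multiple.
#' @return decimated signal of length `floor(length(x) / (fs/fs_out))`.
#' @export
filter_decimate <- function(x, spec = filter_spec(), fs_out = 16) {
  stopifnot(inherits(spec, "filter_spec"))
  m <- spec$fs / fs_out
  if (abs(m - round(m)) > 1e-9)
    stop("configuration error: fs must be an integer multiple of fs_out")
  m <- as.integer(round(m))
  n <- length(x)
  taps <- spec$order + 1L
  if (n < taps)
    stop("length error: signal (", n, " samples) shorter than the filter (",
         taps, " taps)")
  b <- design_lowpass(spec)
  gd <- spec$order %/% 2L
  xp <- c(rep(x[1], gd), x, rep(x[n], gd))
  # causal convolution: z[t] = sum_j b[j] * xp[t - j + 1]
  z <- stats::filter(xp, b, method = "convolution", sides = 1)
  y <- as.numeric(z[(1:n) + 2L * gd])
  keep <- seq(1L, n, by = m)
  out_len <- n %/% m
  y[keep[seq_len(out_len)]]
}

#' Detect heart beats in a photoplethysmogram
#'
#' Local maxima above an adaptive threshold (median plus 40 percent of the
#' median-to-maximum excursion), enforced with a 0.3 s refractory period.
#' Inter-beat intervals are the successive differences of the returned beat
#' times.
#'
#' @param ppg numeric pulse signal.
#' @param fs sampling rate, samples/s.
#' @param refractory_s minimum spacing between accepted beats, s.
#' @return beat times in seconds from the first sample (possibly empty).
#' @export
detect_beats <- function(ppg, fs = 512, refractory_s = 0.3) {
  n <- length(ppg)
  if (n < 2 * fs) stop("length error: need at least 2 s of signal")
  med <- median(ppg)
  thr <- med + 0.4 * (max(ppg) - med)
  if (!(max(ppg) > med)) return(numeric(0))   # flat signal
  core <- ppg[2:(n - 1)]
  is_peak <- core > ppg[1:(n - 2)] & core >= ppg[3:n] & core > thr
  cand <- which(is_peak) + 1L
  if (length(cand) == 0) return(numeric(0))
  keep <- numeric(0)
  last <- -Inf
  gap <- refractory_s * fs
  for (i in cand) {
    if (i - last >= gap) {
      keep <- c(keep, i)
      last <- i
    }
  }
  (keep - 1) / fs
}

#' Segment a session recording into trial records
#'
#' Uses the status channel: each trial-onset marker (code 4) closes a 5 s
#' baseline opened by the preceding baseline-onset marker (code 1) and opens
#' a 60 s stimulus interval.  The conductance channel is filtered and
#' decimated once per session; each record carries the 80-sample baseline and
#' 960-sample stimulus trace at 16 samples/s, beats detected from the raw
#' PPG over the trial span (times relative to baseline onset), the trial's
#' ratings and the fear label from [label_fear()].  Trials containing
#' non-finite samples are excluded and reported in the `exclusions`
#' attribute.
#'
#' @param recording a `session_recording`.
#' @param ratings data frame with columns `trial`, `valence`, `arousal`,
#'   `dominance` covering every trial marker.
#' @param spec FIR specification used before decimation.
#' @param fs_out processed rate, samples/s.
#' @param baseline_s,trial_s interval durations, s.
#' @return list of `trial_record` objects, with attribute `exclusions` (data
#'   frame of trial index and reason).
#' @export
segment_trials <- function(recording, ratings, spec = filter_spec(),
                           fs_out = 16, baseline_s = 5, trial_s = 60) {
  stopifnot(inherits(recording, "session_recording"))
  fs <- recording$fs
  onsets <- which(recording$status == STATUS_TRIAL_ONSET)
  base_on <- which(recording$status == STATUS_BASELINE_ONSET)
  if (length(onsets) == 0) stop("alignment error: no trial-onset markers")
  if (length(base_on) != length(onsets))
    stop("alignment error: ", length(base_on), " baseline markers vs ",
         length(onsets), " trial markers")
  if (!all(ratings$trial[seq_along(onsets)] == seq_along(onsets)) ||
      nrow(ratings) < length(onsets))
    stop("alignment error: ratings table does not cover trials 1..",
         length(onsets))

  m <- as.integer(fs / fs_out)
  gsr16 <- filter_decimate(recording$gsr, spec, fs_out)
  nb <- round(baseline_s * fs_out)
  nt <- round(trial_s * fs_out)

  records <- list()
  excl <- data.frame(trial = integer(0), reason = character(0))
  for (i in seq_along(onsets)) {
    on_raw <- onsets[i]
    # processed-rate index of the stimulus onset (time-aligned decimation)
    on16 <- (on_raw - 1L) %/% m + 1L
    b_idx <- (on16 - nb):(on16 - 1L)
    t_idx <- on16:(on16 + nt - 1L)
    if (min(b_idx) < 1 || max(t_idx) > length(gsr16)) {
      excl <- rbind(excl, data.frame(trial = i, reason = "out of range"))
      next
    }
    bg <- gsr16[b_idx]
    tg <- gsr16[t_idx]
    if (any(!is.finite(bg)) || any(!is.finite(tg))) {
      excl <- rbind(excl, data.frame(trial = i, reason = "non-finite samples"))
      message("segment_trials: excluding trial ", i, " (non-finite samples)")
      next
    }
    raw_b0 <- on_raw - round(baseline_s * fs)
    raw_t1 <- min(length(recording$ppg), on_raw + round(trial_s * fs) - 1L)
    bt <- detect_beats(recording$ppg[raw_b0:raw_t1], fs)
    r <- ratings[ratings$trial == i, ][1, ]
    records[[length(records) + 1L]] <- new_trial_record(
      baseline_gsr = bg, trial_gsr = tg, beat_times = bt,
      valence = r$valence, arousal = r$arousal, dominance = r$dominance,
      fear = label_fear(r$valence, r$arousal, r$dominance),
      subject_id = recording$subject_id, trial_index = i, fs = fs_out)
  }
  attr(records, "exclusions") <- excl
  records
}
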