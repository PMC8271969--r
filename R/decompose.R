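# Tonic/phasic decomposition of the 16 Hz skin conductance trace and
# detection of discrete skin conductance responses (SCRs).
#
# Two-pass procedure with the same output contract as deconvolution-based
# continuous decomposition: (1) a coarse tonic estimate (rolling low
# percentile, smoothed) exposes a provisional phasic trace on which SCRs are
# detected by sequential kernel peeling -- each response's trough-to-peak
# amplitude is measured after subtracting the fitted bi-exponential tails of
# the responses already accepted; (2) the tonic level (SCL) is re-estimated
# by interpolating the conductance through response-free samples, and the
# phasic trace (SCR) is the exact remainder, so SCL + SCR reconstructs the
# input with zero residual.

# centred moving average with edge replication
ma_smooth <- function(x, k) {
  if (k < 1) return(x)
  n <- length(x)
  xp <- c(rep(x[1], k), x, rep(x[n], k))
  w <- rep(1 / (2 * k + 1), 2 * k + 1)
  as.numeric(stats::filter(xp, w, sides = 2)[(k + 1):(k + n)])
}

# rolling quantile evaluated on a hop grid and linearly interpolated
rolling_quantile <- function(x, half_win, q, hop = 4L) {
  n <- length(x)
  centers <- unique(c(seq(1L, n, by = hop), n))
  vals <- vapply(centers, function(c) {
    quantile(x[max(1L, c - half_win):min(n, c + half_win)], q, names = FALSE)
  }, numeric(1))
  if (length(centers) == 1) return(rep(vals, n))
  approx(centers, vals, xout = seq_len(n))$y
}

# Sequential kernel-peeling SCR detector on a phasic trace.  Peaks are
# found on a lightly smoothed copy; each candidate's onset is the latest
# near-baseline trough in a short pre-peak region (the kernel rise lasts
# about 1.2 s) after subtracting the fitted tails of the responses already
# accepted, and its amplitude is the least-squares projection of the
# unsmoothed residual onto the response kernel anchored at the onset.
detect_scr_events <- function(phasic, fs, amp_floor, rise_s, decay_s,
                              refractory_s = 1) {
  n <- length(phasic)
  s <- ma_smooth(phasic, 1L)                 # 3-sample smoothing for peaks
  core <- s[2:(n - 1)]
  peaks <- which(core > s[1:(n - 2)] & core >= s[3:n]) + 1L
  if (length(peaks) == 0)
    return(data.frame(onset = numeric(0), amplitude = numeric(0)))
  tt <- (seq_len(n) - 1) / fs
  model <- numeric(n)
  onsets <- amps <- numeric(0)
  last_peak <- 1L
  fit_len <- round(4 * fs)                   # kernel-projection window
  for (p in peaks) {
    if (length(amps) > 0 && (p - last_peak) < refractory_s * fs) next
    lo <- max(max(1L, last_peak), p - round(2.5 * fs))
    if (lo >= p) next
    r <- s[lo:p] - model[lo:p]
    rmin <- min(r)
    rise <- r[length(r)] - rmin
    if (!is.finite(rise) || rise < amp_floor) next
    near_base <- which(r <= rmin + 0.05 * rise)
    near_base <- near_base[near_base < length(r)]
    t_rel <- if (length(near_base)) max(near_base) else which.min(r)
    trough <- lo + t_rel - 1L
    onset_t <- tt[trough]
    idx <- trough:min(n, trough + fit_len)
    h <- scr_kernel(tt[idx] - onset_t, rise_s, decay_s)
    # least-squares fit of amplitude plus a free local baseline offset, so
    # a single noisy trough sample cannot bias the amplitude
    vh <- sum(h^2) - sum(h)^2 / length(h)
    if (vh <= 0) next
    rr <- phasic[idx] - model[idx]
    a <- (sum(h * rr) - sum(h) * sum(rr) / length(h)) / vh
    if (!is.finite(a) || a < amp_floor) next
    onsets <- c(onsets, onset_t)
    amps <- c(amps, a)
    tail_idx <- trough:n
    model[tail_idx] <- model[tail_idx] +
      a * scr_kernel(tt[tail_idx] - onset_t, rise_s, decay_s)
    last_peak <- p
  }
  data.frame(onset = onsets, amplitude = amps)
}

#' Decompose skin conductance into tonic and phasic components
#'
#' Splits a 16 samples/s conductance trace into the slowly varying tonic
#' level (SCL), the phasic trace (SCR, the exact remainder so additivity is
#' by construction) and a list of detected SCR events with onset times and
#' trough-to-peak amplitudes.  Raising `amp_min` can only remove events.
#'
#' @param gsr numeric conductance trace, microsiemens.
#' @param fs sampling rate, samples/s.
#' @param amp_min minimum SCR amplitude reported, microsiemens.
#' @param rise_s,decay_s bi-exponential response-kernel time constants, s.
#' @param tonic_window_s half-window of the coarse rolling-percentile tonic
#'   estimate, s.
#' @return object of class `eda_components` with fields `scl`, `scr` (both
#'   the length of the input), `events` (data frame `onset`, `amplitude`,
#'   sorted by onset) and `fs`.
#' @export
decompose_eda <- function(gsr, fs = 16, amp_min = 0.05, rise_s = 0.75,
                          decay_s = 2, tonic_window_s = 4) {
  if (any(!is.finite(gsr))) stop("data error: non-finite conductance samples")
  n <- length(gsr)
  if (n < 2 * fs) stop("data error: need at least 2 s of signal")
  half_win <- round(tonic_window_s * fs)

  # pass 1: coarse tonic and provisional events.  The provisional floor is
  # fixed (independent of amp_min) so the tonic estimate -- and with it the
  # final event list before the amplitude filter -- does not move when
  # amp_min does; raising amp_min then strictly filters a fixed list.
  coarse <- ma_smooth(rolling_quantile(gsr, half_win, 0.1), round(fs / 2))
  ev <- detect_scr_events(gsr - coarse, fs, 0.05, rise_s, decay_s)
  floor_amp <- min(0.01, amp_min)

  # pass 2: tonic through response-free samples
  if (nrow(ev) > 0) {
    tt <- (seq_len(n) - 1) / fs
    free <- rep(TRUE, n)
    for (k in seq_len(nrow(ev)))
      free[tt >= ev$onset[k] - 0.5 & tt <= ev$onset[k] + 5 * decay_s] <- FALSE
    if (sum(free) >= 2) {
      scl <- approx(which(free), gsr[free], xout = seq_len(n), rule = 2)$y
      scl <- ma_smooth(scl, round(fs / 2))
    } else {
      scl <- coarse
    }
  } else {
    scl <- ma_smooth(gsr, round(fs / 2))
  }
  scr <- gsr - scl

  ev <- detect_scr_events(scr, fs, floor_amp, rise_s, decay_s)
  ev <- ev[ev$amplitude >= amp_min, , drop = FALSE]
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  structure(list(scl = scl, scr = scr, events = ev, fs = fs),
            class = "eda_components")
}

#' @export
print.eda_components <- function(x, ...) {
  cat(sprintf("<eda_components> %d samples at %g Hz, %d SCR events\n",
              length(x$scl), x$fs, nrow(x$events)))
  invisible(x)
}
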