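# The 40-feature registry: per analysis window, 10 time/frequency features
# for each of the GSR, SCL and SCR traces (30), three SCR-event features,
# and seven heart-rate-variability features.

#' Names of the 40 per-window features
#'
#' 33 electrodermal features (10 per signal for GSR/SCL/SCR plus 3 event
#' features) and 7 heart-rate-variability features.
#'
#' @return character vector of length 40.
#' @export
feature_names <- function() {
  per_sig <- c("mav", "mar", "std", "str", "wl", "ssc", "wamp",
               "fmd", "fmn", "hlr")
  c(as.vector(t(outer(c("GSR", "SCL", "SCR"), per_sig, paste, sep = "_"))),
    "GSR_nimp", "GSR_avimp", "GSR_maximp",
    "HR_std", "HRV_std", "HRV_NN50", "HRV_pNN50", "HRV_NN20", "HRV_pNN20",
    "HRV_hlr")
}

#' Binary fear label from dimensional ratings
#'
#' `fear = 1` iff `valence <= 5 & arousal > 5 & dominance <= 5`; vectorised.
#'
#' @param valence,arousal,dominance ratings on the 1-9 scale.
#' @return integer 0/1 vector.
#' @export
label_fear <- function(valence, arousal, dominance) {
  r <- c(valence, arousal, dominance)
  if (any(!is.finite(r)) || any(r < 1 | r > 9))
    stop("validation error: ratings must lie in [1, 9]")
  as.integer(valence <= 5 & arousal > 5 & dominance <= 5)
}

#' Windowing scheme
#'
#' Non-overlapping: three 20 s windows per 60 s trial.  Overlapping: five
#' 20 s windows with 10 s step.
#'
#' @param mode `"non_overlapping"` or `"overlapping"`.
#' @return object of class `window_scheme` with `mode`, `window_s`, `step_s`.
#' @export
window_scheme <- function(mode = c("non_overlapping", "overlapping")) {
  mode <- match.arg(mode)
  structure(list(mode = mode, window_s = 20,
                 step_s = if (mode == "non_overlapping") 20 else 10),
            class = "window_scheme")
}

#' Window start/end times over a trial
#'
#' @param trial_s trial duration, s.
#' @param scheme a [window_scheme()].
#' @return data frame with `start_s` and `end_s` (half-open intervals).
#' @export
make_windows <- function(trial_s = 60, scheme = window_scheme()) {
  stopifnot(inherits(scheme, "window_scheme"))
  starts <- seq(0, trial_s - scheme$window_s, by = scheme$step_s)
  data.frame(start_s = starts, end_s = starts + scheme$window_s)
}

#' Time-domain features of one analysis window
#'
#' Computes, for a windowed trace `x` with baseline trace `xb`:
#' mean absolute value `mav = mean(|x|)`; baseline ratio
#' `mar = mav(x)/mav(xb)`; sample standard deviation `std` (n-1 denominator);
#' baseline ratio `str = std(x)/std(xb)`; waveform length
#' `wl = sum(diff(x)^2)` (squared first differences; set
#' `wl_squared = FALSE` for the conventional `sum(|diff|)`); slope sign
#' changes `ssc` (interior points where the slope sign flips and both
#' adjacent absolute differences are `>= eps_slope`); Willison amplitude
#' `wamp` (successive absolute differences `>= eps_wamp`).  A zero-mav or
#' zero-std baseline makes `mar`/`str` undefined (`NA`).
#'
#' @param x window samples.
#' @param xb baseline samples (may be `NULL`: `mar`/`str` become `NA`).
#' @param eps_slope slope threshold, microsiemens.
#' @param eps_wamp Willison threshold, microsiemens.
#' @param wl_squared use squared differences for the waveform length.
#' @return named numeric vector `mav, mar, std, str, wl, ssc, wamp`.
#' @export
eda_time_features <- function(x, xb = NULL, eps_slope = 0.001,
                              eps_wamp = 0.5, wl_squared = TRUE) {
  n <- length(x)
  if (n == 0) stop("validation error: empty window")
  mav <- mean(abs(x))
  std <- if (n >= 2) sd(x) else NA_real_
  d <- diff(x)
  wl <- if (n >= 2) { if (wl_squared) sum(d^2) else sum(abs(d)) } else NA_real_
  ssc <- if (n >= 3) {
    d1 <- d[-length(d)]; d2 <- d[-1]
    sum(sign(d1) * sign(d2) < 0 & abs(d1) >= eps_slope & abs(d2) >= eps_slope)
  } else NA_real_
  wamp <- if (n >= 2) sum(abs(d) >= eps_wamp) else NA_real_
  mar <- str <- NA_real_
  if (!is.null(xb) && length(xb) > 0) {
    mav_b <- mean(abs(xb))
    if (is.finite(mav_b) && mav_b > 0) mar <- mav / mav_b
    if (length(xb) >= 2) {
      std_b <- sd(xb)
      if (is.finite(std_b) && std_b > 0 && !is.na(std)) str <- std / std_b
    }
  }
  c(mav = mav, mar = mar, std = std, str = str, wl = wl,
    ssc = as.numeric(ssc), wamp = as.numeric(wamp))
}

#' Power spectral density on a fixed frequency grid
#'
#' Mean-removed, zero-padded one-sided periodogram evaluated on the exact
#' grid `0, df, ..., fmax` (801 lines for the default 0-8 Hz at 0.01 Hz).
#' The zero-padding length `fs/df` makes the grid a subset of the DFT bins,
#' so the estimate is the discrete-time Fourier transform of the window
#' sampled on the grid.  Interior lines are doubled (one-sided convention);
#' the sum of all lines is then proportional to the mean-removed window
#' energy.
#'
#' @param x window samples.
#' @param fs sampling rate, samples/s.
#' @param fmax top grid frequency, Hz (must be `<= fs/2`).
#' @param df grid step, Hz.
#' @return object of class `spectral_density` with `freqs` and `power`.
#' @export
power_spectrum <- function(x, fs = 16, fmax = 8, df = 0.01) {
  if (all(is.na(x))) {
    freqs <- seq(0, fmax, by = df)
    return(structure(list(freqs = freqs,
                          power = rep(NA_real_, length(freqs))),
                     class = "spectral_density"))
  }
  n <- length(x)
  if (n < 2) stop("validation error: window must have at least 2 samples")
  if (fmax > fs / 2 + 1e-12)
    stop("configuration error: fmax must not exceed fs/2")
  npad <- round(fs / df)
  if (abs(fs / df - npad) > 1e-9)
    stop("configuration error: fs/df must be an integer")
  if (n > npad) stop("validation error: window longer than the padded length")
  x0 <- x - mean(x)
  X <- fft(c(x0, numeric(npad - n)))
  nline <- round(fmax / df) + 1L
  p <- Mod(X[seq_len(nline)])^2 / n
  w <- rep(2, nline)
  w[1] <- 1
  if (abs(fmax - fs / 2) < 1e-12) w[nline] <- 1   # Nyquist line
  structure(list(freqs = seq(0, fmax, by = df), power = w * p),
            class = "spectral_density")
}

#' Spectral features: median frequency, mean frequency, band-energy ratio
#'
#' `fmd` is the discrete median frequency -- the smallest grid frequency at
#' which the cumulative power reaches half the total (the minimiser of the
#' half-energy split objective, resolved to the crossing line on ties).
#' `fmn` is the power-weighted mean frequency.  `hlr` is the ratio of the
#' energy in the high band over the low band; band edges are half-open
#' `[low, high)`.  Defaults are the electrodermal bands
#' `[0.01, 0.2)` / `[0.2, 2)` Hz.
#'
#' @param psd a [power_spectrum()] result.
#' @param low_band,high_band numeric length-2 band limits, Hz.
#' @return named numeric vector `fmd, fmn, hlr` (`NA` where undefined:
#'   zero total power for `fmd`/`fmn`, zero low-band power for `hlr`).
#' @export
spectral_features <- function(psd, low_band = c(0.01, 0.2),
                              high_band = c(0.2, 2)) {
  stopifnot(inherits(psd, "spectral_density"))
  p <- psd$power
  f <- psd$freqs
  if (all(is.na(p)))
    return(c(fmd = NA_real_, fmn = NA_real_, hlr = NA_real_))
  tot <- sum(p)
  if (!(tot > 0)) {
    fmd <- fmn <- NA_real_
  } else {
    cum <- cumsum(p)
    fmd <- f[which(cum >= tot / 2)[1]]
    fmn <- sum(f * p) / tot
  }
  lo <- sum(p[f >= low_band[1] & f < low_band[2]])
  hi <- sum(p[f >= high_band[1] & f < high_band[2]])
  hlr <- if (lo > 0) hi / lo else NA_real_
  c(fmd = fmd, fmn = fmn, hlr = hlr)
}

#' SCR event features of one window
#'
#' Events belong to a window when their onset falls inside `[start_s,
#' end_s)`.  With no event, all three features are 0 by convention.
#'
#' @param events data frame with `onset` (s) and `amplitude` (uS), e.g. from
#'   [decompose_eda()].
#' @param start_s,end_s window limits, s.
#' @return named numeric vector `nimp, avimp, maximp`.
#' @export
event_features <- function(events, start_s, end_s) {
  inw <- events[events$onset >= start_s & events$onset < end_s, ,
                drop = FALSE]
  r <- nrow(inw)
  c(nimp = as.numeric(r),
    avimp = if (r > 0) mean(inw$amplitude) else 0,
    maximp = if (r > 0) max(inw$amplitude) else 0)
}

#' Heart-rate-variability features of one window
#'
#' From the inter-beat intervals (IBIs, s) inside the window: `HR_std`, the
#' sample standard deviation of the IBIs; `HRV_std`, the standard deviation
#' of successive IBI differences (denominator `H - 2` as defined); `NN50` /
#' `NN20`, counts of successive differences of at least 50 / 20 ms, and
#' their proportions `pNN50` / `pNN20` relative to the IBI count `H`;
#' `HRV_hlr`, the high/low band-energy ratio (`[0.15, 0.4)` over
#' `[0.04, 0.15)` Hz) of the evenly resampled IBI tachogram (cubic spline of
#' the (beat time, IBI) pairs at 4 samples/s, then the same mean-removed
#' periodogram machinery on a 0-0.5 Hz grid).
#'
#' Std features need `H >= 3` IBIs, NN counts `H >= 2`, the spectral ratio
#' `H >= 4`; features below their minimum are `NA`.
#'
#' @param ibis inter-beat intervals inside the window, s.
#' @param beat_times optional times of the beats closing each interval
#'   (length `length(ibis)`), s; defaults to `cumsum(ibis)`.
#' @param low_band,high_band tachogram band limits, Hz.
#' @param tacho_fs tachogram resampling rate, samples/s.
#' @return named numeric vector `HR_std, HRV_std, NN50, pNN50, NN20, pNN20,
#'   hlr`.
#' @export
hrv_features <- function(ibis, beat_times = NULL,
                         low_band = c(0.04, 0.15), high_band = c(0.15, 0.4),
                         tacho_fs = 4) {
  h <- length(ibis)
  d <- diff(ibis)
  hr_std <- if (h >= 3) sd(ibis) else NA_real_
  hrv_std <- if (h >= 3) {
    dv <- d - mean(d)
    sqrt(sum(dv^2) / (h - 2))
  } else NA_real_
  if (h >= 2) {
    nn50 <- sum(abs(d) >= 0.05)
    nn20 <- sum(abs(d) >= 0.02)
    pnn50 <- nn50 / h
    pnn20 <- nn20 / h
  } else {
    nn50 <- nn20 <- pnn50 <- pnn20 <- NA_real_
  }
  hlr <- NA_real_
  if (h >= 4) {
    bt <- if (is.null(beat_times)) cumsum(ibis) else beat_times
    span <- diff(range(bt))
    if (span > 2 / tacho_fs) {
      grid <- seq(min(bt), max(bt), by = 1 / tacho_fs)
      tach <- spline(bt, ibis, xout = grid)$y
      if (length(tach) >= 2) {
        psd <- power_spectrum(tach, fs = tacho_fs, fmax = 0.5, df = 0.01)
        hlr <- unname(spectral_features(psd, low_band, high_band)["hlr"])
      }
    }
  }
  c(HR_std = hr_std, HRV_std = hrv_std, NN50 = as.numeric(nn50),
    pNN50 = pnn50, NN20 = as.numeric(nn20), pNN20 = pnn20, hlr = hlr)
}
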