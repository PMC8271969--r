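# Synthetic physiological session generator.
#
# Emulates the structure of a DEAP-style recording: 40 trials, each a 5 s
# neutral fixation baseline followed by a 60 s stimulus interval, recorded on
# three channels (skin conductance in microsiemens, photoplethysmogram in
# arbitrary units, integer status markers) at 512 samples/s.  Fear trials
# carry a higher skin-conductance-response rate, a raised tonic level and
# reduced beat-to-beat variability; every random element is reproducible from
# the seed and reported back as ground truth.

#' Simulation configuration
#'
#' Collects and validates every parameter of the synthetic session generator.
#' Defaults are the study conditions the rest of the package is tested under.
#'
#' @param n_trials number of trials per session.
#' @param fs_raw raw sampling rate, samples/s.
#' @param baseline_s neutral fixation baseline duration, s.
#' @param trial_s stimulus interval duration, s.
#' @param fear_fraction probability that a trial is a fear trial, in `[0, 1]`.
#' @param scr_rate_nofear,scr_rate_fear skin-conductance-response rates,
#'   events/min, for non-fear and fear trials (`scr_rate_fear >=
#'   scr_rate_nofear`).
#' @param scr_amp_range range of SCR amplitudes, microsiemens.
#' @param tonic_level_range range of the tonic skin conductance level,
#'   microsiemens (physiological SCL sits between 2 and 20 uS).
#' @param tonic_fear_gain multiplicative tonic raise during fear trials
#'   (`>= 1`).
#' @param ibi_mean mean inter-beat interval, s.
#' @param ibi_sd_nofear,ibi_sd_fear inter-beat-interval standard deviations,
#'   s; fear reduces variability so `ibi_sd_fear <= ibi_sd_nofear`.
#' @param noise_sd Gaussian measurement noise on the conductance channel,
#'   microsiemens.
#' @param scr_rise_s,scr_decay_s time constants of the bi-exponential SCR
#'   kernel, s.
#' @param scr_min_separation_s minimum spacing enforced between SCR onsets
#'   within a trial, s (0 disables thinning; events are then a homogeneous
#'   Poisson process).
#' @param seed integer seed governing all randomness.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_trials = 40, fs_raw = 512, baseline_s = 5,
                       trial_s = 60, fear_fraction = 0.15,
                       scr_rate_nofear = 2, scr_rate_fear = 6,
                       scr_amp_range = c(0.1, 1.3),
                       tonic_level_range = c(2, 12),
                       tonic_fear_gain = 1.3,
                       ibi_mean = 0.85, ibi_sd_nofear = 0.06,
                       ibi_sd_fear = 0.03, noise_sd = 0.01,
                       scr_rise_s = 0.75, scr_decay_s = 2,
                       scr_min_separation_s = 0, seed = 1L) {
  cfg <- list(n_trials = as.integer(n_trials), fs_raw = fs_raw,
              baseline_s = baseline_s, trial_s = trial_s,
              fear_fraction = fear_fraction,
              scr_rate_nofear = scr_rate_nofear,
              scr_rate_fear = scr_rate_fear,
              scr_amp_range = scr_amp_range,
              tonic_level_range = tonic_level_range,
              tonic_fear_gain = tonic_fear_gain,
              ibi_mean = ibi_mean, ibi_sd_nofear = ibi_sd_nofear,
              ibi_sd_fear = ibi_sd_fear, noise_sd = noise_sd,
              scr_rise_s = scr_rise_s, scr_decay_s = scr_decay_s,
              scr_min_separation_s = scr_min_separation_s,
              seed = as.integer(seed))
  if (cfg$n_trials < 1) stop("configuration error: n_trials must be >= 1")
  if (cfg$fear_fraction < 0 || cfg$fear_fraction > 1)
    stop("configuration error: fear_fraction must lie in [0, 1]")
  pos <- c("fs_raw", "baseline_s", "trial_s", "ibi_mean", "ibi_sd_nofear",
           "ibi_sd_fear", "scr_rise_s", "scr_decay_s")
  for (nm in pos)
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop("configuration error: ", nm, " must be positive")
  if (cfg$scr_rate_nofear < 0 || cfg$scr_rate_fear < 0)
    stop("configuration error: SCR rates must be non-negative")
  if (cfg$scr_rate_fear < cfg$scr_rate_nofear)
    stop("configuration error: scr_rate_fear must be >= scr_rate_nofear")
  if (cfg$ibi_sd_fear > cfg$ibi_sd_nofear)
    stop("configuration error: ibi_sd_fear must be <= ibi_sd_nofear")
  if (cfg$noise_sd < 0) stop("configuration error: noise_sd must be >= 0")
  if (cfg$tonic_fear_gain < 1)
    stop("configuration error: tonic_fear_gain must be >= 1")
  if (diff(cfg$scr_amp_range) < 0 || any(cfg$scr_amp_range < 0))
    stop("configuration error: scr_amp_range must be a non-negative interval")
  if (diff(cfg$tonic_level_range) < 0 || any(cfg$tonic_level_range <= 0))
    stop("configuration error: tonic_level_range must be a positive interval")
  if (cfg$scr_decay_s <= cfg$scr_rise_s)
    stop("configuration error: scr_decay_s must exceed scr_rise_s")
  class(cfg) <- "sim_config"
  cfg
}

# Status-channel marker codes of the session CSV dialect.
STATUS_BASELINE_ONSET <- 1L
STATUS_TRIAL_ONSET <- 4L

#' Bi-exponential skin-conductance-response kernel
#'
#' `h(t) = (exp(-t/decay) - exp(-t/rise))`, normalised to unit peak so that
#' an event of amplitude `a` contributes a waveform whose trough-to-peak
#' excursion is `a`.
#'
#' @param t times, s (values `< 0` map to 0).
#' @param rise_s,decay_s rise and decay time constants, s.
#' @return kernel values.
#' @export
scr_kernel <- function(t, rise_s = 0.75, decay_s = 2) {
  tp <- log(decay_s / rise_s) * rise_s * decay_s / (decay_s - rise_s)
  peak <- exp(-tp / decay_s) - exp(-tp / rise_s)
  out <- numeric(length(t))
  ok <- t >= 0
  out[ok] <- (exp(-t[ok] / decay_s) - exp(-t[ok] / rise_s)) / peak
  out
}

#' Sample dimensional ratings consistent with a fear flag
#'
#' Fear maps to the region `valence <= 5 & arousal > 5 & dominance <= 5` of
#' the 1-9 rating cube.  Fear trials are sampled uniformly inside the region;
#' non-fear trials uniformly over its complement (by rejection), so every
#' violation mode -- including boundary cases such as valence exactly 5 --
#' occurs.
#'
#' @param fear 0/1 flag (or logical).
#' @param seed optional integer seed.
#' @return named numeric vector `c(valence, arousal, dominance)`.
#' @export
generate_ratings <- function(fear, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (as.integer(fear) == 1L) {
    v <- runif(1, 1, 5)
    a <- 5 + runif(1) * 4
    if (a <= 5) a <- 5 + 1e-6   # runif can return an endpoint
    d <- runif(1, 1, 5)
  } else {
    repeat {
      v <- runif(1, 1, 9); a <- runif(1, 1, 9); d <- runif(1, 1, 9)
      if (!(v <= 5 && a > 5 && d <= 5)) break
    }
  }
  c(valence = v, arousal = a, dominance = d)
}

# Draw SCR onset times for one stimulus interval: homogeneous Poisson
# process, optionally thinned to a minimum onset separation.
draw_scr_onsets <- function(rate_per_min, trial_s, min_sep) {
  n <- rpois(1, rate_per_min * trial_s / 60)
  if (n == 0) return(numeric(0))
  on <- sort(runif(n, 0, trial_s - 2))   # leave room for the rising edge
  if (min_sep > 0 && length(on) > 1) {
    keep <- c(TRUE, diff(on) >= min_sep)
    while (!all(keep)) {                  # re-thin against kept predecessors
      on <- on[keep]
      if (length(on) < 2) break
      keep <- c(TRUE, diff(on) >= min_sep)
    }
  }
  on
}

# Draw one trial's beat times over [0, dur] s: IBIs are ibi_mean plus a slow
# 0.1 Hz respiratory-style modulation plus Gaussian jitter, truncated away
# from non-physiological values.
draw_beats <- function(dur, ibi_mean, ibi_sd, mod_amp = 0.02) {
  t <- ibi_mean * runif(1)  # random phase offset of the first beat
  beats <- numeric(0)
  while (t <= dur) {
    beats <- c(beats, t)
    ibi <- ibi_mean + mod_amp * sin(2 * pi * 0.1 * t) + rnorm(1, 0, ibi_sd)
    ibi <- max(ibi, 0.25)
    t <- t + ibi
  }
  beats
}

#' Generate a full raw session with ground truth
#'
#' Builds the three raw channels at `fs_raw`: skin conductance as a slowly
#' varying tonic level plus bi-exponential SCR kernels plus Gaussian noise; a
#' photoplethysmogram as a train of Gaussian pulse bumps centred on the
#' ground-truth beat times; and a status channel with marker
#' `1` at each baseline onset and `4` at each trial onset.  Fear trials are
#' drawn i.i.d. with probability `fear_fraction` (or fixed to exactly
#' `n_fear` trials) and receive the fear SCR rate, the tonic gain and the
#' reduced inter-beat variability; ratings are sampled so the fear rule of
#' [label_fear()] reproduces the flag.
#'
#' @param config a [sim_config()].
#' @param subject_id identifier stored with the recording.
#' @param n_fear optionally fix the exact number of fear trials.
#' @return a list with components `recording` (class `session_recording`:
#'   `gsr`, `ppg`, `status`, `fs`, `subject_id`) and `ground_truth` (class
#'   `ground_truth`: per-trial ratings/fear table, SCR event lists with
#'   onsets relative to each stimulus onset, beat-time lists relative to each
#'   baseline onset).
#' @export
generate_session <- function(config = sim_config(), subject_id = "S01",
                             n_fear = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fs <- config$fs_raw
  trial_len <- round((config$baseline_s + config$trial_s) * fs)
  n <- config$n_trials
  total <- trial_len * n

  if (is.null(n_fear)) {
    fear <- rbinom(n, 1, config$fear_fraction)
  } else {
    stopifnot(n_fear >= 0, n_fear <= n)
    fear <- integer(n)
    fear[sample.int(n, n_fear)] <- 1L
  }

  # Session-wide tonic drift: level plus a slow sinusoid.
  level <- runif(1, config$tonic_level_range[1], config$tonic_level_range[2])
  tt <- (seq_len(total) - 1) / fs
  phase <- runif(1, 0, 2 * pi)
  tonic <- level * (1 + 0.04 * sin(2 * pi * tt / 600 + phase))

  gsr <- tonic
  ppg <- numeric(total)
  status <- integer(total)
  ratings <- matrix(NA_real_, n, 3,
                    dimnames = list(NULL, c("valence", "arousal", "dominance")))
  events <- vector("list", n)
  beats <- vector("list", n)
  bump_sd <- 0.04
  bump_half <- ceiling(5 * bump_sd * fs)

  for (i in seq_len(n)) {
    off <- (i - 1L) * trial_len              # samples before this trial
    b0 <- off + 1L                           # baseline onset sample
    s0 <- off + round(config$baseline_s * fs) + 1L  # stimulus onset sample
    status[b0] <- STATUS_BASELINE_ONSET
    status[s0] <- STATUS_TRIAL_ONSET

    # tonic raise during fear stimulus, with 2 s cosine ramps
    if (fear[i] == 1L && config$tonic_fear_gain > 1) {
      idx <- s0:(off + trial_len)
      tloc <- (idx - s0) / fs
      ramp <- pmin(1, tloc / 2)
      ramp <- 0.5 - 0.5 * cos(pi * ramp)
      gsr[idx] <- gsr[idx] + (config$tonic_fear_gain - 1) * level * ramp
    }

    rate <- if (fear[i] == 1L) config$scr_rate_fear else config$scr_rate_nofear
    on <- draw_scr_onsets(rate, config$trial_s, config$scr_min_separation_s)
    amp <- runif(length(on), config$scr_amp_range[1], config$scr_amp_range[2])
    events[[i]] <- data.frame(onset = on, amplitude = amp)
    for (k in seq_along(on)) {
      o_samp <- s0 + round(on[k] * fs)
      tail_idx <- o_samp:min(total, o_samp + 30L * fs)
      gsr[tail_idx] <- gsr[tail_idx] +
        amp[k] * scr_kernel((tail_idx - o_samp) / fs,
                            config$scr_rise_s, config$scr_decay_s)
    }

    sd_i <- if (fear[i] == 1L) config$ibi_sd_fear else config$ibi_sd_nofear
    bt <- draw_beats(config$baseline_s + config$trial_s,
                     config$ibi_mean, sd_i)
    beats[[i]] <- bt
    for (b in bt) {
      c_samp <- off + round(b * fs) + 1L
      idx <- max(1L, c_samp - bump_half):min(total, c_samp + bump_half)
      ppg[idx] <- ppg[idx] +
        exp(-((idx - c_samp) / fs)^2 / (2 * bump_sd^2))
    }

    ratings[i, ] <- generate_ratings(fear[i])
  }

  if (config$noise_sd > 0) gsr <- gsr + rnorm(total, 0, config$noise_sd)

  recording <- structure(
    list(gsr = gsr, ppg = ppg, status = status, fs = fs,
         subject_id = subject_id),
    class = "session_recording")
  gt <- structure(
    list(trials = data.frame(trial = seq_len(n), fear = fear,
                             valence = ratings[, 1], arousal = ratings[, 2],
                             dominance = ratings[, 3]),
         events = events, beats = beats, tonic_level = level),
    class = "ground_truth")
  list(recording = recording, ground_truth = gt)
}

#' Simulate segmented trial records directly at 16 samples/s
#'
#' A trial-level shortcut past the raw 512 Hz stage: emits `trial_record`
#' objects (5 s baseline + 60 s stimulus skin conductance at 16 samples/s,
#' beat times, ratings, fear label) built from the same trial model as
#' [generate_session()] -- flat-plus-drift tonic, bi-exponential SCR kernels,
#' Gaussian noise, modulated inter-beat intervals.  Intended for cohort-scale
#' experiments where synthesising and filtering megasample raw channels would
#' dominate the runtime.
#'
#' @param config a [sim_config()].
#' @param n_trials number of trials (defaults to `config$n_trials`).
#' @param n_fear optionally fix the exact number of fear trials.
#' @param subject_id identifier stored on each record.
#' @param fs processed sampling rate, samples/s.
#' @return list with `trials` (list of `trial_record`) and `ground_truth`.
#' @export
simulate_trial_records <- function(config = sim_config(), n_trials = NULL,
                                   n_fear = NULL, subject_id = "S01",
                                   fs = 16) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- if (is.null(n_trials)) config$n_trials else as.integer(n_trials)
  if (is.null(n_fear)) {
    fear <- rbinom(n, 1, config$fear_fraction)
  } else {
    stopifnot(n_fear >= 0, n_fear <= n)
    fear <- integer(n)
    fear[sample.int(n, n_fear)] <- 1L
  }
  nb <- round(config$baseline_s * fs)
  nt <- round(config$trial_s * fs)
  t_all <- (seq_len(nb + nt) - 1) / fs      # time from baseline onset
  trials <- vector("list", n)
  events <- vector("list", n)
  beats <- vector("list", n)
  ratings <- matrix(NA_real_, n, 3)

  for (i in seq_len(n)) {
    level <- runif(1, config$tonic_level_range[1], config$tonic_level_range[2])
    slope <- runif(1, -0.005, 0.005)
    g <- level + slope * t_all
    if (fear[i] == 1L && config$tonic_fear_gain > 1) {
      tloc <- pmax(0, t_all - config$baseline_s)
      ramp <- 0.5 - 0.5 * cos(pi * pmin(1, tloc / 2))
      ramp[t_all < config$baseline_s] <- 0
      g <- g + (config$tonic_fear_gain - 1) * level * ramp
    }
    rate <- if (fear[i] == 1L) config$scr_rate_fear else config$scr_rate_nofear
    on <- draw_scr_onsets(rate, config$trial_s, config$scr_min_separation_s)
    amp <- runif(length(on), config$scr_amp_range[1], config$scr_amp_range[2])
    events[[i]] <- data.frame(onset = on, amplitude = amp)
    for (k in seq_along(on))
      g <- g + amp[k] * scr_kernel(t_all - config$baseline_s - on[k],
                                   config$scr_rise_s, config$scr_decay_s)
    if (config$noise_sd > 0) g <- g + rnorm(length(g), 0, config$noise_sd)

    sd_i <- if (fear[i] == 1L) config$ibi_sd_fear else config$ibi_sd_nofear
    bt <- draw_beats(config$baseline_s + config$trial_s,
                     config$ibi_mean, sd_i)
    beats[[i]] <- bt
    r <- generate_ratings(fear[i])
    ratings[i, ] <- r
    trials[[i]] <- new_trial_record(
      baseline_gsr = g[seq_len(nb)],
      trial_gsr = g[(nb + 1):(nb + nt)],
      beat_times = bt, valence = r[1], arousal = r[2], dominance = r[3],
      fear = fear[i], subject_id = subject_id, trial_index = i, fs = fs)
  }
  gt <- structure(
    list(trials = data.frame(trial = seq_len(n), fear = fear,
                             valence = ratings[, 1], arousal = ratings[, 2],
                             dominance = ratings[, 3]),
         events = events, beats = beats),
    class = "ground_truth")
  list(trials = trials, ground_truth = gt)
}

# Constructor shared by the generator and the segmentation stage.
new_trial_record <- function(baseline_gsr, trial_gsr, beat_times, valence,
                             arousal, dominance, fear, subject_id,
                             trial_index, fs = 16) {
  structure(list(baseline_gsr = as.numeric(baseline_gsr),
                 trial_gsr = as.numeric(trial_gsr),
                 beat_times = as.numeric(beat_times),
                 valence = unname(valence), arousal = unname(arousal),
                 dominance = unname(dominance), fear = as.integer(fear),
                 subject_id = subject_id,
                 trial_index = as.integer(trial_index), fs = fs),
            class = "trial_record")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> subject %s: %d samples at %g Hz (%.1f s), %d trial markers\n",
              x$subject_id, length(x$gsr), x$fs, length(x$gsr) / x$fs,
              sum(x$status == STATUS_TRIAL_ONSET)))
  invisible(x)
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> subject %s trial %d: fear=%d, %d baseline + %d stimulus samples, %d beats\n",
              x$subject_id, x$trial_index, x$fear, length(x$baseline_gsr),
              length(x$trial_gsr), length(x$beat_times)))
  invisible(x)
}
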