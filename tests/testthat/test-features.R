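# Fear rule, windowing, the 40-feature registry and dataset assembly.

test_that("the fear rule is a strict conjunction with inclusive boundaries", {
  expect_equal(label_fear(3, 7, 2), 1L)
  expect_equal(label_fear(5, 5, 5), 0L)       # arousal must exceed 5
  expect_equal(label_fear(5, 5.001, 5), 1L)   # valence/dominance inclusive
  expect_equal(label_fear(5.001, 7, 5), 0L)
  expect_equal(label_fear(5, 7, 5.001), 0L)
  expect_equal(label_fear(c(3, 6), c(7, 7), c(2, 2)), c(1L, 0L))
  expect_error(label_fear(0.5, 7, 2), "validation error")
  expect_error(label_fear(3, 9.5, 2), "validation error")
})

test_that("window schemes cover the trial as specified", {
  w3 <- make_windows(60, window_scheme("non_overlapping"))
  expect_equal(w3$start_s, c(0, 20, 40))
  expect_equal(w3$end_s, c(20, 40, 60))
  w5 <- make_windows(60, window_scheme("overlapping"))
  expect_equal(w5$start_s, c(0, 10, 20, 30, 40))
  expect_equal(w5$end_s, c(20, 30, 40, 50, 60))
  # non-overlapping windows are disjoint and cover [0, 60)
  expect_true(all(w3$start_s[-1] == w3$end_s[-3]))
})

test_that("the registry holds exactly 33 EDA and 7 HRV features", {
  fn <- feature_names()
  expect_length(fn, 40L)
  hrv <- grep("^HR", fn, value = TRUE)
  expect_length(hrv, 7L)
  expect_length(setdiff(fn, hrv), 33L)
  expect_true(all(c("GSR_nimp", "GSR_avimp", "GSR_maximp") %in% fn))
})

test_that("time-domain features match hand-evaluated examples", {
  f <- eda_time_features(c(1, -1, 1, -1), xb = c(1, -1, 1, -1))
  expect_equal(f[["mav"]], 1)
  expect_equal(f[["ssc"]], 2)
  expect_equal(f[["wamp"]], 3)
  expect_equal(f[["mar"]], 1)
  expect_equal(eda_time_features(c(0, 1, 3))[["wl"]], 5)  # 1^2 + 2^2
  expect_equal(eda_time_features(c(0, 1, 3), wl_squared = FALSE)[["wl"]], 3)
  # constant signal: ratios degenerate, counts zero
  fc <- eda_time_features(rep(2, 10), xb = rep(2, 10))
  expect_equal(fc[["mav"]], 2)
  expect_equal(fc[["mar"]], 1)
  expect_equal(fc[["std"]], 0)
  expect_equal(fc[["wl"]], 0)
  expect_equal(fc[["ssc"]], 0)
  expect_equal(fc[["wamp"]], 0)
  expect_true(is.na(fc[["str"]]))             # zero-variance baseline
})

test_that("time-domain features equal brute-force formula evaluation", {
  set.seed(42)
  for (i in 1:250) {
    n <- sample(5:40, 1)
    x <- round(rnorm(n, sd = runif(1, 0.01, 2)), 4)
    xb <- round(rnorm(sample(5:20, 1), mean = 1, sd = 0.5), 4)
    f <- eda_time_features(x, xb)
    expect_equal(f[["mav"]], o_mav(x), tolerance = 1e-9)
    expect_equal(f[["std"]], o_std(x), tolerance = 1e-9)
    expect_equal(f[["wl"]], o_wl(x), tolerance = 1e-9)
    expect_equal(f[["ssc"]], o_ssc(x))
    expect_equal(f[["wamp"]], o_wamp(x))
    expect_equal(f[["mar"]], o_mav(x) / o_mav(xb), tolerance = 1e-9)
    expect_equal(f[["str"]], o_std(x) / o_std(xb), tolerance = 1e-9)
  }
})

test_that("the periodogram sits on the exact 801-line grid and conserves energy", {
  x <- sin(2 * pi * 1 * (0:319) / 16)
  ps <- power_spectrum(x, fs = 16)
  expect_length(ps$freqs, 801L)
  expect_equal(ps$freqs[1], 0)
  expect_equal(ps$freqs[801], 8)
  expect_equal(diff(ps$freqs), rep(0.01, 800), tolerance = 1e-12)
  expect_true(all(ps$power >= 0))
  expect_equal(ps$freqs[which.max(ps$power)], 1, tolerance = 0.011)

  # Parseval: the one-sided line sum is proportional to the mean-removed
  # energy with constant npad/N, within 1%
  set.seed(3)
  for (i in 1:20) {
    xr <- rnorm(sample(c(64, 160, 320), 1))
    ps2 <- power_spectrum(xr, fs = 16)
    expect_equal(sum(ps2$power),
                 (1600 / length(xr)) * sum((xr - mean(xr))^2),
                 tolerance = 0.01)
  }
  expect_true(all(is.na(power_spectrum(rep(NA_real_, 10))$power)))
})

test_that("spectral features match their definitions on crafted spectra", {
  grid <- seq(0, 8, by = 0.01)
  mk <- function(lines) {
    p <- numeric(length(grid))
    for (l in lines) p[round(l[1] / 0.01) + 1] <- l[2]
    structure(list(freqs = grid, power = p), class = "spectral_density")
  }
  one <- mk(list(c(1.5, 2)))
  sf <- spectral_features(one)
  expect_equal(sf[["fmd"]], 1.5)
  expect_equal(sf[["fmn"]], 1.5)
  two <- mk(list(c(1, 1), c(3, 1)))
  expect_equal(spectral_features(two)[["fmn"]], 2)
  ratio <- mk(list(c(0.1, 1), c(1, 1)))
  expect_equal(spectral_features(ratio)[["hlr"]], 1)
  zero <- mk(list())
  expect_true(all(is.na(spectral_features(zero)[c("fmd", "fmn")])))

  # random positive spectra against the loop oracles
  set.seed(7)
  for (i in 1:200) {
    p <- runif(length(grid))^3
    psd <- structure(list(freqs = grid, power = p),
                     class = "spectral_density")
    sf <- spectral_features(psd)
    expect_equal(sf[["fmd"]], o_fmd(grid, p), tolerance = 1e-12)
    expect_equal(sf[["fmn"]], o_fmn(grid, p), tolerance = 1e-9)
    expect_equal(sf[["hlr"]], o_hlr(grid, p, c(0.01, 0.2), c(0.2, 2)),
                 tolerance = 1e-9)
  }
})

test_that("event features follow the printed conventions", {
  ev <- data.frame(onset = c(2, 9), amplitude = c(0.4, 0.8))
  f <- event_features(ev, 0, 20)
  expect_equal(unname(f), c(2, 0.6, 0.8))
  expect_equal(unname(event_features(ev[0, ], 0, 20)), c(0, 0, 0))
  # membership by onset, half-open window
  ev2 <- data.frame(onset = c(25, 20, 19.99), amplitude = c(1, 1, 0.5))
  f2 <- event_features(ev2, 0, 20)
  expect_equal(f2[["nimp"]], 1)
  expect_equal(f2[["maximp"]], 0.5)
})

test_that("HRV features match direct evaluation of their formulas", {
  f <- hrv_features(c(0.80, 0.86, 0.87))
  expect_equal(f[["NN50"]], 1)
  expect_equal(f[["NN20"]], 1)           # |0.87-0.86| = 0.01 < 0.02
  expect_equal(f[["pNN50"]], 1 / 3)
  expect_equal(f[["pNN20"]], 1 / 3)
  expect_equal(f[["HR_std"]], o_std(c(0.80, 0.86, 0.87)), tolerance = 1e-12)
  expect_equal(f[["HRV_std"]], o_hrv_std(c(0.80, 0.86, 0.87)),
               tolerance = 1e-12)

  fc <- hrv_features(rep(0.8, 10))
  expect_equal(unname(fc[c("HR_std", "HRV_std", "NN50", "NN20")]),
               c(0, 0, 0, 0))

  set.seed(12)
  for (i in 1:100) {
    ib <- round(runif(sample(4:30, 1), 0.6, 1.1), 3)
    f <- hrv_features(ib)
    expect_equal(f[["HR_std"]], o_std(ib), tolerance = 1e-9)
    expect_equal(f[["HRV_std"]], o_hrv_std(ib), tolerance = 1e-9)
    expect_equal(f[["NN50"]], o_nn_count(ib, 0.05))
    expect_equal(f[["NN20"]], o_nn_count(ib, 0.02))
    expect_equal(f[["pNN50"]], o_nn_count(ib, 0.05) / length(ib))
    expect_equal(f[["pNN20"]], o_nn_count(ib, 0.02) / length(ib))
  }
  expect_true(is.na(hrv_features(c(0.8))[["NN50"]]))
})

test_that("a slow pure IBI modulation concentrates tachogram energy in the low band", {
  bt <- cumsum(rep(0.8, 80))
  ib <- 0.8 + 0.05 * sin(2 * pi * 0.1 * bt)
  f <- hrv_features(ib, beat_times = bt)
  expect_lt(f[["hlr"]], 0.2)
})

test_that("extract_trial produces one labeled feature row per window", {
  sim <- simulate_trial_records(sim_config(n_trials = 2, seed = 17), n_fear = 1)
  tr <- sim$trials[[which(sim$ground_truth$trials$fear == 1)]]
  r3 <- extract_trial(tr, window_scheme("non_overlapping"))
  expect_equal(nrow(r3), 3L)
  expect_true(all(feature_names() %in% names(r3)))
  expect_equal(r3$label, rep(1L, 3))
  r5 <- extract_trial(tr, window_scheme("overlapping"))
  expect_equal(nrow(r5), 5L)
  expect_equal(r5$label, rep(1L, 5))
  expect_equal(r5$window_index, 1:5)
})

test_that("windows with identical content yield identical feature rows", {
  tt20 <- (0:(20 * 16 - 1)) / 16
  pat <- 5 + 0.7 * scr_kernel(tt20 - 6)
  tr <- physiofear:::new_trial_record(
    baseline_gsr = rep(5, 80), trial_gsr = rep(pat, 3),
    beat_times = seq(0.4, 64.8, by = 0.8),
    valence = 3, arousal = 7, dominance = 3, fear = 1,
    subject_id = "S", trial_index = 1)
  r <- extract_trial(tr, window_scheme("non_overlapping"))
  gsr_cols <- grep("^GSR_", feature_names(), value = TRUE)
  for (cl in gsr_cols)
    expect_equal(r[[cl]][1], r[[cl]][2], tolerance = 1e-4, label = cl)
  expect_equal(r$GSR_nimp, rep(1, 3))
})

test_that("positive scaling acts on amplitudes and leaves shape features fixed", {
  set.seed(9)
  x <- 3 + cumsum(rnorm(320, sd = 0.05))
  xb <- 3 + cumsum(rnorm(80, sd = 0.05))
  c_ <- 2.7
  f1 <- eda_time_features(x, xb)
  f2 <- eda_time_features(c_ * x, c_ * xb)
  expect_equal(f2[["mav"]], c_ * f1[["mav"]], tolerance = 1e-9)
  expect_equal(f2[["std"]], c_ * f1[["std"]], tolerance = 1e-9)
  expect_equal(f2[["mar"]], f1[["mar"]], tolerance = 1e-9)
  expect_equal(f2[["str"]], f1[["str"]], tolerance = 1e-9)
  s1 <- spectral_features(power_spectrum(x))
  s2 <- spectral_features(power_spectrum(c_ * x))
  expect_equal(s1[["fmd"]], s2[["fmd"]], tolerance = 1e-12)
  expect_equal(s1[["fmn"]], s2[["fmn"]], tolerance = 1e-9)
  expect_equal(s1[["hlr"]], s2[["hlr"]], tolerance = 1e-9)
  ib <- runif(20, 0.7, 1)
  expect_equal(hrv_features(ib)[["pNN50"]], hrv_features(ib)[["pNN50"]])
})

test_that("dataset assembly obeys the column layouts and imputes by median", {
  sim <- simulate_trial_records(sim_config(n_trials = 6, seed = 23), n_fear = 2)
  ds3 <- suppressMessages(
    assemble_dataset(sim$trials, window_scheme("non_overlapping")))
  expect_equal(dim(ds3$X), c(6L, 120L))
  expect_true(all(paste0(feature_names(), "[W1]") %in% colnames(ds3$X)))
  expect_equal(sum(ds3$y), 2L)
  ds5 <- suppressMessages(
    assemble_dataset(sim$trials, window_scheme("overlapping")))
  expect_equal(dim(ds5$X), c(30L, 40L))
  expect_equal(sum(ds5$y), 10L)
  expect_false(anyNA(ds5$X))
  expect_error(assemble_dataset(list()), "validation error")

  f <- tempfile(fileext = ".csv")
  write_dataset_csv(ds5, f)
  back <- read_dataset_csv(f, "overlapping")
  expect_equal(back$X, ds5$X, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back$y, ds5$y)
})

test_that("fear trials show more SCRs and less IBI spread than non-fear trials", {
  coh <- strong_effect_cohort()
  ds <- coh$dataset
  f <- ds$y
  nimp <- rowMeans(ds$X[, paste0("GSR_nimp[W", 1:3, "]")])
  hrstd <- rowMeans(ds$X[, paste0("HR_std[W", 1:3, "]")])
  expect_gt(mean(nimp[f == 1]), mean(nimp[f == 0]))
  expect_lt(mean(hrstd[f == 1]), mean(hrstd[f == 0]))
  expect_lt(stats::wilcox.test(nimp[f == 1], nimp[f == 0],
                               alternative = "greater")$p.value, 0.01)
  expect_lt(stats::wilcox.test(hrstd[f == 1], hrstd[f == 0],
                               alternative = "less")$p.value, 0.01)
})
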