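# Shared synthetic cohorts, built once per test run.

.pf_cache <- new.env(parent = emptyenv())

# 200-trial cohort under the stated strong fear effect -- SCR rate tripled
# and inter-beat variability halved, with the tonic channel held flat so
# exactly those two effect channels drive the labels -- extracted under the
# non-overlapping scheme.
strong_effect_cohort <- function() {
  if (is.null(.pf_cache$strong)) {
    cfg <- sim_config(n_trials = 200, tonic_fear_gain = 1, seed = 101L)
    sim <- simulate_trial_records(cfg)
    ds <- suppressMessages(
      assemble_dataset(sim$trials, window_scheme("non_overlapping")))
    .pf_cache$strong <- list(sim = sim, dataset = ds)
  }
  .pf_cache$strong
}

# small raw 512 Hz session reused by segmentation / beat tests
small_session <- function() {
  if (is.null(.pf_cache$session)) {
    cfg <- sim_config(n_trials = 4, seed = 7L)
    .pf_cache$session <- generate_session(cfg)
  }
  .pf_cache$session
}

ratings_table <- function(gt) {
  f <- tempfile(fileext = ".csv")
  write_ratings_csv(gt, f)
  on.exit(unlink(f))
  read_ratings_csv(f)
}
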