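# Shared fixtures. The full-scale cohort (11 normal + 5 CVD at the default
# simulation settings) is expensive, so it is built once per test run and
# memoized, together with its preprocessed form and feature matrix.

.fixture_cache <- new.env(parent = emptyenv())

memoize <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small, fast configuration for unit tests: 3 trials per session, no
# artifact transients (rejection behavior is tested explicitly).
small_cfg <- function(...) {
  sim_config(n_trials_per_session = 3, artifact_rate = 0, ...)
}

small_cohort <- function() {
  memoize("small_cohort", function() {
    simulate_cohort(3, 2, small_cfg(), seed = 42)
  })
}

small_preprocessed <- function() {
  memoize("small_pre", function() {
    cohort <- small_cohort()
    pre <- lapply(cohort$recording, preprocess_recording,
                  n_trials_per_session = 3)
    names(pre) <- cohort$subject_id
    pre
  })
}

full_cohort <- function() {
  memoize("full_cohort", function() {
    simulate_cohort(11, 5, sim_config(), seed = 7)
  })
}

full_preprocessed <- function() {
  memoize("full_pre", function() {
    cohort <- full_cohort()
    pre <- lapply(cohort$recording, preprocess_recording)
    names(pre) <- cohort$subject_id
    pre
  })
}

full_features <- function() {
  memoize("full_features", function() {
    extract_features(full_preprocessed(), labels = full_cohort()$condition)
  })
}

# A pure sinusoidal recording for filter-response checks.
tone_recording <- function(freq, fs = 250, dur = 4, n_ch = 2, amp = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  eeg_recording(matrix(rep(amp * sin(2 * pi * freq * t), each = n_ch),
                       nrow = n_ch, byrow = FALSE),
                channel_names = paste0("ch", seq_len(n_ch)), fs = fs)
}

rms <- function(x) sqrt(mean(x^2))
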