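# Shared fixtures, built once per test run and memoized. All synthetic, all
# seeded.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, build(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# 60 s noise-free, drift-free record: every beat identical, demodulation and
# labeling can be checked against exact truth.
clean_record <- function() {
  memo("clean_record", function() {
    simulate_subject(sim_config(duration_s = 60, noise_sd = 0,
                                bp_drift_sd = 0, seed = 7))
  })
}

# 60 s record with drift and noise at default (rest) conditions.
noisy_record <- function() {
  memo("noisy_record", function() {
    simulate_subject(sim_config(duration_s = 60, seed = 3))
  })
}

clean_prep <- function() {
  memo("clean_prep", function() preprocess_record(clean_record()))
}

# Small strongly-coupled cohort of windows for training tests.
coupled_windows <- function() {
  memo("coupled_windows", function() {
    base <- sim_config(duration_s = 90, pulse_amp_gain = 0.02,
                       noise_sd = 0.1, seed = 1)
    build_windows(simulate_cohort(4, base, seed = 41))$windows
  })
}

tiny_resnet_cfg <- function() resnet_config(stem_width = 4L, feature_dim = 8L)

expect_close <- function(object, expected, tol = 1e-9) {
  expect_true(max(abs(object - expected)) < tol,
              label = sprintf("max|diff| = %g", max(abs(object - expected))))
}
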