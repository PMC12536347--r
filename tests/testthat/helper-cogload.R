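# Shared fixtures, built in code and memoised across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# One short session (10 min protocol), strong effect.
quick_session <- function(effect = 1, seed = 42) {
  cached(sprintf("session_%g_%d", effect, seed), {
    generate_session(generator_config(),
                     default_profile(scale = 1 / 5, effect_size = effect),
                     "P01", seed = seed)
  })
}

# Feature table of a 10-participant study at one-third scale (15 windows
# per participant); the size used throughout the calibration checks.
study_table <- function(effect, seed) {
  cached(sprintf("study_%g_%d", effect, seed), {
    sess <- simulate_study(generator_config(),
                           default_profile(scale = 1 / 3, effect_size = effect),
                           n_participants = 10, seed = seed)
    suppressWarnings(build_feature_table(sess))
  })
}

# Random feature table with no physiological content: `signal` features
# carry the label linearly, the rest are noise.
random_table <- function(n_participants = 4, windows_per = 12, n_features = 10,
                         signal = 0, seed = 1, n_classes_span = 5) {
  set.seed(seed)
  n <- n_participants * windows_per
  resp <- rep_len(rep(seq_len(n_classes_span), length.out = windows_per),
                  n)
  X <- matrix(rnorm(n * n_features), n, n_features,
              dimnames = list(NULL, sprintf("f%02d", seq_len(n_features))))
  if (signal > 0)
    X[, 1] <- X[, 1] + signal * resp
  tab <- data.frame(
    participant_id = rep(sprintf("P%02d", seq_len(n_participants)),
                         each = windows_per),
    session_id = "S01",
    window_index = rep(seq_len(windows_per), n_participants),
    activity = rep_len(c("Relaxation", "Load", "Summary", "Reading", "Game"), n),
    environment = "controlled",
    workload_response = resp,
    stress_response = resp,
    check.names = FALSE)
  cbind(tab, as.data.frame(X, check.names = FALSE))
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
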