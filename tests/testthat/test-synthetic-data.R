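test_that("EEG synthesis is deterministic and amplitude-zero means silence", {
  a <- synthesize_eeg(c(20, 10, 15, 8, 4), duration_s = 4, seed = 5)
  b <- synthesize_eeg(c(20, 10, 15, 8, 4), duration_s = 4, seed = 5)
  expect_identical(a, b)
  c <- synthesize_eeg(c(20, 10, 15, 8, 4), duration_s = 4, seed = 6)
  expect_false(identical(a, c))
  z <- synthesize_eeg(rep(0, 5), duration_s = 2, seed = 1, noise_sd = 0)
  expect_true(all(z == 0))
  expect_error(synthesize_eeg(rep(1, 5), duration_s = -1), "positive")
})

test_that("an alpha-only configuration dominates every other band", {
  ratios <- sapply(1:20, function(s) {
    m <- synthesize_eeg(c(0, 0, 10, 0, 0), duration_s = 8, seed = s,
                        noise_sd = 0)
    x <- m[, 1]
    a <- band_power(x, 256, "alpha")
    others <- sapply(c("delta", "theta", "beta", "gamma"),
                     function(b) band_power(x, 256, b))
    a / max(others)
  })
  expect_gt(mean(ratios), 10)
})

test_that("metronomic PPG produces the expected number of systolic peaks", {
  for (hr in c(60, 90)) {
    x <- synthesize_ppg(hr, hrv_sd_ms = 0, duration_s = 60, seed = 2)
    expect_lte(abs(length(attr(x, "beat_times")) - hr), 1)
    b <- detect_beats(as.numeric(x), fs = 64)
    expect_lte(abs(length(b$beat_times) - hr), 1)
  }
  expect_error(synthesize_ppg(250, 0, 10), "bpm")
})

test_that("inter-beat jitter is recovered by beat detection", {
  sds <- sapply(1:20, function(s) {
    x <- synthesize_ppg(60, hrv_sd_ms = 50, duration_s = 300, seed = s)
    b <- detect_beats(as.numeric(x), fs = 64)
    sd(b$nn_intervals_ms)
  })
  expect_true(mean(sds) > 25 && mean(sds) < 100)
})

test_that("EDA output equals the tonic drift when no events are planted", {
  x <- synthesize_eda(tonic_level = seq(1, 2, length.out = 240),
                      duration_s = 60, noise_sd = 0)
  expect_equal(as.numeric(x), attr(x, "tonic"))
  x0 <- synthesize_eda(2, scr_event_times = c(10, 30), scr_amplitude = 0,
                       duration_s = 60, noise_sd = 0)
  expect_equal(as.numeric(x0), attr(x0, "tonic"))
  expect_error(synthesize_eda(2, scr_event_times = 70, duration_s = 60),
               "within")
  expect_error(synthesize_eda(-1, duration_s = 60), "non-negative")
})

test_that("planted SCR events are recovered by the downstream peak counter", {
  x <- synthesize_eda(2, scr_event_times = c(20, 60, 100), scr_amplitude = 0.5,
                      duration_s = 180, noise_sd = 0)
  de <- eda_decompose(as.numeric(x), fs = 4)
  expect_equal(scr_statistics(de$scr, 4)$num_scr_peaks, 3)
})

test_that("line-noise injection adds a pure 50 Hz component", {
  ch <- channel("eeg_af7", numeric(256 * 10), 256)
  expect_identical(inject_line_noise(ch, amplitude = 0), ch)
  noisy <- inject_line_noise(ch, amplitude = 2, seed = 3)
  expect_equal(band_power(noisy$samples, 256, c(49, 51)), 2^2 / 2,
               tolerance = 1e-6)
  cleaned <- notch_filter(noisy)
  expect_lt(band_power(cleaned$samples, 256, c(49, 51)),
            0.01 * band_power(noisy$samples, 256, c(49, 51)))
  expect_error(inject_line_noise(channel("eda", numeric(40), 4), amplitude = 1),
               "cannot inject")
})

test_that("sessions are deterministic and conserve modality sample counts", {
  s <- quick_session(effect = 1, seed = 42)
  s2 <- generate_session(generator_config(),
                         default_profile(scale = 1 / 5, effect_size = 1),
                         "P01", seed = 42)
  expect_identical(s$recording$channels$eeg_af7$samples,
                   s2$recording$channels$eeg_af7$samples)
  expect_identical(s$log, s2$log)
  dur <- max(s$log$end) - s$recording$channels$eeg_af7$start_time
  for (nm in names(s$recording$channels)) {
    ch <- s$recording$channels[[nm]]
    expect_lte(abs(length(ch$samples) - ch$fs * dur), ch$fs * 0.5 + 1)
  }
})

test_that("zero effect size decouples heart rate from the latent load", {
  rs <- sapply(c(9, 10, 11), function(sd) {
    s <- generate_session(generator_config(),
                          default_profile(scale = 1 / 2, effect_size = 0,
                                          label_noise_sd = 0),
                          "P01", seed = sd)
    w <- suppressWarnings(process_session(s, sync = FALSE))
    tab <- extract_features(w)
    load_per_block <- s$truth$latent_load[match(tab$activity, s$log$activity)]
    cor(load_per_block, tab[["Mean-Heart-Rate"]])
  })
  # null correlations at ~23 windows: mean |r| stays well below a real effect
  expect_lt(mean(abs(rs)), 0.3)
})

test_that("noiseless labels follow the latent load exactly", {
  prof <- load_profile(data.frame(activity = c("Relaxation", "Load"),
                                  duration_s = c(120, 120),
                                  latent_load = c(0, 1)),
                       effect_size = 1, label_noise_sd = 0)
  s <- generate_session(generator_config(), prof, "P01", seed = 4)
  expect_equal(s$log$workload_response, c(1, 5))
})

test_that("high load raises heart rate across seeds", {
  prof <- load_profile(data.frame(activity = c("Relaxation", "Load"),
                                  duration_s = c(120, 120),
                                  latent_load = c(0.1, 1)),
                       effect_size = 2, label_noise_sd = 0)
  wins <- sapply(1:10, function(sd) {
    s <- generate_session(generator_config(), prof, "P01", seed = sd)
    w <- suppressWarnings(process_session(s, sync = FALSE))
    tab <- extract_features(w)
    hr <- tapply(tab[["Mean-Heart-Rate"]], tab$activity, mean)
    hr[["Load"]] > hr[["Relaxation"]]
  })
  expect_gte(sum(wins), 9)  # sign test: >= 9/10 successes, p < 0.05
})

test_that("population export writes one directory per session, reproducibly", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- generator_config()
  prof <- default_profile(scale = 1 / 10, effect_size = 1)
  p1 <- generate_population(cfg, prof, n_participants = 2, sessions = 2,
                            directory = d1, seed = 5)
  expect_length(p1, 4)
  p2 <- generate_population(cfg, prof, n_participants = 2, sessions = 2,
                            directory = d2, seed = 5)
  for (i in seq_along(p1)) {
    for (fn in c("muse.csv", "EDA.csv", "BVP.csv", "TEMP.csv", "ACC.csv",
                 "protocol.json")) {
      expect_identical(readBin(file.path(p1[i], fn), "raw", 1e7),
                       readBin(file.path(p2[i], fn), "raw", 1e7))
    }
  }
  expect_error(simulate_study(cfg, prof, n_participants = 1, seed = 1),
               "2 participants")
})
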