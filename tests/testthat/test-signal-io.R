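make_small_recording <- function(seed = 1) {
  set.seed(seed)
  t0 <- 1.7e9
  mk <- function(name, fs, units, start = t0)
    channel(name, rnorm(round(fs * 20)), fs, start, units)
  chans <- list(
    eeg_af7 = mk("eeg_af7", 256, "uV"), eeg_af8 = mk("eeg_af8", 256, "uV"),
    eeg_tp9 = mk("eeg_tp9", 256, "uV"), eeg_tp10 = mk("eeg_tp10", 256, "uV"),
    gyro_x = mk("gyro_x", 50, "deg/s"), gyro_y = mk("gyro_y", 50, "deg/s"),
    gyro_z = mk("gyro_z", 50, "deg/s"), ppg_muse = mk("ppg_muse", 64, "a.u."),
    temp = mk("temp", 4, "degC", t0 + 2), eda = mk("eda", 4, "uS", t0 + 2),
    ppg_e4 = mk("ppg_e4", 64, "a.u.", t0 + 2),
    acc_x = mk("acc_x", 32, "g", t0 + 2), acc_y = mk("acc_y", 32, "g", t0 + 2),
    acc_z = mk("acc_z", 32, "g", t0 + 2))
  multimodal_recording("P01", "S01", chans, "controlled", device_offset_s = 2)
}

test_that("the wristband export round-trips field by field", {
  rec <- make_small_recording()
  d <- withr::local_tempdir()
  write_e4_export(rec, d)
  back <- read_e4_export(d)
  for (nm in c("temp", "eda", "ppg_e4", "acc_x", "acc_y", "acc_z")) {
    expect_equal(back[[nm]]$samples, rec$channels[[nm]]$samples)
    expect_equal(back[[nm]]$fs, rec$channels[[nm]]$fs)
    expect_equal(back[[nm]]$start_time, rec$channels[[nm]]$start_time)
  }
  expect_equal(back$eda$fs, 4)
  expect_equal(length(back$acc_x$samples), length(back$acc_z$samples))
  file.remove(file.path(d, "EDA.csv"))
  expect_error(read_e4_export(d), "EDA")
})

test_that("malformed wristband headers report file and line", {
  d <- withr::local_tempdir()
  write_e4_export(make_small_recording(), d)
  writeLines(c("oops", "4", "1", "2"), file.path(d, "EDA.csv"))
  expect_error(read_e4_export(d), "line 1")
})

test_that("the headband CSV round-trips and validates electrode names", {
  rec <- make_small_recording()
  path <- withr::local_tempfile(fileext = ".csv")
  write_muse_csv(rec, path)
  back <- read_muse_csv(path)
  for (nm in c("eeg_af7", "eeg_af8", "eeg_tp9", "eeg_tp10", "gyro_x",
               "ppg_muse")) {
    expect_equal(back[[nm]]$samples, rec$channels[[nm]]$samples)
    expect_equal(back[[nm]]$fs, rec$channels[[nm]]$fs)
    expect_equal(back[[nm]]$start_time, rec$channels[[nm]]$start_time)
  }
  # 256 rows per second for 20 s
  expect_length(back$eeg_af7$samples, 256 * 20)
  # a file holding only AF7 must name the three missing electrodes
  df <- utils::read.csv(path)
  df <- df[df$channel == "AF7", ]
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, p2, row.names = FALSE)
  err <- tryCatch(read_muse_csv(p2), error = conditionMessage)
  expect_match(err, "AF8"); expect_match(err, "TP9"); expect_match(err, "TP10")
  df$channel <- "XX9"
  utils::write.csv(df, p2, row.names = FALSE)
  expect_error(read_muse_csv(p2), "unknown channel")
})

test_that("protocol logs round-trip through JSON and enforce invariants", {
  log <- protocol_log(data.frame(
    activity = c("Relaxation", "Reading"), start = c(0, 600),
    end = c(600, 1200), environment = "controlled",
    workload_response = c(1, 4), stress_response = c(1, 3)))
  path <- withr::local_tempfile(fileext = ".json")
  write_protocol_json(log, path)
  back <- read_protocol_json(path)
  expect_equal(as.data.frame(back), as.data.frame(log))
  expect_error(protocol_log(data.frame(
    activity = "Relaxation", start = 10, end = 5, environment = "controlled",
    workload_response = 1, stress_response = 1)), "positive")
  expect_error(protocol_log(data.frame(
    activity = c("Relaxation", "Reading"), start = c(0, 100),
    end = c(300, 400), environment = "controlled",
    workload_response = 1, stress_response = 1)), "non-overlapping")
})

test_that("sync offset estimation recovers planted offsets", {
  # identical signals: offset zero
  set.seed(3)
  burst <- as.numeric(signal::filtfilt(signal::butter(4, 12 / 16, "low"),
                                       rnorm(32 * 3))) * 20
  x <- c(rnorm(32 * 5), burst, rnorm(32 * 52))
  a <- channel("a", x, 32, start_time = 0)
  expect_lt(abs(estimate_sync_offset(a, a)), 1 / 32)
  # a planted 2.5 s clock offset
  b <- channel("b", x, 32, start_time = 2.5)
  off <- estimate_sync_offset(a, b)
  expect_lt(abs(off - 2.5), 1 / 32)
  # uncorrelated noise: a low-confidence error, never a silent guess
  set.seed(4)
  n1 <- channel("a", rnorm(32 * 60), 32, 0)
  n2 <- channel("b", rnorm(32 * 60), 32, 0)
  expect_error(estimate_sync_offset(n1, n2), "0.5")
})

test_that("applying a recovered offset makes re-estimation idempotent", {
  s <- quick_session(effect = 1, seed = 42)
  rec <- s$recording
  off <- estimate_sync_offset(motion_magnitude(rec, "muse"),
                              motion_magnitude(rec, "e4"))
  expect_lt(abs(off - s$truth$device_offset_s), 1 / 32)
  rec2 <- apply_sync_offset(rec, off)
  off2 <- estimate_sync_offset(motion_magnitude(rec2, "muse"),
                               motion_magnitude(rec2, "e4"))
  expect_lt(abs(off2), 1 / 32)
})

test_that("the notch filter removes 50 Hz and preserves the passband", {
  t <- (0:(256 * 30 - 1)) / 256
  sine50 <- channel("eeg_af7", sin(2 * pi * 50 * t), 256)
  out <- notch_filter(sine50)
  expect_lt(mean(out$samples^2), 0.01 * mean(sine50$samples^2))
  sine10 <- channel("eeg_af7", sin(2 * pi * 10 * t), 256)
  out10 <- notch_filter(sine10)
  expect_equal(mean(out10$samples^2), mean(sine10$samples^2), tolerance = 0.02)
  zero <- channel("eeg_af7", numeric(2560), 256)
  expect_equal(notch_filter(zero)$samples, numeric(2560))
  lowrate <- channel("eda", rnorm(240), 4)
  expect_message(out_lr <- notch_filter(lowrate), "passed through")
  expect_identical(out_lr$samples, lowrate$samples)
})

test_that("windowing drops partial windows and never straddles blocks", {
  t0 <- 1000
  n_min <- 12
  mk <- function(name, fs) channel(name, rnorm(round(fs * 60 * n_min)), fs, t0)
  rec <- multimodal_recording("P01", "S01", list(
    eeg_af7 = mk("eeg_af7", 256), eeg_af8 = mk("eeg_af8", 256),
    eeg_tp9 = mk("eeg_tp9", 256), eeg_tp10 = mk("eeg_tp10", 256),
    eda = mk("eda", 4), temp = mk("temp", 4), ppg_e4 = mk("ppg_e4", 64)),
    "controlled")
  log <- protocol_log(data.frame(
    activity = c("Relaxation", "Reading", "Game"),
    start = t0 + c(0, 600, 690), end = t0 + c(600, 690, 710),
    environment = "controlled",
    workload_response = c(1, 4, 3), stress_response = c(1, 3, 2)))
  w <- segment_windows(rec, log)
  # 10 min -> 10 windows; 90 s -> 1 (30 s remainder dropped); 20 s -> 0
  expect_length(w, 11)
  expect_equal(sum(vapply(w, function(x) x$activity, "") == "Relaxation"), 10)
  expect_equal(sum(vapply(w, function(x) x$activity, "") == "Reading"), 1)
  expect_length(w[[1]]$slices$eeg_af7, 60 * 256)
  expect_length(w[[1]]$slices$eda, 240)
  expect_true(all(vapply(w, function(x) x$workload_response, 0)
                  %in% c(1, 4)))
  # 59 s block: no windows, with a warning
  log59 <- protocol_log(data.frame(
    activity = "Game", start = t0, end = t0 + 59, environment = "controlled",
    workload_response = 3, stress_response = 3))
  expect_warning(w59 <- segment_windows(rec, log59), "0 windows")
  expect_length(w59, 0)
})
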