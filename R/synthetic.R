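eeg_bands <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
                  beta = c(12, 30), gamma = c(30, 45))

#' Generator configuration
#'
#' Sampling rates follow the two consumer devices emulated by the generator
#' (EEG 256 Hz, gyroscope 50 Hz, headband/wristband PPG 64 Hz, skin
#' temperature and EDA 4 Hz, acceleration 32 Hz) and should not normally be
#' changed. Physiology baselines are population means; participant-level
#' variation is drawn around them.
#'
#' @param n_participants Number of participants (default 10).
#' @param fs_eeg,fs_ppg,fs_eda,fs_temp,fs_acc,fs_gyro Sampling rates, Hz.
#' @param line_noise_amplitude Amplitude of the 50 Hz power-line component
#'   added to EEG and PPG, in signal units (default 5).
#' @param inter_device_offset_s Wristband clock minus headband clock,
#'   seconds (default 1.5).
#' @param resting_hr_bpm Baseline heart rate (default 70).
#' @param tonic_scl_us Baseline tonic skin conductance, microsiemens.
#' @param skin_temp_c Baseline skin temperature, Celsius.
#' @param band_amplitudes_uv Per-band EEG component amplitudes (RMS
#'   microvolts) for delta/theta/alpha/beta/gamma.
#' @param session_start UNIX start time of generated sessions.
#' @return List of class `cogload_config`.
#' @export
generator_config <- function(n_participants = 10,
                             fs_eeg = 256, fs_ppg = 64, fs_eda = 4,
                             fs_temp = 4, fs_acc = 32, fs_gyro = 50,
                             line_noise_amplitude = 5,
                             inter_device_offset_s = 1.5,
                             resting_hr_bpm = 70,
                             tonic_scl_us = 2,
                             skin_temp_c = 33,
                             band_amplitudes_uv = c(delta = 20, theta = 10,
                                                    alpha = 15, beta = 8,
                                                    gamma = 4),
                             session_start = 1.7e9) {
  structure(as.list(environment()), class = "cogload_config")
}

#' Latent-load session profile
#'
#' Ordered task blocks with a latent cognitive-load level in \[0, 1\] per
#' block. `effect_size` scales how strongly the latent load shifts
#' physiology (0 = physiology independent of load); `label_noise_sd` is the
#' SD of Gaussian noise added to the questionnaire response before rounding.
#'
#' @param blocks Data frame with columns `activity`, `duration_s`,
#'   `latent_load`.
#' @param effect_size Non-negative scalar (default 1).
#' @param label_noise_sd Non-negative scalar on the 1-5 response scale
#'   (default 0.3).
#' @return List of class `cogload_profile`.
#' @export
load_profile <- function(blocks, effect_size = 1, label_noise_sd = 0.3) {
  need <- c("activity", "duration_s", "latent_load")
  if (!all(need %in% names(blocks)))
    stopf("profile blocks need columns: %s", paste(need, collapse = ", "))
  if (any(!blocks$activity %in% activity_vocabulary))
    stopf("unknown activity in profile")
  if (any(blocks$duration_s <= 0)) stopf("block durations must be positive")
  if (any(blocks$latent_load < 0 | blocks$latent_load > 1))
    stopf("latent_load must lie in [0, 1]")
  if (effect_size < 0 || label_noise_sd < 0)
    stopf("effect_size and label_noise_sd must be non-negative")
  structure(list(blocks = as.data.frame(blocks)[need],
                 effect_size = effect_size,
                 label_noise_sd = label_noise_sd),
            class = "cogload_profile")
}

#' Default session profile
#'
#' A single office-style session: eyes-closed baseline, relaxation, a game,
#' reading, summarising, and a high-load task block, with latent loads
#' spanning the full scale so all five response classes occur. `scale`
#' shrinks every block duration proportionally (used for small simulation
#' studies); durations are kept at whole minutes.
#'
#' @param scale Multiplier on block durations (default 1 = 46 min session).
#' @param effect_size,label_noise_sd Passed to [load_profile()].
#' @export
default_profile <- function(scale = 1, effect_size = 1, label_noise_sd = 0.3) {
  base <- data.frame(
    activity = c("EyesClosed", "Relaxation", "Game", "Reading", "Summary", "Load"),
    duration_s = c(60, 600, 300, 600, 600, 600),
    latent_load = c(0.0, 0.1, 0.3, 0.5, 0.8, 1.0))
  base$duration_s <- pmax(60, round(base$duration_s * scale / 60) * 60)
  load_profile(base, effect_size = effect_size, label_noise_sd = label_noise_sd)
}

fir_bandpass <- function(n_sig, band, fs) {
  ntaps <- min(512L, max(32L, 2L * (n_sig %/% 3L)))
  if (ntaps %% 2L == 1L) ntaps <- ntaps - 1L
  signal::fir1(ntaps, band / (fs / 2), type = "pass")
}

#' Synthesise multi-channel EEG as band-limited noise
#'
#' Each channel is a sum of five FIR-bandpass-filtered white-noise
#' components (delta 0.5-4, theta 4-8, alpha 8-12, beta 12-30, gamma
#' 30-45 Hz), each scaled to the requested RMS amplitude, plus white sensor
#' noise. Expected band powers are therefore proportional to the squared
#' amplitudes. A relative `asymmetry` scales the alpha amplitude up on the
#' right-hemisphere channels (AF8, TP10) and down on the left (AF7, TP9).
#'
#' @param band_amplitudes Length-5 vector (recycled over channels) or a
#'   4 x 5 matrix (rows AF7, AF8, TP9, TP10) of RMS amplitudes per band.
#' @param duration_s Duration, seconds (> 0).
#' @param fs Sampling rate, Hz (>= 90, i.e. twice the top band edge).
#' @param seed Integer seed; fully determines the output.
#' @param noise_sd White-noise floor SD (default 1).
#' @param asymmetry Relative right-minus-left alpha amplitude imbalance
#'   (default 0).
#' @param band_gains Optional `n x 5` matrix of per-sample multiplicative
#'   gains per band (used by the session generator to modulate load).
#' @return Numeric matrix `n x 4` with columns AF7, AF8, TP9, TP10.
#' @export
synthesize_eeg <- function(band_amplitudes, duration_s, fs = 256, seed = 1,
                           noise_sd = 1, asymmetry = 0, band_gains = NULL) {
  check_positive(duration_s, "duration_s")
  if (fs < 2 * 45) stopf("fs must be at least twice the highest band edge (45 Hz)")
  n <- round(duration_s * fs)
  chans <- c("AF7", "AF8", "TP9", "TP10")
  amp <- band_amplitudes
  if (is.null(dim(amp))) amp <- matrix(rep(amp, each = 4), nrow = 4)
  if (!all(dim(amp) == c(4, 5))) stopf("band_amplitudes must be length 5 or 4 x 5")
  # asymmetry scales alpha on right (AF8, TP10) vs left (AF7, TP9)
  amp[, 3] <- amp[, 3] * c(1 - asymmetry / 2, 1 + asymmetry / 2,
                           1 - asymmetry / 2, 1 + asymmetry / 2)
  out <- matrix(0, nrow = n, ncol = 4, dimnames = list(NULL, chans))
  with_local_seed(seed, {
    for (b in seq_along(eeg_bands)) {
      if (all(amp[, b] == 0)) {
        # still consume RNG so per-band structure is seed-stable
        stats::runif(1)
        next
      }
      fir <- fir_bandpass(n, eeg_bands[[b]], fs)
      for (ci in 1:4) {
        if (amp[ci, b] == 0) next
        v <- signal::fftfilt(fir, stats::rnorm(n))
        v <- v / max(pop_sd(v), .Machine$double.eps)
        g <- if (is.null(band_gains)) 1 else band_gains[, b]
        out[, ci] <- out[, ci] + amp[ci, b] * g * v
      }
    }
    if (noise_sd > 0)
      out <- out + matrix(stats::rnorm(n * 4, sd = noise_sd), ncol = 4)
  })
  out
}

# Render a pulse waveform from beat times: a systolic peak (Gaussian, SD
# 50 ms) and a smaller dicrotic bump 250 ms later, plus sensor noise.
ppg_waveform <- function(beat_times, duration_s, fs, noise_sd, seed) {
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  for (bt in beat_times) {
    lo <- max(1L, floor((bt - 0.4) * fs)); hi <- min(n, ceiling((bt + 0.7) * fs))
    if (lo > hi) next
    tt <- t[lo:hi] - bt
    x[lo:hi] <- x[lo:hi] + exp(-0.5 * (tt / 0.05)^2) +
      0.3 * exp(-0.5 * ((tt - 0.25) / 0.09)^2)
  }
  if (noise_sd > 0)
    x <- x + with_local_seed(seed, stats::rnorm(n, sd = noise_sd))
  x
}

#' Synthesise a photoplethysmography channel
#'
#' Systolic peak times follow the instantaneous heart-rate profile with
#' Gaussian inter-beat jitter of SD `hrv_sd_ms`; the rendered waveform is a
#' peaked pulse per beat plus sensor noise. The planted beat times are
#' attached as attribute `"beat_times"`.
#'
#' @param hr_profile Heart rate in bpm: a scalar, or a vector interpreted as
#'   equally spaced over the duration. All values must lie in \[30, 220\].
#' @param hrv_sd_ms Inter-beat jitter SD in milliseconds; scalar or a vector
#'   over the duration.
#' @param duration_s Duration, seconds.
#' @param fs Sampling rate, Hz (default 64).
#' @param seed Integer seed.
#' @param noise_sd Sensor noise SD (default 0.02).
#' @return Numeric vector of `round(duration_s * fs)` samples with attribute
#'   `beat_times` (seconds).
#' @export
synthesize_ppg <- function(hr_profile, hrv_sd_ms = 0, duration_s = 60,
                           fs = 64, seed = 1, noise_sd = 0.02) {
  check_positive(duration_s, "duration_s")
  if (any(hr_profile < 30 | hr_profile > 220))
    stopf("hr_profile must lie within [30, 220] bpm")
  hr_at <- profile_interpolator(hr_profile, duration_s)
  sd_at <- profile_interpolator(hrv_sd_ms, duration_s)
  beats <- with_local_seed(seed, {
    tt <- 0.5
    out <- numeric(0)
    while (tt < duration_s) {
      out <- c(out, tt)
      ibi <- 60 / hr_at(tt) + stats::rnorm(1, sd = sd_at(tt) / 1000)
      tt <- tt + max(0.273, ibi)
    }
    out
  })
  x <- ppg_waveform(beats, duration_s, fs, noise_sd, child_seed(seed, 7))
  attr(x, "beat_times") <- beats
  x
}

profile_interpolator <- function(v, duration_s) {
  if (length(v) == 1L) return(function(t) rep(v, length(t)))
  xs <- seq(0, duration_s, length.out = length(v))
  function(t) stats::approx(xs, v, xout = t, rule = 2)$y
}

# Bi-exponential skin-conductance-response template, peak-normalised.
scr_template <- function(t, tau_rise = 1, tau_decay = 4) {
  h <- exp(-t / tau_decay) - exp(-t / tau_rise)
  tpk <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  h / (exp(-tpk / tau_decay) - exp(-tpk / tau_rise))
}

#' Synthesise an electrodermal activity channel
#'
#' Tonic drift plus one bi-exponential skin conductance response (rise time
#' constant 1 s, decay 4 s, peak-normalised) per event time. The tonic
#' series used is attached as attribute `"tonic"`.
#'
#' @param tonic_level Tonic level in microsiemens: scalar or vector over the
#'   duration (must be >= 0).
#' @param scr_event_times Event onset times, seconds, within
#'   `[0, duration_s)`.
#' @param scr_amplitude Peak SCR amplitude, microsiemens; scalar or one
#'   value per event.
#' @param duration_s Duration, seconds.
#' @param fs Sampling rate, Hz (default 4).
#' @param seed Integer seed.
#' @param noise_sd Measurement noise SD (default 0, i.e. noiseless).
#' @return Numeric vector with attributes `tonic` and `scr_times`.
#' @export
synthesize_eda <- function(tonic_level, scr_event_times = numeric(0),
                           scr_amplitude = 0.5, duration_s = 60, fs = 4,
                           seed = 1, noise_sd = 0) {
  check_positive(duration_s, "duration_s")
  if (any(tonic_level < 0)) stopf("tonic_level must be non-negative")
  if (length(scr_event_times) &&
      any(scr_event_times < 0 | scr_event_times >= duration_s))
    stopf("scr_event_times must lie within [0, duration_s)")
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  tonic <- profile_interpolator(tonic_level, duration_s)(t)
  x <- tonic
  amps <- rep(scr_amplitude, length.out = length(scr_event_times))
  for (i in seq_along(scr_event_times)) {
    et <- scr_event_times[i]
    idx <- which(t >= et)
    x[idx] <- x[idx] + amps[i] * scr_template(t[idx] - et)
  }
  if (noise_sd > 0)
    x <- x + with_local_seed(seed, stats::rnorm(n, sd = noise_sd))
  attr(x, "tonic") <- tonic
  attr(x, "scr_times") <- scr_event_times
  x
}

#' Add power-line interference to a channel
#'
#' Adds `amplitude * sin(2 * pi * f0 * t + phase)` with a seed-determined
#' phase; this is the component the preprocessing notch filter removes.
#'
#' @param ch A [channel()] with `fs > 2 * f0`.
#' @param f0 Interference frequency, Hz (default 50).
#' @param amplitude Peak amplitude in signal units.
#' @param seed Integer seed for the phase.
#' @export
inject_line_noise <- function(ch, f0 = 50, amplitude = 1, seed = 1) {
  if (ch$fs <= 2 * f0)
    stopf("cannot inject %g Hz interference into a %g Hz channel", f0, ch$fs)
  if (amplitude == 0) return(ch)
  phase <- with_local_seed(seed, stats::runif(1, 0, 2 * pi))
  t <- (seq_along(ch$samples) - 1) / ch$fs
  ch$samples <- ch$samples + amplitude * sin(2 * pi * f0 * t + phase)
  ch
}

# Per-participant physiological traits drawn once per participant.
draw_traits <- function(seed) {
  with_local_seed(seed, list(
    hr_offset = stats::rnorm(1, 0, 5),
    scl_gain = exp(stats::rnorm(1, 0, 0.2)),
    temp_offset = stats::rnorm(1, 0, 0.5),
    eeg_gain = exp(stats::rnorm(1, 0, 0.15)),
    asym = stats::rnorm(1, 0, 0.1)))
}

# Load-to-physiology couplings; all scale with effect_size so that
# effect_size = 0 decouples physiology from the latent load entirely.
load_effects <- list(hr_bpm = 8, nn_jitter_ms = -12, eeg_gain = 0.35,
                     scr_per_min = 1.5, scl_us = 0.4, temp_c = -0.2)

#' Generate one participant-session
#'
#' Builds a full multimodal recording plus its protocol log. The latent load
#' of each block shifts physiology monotonically when `effect_size > 0`
#' (higher load: higher beta and prefrontal theta power, higher heart rate,
#' lower inter-beat variability, more frequent skin conductance responses,
#' slightly higher tonic conductance and lower skin temperature). Both
#' devices record a 3 s high-variance shake burst at the session start, and
#' the wristband clock is offset by `config$inter_device_offset_s`.
#' Questionnaire responses are `round(1 + 4 * latent_load + noise)` clipped
#' to 1..5.
#'
#' @param config A [generator_config()].
#' @param profile A [load_profile()].
#' @param participant_id Identifier string.
#' @param seed Integer seed; fully determines the session.
#' @param session_id Identifier string (default `"S01"`).
#' @param environment `"controlled"` or `"uncontrolled"`.
#' @param traits Optional trait list (from an earlier draw) so that several
#'   sessions of one participant share physiology; drawn from `seed` if NULL.
#' @return List with elements `recording` (`cogload_recording`), `log`
#'   (`cogload_protocol`) and `truth` (planted latent loads, beat times, SCR
#'   event times and the device offset).
#' @export
generate_session <- function(config, profile, participant_id, seed,
                             session_id = "S01",
                             environment = "uncontrolled", traits = NULL) {
  stopifnot(inherits(config, "cogload_config"), inherits(profile, "cogload_profile"))
  if (is.null(traits)) traits <- draw_traits(child_seed(seed, 1))
  e <- profile$effect_size
  blocks <- profile$blocks
  lead_s <- 6            # shake + settling before the first block
  t0 <- config$session_start
  starts <- t0 + lead_s + c(0, cumsum(blocks$duration_s))[seq_len(nrow(blocks))]
  ends <- starts + blocks$duration_s
  total_s <- lead_s + sum(blocks$duration_s)

  # per-second latent load trace (lead-in counts as zero load)
  sec <- seq_len(ceiling(total_s))
  load_t <- numeric(length(sec))
  for (b in seq_len(nrow(blocks))) {
    i <- sec > (starts[b] - t0) & sec <= (ends[b] - t0)
    load_t[i] <- blocks$latent_load[b]
  }

  ## EEG: baseline amplitudes with load-modulated beta (all channels) and
  ## prefrontal theta
  n_eeg <- round(total_s * config$fs_eeg)
  li <- pmin(length(load_t), pmax(1L, ceiling((seq_len(n_eeg)) / config$fs_eeg)))
  g_load <- 1 + load_effects$eeg_gain * e * load_t[li]
  gains <- matrix(1, nrow = n_eeg, ncol = 5)
  gains[, 4] <- g_load                     # beta, all channels
  amp <- matrix(rep(config$band_amplitudes_uv * traits$eeg_gain, each = 4), nrow = 4)
  eeg <- synthesize_eeg(amp, total_s, config$fs_eeg, seed = child_seed(seed, 2),
                        noise_sd = 2, asymmetry = traits$asym, band_gains = gains)
  # prefrontal theta modulation (AF7/AF8 only): add extra theta-band noise
  theta_extra <- synthesize_eeg(
    matrix(c(rep(config$band_amplitudes_uv[["theta"]] * traits$eeg_gain, 2), 0, 0,
             rep(0, 16)), nrow = 4),
    total_s, config$fs_eeg, seed = child_seed(seed, 3), noise_sd = 0,
    band_gains = matrix(sqrt(pmax(0, g_load^2 - 1)), nrow = n_eeg, ncol = 5))
  eeg <- eeg + theta_extra

  ## PPG (shared heart for both devices)
  hr_sec <- config$resting_hr_bpm + traits$hr_offset +
    load_effects$hr_bpm * e * load_t +
    slow_wander(length(load_t), sd = 4, scale_s = 45, seed = child_seed(seed, 4))
  hr_sec <- pmin(220, pmax(30, hr_sec))
  jit_sec <- pmax(8, 50 + load_effects$nn_jitter_ms * e * load_t)
  ppg_e4 <- synthesize_ppg(hr_sec, jit_sec, total_s, config$fs_ppg,
                           seed = child_seed(seed, 5))
  beat_times <- attr(ppg_e4, "beat_times")
  ppg_muse <- ppg_waveform(beat_times, total_s, config$fs_ppg,
                           noise_sd = 0.04, seed = child_seed(seed, 6))

  ## EDA: tonic level and Poisson SCR events per block
  tonic_sec <- traits$scl_gain * (config$tonic_scl_us + load_effects$scl_us * e * load_t) +
    slow_wander(length(load_t), sd = 0.1, scale_s = 120, seed = child_seed(seed, 8))
  tonic_sec <- pmax(0.05, tonic_sec)
  scr_times <- with_local_seed(child_seed(seed, 9), {
    out <- numeric(0)
    for (b in seq_len(nrow(blocks))) {
      rate <- (1 + load_effects$scr_per_min * e * blocks$latent_load[b]) / 60
      k <- stats::rpois(1, rate * blocks$duration_s[b])
      if (k > 0)
        out <- c(out, sort(stats::runif(k, starts[b] - t0, ends[b] - t0 - 8)))
    }
    out
  })
  eda <- synthesize_eda(tonic_sec, scr_times, scr_amplitude = 0.3,
                        duration_s = total_s, fs = config$fs_eda,
                        seed = child_seed(seed, 10), noise_sd = 0.003)

  ## skin temperature
  n_temp <- round(total_s * config$fs_temp)
  ti <- pmin(length(load_t), pmax(1L, ceiling(seq_len(n_temp) / config$fs_temp)))
  temp <- config$skin_temp_c + traits$temp_offset +
    load_effects$temp_c * e * load_t[ti] +
    slow_wander(n_temp, sd = 0.08, scale_s = 120 * config$fs_temp,
                seed = child_seed(seed, 11)) +
    with_local_seed(child_seed(seed, 12), stats::rnorm(n_temp, sd = 0.02))

  ## motion: baseline noise plus a 3 s shake burst at session start. The
  ## shake is one physical movement, so both devices sample the same
  ## band-limited (< 12 Hz) trajectory on their own clocks; its broadband
  ## envelope is what makes sub-sample synchronisation possible.
  shake_fns <- lapply(1:3, function(ax) {
    t_hi <- seq(0, 3, by = 1 / 128)
    raw <- with_local_seed(child_seed(seed, 30 + ax),
                           stats::rnorm(length(t_hi)))
    lp <- signal::butter(4, 12 / 64, type = "low")
    sm <- signal::filtfilt(lp, raw)
    env <- 0.5 - 0.5 * cos(2 * pi * t_hi / 3)     # one-hump window
    stats::approxfun(t_hi, sm / max(pop_sd(sm), 1e-12) * env, yleft = 0,
                     yright = 0)
  })
  motion <- function(fs, sd, k, shake_amp, ax) {
    n <- round(total_s * fs)
    x <- with_local_seed(child_seed(seed, k), stats::rnorm(n, sd = sd))
    tt <- (seq_len(n) - 1) / fs
    x + shake_amp * shake_fns[[ax]](tt)
  }
  gyro <- lapply(1:3, function(ax) motion(config$fs_gyro, 2, 12 + ax, 40, ax))
  acc <- lapply(1:3, function(ax) motion(config$fs_acc, 0.02, 15 + ax, 0.4, ax))

  ## line noise on EEG and both PPGs
  mk_muse <- function(name, x, fs, units)
    channel(name, x, fs, start_time = t0, units = units)
  off <- config$inter_device_offset_s
  mk_e4 <- function(name, x, fs, units)
    channel(name, x, fs, start_time = t0 + off, units = units)
  chans <- list(
    eeg_af7 = mk_muse("eeg_af7", eeg[, 1], config$fs_eeg, "uV"),
    eeg_af8 = mk_muse("eeg_af8", eeg[, 2], config$fs_eeg, "uV"),
    eeg_tp9 = mk_muse("eeg_tp9", eeg[, 3], config$fs_eeg, "uV"),
    eeg_tp10 = mk_muse("eeg_tp10", eeg[, 4], config$fs_eeg, "uV"),
    gyro_x = mk_muse("gyro_x", gyro[[1]], config$fs_gyro, "deg/s"),
    gyro_y = mk_muse("gyro_y", gyro[[2]], config$fs_gyro, "deg/s"),
    gyro_z = mk_muse("gyro_z", gyro[[3]], config$fs_gyro, "deg/s"),
    ppg_muse = mk_muse("ppg_muse", as.numeric(ppg_muse), config$fs_ppg, "a.u."),
    temp = mk_e4("temp", temp, config$fs_temp, "degC"),
    eda = mk_e4("eda", as.numeric(eda), config$fs_eda, "uS"),
    ppg_e4 = mk_e4("ppg_e4", as.numeric(ppg_e4), config$fs_ppg, "a.u."),
    acc_x = mk_e4("acc_x", acc[[1]], config$fs_acc, "g"),
    acc_y = mk_e4("acc_y", acc[[2]], config$fs_acc, "g"),
    acc_z = mk_e4("acc_z", acc[[3]], config$fs_acc, "g"))
  # only the EEG rate resolves the 50 Hz fundamental (PPG is sampled at 64 Hz)
  if (config$line_noise_amplitude > 0) {
    for (nm in c("eeg_af7", "eeg_af8", "eeg_tp9", "eeg_tp10"))
      chans[[nm]] <- inject_line_noise(chans[[nm]], 50,
                                       config$line_noise_amplitude,
                                       seed = child_seed(seed, 19))
  }

  ## questionnaire responses per block
  resp <- with_local_seed(child_seed(seed, 20), {
    wl <- round(1 + 4 * blocks$latent_load +
                  stats::rnorm(nrow(blocks), sd = profile$label_noise_sd))
    st <- round(1 + 3.2 * blocks$latent_load +
                  stats::rnorm(nrow(blocks), sd = profile$label_noise_sd))
    list(workload = pmin(5, pmax(1, wl)), stress = pmin(5, pmax(1, st)))
  })
  log <- protocol_log(data.frame(
    activity = blocks$activity, start = starts, end = ends,
    environment = environment,
    workload_response = resp$workload, stress_response = resp$stress))

  rec <- multimodal_recording(participant_id, session_id, chans,
                              environment = environment,
                              device_offset_s = off)
  list(recording = rec, log = log,
       truth = list(latent_load = blocks$latent_load,
                    beat_times = beat_times, scr_times = scr_times,
                    device_offset_s = off))
}

# Smooth slow random wander: Gaussian control points every `scale_s`
# samples joined by a natural cubic spline, rescaled to the requested SD.
# Spline knots keep the trace free of spectral content above ~1/scale_s,
# which matters for the EDA channel where residual wiggle would otherwise
# masquerade as phasic activity.
slow_wander <- function(n, sd, scale_s, seed) {
  if (sd <= 0) return(numeric(n))
  k <- max(4L, ceiling(n / max(3, round(scale_s))) + 2L)
  knots <- seq(1 - scale_s, n + scale_s, length.out = k)
  vals <- with_local_seed(seed, stats::rnorm(k))
  sm <- stats::spline(knots, vals, xout = seq_len(n), method = "natural")$y
  sm <- sm - mean(sm)
  s <- stats::sd(sm)
  if (!is.finite(s) || s == 0) return(numeric(n))
  as.numeric(sm / s * sd)
}

#' Simulate an in-memory study population
#'
#' Draws per-participant physiology traits and generates `sessions` sessions
#' per participant under a common profile. Deterministic under `seed`.
#'
#' @param config A [generator_config()].
#' @param profile A [load_profile()].
#' @param n_participants Number of participants (>= 2).
#' @param sessions Sessions per participant (default 1).
#' @param seed Master seed.
#' @return List of session lists as returned by [generate_session()].
#' @export
simulate_study <- function(config = generator_config(),
                           profile = default_profile(),
                           n_participants = config$n_participants,
                           sessions = 1, seed = 1) {
  if (n_participants < 2)
    stopf("need at least 2 participants (leave-one-participant-out evaluation is undefined for 1)")
  out <- list()
  for (p in seq_len(n_participants)) {
    pid <- sprintf("P%02d", p)
    pseed <- child_seed(seed, 100 + p)
    traits <- draw_traits(pseed)
    for (s in seq_len(sessions)) {
      out[[length(out) + 1L]] <-
        generate_session(config, profile, pid, seed = child_seed(pseed, s),
                         session_id = sprintf("S%02d", s), traits = traits)
    }
  }
  out
}

#' Write a simulated population to disk
#'
#' One directory per participant-session containing the headband long-format
#' CSV (`muse.csv`), the four wristband CSVs and `protocol.json`.
#' Byte-identical across runs with the same seed.
#'
#' @inheritParams simulate_study
#' @param directory Destination directory (created if needed).
#' @return Character vector of session directory paths.
#' @export
generate_population <- function(config = generator_config(),
                                profile = default_profile(),
                                n_participants = config$n_participants,
                                sessions = 1, directory, seed = 1) {
  sess <- simulate_study(config, profile, n_participants, sessions, seed)
  paths <- character(0)
  for (s in sess) {
    d <- file.path(directory, paste0(s$recording$participant_id, "_",
                                     s$recording$session_id))
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
    write_muse_csv(s$recording, file.path(d, "muse.csv"))
    write_e4_export(s$recording, d)
    write_protocol_json(s$log, file.path(d, "protocol.json"))
    paths <- c(paths, d)
  }
  paths
}

#' Read one session directory written by [generate_population()]
#'
#' @param directory Session directory with `muse.csv`, the wristband CSVs
#'   and `protocol.json`.
#' @param participant_id,session_id Identifiers; parsed from the directory
#'   name (`<participant>_<session>`) when NULL.
#' @return List with `recording` and `log`.
#' @export
read_session <- function(directory, participant_id = NULL, session_id = NULL) {
  base <- basename(normalizePath(directory, mustWork = FALSE))
  parts <- strsplit(base, "_")[[1]]
  if (is.null(participant_id)) participant_id <- parts[1]
  if (is.null(session_id)) session_id <- if (length(parts) > 1) parts[2] else "S01"
  chans <- c(read_muse_csv(file.path(directory, "muse.csv")),
             read_e4_export(directory))
  log <- read_protocol_json(file.path(directory, "protocol.json"))
  env <- log$environment[1]
  muse_start <- chans$eeg_af7$start_time
  e4_start <- chans$temp$start_time
  list(recording = multimodal_recording(participant_id, session_id, chans,
                                        environment = env,
                                        device_offset_s = e4_start - muse_start),
       log = log)
}
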