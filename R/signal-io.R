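#' Construct a sampled channel
#'
#' A channel is a uniformly sampled series with a name, sampling rate and a
#' UTC start time in UNIX seconds; the timestamp of sample `i` (1-based) is
#' `start_time + (i - 1) / fs`.
#'
#' @param name Channel name, e.g. `"eeg_af7"`.
#' @param samples Numeric vector.
#' @param fs Sampling rate in Hz (> 0).
#' @param start_time Start time, UNIX seconds (UTC).
#' @param units Unit string (e.g. `"uV"`, `"uS"`, `"degC"`).
#' @return An object of class `cogload_channel`.
#' @export
channel <- function(name, samples, fs, start_time = 0, units = "") {
  check_positive(fs, "fs")
  structure(list(name = as.character(name), samples = as.numeric(samples),
                 fs = fs, start_time = as.numeric(start_time),
                 units = as.character(units)),
            class = "cogload_channel")
}

#' @export
print.cogload_channel <- function(x, ...) {
  cat(sprintf("<channel %s: %d samples @ %g Hz, start %.3f, units '%s'>\n",
              x$name, length(x$samples), x$fs, x$start_time, x$units))
  invisible(x)
}

channel_times <- function(ch) ch$start_time + (seq_along(ch$samples) - 1) / ch$fs

#' Assemble a multimodal recording
#'
#' Bundles the channels of one participant-session across the two virtual
#' devices (EEG headband: 4 EEG channels at 256 Hz, 3 gyroscope axes at
#' 50 Hz, PPG at 64 Hz; wristband: skin temperature and EDA at 4 Hz, PPG at
#' 64 Hz, 3 accelerometer axes at 32 Hz).
#'
#' @param participant_id,session_id Identifiers.
#' @param channels Named list of [channel()] objects.
#' @param environment `"controlled"` or `"uncontrolled"`.
#' @param device_offset_s Wristband clock minus headband clock, seconds.
#' @return An object of class `cogload_recording`.
#' @export
multimodal_recording <- function(participant_id, session_id, channels,
                                 environment = c("controlled", "uncontrolled"),
                                 device_offset_s = 0) {
  environment <- match.arg(environment)
  eeg <- grep("^eeg_", names(channels), value = TRUE)
  if (length(eeg) > 1L) {
    lens <- vapply(channels[eeg], function(c) length(c$samples), integer(1))
    st <- vapply(channels[eeg], function(c) c$start_time, numeric(1))
    if (length(unique(lens)) != 1L || length(unique(st)) != 1L)
      stopf("all EEG channels must share length and start_time")
  }
  structure(list(participant_id = as.character(participant_id),
                 session_id = as.character(session_id),
                 environment = environment,
                 channels = channels,
                 device_offset_s = as.numeric(device_offset_s)),
            class = "cogload_recording")
}

#' @export
print.cogload_recording <- function(x, ...) {
  cat(sprintf("<recording %s/%s (%s): %d channels, device offset %.3f s>\n",
              x$participant_id, x$session_id, x$environment,
              length(x$channels), x$device_offset_s))
  invisible(x)
}

muse_channel_map <- c(AF7 = "eeg_af7", AF8 = "eeg_af8", TP9 = "eeg_tp9",
                      TP10 = "eeg_tp10", GYRO_X = "gyro_x", GYRO_Y = "gyro_y",
                      GYRO_Z = "gyro_z", PPG = "ppg_muse")
muse_rates <- c(eeg_af7 = 256, eeg_af8 = 256, eeg_tp9 = 256, eeg_tp10 = 256,
                gyro_x = 50, gyro_y = 50, gyro_z = 50, ppg_muse = 64)
muse_units <- c(eeg_af7 = "uV", eeg_af8 = "uV", eeg_tp9 = "uV", eeg_tp10 = "uV",
                gyro_x = "deg/s", gyro_y = "deg/s", gyro_z = "deg/s",
                ppg_muse = "a.u.")

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read the headband long-format CSV dialect
#'
#' Long format with columns `timestamp,channel,value`; channel labels are the
#' electrode names AF7/AF8/TP9/TP10 plus GYRO_X/Y/Z and PPG. Sampling rates
#' are fixed by the device convention (EEG 256 Hz, gyroscope 50 Hz, PPG
#' 64 Hz); the start time is recovered from each channel's first timestamp.
#'
#' @param recording A `cogload_recording` (only headband channels are written).
#' @param path CSV file path.
#' @return `write_muse_csv` returns `path` invisibly; `read_muse_csv` returns
#'   a named list of [channel()] objects.
#' @export
write_muse_csv <- function(recording, path) {
  rows <- character(0)
  for (lab in names(muse_channel_map)) {
    cn <- muse_channel_map[[lab]]
    ch <- recording$channels[[cn]]
    if (is.null(ch)) next
    t <- channel_times(ch)
    rows <- c(rows, paste(fmt_num(t), lab, fmt_num(ch$samples), sep = ","))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("timestamp,channel,value", rows), con, sep = "\n")
  invisible(path)
}

#' @rdname write_muse_csv
#' @param require_eeg If `TRUE` (default), fail unless all four EEG
#'   electrodes are present.
#' @export
read_muse_csv <- function(path, require_eeg = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "channel", "value") %in% names(df)))
    stopf("malformed headband CSV '%s': expected columns timestamp,channel,value", path)
  unknown <- setdiff(unique(df$channel), names(muse_channel_map))
  if (length(unknown))
    stopf("unknown channel name(s) in '%s': %s", path,
          paste(unknown, collapse = ", "))
  eeg_labs <- c("AF7", "AF8", "TP9", "TP10")
  if (require_eeg) {
    missing <- setdiff(eeg_labs, unique(df$channel))
    if (length(missing))
      stopf("headband CSV '%s' is missing EEG channel(s): %s", path,
            paste(missing, collapse = ", "))
  }
  out <- list()
  for (lab in intersect(names(muse_channel_map), unique(df$channel))) {
    cn <- muse_channel_map[[lab]]
    sub <- df[df$channel == lab, , drop = FALSE]
    ord <- order(sub$timestamp)
    out[[cn]] <- channel(cn, sub$value[ord], muse_rates[[cn]],
                         start_time = sub$timestamp[ord][1],
                         units = muse_units[[cn]])
  }
  out
}

e4_files <- list(
  TEMP = list(channels = "temp", fs = 4, units = "degC"),
  EDA  = list(channels = "eda", fs = 4, units = "uS"),
  BVP  = list(channels = "ppg_e4", fs = 64, units = "a.u."),
  ACC  = list(channels = c("acc_x", "acc_y", "acc_z"), fs = 32, units = "g"))

#' Write / read the wristband per-signal CSV export
#'
#' One CSV per signal (`TEMP.csv`, `EDA.csv`, `BVP.csv`, `ACC.csv`): row 1 is
#' the start UNIX timestamp, row 2 the sampling rate, then one sample per row
#' (three comma-separated columns for the accelerometer).
#'
#' @param recording A `cogload_recording` (only wristband channels written).
#' @param directory Destination / source directory.
#' @return `write_e4_export` returns `directory` invisibly; `read_e4_export`
#'   returns a named list of [channel()] objects.
#' @export
write_e4_export <- function(recording, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  for (fn in names(e4_files)) {
    info <- e4_files[[fn]]
    chs <- recording$channels[info$channels]
    if (any(vapply(chs, is.null, logical(1))))
      stopf("recording lacks channel(s) %s required for %s.csv",
            paste(info$channels, collapse = ", "), fn)
    mat <- sapply(chs, function(c) c$samples)
    if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1)
    start <- chs[[1]]$start_time
    fs <- chs[[1]]$fs
    k <- ncol(mat)
    lines <- c(paste(rep(fmt_num(start), k), collapse = ","),
               paste(rep(fmt_num(fs), k), collapse = ","),
               apply(mat, 1, function(r) paste(fmt_num(r), collapse = ",")))
    con <- file(file.path(directory, paste0(fn, ".csv")), "wb")
    writeLines(lines, con, sep = "\n")
    close(con)
  }
  invisible(directory)
}

#' @rdname write_e4_export
#' @export
read_e4_export <- function(directory) {
  out <- list()
  for (fn in names(e4_files)) {
    info <- e4_files[[fn]]
    path <- file.path(directory, paste0(fn, ".csv"))
    if (!file.exists(path))
      stopf("missing channel file '%s' in wristband export '%s'", paste0(fn, ".csv"), directory)
    lines <- readLines(path)
    if (length(lines) < 2L)
      stopf("parse error in '%s' line %d: expected timestamp and rate header rows", path, length(lines) + 1L)
    parse_row <- function(i) {
      v <- suppressWarnings(as.numeric(strsplit(lines[i], ",")[[1]]))
      if (anyNA(v)) stopf("parse error in '%s' line %d: non-numeric value", path, i)
      v
    }
    start <- parse_row(1)[1]
    fs <- parse_row(2)[1]
    if (!is.finite(fs) || fs <= 0)
      stopf("parse error in '%s' line 2: invalid sampling rate", path)
    nchan <- length(info$channels)
    body <- lines[-(1:2)]
    mat <- matrix(NA_real_, nrow = length(body), ncol = nchan)
    for (i in seq_along(body)) {
      v <- suppressWarnings(as.numeric(strsplit(body[i], ",")[[1]]))
      if (length(v) != nchan || anyNA(v))
        stopf("parse error in '%s' line %d: expected %d numeric column(s)", path, i + 2L, nchan)
      mat[i, ] <- v
    }
    for (j in seq_len(nchan))
      out[[info$channels[j]]] <- channel(info$channels[j], mat[, j], fs,
                                         start_time = start, units = info$units)
  }
  out
}

#' Write / read a session protocol log
#'
#' The protocol log records the ordered task blocks of a session: activity,
#' start/end (UNIX seconds, UTC), environment, and the 5-point workload and
#' stress questionnaire responses given after the block.
#'
#' @param log A `cogload_protocol` data frame (see [protocol_log()]).
#' @param path JSON file path.
#' @export
write_protocol_json <- function(log, path) {
  jsonlite::write_json(list(blocks = as.data.frame(unclass(log))), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_protocol_json
#' @export
read_protocol_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  protocol_log(obj$blocks)
}

activity_vocabulary <- c("Relaxation", "Load", "Summary", "Reading", "Game",
                         "EyesClosed")

#' Construct a protocol log
#'
#' @param blocks Data frame with columns `activity`, `start`, `end`,
#'   `environment`, `workload_response`, `stress_response`.
#' @return The validated data frame with class `cogload_protocol`.
#' @export
protocol_log <- function(blocks) {
  need <- c("activity", "start", "end", "environment",
            "workload_response", "stress_response")
  if (!all(need %in% names(blocks)))
    stopf("protocol blocks need columns: %s", paste(need, collapse = ", "))
  blocks <- as.data.frame(blocks)[need]
  if (any(!blocks$activity %in% activity_vocabulary))
    stopf("unknown activity; allowed: %s", paste(activity_vocabulary, collapse = ", "))
  if (any(blocks$end <= blocks$start)) stopf("block durations must be positive")
  ord <- order(blocks$start)
  blocks <- blocks[ord, , drop = FALSE]
  if (nrow(blocks) > 1L && any(blocks$start[-1] < blocks$end[-nrow(blocks)] - 1e-9))
    stopf("protocol blocks must be non-overlapping and time-ordered")
  if (any(!blocks$workload_response %in% 1:5) || any(!blocks$stress_response %in% 1:5))
    stopf("questionnaire responses must lie in 1..5")
  rownames(blocks) <- NULL
  class(blocks) <- c("cogload_protocol", "data.frame")
  blocks
}

#' Second-order zero-phase notch filter
#'
#' Removes narrow-band power-line interference with a biquad notch applied
#' forward and backward (zero phase). Channels whose rate does not resolve
#' the notch frequency (`fs <= 2 * f0`, e.g. the 4 Hz wristband channels)
#' pass through unchanged with a notice.
#'
#' @param ch A [channel()].
#' @param f0 Notch frequency in Hz (default 50, the power-line fundamental).
#' @param q Quality factor; bandwidth is `f0 / q` (default 30).
#' @return The filtered channel (same metadata).
#' @export
notch_filter <- function(ch, f0 = 50, q = 30) {
  if (ch$fs <= 2 * f0) {
    message(sprintf("notch_filter: channel '%s' at %g Hz cannot resolve %g Hz; passed through",
                    ch$name, ch$fs, f0))
    return(ch)
  }
  if (length(ch$samples) < 12L) return(ch)
  w0 <- 2 * pi * f0 / ch$fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  # pad several notch time constants (~ 2 q / (2 pi f0) seconds) so the
  # filter's ring-in never reaches the retained samples
  pad <- ceiling(6 * ch$fs * q / (pi * f0))
  ch$samples <- filtfilt_padded(b, a, ch$samples, pad = pad)
  ch
}

# Zero-phase filtering with mirrored edge padding (removes the start-up
# transient that plain forward-backward filtering leaves on short windows).
filtfilt_padded <- function(b, a, x, pad = 90L) {
  n <- length(x)
  pad <- min(n - 1L, pad)
  if (pad < 1L) return(x)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filtfilt(signal::Arma(b = b, a = a), xp)
  y[(pad + 1):(pad + n)]
}

#' Notch-filter the high-rate channels of a recording
#'
#' Applies [notch_filter()] to every channel sampled above `2 * f0` (EEG and
#' PPG); low-rate channels are untouched. No other artefact rejection is
#' performed.
#'
#' @param recording A `cogload_recording`.
#' @inheritParams notch_filter
#' @export
preprocess_recording <- function(recording, f0 = 50, q = 30) {
  recording$channels <- lapply(recording$channels, function(ch) {
    if (ch$fs > 2 * f0) notch_filter(ch, f0, q) else ch
  })
  recording
}

#' Estimate the inter-device clock offset from a shared movement burst
#'
#' Both devices record a co-registered shake at the start of a session. The
#' offset is estimated by locating the burst in each motion channel's energy
#' envelope (magnitude of the mean-removed signal, resampled to a common
#' 32 Hz grid), maximising the normalised cross-correlation of the two
#' envelopes around the bursts, and refining the peak lag by parabolic
#' interpolation.
#'
#' @param motion_a,motion_b Motion-magnitude [channel()]s (e.g. gyroscope and
#'   accelerometer magnitude) of the two devices.
#' @param max_lag_s Largest clock offset searched, seconds.
#' @return Offset in seconds: device-b clock minus device-a clock. Applying
#'   the negated offset to device b's start times aligns the bursts.
#' @export
estimate_sync_offset <- function(motion_a, motion_b, max_lag_s = 30) {
  fs <- 32
  env_of <- function(ch) {
    t <- channel_times(ch)
    if (t[length(t)] - t[1] < 10) stopf("motion channels must span at least 10 s")
    grid <- seq(t[1], t[length(t)], by = 1 / fs)
    e <- abs(ch$samples - mean(ch$samples))
    list(t = grid, e = stats::approx(t, e, xout = grid, rule = 2)$y)
  }
  A <- env_of(motion_a); B <- env_of(motion_b)
  # coarse burst localisation: centre of the 1 s segment with maximal energy
  burst_at <- function(env) {
    w <- fs
    sm <- stats::filter(env$e^2, rep(1 / w, w), sides = 2)
    env$t[which.max(ifelse(is.na(sm), -Inf, sm))]
  }
  ta <- burst_at(A); tb <- burst_at(B)
  seg <- function(env, centre, half = max_lag_s) {
    keep <- env$t >= centre - half & env$t <= centre + half
    list(t = env$t[keep], e = env$e[keep])
  }
  sa <- seg(A, ta); sb <- seg(B, tb)
  za <- sa$e - mean(sa$e); zb <- sb$e - mean(sb$e)
  lags <- seq(-max_lag_s * fs, max_lag_s * fs)
  cc <- vapply(lags, function(l) {
    # correlate sa with sb shifted by l samples relative to the coarse alignment
    ia <- seq_along(za); ib <- ia + l
    ok <- ib >= 1 & ib <= length(zb)
    if (sum(ok) < fs * 2) return(-Inf)
    suppressWarnings(stats::cor(za[ok], zb[ib[ok]]))
  }, numeric(1))
  cc[!is.finite(cc)] <- -1
  i <- which.max(cc)
  if (cc[i] < 0.5)
    stopf("sync failed: peak envelope correlation %.2f < 0.5 (no common burst found)", cc[i])
  # parabolic sub-sample refinement of the correlation peak
  frac <- 0
  if (i > 1L && i < length(lags)) {
    y1 <- cc[i - 1]; y2 <- cc[i]; y3 <- cc[i + 1]
    den <- y1 - 2 * y2 + y3
    if (is.finite(den) && abs(den) > 1e-12) frac <- 0.5 * (y1 - y3) / den
  }
  lag_s <- (lags[i] + frac) / fs
  # burst appears at stamped time tb in b and ta in a; positive result means
  # b's clock reads later than a's for the same physical event
  (tb + lag_s) - ta
}

#' Apply a recovered clock offset to the wristband channels
#'
#' Subtracts `offset_s` (wristband clock minus headband clock, as returned by
#' [estimate_sync_offset()]) from the start time of every wristband channel,
#' putting the whole recording on the headband clock.
#'
#' @param recording A `cogload_recording`.
#' @param offset_s Offset in seconds.
#' @export
apply_sync_offset <- function(recording, offset_s) {
  e4 <- c("temp", "eda", "ppg_e4", "acc_x", "acc_y", "acc_z")
  for (nm in intersect(e4, names(recording$channels)))
    recording$channels[[nm]]$start_time <-
      recording$channels[[nm]]$start_time - offset_s
  recording$device_offset_s <- recording$device_offset_s - offset_s
  recording
}

#' Motion-magnitude channel of one device
#'
#' @param recording A `cogload_recording`.
#' @param device `"muse"` (gyroscope axes) or `"e4"` (accelerometer axes).
#' @return A [channel()] holding the Euclidean magnitude of the three axes.
#' @export
motion_magnitude <- function(recording, device = c("muse", "e4")) {
  device <- match.arg(device)
  axes <- if (device == "muse") c("gyro_x", "gyro_y", "gyro_z")
          else c("acc_x", "acc_y", "acc_z")
  chs <- recording$channels[axes]
  if (any(vapply(chs, is.null, logical(1))))
    stopf("recording lacks motion channels for device '%s'", device)
  mag <- sqrt(Reduce(`+`, lapply(chs, function(c) c$samples^2)))
  channel(paste0(device, "_motion"), mag, chs[[1]]$fs, chs[[1]]$start_time, "")
}

#' Cut a synchronised recording into labelled 60 s windows
#'
#' Within each protocol block, consecutive non-overlapping windows of
#' `window_s` seconds are cut starting at the block start; a trailing partial
#' window is dropped and windows never straddle block boundaries, so every
#' window carries exactly one activity and one pair of questionnaire
#' responses. A window is emitted only if every channel fully covers it.
#'
#' @param recording A synchronised `cogload_recording` (offset applied).
#' @param log A `cogload_protocol` on the same clock.
#' @param window_s Window length in seconds (default 60).
#' @return List of `cogload_window` objects: per-channel sample slices plus
#'   `participant_id`, `window_index`, `activity`, `workload_response`,
#'   `stress_response` and the window start time.
#' @export
segment_windows <- function(recording, log, window_s = 60) {
  windows <- list()
  idx <- 0L
  for (b in seq_len(nrow(log))) {
    n_win <- floor((log$end[b] - log$start[b]) / window_s)
    if (n_win < 1) next
    for (k in seq_len(n_win)) {
      w0 <- log$start[b] + (k - 1) * window_s
      slices <- list(); fs <- list(); ok <- TRUE
      for (nm in names(recording$channels)) {
        ch <- recording$channels[[nm]]
        i0 <- round((w0 - ch$start_time) * ch$fs)
        nsamp <- round(window_s * ch$fs)
        if (i0 < 0 || i0 + nsamp > length(ch$samples)) { ok <- FALSE; break }
        slices[[nm]] <- ch$samples[(i0 + 1):(i0 + nsamp)]
        fs[[nm]] <- ch$fs
      }
      if (!ok) next
      idx <- idx + 1L
      windows[[idx]] <- structure(
        list(slices = slices, fs = fs,
             participant_id = recording$participant_id,
             session_id = recording$session_id,
             window_index = idx, start = w0,
             activity = log$activity[b],
             environment = log$environment[b],
             workload_response = log$workload_response[b],
             stress_response = log$stress_response[b]),
        class = "cogload_window")
    }
  }
  if (!length(windows))
    warning("no overlap between protocol log and recording: returning 0 windows")
  windows
}
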