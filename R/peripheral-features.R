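as_samples <- function(x, fs = NULL) {
  if (inherits(x, "cogload_channel")) list(x = x$samples, fs = x$fs)
  else {
    if (is.null(fs)) stopf("`fs` is required when passing a bare numeric vector")
    list(x = as.numeric(x), fs = fs)
  }
}

#' Construct a beat series from beat times
#'
#' @param beat_times Strictly increasing beat times in seconds.
#' @param nn_range_ms Physiologic NN filter bounds (default 273-2000 ms).
#' @return A `cogload_beats` object (see [detect_beats()]).
#' @export
beat_series <- function(beat_times, nn_range_ms = c(273, 2000)) {
  if (any(diff(beat_times) <= 0)) stopf("beat_times must be strictly increasing")
  nn <- diff(beat_times) * 1000
  ok <- nn >= nn_range_ms[1] & nn <= nn_range_ms[2]
  structure(list(beat_times = beat_times, nn_intervals_ms = nn[ok],
                 nn_times_s = beat_times[-1][ok]),
            class = "cogload_beats")
}

#' Detect heartbeats in a photoplethysmography window
#'
#' Band-passes the signal to 0.5-8 Hz (3rd-order Butterworth, zero phase),
#' picks local maxima above an adaptive threshold (half the rolling 75th
#' percentile of the filtered amplitude, 2 s resolution) with a 330 ms
#' refractory period, and keeps only physiologic normal-to-normal intervals
#' (273-2000 ms).
#'
#' @param ppg A [channel()] or numeric vector.
#' @param fs Sampling rate, Hz (taken from the channel if given).
#' @return List of class `cogload_beats` with `beat_times` (seconds from
#'   window start, strictly increasing) and `nn_intervals_ms`.
#' @export
detect_beats <- function(ppg, fs = NULL) {
  s <- as_samples(ppg, fs)
  x <- s$x; fs <- s$fs
  if (length(x) < 10 * fs) stopf("PPG window must be at least 10 s long")
  bp <- signal::butter(3, c(0.5, 8) / (fs / 2), type = "pass")
  xf <- filtfilt_padded(bp$b, bp$a, x)
  # rolling 75th percentile on 2 s chunks, linearly interpolated
  chunk <- max(1L, round(2 * fs))
  starts <- seq(1L, length(xf), by = chunk)
  q <- vapply(starts, function(i) {
    stats::quantile(xf[i:min(length(xf), i + chunk - 1L)], 0.75, names = FALSE)
  }, numeric(1))
  centers <- pmin(starts + chunk / 2, length(xf))
  thr <- 0.5 * stats::approx(centers, q, xout = seq_along(xf), rule = 2)$y
  n <- length(xf)
  is_peak <- c(FALSE, xf[2:(n - 1)] > xf[1:(n - 2)] &
                 xf[2:(n - 1)] >= xf[3:n], FALSE) & xf > thr
  cand <- which(is_peak)
  refract <- round(0.330 * fs)
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || i - kept[length(kept)] > refract) kept <- c(kept, i)
    else if (xf[i] > xf[kept[length(kept)]]) kept[length(kept)] <- i
  }
  if (length(kept) < 2L)
    stopf("insufficient beats: found %d peak(s) in the window", length(kept))
  beat_times <- (kept - 1) / fs
  nn <- diff(beat_times) * 1000
  ok <- nn >= 273 & nn <= 2000
  structure(list(beat_times = beat_times,
                 nn_intervals_ms = nn[ok],
                 nn_times_s = beat_times[-1][ok]),
            class = "cogload_beats")
}

# Welch power spectral density: Hamming-windowed segments with 50% overlap,
# per-segment mean removal, one-sided density in units^2 / Hz.
welch_psd <- function(x, fs, nperseg = min(length(x), 120L)) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg / 2))
  win <- 0.54 - 0.46 * cos(2 * pi * (seq_len(nperseg) - 1) / (nperseg - 1))
  u <- sum(win^2)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  acc <- NULL
  for (i in starts) {
    seg <- x[i:(i + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    X <- stats::fft(seg)
    k <- seq_len(floor(nperseg / 2))
    p <- 2 * Mod(X[k + 1])^2 / (fs * u)
    acc <- if (is.null(acc)) p else acc + p
  }
  list(freq = seq_len(floor(nperseg / 2)) * fs / nperseg,
       psd = acc / length(starts))
}

#' Heart-rate-variability metrics from detected beats
#'
#' Time-domain metrics use the millisecond normal-to-normal intervals:
#' `HRV_MeanNN`, `HRV_SDNN` (sample SD, n-1), `HRV_RMSSD` (root mean square
#' of successive differences). Spectral metrics interpolate the NN series at
#' 4 Hz (cubic spline over beat times) and integrate a Welch density over
#' the LF (0.04-0.15 Hz) and HF (0.15-0.40 Hz) bands; with fewer than 30 NN
#' intervals the spectral fields are reported missing and flagged
#' `short_window`. Heart-rate statistics are min/mean/max of `60000 / NN`.
#'
#' @param beats A `cogload_beats` object from [detect_beats()].
#' @return Named list: `HRV_MeanNN`, `HRV_SDNN`, `HRV_RMSSD`, `HRV_LF`,
#'   `HRV_HF`, `HRV_ratio_LF_HF` (ms and ms^2), `min_hr`, `mean_hr`,
#'   `max_hr` (bpm), `short_window` flag.
#' @export
hrv_metrics <- function(beats) {
  nn <- beats$nn_intervals_ms
  if (length(nn) < 2L) stopf("need at least 2 NN intervals")
  if (is.null(beats$nn_times_s)) beats$nn_times_s <- cumsum(nn) / 1000
  hr <- 60000 / nn
  lf <- hf <- NA_real_
  short <- length(nn) < 30L
  if (!short) {
    tt <- beats$nn_times_s
    grid <- seq(min(tt), max(tt), by = 1 / 4)
    if (length(grid) >= 16) {
      nn_i <- stats::spline(tt, nn, xout = grid, method = "natural")$y
      w <- welch_psd(nn_i, fs = 4)
      df <- diff(w$freq[1:2])
      lf <- sum(w$psd[w$freq >= 0.04 & w$freq < 0.15]) * df
      hf <- sum(w$psd[w$freq >= 0.15 & w$freq <= 0.40]) * df
    }
  }
  list(HRV_MeanNN = mean(nn),
       HRV_SDNN = if (length(nn) > 1) stats::sd(nn) else 0,
       HRV_RMSSD = sqrt(mean(diff(nn)^2)),
       HRV_LF = lf, HRV_HF = hf,
       HRV_ratio_LF_HF = if (is.finite(hf) && hf > 0) lf / hf else NA_real_,
       min_hr = min(hr), mean_hr = mean(hr), max_hr = max(hr),
       short_window = short)
}

#' Tonic/phasic decomposition of an EDA window
#'
#' The tonic skin conductance level (SCL) is a zero-phase low-pass of the
#' signal with 0.05 Hz bandwidth, computed as a centred 20 s rolling median
#' (1 / 20 s = 0.05 Hz); the median makes the tonic estimate robust against
#' the phasic pulses themselves, which a linear filter would smear into the
#' baseline. The phasic skin conductance response series (SCR) is the
#' residual, so `scl + scr` reconstructs the input exactly.
#'
#' @param eda A [channel()] or numeric vector (>= 30 s).
#' @param fs Sampling rate, Hz (default 4 when a bare vector is given).
#' @return List with numeric vectors `scl` and `scr`.
#' @export
eda_decompose <- function(eda, fs = NULL) {
  s <- as_samples(eda, if (is.null(fs)) 4 else fs)
  x <- s$x; fs <- s$fs
  if (length(x) < 30 * fs) stopf("EDA window must be at least 30 s long")
  k <- min(2L * floor(20 * fs / 2) + 1L, 2L * floor((length(x) - 1) / 2) + 1L)
  scl <- as.numeric(stats::runmed(x, k, endrule = "median"))
  list(scl = scl, scr = x - scl)
}

#' Phasic SCR statistics
#'
#' Peaks are local maxima of the phasic series with amplitude at least
#' 0.01 microsiemens and at least 1 s separation. Zero peaks is a valid
#' result.
#'
#' @param scr Phasic series from [eda_decompose()].
#' @param fs Sampling rate, Hz.
#' @return List: `num_scr_peaks`, `min_scr`, `max_scr`.
#' @export
scr_statistics <- function(scr, fs = 4) {
  n <- length(scr)
  peaks <- integer(0)
  if (n >= 3) {
    cand <- which(c(FALSE, scr[2:(n - 1)] > scr[1:(n - 2)] &
                      scr[2:(n - 1)] >= scr[3:n], FALSE) & scr >= 0.01)
    sep <- round(fs)
    for (i in cand) {
      if (!length(peaks) || i - peaks[length(peaks)] >= sep) peaks <- c(peaks, i)
      else if (scr[i] > scr[peaks[length(peaks)]]) peaks[length(peaks)] <- i
    }
  }
  list(num_scr_peaks = length(peaks), min_scr = min(scr), max_scr = max(scr))
}

e4_feature_names <- c("max-scr", "min-scr", "num-scr-peaks",
                      "min-scl", "mean-scl", "max-scl",
                      "min-skt", "mean-skt", "max-skt",
                      "HRV-MeanNN", "HRV-SDNN", "HRV-RMSSD",
                      "HRV-LF", "HRV-HF", "HRV-ratio-LF-HF",
                      "Min-Heart-Rate", "Mean-Heart-Rate", "Max-Heart-Rate")

#' Wristband feature map of one 60 s window
#'
#' Exactly 18 named features: SCR extrema and peak count, SCL and skin
#' temperature min/mean/max, the six HRV metrics and the three heart-rate
#' statistics. Sub-extractions that fail (e.g. no detectable beats in a flat
#' PPG) yield `NA` markers for their fields only, never silent zeros.
#'
#' @param window A `cogload_window` containing `temp`, `eda` and `ppg_e4`
#'   slices.
#' @return Named numeric vector of length 18.
#' @export
extract_e4_features <- function(window) {
  need <- c("temp", "eda", "ppg_e4")
  miss <- setdiff(need, names(window$slices))
  if (length(miss))
    stopf("window lacks wristband channel(s): %s", paste(miss, collapse = ", "))
  out <- stats::setNames(rep(NA_real_, length(e4_feature_names)), e4_feature_names)
  de <- eda_decompose(window$slices$eda, fs = window$fs$eda)
  ss <- scr_statistics(de$scr, fs = window$fs$eda)
  out["max-scr"] <- ss$max_scr
  out["min-scr"] <- ss$min_scr
  out["num-scr-peaks"] <- ss$num_scr_peaks
  out["min-scl"] <- min(de$scl); out["mean-scl"] <- mean(de$scl)
  out["max-scl"] <- max(de$scl)
  skt <- window$slices$temp
  out["min-skt"] <- min(skt); out["mean-skt"] <- mean(skt); out["max-skt"] <- max(skt)
  hrv <- tryCatch({
    b <- detect_beats(window$slices$ppg_e4, fs = window$fs$ppg_e4)
    hrv_metrics(b)
  }, error = function(e) NULL)
  if (!is.null(hrv)) {
    out["HRV-MeanNN"] <- hrv$HRV_MeanNN
    out["HRV-SDNN"] <- hrv$HRV_SDNN
    out["HRV-RMSSD"] <- hrv$HRV_RMSSD
    out["HRV-LF"] <- hrv$HRV_LF
    out["HRV-HF"] <- hrv$HRV_HF
    out["HRV-ratio-LF-HF"] <- hrv$HRV_ratio_LF_HF
    out["Min-Heart-Rate"] <- hrv$min_hr
    out["Mean-Heart-Rate"] <- hrv$mean_hr
    out["Max-Heart-Rate"] <- hrv$max_hr
  }
  out
}
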