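eeg_channel_order <- c("AF7", "AF8", "TP9", "TP10")

as_eeg_matrix <- function(x) {
  if (inherits(x, "cogload_window")) {
    need <- c("eeg_af7", "eeg_af8", "eeg_tp9", "eeg_tp10")
    if (!all(need %in% names(x$slices))) stopf("window lacks EEG channels")
    x <- cbind(x$slices$eeg_af7, x$slices$eeg_af8,
               x$slices$eeg_tp9, x$slices$eeg_tp10)
  }
  x <- as.matrix(x)
  if (ncol(x) != 4L) stopf("EEG input must have 4 channels (AF7, AF8, TP9, TP10)")
  colnames(x) <- eeg_channel_order
  x
}

#' EEG channel projections
#'
#' Computes the four derived series used throughout the EEG feature bank:
#' `mean` (all four channels), `prefrontal` (mean of AF7 and AF8),
#' `temporal` (mean of TP9 and TP10), and `asymmetry` (right minus left
#' hemisphere, i.e. `mean(AF8, TP10) - mean(AF7, TP9)`).
#'
#' @param eeg A `cogload_window` or an `n x 4` matrix with columns AF7, AF8,
#'   TP9, TP10 (equal lengths required).
#' @return List with numeric vectors `mean`, `prefrontal`, `temporal`,
#'   `asymmetry`.
#' @export
project_channels <- function(eeg) {
  m <- as_eeg_matrix(eeg)
  list(mean = rowMeans(m),
       prefrontal = (m[, "AF7"] + m[, "AF8"]) / 2,
       temporal = (m[, "TP9"] + m[, "TP10"]) / 2,
       asymmetry = (m[, "AF8"] + m[, "TP10"]) / 2 - (m[, "AF7"] + m[, "TP9"]) / 2)
}

#' Spectral band power of a series
#'
#' Total periodogram power over the frequency bins strictly inside the band
#' (rectangular window, mean removed before the transform; the DC bin is
#' thereby excluded from the delta band). A pure sine of amplitude `A` whose
#' frequency falls on a bin contributes `A^2 / 2` to its band, and for white
#' noise the expected band power is proportional to the band width.
#'
#' @param series Numeric vector of at least `fs` samples (1 s).
#' @param fs Sampling rate, Hz.
#' @param band Either a length-2 numeric `(lo, hi)` in Hz or a band name
#'   among `delta`, `theta`, `alpha`, `beta`, `gamma` (edges <4, 4-8, 8-12,
#'   12-30, 30-45 Hz).
#' @return Non-negative scalar (signal units squared).
#' @export
band_power <- function(series, fs, band) {
  if (length(series) < fs) stopf("series must be at least 1 s long (>= fs samples)")
  if (is.character(band)) {
    edges <- switch(band, delta = c(0, 4), theta = c(4, 8), alpha = c(8, 12),
                    beta = c(12, 30), gamma = c(30, 45),
                    stopf("unknown band '%s'", band))
  } else edges <- band
  n <- length(series)
  x <- series - mean(series)
  X <- stats::fft(x)
  k <- seq_len(floor(n / 2))           # positive-frequency bins
  f <- k * fs / n
  keep <- f > edges[1] & f < edges[2]
  if (!any(keep))
    stopf("band (%g, %g) Hz contains no frequency bins at resolution %g Hz",
          edges[1], edges[2], fs / n)
  sum(2 * Mod(X[k + 1][keep])^2 / n^2)
}

band_names <- c("delta", "theta", "alpha", "beta", "gamma")

#' Band powers for all projections and channels of an EEG window
#'
#' @inheritParams project_channels
#' @param fs EEG sampling rate (default 256 Hz).
#' @return List of named 5-vectors (delta..gamma) for `mean`, `prefrontal`,
#'   `temporal`, `AF7`, `AF8`, `TP9`, `TP10`.
#' @export
band_power_set <- function(eeg, fs = 256) {
  m <- as_eeg_matrix(eeg)
  pr <- project_channels(m)
  series <- c(pr[c("mean", "prefrontal", "temporal")],
              lapply(seq_len(4), function(j) m[, j]))
  names(series) <- c("mean", "prefrontal", "temporal", eeg_channel_order)
  lapply(series, function(s) {
    v <- vapply(band_names, function(b) band_power(s, fs, b), numeric(1))
    names(v) <- band_names
    v
  })
}

#' Default workload index registry
#'
#' The index formulas are pinned here and are replaceable by passing a
#' modified registry to [compute_indices()]. Defaults: Engagement Index
#' `beta / (alpha + theta)` on the mean projection; Brain Beat
#' `theta / alpha` on the mean projection; Cognitive Load Index
#' `prefrontal theta / temporal alpha`. Asymmetry indices are
#' log-alpha-power differences right minus left per region
#' (`ln P_alpha(AF8) - ln P_alpha(AF7)` prefrontally, `ln P_alpha(TP10) -
#' ln P_alpha(TP9)` temporally) and ASA is their mean.
#'
#' @return Named list of functions taking a [band_power_set()] result.
#' @export
index_registry <- function() {
  list(
    EngagementIndex = function(bp) safe_ratio(bp$mean[["beta"]],
                                              bp$mean[["alpha"]] + bp$mean[["theta"]]),
    BrainBeat = function(bp) safe_ratio(bp$mean[["theta"]], bp$mean[["alpha"]]),
    CLI = function(bp) safe_ratio(bp$prefrontal[["theta"]], bp$temporal[["alpha"]]),
    AsymmetryIndexPrefrontal = function(bp) log_ratio(bp$AF8[["alpha"]], bp$AF7[["alpha"]]),
    AsymmetryIndexTemporal = function(bp) log_ratio(bp$TP10[["alpha"]], bp$TP9[["alpha"]]),
    ASA = function(bp) {
      p <- log_ratio(bp$AF8[["alpha"]], bp$AF7[["alpha"]])
      t <- log_ratio(bp$TP10[["alpha"]], bp$TP9[["alpha"]])
      (p + t) / 2
    })
}

safe_ratio <- function(num, den) if (!is.finite(den) || den <= 0) NA_real_ else num / den
log_ratio <- function(a, b) {
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) return(NA_real_)
  log(a) - log(b)
}

#' Workload indices from a band-power set
#'
#' Applies the formula registry (see [index_registry()]) to a
#' [band_power_set()] result. Zero or non-finite denominator powers yield
#' `NA` (the window is retained; the feature is treated as missing
#' downstream).
#'
#' @param bandpowers Result of [band_power_set()].
#' @param registry Formula registry (default [index_registry()]).
#' @return Named numeric vector (EngagementIndex, BrainBeat, CLI,
#'   AsymmetryIndexPrefrontal, AsymmetryIndexTemporal, ASA).
#' @export
compute_indices <- function(bandpowers, registry = index_registry()) {
  vapply(registry, function(f) f(bandpowers), numeric(1))
}

dwt_signal_names <- c("AF7", "AF8", "TP9", "TP10", "mean")
dwt_wavelets <- c("db2", "haar")

#' Full EEG feature map of one 60 s window
#'
#' 736 named features: 720 wavelet statistics (five source series - the four
#' notch-filtered channels plus the mean projection - times two mother
#' wavelets times nine level-8 coefficient arrays times eight statistics;
#' names `<signal>_<wavelet>_<coef>_<stat>`) plus 16 spectral/index features
#' (prefrontal and temporal band powers for the five canonical bands, named
#' `<Region><Band>Power`, and the six workload indices).
#'
#' @inheritParams project_channels
#' @param fs EEG sampling rate (default 256).
#' @param registry Index formula registry.
#' @return Named numeric vector of length 736.
#' @export
extract_eeg_features <- function(eeg, fs = 256, registry = index_registry()) {
  m <- as_eeg_matrix(eeg)
  pr <- project_channels(m)
  series <- list(AF7 = m[, 1], AF8 = m[, 2], TP9 = m[, 3], TP10 = m[, 4],
                 mean = pr$mean)
  out <- numeric(0)
  for (sn in dwt_signal_names) {
    for (w in dwt_wavelets) {
      f <- dwt_features(series[[sn]], w, level = 8L)
      names(f) <- paste(sn, w, names(f), sep = "_")
      out <- c(out, f)
    }
  }
  bp <- band_power_set(m, fs)
  band_title <- c("Delta", "Theta", "Alpha", "Beta", "Gamma")
  region_title <- c(prefrontal = "Prefrontal", temporal = "Temporal")
  spow <- numeric(0)
  for (region in names(region_title)) {
    v <- bp[[region]]
    names(v) <- paste0(region_title[[region]], band_title, "Power")
    spow <- c(spow, v)
  }
  c(out, spow, compute_indices(bp, registry))
}
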