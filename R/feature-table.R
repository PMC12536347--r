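meta_columns <- c("participant_id", "session_id", "window_index", "activity",
                  "environment", "workload_response", "stress_response")

#' Canonical feature-name schema
#'
#' The 754 feature names in extraction order: 720 wavelet statistics
#' (`<signal>_<wavelet>_<coef>_<stat>` over signals AF7/AF8/TP9/TP10/mean,
#' wavelets db2/haar, coefficients cA8, cD8..cD1 and the eight statistics),
#' 10 regional band powers, 6 workload indices and the 18 wristband
#' features.
#'
#' @return Character vector of length 754.
#' @export
all_feature_names <- function() {
  dwt <- as.vector(vapply(dwt_signal_names, function(sn)
    vapply(dwt_wavelets, function(w)
      paste(sn, w, rep(c("cA8", sprintf("cD%d", 8:1)), each = 8),
            dwt_stat_names, sep = "_"),
      character(72)), character(144)))
  band_title <- c("Delta", "Theta", "Alpha", "Beta", "Gamma")
  spectral <- c(paste0("Prefrontal", band_title, "Power"),
                paste0("Temporal", band_title, "Power"),
                "EngagementIndex", "BrainBeat", "CLI",
                "AsymmetryIndexPrefrontal", "AsymmetryIndexTemporal", "ASA")
  c(dwt, spectral, e4_feature_names)
}

#' Feature columns of a feature table
#'
#' @param table A feature table.
#' @return Names of the non-metadata columns.
#' @export
feature_columns <- function(table) setdiff(names(table), meta_columns)

#' Extract the full 754-entry feature map of one window
#'
#' @param window A `cogload_window` with EEG, PPG, EDA and temperature
#'   slices (see [segment_windows()]).
#' @return Named numeric vector of length 754.
#' @export
extract_window_features <- function(window) {
  c(extract_eeg_features(window, fs = window$fs$eeg_af7),
    extract_e4_features(window))
}

#' Build a feature table from labelled windows
#'
#' One row per window: the metadata columns (`participant_id`, `session_id`,
#' `window_index`, `activity`, `environment`, `workload_response`,
#' `stress_response`) followed by the 754 features.
#'
#' @param windows List of `cogload_window` objects.
#' @return Data frame of class `cogload_features` (column names are kept
#'   verbatim, including hyphens).
#' @export
extract_features <- function(windows) {
  if (!length(windows)) stopf("no windows to extract features from")
  feats <- t(vapply(windows, extract_window_features,
                    numeric(length(all_feature_names()))))
  meta <- data.frame(
    participant_id = vapply(windows, `[[`, character(1), "participant_id"),
    session_id = vapply(windows, `[[`, character(1), "session_id"),
    window_index = vapply(windows, `[[`, integer(1), "window_index"),
    activity = vapply(windows, `[[`, character(1), "activity"),
    environment = vapply(windows, `[[`, character(1), "environment"),
    workload_response = vapply(windows, `[[`, numeric(1), "workload_response"),
    stress_response = vapply(windows, `[[`, numeric(1), "stress_response"),
    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(meta, as.data.frame(feats, check.names = FALSE))
  class(out) <- c("cogload_features", "data.frame")
  out
}

#' Preprocess and window one session
#'
#' Notch-filters the high-rate channels, estimates the inter-device clock
#' offset from the shake burst (falling back to the declared offset with a
#' warning if no confident burst match is found), applies it, and cuts
#' labelled 60 s windows.
#'
#' @param session List with `recording` and `log` (from
#'   [generate_session()] or [read_session()]).
#' @param window_s Window length, seconds.
#' @param notch_f0,notch_q Notch parameters.
#' @param sync If FALSE, trust `recording$device_offset_s` instead of
#'   re-estimating.
#' @return List of `cogload_window` objects.
#' @export
process_session <- function(session, window_s = 60, notch_f0 = 50,
                            notch_q = 30, sync = TRUE) {
  rec <- preprocess_recording(session$recording, f0 = notch_f0, q = notch_q)
  offset <- if (sync) {
    tryCatch(
      estimate_sync_offset(motion_magnitude(rec, "muse"),
                           motion_magnitude(rec, "e4")),
      error = function(e) {
        warning(sprintf("sync estimation failed (%s); using declared offset",
                        conditionMessage(e)))
        rec$device_offset_s
      })
  } else rec$device_offset_s
  rec <- apply_sync_offset(rec, offset)
  segment_windows(rec, session$log, window_s = window_s)
}

#' Feature table for a whole study
#'
#' Runs [process_session()] and [extract_features()] over a list of
#' sessions.
#'
#' @param sessions List of sessions (each with `recording` and `log`).
#' @param ... Passed to [process_session()].
#' @export
build_feature_table <- function(sessions, ...) {
  windows <- unlist(lapply(sessions, process_session, ...), recursive = FALSE)
  extract_features(windows)
}

#' Write / read a feature table as CSV
#'
#' @param table A feature table.
#' @param path CSV path.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("cogload_features", "data.frame")
  out
}
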