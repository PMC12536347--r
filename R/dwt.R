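#' Discrete wavelet transform filter bank
#'
#' Decomposition filters for the two mother wavelets used by the EEG feature
#' bank. Coefficients follow the standard orthogonal Daubechies construction
#' (db2 has four taps; haar two).
#'
#' @param wavelet `"db2"` or `"haar"`.
#' @return List with numeric vectors `dec_lo` and `dec_hi`.
#' @export
dwt_filters <- function(wavelet = c("db2", "haar")) {
  wavelet <- match.arg(wavelet)
  if (wavelet == "haar") {
    h <- 1 / sqrt(2)
    list(dec_lo = c(h, h), dec_hi = c(-h, h))
  } else {
    s3 <- sqrt(3)
    lo <- c(1 - s3, 3 - s3, 3 + s3, 1 + s3) / (4 * sqrt(2))
    # analysis low-pass and its quadrature-mirror high-pass
    list(dec_lo = lo, dec_hi = rev(lo) * c(-1, 1, -1, 1))
  }
}

# One analysis step: half-point symmetric extension by (filter length - 1)
# samples on each side, full convolution, then dyadic downsampling. Output
# length floor((n + L - 1) / 2), matching the usual filter-bank convention.
dwt_step <- function(x, dec_lo, dec_hi) {
  n <- length(x)
  p <- length(dec_lo) - 1L
  ext <- c(x[p:1], x, x[n:(n - p + 1L)])
  m <- length(ext)
  flen <- length(dec_lo)
  # y[k] = sum_j f[j] * ext[k + j - 1] (correlation with the reversed filter,
  # i.e. convolution); vectorised as a sum of shifted slices.
  nv <- m - flen + 1L
  conv_valid <- function(f) {
    acc <- numeric(nv)
    for (j in seq_len(flen)) acc <- acc + rev(f)[j] * ext[j:(j + nv - 1L)]
    acc
  }
  lo_full <- conv_valid(dec_lo)
  hi_full <- conv_valid(dec_hi)
  keep <- seq(2L, nv, by = 2L)
  list(cA = lo_full[keep], cD = hi_full[keep])
}

#' Multilevel discrete wavelet decomposition
#'
#' Cascaded analysis filter bank: the approximation of each level feeds the
#' next. With `level = 8` the retained coefficient arrays are
#' `cA8, cD8, cD7, ..., cD1` (nine arrays), the set used by the EEG feature
#' bank.
#'
#' @param x Numeric vector.
#' @param wavelet `"db2"` or `"haar"`.
#' @param level Decomposition depth (default 8).
#' @return Named list `cA<level>`, `cD<level>`, ..., `cD1`.
#' @export
wavedec <- function(x, wavelet = c("db2", "haar"), level = 8L) {
  wavelet <- match.arg(wavelet)
  f <- dwt_filters(wavelet)
  min_len <- 2L^level
  if (length(x) < min_len)
    stopf("series of length %d is too short for a level-%d decomposition (need >= %d samples)",
          length(x), level, min_len)
  details <- vector("list", level)
  a <- as.numeric(x)
  for (l in seq_len(level)) {
    st <- dwt_step(a, f$dec_lo, f$dec_hi)
    details[[l]] <- st$cD
    a <- st$cA
  }
  out <- c(list(a), rev(details))
  names(out) <- c(sprintf("cA%d", level), sprintf("cD%d", level:1))
  out
}

dwt_stat_names <- c("STD", "MEAN", "MIN", "MAX", "Skewness",
                    "RelativeWaveletEnergy", "Kurtosis", "ZeroCrossing")

#' Wavelet statistic bank for one series
#'
#' Decomposes `series` to `level` and summarises each of the nine retained
#' coefficient arrays with eight statistics: population STD, MEAN, MIN, MAX,
#' Skewness and Kurtosis (standardised third/fourth central moments, kurtosis
#' not excess-adjusted), RelativeWaveletEnergy (squared norm of the array over
#' the summed squared norms of all nine arrays) and ZeroCrossing (strict sign
#' changes).
#'
#' @inheritParams wavedec
#' @param series Numeric vector, at least `2^level` samples.
#' @return Named numeric vector of length 72 with names `<coef>_<stat>`.
#' @export
dwt_features <- function(series, wavelet = c("db2", "haar"), level = 8L) {
  wavelet <- match.arg(wavelet)
  coefs <- wavedec(series, wavelet, level)
  energies <- vapply(coefs, function(c) sum(c^2), numeric(1))
  tot <- sum(energies)
  out <- numeric(0)
  for (nm in names(coefs)) {
    c <- coefs[[nm]]
    rwe <- if (tot > 0) energies[[nm]] / tot else NaN
    vals <- c(pop_sd(c), mean(c), min(c), max(c), moment_skewness(c),
              rwe, moment_kurtosis(c), as.numeric(zero_crossings(c)))
    names(vals) <- paste(nm, dwt_stat_names, sep = "_")
    out <- c(out, vals)
  }
  out
}
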