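#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs user RNG.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic child-seed spawning: a master seed plus a stream index map to
# an independent-looking 31-bit seed (Lehmer step), keeping modalities and
# participants reproducible yet decoupled.
child_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (i in seq_len(2 + (k %% 7))) {
    s <- (s * 48271) %% 2147483647
  }
  as.integer((s + 104729 * as.double(k)) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stopf("`%s` must be a single positive number", what)
  invisible(x)
}

# Population-convention moments used by the wavelet statistic bank.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

moment_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NaN)
  mean((x - m)^3) / m2^1.5
}

moment_kurtosis <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NaN)
  mean((x - m)^4) / m2^2
}

# Strict sign changes: a crossing is counted only when the product of
# consecutive samples is negative; exact zeros never count.
zero_crossings <- function(x) {
  n <- length(x)
  if (n < 2L) return(0L)
  sum(x[-n] * x[-1L] < 0)
}
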