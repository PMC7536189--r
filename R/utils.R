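# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards so library calls never disturb user randomness.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream seed from a base seed; keeps results < 2^31.
substream_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629
}

# Run-length segments of a logical vector: data.frame(start, end) of
# maximal TRUE runs, in element indices (inclusive).
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Centered moving average with window `k` samples (odd or even); edges
# use the partial window so output length equals input length.
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k == 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half_lo <- (k - 1L) %/% 2L
  half_hi <- k %/% 2L
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Analytic signal via FFT (one-sided spectrum doubling).
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 4) stop("signal too short for analytic transform")
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

hilbert_envelope <- function(x) Mod(analytic_signal(x))
hilbert_phase <- function(x) Arg(analytic_signal(x))

`%||%` <- function(a, b) if (is.null(a)) b else a
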