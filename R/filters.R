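#' Zero-phase Butterworth band-pass filter
#'
#' Filters a signal with a fourth-order Butterworth band-pass applied
#' forward and backward (`signal::filtfilt`), so the output has exactly
#' zero phase shift relative to the input. This is the filter used for
#' all band delineation in the package: the slow-wave band (0.4-4.5 Hz)
#' for slow-oscillation segmentation and phase extraction, the
#' 10-16 Hz band for spindle detection, and the 10-20 Hz band for
#' coupling amplitude.
#'
#' @param x numeric signal (any units; typically EEG in microvolts).
#' @param band length-2 numeric, lower and upper corner frequencies in Hz.
#' @param rate sampling rate in Hz.
#' @param order Butterworth design order (default 4).
#' @return filtered signal, same length as `x`.
#' @examples
#' t <- seq(0, 10, by = 1 / 400)
#' x <- sin(2 * pi * 2 * t) + sin(2 * pi * 30 * t)
#' y <- bandpass_phase_neutral(x, c(0.4, 4.5), 400)
#' @export
bandpass_phase_neutral <- function(x, band, rate, order = 4) {
  stopifnot(is.numeric(x), length(band) == 2, rate > 0)
  low <- band[1]; high <- band[2]
  if (!(low > 0 && high > low && high < rate / 2)) stop("invalid band")
  bf <- signal::butter(order, c(low, high) * 2 / rate, type = "pass")
  flen <- max(length(bf$b), length(bf$a))
  if (length(x) <= 3 * flen) stop("signal too short for filter")
  signal::filtfilt(bf, x)
}

# Welch-style PSD from fixed-length, non-overlapping epochs of a signal.
# `idx` is a list of sample-index vectors (one per epoch, all the same
# length). Hann window, one-sided density in units^2/Hz.
welch_psd_epochs <- function(x, idx, rate) {
  stopifnot(length(idx) >= 1)
  m <- length(idx[[1]])
  w <- 0.5 * (1 - cos(2 * pi * seq_len(m) / (m + 1)))  # Hann
  u <- sum(w^2)
  seg <- vapply(idx, function(i) {
    s <- x[i]
    (s - mean(s)) * w
  }, numeric(m))
  sp <- Mod(stats::mvfft(seg))^2
  nf <- floor(m / 2) + 1L
  psd <- rowMeans(sp[seq_len(nf), , drop = FALSE]) / (rate * u)
  # double all bins except DC (and Nyquist when m is even) for one-sided
  mult <- rep(2, nf); mult[1] <- 1
  if (m %% 2 == 0) mult[nf] <- 1
  data.frame(freq = (seq_len(nf) - 1) * rate / m, psd = psd * mult)
}

# Integrated band power from a Welch PSD table (trapezoid-free simple
# bin sum times resolution; adequate for band ratios).
band_power <- function(psd_tab, band) {
  sel <- psd_tab$freq >= band[1] & psd_tab$freq <= band[2]
  df <- if (nrow(psd_tab) > 1) psd_tab$freq[2] - psd_tab$freq[1] else 1
  sum(psd_tab$psd[sel]) * df
}
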