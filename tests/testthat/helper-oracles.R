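# Shared fixtures and independent oracles for the test suite.
# Oracles re-derive expected results through a different code path than
# the implementation they check.

# Brute-force slow-oscillation oracle: own filtering, segmentation and
# explicit sort-and-cut application of the duration and percentile
# criteria. Returns segment start/end sample indices (1-based).
so_brute_force <- function(eeg, rate) {
  bf <- signal::butter(4, c(0.4, 4.5) * 2 / rate, type = "pass")
  y <- signal::filtfilt(bf, eeg)
  cross <- which(y[-length(y)] < 0 & y[-1] >= 0) + 1L
  if (length(cross) < 2) return(data.frame(s = integer(0), e = integer(0)))
  segs <- data.frame(s = cross[-length(cross)], e = cross[-1])
  segs$dur <- (segs$e - segs$s) / rate
  segs <- segs[segs$dur >= 0.4 & segs$dur <= 2.0, , drop = FALSE]
  if (nrow(segs) == 0) return(segs)
  segs$dn <- mapply(function(a, b) min(y[a:(b - 1)]), segs$s, segs$e)
  segs$pp <- mapply(function(a, b) max(y[a:(b - 1)]), segs$s, segs$e) - segs$dn
  s1 <- segs[order(segs$dn, segs$s), , drop = FALSE]
  s1 <- s1[seq_len(floor(0.35 * nrow(segs))), , drop = FALSE]
  s2 <- s1[order(-s1$pp, s1$s), , drop = FALSE]
  s2 <- s2[seq_len(floor(0.45 * nrow(s1))), , drop = FALSE]
  s2[order(s2$s), , drop = FALSE]
}

# Greedy one-to-one event matching by >= 50% overlap of the reference
# event; returns recall/precision.
match_events <- function(det_s, det_e, ref_s, ref_e) {
  hits <- logical(length(ref_s))
  used <- logical(length(det_s))
  for (k in seq_along(ref_s)) {
    ov <- pmin(det_e, ref_e[k]) - pmax(det_s, ref_s[k])
    j <- which(!used & ov >= 0.5 * (ref_e[k] - ref_s[k]))
    if (length(j)) {
      hits[k] <- TRUE
      used[j[1]] <- TRUE
    }
  }
  list(recall = mean(hits),
       precision = if (length(det_s)) sum(hits) / length(det_s) else NA_real_)
}

# Closed-form modulation-index oracle for a fast envelope proportional
# to (1 + m cos(phi)) with phi uniform: the bin median of a monotone
# function of a uniform variate is its value at the bin midpoint.
mi_cosine_oracle <- function(m, n_bins = 12) {
  centers <- -pi + (seq_len(n_bins) - 0.5) * 2 * pi / n_bins
  p <- 1 + m * cos(centers)
  p <- p / sum(p)
  (log(n_bins) + sum(p * log(p))) / log(n_bins)
}

# Bandlimited random test signal in the slow-frequency range.
random_slow_signal <- function(seed, n, rate) {
  set.seed(seed)
  bf <- signal::butter(2, c(0.3, 6) * 2 / rate, type = "pass")
  as.numeric(signal::filtfilt(bf, stats::rnorm(n))) * 50
}

# Signal holding exactly n duration-valid zero-crossing candidates with
# strictly increasing, well-separated amplitudes (1-s sine cycles; the
# first cycle only opens the first crossing and is not a candidate).
ramped_cycle_signal <- function(n, rate) {
  cycles <- n + 1
  amps <- c(5, 10 + 5 * seq_len(n))
  tt <- seq(0, cycles - 1 / rate, by = 1 / rate)
  amps[pmin(floor(tt) + 1, cycles)] * sin(2 * pi * (tt %% 1))
}

all_nrem_hypnogram <- function(seconds, epoch_length = 4) {
  hypnogram(rep("NREM", floor(seconds / epoch_length)),
            epoch_length = epoch_length)
}
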