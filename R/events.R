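#' Detect slow oscillations in NREM EEG
#'
#' Implements zero-crossing segmentation with percentile amplitude
#' criteria. Within every contiguous artefact-free NREM run the signal
#' is band-passed 0.4-4.5 Hz with a zero-phase fourth-order Butterworth
#' filter (no filtering across run boundaries). Candidate segments are
#' the intervals between consecutive negative-to-positive zero
#' crossings; candidates lasting 0.4-2.0 s are pooled across runs and
#' reduced to the top 35% by most-negative peak amplitude, then to the
#' top 45% of those by negative-to-positive peak-to-peak amplitude.
#' Amplitudes are measured on the filtered trace.
#'
#' Percentile cuts keep the first `floor(q * n)` candidates after
#' sorting descending on the criterion, ties broken by earlier start
#' time. Zero crossings are located at sample-pair sign changes with
#' the boundary on the later sample; segments touching a run boundary
#' are never formed. Runs shorter than three filter lengths are
#' skipped.
#'
#' @param eeg numeric EEG vector (uV) covering the hypnogram span.
#' @param hyp a [hypnogram()] aligned to the first sample of `eeg`.
#' @param rate sampling rate in Hz.
#' @return data.frame of class `so_events` with columns `start`, `end`
#'   (seconds), `duration`, `downstate_amp` (negative, uV) and
#'   `p2p_amp` (uV), ordered by start time.
#' @export
detect_slow_oscillations <- function(eeg, hyp, rate) {
  cand <- so_candidates(eeg, hyp, rate)
  out <- select_so_events(cand)
  class(out) <- c("so_events", "data.frame")
  out
}

# Duration-valid zero-crossing segments of the slow-band trace, pooled
# across artefact-free NREM runs.
so_candidates <- function(eeg, hyp, rate, band = c(0.4, 4.5),
                          dur_range = c(0.4, 2.0)) {
  stopifnot(inherits(hyp, "hypnogram"), rate > 0)
  spe <- round(hyp$epoch_length * rate)
  if (length(eeg) < length(hyp) * spe) stop("rate mismatch")
  runs <- state_sample_runs(hyp, rate, "NREM", artefact_free = TRUE)
  if (nrow(runs) == 0) {
    warning("no NREM epochs; returning empty event list")
    return(empty_so_frame())
  }
  min_len <- 3 * (2 * 4 * 2 + 1)  # three lengths of the order-4 IIR
  res <- list()
  for (r in seq_len(nrow(runs))) {
    seg <- eeg[runs$start_sample[r]:runs$end_sample[r]]
    if (length(seg) < min_len) next
    y <- bandpass_phase_neutral(seg, band, rate)
    cross <- which(y[-length(y)] < 0 & y[-1] >= 0) + 1L  # later sample
    if (length(cross) < 2) next
    st <- cross[-length(cross)]
    en <- cross[-1]
    dur <- (en - st) / rate
    ok <- dur >= dur_range[1] & dur <= dur_range[2]
    if (!any(ok)) next
    st <- st[ok]; en <- en[ok]
    mins <- vapply(seq_along(st), function(i) min(y[st[i]:(en[i] - 1L)]),
                   numeric(1))
    maxs <- vapply(seq_along(st), function(i) max(y[st[i]:(en[i] - 1L)]),
                   numeric(1))
    res[[length(res) + 1L]] <- data.frame(
      start = (runs$start_sample[r] + st - 2L) / rate,
      end = (runs$start_sample[r] + en - 2L) / rate,
      downstate_amp = mins,
      p2p_amp = maxs - mins)
  }
  if (length(res) == 0) return(empty_so_frame())
  out <- do.call(rbind, res)
  out$duration <- out$end - out$start
  out[order(out$start), c("start", "end", "duration",
                          "downstate_amp", "p2p_amp")]
}

# Percentile selection: top 35% by most-negative peak, then top 45% of
# those by peak-to-peak, floor() at each cut, earlier start wins ties.
select_so_events <- function(cand, frac_downstate = 0.35, frac_p2p = 0.45) {
  if (nrow(cand) == 0) return(cand)
  o1 <- order(cand$downstate_amp, cand$start)  # most negative first
  k1 <- floor(frac_downstate * nrow(cand))
  stage1 <- cand[o1[seq_len(k1)], , drop = FALSE]
  if (k1 == 0) return(cand[0, , drop = FALSE])
  o2 <- order(-stage1$p2p_amp, stage1$start)
  k2 <- floor(frac_p2p * nrow(stage1))
  out <- stage1[o2[seq_len(k2)], , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_so_frame <- function() {
  data.frame(start = numeric(0), end = numeric(0), duration = numeric(0),
             downstate_amp = numeric(0), p2p_amp = numeric(0))
}

#' Detect sleep spindles in NREM EEG
#'
#' Band-passes each contiguous artefact-free NREM run at 10-16 Hz
#' (zero-phase fourth-order Butterworth), takes the Hilbert-transform
#' magnitude, smooths it with a 200-ms moving average, and thresholds
#' at mean + 1.5 SD of the smoothed envelope computed over artefact-free
#' NREM samples of the whole span. A spindle is a maximal
#' supra-threshold run lasting 0.4-2.0 s; onset is the time of the
#' first supra-threshold sample. Supra-threshold runs touching an NREM
#' run boundary are discarded rather than truncated.
#'
#' @inheritParams detect_slow_oscillations
#' @param threshold_sd SD multiple above the envelope mean (default 1.5).
#' @return data.frame of class `spindle_events` with columns `onset`,
#'   `duration` (s) and `peak_envelope` (uV).
#' @export
detect_spindles <- function(eeg, hyp, rate, threshold_sd = 1.5) {
  stopifnot(inherits(hyp, "hypnogram"), rate > 0)
  spe <- round(hyp$epoch_length * rate)
  if (length(eeg) < length(hyp) * spe) stop("rate mismatch")
  runs <- state_sample_runs(hyp, rate, "NREM", artefact_free = TRUE)
  empty <- data.frame(onset = numeric(0), duration = numeric(0),
                      peak_envelope = numeric(0))
  class(empty) <- c("spindle_events", "data.frame")
  if (nrow(runs) == 0) {
    warning("no NREM epochs; returning empty event list")
    return(empty)
  }
  min_len <- 3 * (2 * 4 * 2 + 1)
  win <- round(0.2 * rate)
  envs <- vector("list", nrow(runs))
  for (r in seq_len(nrow(runs))) {
    seg <- eeg[runs$start_sample[r]:runs$end_sample[r]]
    if (length(seg) < min_len) next
    y <- bandpass_phase_neutral(seg, c(10, 16), rate)
    envs[[r]] <- moving_average(hilbert_envelope(y), win)
  }
  pooled <- unlist(envs[!vapply(envs, is.null, logical(1))])
  if (is.null(pooled) || length(pooled) == 0) return(empty)
  thr <- mean(pooled) + threshold_sd * stats::sd(pooled)

  out <- list()
  for (r in seq_len(nrow(runs))) {
    env <- envs[[r]]
    if (is.null(env)) next
    supra <- true_runs(env > thr)
    if (nrow(supra) == 0) next
    # discard runs touching the NREM-run boundary
    supra <- supra[supra$start > 1 & supra$end < length(env), , drop = FALSE]
    dur <- (supra$end - supra$start + 1) / rate
    ok <- dur >= 0.4 & dur <= 2.0
    supra <- supra[ok, , drop = FALSE]
    if (nrow(supra) == 0) next
    out[[length(out) + 1L]] <- data.frame(
      onset = (runs$start_sample[r] + supra$start - 2L) / rate,
      duration = (supra$end - supra$start + 1) / rate,
      peak_envelope = vapply(seq_len(nrow(supra)), function(i)
        max(env[supra$start[i]:supra$end[i]]), numeric(1)))
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$onset), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("spindle_events", "data.frame")
  res
}

#' Event counts and densities per minute of NREM
#'
#' @param so data.frame of slow-oscillation events.
#' @param spindles data.frame of spindle events.
#' @param macro a [macro_metrics()] result for the same span.
#' @return list with `so_count`, `spindle_count`, `so_density`,
#'   `spindle_density` (per NREM minute) and `nrem_minutes`.
#' @export
summarize_events <- function(so, spindles, macro) {
  stopifnot(inherits(macro, "sleep_macro"))
  n_so <- nrow(so); n_sp <- nrow(spindles)
  if (macro$nrem_minutes == 0 && (n_so > 0 || n_sp > 0))
    stop("inconsistent inputs: events reported with zero NREM time")
  dens <- function(k) if (macro$nrem_minutes > 0) k / macro$nrem_minutes else 0
  list(so_count = n_so, spindle_count = n_sp,
       so_density = dens(n_so), spindle_density = dens(n_sp),
       nrem_minutes = macro$nrem_minutes)
}
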