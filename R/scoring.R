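#' Configuration for the rule-based epoch scorer
#'
#' Wake is recognised by high muscle tone, REM by a theta-dominant EEG
#' together with muscle atonia, everything else is NREM. Thresholds are
#' expressed relative to the recording itself: the wake cut-off is a
#' multiple of the recording-wide median of per-epoch EMG RMS, and the
#' REM atonia bound is a fraction of that wake cut-off, so the scorer is
#' invariant to overall EMG gain.
#'
#' @param emg_wake_threshold wake cut-off as a multiple of the median
#'   per-epoch EMG RMS (default 2).
#' @param delta_band,theta_band Hz intervals for the spectral ratio
#'   (defaults 0.5-4 and 6-9; the REM theta peak is expected at 7-8 Hz).
#' @param theta_delta_ratio_rem theta/delta power ratio above which an
#'   atonic epoch is scored REM (default 1).
#' @param rem_atonia_fraction REM requires EMG RMS below this fraction
#'   of the wake cut-off (default 0.6).
#' @param rem_theta_fraction minimum share of total EEG power in the
#'   theta band for an epoch to qualify as REM (default 0.3); ensures a
#'   clear theta peak rather than an incidental band ratio.
#' @param nrem_delta_fraction minimum share of total EEG power in the
#'   delta band for an epoch to qualify as NREM (default 0.6); epochs
#'   with neither muscle tone above the wake cut-off nor a delta- or
#'   theta-dominant spectrum are scored WAKE (mixed-frequency EEG
#'   without a clear spectral peak).
#' @param artefact_amp_bound absolute EEG amplitude (uV) above which an
#'   epoch is flagged as artefact (default 1000).
#' @return object of class `scoring_config`.
#' @export
scoring_config <- function(emg_wake_threshold = 2,
                           delta_band = c(0.5, 4),
                           theta_band = c(6, 9),
                           theta_delta_ratio_rem = 1,
                           rem_atonia_fraction = 0.6,
                           rem_theta_fraction = 0.3,
                           nrem_delta_fraction = 0.6,
                           artefact_amp_bound = 1000) {
  if (emg_wake_threshold <= 0 || theta_delta_ratio_rem <= 0 ||
      rem_atonia_fraction <= 0 || artefact_amp_bound <= 0 ||
      nrem_delta_fraction <= 0 || nrem_delta_fraction >= 1 ||
      rem_theta_fraction <= 0 || rem_theta_fraction >= 1)
    stop("thresholds must be positive")
  if (max(delta_band[1], theta_band[1]) < min(delta_band[2], theta_band[2]))
    stop("delta and theta bands must not overlap")
  structure(list(emg_wake_threshold = emg_wake_threshold,
                 delta_band = delta_band, theta_band = theta_band,
                 theta_delta_ratio_rem = theta_delta_ratio_rem,
                 rem_atonia_fraction = rem_atonia_fraction,
                 rem_theta_fraction = rem_theta_fraction,
                 nrem_delta_fraction = nrem_delta_fraction,
                 artefact_amp_bound = artefact_amp_bound),
            class = "scoring_config")
}

#' Rule-based sleep staging of 4-s epochs
#'
#' Scores every complete epoch of a recording as WAKE, NREM or REM:
#' WAKE when the epoch EMG RMS exceeds the wake cut-off; otherwise REM
#' when the EEG is theta-dominant (theta/delta ratio above
#' `theta_delta_ratio_rem` with at least `rem_theta_fraction` of total
#' power in the theta band) and the EMG is below the atonia bound;
#' otherwise NREM when the delta band holds at least
#' `nrem_delta_fraction` of total power; otherwise WAKE
#' (mixed-frequency EEG without a clear spectral peak). Epochs whose
#' EEG amplitude exceeds `artefact_amp_bound` are flagged as artefact.
#' A trailing partial epoch is discarded.
#'
#' @param rec a [recording()] with an EMG role and at least one EEG role.
#' @param config a [scoring_config()].
#' @param epoch_length epoch duration in seconds (default 4).
#' @return a [hypnogram()].
#' @export
score_epochs <- function(rec, config = scoring_config(), epoch_length = 4) {
  stopifnot(inherits(rec, "recording"), inherits(config, "scoring_config"))
  emg <- tryCatch(get_channel(rec, "EMG"),
                  error = function(e) stop("EMG required"))
  eeg <- tryCatch(get_channel(rec, "EEG_parietal"), error = function(e)
    tryCatch(get_channel(rec, "EEG_frontal"),
             error = function(e2) stop("EEG role required")))
  rate <- rec$sample_rate
  spe <- round(epoch_length * rate)
  n_ep <- floor(n_samples(rec) / spe)
  if (n_ep < 1) stop("recording shorter than one epoch")

  used <- seq_len(n_ep * spe)
  emg_mat <- matrix(emg[used], nrow = spe)
  rms <- sqrt(colMeans(emg_mat^2))

  # per-epoch Hann periodogram band powers, chunked to bound memory
  w <- 0.5 * (1 - cos(2 * pi * seq_len(spe) / (spe + 1)))
  freqs <- (seq_len(floor(spe / 2) + 1L) - 1) * rate / spe
  dsel <- freqs >= config$delta_band[1] & freqs <= config$delta_band[2]
  tsel <- freqs >= config$theta_band[1] & freqs <= config$theta_band[2]
  delta_p <- numeric(n_ep); theta_p <- numeric(n_ep)
  total_p <- numeric(n_ep); amax <- numeric(n_ep)
  chunk <- 4096L
  for (b in seq(1L, n_ep, by = chunk)) {
    ep <- b:min(b + chunk - 1L, n_ep)
    m <- matrix(eeg[((ep[1] - 1L) * spe + 1L):(ep[length(ep)] * spe)],
                nrow = spe)
    amax[ep] <- apply(abs(m), 2, max)
    m <- sweep(m, 2, colMeans(m)) * w
    sp <- Mod(stats::mvfft(m))^2
    delta_p[ep] <- colSums(sp[dsel, , drop = FALSE])
    theta_p[ep] <- colSums(sp[tsel, , drop = FALSE])
    total_p[ep] <- colSums(sp[seq_along(freqs), , drop = FALSE])
  }

  thr <- config$emg_wake_threshold * stats::median(rms)
  ratio <- theta_p / pmax(delta_p, .Machine$double.eps)
  # default WAKE: mixed-frequency EEG without a dominant peak; NREM
  # requires delta dominance, REM a theta-dominant spectrum with atonia
  labels <- rep("WAKE", n_ep)
  labels[delta_p / pmax(total_p, .Machine$double.eps) >=
           config$nrem_delta_fraction] <- "NREM"
  is_rem <- ratio > config$theta_delta_ratio_rem &
    theta_p / pmax(total_p, .Machine$double.eps) >=
      config$rem_theta_fraction &
    rms < config$rem_atonia_fraction * thr
  labels[is_rem] <- "REM"
  labels[rms > thr] <- "WAKE"
  hypnogram(labels, amax > config$artefact_amp_bound, epoch_length)
}

#' State-restricted Welch power spectral density
#'
#' Averages Hann-windowed periodograms over all artefact-free epochs of
#' one state, giving a one-sided PSD in uV^2/Hz with a frequency
#' resolution of 1/epoch_length Hz (0.25 Hz for 4-s epochs). Epochs
#' containing artefacts are excluded.
#'
#' @param rec a [recording()].
#' @param hyp a [hypnogram()] aligned to the recording start.
#' @param state `"WAKE"`, `"NREM"` or `"REM"`.
#' @param channel_role which channel to analyse (default parietal EEG).
#' @return data.frame with columns `freq` (Hz) and `psd` (uV^2/Hz).
#' @export
state_psd <- function(rec, hyp, state, channel_role = "EEG_parietal") {
  stopifnot(inherits(rec, "recording"), inherits(hyp, "hypnogram"))
  state <- normalize_stage_labels(state)
  x <- get_channel(rec, channel_role)
  rate <- rec$sample_rate
  spe <- round(hyp$epoch_length * rate)
  n_ep_avail <- floor(length(x) / spe)
  ep <- which(hyp$labels == state & !hyp$artefact)
  ep <- ep[ep <= n_ep_avail]
  if (length(ep) == 0) stop("no epochs for state")
  welch_psd_epochs(x, epoch_sample_index(hyp, rate, ep), rate)
}
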