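#' Configuration for the synthetic polysomnography generator
#'
#' Bundles every knob of the simulator: the epoch-resolution Markov
#' chain over wake/NREM/REM, state-dependent spectral weights for the
#' EEG background, EMG tone per state, rates and amplitudes of embedded
#' slow oscillations and sleep spindles, and the depth of slow-phase
#' modulation of spindle-band amplitude.
#'
#' The defaults emulate a mouse 24-h polysomnogram: roughly 43% wake,
#' 50% NREM and 7% REM at stationarity, a delta-dominant NREM spectrum,
#' a 7-8 Hz theta peak in REM, strong EMG tone in wake and atonia in
#' REM. Slow oscillations are inserted at 10 per NREM minute with
#' down-state amplitudes around -120 uV; spindles at 5 per NREM minute
#' as 12-Hz bursts whose envelope peaks at `spindle_amp_sd_multiple`
#' times the 10-16 Hz background SD. `pac_depth = 0` means no coupling
#' unless requested.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param duration recording duration in seconds (default 3600).
#' @param epoch_length epoch duration in seconds (default 4).
#' @param sample_rate sampling rate in Hz (default 400).
#' @param transition_matrix 3x3 row-stochastic matrix over
#'   (WAKE, NREM, REM) at epoch resolution. In the default matrix REM
#'   is reachable only from NREM.
#' @param so_rate slow oscillations per minute of NREM (default 10).
#' @param so_downstate_amp c(mean, sd) of the down-state magnitude in uV.
#' @param spindle_rate spindles per minute of NREM (default 5).
#' @param spindle_freq spindle carrier frequency in Hz (default 12).
#' @param spindle_amp_sd_multiple burst envelope peak as a multiple of
#'   the 10-16 Hz background SD (default 5).
#' @param pac_depth modulation depth m in \[0,1\]: spindle-band amplitude
#'   in NREM is scaled by (1 + m cos(phase of the slow component)).
#' @param noise_sd named per-state SD (uV) of the broadband 1/f floor.
#' @param delta_sd,theta_sd,sigma_sd named per-state SD (uV) of the
#'   0.5-4, 6.5-8.5 and 10-16 Hz background components.
#' @param emg_tone named per-state EMG RMS in uV.
#' @param artefact_rate per-epoch probability of an artefact flag
#'   (default 0); flagged epochs receive saturation-amplitude pulses.
#' @param event_spacing `"deterministic"` (rate-exact even spacing,
#'   the default, so ground-truth counts are exact) or `"poisson"`.
#' @param n_eeg number of EEG channels to synthesise (1 or 2).
#' @return object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         duration = 3600,
                         epoch_length = 4,
                         sample_rate = 400,
                         transition_matrix = default_transition_matrix(),
                         so_rate = 10,
                         so_downstate_amp = c(mean = 120, sd = 15),
                         spindle_rate = 5,
                         spindle_freq = 12,
                         spindle_amp_sd_multiple = 5,
                         pac_depth = 0,
                         noise_sd = c(WAKE = 6, NREM = 4, REM = 2.5),
                         delta_sd = c(WAKE = 4, NREM = 25, REM = 2),
                         theta_sd = c(WAKE = 3, NREM = 1, REM = 12),
                         sigma_sd = c(WAKE = 2, NREM = 2, REM = 1.5),
                         emg_tone = c(WAKE = 30, NREM = 10, REM = 4),
                         artefact_rate = 0,
                         event_spacing = c("deterministic", "poisson"),
                         n_eeg = 2) {
  event_spacing <- match.arg(event_spacing)
  tm <- as.matrix(transition_matrix)
  if (!all(dim(tm) == c(3, 3)) || any(tm < 0) ||
      any(abs(rowSums(tm) - 1) > 1e-12))
    stop("invalid transition matrix")
  if (!(pac_depth >= 0 && pac_depth <= 1)) stop("pac_depth must be in [0,1]")
  if (so_rate < 0 || spindle_rate < 0) stop("event rates must be >= 0")
  if (duration <= 0) stop("duration must be positive")
  states <- c("WAKE", "NREM", "REM")
  for (v in list(noise_sd, delta_sd, theta_sd, sigma_sd, emg_tone))
    if (!all(states %in% names(v)))
      stop("per-state parameters need WAKE, NREM and REM entries")
  structure(list(seed = as.integer(seed), duration = duration,
                 epoch_length = epoch_length, sample_rate = sample_rate,
                 transition_matrix = tm, so_rate = so_rate,
                 so_downstate_amp = so_downstate_amp,
                 spindle_rate = spindle_rate, spindle_freq = spindle_freq,
                 spindle_amp_sd_multiple = spindle_amp_sd_multiple,
                 pac_depth = pac_depth, noise_sd = noise_sd,
                 delta_sd = delta_sd, theta_sd = theta_sd,
                 sigma_sd = sigma_sd, emg_tone = emg_tone,
                 artefact_rate = artefact_rate,
                 event_spacing = event_spacing, n_eeg = as.integer(n_eeg)),
            class = "synth_config")
}

#' Default epoch-resolution state transition matrix
#'
#' Rows/columns are (WAKE, NREM, REM). REM is entered only from NREM;
#' mean bout lengths are about 40 s (wake), 45 s (NREM) and 27 s (REM),
#' giving a stationary distribution of roughly 43/50/7%.
#'
#' @return 3x3 row-stochastic matrix.
#' @export
default_transition_matrix <- function() {
  m <- matrix(c(0.90, 0.10, 0.00,
                0.07, 0.91, 0.02,
                0.12, 0.03, 0.85),
              nrow = 3, byrow = TRUE)
  dimnames(m) <- list(c("WAKE", "NREM", "REM"), c("WAKE", "NREM", "REM"))
  m
}

#' Generate a ground-truth hypnogram from the state Markov chain
#'
#' Simulates the epoch-resolution chain defined by
#' `config$transition_matrix`, starting in WAKE. Deterministic given
#' `config$seed`. Artefact flags are all `FALSE` unless
#' `config$artefact_rate > 0`.
#'
#' @param config a [synth_config()].
#' @return a [hypnogram()].
#' @export
generate_hypnogram <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n_ep <- round(config$duration / config$epoch_length)
  if (n_ep < 1) stop("duration shorter than one epoch")
  tm <- config$transition_matrix
  states <- c("WAKE", "NREM", "REM")
  cum <- t(apply(tm, 1, cumsum))
  with_seed(substream_seed(config$seed, 1), {
    u <- stats::runif(n_ep)
    s <- integer(n_ep)
    cur <- 1L
    for (i in seq_len(n_ep)) {
      cur <- 1L + sum(u[i] > cum[cur, ])
      s[i] <- cur
    }
    art <- if (config$artefact_rate > 0)
      stats::runif(n_ep) < config$artefact_rate else rep(FALSE, n_ep)
    hypnogram(states[s], art, config$epoch_length)
  })
}

# 1/f-shaped broadband noise, unit SD; spectrum flattened below 0.75 Hz
# so low-frequency power stays bounded.
pink_noise <- function(n, rate) {
  w <- stats::rnorm(n)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * rate / n
  s <- 1 / sqrt(pmax(f, 0.75))
  x <- Re(stats::fft(stats::fft(w) * s, inverse = TRUE) / n)
  x / stats::sd(x)
}

band_noise <- function(n, band, rate, order = 2) {
  bf <- signal::butter(order, band * 2 / rate, type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x / stats::sd(x)
}

# Slow-oscillation template over a support of m samples. The shape is
# built so that zero-crossing segmentation recovers the inserted cycle:
# a small negative lead-in dip (8% of the support) forces a
# negative-to-positive crossing at 8%, the up state (37%) and down
# state (47%) follow, and a small positive tail (8%) forces the closing
# crossing at 92%. The event proper therefore spans 84% of the support.
so_lead_frac <- 0.08
so_tail_frac <- 0.08
so_up_frac <- 0.37

# Gaussian smoothing (sigma in seconds) used to keep the template free
# of slope discontinuities, whose harmonics would otherwise leak
# phase-locked energy into the spindle band. Returns the input length
# plus 2 * pad samples.
gauss_smooth_padded <- function(w, rate, sigma = 0.025) {
  pad <- ceiling(3 * sigma * rate)
  k <- stats::dnorm(seq(-pad, pad), sd = sigma * rate)
  k <- k / sum(k)
  full <- c(numeric(pad), w, numeric(pad))
  out <- stats::convolve(c(numeric(pad), full, numeric(pad)), rev(k),
                         type = "filter")
  attr(out, "pad") <- pad
  out
}

so_waveform <- function(m, a_down, a_up) {
  tt <- seq_len(m) / m
  b1 <- so_lead_frac
  b2 <- so_lead_frac + so_up_frac
  b3 <- 1 - so_tail_frac
  w <- numeric(m)
  s <- tt <= b1
  w[s] <- -0.15 * a_down * sin(pi * tt[s] / b1)
  s <- tt > b1 & tt <= b2
  w[s] <- a_up * sin(pi * (tt[s] - b1) / (b2 - b1))
  s <- tt > b2 & tt <= b3
  w[s] <- -a_down * sin(pi * (tt[s] - b2) / (b3 - b2))
  s <- tt > b3
  w[s] <- 0.15 * a_down * sin(pi * (tt[s] - b3) / (1 - b3))
  w
}

# Spindle burst: sinusoidal carrier under a flat-topped envelope with
# 25-ms raised-cosine ramps at each edge. The steep envelope onset
# keeps the threshold-crossing time of an envelope detector close to
# the true insertion time.
spindle_burst <- function(m, amp, freq, rate, phase) {
  tt <- (seq_len(m) - 1) / rate
  env <- rep(1, m)
  ramp <- max(2L, min(round(0.01 * rate), m %/% 3))
  up <- seq_len(ramp)
  env[up] <- 0.5 * (1 - cos(pi * (up - 1) / ramp))
  env[m - ramp + up] <- rev(env[up])
  amp * env * sin(2 * pi * freq * tt + phase)
}

# Event centres in concatenated-NREM sample space. Deterministic mode
# is rate-exact (one event per spacing slot) with uniform jitter inside
# the slot, which keeps counts exact while decorrelating the relative
# timing of the two event families. Poisson mode draws positions
# uniformly.
event_centres <- function(n_events, total, spacing, phase_frac) {
  if (n_events == 0) return(integer(0))
  if (spacing == "deterministic") {
    jit <- stats::runif(n_events, -0.35, 0.35)
    round((seq_len(n_events) - phase_frac + jit) / n_events * total)
  } else {
    sort(sample.int(total, n_events))
  }
}

#' Synthesise an EEG/EMG recording with ground-truth events
#'
#' Builds state-coloured background EEG (delta-weighted in NREM, a
#' 7-8 Hz theta component in REM, broadband in wake, all over a 1/f
#' floor), inserts biphasic slow-oscillation waveforms and Hann-ramped
#' spindle bursts into artefact-free NREM, optionally modulates the
#' spindle-band amplitude by the phase of the slow component
#' (`pac_depth`), and adds a white-noise EMG channel whose RMS follows
#' the state. Every inserted event is returned in the ground truth.
#'
#' With `event_spacing = "deterministic"` (default) exactly
#' `floor(rate x NREM minutes)` events of each type are scheduled at
#' even spacing through NREM; events that cannot be placed without
#' overlapping a run boundary or a same-type event are dropped from both
#' signal and ground truth (rare at default rates).
#'
#' @param hyp a [hypnogram()] (e.g. from [generate_hypnogram()]).
#' @param config a [synth_config()].
#' @return list with elements `recording` (a [recording()] with channels
#'   `EEG1` = parietal, optionally `EEG2` = frontal, and `EMG`) and
#'   `ground_truth` (class `ground_truth`: `$hypnogram`, `$so_events`,
#'   `$spindle_events`, `$pac_depth`).
#' @export
synthesize_recording <- function(hyp, config) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(config, "synth_config"))
  if (length(hyp) == 0) stop("empty hypnogram")
  rate <- config$sample_rate
  spe <- round(hyp$epoch_length * rate)
  n <- length(hyp) * spe
  state <- rep(hyp$labels, each = spe)

  # refuse rate combinations whose events would tile > 50% of NREM
  if ((config$so_rate * 1.2 + config$spindle_rate * 1.0) / 60 > 0.5)
    stop("event collision")

  runs <- state_sample_runs(hyp, rate, "NREM", artefact_free = TRUE)
  run_len <- if (nrow(runs)) runs$end_sample - runs$start_sample + 1L else integer(0)
  total_nrem <- sum(run_len)
  nrem_min <- total_nrem / rate / 60

  with_seed(substream_seed(config$seed, 2), {
    ## ---- event schedule (shared across EEG channels) ----
    guard <- round(0.1 * rate)
    place_events <- function(n_ev, dur_range, phase_frac) {
      if (n_ev == 0 || total_nrem == 0)
        return(data.frame(start = integer(0), end = integer(0),
                          dur = numeric(0)))
      centres <- event_centres(n_ev, total_nrem, config$event_spacing,
                               phase_frac)
      durs <- stats::runif(n_ev, dur_range[1], dur_range[2])
      cum <- cumsum(run_len)
      out_start <- integer(0); out_end <- integer(0); out_dur <- numeric(0)
      last_end <- rep(0L, nrow(runs))
      for (k in seq_len(n_ev)) {
        p <- min(max(centres[k], 1L), total_nrem)
        r <- findInterval(p - 1L, c(0L, cum))  # run index
        off <- p - c(0L, cum)[r]
        rs <- runs$start_sample[r]; re <- runs$end_sample[r]
        m <- round(durs[k] * rate)
        avail <- re - rs + 1L - 2L * guard
        if (avail < round(0.4 * rate)) next
        if (m > avail) m <- avail
        half <- m %/% 2L
        c0 <- rs + off - 1L
        st <- min(max(c0 - half, rs + guard), re - guard - m + 1L)
        if (st <= last_end[r]) st <- last_end[r] + 1L
        en <- st + m - 1L
        if (en > re - guard) next
        last_end[r] <- en
        out_start <- c(out_start, st); out_end <- c(out_end, en)
        out_dur <- c(out_dur, m / rate)
      }
      data.frame(start = out_start, end = out_end, dur = out_dur)
    }

    n_so <- if (config$event_spacing == "deterministic")
      floor(config$so_rate * nrem_min)
    else stats::rpois(1, config$so_rate * nrem_min)
    n_sp <- if (config$event_spacing == "deterministic")
      floor(config$spindle_rate * nrem_min)
    else stats::rpois(1, config$spindle_rate * nrem_min)

    # SO support is drawn longer than the event proper (the lead-in and
    # tail of the template consume 16% of the support)
    so_tab <- place_events(n_so, c(0.6, 2.1), 0.5)
    sp_tab <- place_events(n_sp, c(0.5, 1.5), 0.63)

    a_down <- pmax(stats::rnorm(nrow(so_tab), config$so_downstate_amp["mean"],
                                config$so_downstate_amp["sd"]), 40)
    a_up <- 0.7 * a_down
    sp_phase <- stats::runif(nrow(sp_tab), 0, 2 * pi)

    so_signal <- numeric(n)
    delta_atten <- rep(1, n)  # delta background is damped under each SO
    for (k in seq_len(nrow(so_tab))) {
      idx <- so_tab$start[k]:so_tab$end[k]
      m <- length(idx)
      sm <- gauss_smooth_padded(so_waveform(m, a_down[k], a_up[k]), rate)
      pad <- attr(sm, "pad")
      ext <- max(1L, so_tab$start[k] - pad):min(n, so_tab$end[k] + pad)
      so_signal[ext] <- so_signal[ext] +
        sm[seq_along(ext) + (ext[1] - (so_tab$start[k] - pad))]
      ramp <- max(2L, min(round(0.05 * rate), m %/% 3))
      tap <- rep(1, m)
      tap[seq_len(ramp)] <- 0.5 * (1 - cos(pi * (seq_len(ramp) - 1) / ramp))
      tap[m - ramp + seq_len(ramp)] <- rev(tap[seq_len(ramp)])
      delta_atten[idx] <- pmin(delta_atten[idx], 1 - 0.7 * tap)
    }

    nrem_mask <- logical(n)
    for (r in seq_len(nrow(runs)))
      nrem_mask[runs$start_sample[r]:runs$end_sample[r]] <- TRUE

    ## ---- channels ----
    g <- function(v) unname(v[state])
    channels <- list()
    sigma_ref <- NA_real_
    spindle_signal <- NULL
    for (ch in seq_len(config$n_eeg)) {
      base <- pink_noise(n, rate) * g(config$noise_sd) +
        band_noise(n, c(0.5, 4), rate) * g(config$delta_sd) * delta_atten +
        band_noise(n, c(6.5, 8.5), rate) * g(config$theta_sd)
      sigma_bg <- band_noise(n, c(10, 16), rate) * g(config$sigma_sd)
      if (ch == 1) {
        # burst amplitude is anchored to the sigma-band background SD of
        # the first channel, measured in NREM before insertion
        in_band <- bandpass_phase_neutral(base + sigma_bg, c(10, 16), rate)
        sigma_ref <- stats::sd(in_band[nrem_mask])
        amp <- config$spindle_amp_sd_multiple * sigma_ref
        spindle_signal <- numeric(n)
        for (k in seq_len(nrow(sp_tab))) {
          idx <- sp_tab$start[k]:sp_tab$end[k]
          spindle_signal[idx] <- spindle_signal[idx] +
            spindle_burst(length(idx), amp, config$spindle_freq, rate,
                          sp_phase[k])
        }
      }
      sigma_total <- sigma_bg + spindle_signal
      if (config$pac_depth > 0 && any(nrem_mask)) {
        # modulating phase comes from the composed slow signal
        # (delta background + inserted slow oscillations), not raw noise
        slow_total <- so_signal +
          bandpass_phase_neutral(base, c(0.4, 4.5), rate)
        phi <- hilbert_phase(bandpass_phase_neutral(slow_total,
                                                    c(0.4, 4.5), rate))
        mod <- 1 + config$pac_depth * cos(phi)
        sigma_total[nrem_mask] <- sigma_total[nrem_mask] * mod[nrem_mask]
      }
      eeg <- base + sigma_total + so_signal
      if (any(hyp$artefact)) {
        art_ep <- which(hyp$artefact)
        for (e in art_ep) {
          idx <- ((e - 1L) * spe + 1L):(e * spe)
          eeg[idx] <- eeg[idx] +
            1500 * sign(sin(2 * pi * (seq_along(idx)) / rate))
        }
      }
      channels[[paste0("EEG", ch)]] <- eeg
    }
    channels$EMG <- stats::rnorm(n) * g(config$emg_tone)

    roles <- c(EEG1 = "EEG_parietal", EMG = "EMG")
    if (config$n_eeg >= 2) roles <- c(roles, EEG2 = "EEG_frontal")

    rec <- recording(channels, rate, channel_roles = roles)
    gt <- structure(list(
      hypnogram = hyp,
      so_events = data.frame(
        start = (so_tab$start - 1) / rate + so_lead_frac * so_tab$dur,
        end = (so_tab$start - 1) / rate + (1 - so_tail_frac) * so_tab$dur,
        downstate_amp = -a_down,
        p2p_amp = a_down + a_up),
      spindle_events = data.frame(
        onset = (sp_tab$start - 1) / rate,
        duration = sp_tab$dur),
      pac_depth = config$pac_depth,
      sigma_ref_sd = sigma_ref),
      class = "ground_truth")
    list(recording = rec, ground_truth = gt)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", nrow(x$so_events), " slow oscillations, ",
      nrow(x$spindle_events), " spindles, pac_depth=", x$pac_depth,
      "\n", sep = "")
  invisible(x)
}
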