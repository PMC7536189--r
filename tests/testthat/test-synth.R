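test_that("an absorbing transition matrix keeps the chain in WAKE", {
  tm <- diag(3)
  dimnames(tm) <- list(c("WAKE", "NREM", "REM"), c("WAKE", "NREM", "REM"))
  cfg <- synth_config(seed = 1, duration = 40, transition_matrix = tm)
  h <- generate_hypnogram(cfg)
  expect_equal(h$labels, rep("WAKE", 10))
})

test_that("hypnogram generation is deterministic in the seed", {
  cfg <- synth_config(seed = 77, duration = 4000)
  expect_identical(generate_hypnogram(cfg)$labels,
                   generate_hypnogram(cfg)$labels)
  cfg2 <- synth_config(seed = 78, duration = 4000)
  expect_false(identical(generate_hypnogram(cfg)$labels,
                         generate_hypnogram(cfg2)$labels))
})

test_that("empirical state frequencies match the analytic stationary law", {
  # eigen-decomposition oracle for the stationary distribution
  tm <- default_transition_matrix()
  ev <- eigen(t(tm))
  stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  stat <- stat / sum(stat)
  cfg <- synth_config(seed = 5, duration = 50000 * 4)
  h <- generate_hypnogram(cfg)
  freq <- table(factor(h$labels, c("WAKE", "NREM", "REM"))) / length(h)
  se <- sqrt(stat * (1 - stat) / length(h))
  # epochs are autocorrelated (bouts ~10 epochs): allow 3 SE of an
  # effective sample size reduced by the mean bout length
  neff_scale <- sqrt(10)
  for (i in 1:3)
    expect_lt(abs(freq[i] - stat[i]), 3 * se[i] * neff_scale)
})

test_that("non-stochastic matrices are rejected", {
  tm <- matrix(0.5, 3, 3)
  expect_error(synth_config(transition_matrix = tm),
               "invalid transition matrix")
})

test_that("zero event rates give empty ground truth", {
  cfg <- synth_config(seed = 2, duration = 240, so_rate = 0,
                      spindle_rate = 0, n_eeg = 1)
  sim <- synthesize_recording(all_nrem_hypnogram(240), cfg)
  expect_equal(nrow(sim$ground_truth$so_events), 0)
  expect_equal(nrow(sim$ground_truth$spindle_events), 0)
})

test_that("deterministic spacing yields rate-exact event counts", {
  cfg <- synth_config(seed = 3, duration = 600, spindle_rate = 10,
                      so_rate = 0, n_eeg = 1)
  sim <- synthesize_recording(all_nrem_hypnogram(600), cfg)
  expect_equal(nrow(sim$ground_truth$spindle_events), 100)  # 10/min x 10 min
})

test_that("excessive event rates raise an event collision error", {
  cfg <- synth_config(seed = 1, duration = 240, so_rate = 20,
                      spindle_rate = 20, n_eeg = 1)
  expect_error(synthesize_recording(all_nrem_hypnogram(240), cfg),
               "event collision")
})

test_that("all ground-truth events lie inside NREM epochs", {
  cfg <- synth_config(seed = 9, duration = 1200, n_eeg = 1)
  h <- generate_hypnogram(cfg)
  sim <- synthesize_recording(h, cfg)
  gt <- sim$ground_truth
  in_nrem <- function(t0, t1) {
    e0 <- floor(t0 / h$epoch_length) + 1
    e1 <- ceiling(t1 / h$epoch_length)
    all(h$labels[e0:e1] == "NREM")
  }
  so <- gt$so_events
  expect_true(all(mapply(in_nrem, so$start, so$end)))
  sp <- gt$spindle_events
  expect_true(all(mapply(in_nrem, sp$onset, sp$onset + sp$duration)))
})

test_that("synthetic state spectra peak in the defining bands", {
  cfg <- synth_config(seed = 12, duration = 1600, n_eeg = 1)
  h <- generate_hypnogram(cfg)
  sim <- synthesize_recording(h, cfg)
  p_n <- state_psd(sim$recording, h, "NREM")
  f_n <- p_n$freq[which.max(p_n$psd)]
  expect_true(f_n >= 0.5 && f_n <= 4)
  p_r <- state_psd(sim$recording, h, "REM")
  f_r <- p_r$freq[which.max(p_r$psd)]
  expect_true(f_r >= 6 && f_r <= 9)
})

test_that("without coupling the spindle envelope is independent of slow phase", {
  cfg <- synth_config(seed = 4, duration = 3600, pac_depth = 0, n_eeg = 1)
  h <- all_nrem_hypnogram(3600)
  sim <- synthesize_recording(h, cfg)
  eeg <- get_channel(sim$recording, "EEG_parietal")
  phi <- somnotools:::hilbert_phase(
    bandpass_phase_neutral(eeg, c(0.4, 4.5), 400))
  amp <- somnotools:::hilbert_envelope(
    bandpass_phase_neutral(eeg, c(10, 16), 400))
  # circular-linear correlation
  r <- sqrt(stats::cor(amp, cos(phi))^2 + stats::cor(amp, sin(phi))^2)
  expect_lt(r, 0.05)
})

test_that("realized phase modulation grows with the coupling depth", {
  mi_at <- function(m) {
    cfg <- synth_config(seed = 21, duration = 1200, pac_depth = m,
                        n_eeg = 1)
    sim <- synthesize_recording(all_nrem_hypnogram(1200), cfg)
    compute_modulation_index(get_channel(sim$recording, "EEG_parietal"),
                             all_nrem_hypnogram(1200), 400)$mi
  }
  m1 <- mi_at(0.2); m2 <- mi_at(0.6)
  expect_gt(m2, m1)
})

test_that("trajectory generation is deterministic and archetype-true", {
  t1 <- generate_trajectory("thigmotaxis", seed = 8)
  t2 <- generate_trajectory("thigmotaxis", seed = 8)
  expect_identical(t1$x, t2$x)
  r <- sqrt(t1$x^2 + t1$y^2)
  expect_gte(mean(r > 0.85 * 100), 0.8)
  expect_error(generate_trajectory("swimming_backwards"), "unknown strategy")
})
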