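test_that("percentile composition keeps floor(floor(0.35 n) x 0.45) candidates", {
  rate <- 50
  for (n in c(20, 100)) {
    x <- ramped_cycle_signal(n, rate)
    hyp <- hypnogram(rep("NREM", floor(length(x) / (4 * rate))))
    det <- detect_slow_oscillations(x[seq_len(length(hyp) * 4 * rate)],
                                    hyp, rate)
    expect_equal(nrow(det), floor(floor(0.35 * n) * 0.45))
  }
})

test_that("ramped-amplitude cycles select exactly the largest cycles", {
  rate <- 50
  n <- 40
  x <- ramped_cycle_signal(n, rate)
  hyp <- hypnogram(rep("NREM", floor(length(x) / (4 * rate))))
  det <- detect_slow_oscillations(x[seq_len(length(hyp) * 4 * rate)],
                                  hyp, rate)
  # cycles are 1 s long in ascending amplitude; the selected segments
  # must start at the last floor(floor(.35n)*.45) full cycles (segment
  # starting at t = j covers cycle j + 1)
  k <- floor(floor(0.35 * n) * 0.45)
  sel_starts <- sort(round(det$start))
  expect_equal(sel_starts, seq(n - k, n - 1))
})

test_that("detector equals the brute-force sort oracle on random signals", {
  rate <- 100
  for (seed in 1:15) {
    eeg <- random_slow_signal(seed, 1e4, rate)
    hyp <- hypnogram(rep("NREM", 25))
    det <- detect_slow_oscillations(eeg, hyp, rate)
    orc <- so_brute_force(eeg, rate)
    expect_equal(round(det$start * rate), orc$s - 1)
    expect_equal(round(det$end * rate), orc$e - 1)
    expect_equal(det$downstate_amp, orc$dn, tolerance = 1e-12)
  }
})

test_that("implanted slow oscillations are recovered inside NREM", {
  cfg <- synth_config(seed = 7, duration = 1800, n_eeg = 1)
  hyp <- all_nrem_hypnogram(1800)
  sim <- synthesize_recording(hyp, cfg)
  gt <- sim$ground_truth$so_events
  eeg <- get_channel(sim$recording, "EEG_parietal")
  so <- detect_slow_oscillations(eeg, hyp, 400)
  m <- match_events(so$start, so$end, gt$start, gt$end)
  expect_gte(m$recall, 0.9)
  expect_gte(m$precision, 0.8)
  expect_true(all(so$duration >= 0.4 & so$duration <= 2.0))
  expect_true(all(so$downstate_amp < 0))
  expect_true(all(so$p2p_amp > abs(so$downstate_amp)))
})

test_that("events are confined to artefact-free NREM", {
  cfg <- synth_config(seed = 13, duration = 1600, n_eeg = 1,
                      artefact_rate = 0.1)
  h <- generate_hypnogram(cfg)
  sim <- synthesize_recording(h, cfg)
  eeg <- get_channel(sim$recording, "EEG_parietal")
  ok_epoch <- function(t0, t1) {
    e0 <- floor(t0 / 4) + 1
    e1 <- min(ceiling(t1 / 4), length(h))
    all(h$labels[e0:e1] == "NREM" & !h$artefact[e0:e1])
  }
  so <- detect_slow_oscillations(eeg, h, 400)
  expect_true(all(mapply(ok_epoch, so$start, so$end)))
  sp <- detect_spindles(eeg, h, 400)
  expect_true(all(mapply(ok_epoch, sp$onset, sp$onset + sp$duration)))
})

test_that("amplitude doubling leaves both detectors' event sets unchanged", {
  cfg <- synth_config(seed = 17, duration = 1200, n_eeg = 1)
  hyp <- all_nrem_hypnogram(1200)
  sim <- synthesize_recording(hyp, cfg)
  eeg <- get_channel(sim$recording, "EEG_parietal")
  so1 <- detect_slow_oscillations(eeg, hyp, 400)
  so2 <- detect_slow_oscillations(2 * eeg, hyp, 400)
  expect_equal(so1$start, so2$start)
  expect_equal(so2$downstate_amp, 2 * so1$downstate_amp, tolerance = 1e-9)
  sp1 <- detect_spindles(eeg, hyp, 400)
  sp2 <- detect_spindles(2 * eeg, hyp, 400)
  expect_equal(sp1$onset, sp2$onset)
  expect_equal(sp1$duration, sp2$duration)
})

test_that("no-NREM hypnograms yield empty results with a warning", {
  eeg <- rnorm(4 * 400 * 5)
  h <- hypnogram(rep("W", 5))
  expect_warning(so <- detect_slow_oscillations(eeg, h, 400), "no NREM")
  expect_equal(nrow(so), 0)
  expect_warning(sp <- detect_spindles(eeg, h, 400), "no NREM")
  expect_equal(nrow(sp), 0)
  expect_error(detect_spindles(rnorm(10), hypnogram(rep("N", 5)), 400),
               "rate mismatch")
})

test_that("spindle bursts are recovered with accurate onsets", {
  cfg <- synth_config(seed = 11, duration = 1800, n_eeg = 1)
  hyp <- all_nrem_hypnogram(1800)
  sim <- synthesize_recording(hyp, cfg)
  gt <- sim$ground_truth$spindle_events
  eeg <- get_channel(sim$recording, "EEG_parietal")
  sp <- detect_spindles(eeg, hyp, 400)
  m <- match_events(sp$onset, sp$onset + sp$duration,
                    gt$onset, gt$onset + gt$duration)
  expect_gte(m$recall, 0.9)
  expect_gte(m$precision, 0.8)
  err <- vapply(gt$onset, function(o) {
    d <- abs(sp$onset - o)
    if (any(d < 0.5)) min(d) else NA_real_
  }, numeric(1))
  expect_lte(stats::median(err, na.rm = TRUE), 0.05)
})

test_that("too-short and too-long oscillatory bursts never become spindles", {
  rate <- 400
  n <- 600 * rate
  set.seed(31)
  bg <- somnotools:::band_noise(n, c(10, 16), rate) * 2 +
    somnotools:::pink_noise(n, rate) * 4
  sig <- sd(bandpass_phase_neutral(bg, c(10, 16), rate))
  add_burst <- function(x, t0, d) {
    idx <- round(t0 * rate):(round(t0 * rate) + round(d * rate) - 1)
    x[idx] <- x[idx] +
      somnotools:::spindle_burst(length(idx), 5 * sig, 12, rate, 0.7)
    x
  }
  x <- add_burst(add_burst(bg, 100, 0.3), 300, 3.0)
  sp <- detect_spindles(x, all_nrem_hypnogram(600), rate)
  overlaps <- function(t0, d) any(sp$onset < t0 + d & sp$onset + sp$duration > t0)
  expect_false(overlaps(100, 0.3))
  expect_false(overlaps(300, 3.0))
})

test_that("event summaries divide counts by NREM minutes", {
  macro <- macro_metrics(hypnogram(rep("N", 900)))  # 60 min NREM
  so <- data.frame(start = numeric(0))
  sp <- data.frame(onset = seq_len(300))
  s <- summarize_events(so, sp, macro)
  expect_equal(s$spindle_density, 5)
  expect_equal(s$so_density, 0)

  empty <- summarize_events(data.frame(), data.frame(), macro)
  expect_equal(empty$spindle_count, 0)
  expect_equal(empty$spindle_density, 0)

  macro0 <- macro_metrics(hypnogram(rep("W", 10)))
  expect_error(summarize_events(sp, sp, macro0), "inconsistent")
})
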