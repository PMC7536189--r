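test_that("modulation index matches the closed-form binning oracle", {
  rate <- 400
  tt <- seq(0, 600 - 1 / rate, by = 1 / rate)
  slow <- 40 * cos(2 * pi * 1 * tt)
  fast <- (1 + 0.5 * cos(2 * pi * 1 * tt)) * 5 * sin(2 * pi * 15 * tt)
  res <- compute_modulation_index(slow + fast, all_nrem_hypnogram(600), rate)
  oracle <- mi_cosine_oracle(0.5)
  expect_lt(abs(res$mi - oracle) / oracle, 0.02)
  # preferred phase at the envelope maximum (phase 0)
  expect_lt(abs(res$preferred_phase), pi / 6)
  expect_equal(sum(res$normalized_profile), 1, tolerance = 1e-9)
  expect_equal(length(res$bin_profile), 12)
})

test_that("MI limits: single-bin profile gives 1, flat profile gives 0", {
  expect_equal(mi_from_profile(c(rep(0, 11), 2.4))$mi, 1)
  expect_equal(mi_from_profile(rep(3.3, 12))$mi, 0)
  expect_error(mi_from_profile(c(-1, rep(1, 11))), "non-negative")
})

test_that("uncoupled synthetic NREM has near-zero MI", {
  cfg <- synth_config(seed = 19, duration = 1800, pac_depth = 0, n_eeg = 1)
  hyp <- all_nrem_hypnogram(1800)
  sim <- synthesize_recording(hyp, cfg)
  mi <- compute_modulation_index(get_channel(sim$recording, "EEG_parietal"),
                                 hyp, 400)$mi
  expect_lt(mi, 0.01)
})

test_that("MI is exactly invariant to positive rescaling", {
  rate <- 400
  tt <- seq(0, 120 - 1 / rate, by = 1 / rate)
  x <- 30 * cos(2 * pi * 1.3 * tt) +
    (1 + 0.4 * cos(2 * pi * 1.3 * tt)) * 4 * sin(2 * pi * 14 * tt)
  # invariance up to floating-point bin hops at the phase-bin edges
  h <- all_nrem_hypnogram(120)
  expect_equal(compute_modulation_index(x, h, rate)$mi,
               compute_modulation_index(7.3 * x, h, rate)$mi,
               tolerance = 1e-3)
})

test_that("phase-shuffled surrogates collapse the MI", {
  cfg <- synth_config(seed = 6, duration = 1800, pac_depth = 0.5, n_eeg = 1)
  hyp <- all_nrem_hypnogram(1800)
  sim <- synthesize_recording(hyp, cfg)
  eeg <- get_channel(sim$recording, "EEG_parietal")
  mi <- compute_modulation_index(eeg, hyp, 400)$mi
  mi_surr <- compute_modulation_index(eeg, hyp, 400,
                                      surrogate_shift_s = 30)$mi
  expect_lt(mi_surr, 0.2 * mi)
})

test_that("insufficient NREM raises an error rather than a number", {
  x <- rnorm(400 * 40)
  expect_error(compute_modulation_index(x, hypnogram(rep("N", 10)), 400),
               "insufficient data")
  expect_error(compute_modulation_index(x, hypnogram(rep("W", 10)), 400),
               "insufficient data")
})

test_that("per-day MI splits blocks and flags missing ones", {
  rate <- 400
  tt <- seq(0, 480 - 1 / rate, by = 1 / rate)
  x <- 30 * cos(2 * pi * 1 * tt) +
    (1 + 0.4 * cos(2 * pi * 1 * tt)) * 4 * sin(2 * pi * 14 * tt)
  h <- all_nrem_hypnogram(480)
  res <- mi_by_day(x, h, rate, c(0, 240, 480))
  expect_length(res, 2)
  expect_lt(abs(res$block1$mi - res$block2$mi), 0.1 * res$block1$mi)

  # second block all wake -> missing flag
  h2 <- hypnogram(c(rep("N", 60), rep("W", 60)))
  res2 <- mi_by_day(x, h2, rate, c(0, 240, 480))
  expect_false(is.null(res2$block2$missing))
  expect_true(res2$block2$missing)
  expect_s3_class(res2$block1, "pac_result")

  # coupled block scores higher than uncoupled block
  cfgA <- synth_config(seed = 23, duration = 600, pac_depth = 0, n_eeg = 1)
  cfgB <- synth_config(seed = 23, duration = 600, pac_depth = 0.6, n_eeg = 1)
  hA <- all_nrem_hypnogram(600)
  xa <- get_channel(synthesize_recording(hA, cfgA)$recording, "EEG_parietal")
  xb <- get_channel(synthesize_recording(hA, cfgB)$recording, "EEG_parietal")
  res3 <- mi_by_day(c(xa, xb), all_nrem_hypnogram(1200), 400, c(0, 600, 1200))
  expect_gt(res3$block2$mi, res3$block1$mi)
})
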