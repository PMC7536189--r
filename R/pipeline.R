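#' Configuration of the end-to-end simulated-cohort pipeline
#'
#' Defines a two-group experiment (a control group and a group with a
#' fragmented-sleep, low-spindle phenotype) with one baseline and one
#' learning recording block per animal plus a multi-day water-maze
#' protocol. Block lengths are scaled down from full 24-h days so the
#' whole pipeline runs in minutes; every random draw derives from
#' `seed`.
#'
#' @param seed master seed.
#' @param n_per_group animals per group (default 3).
#' @param block_minutes duration of each recording block in minutes
#'   (default 20).
#' @param mwm_days water-maze training days (default 2).
#' @param trials_per_day trials per day (default 6).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_per_group = 3, block_minutes = 20,
                            mwm_days = 2, trials_per_day = 6) {
  stopifnot(n_per_group >= 2, block_minutes >= 10, mwm_days >= 1,
            trials_per_day >= 1)
  structure(list(seed = as.integer(seed), n_per_group = n_per_group,
                 block_minutes = block_minutes, mwm_days = mwm_days,
                 trials_per_day = trials_per_day),
            class = "pipeline_config")
}

# Group/condition generator settings: the deficient group sleeps less,
# fragments more and spindles less; learning increases NREM pressure in
# both groups, more so in controls.
pipeline_synth_config <- function(group, condition, seed, minutes) {
  frag <- group == "KO"
  learn <- condition == "learning"
  tm <- matrix(c(0.90, 0.10, 0.00,
                 0.07, 0.91, 0.02,
                 0.12, 0.03, 0.85), nrow = 3, byrow = TRUE)
  if (frag) {                      # more wake, more brief awakenings
    tm[1, ] <- c(0.92, 0.08, 0.00)
    tm[2, ] <- c(0.12, 0.86, 0.02)
  }
  if (learn) {                     # NREM pressure after training
    tm[2, 1] <- tm[2, 1] * 0.7
    tm[2, 2] <- 1 - tm[2, 1] - tm[2, 3]
  }
  synth_config(seed = seed, duration = minutes * 60, n_eeg = 1,
               transition_matrix = tm,
               spindle_rate = if (frag) 4 else 5 + (if (learn) 1 else 0),
               so_rate = 10,
               pac_depth = if (frag) 0.15 else 0.4)
}

mwm_strategy_mix <- function(group, day) {
  undirected <- c("thigmotaxis", "random_search", "scanning", "chaining")
  levels_up <- c("directed_search", "focal_search", "direct_swimming")
  # progression toward spatial strategies; slower in the deficient group
  p_spatial <- min(0.9, 0.15 + (day - 1) * (if (group == "KO") 0.2 else 0.4))
  list(undirected = undirected, spatial = levels_up, p_spatial = p_spatial)
}

#' Run the full simulated-cohort pipeline
#'
#' Chains every analysis stage on synthetic data: simulate recordings
#' per animal and condition, score them with the rule-based stager,
#' compute macrostructure, detect slow oscillations and spindles,
#' compute the coupling modulation index, simulate and score water-maze
#' trials, and build the group/condition report. All outputs are
#' written as CSV files into `out_dir`; identical configurations
#' produce byte-identical files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with `sleep_metrics`, `mwm_trials`,
#'   `events`, `strategy_by_day` and `report`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  groups <- c("WT", "KO")
  conditions <- c("baseline", "learning")
  sleep_rows <- list(); event_rows <- list()
  idx <- 0L
  for (g in groups) for (a in seq_len(config$n_per_group)) {
    animal <- sprintf("%s_%02d", g, a)
    ki67 <- with_seed(substream_seed(config$seed, 900 + idx), {
      if (g == "WT") max(500, stats::rnorm(1, 3600, 950))
      else max(20, stats::rnorm(1, 170, 60))
    })
    for (cc in conditions) {
      idx <- idx + 1L
      cfg <- pipeline_synth_config(g, cc,
                                   substream_seed(config$seed, idx),
                                   config$block_minutes)
      hyp <- generate_hypnogram(cfg)
      sim <- synthesize_recording(hyp, cfg)
      rec <- sim$recording
      scored <- score_epochs(rec)
      eeg <- get_channel(rec, "EEG_parietal")
      macro <- macro_metrics(scored)
      so <- detect_slow_oscillations(eeg, scored, rec$sample_rate)
      sp <- detect_spindles(eeg, scored, rec$sample_rate)
      ev <- summarize_events(so, sp, macro)
      mi <- tryCatch(
        compute_modulation_index(eeg, scored, rec$sample_rate)$mi,
        error = function(e) NA_real_)
      sleep_rows[[idx]] <- data.frame(
        animal = animal, group = g, condition = cc,
        tst = macro$tst, nrem_minutes = macro$nrem_minutes,
        rem_minutes = macro$rem_minutes,
        nrem_rem_ratio = macro$nrem_rem_ratio,
        arousal_index = macro$arousal_index,
        so_count = ev$so_count, spindle_count = ev$spindle_count,
        so_density = ev$so_density, spindle_density = ev$spindle_density,
        mi = mi, ki67 = ki67, stringsAsFactors = FALSE)
      if (nrow(so) > 0)
        event_rows[[length(event_rows) + 1L]] <- data.frame(
          animal = animal, condition = cc, type = "slow_oscillation",
          start_s = so$start, duration_s = so$duration,
          amp1 = so$downstate_amp, amp2 = so$p2p_amp,
          stringsAsFactors = FALSE)
      if (nrow(sp) > 0)
        event_rows[[length(event_rows) + 1L]] <- data.frame(
          animal = animal, condition = cc, type = "spindle",
          start_s = sp$onset, duration_s = sp$duration,
          amp1 = sp$peak_envelope, amp2 = NA_real_,
          stringsAsFactors = FALSE)
    }
  }
  sleep_metrics <- do.call(rbind, sleep_rows)
  events <- do.call(rbind, event_rows)

  ## water maze
  trial_rows <- list(); t_idx <- 0L
  for (g in groups) for (a in seq_len(config$n_per_group)) {
    animal <- sprintf("%s_%02d", g, a)
    for (d in seq_len(config$mwm_days)) for (tr in
                                             seq_len(config$trials_per_day)) {
      t_idx <- t_idx + 1L
      mix <- mwm_strategy_mix(g, d)
      pick <- with_seed(substream_seed(config$seed, 5000 + t_idx), {
        if (stats::runif(1) < mix$p_spatial)
          sample(mix$spatial, 1, prob = c(0.4, 0.35, 0.25))
        else sample(mix$undirected, 1)
      })
      trj <- generate_trajectory(pick, seed = substream_seed(config$seed,
                                                             6000 + t_idx))
      tm <- trial_metrics(trj)
      trial_rows[[t_idx]] <- data.frame(
        animal = animal, group = g, day = d, trial = tr,
        archetype = pick, strategy = tm$strategy,
        strategy_score = tm$strategy_score,
        route_efficiency = tm$route_efficiency,
        time_to_target = tm$time_to_target, censored = tm$censored,
        path_length = tm$path_length, mean_speed = tm$mean_speed,
        quadrant_target = tm$quadrant_time[["target"]],
        stringsAsFactors = FALSE)
    }
  }
  mwm_trials <- do.call(rbind, trial_rows)
  strategy_by_day <- do.call(rbind, lapply(split(
    mwm_trials, list(mwm_trials$group, mwm_trials$animal), drop = TRUE),
    function(s) data.frame(animal = s$animal[1], group = s$group[1],
                           strategy_ranking(s$strategy_score, s$day),
                           stringsAsFactors = FALSE)))
  strategy_by_day <- strategy_by_day[order(strategy_by_day$animal,
                                           strategy_by_day$day), ]
  rownames(strategy_by_day) <- NULL

  ## merge mean late-day route efficiency into learning rows for the
  ## sleep/performance correlation panels
  late <- mwm_trials[mwm_trials$day >= min(2, config$mwm_days), ]
  re_mean <- stats::aggregate(list(route_efficiency = late$route_efficiency),
                              by = list(animal = late$animal), FUN = mean)
  sleep_metrics <- merge(sleep_metrics, re_mean, by = "animal",
                         all.x = TRUE, sort = FALSE)
  sleep_metrics$route_efficiency[sleep_metrics$condition == "baseline"] <-
    NA_real_
  sleep_metrics <- sleep_metrics[order(sleep_metrics$group,
                                       sleep_metrics$animal,
                                       sleep_metrics$condition), ]
  rownames(sleep_metrics) <- NULL

  report <- build_report(sleep_metrics)

  wr <- function(tab, name)
    utils::write.csv(tab, file.path(out_dir, name), row.names = FALSE)
  wr(sleep_metrics, "sleep_metrics.csv")
  wr(events, "events.csv")
  wr(mwm_trials, "mwm_trials.csv")
  wr(strategy_by_day, "strategy_by_day.csv")
  wr(report$group_tests, "report_group_tests.csv")
  wr(report$learning_tests, "report_learning_tests.csv")
  wr(report$correlations, "report_correlations.csv")

  invisible(list(sleep_metrics = sleep_metrics, mwm_trials = mwm_trials,
                 events = events, strategy_by_day = strategy_by_day,
                 report = report))
}
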