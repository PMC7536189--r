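#' Sleep macrostructure metrics
#'
#' Computes the standard description of sleep architecture from a
#' hypnogram: total sleep time (TST = NREM + REM), per-state durations,
#' the NREM:REM ratio, episode counts and mean episode durations, and
#' the arousal index.
#'
#' An *arousal* is a maximal run of 1 to `arousal_max_epochs` WAKE
#' epochs immediately flanked by sleep on both sides; the arousal index
#' is arousals per minute of TST (undefined when TST is zero). A *sleep
#' episode* is a maximal stretch of sleep that may contain embedded
#' arousals and holds at least `episode_min_epochs` sleep epochs; NREM
#' and REM episodes are maximal same-label runs. Durations are epoch
#' counts times the epoch length; sleep-episode duration spans from the
#' first to the last sleep epoch of the episode, embedded arousals
#' included.
#'
#' @param hyp a [hypnogram()].
#' @param arousal_max_epochs longest wake run still counted as an
#'   arousal, in epochs (default 4, i.e. 16 s at 4-s epochs).
#' @param episode_min_epochs minimum sleep epochs per sleep episode
#'   (default 3).
#' @return object of class `sleep_macro` (a list; see Details).
#' @examples
#' h <- hypnogram(c("W","N","N","N","R","R","N","N","W","W"))
#' macro_metrics(h)$nrem_rem_ratio  # 2.5
#' @export
macro_metrics <- function(hyp, arousal_max_epochs = 4,
                          episode_min_epochs = 3) {
  stopifnot(inherits(hyp, "hypnogram"))
  lab <- hyp$labels
  n <- length(lab)
  epm <- hyp$epoch_length / 60  # minutes per epoch

  nrem_min <- sum(lab == "NREM") * epm
  rem_min <- sum(lab == "REM") * epm
  wake_min <- sum(lab == "WAKE") * epm
  tst <- nrem_min + rem_min

  # arousals: interior wake runs of bounded length (flanks are sleep by
  # maximality of the run)
  wr <- true_runs(lab == "WAKE")
  interior <- wr$start > 1 & wr$end < n
  arousal_runs <- wr[interior & (wr$end - wr$start + 1) <= arousal_max_epochs, ,
                     drop = FALSE]
  n_arousals <- nrow(arousal_runs)
  arousal_defined <- tst > 0
  arousal_index <- if (arousal_defined) n_arousals / tst else NA_real_

  # sleep episodes: sleep epochs glued across embedded arousals
  sleepish <- lab != "WAKE"
  for (k in seq_len(n_arousals))
    sleepish[arousal_runs$start[k]:arousal_runs$end[k]] <- TRUE
  ep_runs <- true_runs(sleepish)
  sleep_counts <- vapply(seq_len(nrow(ep_runs)), function(k)
    sum(lab[ep_runs$start[k]:ep_runs$end[k]] != "WAKE"), integer(1))
  keep <- sleep_counts >= episode_min_epochs
  sleep_eps <- ep_runs[keep, , drop = FALSE]
  # episode span: first to last sleep epoch inside the run
  span_epochs <- vapply(seq_len(nrow(sleep_eps)), function(k) {
    idx <- sleep_eps$start[k]:sleep_eps$end[k]
    s <- idx[lab[idx] != "WAKE"]
    max(s) - min(s) + 1L
  }, integer(1))

  nrem_runs <- true_runs(lab == "NREM")
  rem_runs <- true_runs(lab == "REM")

  mean_dur <- function(lens) if (length(lens)) mean(lens) * epm else NA_real_

  structure(list(
    tst = tst,
    nrem_minutes = nrem_min,
    rem_minutes = rem_min,
    wake_minutes = wake_min,
    total_minutes = n * epm,
    nrem_rem_ratio = if (rem_min > 0) nrem_min / rem_min else NA_real_,
    ratio_defined = rem_min > 0,
    arousal_index = arousal_index,
    arousal_defined = arousal_defined,
    n_arousals = n_arousals,
    n_sleep_episodes = nrow(sleep_eps),
    n_nrem_episodes = nrow(nrem_runs),
    n_rem_episodes = nrow(rem_runs),
    mean_episode_durations = c(
      sleep = mean_dur(span_epochs),
      nrem = mean_dur(nrem_runs$end - nrem_runs$start + 1),
      rem = mean_dur(rem_runs$end - rem_runs$start + 1))),
    class = "sleep_macro")
}

#' @export
print.sleep_macro <- function(x, ...) {
  cat("<sleep_macro>\n")
  cat(sprintf("  TST %.2f min (NREM %.2f, REM %.2f), wake %.2f of %.2f min\n",
              x$tst, x$nrem_minutes, x$rem_minutes, x$wake_minutes,
              x$total_minutes))
  cat(sprintf("  NREM:REM %s; arousal index %s/min (%d arousals)\n",
              if (x$ratio_defined) sprintf("%.2f", x$nrem_rem_ratio) else "undefined",
              if (x$arousal_defined) sprintf("%.2f", x$arousal_index) else "undefined",
              x$n_arousals))
  cat(sprintf("  episodes: %d sleep, %d NREM, %d REM\n",
              x$n_sleep_episodes, x$n_nrem_episodes, x$n_rem_episodes))
  invisible(x)
}
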