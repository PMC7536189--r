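#' Hypnogram: epoch-wise sleep stage labels
#'
#' A hypnogram is the temporal backbone of all state-restricted
#' computation: a sequence of consecutive, non-overlapping epochs
#' (4 s by default) labelled `WAKE`, `NREM` or `REM`, with a parallel
#' logical artefact flag per epoch. Artefact-contaminated epochs are
#' excluded from spectral and event analyses.
#'
#' @param labels character vector over `WAKE`, `NREM`, `REM` (aliases
#'   `W`, `N`, `R` accepted, case-insensitive).
#' @param artefact logical vector, same length as `labels`
#'   (default all `FALSE`).
#' @param epoch_length epoch duration in seconds (default 4).
#' @return object of class `hypnogram`.
#' @export
hypnogram <- function(labels, artefact = NULL, epoch_length = 4) {
  labels <- normalize_stage_labels(labels)
  if (length(labels) == 0) stop("empty hypnogram")
  if (is.null(artefact)) artefact <- rep(FALSE, length(labels))
  if (length(artefact) != length(labels))
    stop("labels and artefact must have the same length")
  if (!is.numeric(epoch_length) || epoch_length <= 0)
    stop("epoch_length must be positive")
  structure(list(labels = labels, artefact = as.logical(artefact),
                 epoch_length = as.numeric(epoch_length)),
            class = "hypnogram")
}

normalize_stage_labels <- function(labels) {
  up <- toupper(trimws(as.character(labels)))
  map <- c(W = "WAKE", WAKE = "WAKE", N = "NREM", NREM = "NREM",
           R = "REM", REM = "REM")
  out <- map[up]
  if (anyNA(out)) stop("unknown stage: ", paste(unique(up[is.na(out)]),
                                                collapse = ", "))
  unname(out)
}

#' @export
print.hypnogram <- function(x, ...) {
  n <- length(x$labels)
  cat("<hypnogram> ", n, " epochs x ", x$epoch_length, " s (",
      round(n * x$epoch_length / 60, 1), " min); ",
      sum(x$artefact), " artefact epoch(s)\n", sep = "")
  tab <- table(factor(x$labels, levels = c("WAKE", "NREM", "REM")))
  cat("  ", paste(names(tab), tab, sep = "=", collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$labels)

#' Read a hypnogram from CSV
#'
#' Expects a comma-separated file with a header row and columns
#' `label` (stage token) and `artefact` (0/1); row order is preserved.
#'
#' @param path file path.
#' @param epoch_length epoch duration in seconds (default 4).
#' @return a [hypnogram()].
#' @export
read_hypnogram <- function(path, epoch_length = 4) {
  tab <- tryCatch(utils::read.csv(path), error = function(e) NULL)
  if (is.null(tab) || nrow(tab) == 0) stop("empty hypnogram")
  if (!"label" %in% names(tab)) stop("hypnogram CSV needs a 'label' column")
  art <- if ("artefact" %in% names(tab)) tab$artefact != 0
         else rep(FALSE, nrow(tab))
  hypnogram(tab$label, art, epoch_length)
}

#' Write a hypnogram to CSV
#' @param hyp a [hypnogram()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  utils::write.csv(data.frame(label = hyp$labels,
                              artefact = as.integer(hyp$artefact)),
                   path, row.names = FALSE)
  invisible(path)
}

# Sample-index ranges of contiguous artefact-free runs of one state.
# Returns data.frame(start_epoch, end_epoch, start_sample, end_sample);
# sample indices are 1-based and assume the recording starts at epoch 1.
state_sample_runs <- function(hyp, rate, state = "NREM",
                              artefact_free = TRUE) {
  flag <- hyp$labels == state
  if (artefact_free) flag <- flag & !hyp$artefact
  runs <- true_runs(flag)
  spe <- round(hyp$epoch_length * rate)
  if (abs(spe - hyp$epoch_length * rate) > 1e-6)
    stop("epoch_length x rate must be an integer number of samples")
  data.frame(start_epoch = runs$start, end_epoch = runs$end,
             start_sample = (runs$start - 1L) * spe + 1L,
             end_sample = runs$end * spe)
}

# Per-epoch sample index list for epochs satisfying a predicate.
epoch_sample_index <- function(hyp, rate, epochs) {
  spe <- round(hyp$epoch_length * rate)
  lapply(epochs, function(e) ((e - 1L) * spe + 1L):(e * spe))
}
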