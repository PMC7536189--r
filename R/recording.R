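#' Multichannel electrophysiology recording
#'
#' Container for a continuous EEG/EMG recording: a named list of signal
#' vectors in microvolts sampled at a common rate, plus a role map
#' declaring which channel is frontal EEG, parietal EEG and EMG.
#'
#' @param channels named list of numeric vectors (microvolts), all the
#'   same length.
#' @param sample_rate sampling rate in Hz (default 400).
#' @param channel_roles named character vector mapping channel name to
#'   one of `"EEG_frontal"`, `"EEG_parietal"`, `"EMG"`.
#' @param start_time recording start offset in seconds (default 0).
#' @return object of class `recording`.
#' @export
recording <- function(channels, sample_rate = 400, channel_roles = NULL,
                      start_time = 0) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(names(channels) == ""))
    stop("channels must be a named list of numeric vectors")
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1) stop("malformed recording")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be positive")
  if (is.null(channel_roles))
    channel_roles <- stats::setNames(rep(NA_character_, length(channels)),
                                     names(channels))
  ok_roles <- c("EEG_frontal", "EEG_parietal", "EMG")
  if (!all(is.na(channel_roles) | channel_roles %in% ok_roles))
    stop("unknown channel role")
  if (!all(names(channel_roles) %in% names(channels)))
    stop("role missing")
  structure(list(channels = lapply(channels, as.numeric),
                 sample_rate = as.numeric(sample_rate),
                 channel_roles = channel_roles,
                 start_time = as.numeric(start_time)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat("<recording> ", length(x$channels), " channel(s), ",
      n_samples(x), " samples @ ", x$sample_rate, " Hz (",
      round(duration_seconds(x), 2), " s)\n", sep = "")
  for (nm in names(x$channels)) {
    role <- x$channel_roles[nm]
    cat("  ", nm, if (!is.na(role)) paste0(" [", role, "]"), "\n", sep = "")
  }
  invisible(x)
}

#' Number of samples per channel of a recording
#' @param rec a [recording()].
#' @export
n_samples <- function(rec) length(rec$channels[[1]])

#' Recording duration in seconds
#' @param rec a [recording()].
#' @export
duration_seconds <- function(rec) n_samples(rec) / rec$sample_rate

#' Extract a channel by role
#'
#' @param rec a [recording()].
#' @param role one of `"EEG_frontal"`, `"EEG_parietal"`, `"EMG"`.
#' @return the numeric signal vector.
#' @export
get_channel <- function(rec, role) {
  hit <- names(rec$channel_roles)[!is.na(rec$channel_roles) &
                                    rec$channel_roles == role]
  if (length(hit) == 0) stop("role missing")
  rec$channels[[hit[1]]]
}

#' Read a recording from EDF or columnar text
#'
#' EDF (European Data Format) files are recognised by their header;
#' anything else is parsed as the package's columnar text format
#' (`# sample_rate=<Hz>` comment line, a header row of channel names,
#' then one comma-separated row per sample). Signals are returned in
#' microvolts, converted with the file's physical/digital scaling
#' fields in the EDF case.
#'
#' @param path file path.
#' @param channel_roles named character vector: names are channel labels
#'   that must exist in the file, values are roles. A role naming a
#'   channel absent from the file raises `"role missing"`.
#' @return a [recording()].
#' @export
read_recording <- function(path, channel_roles = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is_edf_file(path)) {
    parsed <- read_edf(path)
  } else {
    parsed <- read_recording_text(path)
  }
  if (!is.null(channel_roles) &&
      !all(names(channel_roles) %in% names(parsed$channels)))
    stop("role missing")
  recording(parsed$channels, parsed$sample_rate,
            channel_roles = channel_roles)
}

#' Write a recording to EDF or columnar text
#'
#' @param rec a [recording()].
#' @param path output path.
#' @param format `"edf"` (binary, 16-bit with per-channel scaling) or
#'   `"text"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("edf", "text")) {
  format <- match.arg(format)
  if (format == "edf") write_edf(rec, path) else write_recording_text(rec, path)
  invisible(path)
}

read_recording_text <- function(path) {
  first <- readLines(path, n = 1)
  m <- regmatches(first, regexec("sample_rate\\s*[=:]\\s*([0-9.]+)", first))[[1]]
  if (length(m) < 2) stop("text recording lacks a sample_rate header")
  rate <- as.numeric(m[2])
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  list(channels = as.list(tab), sample_rate = rate)
}

write_recording_text <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate=%g", rec$sample_rate), con)
  utils::write.csv(as.data.frame(rec$channels, check.names = FALSE),
                   con, row.names = FALSE)
}
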