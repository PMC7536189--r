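# Minimal EDF (European Data Format) reader/writer.
#
# Supports continuous recordings with a common sampling rate across
# channels and 1-second data records of 16-bit little-endian samples,
# which covers standard rodent polysomnography exports. Physical units
# are taken as written; this package writes "uV".

edf_pad <- function(x, width) formatC(as.character(x), width = width, flag = "-")

is_edf_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 8)
  length(hdr) == 8 && rawToChar(hdr) == "0       "
}

write_edf <- function(rec, path) {
  rate <- rec$sample_rate
  if (abs(rate - round(rate)) > 1e-9)
    stop("EDF export requires an integer sample rate")
  rate <- as.integer(round(rate))
  ns <- length(rec$channels)
  n <- n_samples(rec)
  n_rec <- ceiling(n / rate)
  pad <- n_rec * rate - n
  if (pad > 0)
    warning("padding final EDF record with ", pad, " zero sample(s)")

  labels <- names(rec$channels)
  phys_max <- vapply(rec$channels, function(x) {
    m <- max(abs(x), 1e-6)
    signif(m * 1.0001, 7)
  }, numeric(1))
  dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  writeChar(paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.01", 8), edf_pad("00.00.00", 8),
    edf_pad(hdr_bytes, 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4),
    paste(edf_pad(labels, 16), collapse = ""),
    paste(edf_pad(rep("", ns), 80), collapse = ""),
    paste(edf_pad(rep("uV", ns), 8), collapse = ""),
    paste(edf_pad(sprintf("%.6g", -phys_max), 8), collapse = ""),
    paste(edf_pad(sprintf("%.6g", phys_max), 8), collapse = ""),
    paste(edf_pad(rep(-dig_max, ns), 8), collapse = ""),
    paste(edf_pad(rep(dig_max, ns), 8), collapse = ""),
    paste(edf_pad(rep("", ns), 80), collapse = ""),
    paste(edf_pad(rep(rate, ns), 8), collapse = ""),
    paste(edf_pad(rep("", ns), 32), collapse = "")
  ), con, eos = NULL)

  digitized <- lapply(seq_len(ns), function(j) {
    x <- c(rec$channels[[j]], numeric(pad))
    as.integer(round(x / phys_max[j] * dig_max))
  })
  for (r in seq_len(n_rec)) {
    sel <- ((r - 1L) * rate + 1L):(r * rate)
    for (j in seq_len(ns))
      writeBin(digitized[[j]][sel], con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(rawToChar(readBin(con, "raw", n = w)))
  version <- rd(8)
  if (version != "0") stop("not an EDF file")
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                      # header bytes (recomputed below)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- rdv(16)
  rdv(80)                    # transducer
  rdv(8)                     # dimension
  phys_min <- as.numeric(rdv(8))
  phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8))
  dig_max <- as.numeric(rdv(8))
  rdv(80)                    # prefilter
  spr <- as.integer(rdv(8))  # samples per record
  rdv(32)
  if (length(unique(spr)) != 1)
    stop("channels with differing sampling rates are not supported")
  rate <- spr[1] / rec_dur

  raw_mat <- matrix(0L, nrow = n_rec * spr[1], ncol = ns)
  for (r in seq_len(n_rec)) {
    sel <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    for (j in seq_len(ns))
      raw_mat[sel, j] <- readBin(con, "integer", n = spr[j], size = 2,
                                 endian = "little")
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  channels <- lapply(seq_len(ns), function(j)
    phys_min[j] + (raw_mat[, j] - dig_min[j]) * gain[j])
  names(channels) <- labels
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1) stop("malformed recording")
  list(channels = channels, sample_rate = rate)
}
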