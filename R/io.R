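# Recording I/O: long-format CSV and minimal 16-bit EDF.

#' Write a recording as long-format CSV
#'
#' Columns `time_s`, `channel`, `value_uV`; one row per (sample, channel).
#'
#' @param rec An [eeg_recording()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  n <- ncol(rec$data)
  t <- rec$start_time_s + (seq_len(n) - 1) / rec$fs
  df <- data.frame(
    time_s = rep(t, times = nrow(rec$data)),
    channel = rep(rec$channels, each = n),
    value_uV = as.vector(t(rec$data))
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_recording_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "channel", "value_uV")
  if (!all(need %in% names(df))) {
    stop("CSV must have columns time_s, channel, value_uV")
  }
  channels <- unique(df$channel)
  lens <- table(df$channel)
  if (length(unique(lens)) != 1) {
    stop("inconsistent channel lengths in ", path)
  }
  n <- unname(lens[1])
  t <- sort(unique(df$time_s))
  if (length(t) != n) stop("channel samples do not share a time grid")
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-9) stop("cannot infer fs: irregular time grid")
  fs <- 1 / mean(dt)
  data <- matrix(0, length(channels), n)
  for (ci in seq_along(channels)) {
    sub <- df[df$channel == channels[ci], ]
    data[ci, ] <- sub$value_uV[order(sub$time_s)]
  }
  eeg_recording(data, fs, channels, start_time_s = t[1])
}

pad_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width, flag = " ")
}

#' Write a recording as EDF
#'
#' Minimal European Data Format writer: one data record spanning the
#' whole signal, 16-bit samples, physical units microvolt. Values are
#' quantized to the symmetric physical range of the data; the
#' quantization step is `max(abs(data)) / 32767` per channel set.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_recording_edf <- function(rec, path) {
  ns <- nrow(rec$data)
  n <- ncol(rec$data)
  pmax_ <- max(1e-6, max(abs(rec$data)))
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)
  wr("Startdate X X X X", 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(256 * (ns + 1), 8)
  wr("", 44)
  wr(1, 8)                                   # one data record
  wr(format(n / rec$fs, digits = 8), 8)      # record duration, s
  wr(ns, 4)
  for (ch in rec$channels) wr(ch, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(format(-pmax_, digits = 6), 8)
  for (i in seq_len(ns)) wr(format(pmax_, digits = 6), 8)
  for (i in seq_len(ns)) wr(-32768, 8)
  for (i in seq_len(ns)) wr(32767, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(n, 8)
  for (i in seq_len(ns)) wr("", 32)
  for (ci in seq_len(ns)) {
    dig <- round((rec$data[ci, ] + pmax_) / (2 * pmax_) * 65535 - 32768)
    dig <- pmin(32767, pmax(-32768, dig))
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("not an EDF file: ", path)
  rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header in ", path)
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  data <- matrix(0, ns, spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (ci in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ci], size = 2,
                     endian = "little")
      if (length(dig) != spr[ci]) stop("truncated EDF data in ", path)
      phys <- pmin_[ci] + (dig - dmin_[ci]) *
        (pmax_[ci] - pmin_[ci]) / (dmax_[ci] - dmin_[ci])
      data[ci, ((r - 1) * spr[ci] + 1):(r * spr[ci])] <- phys
    }
  }
  fs <- spr[1] / (rec_dur / 1)
  eeg_recording(data, fs, labels)
}

#' Read a recording from EDF or CSV
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"edf"` or `"csv"`.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  switch(format,
         edf = read_recording_edf(path),
         csv = read_recording_csv(path))
}

#' Write a recording
#'
#' @param rec An [eeg_recording()].
#' @param path Output file.
#' @param format `"auto"` (by extension), `"edf"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  switch(format,
         edf = write_recording_edf(rec, path),
         csv = write_recording_csv(rec, path))
}
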