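# Minimal European Data Format (EDF) I/O: ASCII header, 1-second data
# records of 16-bit little-endian integers, one physical-range scaling per
# signal. Covers what the synthetic and clinical speller paths need; it is
# not a general EDF+ implementation (no annotations channel).

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  paste0(s, strrep(" ", width - nchar(s)))
}

#' Write a recording to an EDF file
#'
#' 16-bit EDF with one-second data records. The sampling rate must be an
#' integer. The final record is zero-padded; the true sample count is
#' stored in the header's reserved field so [read_edf()] can trim the
#' padding. Events are not stored in the EDF; keep them in the sidecar
#' TSV written by [write_events_tsv()].
#'
#' @param rec An [eeg_recording()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs))
    stop("EDF export needs an integer sampling rate", call. = FALSE)
  nch <- nrow(rec$data)
  ns <- ncol(rec$data)
  n_rec <- ceiling(ns / fs)
  phys_min <- apply(rec$data, 1, min)
  phys_max <- apply(rec$data, 1, max)
  flat <- phys_max - phys_min <= 0
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  scale <- (phys_max - phys_min) / 65535
  offset <- phys_min + 32768 * scale

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con,
                                     nchars = width, eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)
  wr("Startdate X X X X", 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(256 * (nch + 1), 8)
  wr(paste0("ns=", ns), 44)
  wr(n_rec, 8)
  wr("1", 8)
  wr(nch, 4)
  for (lab in rec$channel_labels) wr(paste("EEG", lab), 16)
  for (i in seq_len(nch)) wr("AgAgCl electrode", 80)
  for (i in seq_len(nch)) wr("uV", 8)
  for (i in seq_len(nch)) wr(sprintf("%.8g", phys_min[i]), 8)
  for (i in seq_len(nch)) wr(sprintf("%.8g", phys_max[i]), 8)
  for (i in seq_len(nch)) wr("-32768", 8)
  for (i in seq_len(nch)) wr("32767", 8)
  for (i in seq_len(nch)) wr("", 80)
  for (i in seq_len(nch)) wr(fs, 8)
  for (i in seq_len(nch)) wr("", 32)

  padded <- cbind(rec$data, matrix(0, nch, n_rec * fs - ns))
  dig <- round((padded - offset) / scale)
  dig[dig > 32767] <- 32767
  dig[dig < -32768] <- -32768
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by this package (or any plain 16-bit EDF)
#'
#' @param path EDF file.
#' @param events Optional events data frame or path to an events TSV
#'   (see [read_events_tsv()]) to attach to the recording.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, events = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- vapply(seq_len(nch), function(i) rd(16), "")
  for (i in seq_len(nch)) rd(80)
  for (i in seq_len(nch)) rd(8)
  phys_min <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(nch)) rd(80)
  spr <- vapply(seq_len(nch), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(nch)) rd(32)
  if (length(unique(spr)) != 1)
    stop("mixed per-signal sampling rates are not supported", call. = FALSE)
  fs <- spr[1] / rec_dur
  data <- matrix(0, nch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = nch * spr[1], size = 2,
                     signed = TRUE, endian = "little")
    m <- matrix(block, nrow = spr[1], ncol = nch)
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    data[, cols] <- t(m)
  }
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - dig_min * scale
  data <- data * scale + offset
  if (grepl("^ns=", reserved)) {
    ns <- as.integer(sub("^ns=", "", reserved))
    data <- data[, seq_len(ns), drop = FALSE]
  }
  labels <- sub("^EEG ", "", labels)
  if (is.character(events)) events <- read_events_tsv(events)
  eeg_recording(data, fs, labels, events)
}
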