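# Minimal EDF (European Data Format) reader and writer.
#
# Supports the classic 16-bit EDF layout: a 256-byte fixed ASCII header,
# 256 bytes of per-signal header fields per channel, and little-endian
# int16 data records. Physical scaling honours the per-channel physical and
# digital min/max fields. This covers the resting-state EEG exports the
# pipeline consumes; EDF+ annotations are not interpreted.

pad_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1L, width)
}

#' Write a recording to an EDF file
#'
#' Samples are scaled per channel to the full 16-bit digital range; the
#' quantisation step is `(max - min) / 65535` of each channel's physical
#' range.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @param record_duration_s Data-record length in seconds (default 1).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, record_duration_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$samples)
  spr <- round(rec$fs * record_duration_s)      # samples per record per signal
  n_rec <- floor(ncol(rec$samples) / spr)
  if (n_rec < 1L) stop("recording shorter than one data record", call. = FALSE)
  X <- rec$samples[, seq_len(n_rec * spr), drop = FALSE]
  phys_min <- apply(X, 1L, min)
  phys_max <- apply(X, 1L, max)
  flat <- phys_max - phys_min < 1e-9
  phys_max[flat] <- phys_min[flat] + 1          # guard degenerate channels
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8L),
    pad_field(paste0("subject ", rec$subject_id), 80L),
    pad_field("recording synthetic", 80L),
    pad_field("01.01.26", 8L), pad_field("00.00.00", 8L),
    pad_field(256L * (1L + ns), 8L),
    pad_field("", 44L),
    pad_field(n_rec, 8L),
    pad_field(format(record_duration_s), 8L),
    pad_field(ns, 4L))
  writeChar(hdr, con, eos = NULL)
  sig_field <- function(vals, width)
    writeChar(paste(vapply(vals, pad_field, "", width = width), collapse = ""),
              con, eos = NULL)
  sig_field(rec$channel_labels, 16L)
  sig_field(rep("synthetic EEG", ns), 80L)
  sig_field(rep("uV", ns), 8L)
  sig_field(formatC(phys_min, format = "g", digits = 7), 8L)
  sig_field(formatC(phys_max, format = "g", digits = 7), 8L)
  sig_field(rep(dig_min, ns), 8L)
  sig_field(rep(dig_max, ns), 8L)
  sig_field(rep("", ns), 80L)
  sig_field(rep(spr, ns), 8L)
  sig_field(rep("", ns), 32L)

  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- round((X[ch, cols] - phys_min[ch]) * scale[ch] + dig_min)
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' @param path EDF file path.
#' @param subject_id,label,therapy Metadata to attach (EDF stores only a
#'   free-text patient field).
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, subject_id = NULL, label = NA_character_,
                     therapy = NA_character_) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) {
    raw <- readBin(con, "raw", nchars)
    trimws(rawToChar(raw))
  }
  rd(8L)                                       # version
  patient <- rd(80L)
  rd(80L); rd(8L); rd(8L)                      # recording id, date, time
  rd(8L)                                       # header bytes
  rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  labels <- vapply(seq_len(ns), function(i) rd(16L), "")
  for (i in seq_len(ns)) rd(80L)               # transducer
  for (i in seq_len(ns)) rd(8L)                # unit
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  for (i in seq_len(ns)) rd(80L)               # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8L), ""))
  for (i in seq_len(ns)) rd(32L)
  if (length(unique(spr)) != 1L)
    stop("mixed per-signal sampling rates are not supported", call. = FALSE)
  fs <- spr[1L] / rec_dur
  X <- matrix(0, ns, n_rec * spr[1L])
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[ch], size = 2L, signed = TRUE,
                     endian = "little")
      X[ch, ((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <-
        (dig - dig_min[ch]) * scale[ch] + phys_min[ch]
    }
  }
  if (is.null(subject_id))
    subject_id <- sub("^subject\\s+", "", patient)
  eeg_recording(X, fs, labels, subject_id = subject_id, label = label,
                therapy = therapy)
}
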