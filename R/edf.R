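# Minimal European Data Format (EDF) I/O: fixed 256-byte main header,
# 256 bytes per signal, then 1-s data records of little-endian 16-bit
# integers. Covers continuous equal-rate signals, which is all this package
# produces or consumes.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' Signals are stored as 16-bit integers with per-channel physical scaling in
#' microvolts and a 1-second record duration, so the recording is truncated to
#' a whole number of seconds (recordings built from 30-s epochs are unaffected).
#' Quantisation error is bounded by the physical range divided by 2^16.
#'
#' @param recording an [eeg_recording()].
#' @param path output file path.
#' @param patient_id,recording_id free-text header fields (80 chars max).
#' @param startdate,starttime header timestamps, `dd.mm.yy` / `hh.mm.ss`.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, patient_id = "X", recording_id = "X",
                      startdate = "01.01.00", starttime = "00.00.00") {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  ns <- length(recording$channels)
  n_rec <- floor(nrow(recording$data) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  dat <- recording$data[seq_len(n_rec * fs), , drop = FALSE]

  pmin_ <- apply(dat, 2, min)
  pmax_ <- apply(dat, 2, max)
  flat <- pmax_ - pmin_ < 1e-9
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(patient_id, 80),
    edf_pad(recording_id, 80),
    edf_pad(startdate, 8),
    edf_pad(starttime, 8),
    edf_pad(256 * (1 + ns), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),
    edf_pad(ns, 4)
  )
  field <- function(vals, width) paste(vapply(vals, edf_pad, "", width = width), collapse = "")
  hdr <- paste0(
    hdr,
    field(recording$channels, 16),
    field(rep("", ns), 80),                       # transducer
    field(rep("uV", ns), 8),                      # physical dimension
    field(sprintf("%.6g", pmin_), 8),
    field(sprintf("%.6g", pmax_), 8),
    field(rep("-32768", ns), 8),
    field(rep("32767", ns), 8),
    field(rep("", ns), 80),                       # prefiltering
    field(rep(fs, ns), 8),                        # samples per record
    field(rep("", ns), 32)
  )
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)

  # digital conversion per channel, then interleave by record
  dig <- matrix(0L, nrow(dat), ns)
  for (j in seq_len(ns)) {
    d <- round((dat[, j] - pmin_[j]) / (pmax_[j] - pmin_[j]) * 65535 - 32768)
    dig[, j] <- as.integer(pmax(pmin(d, 32767), -32768))
  }
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.vector(dig[idx, ]), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return An [eeg_recording()]; header fields are attached as attribute
#'   `edf_header` (list with `patient_id`, `recording_id`, `startdate`,
#'   `starttime`, `n_records`, `record_duration`).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("not an EDF file (version field != 0): ", path)
  patient_id <- rd(80); recording_id <- rd(80)
  startdate <- rd(8); starttime <- rd(8)
  rd(8)                                  # header bytes
  rd(44)                                 # reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16)
  rdv(80)                                # transducer
  rdv(8)                                 # dimension
  pmin_ <- as.numeric(rdv(8))
  pmax_ <- as.numeric(rdv(8))
  dmin_ <- as.numeric(rdv(8))
  dmax_ <- as.numeric(rdv(8))
  rdv(80)                                # prefiltering
  spr <- as.integer(rdv(8))
  rdv(32)                                # reserved
  if (length(unique(spr)) != 1) stop("EDF reader supports equal-rate signals only")
  fs <- spr[1] / rec_dur

  dat <- matrix(0, n_rec * spr[1], ns)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, integer(), n = spr[1] * ns, size = 2,
                     endian = "little", signed = TRUE)
    block <- matrix(block, nrow = spr[1], ncol = ns)
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    dat[idx, ] <- block
  }
  for (j in seq_len(ns)) {
    dat[, j] <- (dat[, j] - dmin_[j]) / (dmax_[j] - dmin_[j]) * (pmax_[j] - pmin_[j]) + pmin_[j]
  }
  rec <- eeg_recording(dat, fs = fs, channels = labels)
  attr(rec, "edf_header") <- list(patient_id = patient_id, recording_id = recording_id,
                                  startdate = startdate, starttime = starttime,
                                  n_records = n_rec, record_duration = rec_dur)
  rec
}
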