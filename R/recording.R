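#' Multichannel EEG recording
#'
#' Container for a fixed-rate multichannel EEG signal in microvolts. The two
#' channels used throughout the package are the central derivations `C3` and
#' `C4`, but any channel set is accepted.
#'
#' @param data numeric matrix, one column per channel, amplitudes in uV.
#' @param fs sampling rate in Hz (must be positive).
#' @param channels character vector of channel names, one per column.
#' @return An object of class `eeg_recording`: a list with elements `data`,
#'   `fs`, `channels` and `duration` (seconds).
#' @examples
#' rec <- eeg_recording(cbind(C3 = sin(1:250), C4 = cos(1:250)), fs = 125)
#' rec
#' @export
eeg_recording <- function(data, fs, channels = colnames(data)) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("`fs` must be a positive scalar")
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(data)))
  if (length(channels) != ncol(data)) stop("one channel name per column required")
  colnames(data) <- channels
  structure(
    list(data = data, fs = fs, channels = channels,
         duration = nrow(data) / fs),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) [%s], %.1f s at %g Hz\n",
              length(x$channels), paste(x$channels, collapse = ", "),
              x$duration, x$fs))
  invisible(x)
}

#' Extract one channel of a recording
#' @param recording an [eeg_recording()].
#' @param channel channel name.
#' @return Numeric vector of samples.
#' @export
channel_data <- function(recording, channel) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (!channel %in% recording$channels) {
    stop(sprintf("channel '%s' not present (have: %s)", channel,
                 paste(recording$channels, collapse = ", ")))
  }
  recording$data[, channel]
}

hypnogram_stages <- c("W", "N1", "N2", "N3", "R")

#' Hypnogram (per-epoch sleep-stage labels)
#'
#' A hypnogram is the sequence of manually or automatically scored sleep
#' stages, one label per 30-second epoch, aligned to the start of the
#' recording. Stages follow AASM conventions: wake (`W`), NREM stages
#' `N1`/`N2`/`N3`, and REM (`R`).
#'
#' @param stages character vector of stage labels (subset of
#'   `W, N1, N2, N3, R`), one per 30-s epoch; may be empty.
#' @param epoch_s epoch length in seconds (fixed at 30 in standard scoring).
#' @return Object of class `hypnogram` (a character vector with attributes).
#' @export
hypnogram <- function(stages, epoch_s = 30) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), hypnogram_stages)
  if (length(bad)) stop("unknown sleep stage label(s): ", paste(bad, collapse = ", "))
  structure(stages, epoch_s = epoch_s, class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d x %g-s epochs (%.1f min)\n",
              length(x), attr(x, "epoch_s"), length(x) * attr(x, "epoch_s") / 60))
  if (length(x)) print(table(factor(unclass(x), levels = hypnogram_stages)))
  invisible(x)
}

#' Merged time intervals covered by a sleep stage
#'
#' @param hyp a [hypnogram()].
#' @param stage stage label to extract.
#' @return Two-column matrix of half-open `[start, end)` intervals in seconds
#'   from recording start, consecutive epochs merged.
#' @export
stage_intervals <- function(hyp, stage = "N2") {
  stopifnot(inherits(hyp, "hypnogram"))
  ep <- attr(hyp, "epoch_s")
  idx <- which(unclass(hyp) == stage)
  if (!length(idx)) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  merge_intervals(cbind((idx - 1) * ep, idx * ep))
}

#' Write / read a hypnogram as CSV
#'
#' Plain-text interchange format: columns `epoch_index` (0-based) and `stage`.
#'
#' @param hyp a [hypnogram()].
#' @param path file path.
#' @return `write_hypnogram_csv` returns `path` invisibly;
#'   `read_hypnogram_csv` returns a [hypnogram()].
#' @export
write_hypnogram_csv <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  df <- data.frame(epoch_index = seq_along(hyp) - 1L, stage = unclass(hyp))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram_csv
#' @export
read_hypnogram_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "stage") %in% names(df))) {
    stop("hypnogram CSV must have columns epoch_index, stage")
  }
  hypnogram(df$stage[order(df$epoch_index)])
}
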