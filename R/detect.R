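#' Spindle detector parameters
#'
#' Defaults follow the LUNA wavelet detector's primary options: a complex
#' Morlet wavelet centred on 13.5 Hz with 7 cycles, a core threshold of 4.5
#' times the mean wavelet power over NREM2, spindle durations between 0.5 and
#' 3 s, fragments closer than 0.5 s merged, and a quality cutoff q >= 0.
#'
#' @param fc wavelet centre frequency, Hz.
#' @param cycles number of wavelet cycles (sets the time/frequency trade-off).
#' @param threshold_multiplier core threshold as a multiple of the mean
#'   smoothed wavelet power over the baseline (artifact-free NREM2) samples.
#' @param boundary_multiplier secondary (extent) threshold as a multiple of
#'   the mean smoothed power: a candidate event is a maximal run above this
#'   boundary that contains at least one sample above the core threshold.
#'   Must not exceed `threshold_multiplier`; setting it equal collapses the
#'   detector to a single-threshold rule.
#' @param min_duration,max_duration admissible event duration bounds, s.
#' @param merge_gap maximum gap between supra-threshold fragments that are
#'   merged into one event, s.
#' @param q_min minimum quality score (see [quality_score()]); events below
#'   are discarded.
#' @param smoothing_window moving-average width applied to the wavelet power
#'   before thresholding, s.
#' @return A list of class `detector_params`.
#' @export
detector_params <- function(fc = 13.5, cycles = 7, threshold_multiplier = 4.5,
                            boundary_multiplier = 2, min_duration = 0.5,
                            max_duration = 3, merge_gap = 0.5, q_min = 0,
                            smoothing_window = 0.1) {
  if (min_duration >= max_duration) stop("min_duration must be < max_duration")
  vals <- c(fc, cycles, threshold_multiplier, boundary_multiplier,
            min_duration, max_duration, merge_gap, smoothing_window)
  if (any(vals <= 0)) stop("all detector parameters except q_min must be positive")
  if (boundary_multiplier > threshold_multiplier) {
    stop("boundary_multiplier must not exceed threshold_multiplier")
  }
  structure(list(fc = fc, cycles = cycles,
                 threshold_multiplier = threshold_multiplier,
                 boundary_multiplier = boundary_multiplier,
                 min_duration = min_duration, max_duration = max_duration,
                 merge_gap = merge_gap, q_min = q_min,
                 smoothing_window = smoothing_window),
            class = "detector_params")
}

#' Complex Morlet wavelet power at one centre frequency
#'
#' Convolves the signal with a complex Morlet wavelet (Gaussian-windowed
#' complex exponential with `sigma_t = cycles / (2 pi fc)`) and returns the
#' pointwise magnitude-squared coefficient. The wavelet is normalised so a
#' unit-amplitude sinusoid at `fc` yields a constant power of 0.25 (amplitude
#' response 1/2), making the output proportional to narrow-band power in uV^2.
#' Samples within half a wavelet length of either end ride on zero-padding
#' and are unreliable; their count is attached as attribute `edge_samples`.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param fc centre frequency, Hz.
#' @param cycles wavelet cycles.
#' @return Numeric power series, same length as `x`, with attribute
#'   `edge_samples`.
#' @export
cwt_power <- function(x, fs, fc = 13.5, cycles = 7) {
  n <- length(x)
  if (n <= cycles * fs / fc) stop("signal too short for the requested wavelet")
  sigma_t <- cycles / (2 * pi * fc)
  half <- ceiling(3.5 * sigma_t * fs)
  tt <- (-half:half) / fs
  env <- exp(-tt^2 / (2 * sigma_t^2))
  w <- exp(2i * pi * fc * tt) * env / sum(env)
  nw <- length(w)
  nf <- next_fast_len(n + nw - 1)
  cf <- stats::fft(stats::fft(c(x, rep(0, nf - n))) * stats::fft(c(w, rep(0, nf - nw))),
                   inverse = TRUE) / nf
  coef <- cf[(half + 1):(half + n)]
  power <- Mod(coef)^2
  attr(power, "edge_samples") <- half
  power
}

#' Threshold a wavelet power series into candidate spindle events
#'
#' The power series is smoothed with a centred moving average
#' (`smoothing_window`); the core threshold is `threshold_multiplier` times
#' the mean smoothed power over the baseline samples and the extent
#' (boundary) threshold is `boundary_multiplier` times that mean. Candidate
#' events are maximal supra-boundary runs within the baseline mask that
#' contain at least one supra-core sample. Runs separated by less than
#' `merge_gap` (with the gap itself inside the mask) are merged, then runs
#' shorter than `min_duration` or longer than `max_duration` are discarded.
#'
#' @param power nonnegative power series (e.g. from [cwt_power()]).
#' @param fs sampling rate, Hz.
#' @param baseline_mask logical vector, `TRUE` for artifact-free NREM2
#'   samples; both the threshold estimate and the candidate runs are
#'   restricted to it.
#' @param params a [detector_params()].
#' @return Two-column matrix of half-open `(start, end)` event intervals in
#'   seconds; attribute `threshold` holds the power threshold used.
#' @export
detect_events <- function(power, fs, baseline_mask = rep(TRUE, length(power)),
                          params = detector_params()) {
  if (any(power < 0)) stop("power must be nonnegative")
  if (length(baseline_mask) != length(power)) stop("mask/power length mismatch")
  if (!any(baseline_mask)) stop("empty baseline: no samples to estimate the threshold from")
  sm <- moving_average(as.numeric(power), round(params$smoothing_window * fs))
  base_mean <- mean(sm[baseline_mask])
  thr <- params$threshold_multiplier * base_mean
  thr_b <- params$boundary_multiplier * base_mean
  above <- sm > thr_b & baseline_mask
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], ends[r$values])
  if (nrow(runs)) {
    has_core <- vapply(seq_len(nrow(runs)),
                       function(i) any(sm[runs[i, 1]:runs[i, 2]] > thr), logical(1))
    runs <- runs[has_core, , drop = FALSE]
  }
  if (nrow(runs) == 0) {
    out <- matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
    attr(out, "threshold") <- thr
    return(out)
  }
  # merge runs separated by < merge_gap, gap samples inside the mask
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      k <- nrow(merged)
      gap_samples <- runs[i, 1] - merged[k, 2] - 1
      gap_idx <- if (gap_samples >= 1) (merged[k, 2] + 1):(runs[i, 1] - 1) else integer(0)
      gap_in_mask <- all(baseline_mask[gap_idx])
      if (gap_samples / fs < params$merge_gap && gap_in_mask) {
        merged[k, 2] <- runs[i, 2]
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
  }
  dur <- (merged[, 2] - merged[, 1] + 1) / fs
  keep <- dur >= params$min_duration & dur <= params$max_duration
  out <- cbind(start = (merged[keep, 1] - 1) / fs, end = merged[keep, 2] / fs)
  attr(out, "threshold") <- thr
  out
}

# Band power (uV^2) of a segment by zero-padded periodogram: the summed
# spectral mass in each requested band. A unit sinusoid inside a band gives
# ~0.5. `bands` is a list of length-2 (flo, fhi) vectors; returns one power
# per band from a single FFT.
multi_band_power <- function(x, fs, bands, nfft = NULL) {
  n <- length(x)
  x <- x - mean(x)
  if (is.null(nfft)) nfft <- max(512, 2^ceiling(log2(n)))
  X <- stats::fft(c(x, rep(0, nfft - n)))
  f <- (0:(nfft - 1)) * fs / nfft
  half <- 2:(nfft %/% 2)  # positive frequencies, skip DC
  p <- 2 * Mod(X[half])^2 / (n * nfft)
  fh <- f[half]
  vapply(bands, function(b) sum(p[fh >= b[1] & fh <= b[2]]), numeric(1))
}

band_power_fft <- function(x, fs, flo, fhi, nfft = NULL) {
  multi_band_power(x, fs, list(c(flo, fhi)), nfft)[1]
}

#' Spindle quality score
#'
#' Spectral enrichment of an event relative to baseline:
#' `q = log2( (event sigma power / event broadband power) /
#'            (baseline sigma power / baseline broadband power) )`,
#' with sigma = 10-16 Hz and broadband = 0.3-35 Hz. An event spectrally
#' identical to baseline scores 0; sigma-enriched events score positive.
#'
#' @param x full signal (one channel).
#' @param fs sampling rate, Hz.
#' @param event length-2 numeric, half-open `(start, end)` in seconds.
#' @param baseline two-column matrix of baseline intervals in seconds
#'   (typically artifact-free NREM2 epochs), or a precomputed list with
#'   elements `sigma` and `broad` (mean baseline band powers) as returned by
#'   `baseline_band_powers()` -- useful when scoring many events against the
#'   same baseline.
#' @param sigma_band,broad_band numeric length-2 band edges, Hz.
#' @return Scalar quality score `q`.
#' @export
quality_score <- function(x, fs, event, baseline,
                          sigma_band = c(10, 16), broad_band = c(0.3, 35)) {
  ev <- multi_band_power(x[(floor(event[1] * fs) + 1):min(length(x), round(event[2] * fs))],
                         fs, list(sigma_band, broad_band))
  bl <- if (is.list(baseline)) baseline else
    baseline_band_powers(x, fs, baseline, sigma_band, broad_band)
  if (bl$sigma <= 0 || bl$broad <= 0 || ev[2] <= 0) {
    stop("zero baseline or event power: quality score undefined")
  }
  log2((ev[1] / ev[2]) / (bl$sigma / bl$broad))
}

# Mean sigma/broadband power over a set of baseline intervals (one channel).
baseline_band_powers <- function(x, fs, intervals,
                                 sigma_band = c(10, 16), broad_band = c(0.3, 35)) {
  intervals <- matrix(intervals, ncol = 2)
  pw <- vapply(seq_len(nrow(intervals)), function(i) {
    i0 <- floor(intervals[i, 1] * fs) + 1
    i1 <- min(length(x), round(intervals[i, 2] * fs))
    multi_band_power(x[i0:i1], fs, list(sigma_band, broad_band))
  }, numeric(2))
  list(sigma = mean(pw[1, ]), broad = mean(pw[2, ]))
}

#' Detect sleep spindles in a two-channel recording
#'
#' Runs the full per-channel detection pipeline on a band-pass-filtered
#' recording: NREM2 segmentation into 10-s windows, Hjorth artifact
#' screening, Morlet wavelet power at `fc`, thresholding/merging/duration
#' filtering, and quality scoring. Detection is limited to artifact-free
#' NREM2 samples.
#'
#' @param recording an [eeg_recording()] containing channels `C3` and `C4`,
#'   already band-pass filtered (see [bandpass()]).
#' @param hyp the recording's [hypnogram()].
#' @param params a [detector_params()].
#' @param epochs optional pre-computed artifact-screened `epoch_set`; computed
#'   from the recording when missing.
#' @return A data frame of class `spindle_events`, sorted by (channel, start),
#'   with columns `channel`, `start`, `end`, `duration`, `mean_power`
#'   (sigma-band power over the event, uV^2), `peak_frequency` (Hz, argmax of
#'   the event spectrum) and `quality_q`.
#' @export
detect_spindles <- function(recording, hyp, params = detector_params(),
                            epochs = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (!all(c("C3", "C4") %in% recording$channels)) {
    stop("recording must contain channels C3 and C4")
  }
  fs <- recording$fs
  if (is.null(epochs)) {
    epochs <- reject_artifacts(recording, segment_epochs(recording, hyp))
  }
  empty <- data.frame(channel = character(0), start = numeric(0), end = numeric(0),
                      duration = numeric(0), mean_power = numeric(0),
                      peak_frequency = numeric(0), quality_q = numeric(0),
                      stringsAsFactors = FALSE)
  clean <- epochs[!epochs$flagged, , drop = FALSE]
  if (nrow(clean) == 0) {
    return(structure(empty, class = c("spindle_events", "data.frame")))
  }
  n <- nrow(recording$data)
  mask <- rep(FALSE, n)
  for (i in seq_len(nrow(clean))) {
    mask[(floor(clean$start[i] * fs) + 1):min(n, round(clean$end[i] * fs))] <- TRUE
  }
  baseline_iv <- merge_intervals(cbind(clean$start, clean$end))

  rows <- list()
  for (ch in c("C3", "C4")) {
    x <- channel_data(recording, ch)
    pw <- cwt_power(x, fs, params$fc, params$cycles)
    ev <- detect_events(pw, fs, baseline_mask = mask, params = params)
    bl <- baseline_band_powers(x, fs, baseline_iv)
    for (i in seq_len(nrow(ev))) {
      q <- quality_score(x, fs, ev[i, ], bl)
      if (q < params$q_min) next
      i0 <- floor(ev[i, 1] * fs) + 1
      i1 <- min(n, round(ev[i, 2] * fs))
      seg <- x[i0:i1] - mean(x[i0:i1])
      m <- length(seg)
      nfft <- max(1024, 2^ceiling(log2(m)))
      X2 <- Mod(stats::fft(c(seg, rep(0, nfft - m))))^2
      f <- (0:(nfft - 1)) * fs / nfft
      pos <- which(f > 0.3 & f <= 35)
      sig <- which(f >= 10 & f <= 16)
      rows[[length(rows) + 1]] <- data.frame(
        channel = ch, start = ev[i, 1], end = ev[i, 2],
        duration = ev[i, 2] - ev[i, 1],
        mean_power = 2 * sum(X2[sig]) / (m * nfft),
        peak_frequency = f[pos[which.max(X2[pos])]],
        quality_q = q, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[order(out$channel, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("spindle_events", "data.frame"))
}

#' @export
print.spindle_events <- function(x, ...) {
  cat(sprintf("<spindle_events> %d event(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Spindle density in events per minute
#'
#' @param events a `spindle_events` data frame (or an event count).
#' @param n2_minutes minutes of NREM2 analysed (> 0).
#' @return Data frame with one row per channel plus a pooled `all` row
#'   (total events over `n2_minutes`).
#' @export
spindle_density <- function(events, n2_minutes) {
  if (n2_minutes <= 0) stop("n2_minutes must be positive")
  if (is.numeric(events) && length(events) == 1) {
    return(data.frame(channel = "all", n_events = events,
                      density = events / n2_minutes, stringsAsFactors = FALSE))
  }
  chans <- sort(unique(as.character(events$channel)))
  counts <- vapply(chans, function(ch) sum(events$channel == ch), 0)
  df <- data.frame(channel = c(chans, "all"),
                   n_events = c(counts, nrow(events)),
                   density = c(counts, nrow(events)) / n2_minutes,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Score detections against ground truth
#'
#' A ground-truth event counts as recovered when some detection on the same
#' channel overlaps it by at least `min_frac` of the shorter interval;
#' detections are false discoveries when they match no ground-truth event by
#' the same rule.
#'
#' @param detected a `spindle_events` data frame.
#' @param truth ground-truth data frame (`channel`, `start`, `end`).
#' @param min_frac minimum overlap as a fraction of the shorter interval.
#' @return List with `sensitivity`, `false_discovery_rate`, `n_truth`,
#'   `n_detected`.
#' @export
score_detections <- function(detected, truth, min_frac = 0.5) {
  hit_any <- function(a, b) {
    # does any row of b overlap [a1,a2) by >= min_frac of the shorter interval?
    if (nrow(b) == 0) return(FALSE)
    ov <- interval_overlap(a[1], a[2], as.matrix(b[, c("start", "end")]))
    shorter <- pmin(a[2] - a[1], b$end - b$start)
    any(ov >= min_frac * shorter)
  }
  n_truth <- nrow(truth)
  n_det <- nrow(detected)
  tp_truth <- 0
  for (i in seq_len(n_truth)) {
    b <- detected[detected$channel == truth$channel[i], , drop = FALSE]
    if (hit_any(c(truth$start[i], truth$end[i]), b)) tp_truth <- tp_truth + 1
  }
  fp <- 0
  for (i in seq_len(n_det)) {
    b <- truth[truth$channel == detected$channel[i], , drop = FALSE]
    if (!hit_any(c(detected$start[i], detected$end[i]), b)) fp <- fp + 1
  }
  list(sensitivity = if (n_truth) tp_truth / n_truth else NA_real_,
       false_discovery_rate = if (n_det) fp / n_det else NA_real_,
       n_truth = n_truth, n_detected = n_det)
}
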