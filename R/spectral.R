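#' Spectral analysis parameters
#'
#' @param band_low,band_high sigma band edges in Hz (default 10-16 Hz).
#' @param epoch_length analysis window length in seconds for stage-wide
#'   metrics (default 10 s).
#' @param half_bandwidth multitaper half-bandwidth W in Hz for full-length
#'   epochs (default 1 Hz, i.e. time-bandwidth product NW = 10 for 10-s
#'   epochs). Short spindle segments automatically widen W so that NW >= 3
#'   (at least 5 tapers), trading frequency resolution for estimator
#'   variance where the segment length forces the trade anyway.
#' @return A list of class `spectral_params`.
#' @export
spectral_params <- function(band_low = 10, band_high = 16, epoch_length = 10,
                            half_bandwidth = 1) {
  if (!(band_low > 0 && band_low < band_high)) stop("need 0 < band_low < band_high")
  structure(list(band_low = band_low, band_high = band_high,
                 epoch_length = epoch_length, half_bandwidth = half_bandwidth),
            class = "spectral_params")
}

# DPSS (Slepian) tapers via the standard symmetric tridiagonal eigenproblem;
# columns are unit-norm tapers ordered by decreasing eigenvalue. Cached per
# (n, nw, k) for the life of the session.
.dpss_cache <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw, k) {
  key <- paste(n, round(nw, 6), k, sep = "|")
  hit <- get0(key, envir = .dpss_cache)
  if (!is.null(hit)) return(hit)
  w <- nw / n
  t <- 0:(n - 1)
  A <- matrix(0, n, n)
  diag(A) <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  off <- (t[-1]) * (n - t[-1]) / 2
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, seq_len(k), drop = FALSE]
  # sign convention: each taper positive near the centre lobe
  for (j in seq_len(k)) {
    if (sum(v[seq_len(ceiling(n / 2)), j]) < 0) v[, j] <- -v[, j]
  }
  assign(key, v, envir = .dpss_cache)
  v
}

#' Multitaper auto- and cross-spectra over a set of analysis windows
#'
#' Estimates per-window Slepian-taper power spectral densities for two
#' channels and their complex cross-spectral density. All windows share one
#' zero-padded frequency grid (the smallest fast FFT length at or above the
#' longest window), so spectra of variable-length spindle segments can be
#' averaged per frequency. PSDs are scaled so that the integral over
#' frequency (factor 2 over positive frequencies) recovers the tapered
#' signal variance in uV^2.
#'
#' @param recording an [eeg_recording()].
#' @param intervals two-column matrix of half-open `(start, end)` windows in
#'   seconds.
#' @param params a [spectral_params()].
#' @param channels the two channels to analyse.
#' @return Object of class `epoch_spectra`: list with `freq` (Hz), `df` (bin
#'   width), matrices `sxx`, `syy` (real, `nfreq x n_epochs`), `sxy`
#'   (complex), `n_epochs` and `fs`.
#' @export
compute_cross_spectra <- function(recording, intervals, params = spectral_params(),
                                  channels = c("C3", "C4")) {
  stopifnot(inherits(recording, "eeg_recording"))
  intervals <- matrix(as.numeric(intervals), ncol = 2)
  if (nrow(intervals) == 0) stop("no intervals to analyse")
  fs <- recording$fs
  x <- channel_data(recording, channels[1])
  y <- channel_data(recording, channels[2])
  idx0 <- floor(intervals[, 1] * fs) + 1
  idx1 <- pmin(length(x), round(intervals[, 2] * fs))
  lens <- idx1 - idx0 + 1
  if (any(lens < 2 * fs)) {
    if (any(lens < 0.4 * fs)) stop("interval too short for spectral estimation")
  }
  nfft <- next_fast_len(max(256, max(lens)))
  if (nfft %% 2 == 1) nfft <- nfft + 1
  nfreq <- nfft %/% 2 + 1
  freq <- (0:(nfft %/% 2)) * fs / nfft
  m <- nrow(intervals)
  sxx <- matrix(0, nfreq, m)
  syy <- matrix(0, nfreq, m)
  sxy <- matrix(0 + 0i, nfreq, m)

  conj_idx <- c(1, nfft:2)
  for (len in unique(lens)) {
    cols <- which(lens == len)
    segx <- matrix(vapply(cols, function(i) x[idx0[i]:idx1[i]], numeric(len)), nrow = len)
    segy <- matrix(vapply(cols, function(i) y[idx0[i]:idx1[i]], numeric(len)), nrow = len)
    segx <- sweep(segx, 2, colMeans(segx))
    segy <- sweep(segy, 2, colMeans(segy))
    # short spindle segments widen the bandwidth so at least 5 tapers are
    # averaged; long stage epochs use the configured half-bandwidth
    nw <- max(len / fs * params$half_bandwidth, 3)
    k <- max(1, floor(2 * nw - 1))
    tap <- dpss_tapers(len, nw, k)
    pad <- matrix(0 + 0i, nfft - len, length(cols))
    axx <- matrix(0, nfreq, length(cols))
    ayy <- matrix(0, nfreq, length(cols))
    axy <- matrix(0 + 0i, nfreq, length(cols))
    for (j in seq_len(k)) {
      # both channels in one FFT: transform x + iy, then split by Hermitian
      # symmetry
      Fz <- stats::mvfft(rbind((segx + 1i * segy) * tap[, j], pad))
      Frev <- Conj(Fz[conj_idx, , drop = FALSE])
      X <- ((Fz + Frev) / 2)[seq_len(nfreq), , drop = FALSE]
      Y <- ((Fz - Frev) / 2i)[seq_len(nfreq), , drop = FALSE]
      axx <- axx + Mod(X)^2
      ayy <- ayy + Mod(Y)^2
      axy <- axy + X * Conj(Y)
    }
    sxx[, cols] <- axx / (k * fs)
    syy[, cols] <- ayy / (k * fs)
    sxy[, cols] <- axy / (k * fs)
  }
  structure(list(freq = freq, df = fs / nfft, sxx = sxx, syy = syy, sxy = sxy,
                 n_epochs = m, fs = fs),
            class = "epoch_spectra")
}

#' Sigma-band power averaged over epochs and channels
#'
#' Integrates the per-epoch power spectral density over the sigma band,
#' averages across epochs, then averages the two channels.
#'
#' @param spectra an `epoch_spectra` object from `compute_cross_spectra()`.
#' @param params a [spectral_params()].
#' @return Band power in uV^2.
#' @export
band_sigma_power <- function(spectra, params = spectral_params()) {
  stopifnot(inherits(spectra, "epoch_spectra"))
  if (spectra$n_epochs == 0) stop("empty spectra set")
  band <- spectra$freq >= params$band_low & spectra$freq <= params$band_high
  px <- 2 * colSums(spectra$sxx[band, , drop = FALSE]) * spectra$df
  py <- 2 * colSums(spectra$syy[band, , drop = FALSE]) * spectra$df
  (mean(px) + mean(py)) / 2
}

#' Magnitude-squared-free epoch-averaged coherence over the sigma band
#'
#' Coherence is the magnitude of the across-epoch mean cross-spectral density
#' normalised by the geometric mean of the across-epoch mean auto-spectral
#' densities, computed per frequency and then averaged over the sigma band:
#' `abs(E[S_xy]) / sqrt(E[S_xx] * E[S_yy])`. Identical channels give exactly
#' 1; the magnitude makes the estimate invariant to a sign flip of one
#' channel.
#'
#' @inheritParams band_sigma_power
#' @return Coherence in `[0, 1]`.
#' @export
coherence_over_epochs <- function(spectra, params = spectral_params()) {
  stopifnot(inherits(spectra, "epoch_spectra"))
  band <- spectra$freq >= params$band_low & spectra$freq <= params$band_high
  mxx <- rowMeans(spectra$sxx[band, , drop = FALSE])
  myy <- rowMeans(spectra$syy[band, , drop = FALSE])
  mxy <- rowMeans(spectra$sxy[band, , drop = FALSE])
  den <- sqrt(mxx * myy)
  if (any(den == 0)) stop("zero spectral density in the band: coherence undefined")
  mean(Mod(mxy) / den)
}

#' Merged spindle analysis segments
#'
#' Union of detected spindle intervals across both channels, with
#' overlapping or abutting intervals merged. These segments are the analysis
#' windows for the spindle-restricted ("spindle sigma") metrics.
#'
#' @param events a `spindle_events` data frame (or any data frame with
#'   `start`/`end` columns).
#' @return Two-column matrix of half-open merged intervals in seconds.
#' @export
spindle_segments <- function(events) {
  if (nrow(events) == 0) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  merge_intervals(cbind(events$start, events$end))
}

#' Per-recording sigma power, coherence and spindle metrics
#'
#' Computes the four per-subject spectral metrics: sigma power and C3-C4
#' coherence over all artifact-free 10-s NREM2 epochs ("NREM2 sigma"), and
#' the same quantities over the merged detected-spindle segments ("spindle
#' sigma"), plus the detected spindle density. With zero detected spindles
#' the spindle metrics are returned as `NA` (missing), never as zero.
#'
#' @param recording a band-pass-filtered [eeg_recording()] with channels
#'   C3, C4.
#' @param hyp the recording's [hypnogram()].
#' @param events detected `spindle_events` (see [detect_spindles()]).
#' @param params a [spectral_params()].
#' @param subject_id,visit,age identifiers copied into the output row.
#' @param epochs optional artifact-screened `epoch_set` (computed if missing).
#' @return One-row data frame of class `subject_metrics` with columns
#'   `subject_id`, `visit`, `age`, `n2_sigma_power`, `n2_sigma_coherence`,
#'   `spindle_sigma_power`, `spindle_sigma_coherence`, `spindle_density`,
#'   `n_epochs_used`.
#' @export
compute_subject_metrics <- function(recording, hyp, events,
                                    params = spectral_params(),
                                    subject_id = "S1", visit = "baseline",
                                    age = NA_real_, epochs = NULL) {
  if (is.null(epochs)) {
    epochs <- reject_artifacts(
      recording, segment_epochs(recording, hyp, "N2", params$epoch_length))
  }
  clean <- epochs[!epochs$flagged, , drop = FALSE]
  if (nrow(clean) == 0) stop("no artifact-free NREM2 epochs: metrics undefined")
  n2_spec <- compute_cross_spectra(recording, cbind(clean$start, clean$end), params)
  n2_pow <- band_sigma_power(n2_spec, params)
  n2_coh <- coherence_over_epochs(n2_spec, params)

  segs <- spindle_segments(events)
  if (nrow(segs) > 0) {
    sp_spec <- compute_cross_spectra(recording, segs, params)
    sp_pow <- band_sigma_power(sp_spec, params)
    sp_coh <- coherence_over_epochs(sp_spec, params)
  } else {
    sp_pow <- NA_real_
    sp_coh <- NA_real_
  }
  n2_min <- nrow(clean) * params$epoch_length / 60
  dens <- if (nrow(events)) nrow(events) / 2 / n2_min else 0  # per-channel average
  structure(data.frame(
    subject_id = subject_id, visit = visit, age = age,
    n2_sigma_power = n2_pow, n2_sigma_coherence = n2_coh,
    spindle_sigma_power = sp_pow, spindle_sigma_coherence = sp_coh,
    spindle_density = dens, n_epochs_used = nrow(clean),
    stringsAsFactors = FALSE
  ), class = c("subject_metrics", "data.frame"))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Asymptotic two-sample KS test of whether two metric distributions differ;
#' thin wrapper over [stats::ks.test()] returning the D statistic and
#' asymptotic p-value.
#'
#' @param a,b numeric vectors (each with at least 2 values).
#' @return List with `D` and `p_value`.
#' @export
ks_compare <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("both groups need >= 2 values")
  res <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(res$statistic), p_value = res$p.value)
}
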