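#' Subject-level parameters for synthetic sleep EEG
#'
#' Describes one simulated sleeper: background EEG level, spindle rate and
#' morphology, and the inter-channel (C3-C4) coherence of background and
#' spindle activity. Defaults emulate a middle-aged polysomnography cohort:
#' spindle density a little under two per NREM2 minute, spindle bursts five
#' times the background RMS, background coherence near 0.44 and spindle
#' coherence near 0.58 with a 0.04 decline between paired visits.
#'
#' @param subject_id identifier string.
#' @param age_baseline age in years at the first recording.
#' @param followup_interval years between paired visits (cohort convention:
#'   at least 3).
#' @param spindle_density spindle events per minute of NREM2 sleep (>= 0).
#' @param spindle_amplitude envelope peak of injected spindle bursts, uV.
#' @param spindle_coherence_baseline population C3-C4 magnitude coherence of
#'   spindle activity at baseline, in `[0, 1]`.
#' @param coherence_decline_per_visit drop in spindle coherence from baseline
#'   to follow-up (applied in [generate_paired_cohort()], floored at 0).
#' @param background_coherence C3-C4 coherence of the 1/f background, `[0, 1]`.
#' @param background_rms RMS amplitude of the background EEG, uV.
#' @return A list of class `subject_spec`.
#' @export
subject_spec <- function(subject_id = "S1",
                         age_baseline = 60,
                         followup_interval = 5,
                         spindle_density = 2,
                         spindle_amplitude = 50,
                         spindle_coherence_baseline = 0.58,
                         coherence_decline_per_visit = 0.04,
                         background_coherence = 0.44,
                         background_rms = 10) {
  coh <- c(spindle_coherence_baseline, coherence_decline_per_visit, background_coherence)
  if (any(coh < 0) || any(c(spindle_coherence_baseline, background_coherence) > 1)) {
    stop("coherence parameters must lie in [0, 1]")
  }
  if (spindle_density < 0) stop("spindle_density must be >= 0")
  if (spindle_amplitude < 0) stop("spindle_amplitude must be >= 0")
  if (background_rms <= 0) stop("background_rms must be positive")
  structure(list(
    subject_id = subject_id, age_baseline = age_baseline,
    followup_interval = followup_interval,
    spindle_density = spindle_density, spindle_amplitude = spindle_amplitude,
    spindle_coherence_baseline = spindle_coherence_baseline,
    coherence_decline_per_visit = coherence_decline_per_visit,
    background_coherence = background_coherence, background_rms = background_rms
  ), class = "subject_spec")
}

#' Cohort-level parameters for synthetic generation
#'
#' @param n_subjects number of subjects (>= 1).
#' @param seed master seed; every random quantity in the cohort derives from it.
#' @param recording_duration seconds of signal per visit.
#' @param sampling_rate Hz; home-PSG montages are typically 125 or 250 Hz.
#' @param effect_size_d standardized paired effect used by the metric-level
#'   generator [generate_paired_metrics()].
#' @param hypnogram_type `"cycling"` for full-night stage cycling via
#'   [generate_hypnogram()], or `"n2"` for condensed all-NREM2 recordings
#'   (fast benchmark cohorts: only NREM2 is analysed downstream anyway).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, seed = 1, recording_duration = 3600,
                        sampling_rate = 125, effect_size_d = 0,
                        hypnogram_type = c("cycling", "n2")) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (!sampling_rate %in% c(125, 250)) stop("sampling_rate must be 125 or 250 Hz")
  structure(list(
    n_subjects = as.integer(n_subjects), seed = as.integer(seed),
    recording_duration = recording_duration, sampling_rate = sampling_rate,
    effect_size_d = effect_size_d,
    hypnogram_type = match.arg(hypnogram_type)
  ), class = "cohort_spec")
}

# 1/f-shaped ("pink") noise with unit RMS, by spectral shaping of white
# noise. The amplitude profile is f^(-1/2), flattened below 0.5 Hz so that
# ultra-slow drift (removed later by the 0.3 Hz high-pass anyway) does not
# dominate the variance. Consumes the current RNG stream.
pink_noise <- function(n, fs) {
  if (n < 2) return(rnorm(n))
  white <- stats::rnorm(n)
  x <- stats::fft(white)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) * fs / n
  shape <- 1 / sqrt(pmax(f, 0.5))
  shape[1] <- 0
  out <- Re(stats::fft(x * shape, inverse = TRUE)) / n
  out / stats::sd(out)
}

# Low-frequency ("slow-wave") noise: 1/f-shaped below ~3 Hz with a steep
# roll-off above, unit RMS. Models the delta-band activity whose epoch-to-
# epoch waxing dominates the spectral variability of real NREM sleep.
# Consumes the current RNG stream.
slow_wave_noise <- function(n, fs) {
  if (n < 2) return(rnorm(n))
  white <- stats::rnorm(n)
  x <- stats::fft(white)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) * fs / n
  shape <- 1 / sqrt(pmax(f, 0.5)) / (1 + (f / 3)^4)
  shape[1] <- 0
  out <- Re(stats::fft(x * shape, inverse = TRUE)) / n
  out / stats::sd(out)
}

# Slowly varying log-normal amplitude envelope emulating drifting arousal
# level / electrode contact: Gaussian control points every `step` seconds,
# spline-interpolated to sample rate, exp() of sd*log_sd. Consumes the
# current RNG stream.
slow_amplitude_envelope <- function(n, fs, log_sd = 0.15, step = 30) {
  k <- max(4, ceiling(n / fs / step) + 2)
  ctrl <- stats::rnorm(k)
  g <- stats::spline(x = seq(0, by = step * fs, length.out = k), y = ctrl,
                     xout = seq_len(n) - 1)$y
  exp(log_sd * g)
}

#' Generate a synthetic hypnogram
#'
#' Builds a night of 30-s epochs from fixed-order sleep cycles
#' (W, then repeated N1 - N2 - N3 - N2 - R blocks with occasional brief
#' awakenings) with gamma-distributed stage durations. The generator aims for
#' realistic NREM2 coverage, not full sleep-architecture realism: under
#' defaults roughly half of the sleep epochs are N2.
#'
#' @param duration recording duration in seconds (>= 0); truncated to whole
#'   30-s epochs.
#' @param seed integer seed; output is deterministic given `(duration, seed)`.
#' @param mean_minutes named numeric vector of mean stage-block durations in
#'   minutes for `wake_onset`, `N1`, `N2`, `N3`, `N2b`, `R`, `wake_brief`.
#' @return A [hypnogram()].
#' @export
generate_hypnogram <- function(duration, seed = 1,
                               mean_minutes = c(wake_onset = 10, N1 = 4, N2 = 22,
                                                N3 = 15, N2b = 8, R = 16,
                                                wake_brief = 2)) {
  if (duration < 0) stop("duration must be >= 0")
  n_epochs <- floor(duration / 30)
  if (n_epochs == 0) return(hypnogram(character(0)))
  local_rng(derive_seed(seed, "hypnogram"), {
    draw <- function(mean_min) {
      max(1L, round(stats::rgamma(1, shape = 4, scale = mean_min / 4) * 2))  # epochs
    }
    stages <- rep("W", draw(mean_minutes[["wake_onset"]]))
    cycle <- c(N1 = "N1", N2 = "N2", N3 = "N3", N2b = "N2", R = "R")
    while (length(stages) < n_epochs) {
      for (blk in names(cycle)) {
        stages <- c(stages, rep(cycle[[blk]], draw(mean_minutes[[blk]])))
      }
      if (stats::runif(1) < 0.5) {
        stages <- c(stages, rep("W", draw(mean_minutes[["wake_brief"]])))
      }
    }
    hypnogram(stages[seq_len(n_epochs)])
  })
}

#' Synthesize a two-channel NREM2 sleep-EEG recording with known spindles
#'
#' The background on each channel is 1/f-shaped noise built from a shared
#' source (weight `sqrt(background_coherence)`) plus an independent private
#' source, scaled to `background_rms`. During N2 epochs, spindle events arrive
#' as a Poisson process at `spindle_density`, with duration ~ Uniform(0.5, 2) s
#' and carrier ~ Uniform(13, 14) Hz; each event is a Hann-windowed sinusoid of
#' envelope peak `spindle_amplitude` injected into both channels, with the C4
#' copy phase-shifted by a per-event offset delta ~ Normal(0, -2 log(rho)),
#' where `rho` is the spindle coherence. The epoch-averaged coherence of a
#' pure carrier pair is `|E[exp(i delta)]| = exp(-var/2) = rho`, so the
#' population C3-C4 coherence over spindle segments is `rho` by construction
#' while the envelope amplitude stays exactly `spindle_amplitude` on both
#' channels. Every injected event is returned as ground truth.
#'
#' Background and event randomness use separate seed streams derived from
#' `seed`, so e.g. a zero-amplitude synthesis has exactly the background of a
#' zero-density one.
#'
#' @param spec a [subject_spec()]; `spindle_coherence` below overrides which
#'   visit's coherence applies.
#' @param hyp a [hypnogram()] covering the recording.
#' @param seed integer seed.
#' @param fs sampling rate in Hz.
#' @param spindle_coherence C3-C4 coherence of the injected spindles; defaults
#'   to `spec$spindle_coherence_baseline`.
#' @return List with `recording` (an [eeg_recording()] with channels C3, C4)
#'   and `ground_truth`: a data frame with columns `channel`, `start`, `end`
#'   (half-open, seconds) and `carrier_hz`, two rows (C3 and C4) per event.
#' @export
synthesize_recording <- function(spec, hyp, seed = 1, fs = 125,
                                 spindle_coherence = spec$spindle_coherence_baseline) {
  stopifnot(inherits(spec, "subject_spec"), inherits(hyp, "hypnogram"))
  dur <- length(hyp) * attr(hyp, "epoch_s")
  if (dur <= 0) stop("hypnogram must cover a positive recording duration")
  n <- round(dur * fs)

  bg <- local_rng(derive_seed(seed, "background"), {
    w <- spec$background_coherence
    mix <- function(shared, private) sqrt(w) * shared + sqrt(1 - w) * private
    # broadband 1/f component plus an independently waxing slow-wave
    # component; both nonstationarities are shared across channels (they
    # model global arousal-level drift) so coherence is untouched. Real
    # sleep EEG is far from epoch-stationary, and the artifact screen
    # downstream relies on realistic between-epoch variability.
    shared_p <- pink_noise(n, fs)
    shared_s <- slow_wave_noise(n, fs)
    p3 <- pink_noise(n, fs); p4 <- pink_noise(n, fs)
    s3 <- slow_wave_noise(n, fs); s4 <- slow_wave_noise(n, fs)
    env_b <- slow_amplitude_envelope(n, fs, log_sd = 0.15)
    env_s <- slow_amplitude_envelope(n, fs, log_sd = 0.4)
    c3 <- mix(shared_p, p3) * env_b + 0.8 * mix(shared_s, s3) * env_s
    c4 <- mix(shared_p, p4) * env_b + 0.8 * mix(shared_s, s4) * env_s
    list(c3 = c3 / stats::sd(c3) * spec$background_rms,
         c4 = c4 / stats::sd(c4) * spec$background_rms)
  })
  x3 <- bg$c3
  x4 <- bg$c4

  n2 <- stage_intervals(hyp, "N2")
  events <- local_rng(derive_seed(seed, "events"), {
    ev <- list()
    rho <- spindle_coherence
    for (r in seq_len(nrow(n2))) {
      run_min <- (n2[r, 2] - n2[r, 1]) / 60
      k <- stats::rpois(1, spec$spindle_density * run_min)
      if (k == 0) next
      for (i in seq_len(k)) {
        d <- stats::runif(1, 0.5, 2)
        if (n2[r, 2] - n2[r, 1] <= d) next
        s <- stats::runif(1, n2[r, 1], n2[r, 2] - d)
        carrier <- stats::runif(1, 13, 14)
        ph <- stats::runif(1, 0, 2 * pi)
        delta <- if (rho <= 0) stats::runif(1, 0, 2 * pi) else
          stats::rnorm(1, 0, sqrt(-2 * log(min(rho, 1))))
        ev[[length(ev) + 1]] <- list(start = s, dur = d, carrier = carrier,
                                     ph = ph, delta = delta)
      }
    }
    ev
  })

  gt <- data.frame(channel = character(0), start = numeric(0), end = numeric(0),
                   carrier_hz = numeric(0), stringsAsFactors = FALSE)
  if (length(events) && spec$spindle_amplitude >= 0) {
    A <- spec$spindle_amplitude
    for (e in events) {
      i0 <- floor(e$start * fs) + 1
      m <- round(e$dur * fs)
      if (m < 2 || i0 + m - 1 > n) next
      tt <- (seq_len(m) - 1) / fs
      hann <- 0.5 * (1 - cos(2 * pi * seq_len(m) / (m + 1)))
      wav3 <- A * hann * sin(2 * pi * e$carrier * tt + e$ph)
      wav4 <- A * hann * sin(2 * pi * e$carrier * tt + e$ph + e$delta)
      idx <- i0:(i0 + m - 1)
      x3[idx] <- x3[idx] + wav3
      x4[idx] <- x4[idx] + wav4
      gt <- rbind(gt, data.frame(channel = c("C3", "C4"),
                                 start = (i0 - 1) / fs, end = (i0 - 1 + m) / fs,
                                 carrier_hz = e$carrier, stringsAsFactors = FALSE))
    }
  }
  gt <- gt[order(gt$channel, gt$start), , drop = FALSE]
  rownames(gt) <- NULL
  list(
    recording = eeg_recording(cbind(C3 = x3, C4 = x4), fs = fs),
    ground_truth = gt
  )
}

#' Generate a paired baseline/follow-up synthetic cohort
#'
#' Per-subject parameters are jittered around the template (log-normal jitter
#' with 15% coefficient of variation on density and amplitude, Gaussian
#' +/- 0.03 on the coherences, ages Normal(template, 8) truncated at 40,
#' follow-up intervals Uniform(3, 8) years). The same jittered subject
#' parameters apply to both visits, with two exceptions. First, each visit's
#' spindle and background coherences receive independent night-to-night
#' jitter (`visit_jitter_sd`), emulating the state and electrode-placement
#' variability of recordings taken years apart -- without it, paired metric
#' noise would be pure estimator noise, which real longitudinal designs never
#' enjoy. Second, the only systematic visit difference is the spindle
#' coherence, which drops by `coherence_decline_per_visit` (floored at 0) at
#' follow-up. Fully reproducible from `cohort$seed`.
#'
#' @param cohort a [cohort_spec()].
#' @param template a [subject_spec()] giving population-level parameters.
#' @param visit_jitter_sd SD of the per-visit Gaussian jitter applied to the
#'   spindle and background coherences (default 0.04).
#' @return List of length `n_subjects`; each element has `spec` (the jittered
#'   [subject_spec()]), `age_baseline`, `age_followup`, and `baseline` /
#'   `followup` entries each holding `hypnogram`, `recording`, `ground_truth`
#'   and the realised spindle coherence `rho`.
#' @export
generate_paired_cohort <- function(cohort, template = subject_spec(),
                                   visit_jitter_sd = 0.04) {
  stopifnot(inherits(cohort, "cohort_spec"), inherits(template, "subject_spec"))
  clamp01 <- function(x) min(0.98, max(0.02, x))
  out <- vector("list", cohort$n_subjects)
  for (i in seq_len(cohort$n_subjects)) {
    sid <- sprintf("S%03d", i)
    sseed <- derive_seed(cohort$seed, "subject", i)
    pars <- local_rng(derive_seed(sseed, "params"), {
      list(
        density = template$spindle_density * exp(stats::rnorm(1, 0, 0.15)),
        amplitude = template$spindle_amplitude * exp(stats::rnorm(1, 0, 0.15)),
        rho_sp = clamp01(template$spindle_coherence_baseline + stats::rnorm(1, 0, 0.03)),
        rho_bg = clamp01(template$background_coherence + stats::rnorm(1, 0, 0.03)),
        age = max(40, stats::rnorm(1, template$age_baseline, 8)),
        interval = stats::runif(1, 3, 8),
        night = stats::rnorm(4, 0, visit_jitter_sd)  # sp/bg x baseline/followup
      )
    })
    spec_i <- subject_spec(
      subject_id = sid, age_baseline = pars$age, followup_interval = pars$interval,
      spindle_density = pars$density, spindle_amplitude = pars$amplitude,
      spindle_coherence_baseline = pars$rho_sp,
      coherence_decline_per_visit = template$coherence_decline_per_visit,
      background_coherence = pars$rho_bg, background_rms = template$background_rms
    )
    make_visit <- function(visit, rho, rho_bg) {
      hseed <- derive_seed(sseed, visit, "hyp")
      hyp <- if (cohort$hypnogram_type == "n2") {
        hypnogram(rep("N2", floor(cohort$recording_duration / 30)))
      } else {
        generate_hypnogram(cohort$recording_duration, seed = hseed)
      }
      spec_v <- spec_i
      spec_v$background_coherence <- rho_bg
      syn <- synthesize_recording(spec_v, hyp, seed = derive_seed(sseed, visit, "sig"),
                                  fs = cohort$sampling_rate, spindle_coherence = rho)
      list(hypnogram = hyp, recording = syn$recording,
           ground_truth = syn$ground_truth, rho = rho, rho_background = rho_bg)
    }
    rho_b <- clamp01(pars$rho_sp + pars$night[1])
    rho_f <- clamp01(max(0, pars$rho_sp - template$coherence_decline_per_visit) + pars$night[2])
    bg_b <- clamp01(pars$rho_bg + pars$night[3])
    bg_f <- clamp01(pars$rho_bg + pars$night[4])
    out[[i]] <- list(
      subject_id = sid, spec = spec_i,
      age_baseline = pars$age, age_followup = pars$age + pars$interval,
      baseline = make_visit("baseline", rho_b, bg_b),
      followup = make_visit("followup", rho_f, bg_f)
    )
  }
  out
}

#' Fast metric-level paired cohort with a known effect size
#'
#' Bypasses signal synthesis entirely: draws per-subject paired metric values
#' whose baseline-minus-follow-up differences are Normal with mean `d` and
#' standard deviation 1, i.e. a paired Cohen's d of exactly `d` at the
#' population level. Used to exercise and calibrate the trial simulator.
#'
#' @param n number of subjects (>= 2).
#' @param d standardized paired effect size.
#' @param seed integer seed.
#' @return Data frame with columns `subject_id`, `baseline`, `followup`.
#' @export
generate_paired_metrics <- function(n, d, seed = 1) {
  if (n < 2) stop("n must be >= 2")
  local_rng(derive_seed(seed, "paired-metrics"), {
    base <- stats::rnorm(n)
    diffs <- stats::rnorm(n, mean = d, sd = 1)
    data.frame(subject_id = sprintf("S%05d", seq_len(n)),
               baseline = base, followup = base - diffs,
               stringsAsFactors = FALSE)
  })
}

#' Write ground-truth spindle events to TSV
#'
#' Columns: `subject_id`, `visit`, `channel`, `start_s`, `end_s`,
#' `carrier_hz`. Intervals are half-open, in seconds from recording start.
#'
#' @param gt ground-truth data frame from [synthesize_recording()].
#' @param path output path; `subject_id`, `visit` label the rows.
#' @param subject_id,visit identifiers recorded with each event.
#' @param append append to an existing file (no header)?
#' @return `path`, invisibly.
#' @export
write_ground_truth_tsv <- function(gt, path, subject_id = "S1", visit = "baseline",
                                   append = FALSE) {
  df <- data.frame(subject_id = rep(subject_id, nrow(gt)),
                   visit = rep(visit, nrow(gt)),
                   channel = gt$channel,
                   start_s = fmt_num(gt$start), end_s = fmt_num(gt$end),
                   carrier_hz = fmt_num(gt$carrier_hz), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     col.names = !append, append = append)
  invisible(path)
}
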