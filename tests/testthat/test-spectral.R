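test_that("multitaper spectra satisfy basic spectral identities", {
  fs <- 125
  rec <- sine_recording(13, 13)
  sp <- spindlepower:::compute_cross_spectra(rec, cbind(0, 10))
  expect_equal(Re(sp$sxy[, 1]), sp$sxx[, 1], tolerance = 1e-10)
  expect_lt(max(abs(Im(sp$sxy[, 1]))), 1e-10)

  # unit sinusoid: band-integrated sigma power A^2/2 within 5%
  expect_equal(band_sigma_power(sp), 0.5, tolerance = 0.05)

  # a 20 Hz tone leaks almost nothing into the sigma band
  rec20 <- sine_recording(20, 20)
  sp20 <- spindlepower:::compute_cross_spectra(rec20, cbind(0, 10))
  expect_lt(band_sigma_power(sp20), 0.02 * 0.5)

  # all-zero epochs give zero power
  silent <- sine_recording(0, 0)
  sps <- spindlepower:::compute_cross_spectra(silent, cbind(0, 10))
  expect_equal(band_sigma_power(sps), 0)

  expect_error(spindlepower:::compute_cross_spectra(rec, cbind(0, 0.2)), "too short")
})

test_that("integrated multitaper PSD recovers white-noise variance", {
  fs <- 125
  set.seed(14)
  n_ep <- 100
  x <- rnorm(n_ep * 10 * fs, sd = 3)
  rec <- eeg_recording(cbind(C3 = x, C4 = rnorm(n_ep * 10 * fs)), fs)
  sp <- spindlepower:::compute_cross_spectra(rec, epoch_grid(n_ep))
  total <- mean(2 * colSums(sp$sxx) * sp$df)
  expect_equal(total, 9, tolerance = 0.9)
})

test_that("epoch-averaged coherence behaves like a coherence", {
  fs <- 125
  set.seed(15)
  x <- spindlepower:::pink_noise(200 * 10 * fs, fs)
  same <- eeg_recording(cbind(C3 = x, C4 = x), fs)
  sp <- spindlepower:::compute_cross_spectra(same, epoch_grid(200))
  expect_equal(coherence_over_epochs(sp), 1, tolerance = 1e-6)

  flip <- eeg_recording(cbind(C3 = x, C4 = -x), fs)
  spf <- spindlepower:::compute_cross_spectra(flip, epoch_grid(200))
  expect_equal(coherence_over_epochs(spf), 1, tolerance = 1e-6)

  indep <- eeg_recording(cbind(C3 = rnorm(200 * 10 * fs), C4 = rnorm(200 * 10 * fs)), fs)
  spi <- spindlepower:::compute_cross_spectra(indep, epoch_grid(200))
  expect_lt(coherence_over_epochs(spi), 0.15)

  # shared noise raises coherence, independent noise lowers it
  base <- mixed_noise_recording(0.5, 50, seed = 16)
  sp0 <- coherence_over_epochs(spindlepower:::compute_cross_spectra(base, epoch_grid(50)))
  set.seed(17)
  shared <- spindlepower:::pink_noise(50 * 10 * fs, fs)
  plus_shared <- eeg_recording(base$data + cbind(shared, shared), fs,
                               channels = c("C3", "C4"))
  sp_up <- coherence_over_epochs(spindlepower:::compute_cross_spectra(plus_shared, epoch_grid(50)))
  plus_indep <- eeg_recording(base$data + cbind(spindlepower:::pink_noise(50 * 10 * fs, fs),
                                                spindlepower:::pink_noise(50 * 10 * fs, fs)),
                              fs, channels = c("C3", "C4"))
  sp_dn <- coherence_over_epochs(spindlepower:::compute_cross_spectra(plus_indep, epoch_grid(50)))
  expect_gt(sp_up, sp0)
  expect_lt(sp_dn, sp0)
})

test_that("spindle segment union merges across channels", {
  empty <- data.frame(channel = character(0), start = numeric(0), end = numeric(0))
  expect_identical(nrow(spindle_segments(empty)), 0L)

  ev <- data.frame(channel = c("C3", "C4"), start = c(10, 10.5), end = c(11, 11.5))
  segs <- spindle_segments(ev)
  expect_equal(unname(segs), matrix(c(10, 11.5), ncol = 2))

  disj <- data.frame(channel = c("C3", "C3", "C4"), start = c(1, 5, 9),
                     end = c(2, 6, 10))
  expect_identical(nrow(spindle_segments(disj)), 3L)
})

test_that("subject metrics contrast spindle segments with all of NREM2", {
  hyp <- n2_hypnogram(10)
  syn <- default_study_recording(seed = 19)
  rec <- bandpass(syn$recording)
  ev <- detect_spindles(rec, hyp)
  m <- compute_subject_metrics(rec, hyp, ev, subject_id = "X", visit = "baseline")
  expect_gt(m$spindle_sigma_power / m$n2_sigma_power, 5)
  expect_true(m$n2_sigma_coherence >= 0 && m$n2_sigma_coherence <= 1)
  expect_identical(m$n_epochs_used, 60L)

  # coherent spindles on weakly coherent background separate the coherences
  spec <- subject_spec(spindle_coherence_baseline = 0.9, background_coherence = 0.3,
                       spindle_density = 3)
  syn2 <- synthesize_recording(spec, hyp, seed = 23)
  rec2 <- bandpass(syn2$recording)
  m2 <- compute_subject_metrics(rec2, hyp, detect_spindles(rec2, hyp))
  expect_gt(m2$spindle_sigma_coherence, m2$n2_sigma_coherence)

  # no events: spindle metrics missing, never zero
  m0 <- compute_subject_metrics(rec, hyp,
                                data.frame(channel = character(0),
                                           start = numeric(0), end = numeric(0)))
  expect_true(is.na(m0$spindle_sigma_power) && is.na(m0$spindle_sigma_coherence))
  expect_true(is.finite(m0$n2_sigma_power))

  expect_error(compute_subject_metrics(rec, hypnogram(rep("W", 20)), ev),
               "no artifact-free")
})

test_that("NREM2 sigma power is invariant to epoch order", {
  syn <- default_study_recording(seed = 25, minutes = 5)
  iv <- epoch_grid(30)
  sp1 <- spindlepower:::compute_cross_spectra(syn$recording, iv)
  sp2 <- spindlepower:::compute_cross_spectra(syn$recording, iv[sample(30), ])
  expect_equal(band_sigma_power(sp1), band_sigma_power(sp2))
  expect_equal(coherence_over_epochs(sp1), coherence_over_epochs(sp2))
})

test_that("KS comparison matches a brute-force ECDF oracle", {
  expect_error(ks_compare(1, 1:5), ">= 2")
  same <- c(1, 2, 3, 4)
  expect_equal(ks_compare(same, same)$D, 0)
  expect_equal(ks_compare(1:10, 101:110)$D, 1)

  set.seed(33)
  a <- rnorm(20); b <- rnorm(20, 0.5)
  grid <- sort(c(a, b))
  oracle <- max(abs(vapply(grid, function(g) mean(a <= g) - mean(b <= g), numeric(1))))
  res <- ks_compare(a, b)
  expect_equal(res$D, oracle)
  expect_equal(res$p_value,
               suppressWarnings(stats::ks.test(a, b, exact = FALSE)$p.value))
})
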