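test_that("Morlet wavelet power is selective for its centre frequency", {
  fs <- 125
  expect_error(cwt_power(rnorm(10), fs), "too short")
  t <- seq(1 / fs, 20, by = 1 / fs)

  z <- cwt_power(rep(0, length(t)), fs)
  expect_true(all(z == 0))

  p <- cwt_power(sin(2 * pi * 13.5 * t), fs)
  e <- attr(p, "edge_samples")
  core <- p[(e + 1):(length(p) - e)]
  expect_lt(max(abs(core / mean(core) - 1)), 0.05)   # constant within 5%

  p5 <- cwt_power(sin(2 * pi * 5 * t), fs)
  core5 <- p5[(e + 1):(length(p5) - e)]
  expect_lt(mean(core5), 0.01 * mean(core))
})

test_that("event thresholding applies merge and duration rules exactly", {
  fs <- 125
  pars <- detector_params(smoothing_window = 1 / fs)  # no smoothing: crisp edges
  run <- function(spans, dur = 60, level = 100) {
    # baseline power 1 with supra-threshold plateaus at `level`
    p <- rep(1, dur * fs)
    for (s in spans) p[(round(s[1] * fs) + 1):round(s[2] * fs)] <- level
    detect_events(p, fs, params = pars)
  }
  # constant series never crosses 4.5x its own mean
  expect_identical(nrow(detect_events(rep(3.7, 1000), fs, params = pars)), 0L)

  # two 0.6-s runs separated by 0.4 s merge into one 1.6-s event
  ev <- run(list(c(10, 10.6), c(11, 11.6)))
  expect_identical(nrow(ev), 1L)
  expect_equal(unname(ev[1, 2] - ev[1, 1]), 1.6, tolerance = 0.02)

  # runs separated by >= merge gap stay separate
  ev2 <- run(list(c(10, 10.6), c(11.2, 11.8)))
  expect_identical(nrow(ev2), 2L)

  # too-short and too-long runs are rejected
  expect_identical(nrow(run(list(c(10, 10.3)))), 0L)
  expect_identical(nrow(run(list(c(10, 13.5)), dur = 90)), 0L)

  # boundary run must contain a supra-core sample
  p <- rep(1, 60 * fs)
  p[(10 * fs):(11 * fs)] <- 3  # above boundary 2x mean, below core 4.5x
  expect_identical(nrow(detect_events(p, fs, params = pars)), 0L)

  expect_error(detect_events(rep(1, 100), fs, baseline_mask = rep(FALSE, 100),
                             params = pars), "empty baseline")
  expect_error(detect_events(c(-1, rep(1, 99)), fs, params = pars), "nonnegative")
})

test_that("quality score measures sigma enrichment against baseline", {
  fs <- 125
  set.seed(31)
  seg <- spindlepower:::pink_noise(10 * fs, fs)
  x <- rep(seg, 6)  # event identical to every baseline epoch
  q0 <- quality_score(x, fs, c(10, 20), cbind((0:5) * 10, (1:6) * 10))
  expect_equal(q0, 0, tolerance = 1e-9)

  # sigma burst on broadband baseline scores positive, 5 Hz burst negative
  t <- seq(1 / fs, 10, by = 1 / fs)
  burst13 <- x
  burst13[(12.5 * fs):(14 * fs)] <- 5 * sin(2 * pi * 13.5 * t[1:(1.5 * fs + 1)])
  expect_gt(quality_score(burst13, fs, c(12.5, 14), cbind(c(0, 30), c(10, 40))), 0)
  burst5 <- x
  burst5[(12.5 * fs):(14 * fs)] <- 5 * sin(2 * pi * 5 * t[1:(1.5 * fs + 1)])
  expect_lt(quality_score(burst5, fs, c(12.5, 14), cbind(c(0, 30), c(10, 40))), 0)
  expect_error(quality_score(rep(0, 1000), fs, c(0, 2), cbind(2, 4)), "zero")
})

test_that("detector recovers injected spindles and ignores quiet recordings", {
  # background with no injected events: under the single-threshold rule
  # nothing sustains 4.5x the mean power for half a second, and even with
  # the boundary-extent rule chance detections stay rare
  rec0 <- bandpass(mixed_noise_recording(0.4, 30, seed = 21))
  rec0$data <- rec0$data * 5
  single <- detector_params(threshold_multiplier = 4.5, boundary_multiplier = 4.5)
  expect_identical(nrow(detect_spindles(rec0, n2_hypnogram(5), single)), 0L)
  expect_lte(nrow(detect_spindles(rec0, n2_hypnogram(5))), 2L)
  expect_error(detect_spindles(eeg_recording(cbind(A = 1:300), 10), n2_hypnogram(1)),
               "C3 and C4")

  scores <- lapply(1:3, function(s) {
    syn <- default_study_recording(seed = s)
    ev <- detect_spindles(bandpass(syn$recording), n2_hypnogram(10))
    list(score = score_detections(ev, syn$ground_truth), events = ev)
  })
  sens <- mean(vapply(scores, function(x) x$score$sensitivity, numeric(1)))
  expect_gte(sens, 0.9)
  for (x in scores) {
    ev <- x$events
    expect_true(all(ev$duration >= 0.5 & ev$duration <= 3))
    expect_true(all(ev$quality_q >= 0))
    # within a channel: no overlaps, gaps at least merge_gap
    for (ch in c("C3", "C4")) {
      e <- ev[ev$channel == ch, ]
      if (nrow(e) > 1) expect_true(all(e$start[-1] - e$end[-nrow(e)] >= 0.5))
    }
  }
})

test_that("detection count is monotone non-increasing in the core threshold", {
  syn <- default_study_recording(seed = 8)
  rec <- bandpass(syn$recording)
  hyp <- n2_hypnogram(10)
  counts <- vapply(c(3.5, 4.5, 5.5), function(th) {
    nrow(detect_spindles(rec, hyp, detector_params(threshold_multiplier = th)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("spindle density is count over minutes, per channel and pooled", {
  expect_equal(spindle_density(0, 60)$density, 0)
  expect_equal(spindle_density(120, 60)$density, 2)
  ev <- data.frame(channel = rep(c("C3", "C4"), each = 3),
                   start = 1:6, end = 2:7)
  d <- spindle_density(ev, 3)
  expect_equal(d$density[d$channel == "C3"], 1)
  expect_equal(d$density[d$channel == "all"], 2)
  expect_error(spindle_density(ev, 0), "positive")
})
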