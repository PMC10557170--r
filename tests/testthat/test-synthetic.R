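test_that("hypnogram generator handles edge cases and is reproducible", {
  expect_length(generate_hypnogram(0, seed = 1), 0)
  expect_error(generate_hypnogram(-10, seed = 1), "duration")
  h1 <- generate_hypnogram(4 * 3600, seed = 42)
  h2 <- generate_hypnogram(4 * 3600, seed = 42)
  expect_identical(unclass(h1), unclass(h2))
  expect_length(h1, 480)
  expect_true(all(unclass(h1) %in% c("W", "N1", "N2", "N3", "R")))
})

test_that("overnight hypnograms give realistic NREM2 coverage", {
  n2 <- 0; sleep <- 0
  for (s in 1:50) {
    st <- unclass(generate_hypnogram(8 * 3600, seed = s))
    n2 <- n2 + sum(st == "N2")
    sleep <- sleep + sum(st != "W")
  }
  frac <- n2 / sleep
  expect_gt(frac, 0.35)
  expect_lt(frac, 0.60)
  # every single night keeps at least 20% of sleep in N2
  each <- vapply(1:50, function(s) {
    st <- unclass(generate_hypnogram(8 * 3600, seed = s))
    sum(st == "N2") / sum(st != "W")
  }, numeric(1))
  expect_true(all(each >= 0.20))
})

test_that("recording synthesis honours trivial generator contracts", {
  hyp <- n2_hypnogram(2)
  none <- synthesize_recording(subject_spec(spindle_density = 0), hyp, seed = 5)
  expect_identical(nrow(none$ground_truth), 0L)

  flat <- synthesize_recording(subject_spec(spindle_amplitude = 0), hyp, seed = 5)
  expect_equal(flat$recording$data, none$recording$data)

  expect_error(synthesize_recording(subject_spec(), hypnogram(character(0)), seed = 1),
               "positive")
  expect_error(subject_spec(spindle_density = -1), "density")
  expect_error(subject_spec(background_coherence = 1.2), "coherence")
})

test_that("injected spindles stay inside N2 and arrive at the Poisson rate", {
  hyp <- generate_hypnogram(2 * 3600, seed = 3)
  syn <- synthesize_recording(subject_spec(), hyp, seed = 3)
  n2 <- stage_intervals(hyp, "N2")
  gt <- syn$ground_truth
  for (i in seq_len(nrow(gt))) {
    inside <- any(gt$start[i] >= n2[, 1] & gt$end[i] <= n2[, 2])
    expect_true(inside)
  }
  expect_true(all(gt$end - gt$start >= 0.5 & gt$end - gt$start <= 2))
  expect_true(all(gt$carrier_hz >= 13 & gt$carrier_hz <= 14))

  # 30 min of pure N2 at 2/min: lambda = 60 events; average over 10 seeds
  counts <- vapply(1:10, function(s) {
    g <- synthesize_recording(subject_spec(), n2_hypnogram(30), seed = s)$ground_truth
    nrow(g) / 2  # two rows (C3, C4) per event
  }, numeric(1))
  expect_lt(abs(mean(counts) - 60), 3 * sqrt(60 / 10))
})

test_that("spindle coherence rises monotonically with the rho parameter", {
  est <- vapply(c(0.2, 0.5, 0.9), function(rho) {
    syn <- synthesize_recording(
      subject_spec(spindle_density = 4, spindle_amplitude = 60),
      n2_hypnogram(10), seed = 77, spindle_coherence = rho)
    segs <- spindle_segments(syn$ground_truth)
    sp <- spindlepower:::compute_cross_spectra(syn$recording, segs)
    coherence_over_epochs(sp)
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("paired cohorts regenerate bit-identically and carry the decline", {
  cc <- cohort_spec(n_subjects = 3, seed = 9, recording_duration = 120,
                    hypnogram_type = "n2")
  a <- generate_paired_cohort(cc)
  b <- generate_paired_cohort(cc)
  expect_identical(a[[1]]$baseline$recording$data, b[[1]]$baseline$recording$data)
  expect_identical(a[[3]]$followup$ground_truth, b[[3]]$followup$ground_truth)

  # realised per-visit spindle coherences differ by the configured decline
  # on average (night-to-night jitter is mean zero)
  cc2 <- cohort_spec(n_subjects = 60, seed = 10, recording_duration = 30,
                     hypnogram_type = "n2")
  tpl <- subject_spec(coherence_decline_per_visit = 0.04, spindle_density = 0)
  coh <- generate_paired_cohort(cc2, tpl)
  drop <- vapply(coh, function(s) s$baseline$rho - s$followup$rho, numeric(1))
  expect_lt(abs(mean(drop) - 0.04), 3 * sd(drop) / sqrt(length(drop)))

  null <- generate_paired_cohort(cc2, subject_spec(coherence_decline_per_visit = 0,
                                                   spindle_density = 0))
  drop0 <- vapply(null, function(s) s$baseline$rho - s$followup$rho, numeric(1))
  expect_lt(abs(mean(drop0)), 3 * sd(drop0) / sqrt(length(drop0)))
})

test_that("metric-level paired generator has the stated moments", {
  expect_error(generate_paired_metrics(1, 0.5), ">= 2")
  tab <- generate_paired_metrics(1e5, 0.5, seed = 4)
  expect_identical(tab, generate_paired_metrics(1e5, 0.5, seed = 4))
  d <- tab$baseline - tab$followup
  expect_lt(abs(mean(d) - 0.5), 4 / sqrt(1e5))
  expect_lt(abs(sd(d) - 1), 0.02)
  d0 <- with(generate_paired_metrics(1e5, 0, seed = 8), baseline - followup)
  expect_lt(abs(mean(d0)), 4 / sqrt(1e5))
})
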