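test_that("paired t-test matches the direct formula and conventions", {
  x <- c(5, 6, 7, 8)
  r <- paired_t(x + c(1, 2, 3, 4), x)
  expect_equal(r$statistic, 3.872983, tolerance = 1e-6)
  expect_equal(r$p_value, 0.03046629, tolerance = 1e-6)
  tt <- t.test(x + c(1, 2, 3, 4), x, paired = TRUE)
  expect_equal(r$statistic, unname(tt$statistic))
  expect_equal(r$p_value, tt$p.value)

  expect_equal(paired_t(x, x)$p_value, 1)      # all-zero differences
  swap <- paired_t(x, x + c(1, 2, 3, 4))
  expect_equal(swap$statistic, -r$statistic)
  expect_equal(swap$p_value, r$p_value)

  expect_error(paired_t(1:3, 1:4), "mismatch")
  expect_error(paired_t(1, 2), "at least 2")
})

test_that("OLS age trend recovers built-in declines", {
  ages <- c(40, 50, 60, 70)
  fit <- suppressWarnings(ols_age_trend(ages, 2 - 0.01 * ages))
  expect_equal(fit$slope, -0.01, tolerance = 1e-12)
  expect_equal(suppressWarnings(ols_age_trend(ages, rep(0.5, 4))$slope), 0, tolerance = 1e-12)
  expect_error(ols_age_trend(rep(50, 4), 1:4), "variance")

  # CI covers the true slope in >= 90% of repetitions
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    a <- runif(40, 40, 80)
    y <- 1 - 0.004 * a + rnorm(40, 0, 0.05)
    ci <- ols_age_trend(a, y)$ci
    hits <- hits + (ci[1] <= -0.004 && -0.004 <= ci[2])
  }
  expect_gte(hits, 90)
})

test_that("closed-form paired power is a valid noncentral-t power", {
  expect_equal(closed_form_paired_power(0, 50), 0.05, tolerance = 1e-10)
  pw <- closed_form_paired_power(0.5, c(10, 20, 40, 80, 160))
  expect_true(all(diff(pw) > 0))
  expect_gt(closed_form_paired_power(0.5, 500), 0.9999)
  # frozen Monte-Carlo oracle (1e6 replicates): power(d=0.5, n=34) = 0.8074
  expect_equal(closed_form_paired_power(0.5, 34), 0.807368, tolerance = 0.005)
  expect_error(closed_form_paired_power(0.5, 1), ">= 2")
})

test_that("subsampled trial power agrees with the noncentral-t oracle", {
  des <- trial_design(reps = 10000, seed = 5)
  tab <- generate_paired_metrics(5000, 0.5, seed = 6)
  est <- estimate_power(tab, 45, des)
  d_real <- with(tab, mean(baseline - followup) / sd(baseline - followup))
  expect_lt(abs(est$power - closed_form_paired_power(d_real, 45)), 2 * est$se + 0.005)

  big <- estimate_power(generate_paired_metrics(500, 2, seed = 7), 20, des)
  expect_gt(big$power, 0.999)

  expect_error(estimate_power(generate_paired_metrics(30, 0.5), 50, des), "exceeds")

  # missing metrics are excluded, not imputed
  tab$followup[1:10] <- NA
  est2 <- estimate_power(tab, 45, des)
  expect_identical(attr(est2, "n_excluded"), 10L)
})

test_that("power curves are monotone, flat under the null, and ordered by effect", {
  des <- trial_design(n_grid = seq(10, 60, 10), reps = 4000, seed = 11)
  null <- power_curve(generate_paired_metrics(2000, 0, seed = 12), des, "null")
  expect_true(all(abs(null$power - 0.05) < 3 * pmax(null$mc_se, 1e-3) + 0.01))

  cv <- power_curve(generate_paired_metrics(2000, 0.4, seed = 13), des, "d04")
  expect_true(all(diff(cv$power) > -2 * (cv$mc_se[-1] + cv$mc_se[-nrow(cv)])))

  cv2 <- power_curve(generate_paired_metrics(2000, 0.6, seed = 13), des, "d06")
  expect_true(all(cv2$power >= cv$power - 2 * (cv2$mc_se + cv$mc_se)))

  expect_warning(power_curve(generate_paired_metrics(40, 0.4, seed = 14), des),
                 "truncated")
})

test_that("minimal sample size reads the curve correctly", {
  fake <- structure(data.frame(n = c(10, 20), power = c(0.2, 0.96),
                               mc_se = c(0.01, 0.01), reps = 2000),
                    design = trial_design(target_power = 0.95),
                    metric_name = "fake",
                    class = c("power_curve", "data.frame"))
  expect_identical(min_sample_size(fake), 20)
  fake$power <- c(0.2, 0.5)
  expect_error(min_sample_size(fake), "insufficient grid")

  # analytic inversion: closed-form curve for d = 0.465 crosses 0.95 at n = 63
  grid <- 2:200
  curve <- structure(data.frame(n = grid,
                                power = closed_form_paired_power(0.465, grid),
                                mc_se = 0, reps = 0),
                     design = trial_design(target_power = 0.95),
                     metric_name = "analytic",
                     class = c("power_curve", "data.frame"))
  expect_identical(min_sample_size(curve), 63L)
})

test_that("trial design validates its invariants", {
  expect_error(trial_design(alpha = 0), "alpha")
  expect_error(trial_design(n_grid = c(10, 10, 20)), "ascending")
  expect_error(trial_design(reps = 10), "reps")
})
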