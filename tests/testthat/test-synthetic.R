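test_that("generators are pure functions of their configs", {
  cfg <- cohort_config(n_subjects = 20, design = "repeated", seed = 21)
  expect_identical(sample_cohort(cfg), sample_cohort(cfg))
  scfg <- signal_config(duration_s = 120, seed = 22)
  expect_identical(simulate_rr(scfg)$peak_times, simulate_rr(scfg)$peak_times)
  co <- sample_cohort(cfg)
  eff <- effect_config("rmssd")
  expect_identical(simulate_features(co, eff, 5), simulate_features(co, eff, 5))
})

test_that("cohorts match the published demographic ranges", {
  meds <- vapply(1:50, function(i) {
    co <- sample_cohort(cohort_config(n_subjects = 290, seed = i))
    c(median(co$age), median(co$bmi))
  }, numeric(2))
  expect_gte(mean(meds[1, ] >= 28 & meds[1, ] <= 34), 0.95)
  expect_true(all(meds[2, ] > 20.7 & meds[2, ] < 25.9))
  co <- sample_cohort(cohort_config(n_subjects = 290, seed = 1))
  expect_true(all(co$age >= 18 & co$age <= 45))
  expect_true(all(co$bmi > 15))
  expect_true(all(co$ga >= 12 & co$ga <= 42))
})

test_that("repeated design follows the visit schedule with dropout", {
  co <- sample_cohort(cohort_config(n_subjects = 29, design = "repeated",
                                    dropout_prob = 0, seed = 2))
  expect_equal(as.integer(table(co$subject_id)), rep(10L, 29))
  cod <- sample_cohort(cohort_config(n_subjects = 200, design = "repeated",
                                     dropout_prob = 0.2, seed = 3))
  per <- table(cod$subject_id)
  expect_equal(mean(per), 8, tolerance = 0.05)
  expect_true(all(per >= 1))
})

test_that("feature generator obeys its variance algebra", {
  eff <- effect_config("rmssd", icc = 0.5, total_var = 0.2)
  expect_equal(eff$sigma2_b + eff$sigma2_e, 0.2)
  expect_equal(eff$icc, 0.5)

  # zero variances: y exactly linear in X
  co <- balanced_cohort(10, seed = 4)
  eff0 <- effect_config("rmssd", icc = 0, total_var = 1e-300)
  fr <- simulate_features(co, eff0, seed = 5)
  X <- as.matrix(fr[names(eff0$beta)])
  expect_equal(fr$y, eff0$beta0 + drop(X %*% eff0$beta), tolerance = 1e-6)

  # subject-mean variance ~ sigma2_b + sigma2_e / n_rep at 200 subjects
  co2 <- balanced_cohort(200, seed = 6)
  eff2 <- effect_config("rmssd", icc = 0.5, total_var = 0.2,
                        beta = c(age = 0, bmi = 0, ga = 0, parity = 0,
                                 median_hr = 0, median_br = 0), beta0 = 0)
  fr2 <- simulate_features(co2, eff2, seed = 7)
  vs <- var(tapply(fr2$y, fr2$subject_id, mean))
  expect_equal(vs, eff2$sigma2_b + eff2$sigma2_e / 8, tolerance = 0.3)
})

test_that("RR generator hits its beat-count and recovery targets", {
  ps <- simulate_rr(signal_config(duration_s = 600, base_rr_ms = 800,
                                  rsa_amp_ms = 0, lf_amp_ms = 0,
                                  noise_sd_ms = 0, seed = 8))
  expect_lte(abs(length(ps$peak_times) - 750), 2)
  t <- build_tachogram(ps)
  expect_true(all(abs(t$rr_ms - 800) < 1e-9))
  expect_error(signal_config(base_rr_ms = 300), "base_rr_ms")
  expect_error(signal_config(br_hz = 0.6), "br_hz")
  expect_error(signal_config(rsa_amp_ms = 500, lf_amp_ms = 400), "amplitudes")
})

test_that("artifact injection is seeded, counted, and detectable", {
  ps <- simulate_rr(signal_config(duration_s = 800, seed = 9))
  expect_identical(inject_artifacts(ps, 0.05, 1)$corrupted,
                   inject_artifacts(ps, 0.05, 1)$corrupted)
  art0 <- inject_artifacts(ps, 0, 1)
  expect_identical(art0$peaks$peak_times, ps$peak_times)
  expect_equal(sum(art0$corrupted), 0)

  n <- length(ps$peak_times)
  art <- inject_artifacts(ps, 0.05, 2)
  expect_lt(abs(art$n_events - 0.05 * (n - 2)),
            4 * sqrt(0.05 * 0.95 * (n - 2)))
  expect_error(inject_artifacts(ps, 0.5, 1), "rate")

  # >= 90% of truth-masked intervals are caught by the cleaning cascade
  t <- clean_tachogram(build_tachogram(art$peaks))
  expect_gte(mean(t$flag[art$corrupted] != "VALID"), 0.9)
})

test_that("signal-to-feature path responds monotonically to modulation", {
  amps <- seq(10, 45, length.out = 8)
  out <- vapply(amps, function(a) {
    t <- clean_tachogram(build_tachogram(simulate_rr(
      signal_config(duration_s = 240, rsa_amp_ms = a, seed = 77))))
    c(rmssd(t), sdnn(nn_intervals(t)))
  }, numeric(2))
  expect_gt(cor(amps, out[1, ], method = "spearman"), 0.95)
  expect_gt(cor(amps, out[2, ], method = "spearman"), 0.9)
})
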