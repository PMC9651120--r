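test_that("tachogram construction differences peak times and validates input", {
  t <- build_tachogram(rpeak_series(c(0.0, 0.8, 1.6)))
  expect_equal(t$rr_ms, c(800, 800))
  expect_equal(t$onset_s, c(0.0, 0.8))
  expect_equal(t$flag, c("VALID", "VALID"))

  t1 <- build_tachogram(rpeak_series(c(0.0, 0.5)))
  expect_equal(t1$rr_ms, 500)

  expect_error(rpeak_series(c(0.0, 0.8, 0.7)), "increasing")
  expect_error(build_tachogram(rpeak_series(0.5)), "at least 2")

  # round trip: cumulative sums recover the peak times
  pt <- c(0, cumsum(runif(50, 0.6, 1.0)))
  t2 <- build_tachogram(rpeak_series(pt))
  expect_equal(pt[1] + cumsum(c(0, t2$rr_ms)) / 1000, pt, tolerance = 1e-9)
})

test_that("range rule rejects outside 0.4-2 s with inclusive bounds", {
  t <- flag_range(toy_tachogram(c(850, 300, 860)))
  expect_equal(t$flag, c("VALID", "REJECT_RANGE", "VALID"))
  expect_equal(flag_range(toy_tachogram(c(400, 2000)))$flag,
               c("VALID", "VALID"))
  expect_equal(flag_range(toy_tachogram(c(2500)))$flag, "REJECT_RANGE")
  expect_error(flag_range(toy_tachogram(800), lo_ms = 900, hi_ms = 800))
})

test_that("delta rule is strict at 20% and references the last accepted interval", {
  t <- flag_delta(flag_range(toy_tachogram(c(800, 1000, 990))))
  expect_equal(t$flag[1:2], c("VALID", "REJECT_DELTA"))
  expect_equal(flag_delta(flag_range(toy_tachogram(c(800, 900))))$flag,
               c("VALID", "VALID"))
  # exactly 20% accepted (strict "more than")
  expect_equal(flag_delta(flag_range(toy_tachogram(c(800, 960))))$flag,
               c("VALID", "VALID"))
  # after a rejection the reference does not advance: 990 vs 800 is >20%
  expect_equal(t$flag[3], "REJECT_DELTA")
  # raw-predecessor mode compares 990 against 1000 instead
  t2 <- flag_delta(flag_range(toy_tachogram(c(800, 1000, 990))),
                   reference = "previous")
  expect_equal(t2$flag, c("VALID", "REJECT_DELTA", "VALID"))
})

test_that("neighbor rule isolates intervals between two rejections, single pass", {
  t <- toy_tachogram(c(800, 800, 800))
  t$flag <- c("REJECT_RANGE", "VALID", "REJECT_DELTA")
  expect_equal(flag_neighbor(t)$flag[2], "REJECT_NEIGHBOR")
  t$flag <- c("REJECT_RANGE", "VALID", "VALID")
  expect_equal(flag_neighbor(t)$flag, c("REJECT_RANGE", "VALID", "VALID"))
  # first/last intervals never neighbor-rejected
  t$flag <- c("VALID", "REJECT_RANGE", "VALID")
  expect_equal(flag_neighbor(t)$flag[c(1, 3)], c("VALID", "VALID"))
})

test_that("full cleaning cascade matches the hand-simulated flag sequence", {
  # hand application of range -> delta(last-accepted) -> neighbor:
  # 300 and 2500 out of range; 1100 is 27.9% from 860; 860 and 870 are
  # then isolated between rejections; first/last survive
  t <- clean_tachogram(toy_tachogram(c(850, 300, 860, 1100, 870, 2500, 865)))
  expect_equal(t$flag,
               c("VALID", "REJECT_RANGE", "REJECT_NEIGHBOR", "REJECT_DELTA",
                 "REJECT_NEIGHBOR", "REJECT_RANGE", "VALID"))
  expect_equal(sum(t$flag == "VALID"), 2)

  # idempotence and all-valid identity
  expect_identical(clean_tachogram(t)$flag, t$flag)
  t0 <- clean_tachogram(toy_tachogram(rep(800, 20)))
  expect_true(all(t0$flag == "VALID"))

  # flags exhaustive and mutually exclusive by construction
  expect_true(all(t$flag %in% c("VALID", "REJECT_RANGE", "REJECT_DELTA",
                                "REJECT_NEIGHBOR")))
})

test_that("reliability gate is strict at 25% and shift-invariant", {
  t <- toy_tachogram(rep(800, 10))
  t$flag[1:3] <- "REJECT_RANGE"
  r <- reliability(t)
  expect_equal(r$unreliable_fraction, 0.3)
  expect_false(r$usable)
  t$flag <- c(rep("REJECT_RANGE", 2), rep("VALID", 8))
  expect_true(reliability(t)$usable)
  t4 <- toy_tachogram(rep(800, 4))
  t4$flag[1] <- "REJECT_DELTA"
  expect_true(reliability(t4)$usable)  # exactly 25% passes

  # invariant under time shift of all peaks
  rr <- c(850, 300, 860, 1100, 870, 2500, 865)
  f1 <- reliability(clean_tachogram(toy_tachogram(rr)))$unreliable_fraction
  shifted <- build_tachogram(rpeak_series(cumsum(c(0, rr)) / 1000 + 123.4))
  f2 <- reliability(clean_tachogram(shifted))$unreliable_fraction
  expect_identical(f1, f2)
})

test_that("interpolation bridges rejected gaps linearly on a uniform grid", {
  t <- clean_tachogram(toy_tachogram(rep(800, 20)))
  u <- interpolate_tachogram(t, fs_hz = 4)
  expect_equal(u$values_ms, rep(800, length(u$values_ms)))
  expect_equal(diff(u$time_s), rep(0.25, length(u$time_s) - 1))
  expect_true(all(u$reliable_mask))

  # one rejected interval bracketed by 800 and 900: strictly between
  t2 <- toy_tachogram(c(800, 1500, 900, 900))
  t2$flag <- c("VALID", "REJECT_RANGE", "VALID", "VALID")
  u2 <- interpolate_tachogram(t2, fs_hz = 4)
  gap <- u2$time_s > 0.8 & u2$time_s < 2.3
  expect_true(all(u2$values_ms[gap] > 800 & u2$values_ms[gap] < 900))
  expect_true(any(!u2$reliable_mask))

  # mask fraction ~ rejected time fraction on a constructed 20-interval case
  t3 <- toy_tachogram(rep(1000, 20))
  t3$flag[8:11] <- "REJECT_DELTA"
  u3 <- interpolate_tachogram(t3, fs_hz = 4)
  span <- u3$time_s[length(u3$time_s)] - u3$time_s[1]
  expect_equal(mean(!u3$reliable_mask), 4 / span,
               tolerance = 1 / (4 * span) + 1e-9)
  expect_error(interpolate_tachogram(toy_tachogram(800)), "VALID")
})

test_that("median heart rate uses VALID intervals only", {
  expect_equal(median_hr(clean_tachogram(toy_tachogram(rep(800, 5)))), 75)
  # all flagged VALID: median of instantaneous rates 100, 80, 60
  expect_equal(median_hr(toy_tachogram(c(600, 750, 1000))), 80)
  t <- toy_tachogram(c(800, 300, 800))
  t <- clean_tachogram(t)
  expect_equal(median_hr(t), 75)
  t$flag <- rep("REJECT_RANGE", 3)
  expect_error(median_hr(t), "VALID")
})

test_that("clean synthetic series with modest modulation incur zero rejections", {
  ps <- simulate_rr(signal_config(duration_s = 400, artifact_rate = 0, seed = 7))
  t <- clean_tachogram(build_tachogram(ps))
  expect_equal(sum(t$flag != "VALID"), 0)
})
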