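# Feature-level frame for model tests.
sim_frame <- function(icc = 0.5, n_subjects = 29, seed = 1,
                      dv = "rmssd") {
  co <- balanced_cohort(n_subjects, seed = seed)
  simulate_features(co, effect_config(dv, icc = icc), seed = seed + 1000)
}

test_that("VIF matches its closed form, car::vif, and flags collinearity", {
  set.seed(10)
  n <- 200
  d <- data.frame(y = rnorm(n), x1 = scale(rnorm(n))[, 1])
  d$x2 <- scale(rnorm(n))[, 1]
  v <- vif_values(d, c("x1", "x2"))
  expect_equal(unname(v), c(1, 1) / (1 - cor(d$x1, d$x2)^2))

  # near-collinear pair: VIF >> 5 and equal to 1/(1-R^2) by hand
  d$x3 <- d$x1 + rnorm(n, 0, 0.05)
  v3 <- vif_values(d, c("x1", "x2", "x3"))
  expect_gt(v3[["x3"]], 5)
  r2 <- summary(lm(x3 ~ x1 + x2, d))$r.squared
  expect_equal(v3[["x3"]], 1 / (1 - r2))
  expect_equal(unname(v3), unname(car::vif(lm(y ~ x1 + x2 + x3, d))),
               tolerance = 1e-8)

  # exact duplicate: infinite-VIF signal
  d$x4 <- d$x1
  expect_true(is.infinite(vif_values(d, c("x1", "x4"))[["x4"]]))
})

test_that("MLR recovers exact fits and its closed-form statistics", {
  d <- data.frame(x = 1:20)
  d$y <- 2 + 3 * d$x
  fit <- suppressWarnings(fit_mlr(d, "x"))  # noiseless fit by design
  expect_equal(unname(fit$beta), c(2, 3))
  expect_equal(fit$r2, 1)

  # adjusted R2 closed form on a noisy fit
  set.seed(2)
  fr <- sim_frame(icc = 0, seed = 3)
  m <- fit_mlr(fr)
  expect_equal(m$r2_adjusted,
               1 - (1 - m$r2) * (m$n - 1) / (m$n - m$p - 1))
  # F-statistic against the independent formula ((ESS/p)/(RSS/(n-p-1)))
  rss <- sum(m$residuals^2)
  ess <- sum((m$fitted - mean(fr$y))^2)
  expect_equal(m$f_statistic, (ess / m$p) / (rss / (m$n - m$p - 1)))
  # leverage trace identity
  expect_equal(sum(m$leverage), m$p + 1)

  d$dup <- d$x
  expect_error(fit_mlr(d, c("x", "dup")), "rank-deficient")
})

test_that("worked adjusted-R2 example: R2 0.5 at n 100, p 6", {
  expect_equal(1 - 0.5 * 99 / 93, 0.467742, tolerance = 1e-6)
})

test_that("LMM estimates variance components and the ICC ratio", {
  # generated without between-subject variance: ICC near zero
  set.seed(30)
  iccs <- vapply(1:20, function(i) icc(fit_lmm(sim_frame(0, seed = i))),
                 numeric(1))
  expect_lt(mean(iccs), 0.05)

  # ratio definition
  fit <- fit_lmm(sim_frame(0.5, seed = 4))
  expect_equal(fit$icc, fit$sigma2_b / (fit$sigma2_b + fit$sigma2_e))

  # balanced-design oracle: the ANOVA estimator agrees on the covariate-free
  # residual structure
  set.seed(5)
  g <- rep(sprintf("S%02d", 1:30), each = 8)
  y <- rnorm(30)[as.integer(factor(g))] * sqrt(2) + rnorm(240)
  d <- data.frame(y = y, subject_id = g, x = rnorm(240))
  f <- fit_lmm(d, "x")
  expect_equal(f$icc, anova_icc(y, g), tolerance = 0.05)
})

test_that("likelihood-ratio test applies the boundary mixture", {
  fr <- sim_frame(0.5, seed = 6)
  lmmf <- fit_lmm(fr)
  mlrf <- fit_mlr(fr)
  lr <- lrt(lmmf, mlrf)
  expect_gte(lr$stat, 0)
  expect_equal(lr$stat, 2 * (lmmf$loglik - mlrf$loglik))
  expect_equal(lr$p_chisq1, 2 * lr$p_value)

  # closed forms: stat 3.841 -> p ~ 0.025; identical logliks -> p 1
  p <- 0.5 * pchisq(3.841, 1, lower.tail = FALSE)
  expect_equal(p, 0.025, tolerance = 1e-3)
  lmm0 <- lmmf; lmm0$loglik <- mlrf$loglik
  lr0 <- lrt(lmm0, mlrf)
  expect_equal(lr0$stat, 0)
  expect_equal(lr0$p_value, 1)

  expect_error(lrt(lmmf, fit_mlr(fr[1:100, ])), "same frame")
})

test_that("nesting: LMM ML log-likelihood is never below the MLR's", {
  for (i in 1:5) {
    fr <- sim_frame(runif(1, 0, 0.6), seed = 40 + i)
    expect_gte(fit_lmm(fr)$loglik, fit_mlr(fr)$loglik - 1e-6)
  }
})

test_that("effect curves are linear, consistent, and percentile-bounded", {
  fr <- sim_frame(0.3, seed = 8)
  m <- fit_mlr(fr)
  cv <- effect_curve(m, "median_hr")
  expect_equal(range(cv$iv_value),
               unname(quantile(fr$median_hr, c(0.05, 0.95))))
  # slope equals the fitted coefficient
  slopes <- diff(cv$yhat) / diff(cv$iv_value)
  expect_equal(unname(slopes), rep(unname(m$beta["median_hr"]),
                                   length(slopes)))
  # at the all-median point the curve equals the fitted value there
  med <- as.data.frame(lapply(as.data.frame(fr)[m$covariates], median))
  cv2 <- effect_curve(m, "age")
  pred_med <- predict(m, med)
  j <- which.min(abs(cv2$iv_value - med$age))
  expect_equal(cv2$yhat[j] -
                 unname(m$beta["age"]) * (cv2$iv_value[j] - med$age),
               unname(pred_med))
  # binary covariate: grid {0, 1}
  cvp <- effect_curve(m, "parity")
  expect_equal(cvp$iv_value, c(0, 1))
  # a zero-coefficient covariate gives a flat curve inside its own band
  d <- data.frame(y = rnorm(100), x = rnorm(100), z = rnorm(100))
  mz <- fit_mlr(d, c("x", "z"))
  cvz <- effect_curve(mz, "z")
  expect_true(all(cvz$ci_low < mean(cvz$yhat) & cvz$ci_high > mean(cvz$yhat)))
  expect_error(effect_curve(m, "nope"), "unknown covariate")
  # curves also come off the mixed model
  l <- fit_lmm(fr)
  cvl <- effect_curve(l, "median_hr")
  s2 <- diff(cvl$yhat) / diff(cvl$iv_value)
  expect_equal(unname(s2), rep(unname(l$beta["median_hr"]), length(s2)))
})

test_that("diagnostics expose the series behind the assumption checks", {
  fr <- sim_frame(0.3, seed = 9)
  m <- fit_mlr(fr)
  dg <- diagnostics(m)
  expect_equal(nrow(dg$qq), m$n)
  expect_equal(dg$fitted_resid$resid, unname(m$residuals))
  expect_equal(sum(dg$leverage), m$p + 1)
  # a duplicated centroid-like point has near-zero Cook's distance
  d <- data.frame(y = c(rnorm(50), 0), x = c(rnorm(50), 0))
  d$y[51] <- mean(d$y[1:50]); d$x[51] <- mean(d$x[1:50])
  d$y[51] <- predict(lm(y ~ x, d[1:50, ]), d[51, ])
  mm <- fit_mlr(d, "x")
  expect_lt(mm$cooks_d[51], 1e-10)
  l <- fit_lmm(fr)
  expect_named(diagnostics(l), c("qq", "fitted_resid", "blups"))
})

test_that("influence removal takes out planted gross outliers only", {
  set.seed(11)
  n <- 60
  d <- data.frame(x = rnorm(n))
  d$y <- 1 + 2 * d$x + rnorm(n, 0, 0.5)
  # two planted high-leverage response outliers
  d$x[c(59, 60)] <- c(8, -8)
  d$y[c(59, 60)] <- c(-30, 35)
  m <- fit_mlr(d, "x")
  expect_equal(which.max(m$cooks_d) %in% c(59, 60), TRUE)
  rem <- remove_influential(m)
  expect_setequal(rem$removed$row, c(59, 60))
  expect_true(all(rem$removed$cooks_d > 1))
  # slope recovers after removal
  expect_lt(abs(rem$coef_after[["x"]] - 2),
            abs(rem$coef_before[["x"]] - 2))
  # clean data: zero removals, report still well-formed
  fr <- sim_frame(0.3, seed = 12)
  rem0 <- remove_influential(fit_mlr(fr))
  expect_equal(nrow(rem0$removed), 0)
  expect_identical(rem0$coef_before, rem0$coef_after)
})

test_that("the CHD screen keeps a planted effect and drops a null one", {
  co <- sample_cohort(cohort_config(n_subjects = 120, design = "single",
                                    chd_prob = 0.3, seed = 13))
  eff <- effect_config("rmssd", icc = 0)
  # null CHD: simulate features ignoring chd entirely
  drops <- 0L
  for (i in 1:25) {
    ft <- simulate_features(co, eff, seed = 100 + i)
    ft$sdnn_ms <- exp(ft$y); ft$rmssd_ms <- exp(ft$y)
    ft$sampen <- sqrt(abs(ft$y)) / 2
    ft$median_hr_bpm <- ft$median_hr; ft$median_br_brpm <- ft$median_br
    ft$usable <- TRUE
    rep <- chd_screen(ft, co, dv_names = "rmssd")
    drops <- drops + (rep$decision == "drop")
  }
  expect_gte(drops / 25, 0.8)

  # planted effect of ~2 residual SDs: kept
  ft <- simulate_features(co, eff, seed = 999)
  ft$y <- ft$y + 2 * sqrt(eff$sigma2_e) * co$chd
  ft$rmssd_ms <- exp(ft$y)
  ft$sdnn_ms <- exp(ft$y); ft$sampen <- 1.2
  ft$median_hr_bpm <- ft$median_hr; ft$median_br_brpm <- ft$median_br
  ft$usable <- TRUE
  expect_equal(chd_screen(ft, co, dv_names = "rmssd")$decision, "keep")

  # constant CHD column: skipped with notice
  co0 <- co; co0$chd <- 0
  expect_message(out <- chd_screen(ft, co0), "constant")
  expect_equal(nrow(out), 0)
})

test_that("frames join, gate, transform, and code parity", {
  co <- balanced_cohort(4, seed = 14)
  ft <- simulate_features(co, effect_config("sdnn"), seed = 15)
  ft$sdnn_ms <- exp(ft$y); ft$rmssd_ms <- exp(ft$y); ft$sampen <- 1.2
  ft$median_hr_bpm <- ft$median_hr; ft$median_br_brpm <- ft$median_br
  ft$usable <- TRUE
  ft$usable[1] <- FALSE
  fr <- build_frame(ft, co, "sdnn")
  expect_equal(nrow(fr), nrow(ft) - 1)
  expect_equal(attr(fr, "n_unusable"), 1)
  expect_equal(fr$y, log(ft$sdnn_ms[-1]))
  expect_true(all(fr$parity %in% c(0, 1)))
  frn <- build_frame(ft, co, "sdnn", parity_coding = "numeric")
  expect_true(max(frn$parity) >= max(fr$parity))
  # a missing covariate row is dropped and counted
  ft2 <- ft; ft2$median_br_brpm[3] <- NA
  fr2 <- build_frame(ft2, co, "sdnn")
  expect_equal(attr(fr2, "n_dropped"), 1)
  # duplicate keys are a keying error
  expect_error(build_frame(rbind(ft, ft[2, ]), co, "sdnn"), "unique")
})
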