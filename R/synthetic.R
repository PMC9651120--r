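# Synthetic cohorts, feature-level repeated measures, and RR series with
# known ground truth. Defaults are calibrated to the published cohort
# summaries for healthy pregnant populations: age median ~31 (IQR 28-34)
# years, pre-pregnancy BMI median ~22.8 (IQR ~20.7-26) kg/m^2, median HR
# ~78 bpm, median BR ~14 brpm, and a repeated-measurement schedule at
# approximately 14, 18, 22, 24, 26, 30, 34, 36, 38 and 40 weeks GA.

rtnorm <- function(n, mean, sd, lo, hi) {
  qnorm(runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd)), mean, sd)
}

#' Cohort generator configuration
#'
#' @param n_subjects Number of subjects (290 single-design, 29 repeated).
#' @param design `"single"` (one measurement per subject) or `"repeated"`
#'   (a gestational-age visit schedule per subject).
#' @param ga_schedule Visit weeks for the repeated design.
#' @param age_mean,age_sd Age distribution (normal, truncated to 18-45,
#'   rounded to whole years).
#' @param bmi_meanlog,bmi_sdlog BMI distribution (log-normal, truncated
#'   below at 15).
#' @param parity_probs Probabilities of 0, 1, 2 prior births.
#' @param chd_prob Probability of a fetal-CHD flag per subject.
#' @param dropout_prob Per-visit missingness in the repeated design
#'   (default 0.2, giving a median of about 8 of 10 scheduled visits).
#' @param seed Integer seed; every generator output is a pure function of
#'   its config including the seed.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 290,
                          design = c("single", "repeated"),
                          ga_schedule = c(14, 18, 22, 24, 26, 30, 34, 36, 38, 40),
                          age_mean = 31, age_sd = 4.5,
                          bmi_meanlog = log(22.8), bmi_sdlog = 0.17,
                          parity_probs = c(0.55, 0.35, 0.10),
                          chd_prob = NULL, dropout_prob = 0.2, seed = 1L) {
  design <- match.arg(design)
  if (is.null(chd_prob)) chd_prob <- if (design == "single") 0.269 else 0
  if (age_sd <= 0 || bmi_sdlog <= 0) stop("distribution scales must be positive")
  if (abs(sum(parity_probs) - 1) > 1e-8) stop("parity_probs must sum to 1")
  if (dropout_prob < 0 || dropout_prob >= 1) stop("dropout_prob must be in [0,1)")
  structure(list(n_subjects = n_subjects, design = design,
                 ga_schedule = ga_schedule, age_mean = age_mean,
                 age_sd = age_sd, bmi_meanlog = bmi_meanlog,
                 bmi_sdlog = bmi_sdlog, parity_probs = parity_probs,
                 chd_prob = chd_prob, dropout_prob = dropout_prob,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Sample a synthetic cohort table
#'
#' One row per (subject, measurement): age (years, 18-45), BMI (kg/m^2),
#' gestational age (decimal weeks), parity (prior births), fetal-CHD
#' flag. In the repeated design each scheduled visit is independently
#' missing with `dropout_prob` (at least one visit is always kept).
#'
#' @param cfg A [cohort_config].
#' @return data.frame with columns `subject_id`, `measurement_id`, `age`,
#'   `bmi`, `ga`, `parity`, `chd`.
#' @export
sample_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  ns <- cfg$n_subjects
  subj <- sprintf("S%03d", seq_len(ns))
  age <- round(rtnorm(ns, cfg$age_mean, cfg$age_sd, 18, 45))
  bmi <- pmax(15.01, rlnorm(ns, cfg$bmi_meanlog, cfg$bmi_sdlog))
  parity <- sample(seq_along(cfg$parity_probs) - 1L, ns, replace = TRUE,
                   prob = cfg$parity_probs)
  chd <- rbinom(ns, 1, cfg$chd_prob)
  if (cfg$design == "single") {
    ga <- rtnorm(ns, 20.4, 1.0, 18, 24)
    out <- data.frame(subject_id = subj, measurement_id = "M01",
                      age = age, bmi = bmi, ga = ga, parity = parity,
                      chd = chd, stringsAsFactors = FALSE)
  } else {
    rows <- lapply(seq_len(ns), function(i) {
      keep <- runif(length(cfg$ga_schedule)) >= cfg$dropout_prob
      if (!any(keep)) keep[1] <- TRUE
      ga <- pmin(42, pmax(12, cfg$ga_schedule[keep] +
                            rnorm(sum(keep), 0, 0.3)))
      data.frame(subject_id = subj[i],
                 measurement_id = sprintf("M%02d", which(keep)),
                 age = age[i], bmi = bmi[i], ga = ga,
                 parity = parity[i], chd = chd[i],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
  }
  out
}

#' Generative model for transformed HRV features
#'
#' Defaults per dependent variable place the mean response at the
#' published feature medians when covariates sit at their typical values,
#' with a heart-rate-dominated negative fixed-effect structure, and split
#' a fixed total residual variance between the subject intercept and the
#' measurement noise according to the target intra-class correlation.
#'
#' @param dv_name One of `"sdnn"`, `"rmssd"`, `"sampen"`.
#' @param icc Target intra-class correlation sigma2_b/(sigma2_b+sigma2_e);
#'   defaults per DV (0.48, 0.68, 0.28).
#' @param total_var Total residual variance sigma2_b + sigma2_e on the
#'   transformed scale; defaults per DV.
#' @param beta Named coefficient vector over `age`, `bmi`, `ga`,
#'   `parity`, `median_hr`, `median_br`; a default is supplied.
#' @param beta0 Intercept on the transformed scale; a default is derived
#'   so the mean matches the published feature median at typical
#'   covariate levels.
#' @return List of class `effect_config` with `beta0`, `beta`,
#'   `sigma2_b`, `sigma2_e`, `icc`.
#' @export
effect_config <- function(dv_name = c("sdnn", "rmssd", "sampen"),
                          icc = NULL, total_var = NULL, beta = NULL,
                          beta0 = NULL) {
  dv_name <- match.arg(dv_name)
  def <- switch(dv_name,
    sdnn = list(icc = 0.48, total_var = 0.09,
                beta = c(age = -0.008, bmi = 0, ga = -0.004, parity = 0,
                         median_hr = -0.020, median_br = -0.030),
                center = log(47.2)),
    rmssd = list(icc = 0.68, total_var = 0.16,
                 beta = c(age = -0.012, bmi = 0, ga = -0.010, parity = 0,
                          median_hr = -0.035, median_br = -0.015),
                 center = log(22.5)),
    sampen = list(icc = 0.28, total_var = 0.10,
                  beta = c(age = -0.005, bmi = 0, ga = -0.020, parity = 0,
                           median_hr = -0.010, median_br = -0.030),
                  center = 1.2^2))
  if (is.null(icc)) icc <- def$icc
  if (is.null(total_var)) total_var <- def$total_var
  if (is.null(beta)) beta <- def$beta
  if (icc < 0 || icc >= 1) stop("icc must be in [0, 1)")
  if (total_var <= 0) stop("total_var must be positive")
  if (is.null(beta0)) {
    typical <- c(age = 31, bmi = 22.8, ga = 27, parity = 0.4,
                 median_hr = 79, median_br = 14)
    beta0 <- def$center - sum(beta * typical[names(beta)])
  }
  structure(list(dv_name = dv_name, beta0 = beta0, beta = beta,
                 sigma2_b = icc * total_var,
                 sigma2_e = (1 - icc) * total_var, icc = icc),
            class = "effect_config")
}

#' Simulate transformed HRV features from a linear mixed model
#'
#' Draws per-measurement median HR and BR covariates from truncated
#' normals centred at the typical published values (HR 78 bpm, BR 14
#' brpm), then generates
#' y = beta0 + X beta + b_subject + e, with b ~ N(0, sigma2_b),
#' e ~ N(0, sigma2_e). Parity enters the linear predictor as the binary
#' nulliparous/parous indicator.
#'
#' @param cohort A [sample_cohort] table.
#' @param effects An [effect_config].
#' @param seed Integer seed.
#' @return data.frame with the covariate columns (`parity` binarized),
#'   `median_hr`, `median_br`, `subject_id`, `measurement_id`, and the
#'   response `y`; attribute `truth` records the per-subject intercepts
#'   and all generative parameters.
#' @export
simulate_features <- function(cohort, effects = effect_config("rmssd"),
                              seed = 1L) {
  stopifnot(inherits(effects, "effect_config"))
  set.seed(seed)
  n <- nrow(cohort)
  subj <- unique(cohort$subject_id)
  b <- setNames(rnorm(length(subj), 0, sqrt(effects$sigma2_b)), subj)
  out <- data.frame(subject_id = cohort$subject_id,
                    measurement_id = cohort$measurement_id,
                    age = cohort$age, bmi = cohort$bmi, ga = cohort$ga,
                    parity = as.integer(cohort$parity > 0),
                    median_hr = rtnorm(n, 78, 9, 50, 120),
                    median_br = rtnorm(n, 14, 1.8, 9, 24),
                    stringsAsFactors = FALSE)
  X <- as.matrix(out[names(effects$beta)])
  out$y <- effects$beta0 + drop(X %*% effects$beta) +
    b[out$subject_id] + rnorm(n, 0, sqrt(effects$sigma2_e))
  attr(out, "truth") <- list(effects = effects, b = b, seed = seed)
  out
}

#' Signal generator configuration
#'
#' RR modulation is additive-sinusoidal: a respiratory sinus arrhythmia
#' component at the breathing frequency, a slow modulation at 0.1 Hz
#' (random phase), and white beat-to-beat noise. This gives analytic
#' ground truth for the breathing rate and the variance structure; it is
#' not an integral-pulse-frequency-modulation heart model.
#'
#' @param duration_s Recording length in seconds; default 1800 (a
#'   30-minute measurement).
#' @param base_rr_ms Baseline RR, default 770 ms (about 78 bpm).
#' @param rsa_amp_ms Respiratory modulation amplitude, default 30 ms.
#' @param br_hz Breathing rate in Hz, within 0.1-0.5; default 0.233
#'   (14 brpm).
#' @param lf_amp_ms Slow (0.1 Hz) modulation amplitude, default 25 ms.
#' @param noise_sd_ms Beat-to-beat white noise SD, default 2 ms.
#' @param artifact_rate Per-beat corruption probability in \[0, 0.3\];
#'   default 0.
#' @param seed Integer seed.
#' @return List of class `signal_config`.
#' @export
signal_config <- function(duration_s = 1800, base_rr_ms = 770,
                          rsa_amp_ms = 30, br_hz = 0.233, lf_amp_ms = 25,
                          noise_sd_ms = 2, artifact_rate = 0, seed = 1L) {
  if (base_rr_ms <= 400 || base_rr_ms >= 2000)
    stop("base_rr_ms must lie inside (400, 2000)")
  if (br_hz < 0.1 || br_hz > 0.5) stop("br_hz must lie in [0.1, 0.5]")
  if (artifact_rate < 0 || artifact_rate > 0.3)
    stop("artifact_rate must lie in [0, 0.3]")
  if (base_rr_ms - rsa_amp_ms - lf_amp_ms <= 0)
    stop("modulation amplitudes exceed the baseline RR")
  structure(list(duration_s = duration_s, base_rr_ms = base_rr_ms,
                 rsa_amp_ms = rsa_amp_ms, br_hz = br_hz,
                 lf_amp_ms = lf_amp_ms, noise_sd_ms = noise_sd_ms,
                 artifact_rate = artifact_rate, seed = as.integer(seed)),
            class = "signal_config")
}

#' Simulate an R-peak series with respiratory sinus arrhythmia
#'
#' Beat-by-beat generation: the next peak falls one RR interval after the
#' current one, with
#' RR(t) = base + rsa_amp sin(2 pi br t) + lf_amp sin(2 pi 0.1 t + phi)
#' + N(0, noise_sd). When `artifact_rate > 0` the clean series is passed
#' through [inject_artifacts] and the truth mask is attached.
#'
#' @param cfg A [signal_config].
#' @param subject_id,measurement_id Identifiers for the series.
#' @return An [rpeak_series]; with artifacts, attribute `corrupted` holds
#'   the truth mask over intervals and `n_events` the corruption count.
#' @export
simulate_rr <- function(cfg = signal_config(), subject_id = "S1",
                        measurement_id = "M1") {
  stopifnot(inherits(cfg, "signal_config"))
  set.seed(cfg$seed)
  phi <- runif(1, 0, 2 * pi)
  n_max <- ceiling(cfg$duration_s / (cfg$base_rr_ms / 1000)) + 64
  noise <- rnorm(n_max, 0, cfg$noise_sd_ms)
  t <- 0
  peaks <- numeric(n_max)
  k <- 1L
  while (t < cfg$duration_s && k <= n_max) {
    peaks[k] <- t
    rr <- cfg$base_rr_ms +
      cfg$rsa_amp_ms * sin(2 * pi * cfg$br_hz * t) +
      cfg$lf_amp_ms * sin(2 * pi * 0.1 * t + phi) +
      noise[k]
    if (rr <= 0) stop("configuration produced a non-positive RR interval")
    t <- t + rr / 1000
    k <- k + 1L
  }
  out <- rpeak_series(peaks[seq_len(k - 1L)], subject_id, measurement_id)
  if (cfg$artifact_rate > 0) {
    art <- inject_artifacts(out, cfg$artifact_rate, seed = cfg$seed + 1L)
    out <- art$peaks
    attr(out, "corrupted") <- art$corrupted
    attr(out, "n_events") <- art$n_events
  }
  out
}

#' Corrupt an R-peak series with missed and spurious beats
#'
#' Each interior beat is independently corrupted with probability `rate`;
#' a corrupted beat is either deleted (missed beat, merging two intervals
#' into one long one) or a spurious peak is inserted at the midpoint of
#' its following interval (two short intervals), with equal probability.
#' The truth mask marks, over the intervals of the corrupted series,
#' those affected: intervals containing a deleted peak in their interior
#' or bounded by an inserted peak.
#'
#' @param peaks A clean [rpeak_series].
#' @param rate Per-beat corruption probability in \[0, 0.3\].
#' @param seed Integer seed.
#' @return List: `peaks` (corrupted series), `corrupted` (logical per
#'   interval of the corrupted series), `n_events`, `n_deleted`,
#'   `n_inserted`.
#' @export
inject_artifacts <- function(peaks, rate, seed = 1L) {
  stopifnot(inherits(peaks, "rpeak_series"))
  if (rate < 0 || rate > 0.3) stop("rate must lie in [0, 0.3]")
  set.seed(seed)
  p <- peaks$peak_times
  n <- length(p)
  interior <- 2:(n - 1)
  hit <- interior[runif(length(interior)) < rate]
  is_del <- runif(length(hit)) < 0.5
  del_idx <- hit[is_del]
  ins_after <- hit[!is_del]                       # insert mid of (p_i, p_{i+1})
  ins_times <- (p[ins_after] + p[ins_after + 1]) / 2
  kept <- if (length(del_idx)) p[-del_idx] else p
  new_p <- sort(c(kept, ins_times))
  inserted <- new_p %in% ins_times
  corrupted <- logical(length(new_p) - 1L)
  # deleted peak strictly inside an interval of the new series
  if (length(del_idx)) {
    j <- findInterval(p[del_idx], new_p)
    j <- j[j >= 1 & j < length(new_p)]
    corrupted[j] <- TRUE
  }
  # intervals bounded by an inserted peak
  corrupted[inserted[-length(new_p)] | inserted[-1]] <- TRUE
  list(peaks = rpeak_series(new_p, peaks$subject_id, peaks$measurement_id),
       corrupted = corrupted, n_events = length(hit),
       n_deleted = length(del_idx), n_inserted = length(ins_after))
}
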