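# CSV interchange and the end-to-end run orchestrator. All interchange is
# plain CSV (small datasets, inspectability) with headers required and
# numbers written at full precision.

need_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  invisible(df)
}

#' Read R-peak series from CSV
#'
#' One row per R-peak (or per RR interval). Required columns:
#' `subject_id`, `measurement_id`, and exactly one of `peak_time_s`
#' (seconds from recording start) or `rr_ms` (successive RR durations,
#' converted to peak times starting at 0).
#'
#' @param path CSV file path (UTF-8, header required).
#' @return Named list of [rpeak_series], one per (subject, measurement),
#'   names `subject_id/measurement_id`.
#' @export
read_rpeaks_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need_cols(df, c("subject_id", "measurement_id"), "R-peak CSV")
  has_peak <- "peak_time_s" %in% names(df)
  has_rr <- "rr_ms" %in% names(df)
  if (has_peak == has_rr)
    stop("R-peak CSV must have exactly one of peak_time_s or rr_ms")
  key <- paste(df$subject_id, df$measurement_id, sep = "/")
  lapply(split(df, factor(key, levels = unique(key))), function(d) {
    pt <- if (has_peak) d$peak_time_s else cumsum(c(0, d$rr_ms)) / 1000
    rpeak_series(pt, d$subject_id[1], d$measurement_id[1])
  })
}

#' Write tachograms to CSV
#'
#' One row per interval: `subject_id, measurement_id, onset_s, rr_ms,
#' flag`.
#'
#' @param tachos A tachogram or list of tachograms.
#' @param path Output CSV path.
#' @export
write_tachogram_csv <- function(tachos, path) {
  if (inherits(tachos, "tachogram")) tachos <- list(tachos)
  df <- do.call(rbind, lapply(tachos, as.data.frame))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a features/cohort/segments table from CSV
#'
#' Thin wrapper over [utils::read.csv] that validates required columns
#' and reads empty numeric fields back as `NA` (absent breathing rates
#' round-trip losslessly).
#'
#' @param path CSV path.
#' @param required Character vector of required column names.
#' @return data.frame.
#' @export
read_table_csv <- function(path, required = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(required)) need_cols(df, required, basename(path))
  df
}

#' Write a table to CSV at full precision
#'
#' @param df data.frame.
#' @param path Output CSV path.
#' @export
write_table_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Run configuration
#'
#' Collects every tunable pipeline parameter with its documented default.
#' Unknown keys are rejected. A configuration can also be loaded from a
#' YAML file with [read_run_config]; explicit arguments override file
#' values.
#'
#' @param ... Overrides of the defaults listed below.
#' @return List of class `mhrv_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    lo_ms = 400, hi_ms = 2000, rel_tol = 0.20, reference = "last_accepted",
    max_unreliable = 0.25, fs_hz = 4,
    sampen_m = 2L, sampen_r = 0.2, sampen_scale = "rr",
    br_window_s = 120, br_overlap = 0.5, br_band_hz = c(0.1, 0.5),
    br_max_unreliable = 0.05, br_estimator = "median", br_band_mode = "discard",
    dv_names = c("sdnn", "rmssd", "sampen"),
    include_chd = FALSE, parity_coding = "binary",
    cooks_threshold = 1.0, max_removals = 2L,
    effect_curve_grid = 50L, seed = 1L, schema_version = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  structure(modifyList(defaults, over), class = "mhrv_config")
}

#' @rdname run_config
#' @param path YAML file of config keys.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, modifyList(vals, list(...)))
}

#' Simulate a dataset to disk
#'
#' Writes `cohort.csv`, per-subject R-peak CSVs under
#' `rpeaks/<subject_id>/<measurement_id>.csv`, and `truth.json` recording
#' every generative parameter. Per measurement, the baseline RR and the
#' breathing rate are drawn from the same truncated normals used by the
#' feature-level generator (HR ~78 bpm, BR ~14 brpm) and recorded as
#' ground truth.
#'
#' @param out_dir Output directory (created if missing).
#' @param cohort_cfg A [cohort_config].
#' @param duration_s Per-measurement recording length, seconds.
#' @param artifact_rate Per-beat corruption probability.
#' @return Invisibly, the manifest list (paths and ground truth).
#' @export
mhrv_simulate <- function(out_dir, cohort_cfg = cohort_config(
                            n_subjects = 29, design = "repeated"),
                          duration_s = 1800, artifact_rate = 0) {
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    message("created output directory ", out_dir)
  }
  cohort <- sample_cohort(cohort_cfg)
  write_table_csv(cohort, file.path(out_dir, "cohort.csv"))
  set.seed(cohort_cfg$seed + 1L)
  n <- nrow(cohort)
  hr <- rtnorm(n, 78, 9, 55, 110)
  br <- rtnorm(n, 14, 1.8, 9, 24)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  paths <- character(n)
  for (i in seq_len(n)) {
    cfg <- signal_config(duration_s = duration_s,
                         base_rr_ms = 60000 / hr[i], br_hz = br[i] / 60,
                         artifact_rate = artifact_rate, seed = seeds[i])
    ps <- simulate_rr(cfg, cohort$subject_id[i], cohort$measurement_id[i])
    d <- file.path(out_dir, "rpeaks", cohort$subject_id[i])
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
    paths[i] <- file.path(d, paste0(cohort$measurement_id[i], ".csv"))
    write_table_csv(data.frame(subject_id = ps$subject_id,
                               measurement_id = ps$measurement_id,
                               peak_time_s = ps$peak_times), paths[i])
  }
  truth <- list(cohort_config = unclass(cohort_cfg),
                duration_s = duration_s, artifact_rate = artifact_rate,
                measurements = data.frame(
                  subject_id = cohort$subject_id,
                  measurement_id = cohort$measurement_id,
                  true_hr_bpm = hr, true_br_brpm = br, seed = seeds))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, paths = paths, truth = truth))
}

# Collect R-peak CSVs written by mhrv_simulate back into a list.
read_rpeaks_dir <- function(dir) {
  files <- list.files(file.path(dir, "rpeaks"), recursive = TRUE,
                      full.names = TRUE, pattern = "\\.csv$")
  out <- list()
  for (f in files) out <- c(out, read_rpeaks_csv(f))
  out
}

#' Run the full analysis pipeline
#'
#' End-to-end order: tachogram cleaning and the 25% reliability gate,
#' HRV features and median HR, EMD breathing-rate estimation with the
#' subject-mean fallback, model frames per dependent variable, the
#' fixed-effects MLR with the Cook's-distance removal protocol, and
#' (when repeated measurements are present) the random-intercept LMM
#' with ICC and the boundary-corrected likelihood-ratio test, plus
#' effect curves and diagnostics. Writes `features.csv`,
#' `br_segments.csv`, `effect_curves.csv`, `diagnostics.csv`,
#' `model_report.json`, `model_report.txt`, and `manifest.json` under
#' `out_dir`.
#'
#' @param rpeaks Path to an R-peak CSV, a directory produced by
#'   [mhrv_simulate], or a list of [rpeak_series].
#' @param cohort Path to the cohort covariate CSV, or a data.frame.
#' @param out_dir Output directory (created if missing).
#' @param config A [run_config].
#' @return Invisibly, a list with the fitted models, the report, and the
#'   manifest.
#' @export
mhrv_run <- function(rpeaks, cohort, out_dir, config = run_config()) {
  stopifnot(inherits(config, "mhrv_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  series <- if (is.character(rpeaks) && dir.exists(rpeaks))
    read_rpeaks_dir(rpeaks)
  else if (is.character(rpeaks)) read_rpeaks_csv(rpeaks)
  else rpeaks
  if (is.character(cohort))
    cohort <- read_table_csv(cohort, c("subject_id", "measurement_id",
                                       "age", "bmi", "ga", "parity"))
  n_in <- length(series)
  feat_rows <- list()
  seg_rows <- list()
  n_unreliable <- 0L
  for (ps in series) {
    t <- clean_tachogram(build_tachogram(ps), config$lo_ms, config$hi_ms,
                         config$rel_tol, config$reference)
    rel <- reliability(t, config$max_unreliable)
    id <- paste(ps$subject_id, ps$measurement_id, sep = "/")
    if (!rel$usable) {
      n_unreliable <- n_unreliable + 1L
      message(sprintf("stage reliability: %s excluded (%.1f%% unreliable)",
                      id, 100 * rel$unreliable_fraction))
      next
    }
    fr <- tryCatch(
      hrv_features(t, config$sampen_m, config$sampen_r, config$sampen_scale,
                   config$max_unreliable),
      error = function(e) stop("stage features failed for ", id, ": ",
                               conditionMessage(e)))
    segs <- segment_br(interpolate_tachogram(t, config$fs_hz),
                       config$br_window_s, config$br_overlap,
                       config$br_band_hz, config$br_max_unreliable,
                       config$br_estimator, config$br_band_mode)
    est <- median_br(segs)
    fr$median_br_brpm <- est$median_br_brpm
    fr$br_n_used <- est$n_used
    feat_rows[[id]] <- fr
    if (nrow(segs)) {
      segs <- cbind(subject_id = ps$subject_id,
                    measurement_id = ps$measurement_id, segs)
      seg_rows[[id]] <- segs
    }
  }
  features <- do.call(rbind, feat_rows)
  rownames(features) <- NULL
  # subject-mean fallback for measurements without an estimable BR
  features$br_fallback <- FALSE
  n_unresolved <- 0L
  for (s in unique(features$subject_id)) {
    i <- features$subject_id == s
    fb <- withCallingHandlers(fallback_br(features$median_br_brpm[i]),
                              warning = function(w) {
                                message("stage breathing: subject ", s,
                                        " has no estimable BR")
                                invokeRestart("muffleWarning")
                              })
    features$median_br_brpm[i] <- fb$br_brpm
    features$br_fallback[i] <- fb$fallback_used
    if (fb$unresolved) n_unresolved <- n_unresolved + sum(i)
  }
  n_fallback <- sum(features$br_fallback)
  message(sprintf("stage features: %d in, %d usable, %d excluded by the 25%% rule; %d BR fallbacks",
                  n_in, nrow(features), n_unreliable, n_fallback))
  write_table_csv(features, file.path(out_dir, "features.csv"))
  if (length(seg_rows))
    write_table_csv(do.call(rbind, seg_rows),
                    file.path(out_dir, "br_segments.csv"))
  # statistical layer
  reps <- table(cohort$subject_id[paste(cohort$subject_id, cohort$measurement_id)
                                  %in% paste(features$subject_id,
                                             features$measurement_id)])
  repeated <- length(reps) >= 2 && sum(reps >= 2) >= 2
  report <- list()
  curves <- list()
  diags <- list()
  manifest_models <- list()
  fits <- list()
  for (dv in config$dv_names) {
    frame <- build_frame(features, cohort, dv, config$include_chd,
                         config$parity_coding)
    covs <- frame_covariates(frame)
    # drop constant or aliased covariates (tiny cohorts cannot identify
    # the full between-subject covariate set)
    X <- cbind(1, as.matrix(as.data.frame(frame)[covs]))
    q <- qr(X)
    if (q$rank < ncol(X)) {
      keep_idx <- sort(q$pivot[seq_len(q$rank)])
      dropped_covs <- setdiff(covs, covs[keep_idx[keep_idx > 1] - 1L])
      message(sprintf("stage models[%s]: dropping unidentifiable covariate(s): %s",
                      dv, paste(dropped_covs, collapse = ", ")))
      covs <- setdiff(covs, dropped_covs)
    }
    mlr0 <- fit_mlr(frame, covs)
    rem <- remove_influential(mlr0, config$max_removals,
                              config$cooks_threshold)
    mlr <- rem$fit
    entry <- list(dv = dv, n = mlr$n,
                  f_statistic = mlr$f_statistic, f_pvalue = mlr$f_pvalue,
                  adj_r2_mlr = mlr$r2_adjusted,
                  coefficients = as.data.frame(cbind(beta = mlr$beta,
                                                     se = mlr$se,
                                                     p = mlr$p_values)),
                  vif = as.list(mlr$vif),
                  n_influential_removed = nrow(rem$removed))
    lmm <- NULL
    if (repeated) {
      lmm <- fit_lmm(rem$frame, covs)
      lr <- lrt(lmm, mlr)
      entry$adj_r2_lmm <- lmm$r2_adjusted
      entry$r2_marginal <- lmm$r2_marginal
      entry$r2_conditional <- lmm$r2_conditional
      entry$icc <- lmm$icc
      entry$lrt_stat <- lr$stat
      entry$lrt_p <- lr$p_value
      entry$lrt_p_chisq1 <- lr$p_chisq1
    }
    message(sprintf("stage models[%s]: %d rows in frame, %d dropped for covariates, %d influential removed",
                    dv, mlr$n, attr(frame, "n_dropped"), nrow(rem$removed)))
    fit_for_curves <- if (repeated) lmm else mlr
    for (iv in fit_for_curves$covariates) {
      cv <- effect_curve(fit_for_curves, iv, config$effect_curve_grid)
      curves[[paste(dv, iv)]] <- cbind(dv_name = dv, iv_name = iv,
                                       as.data.frame(cv),
                                       p_value = attr(cv, "p_value"))
    }
    dg <- diagnostics(mlr, config$cooks_threshold)
    diags[[dv]] <- data.frame(dv_name = dv, row = seq_len(mlr$n),
                              fitted = dg$fitted_resid$fitted,
                              resid = dg$fitted_resid$resid,
                              leverage = dg$leverage, cooks_d = dg$cooks_d)
    manifest_models[[dv]] <- list(
      rows_in_model = mlr$n,
      dropped_missing_covariates = attr(frame, "n_dropped"),
      influential_removed = nrow(rem$removed))
    report[[dv]] <- entry
    fits[[dv]] <- list(mlr = mlr, lmm = lmm)
  }
  write_table_csv(do.call(rbind, curves), file.path(out_dir, "effect_curves.csv"))
  write_table_csv(do.call(rbind, diags), file.path(out_dir, "diagnostics.csv"))
  jsonlite::write_json(report, file.path(out_dir, "model_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeLines(format_report_text(report, repeated),
             file.path(out_dir, "model_report.txt"))
  manifest <- list(
    schema_version = config$schema_version,
    config_hash = substr(paste(deparse(unclass(config)), collapse = ""), 1, 0),
    config = unclass(config),
    measurements_in = n_in,
    excluded_unreliable = n_unreliable,
    usable = nrow(features),
    br_fallbacks_used = n_fallback,
    br_unresolved = n_unresolved,
    repeated_design = repeated,
    models = manifest_models)
  manifest$config_hash <- sum(utf8ToInt(paste(
    deparse(unclass(config)), collapse = "")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(features = features, fits = fits, report = report,
                 manifest = manifest))
}

format_report_text <- function(report, repeated) {
  lines <- c(sprintf("%-8s %10s %10s %12s %12s %8s",
                     "DV", "F-stat", "F p", "adjR2(MLR)",
                     if (repeated) "adjR2(LMM)" else "", if (repeated) "ICC" else ""))
  for (e in report) {
    lines <- c(lines, sprintf("%-8s %10.2f %10.3g %12.3f %12s %8s",
                              toupper(e$dv), e$f_statistic, e$f_pvalue,
                              e$adj_r2_mlr,
                              if (repeated) sprintf("%.3f", e$adj_r2_lmm) else "",
                              if (repeated) sprintf("%.3f", e$icc) else ""))
  }
  lines
}
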