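#' Assemble a model frame from features and cohort covariates
#'
#' Joins the per-measurement HRV feature table with the cohort covariate
#' table on (subject_id, measurement_id), drops measurements failing the
#' reliability gate, transforms the dependent variable (log for SDNN and
#' RMSSD, square for SampEn), and drops rows with unresolved covariates
#' (counted in the `n_dropped` attribute).
#'
#' @param features data.frame as produced by [hrv_features] rows (columns
#'   `subject_id`, `measurement_id`, `sdnn_ms`, `rmssd_ms`, `sampen`,
#'   `median_hr_bpm`, `median_br_brpm`, `usable`).
#' @param cohort data.frame with columns `subject_id`, `measurement_id`,
#'   `age`, `bmi`, `ga`, `parity` (prior births), and optionally `chd`.
#' @param dv_name One of `"sdnn"`, `"rmssd"`, `"sampen"`.
#' @param include_chd Add the fetal-CHD flag as a covariate.
#' @param parity_coding `"binary"` (default; nulliparous 0 / parous 1) or
#'   `"numeric"` (keep the birth count).
#' @return data.frame of class `mhrv_frame` with columns `subject_id`,
#'   `measurement_id`, `y`, `age`, `bmi`, `ga`, `parity`, `median_hr`,
#'   `median_br` (+ `chd`); attributes `dv_name`, `transform`,
#'   `n_dropped` (missing covariates), `n_unusable` (reliability gate).
#' @export
build_frame <- function(features, cohort,
                        dv_name = c("sdnn", "rmssd", "sampen"),
                        include_chd = FALSE,
                        parity_coding = c("binary", "numeric")) {
  dv_name <- match.arg(dv_name)
  parity_coding <- match.arg(parity_coding)
  keys <- c("subject_id", "measurement_id")
  for (nm in keys) {
    if (!nm %in% names(features) || !nm %in% names(cohort))
      stop("both tables need subject_id and measurement_id columns")
  }
  if (anyDuplicated(features[keys]) || anyDuplicated(cohort[keys]))
    stop("keys (subject_id, measurement_id) must be unique in each table")
  raw_col <- switch(dv_name, sdnn = "sdnn_ms", rmssd = "rmssd_ms",
                    sampen = "sampen")
  need_feat <- c(keys, raw_col, "median_hr_bpm", "median_br_brpm", "usable")
  need_coh <- c(keys, "age", "bmi", "ga", "parity",
                if (include_chd) "chd")
  for (nm in setdiff(need_feat, names(features)))
    stop("features table is missing column ", nm)
  for (nm in setdiff(setdiff(need_coh, "chd"), names(cohort)))
    stop("cohort table is missing column ", nm)
  m <- merge(features[need_feat],
             cohort[intersect(need_coh, names(cohort))], by = keys)
  if (nrow(m) == 0) stop("no rows after joining features and cohort")
  n_unusable <- sum(!m$usable)
  m <- m[m$usable, , drop = FALSE]
  out <- data.frame(subject_id = m$subject_id,
                    measurement_id = m$measurement_id,
                    y = transform_dv(m[[raw_col]], dv_name),
                    age = m$age, bmi = m$bmi, ga = m$ga,
                    parity = if (parity_coding == "binary")
                      as.integer(m$parity > 0) else m$parity,
                    median_hr = m$median_hr_bpm,
                    median_br = m$median_br_brpm,
                    stringsAsFactors = FALSE)
  if (include_chd) {
    if (!"chd" %in% names(m)) stop("cohort has no chd column")
    out$chd <- as.integer(m$chd)
  }
  used <- setdiff(names(out), keys)
  keep <- complete.cases(out[used])
  dropped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, dv_name = dv_name,
            transform = if (dv_name == "sampen") "square" else "log",
            n_dropped = dropped, n_unusable = n_unusable,
            class = c("mhrv_frame", "data.frame"))
}

# Covariate columns of a frame: everything numeric except the response
# and identifiers.
frame_covariates <- function(frame) {
  setdiff(names(frame), c("y", "subject_id", "measurement_id"))
}
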