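#' SDNN: standard deviation of NN intervals
#'
#' Sample standard deviation (n-1 denominator, as an estimator of the
#' population SD from a finite recording) of the accepted NN intervals.
#'
#' @param nn_ms Numeric vector of accepted (VALID) RR durations in ms.
#' @return SDNN in milliseconds.
#' @export
sdnn <- function(nn_ms) {
  nn_ms <- as.numeric(nn_ms)
  if (length(nn_ms) < 2) stop("need at least 2 NN intervals for SDNN")
  sd(nn_ms)
}

#' RMSSD: root mean square of successive NN differences
#'
#' Differences are taken only between intervals that are adjacent in the
#' original tachogram and both VALID; pairs spanning a rejected interval
#' are excluded rather than differenced across the gap.
#'
#' @param t A cleaned [build_tachogram] object, or a numeric vector of NN
#'   intervals (all treated as adjacent).
#' @return RMSSD in milliseconds.
#' @export
rmssd <- function(t) {
  if (is.numeric(t)) {
    rr <- t
    ok_pair <- rep(TRUE, max(length(rr) - 1L, 0L))
  } else {
    stopifnot(inherits(t, "tachogram"))
    rr <- t$rr_ms
    v <- t$flag == "VALID"
    ok_pair <- v[-length(v)] & v[-1]
  }
  if (!any(ok_pair)) stop("no admissible successive NN pair for RMSSD")
  d <- (rr[-1] - rr[-length(rr)])[ok_pair]
  sqrt(mean(d^2))
}

#' Sample entropy
#'
#' SampEn(m, r) = -ln(A/B), where B counts ordered pairs (i != j),
#' i, j in 1..N-m, of length-m templates within Chebyshev distance
#' r = `r_frac` x SD(series), and A counts the same for length m+1
#' templates (Richman-Moorman convention; self-matches excluded). Lower
#' values indicate a more regular series.
#'
#' The series analysed is the accepted NN intervals concatenated in
#' order, not the interpolated tachogram: interpolation manufactures
#' regularity and would bias the entropy downward. An HR-scale series
#' (60000/RR) can be passed instead via `scale = "hr"` on the wrapper
#' [hrv_features].
#'
#' @param x Numeric series.
#' @param m Embedding dimension, default 2.
#' @param r_frac Tolerance as a fraction of the series SD, default 0.2.
#' @return SampEn (dimensionless); `NA_real_` when no template pair of
#'   either length matches (entropy undefined; reported as missing, not
#'   infinity).
#' @export
sampen <- function(x, m = 2L, r_frac = 0.2) {
  x <- as.numeric(x)
  n <- length(x)
  if (m < 1) stop("m must be >= 1")
  if (r_frac <= 0) stop("r_frac must be > 0")
  if (n <= m + 1) stop("series too short for the chosen m")
  sdx <- sd(x)
  if (sdx == 0) stop("zero-variance series: SampEn tolerance degenerate")
  r <- r_frac * sdx
  # rows of E are (x[i+m], ..., x[i]) for i = 1..n-m: the full row is the
  # (m+1)-template at i, columns 2..(m+1) the m-template at i
  E <- stats::embed(x, m + 1L)
  nt <- nrow(E)
  A <- 0L
  B <- 0L
  for (i in seq_len(nt - 1L)) {
    js <- (i + 1L):nt
    dm <- abs(E[js, 2L] - E[i, 2L])
    if (m > 1) {
      for (k in 3L:(m + 1L)) dm <- pmax(dm, abs(E[js, k] - E[i, k]))
    }
    bm <- dm <= r
    B <- B + sum(bm)
    A <- A + sum(bm & pmax(dm, abs(E[js, 1L] - E[i, 1L])) <= r)
  }
  if (B == 0L || A == 0L) return(NA_real_)
  -log(A / B)  # ordered-pair counts are 2A/2B; the factor cancels
}

#' Distribution-normalizing transform for modeling
#'
#' SDNN and RMSSD are right-skewed and are log-transformed; SampEn is
#' left-skewed and is squared. [inverse_dv] undoes the transform.
#'
#' @param value Raw feature value(s); strictly positive for the log DVs.
#' @param dv_name One of `"sdnn"`, `"rmssd"`, `"sampen"`.
#' @return Transformed value(s).
#' @export
transform_dv <- function(value, dv_name = c("sdnn", "rmssd", "sampen")) {
  dv_name <- match.arg(dv_name)
  if (dv_name %in% c("sdnn", "rmssd")) {
    if (any(value <= 0, na.rm = TRUE))
      stop("log transform requires strictly positive ", dv_name)
    log(value)
  } else {
    value^2
  }
}

#' @rdname transform_dv
#' @export
inverse_dv <- function(value, dv_name = c("sdnn", "rmssd", "sampen")) {
  dv_name <- match.arg(dv_name)
  if (dv_name %in% c("sdnn", "rmssd")) exp(value) else sqrt(value)
}

#' Per-measurement HRV feature row
#'
#' Computes SDNN, RMSSD, SampEn and the median HR for one cleaned
#' tachogram, together with the transformed values used for modeling and
#' the reliability gate. The median breathing rate column is left `NA`
#' and is filled by the EMD stage (see [estimate_br]).
#'
#' @param t A cleaned tachogram.
#' @param sampen_m,sampen_r SampEn parameters (embedding dimension and
#'   tolerance fraction).
#' @param scale Series SampEn is computed on: `"rr"` (NN intervals,
#'   default) or `"hr"` (60000/NN).
#' @param max_unreliable Reliability gate threshold, default 0.25.
#' @return One-row data.frame.
#' @export
hrv_features <- function(t, sampen_m = 2L, sampen_r = 0.2,
                         scale = c("rr", "hr"), max_unreliable = 0.25) {
  stopifnot(inherits(t, "tachogram"))
  scale <- match.arg(scale)
  rel <- reliability(t, max_unreliable)
  nn <- nn_intervals(t)
  s <- sdnn(nn)
  r <- rmssd(t)
  se_series <- if (scale == "rr") nn else 60000 / nn
  se <- sampen(se_series, m = sampen_m, r_frac = sampen_r)
  data.frame(subject_id = t$subject_id, measurement_id = t$measurement_id,
             sdnn_ms = s, rmssd_ms = r, sampen = se,
             median_hr_bpm = median_hr(t), median_br_brpm = NA_real_,
             log_sdnn = log(s), log_rmssd = log(r),
             sampen_sq = if (is.na(se)) NA_real_ else se^2,
             usable = rel$usable, stringsAsFactors = FALSE)
}
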