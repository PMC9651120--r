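#' R-peak series
#'
#' Container for the R-peak occurrence times of one measurement. Peak
#' detection itself is upstream of this package: recordings are assumed to
#' have been reduced to maternal R-peak times (seconds from recording
#' start), from which the tachogram is built.
#'
#' @param peak_times Numeric vector of R-peak times in seconds, strictly
#'   increasing, all non-negative.
#' @param subject_id,measurement_id Identifiers carried through the
#'   pipeline.
#' @return An object of class `rpeak_series`.
#' @export
rpeak_series <- function(peak_times, subject_id = "S1", measurement_id = "M1") {
  peak_times <- as.numeric(peak_times)
  if (anyNA(peak_times)) stop("peak_times contains missing values")
  if (any(peak_times < 0)) stop("peak_times must be non-negative")
  if (is.unsorted(peak_times, strictly = TRUE))
    stop("peak_times must be strictly increasing")
  structure(list(subject_id = subject_id, measurement_id = measurement_id,
                 peak_times = peak_times),
            class = "rpeak_series")
}

#' @export
print.rpeak_series <- function(x, ...) {
  cat(sprintf("R-peak series %s/%s: %d peaks over %.1f s\n",
              x$subject_id, x$measurement_id, length(x$peak_times),
              diff(range(x$peak_times))))
  invisible(x)
}

FLAG_LEVELS <- c("VALID", "REJECT_RANGE", "REJECT_DELTA", "REJECT_NEIGHBOR")

#' Build a tachogram from R-peak times
#'
#' Differences consecutive R-peak times into RR-interval durations
#' (milliseconds). Interval i spans the half-open window
#' `[peak_i, peak_{i+1})` and is stamped with its onset time (seconds).
#' All intervals start out flagged `VALID`.
#'
#' @param peaks An [rpeak_series], or a numeric vector of peak times in
#'   seconds.
#' @return An object of class `tachogram` with elements `onset_s`,
#'   `rr_ms`, `flag`, and the identifiers.
#' @export
build_tachogram <- function(peaks) {
  if (is.numeric(peaks)) peaks <- rpeak_series(peaks)
  if (!inherits(peaks, "rpeak_series")) stop("peaks must be an rpeak_series")
  pt <- peaks$peak_times
  if (length(pt) < 2) stop("need at least 2 peaks to form an interval")
  structure(list(subject_id = peaks$subject_id,
                 measurement_id = peaks$measurement_id,
                 onset_s = pt[-length(pt)],
                 rr_ms = diff(pt) * 1000,
                 flag = rep("VALID", length(pt) - 1L)),
            class = "tachogram")
}

#' @export
print.tachogram <- function(x, ...) {
  tab <- table(factor(x$flag, levels = FLAG_LEVELS))
  cat(sprintf("Tachogram %s/%s: %d intervals, %d valid (%.1f%%)\n",
              x$subject_id, x$measurement_id, length(x$rr_ms), tab[["VALID"]],
              100 * tab[["VALID"]] / length(x$rr_ms)))
  if (sum(tab[-1]) > 0) {
    cat("  rejected:",
        paste(sprintf("%s=%d", names(tab[-1])[tab[-1] > 0], tab[-1][tab[-1] > 0]),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flag RR intervals outside the physiological range
#'
#' Intervals shorter than `lo_ms` or longer than `hi_ms` are marked
#' `REJECT_RANGE`. The bounds themselves are accepted (an interval of
#' exactly 400 or 2000 ms is inside the admissible range).
#'
#' @param t A [build_tachogram] result.
#' @param lo_ms,hi_ms Admissible RR range in milliseconds; defaults 400
#'   and 2000 (0.4-2 s).
#' @return The tachogram with updated flags.
#' @export
flag_range <- function(t, lo_ms = 400, hi_ms = 2000) {
  stopifnot(inherits(t, "tachogram"))
  if (lo_ms >= hi_ms) stop("lo_ms must be < hi_ms")
  out <- t$rr_ms < lo_ms | t$rr_ms > hi_ms
  t$flag[out] <- "REJECT_RANGE"
  t
}

#' Flag RR intervals deviating from their predecessor
#'
#' An interval whose relative difference from the reference preceding
#' interval exceeds `rel_tol` (strictly) is marked `REJECT_DELTA`.
#' The reference is the most recent interval not already rejected
#' (`reference = "last_accepted"`, the default), so one ectopic beat does
#' not cascade into rejecting the whole record; `reference = "previous"`
#' compares against the raw predecessor instead.
#'
#' @param t Tachogram, typically after [flag_range].
#' @param rel_tol Relative tolerance; default 0.20 (reject when the
#'   difference exceeds 20%).
#' @param reference Either `"last_accepted"` or `"previous"`.
#' @return The tachogram with updated flags.
#' @export
flag_delta <- function(t, rel_tol = 0.20,
                       reference = c("last_accepted", "previous")) {
  stopifnot(inherits(t, "tachogram"))
  reference <- match.arg(reference)
  rr <- t$rr_ms
  flag <- t$flag
  if (reference == "previous") {
    for (i in seq_along(rr)[-1]) {
      if (flag[i] != "VALID") next
      if (abs(rr[i] - rr[i - 1]) / rr[i - 1] > rel_tol) flag[i] <- "REJECT_DELTA"
    }
  } else {
    ref <- NA_real_
    for (i in seq_along(rr)) {
      if (flag[i] != "VALID") next  # already rejected; never a reference
      if (is.na(ref)) {
        ref <- rr[i]
      } else if (abs(rr[i] - ref) / ref > rel_tol) {
        flag[i] <- "REJECT_DELTA"
      } else {
        ref <- rr[i]
      }
    }
  }
  t$flag <- flag
  t
}

#' Flag intervals isolated between two rejections
#'
#' A still-`VALID` interval whose immediate predecessor and successor are
#' both rejected is marked `REJECT_NEIGHBOR`. Applied in a single pass;
#' the first and last intervals, having only one neighbour, are never
#' flagged by this rule.
#'
#' @param t Tachogram after range and delta flagging.
#' @return The tachogram with updated flags.
#' @export
flag_neighbor <- function(t) {
  stopifnot(inherits(t, "tachogram"))
  n <- length(t$flag)
  if (n >= 3) {
    rejected <- t$flag != "VALID"
    mid <- 2:(n - 1)
    hit <- mid[!rejected[mid] & rejected[mid - 1] & rejected[mid + 1]]
    t$flag[hit] <- "REJECT_NEIGHBOR"
  }
  t
}

#' Apply the full artifact-rejection cascade
#'
#' Resets all flags and applies, in order: the physiological-range rule,
#' the successive-difference rule, and the rejected-neighbour rule. The
#' result depends only on the RR values, so repeated application is a
#' no-op (idempotent).
#'
#' @inheritParams flag_range
#' @inheritParams flag_delta
#' @return The cleaned tachogram.
#' @export
clean_tachogram <- function(t, lo_ms = 400, hi_ms = 2000, rel_tol = 0.20,
                            reference = c("last_accepted", "previous")) {
  stopifnot(inherits(t, "tachogram"))
  t$flag <- rep("VALID", length(t$rr_ms))
  t <- flag_range(t, lo_ms, hi_ms)
  t <- flag_delta(t, rel_tol, match.arg(reference))
  flag_neighbor(t)
}

#' Recording reliability report
#'
#' Fraction of intervals carrying any rejection flag. A recording is
#' usable when at most 25% of its intervals are unreliable (the gate is
#' strict: exactly 25% still passes).
#'
#' @param t A cleaned tachogram.
#' @param max_unreliable Exclusion threshold on the unreliable fraction.
#' @return A list of class `reliability_report` with `n_total`,
#'   `n_unreliable`, `unreliable_fraction`, `usable`.
#' @export
reliability <- function(t, max_unreliable = 0.25) {
  stopifnot(inherits(t, "tachogram"))
  n <- length(t$rr_ms)
  if (n == 0) stop("empty tachogram")
  bad <- sum(t$flag != "VALID")
  structure(list(n_total = n, n_unreliable = bad,
                 unreliable_fraction = bad / n,
                 usable = bad / n <= max_unreliable),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("%d/%d intervals unreliable (%.1f%%) -> %s\n",
              x$n_unreliable, x$n_total, 100 * x$unreliable_fraction,
              if (x$usable) "usable" else "excluded"))
  invisible(x)
}

#' Uniformly resampled tachogram
#'
#' Interpolates the RR-versus-time function through the VALID intervals
#' only (rejected intervals are the "missing values", bridged linearly)
#' and resamples it on a uniform grid between the first and last VALID
#' onset. `reliable_mask` is FALSE for grid samples that fall inside the
#' time span of a rejected interval.
#'
#' @param t A cleaned tachogram with at least 2 VALID intervals.
#' @param fs_hz Grid sampling rate in Hz; default 4 (standard for HRV
#'   spectral and EMD analysis).
#' @return A list of class `uniform_rr`: `time_s`, `values_ms`, `fs_hz`,
#'   `reliable_mask`.
#' @export
interpolate_tachogram <- function(t, fs_hz = 4) {
  stopifnot(inherits(t, "tachogram"))
  ok <- t$flag == "VALID"
  if (sum(ok) < 2) stop("need at least 2 VALID intervals to interpolate")
  x <- t$onset_s[ok]
  grid <- seq(x[1], x[length(x)], by = 1 / fs_hz)
  vals <- approx(x, t$rr_ms[ok], xout = grid)$y
  mask <- rep(TRUE, length(grid))
  bad <- which(!ok)
  for (j in bad) {
    inside <- grid >= t$onset_s[j] & grid < t$onset_s[j] + t$rr_ms[j] / 1000
    mask[inside] <- FALSE
  }
  structure(list(time_s = grid, values_ms = vals, fs_hz = fs_hz,
                 reliable_mask = mask),
            class = "uniform_rr")
}

#' Median heart rate of a measurement
#'
#' Median over VALID intervals of the instantaneous heart rate
#' 60000 / RR_ms, in beats per minute. Rejected intervals are excluded,
#' consistent with the unreliable-data handling elsewhere.
#'
#' @param t A cleaned tachogram with at least one VALID interval.
#' @return Median heart rate in bpm.
#' @export
median_hr <- function(t) {
  stopifnot(inherits(t, "tachogram"))
  rr <- t$rr_ms[t$flag == "VALID"]
  if (length(rr) == 0) stop("no VALID intervals")
  median(60000 / rr)
}

#' VALID (normal-to-normal) intervals of a tachogram
#'
#' @param t A cleaned tachogram.
#' @return Numeric vector of the surviving RR durations in ms, in order.
#' @export
nn_intervals <- function(t) {
  stopifnot(inherits(t, "tachogram"))
  t$rr_ms[t$flag == "VALID"]
}

#' @export
as.data.frame.tachogram <- function(x, ...) {
  data.frame(subject_id = x$subject_id, measurement_id = x$measurement_id,
             onset_s = x$onset_s, rr_ms = x$rr_ms, flag = x$flag,
             stringsAsFactors = FALSE)
}
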