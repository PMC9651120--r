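# Empirical mode decomposition: sifting with cubic-spline envelopes,
# mirror-extended extrema, and a Cauchy-type stopping criterion.

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
}

local_minima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] < x[i - 1] & x[i] <= x[i + 1]]
}

# Cubic-spline envelope through (idx, val) with the first/last two extrema
# mirrored beyond the signal ends to suppress spline end swings.
spline_envelope <- function(idx, val, n) {
  k <- length(idx)
  lx <- 2 - idx[c(2, 1)]
  ly <- val[c(2, 1)]
  rx <- 2 * n - idx[c(k, k - 1)]
  ry <- val[c(k, k - 1)]
  splinefun(c(lx, idx, rx), c(ly, val, ry), method = "fmm")(seq_len(n))
}

#' Extract one intrinsic mode function by sifting
#'
#' Iteratively subtracts the mean of the upper and lower cubic-spline
#' envelopes (through local maxima and minima, mirror-extended at the
#' ends) until the Cauchy-type criterion
#' sum((h_prev - h_new)^2) / sum(h_prev^2) falls below `sd_tol`, or
#' `max_iter` sifts have been performed.
#'
#' @param x Numeric signal on a uniform grid.
#' @param sd_tol Stopping threshold between successive sifts; default 0.2.
#' @param max_iter Hard cap on sift iterations; default 50.
#' @return The converged IMF, or `NULL` when the signal has fewer than two
#'   interior maxima or minima (monotone / trend-only signal: the caller
#'   stops decomposing).
#' @export
emd_sift <- function(x, sd_tol = 0.2, max_iter = 50L) {
  h <- as.numeric(x)
  n <- length(h)
  for (iter in seq_len(max_iter)) {
    mx <- local_maxima(h)
    mn <- local_minima(h)
    if (length(mx) < 2 || length(mn) < 2) {
      return(if (iter == 1L) NULL else h)
    }
    env_mean <- (spline_envelope(mx, h[mx], n) +
                 spline_envelope(mn, h[mn], n)) / 2
    denom <- sum(h^2)
    if (denom == 0) return(NULL)
    crit <- sum(env_mean^2) / denom
    h <- h - env_mean
    if (crit < sd_tol) return(h)
  }
  h
}

#' Empirical mode decomposition
#'
#' Repeatedly sifts the residue until it is monotone (no longer supports
#' two maxima and two minima) or `max_imfs` IMFs have been extracted.
#' IMFs are ordered highest-frequency first; by construction the IMFs and
#' the residue sum exactly to the input.
#'
#' @param x Numeric signal on a uniform grid.
#' @param max_imfs Maximum number of IMFs; default 10.
#' @param sd_tol,max_iter Passed to [emd_sift].
#' @return List of class `imf_set` with `imfs` (list, possibly empty) and
#'   `residue`.
#' @export
emd <- function(x, max_imfs = 10L, sd_tol = 0.2, max_iter = 50L) {
  residue <- as.numeric(x)
  imfs <- list()
  while (length(imfs) < max_imfs) {
    imf <- emd_sift(residue, sd_tol = sd_tol, max_iter = max_iter)
    if (is.null(imf)) break
    imfs[[length(imfs) + 1L]] <- imf
    residue <- residue - imf
  }
  structure(list(imfs = imfs, residue = residue), class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("EMD: %d IMFs + residue (n = %d)\n",
              length(x$imfs), length(x$residue)))
  invisible(x)
}

# Analytic signal via the frequency-domain Hilbert transform.
hilbert_analytic <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous frequency of an IMF
#'
#' Computes the analytic signal (FFT Hilbert transform), takes wrapped
#' phase increments between consecutive samples, and scales by
#' fs / (2 pi). The first and last two samples, where the analytic signal
#' is edge-distorted, are discarded.
#'
#' @param imf Numeric IMF, length >= 8.
#' @param fs_hz Sampling rate of the grid in Hz.
#' @return List with `freq_hz` and the matching analytic `amp`litude
#'   (midpoint of the two samples bounding each increment).
#' @export
inst_freq <- function(imf, fs_hz) {
  imf <- as.numeric(imf)
  n <- length(imf)
  if (n < 8) stop("IMF too short for instantaneous frequency")
  if (all(imf == 0)) stop("degenerate (all-zero) IMF")
  z <- hilbert_analytic(imf)
  dp <- diff(Arg(z))
  dp <- (dp + pi) %% (2 * pi) - pi
  f <- dp * fs_hz / (2 * pi)
  a <- (Mod(z)[-1] + Mod(z)[-n]) / 2
  keep <- 3:(length(f) - 2)
  list(freq_hz = f[keep], amp = a[keep])
}
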