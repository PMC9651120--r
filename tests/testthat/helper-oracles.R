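# Independent oracles and small fixture builders used across the suite.

# Brute-force SampEn by explicit pair enumeration (Richman-Moorman:
# templates of length m and m+1 both indexed i = 1..N-m, self-matches
# excluded). Written independently of the package implementation; returns
# the match counts as well so equality can be asserted at the count level.
sampen_bruteforce <- function(x, m = 2, r_frac = 0.2) {
  n <- length(x)
  r <- r_frac * sd(x)
  nt <- n - m
  A <- 0L
  B <- 0L
  for (i in 1:nt) {
    for (j in 1:nt) {
      if (i == j) next
      dm <- 0
      for (k in 0:(m - 1)) dm <- max(dm, abs(x[i + k] - x[j + k]))
      if (dm <= r) {
        B <- B + 1L
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) A <- A + 1L
      }
    }
  }
  list(A = A, B = B,
       sampen = if (A == 0L || B == 0L) NA_real_ else -log(A / B))
}

# Tachogram with a given RR sequence (ms), onset-timed from zero.
toy_tachogram <- function(rr_ms) {
  build_tachogram(rpeak_series(cumsum(c(0, rr_ms)) / 1000))
}

# Balanced repeated-measures cohort: n_subjects x 8 visits, no dropout.
balanced_cohort <- function(n_subjects = 29, seed = 1) {
  sample_cohort(cohort_config(
    n_subjects = n_subjects, design = "repeated",
    ga_schedule = c(14, 18, 22, 26, 30, 34, 38, 40),
    dropout_prob = 0, seed = seed))
}

# One-way random-effects ANOVA estimator of the variance components on a
# balanced design (independent closed-form oracle for the ICC).
anova_icc <- function(y, group) {
  k <- length(unique(group))
  m <- length(y) / k
  gm <- tapply(y, group, mean)
  msb <- m * sum((gm - mean(y))^2) / (k - 1)
  msw <- sum((y - gm[group])^2) / (k * (m - 1))
  s2b <- max(0, (msb - msw) / m)
  s2b / (s2b + msw)
}
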