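#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j), with R^2_j from regressing covariate j on all
#' the others (with intercept). Values between 1 and 5 are conventionally
#' acceptable. Exact collinearity yields `Inf` for the columns involved.
#'
#' @param frame A data.frame; the covariates are all columns except `y`,
#'   `subject_id`, `measurement_id`, or an explicit `covariates` vector.
#' @param covariates Optional character vector of covariate columns.
#' @return Named numeric vector of VIFs.
#' @export
vif_values <- function(frame, covariates = NULL) {
  if (is.null(covariates)) covariates <- frame_covariates(frame)
  if (length(covariates) < 2) stop("VIF needs at least 2 covariates")
  X <- as.data.frame(frame)[covariates]
  vapply(covariates, function(j) {
    f <- lm(as.formula(paste0("`", j, "` ~ .")), data = X)
    r2 <- suppressWarnings(summary(f)$r.squared)  # exact fit is the Inf case
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Fit the fixed-effects multiple linear regression
#'
#' Least-squares fit of the transformed HRV feature on the demographic
#' and cardiorespiratory covariates, with the overall F-test against the
#' intercept-only model, adjusted R^2, VIFs, leverage, and Cook's
#' distances. The log-likelihood is the ML value, directly comparable
#' with the ML-fitted mixed model in [lrt].
#'
#' @param frame A [build_frame] result (or any data.frame with a `y`
#'   column and covariate columns).
#' @param covariates Covariate columns; default all columns except `y`
#'   and the identifiers.
#' @return Object of class `mhrv_mlr`.
#' @export
fit_mlr <- function(frame, covariates = NULL) {
  if (is.null(covariates)) covariates <- frame_covariates(frame)
  dat <- as.data.frame(frame)
  p <- length(covariates)
  if (nrow(dat) <= p + 1) stop("more parameters than observations")
  fml <- as.formula(paste("y ~", paste0("`", covariates, "`", collapse = " + ")))
  fit <- lm(fml, data = dat)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; offending columns: ",
         paste(bad, collapse = ", "))
  }
  s <- summary(fit)
  structure(list(
    fit = fit, frame = frame, covariates = covariates,
    dv_name = attr(frame, "dv_name"),
    n = nrow(dat), p = p,
    beta = coef(fit), se = s$coefficients[, "Std. Error"],
    ci95 = confint(fit), p_values = s$coefficients[, 4],
    residuals = resid(fit), fitted = fitted(fit),
    f_statistic = unname(s$fstatistic["value"]),
    f_pvalue = unname(pf(s$fstatistic["value"], s$fstatistic["numdf"],
                         s$fstatistic["dendf"], lower.tail = FALSE)),
    r2 = s$r.squared, r2_adjusted = s$adj.r.squared,
    loglik = as.numeric(logLik(fit)),
    vif = if (p >= 2) vif_values(dat, covariates) else NULL,
    leverage = unname(hatvalues(fit)),
    cooks_d = unname(cooks.distance(fit))
  ), class = "mhrv_mlr")
}

#' @export
print.mhrv_mlr <- function(x, ...) {
  cat(sprintf("MLR (fixed effects only)%s: n = %d, p = %d\n",
              if (!is.null(x$dv_name)) paste0(" for ", toupper(x$dv_name)) else "",
              x$n, x$p))
  cat(sprintf("  F = %.2f (p = %.3g), adjusted R^2 = %.3f\n",
              x$f_statistic, x$f_pvalue, x$r2_adjusted))
  invisible(x)
}

#' @export
summary.mhrv_mlr <- function(object, ...) summary(object$fit, ...)

#' @export
coef.mhrv_mlr <- function(object, ...) object$beta

#' @export
residuals.mhrv_mlr <- function(object, ...) object$residuals

#' @export
logLik.mhrv_mlr <- function(object, ...) logLik(object$fit)

#' @export
predict.mhrv_mlr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  predict(object$fit, newdata = as.data.frame(newdata), ...)
}

#' @export
plot.mhrv_mlr <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  stats::qqnorm(x$residuals, main = "Normal Q-Q of residuals")
  stats::qqline(x$residuals)
  plot(x$fitted, x$residuals, xlab = "Fitted", ylab = "Residuals",
       main = "Fitted vs residuals"); graphics::abline(h = 0, lty = 2)
  plot(x$leverage, x$residuals, xlab = "Leverage", ylab = "Residuals",
       main = "Residuals vs leverage",
       cex = 0.5 + 2 * sqrt(x$cooks_d / max(x$cooks_d, na.rm = TRUE)))
  graphics::hist(x$residuals, main = "Residual histogram", xlab = "Residual")
  invisible(x)
}

#' Regression diagnostics bundle
#'
#' Numeric series behind the standard assumption checks: normal-quantile
#' pairs for the residuals, fitted-versus-residual pairs, leverage and
#' Cook's distance per row (fixed-effects model), per-subject intercept
#' deviations (mixed model), and the rows flagged as influential.
#'
#' @param fit An `mhrv_mlr` or `mhrv_lmm` object.
#' @param cooks_threshold Primary influence flag, default D > 1; an
#'   advisory list at D > 4/n is always included for the MLR.
#' @return List of class `mhrv_diagnostics`.
#' @export
diagnostics <- function(fit, cooks_threshold = 1.0) {
  r <- if (inherits(fit, "mhrv_mlr")) fit$residuals else fit$residuals
  n <- length(r)
  qq <- data.frame(theoretical = qnorm(ppoints(n)), sample = sort(r))
  out <- list(qq = qq,
              fitted_resid = data.frame(fitted = fit$fitted, resid = r))
  if (inherits(fit, "mhrv_mlr")) {
    out$leverage <- fit$leverage
    out$cooks_d <- fit$cooks_d
    out$influential <- which(fit$cooks_d > cooks_threshold)
    out$advisory <- which(fit$cooks_d > 4 / n)
  } else if (inherits(fit, "mhrv_lmm")) {
    out$blups <- fit$blups
  } else stop("fit must be mhrv_mlr or mhrv_lmm")
  structure(out, class = "mhrv_diagnostics")
}

#' Remove unduly influential observations and refit
#'
#' Flags rows whose Cook's distance exceeds `threshold` (default 1.0),
#' removes at most `max_removals` of them (largest first), refits, and
#' reports the before/after coefficients together with the removed rows
#' and their distances. Zero removals is a valid outcome.
#'
#' @param fit An `mhrv_mlr` object.
#' @param max_removals Cap on removed rows, default 2.
#' @param threshold Cook's distance threshold, default 1.0.
#' @return List with `fit` (refit, or the original when nothing was
#'   removed), `frame`, `removed` (data.frame of row indices and
#'   distances), `coef_before`, `coef_after`.
#' @export
remove_influential <- function(fit, max_removals = 2L, threshold = 1.0) {
  stopifnot(inherits(fit, "mhrv_mlr"))
  d <- fit$cooks_d
  cand <- which(d > threshold)
  cand <- cand[order(d[cand], decreasing = TRUE)]
  # never remove so many rows that the model becomes unidentifiable
  max_allowed <- max(0L, fit$n - (fit$p + 2L))
  rows <- head(cand, min(max_removals, max_allowed))
  removed <- data.frame(row = rows, cooks_d = d[rows])
  if (length(rows) == 0) {
    return(list(fit = fit, frame = fit$frame, removed = removed,
                coef_before = fit$beta, coef_after = fit$beta))
  }
  frame2 <- fit$frame[-rows, , drop = FALSE]
  for (a in c("dv_name", "transform", "n_dropped", "n_unusable"))
    attr(frame2, a) <- attr(fit$frame, a)
  fit2 <- fit_mlr(frame2, fit$covariates)
  list(fit = fit2, frame = frame2, removed = removed,
       coef_before = fit$beta, coef_after = fit2$beta)
}

#' Screen the fetal-CHD covariate
#'
#' Fits each dependent variable's MLR with and without the fetal-CHD
#' flag and reports the CHD coefficient, its p-value, and the drop/keep
#' decision at alpha = 0.05 (CHD is retained only when it has a
#' significant effect).
#'
#' @param features,cohort As for [build_frame]; `cohort` must carry a
#'   `chd` column.
#' @param dv_names Dependent variables to screen.
#' @param alpha Significance level for keeping CHD, default 0.05.
#' @return data.frame with one row per DV: coefficient, p, decision; or,
#'   when the CHD column is constant (all 0 or all 1), a zero-row frame
#'   with attribute `skipped` explaining why.
#' @export
chd_screen <- function(features, cohort,
                       dv_names = c("sdnn", "rmssd", "sampen"),
                       alpha = 0.05) {
  if (!"chd" %in% names(cohort)) {
    out <- data.frame()
    attr(out, "skipped") <- "no chd column in cohort"
    message("CHD screen skipped: no chd column")
    return(out)
  }
  if (length(unique(cohort$chd)) < 2) {
    out <- data.frame()
    attr(out, "skipped") <- "chd column is constant"
    message("CHD screen skipped: chd column is constant")
    return(out)
  }
  rows <- lapply(dv_names, function(dv) {
    fr <- build_frame(features, cohort, dv, include_chd = TRUE)
    fit <- fit_mlr(fr)
    fr0 <- build_frame(features, cohort, dv, include_chd = FALSE)
    fit0 <- fit_mlr(fr0)
    p <- unname(fit$p_values["chd"])
    data.frame(dv_name = dv, chd_beta = unname(fit$beta["chd"]),
               chd_p = p, decision = if (p < alpha) "keep" else "drop",
               adj_r2_with = fit$r2_adjusted, adj_r2_without = fit0$r2_adjusted,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Covariate effect curve at median co-levels
#'
#' Predicted transformed DV as the chosen covariate sweeps its 5th to
#' 95th percentile (for a binary covariate, the grid is {0, 1}) while all
#' other covariates are held at their sample medians; pointwise 95%
#' confidence bands come from the coefficient covariance. The covariate's
#' p-value is attached, with `significant = TRUE` below `alpha` (the
#' plot-annotation rule).
#'
#' @param fit An `mhrv_mlr` or `mhrv_lmm` object.
#' @param iv_name Covariate to sweep.
#' @param n_grid Grid length, default 50.
#' @param alpha Annotation threshold, default 0.05.
#' @return data.frame of class `mhrv_effect_curve` with columns
#'   `iv_value`, `yhat`, `ci_low`, `ci_high`; attributes `iv_name`,
#'   `dv_name`, `p_value`, `significant`.
#' @export
effect_curve <- function(fit, iv_name, n_grid = 50L, alpha = 0.05) {
  stopifnot(inherits(fit, "mhrv_mlr") || inherits(fit, "mhrv_lmm"))
  covs <- fit$covariates
  if (!iv_name %in% covs) stop("unknown covariate: ", iv_name)
  dat <- as.data.frame(fit$frame)
  xv <- dat[[iv_name]]
  grid <- if (all(xv %in% c(0, 1))) c(0, 1) else {
    q <- quantile(xv, c(0.05, 0.95), names = FALSE)
    seq(q[1], q[2], length.out = n_grid)
  }
  newdata <- as.data.frame(lapply(dat[covs], median))
  newdata <- newdata[rep(1, length(grid)), , drop = FALSE]
  newdata[[iv_name]] <- grid
  X <- cbind(1, as.matrix(newdata[covs]))
  beta <- fit$beta
  V <- if (inherits(fit, "mhrv_mlr")) vcov(fit$fit) else fit$vcov_beta
  yhat <- drop(X %*% beta)
  se <- sqrt(rowSums((X %*% V) * X))
  z <- if (inherits(fit, "mhrv_mlr"))
    qt(0.975, stats::df.residual(fit$fit)) else qnorm(0.975)
  p <- unname(fit$p_values[iv_name])
  structure(data.frame(iv_value = grid, yhat = yhat,
                       ci_low = yhat - z * se, ci_high = yhat + z * se),
            iv_name = iv_name, dv_name = fit$dv_name, p_value = p,
            significant = is.finite(p) && p < alpha,
            class = c("mhrv_effect_curve", "data.frame"))
}

#' @export
plot.mhrv_effect_curve <- function(x, ...) {
  plot(x$iv_value, x$yhat, type = "l", ylim = range(x$ci_low, x$ci_high),
       xlab = attr(x, "iv_name"),
       ylab = paste("transformed", attr(x, "dv_name")), ...)
  graphics::lines(x$iv_value, x$ci_low, lty = 2)
  graphics::lines(x$iv_value, x$ci_high, lty = 2)
  if (isTRUE(attr(x, "significant")))
    graphics::mtext(sprintf("p = %.3g", attr(x, "p_value")), side = 3,
                    adj = 1, cex = 0.8)
  invisible(x)
}
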