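#' Fit the random-intercept linear mixed model
#'
#' Fits y = X beta + b_subject + e, with b ~ N(0, sigma2_b) a per-subject
#' intercept deviation and e ~ N(0, sigma2_e), twice: by maximum
#' likelihood, whose log-likelihood underlies the valid likelihood-ratio
#' test against the fixed-effects-only model ([lrt]) and whose
#' coefficients are reported, and by REML, whose variance components are
#' the ones reported and used for the intra-class correlation. REML is
#' used for the components because the ML estimate of sigma2_b is biased
#' low by a factor of about (n_subjects - q)/n_subjects when q
#' between-subject fixed parameters are estimated - material at 29
#' subjects with age, BMI and parity in the model (the ML components are
#' still available as `sigma2_b_ml`, `sigma2_e_ml`, `icc_ml`).
#'
#' Also returned: per-subject BLUPs and two goodness-of-fit summaries -
#' an adjusted R^2 computed from the conditional
#' (random-effects-included) fitted values, and the Nakagawa-style
#' marginal/conditional pseudo-R^2 pair.
#'
#' @param frame A [build_frame] result or any data.frame with `y`,
#'   covariates, and a `subject_id` grouping column (>= 2 subjects with
#'   repeated measurements for identifiability).
#' @param covariates Covariate columns; default all except `y` and
#'   identifiers.
#' @return Object of class `mhrv_lmm`.
#' @export
fit_lmm <- function(frame, covariates = NULL) {
  if (is.null(covariates)) covariates <- frame_covariates(frame)
  dat <- as.data.frame(frame)
  if (!"subject_id" %in% names(dat)) stop("frame needs a subject_id column")
  if (length(unique(dat$subject_id)) < 2) stop("need >= 2 subjects")
  fml <- as.formula(paste("y ~", paste0("`", covariates, "`", collapse = " + "),
                          "+ (1 | subject_id)"))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- lmerTest::lmer(fml, data = dat, REML = FALSE, control = ctrl)
  fit_reml <- lme4::lmer(fml, data = dat, REML = TRUE, control = ctrl)
  vc_ml <- as.data.frame(lme4::VarCorr(fit))
  sigma2_b_ml <- vc_ml$vcov[vc_ml$grp == "subject_id"]
  sigma2_e_ml <- stats::sigma(fit)^2
  vc <- as.data.frame(lme4::VarCorr(fit_reml))
  sigma2_b <- vc$vcov[vc$grp == "subject_id"]
  sigma2_e <- stats::sigma(fit_reml)^2
  beta <- lme4::fixef(fit)
  names(beta) <- gsub("`", "", names(beta))
  V <- as.matrix(vcov(fit))
  dimnames(V) <- list(names(beta), names(beta))
  se <- sqrt(diag(V))
  # Satterthwaite degrees of freedom: between-subject covariates carry
  # far fewer effective df than rows, so z intervals would under-cover
  st <- tryCatch(coef(summary(fit)), error = function(e) NULL)
  if (!is.null(st) && "df" %in% colnames(st)) {
    df_t <- st[, "df"]
    p_values <- st[, "Pr(>|t|)"]
  } else {
    df_t <- rep(Inf, length(beta))
    p_values <- 2 * pnorm(-abs(beta / se))
  }
  names(df_t) <- names(p_values) <- names(beta)
  tcrit <- qt(0.975, df_t)
  n <- nrow(dat)
  p <- length(covariates)
  fitted_c <- fitted(fit)     # conditional: includes the subject intercepts
  r <- dat$y - fitted_c
  sse <- sum(r^2)
  sst <- sum((dat$y - mean(dat$y))^2)
  r2_adj <- 1 - (sse / sst) * (n - 1) / (n - p - 1)
  # Nakagawa decomposition: fixed-effect variance vs variance components
  var_f <- var(drop(cbind(1, as.matrix(dat[covariates])) %*% beta))
  tot <- var_f + sigma2_b + sigma2_e
  blups <- lme4::ranef(fit_reml)$subject_id
  structure(list(
    fit = fit, frame = frame, covariates = covariates,
    dv_name = attr(frame, "dv_name"), n = n, p = p,
    n_subjects = length(unique(dat$subject_id)),
    beta = beta, se = se, vcov_beta = V, df_satterthwaite = df_t,
    ci95 = cbind(lower = beta - tcrit * se,
                 upper = beta + tcrit * se),
    p_values = p_values,
    sigma2_b = sigma2_b, sigma2_e = sigma2_e,
    icc = sigma2_b / (sigma2_b + sigma2_e),
    sigma2_b_ml = sigma2_b_ml, sigma2_e_ml = sigma2_e_ml,
    icc_ml = sigma2_b_ml / (sigma2_b_ml + sigma2_e_ml),
    loglik = as.numeric(logLik(fit)),
    r2_adjusted = r2_adj,
    r2_marginal = var_f / tot,
    r2_conditional = (var_f + sigma2_b) / tot,
    residuals = r, fitted = fitted_c,
    blups = setNames(blups[, 1], rownames(blups))
  ), class = "mhrv_lmm")
}

#' @export
print.mhrv_lmm <- function(x, ...) {
  cat(sprintf("Random-intercept LMM%s: n = %d rows, %d subjects\n",
              if (!is.null(x$dv_name)) paste0(" for ", toupper(x$dv_name)) else "",
              x$n, x$n_subjects))
  cat(sprintf("  sigma2_b = %.4f, sigma2_e = %.4f, ICC = %.3f\n",
              x$sigma2_b, x$sigma2_e, x$icc))
  cat(sprintf("  adjusted R^2 (conditional fit) = %.3f; Nakagawa R^2m = %.3f, R^2c = %.3f\n",
              x$r2_adjusted, x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' @export
summary.mhrv_lmm <- function(object, ...) summary(object$fit, ...)

#' @export
coef.mhrv_lmm <- function(object, ...) object$beta

#' @export
residuals.mhrv_lmm <- function(object, ...) object$residuals

#' @export
logLik.mhrv_lmm <- function(object, ...) logLik(object$fit)

#' @export
predict.mhrv_lmm <- function(object, newdata = NULL, level = 0, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- cbind(1, as.matrix(as.data.frame(newdata)[object$covariates]))
  drop(X %*% object$beta)
}

#' Intra-class correlation of a fitted mixed model
#'
#' sigma2_b / (sigma2_b + sigma2_e): the fraction of residual variance in
#' the (transformed) HRV feature attributable to stable inter-subject
#' differences.
#'
#' @param fit An `mhrv_lmm` object.
#' @return ICC in \[0, 1\].
#' @export
icc <- function(fit) {
  stopifnot(inherits(fit, "mhrv_lmm"))
  fit$icc
}

#' Likelihood-ratio test for the random intercept
#'
#' stat = 2 (logLik_LMM - logLik_MLR), clipped at zero. Because the null
#' value of the intercept variance lies on the boundary of the parameter
#' space, the reference distribution is the 50:50 mixture of chi-square
#' with 0 and 1 degrees of freedom; the naive chi-square(1) p-value is
#' also reported for comparability with software that uses it.
#'
#' @param lmm An `mhrv_lmm` fit.
#' @param mlr The `mhrv_mlr` fit on the same frame with the same fixed
#'   effects (both ML).
#' @return List of class `mhrv_lrt`: `stat`, `p_value` (mixture),
#'   `p_chisq1` (naive), `df`.
#' @export
lrt <- function(lmm, mlr) {
  stopifnot(inherits(lmm, "mhrv_lmm"), inherits(mlr, "mhrv_mlr"))
  if (lmm$n != mlr$n || !identical(sort(lmm$covariates), sort(mlr$covariates)))
    stop("models were not fit to the same frame with the same fixed effects")
  stat <- max(0, 2 * (lmm$loglik - mlr$loglik))
  p_mix <- if (stat == 0) 1 else 0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
  structure(list(stat = stat, p_value = p_mix,
                 p_chisq1 = pchisq(stat, df = 1, lower.tail = FALSE), df = 1),
            class = "mhrv_lrt")
}

#' @export
print.mhrv_lrt <- function(x, ...) {
  cat(sprintf("LRT for the random intercept: stat = %.3f, p = %.3g (chi2_0/chi2_1 mixture; naive chi2_1 p = %.3g)\n",
              x$stat, x$p_value, x$p_chisq1))
  invisible(x)
}
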