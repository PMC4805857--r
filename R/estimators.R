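#' Per-SNP Wald ratio estimates
#'
#' The Wald ratio divides the SNP-outcome effect by the SNP-exposure effect;
#' its first-order standard error is `se_y / |bx|`, which ignores exposure-
#' side sampling error (the summary-data convention; exposure uncertainty is
#' propagated instead by the parametric bootstrap, see [mr_bootstrap()]).
#'
#' @param bx SNP-exposure effect(s); must be nonzero.
#' @param by SNP-outcome effect(s).
#' @param se_y Standard error(s) of `by` (> 0).
#' @return A tibble with columns `ratio` and `se`, one row per SNP.
#' @examples
#' wald_ratio(0.2, 0.05, 0.02)
#' @export
wald_ratio <- function(bx, by, se_y) {
  if (any(bx == 0)) {
    abort("Wald ratio undefined for bx = 0", class = "mrpipe_domain_error")
  }
  if (any(se_y <= 0)) {
    abort("se_y must be positive", class = "mrpipe_validation_error")
  }
  tibble(ratio = by / bx, se = se_y / abs(bx))
}

#' Per-SNP Wald ratio table for an instrument
#'
#' Convenience wrapper producing the per-SNP causal-estimate table used for
#' forest and funnel displays.
#'
#' @param instrument An `mr_instrument`.
#' @param level Confidence level for the per-SNP intervals.
#' @return A tibble with `snp`, `bx`, `by`, `se_y`, `ratio`, `se`,
#'   `ci_low`, `ci_high` (ratio-scale bounds on the log scale), and
#'   `precision` (`1 / se`, the funnel ordinate).
#' @export
wald_ratios <- function(instrument, level = 0.95) {
  instrument <- as_instrument(instrument)
  wr <- wald_ratio(instrument$bx, instrument$by, instrument$se_y)
  z <- qnorm((1 + level) / 2)
  tibble(
    snp = instrument$snp,
    bx = instrument$bx,
    by = instrument$by,
    se_y = instrument$se_y,
    ratio = wr$ratio,
    se = wr$se,
    ci_low = wr$ratio - z * wr$se,
    ci_high = wr$ratio + z * wr$se,
    precision = 1 / wr$se
  )
}

# Weighted least squares by explicit normal equations.
# Returns coefficients, both fixed-effect and dispersion-scaled covariance,
# residual dispersion and df. The fixed-effect vcov is solve(X'WX); the
# multiplicative-dispersion vcov scales it by the weighted residual mean
# square sum(w e^2) / (n - p).
.wls <- function(X, y, w, term_names = colnames(X)) {
  n <- nrow(X)
  p <- ncol(X)
  A <- crossprod(X, w * X)
  qrA <- qr(A)
  if (qrA$rank < p) {
    keep <- qrA$pivot[seq_len(qrA$rank)]
    bad <- term_names[setdiff(seq_len(p), keep)]
    abort(
      paste0("design is rank deficient; collinear column(s): ",
             paste(bad, collapse = ", ")),
      class = "mrpipe_singularity_error"
    )
  }
  coef <- drop(solve(A, crossprod(X, w * y)))
  names(coef) <- term_names
  resid <- y - drop(X %*% coef)
  df <- n - p
  sigma2 <- if (df > 0) sum(w * resid^2) / df else NA_real_
  vcov_fixed <- solve(A)
  dimnames(vcov_fixed) <- list(term_names, term_names)
  list(
    coef = coef,
    vcov_fixed = vcov_fixed,
    vcov_dispersion = sigma2 * vcov_fixed,
    sigma2 = sigma2,
    df = df,
    residuals = resid
  )
}

new_mr_estimate <- function(method, beta, se, p, nsnp, level,
                            df = Inf, covariates = character(),
                            intercept = NULL, intercept_se = NULL,
                            intercept_p = NULL, coefficients = NULL) {
  structure(
    list(
      method = method, beta = beta, se = se, p = p, nsnp = nsnp,
      level = level, df = df, covariates = covariates,
      intercept = intercept, intercept_se = intercept_se,
      intercept_p = intercept_p, coefficients = coefficients
    ),
    class = "mr_estimate"
  )
}

#' Inverse-variance-weighted (IVW) causal estimate
#'
#' Regresses SNP-outcome effects on SNP-exposure effects through the origin,
#' weighting each SNP by the inverse variance of its outcome effect:
#' `beta = sum(w * bx * by) / sum(w * bx^2)` with `w = 1 / se_y^2` and
#' fixed-effect SE `sqrt(1 / sum(w * bx^2))`. Equivalent to the precision-
#' weighted average of the per-SNP Wald ratios.
#'
#' @param instrument An `mr_instrument` (or wide table coercible via
#'   [as_instrument()]).
#' @param level Confidence level for reported intervals.
#' @param dispersion `"fixed"` (default) uses the fixed-effect SE with a
#'   normal p-value; `"multiplicative"` inflates the SE by the residual
#'   dispersion and uses t(J - 1) inference.
#' @return An `mr_estimate`; see [tidy.mr_estimate()] and
#'   [glance.mr_estimate()].
#' @examples
#' inst <- as_instrument(data.frame(
#'   snp = paste0("rs", 1:3), bx = c(0.1, 0.2, 0.3), se_x = 0.01,
#'   by = c(0.02, 0.05, 0.06), se_y = c(0.01, 0.02, 0.03)
#' ))
#' mr_ivw(inst)
#' @export
mr_ivw <- function(instrument, level = 0.95,
                   dispersion = c("fixed", "multiplicative")) {
  dispersion <- match.arg(dispersion)
  instrument <- as_instrument(instrument)
  if (all(instrument$bx == 0)) {
    abort("all exposure effects are zero; instrument is singular",
          class = "mrpipe_singularity_error")
  }
  X <- matrix(instrument$bx, ncol = 1, dimnames = list(NULL, "exposure"))
  w <- 1 / instrument$se_y^2
  fit <- .wls(X, instrument$by, w)
  .estimate_from_fit(fit, method = "ivw", slope_term = "exposure",
                     nsnp = nrow(instrument), level = level,
                     dispersion = dispersion)
}

#' Multivariable MR estimate adjusting for measured pleiotropy
#'
#' Extends the IVW regression with the SNPs' associations with measured
#' pleiotropic phenotypes as additional covariate columns (no intercept,
#' weights `1 / se_y^2`). The reported effect is the exposure coefficient
#' from the weighted normal equations; covariate path coefficients are
#' available via [tidy.mr_estimate()].
#'
#' @inheritParams mr_ivw
#' @param covariates Labels of covariate columns to adjust for; defaults to
#'   every covariate carried by the instrument.
#' @return An `mr_estimate` with a `coefficients` table holding all fitted
#'   terms.
#' @export
mr_mvmr <- function(instrument, covariates = instrument_covariates(instrument),
                    level = 0.95, dispersion = c("fixed", "multiplicative")) {
  dispersion <- match.arg(dispersion)
  instrument <- as_instrument(instrument)
  covariates <- as.character(covariates)
  missing <- setdiff(covariates, instrument_covariates(instrument))
  if (length(missing) > 0) {
    abort(paste0("instrument carries no covariate(s): ",
                 paste(missing, collapse = ", ")),
          class = "mrpipe_parameter_error")
  }
  J <- nrow(instrument)
  if (J < length(covariates) + 1) {
    abort("need at least one more SNP than fitted terms",
          class = "mrpipe_parameter_error")
  }
  BC <- .cov_matrix(instrument, covariates)
  zero <- colSums(BC != 0) == 0
  if (any(zero)) {
    # a covariate with no SNP associations carries no adjustment information
    inform(paste0("covariate(s) with all-zero associations dropped from fit: ",
                  paste(covariates[zero], collapse = ", ")))
    BC <- BC[, !zero, drop = FALSE]
  }
  X <- cbind(exposure = instrument$bx, BC)
  w <- 1 / instrument$se_y^2
  fit <- .wls(X, instrument$by, w)
  .estimate_from_fit(fit, method = "mvmr", slope_term = "exposure",
                     nsnp = J, level = level, dispersion = dispersion,
                     covariates = covariates)
}

#' Egger-regression MR estimate and pleiotropy test
#'
#' Weighted regression of outcome on exposure effects with an unconstrained
#' intercept (weights `1 / se_y^2`). The intercept estimates the average
#' directional (horizontal) pleiotropic effect; a nonzero intercept is
#' evidence of unbalanced pleiotropy, and the slope is a pleiotropy-robust
#' causal estimate under the InSIDE assumption. Because the intercept is not
#' invariant to allele orientation, SNPs are re-oriented so every exposure
#' effect is non-negative before fitting. Inference uses t(J - 2) with the
#' residual-dispersion-scaled SE.
#'
#' @inheritParams mr_ivw
#' @return An `mr_estimate` with `intercept`, `intercept_se`, `intercept_p`.
#' @export
mr_egger <- function(instrument, level = 0.95) {
  instrument <- as_instrument(instrument)
  J <- nrow(instrument)
  if (J < 3) {
    abort("Egger regression needs at least 3 SNPs",
          class = "mrpipe_insufficient_snps_error")
  }
  flip <- sign(instrument$bx)
  flip[flip == 0] <- 1
  X <- cbind(intercept = 1, exposure = flip * instrument$bx)
  y <- flip * instrument$by
  w <- 1 / instrument$se_y^2
  fit <- .wls(X, y, w)
  se_all <- sqrt(diag(fit$vcov_dispersion))
  tstat <- fit$coef / se_all
  pvals <- 2 * pt(abs(tstat), df = fit$df, lower.tail = FALSE)
  z <- qnorm((1 + level) / 2)
  est <- new_mr_estimate(
    method = "egger",
    beta = unname(fit$coef["exposure"]),
    se = unname(se_all["exposure"]),
    p = unname(pvals["exposure"]),
    nsnp = J, level = level, df = fit$df,
    intercept = unname(fit$coef["intercept"]),
    intercept_se = unname(se_all["intercept"]),
    intercept_p = unname(pvals["intercept"]),
    coefficients = tibble(
      term = names(fit$coef),
      estimate = unname(fit$coef),
      std.error = unname(se_all),
      statistic = unname(tstat),
      p.value = unname(pvals)
    )
  )
  est
}

.estimate_from_fit <- function(fit, method, slope_term, nsnp, level,
                               dispersion, covariates = character()) {
  if (dispersion == "fixed" || fit$df <= 0) {
    vc <- fit$vcov_fixed
    df <- Inf
  } else {
    vc <- fit$vcov_dispersion
    df <- fit$df
  }
  se_all <- sqrt(diag(vc))
  stat <- fit$coef / se_all
  pvals <- if (is.infinite(df)) {
    2 * pnorm(abs(stat), lower.tail = FALSE)
  } else {
    2 * pt(abs(stat), df = df, lower.tail = FALSE)
  }
  new_mr_estimate(
    method = method,
    beta = unname(fit$coef[slope_term]),
    se = unname(se_all[slope_term]),
    p = unname(pvals[slope_term]),
    nsnp = nsnp, level = level, df = df, covariates = covariates,
    coefficients = tibble(
      term = names(fit$coef),
      estimate = unname(fit$coef),
      std.error = unname(se_all),
      statistic = unname(stat),
      p.value = unname(pvals)
    )
  )
}

#' Cochran Q heterogeneity of per-SNP causal estimates
#'
#' Measures the dispersion of the per-SNP Wald ratios around a causal
#' estimate `theta`: `Q = sum((ratio_j - theta)^2 / se_rj^2)` with
#' first-order ratio SEs `se_y / |bx|`, referred to chi-square on `J - 1`
#' df. Excess heterogeneity suggests pleiotropy or otherwise invalid
#' instruments.
#'
#' @param instrument An `mr_instrument` with at least 2 SNPs.
#' @param theta Causal effect to measure dispersion around; defaults to the
#'   IVW estimate of the instrument.
#' @return A one-row tibble: `q`, `df`, `p`.
#' @export
cochran_q <- function(instrument, theta = NULL) {
  instrument <- as_instrument(instrument)
  if (nrow(instrument) < 2) {
    abort("Cochran Q needs at least 2 SNPs", class = "mrpipe_parameter_error")
  }
  if (is.null(theta)) theta <- mr_ivw(instrument)$beta
  wr <- wald_ratio(instrument$bx, instrument$by, instrument$se_y)
  q <- sum((wr$ratio - theta)^2 / wr$se^2)
  df <- nrow(instrument) - 1L
  tibble(q = q, df = df, p = pchisq(q, df = df, lower.tail = FALSE))
}

#' Run every MR estimator on one instrument
#'
#' Produces a results table in the conventional layout of summary-data MR
#' reports: one row per method with the odds ratio per SD of exposure, its
#' confidence interval, p-value, Egger intercept test, and the Cochran Q
#' heterogeneity of the instrument.
#'
#' @inheritParams mr_mvmr
#' @param methods Which estimators to run.
#' @return A tibble, one row per method, as returned by
#'   [glance.mr_estimate()] plus `q`, `q_df`, `q_p`.
#' @export
mr_all <- function(instrument,
                   covariates = instrument_covariates(instrument),
                   methods = c("ivw", "mvmr", "egger"),
                   level = 0.95) {
  instrument <- as_instrument(instrument)
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(covariates) == 0) methods <- setdiff(methods, "mvmr")
  fits <- purrr::map(methods, function(m) {
    switch(m,
      ivw = mr_ivw(instrument, level = level),
      mvmr = mr_mvmr(instrument, covariates = covariates, level = level),
      egger = mr_egger(instrument, level = level)
    )
  })
  het <- cochran_q(instrument)
  dplyr::bind_rows(purrr::map(fits, glance)) |>
    dplyr::mutate(q = het$q, q_df = het$df, q_p = het$p)
}

# Dispatches an estimator by label; used by resampling and the pipeline.
.fit_method <- function(instrument, method, covariates = character(),
                        level = 0.95) {
  switch(method,
    ivw = mr_ivw(instrument, level = level),
    mvmr = mr_mvmr(instrument, covariates = covariates, level = level),
    egger = mr_egger(instrument, level = level),
    abort(paste0("unknown method: ", method), class = "mrpipe_parameter_error")
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  lab <- switch(x$method,
    ivw = "Inverse-variance-weighted MR",
    mvmr = "Multivariable MR",
    egger = "Egger-regression MR",
    x$method
  )
  ci <- to_effect_with_ci(x$beta, x$se, x$level)
  cat(lab, sprintf("(%d SNPs)\n", x$nsnp))
  if (length(x$covariates) > 0) {
    cat("  adjusted for:", paste(x$covariates, collapse = ", "), "\n")
  }
  cat(sprintf("  beta %.4f (se %.4f), OR %.4f (%d%% CI %.4f-%.4f), p = %.3g\n",
              x$beta, x$se, ci$or, round(100 * x$level), ci$ci_low,
              ci$ci_high, x$p))
  if (!is.null(x$intercept)) {
    cat(sprintf("  Egger intercept %.5f (se %.5f), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  }
  invisible(x)
}

#' Tidy an MR estimate
#'
#' @param x An `mr_estimate`.
#' @param ... Unused.
#' @return A tibble with one row per fitted term (`term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`).
#' @method tidy mr_estimate
#' @export
tidy.mr_estimate <- function(x, ...) {
  if (!is.null(x$coefficients)) {
    dplyr::mutate(x$coefficients, method = x$method, .before = 1)
  } else {
    tibble(method = x$method, term = "exposure", estimate = x$beta,
           std.error = x$se, statistic = x$beta / x$se, p.value = x$p)
  }
}

#' One-row summary of an MR estimate
#'
#' @param x An `mr_estimate`.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `nsnp`, `covariates`, `beta`, `se`,
#'   `or`, `ci_low`, `ci_high`, `p`, `intercept`, `intercept_se`,
#'   `intercept_p`, `level`.
#' @method glance mr_estimate
#' @export
glance.mr_estimate <- function(x, ...) {
  ci <- to_effect_with_ci(x$beta, x$se, x$level)
  tibble(
    method = x$method,
    nsnp = x$nsnp,
    covariates = paste(x$covariates, collapse = ","),
    beta = x$beta,
    se = x$se,
    or = ci$or,
    ci_low = ci$ci_low,
    ci_high = ci$ci_high,
    p = x$p,
    intercept = x$intercept %||% NA_real_,
    intercept_se = x$intercept_se %||% NA_real_,
    intercept_p = x$intercept_p %||% NA_real_,
    level = x$level
  )
}
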