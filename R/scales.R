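#' Standard error from a published odds-ratio confidence interval
#'
#' Recovers the log-scale standard error implied by a symmetric Wald
#' confidence interval reported on the odds-ratio scale:
#' `(log(or_high) - log(or_low)) / (2 * z)` with `z` the standard-normal
#' quantile at `(1 + level) / 2`.
#'
#' @param or_low,or_high Lower and upper interval bounds (ratios, > 0).
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Standard error on the log-odds scale.
#' @examples
#' ci_to_se(0.9191, 1.1968) # SE behind an OR 1.05 (0.92-1.20)
#' @export
ci_to_se <- function(or_low, or_high, level = 0.95) {
  if (any(or_low <= 0)) {
    abort("or_low must be positive", class = "mrpipe_domain_error")
  }
  if (any(or_high < or_low)) {
    abort("or_high must be >= or_low", class = "mrpipe_domain_error")
  }
  if (level <= 0 || level >= 1) {
    abort("level must be in (0, 1)", class = "mrpipe_domain_error")
  }
  (log(or_high) - log(or_low)) / (2 * qnorm((1 + level) / 2))
}

#' Present a log-scale effect as an odds ratio with confidence interval
#'
#' @param beta Log-scale effect (log-odds per SD for binary outcomes).
#' @param se Standard error of `beta` (>= 0).
#' @param level Confidence level in (0, 1).
#' @return A one-row tibble per input with `beta`, `se`, `or`, `ci_low`,
#'   `ci_high`, `level`. Vectorised over `beta` and `se`.
#' @examples
#' to_effect_with_ci(log(1.1766), 0.04547)
#' @export
to_effect_with_ci <- function(beta, se, level = 0.95) {
  if (any(se < 0)) {
    abort("se must be non-negative", class = "mrpipe_domain_error")
  }
  if (level <= 0 || level >= 1) {
    abort("level must be in (0, 1)", class = "mrpipe_domain_error")
  }
  z <- qnorm((1 + level) / 2)
  tibble(
    beta = beta,
    se = se,
    or = exp(beta),
    ci_low = exp(beta - z * se),
    ci_high = exp(beta + z * se),
    level = level
  )
}

#' Separation of the outer tertile means of a normal distribution
#'
#' For a normally distributed exposure, the mean of the top tertile sits
#' `3 * dnorm(qnorm(2/3))` SDs above the overall mean (the truncated-normal
#' mean), and by symmetry the bottom tertile the same distance below, so the
#' top-versus-bottom-tertile contrast corresponds to
#' `6 * dnorm(qnorm(2/3))` = 2.18 SDs. Used to place published
#' tertile-contrast odds ratios on the per-SD scale.
#'
#' @return The separation in SD units (about 2.18).
#' @export
tertile_sd_factor <- function() {
  6 * dnorm(qnorm(2 / 3))
}

#' Convert a top-versus-bottom-tertile odds ratio to a per-SD odds ratio
#'
#' @param or_tertile Odds ratio comparing top with bottom exposure tertile.
#' @return Odds ratio per 1 SD of the (normally distributed) exposure.
#' @examples
#' tertile_or_to_per_sd(1.16)
#' @export
tertile_or_to_per_sd <- function(or_tertile) {
  if (any(or_tertile <= 0)) {
    abort("or_tertile must be positive", class = "mrpipe_domain_error")
  }
  exp(log(or_tertile) / tertile_sd_factor())
}
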