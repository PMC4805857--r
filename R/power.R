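#' Prospective (design-based) power for a two-sample MR analysis
#'
#' Approximate power of an IVW-style MR analysis from design quantities
#' alone, following the non-centrality argument of the mRnd-style
#' calculation: the expected test statistic is
#' `z = |true_effect| * sqrt(n * r2 * v)` with `v = case_fraction *
#' (1 - case_fraction)` for binary outcomes (log-OR effects) and `v = 1`
#' for continuous outcomes, and
#' `power = pnorm(z - z_alpha) + pnorm(-z - z_alpha)` with
#' `z_alpha = qnorm(1 - alpha / 2)`.
#'
#' @param n Outcome-sample size.
#' @param r2 Proportion of exposure variance explained by the instrument,
#'   in (0, 1).
#' @param true_effect Hypothesised causal effect per SD of exposure
#'   (log-OR for binary outcomes, SD units for continuous). Supply either
#'   this or `true_or`.
#' @param true_or Hypothesised odds ratio per SD (binary outcomes);
#'   converted to `log(true_or)`.
#' @param case_fraction Proportion of cases in (0, 1) for binary outcomes;
#'   leave `NULL` for continuous outcomes.
#' @param alpha Two-sided significance level.
#' @return Power in `[0, 1]`.
#' @examples
#' # CHD outcome: 198,598 individuals, 65,877 events, instrument R2 4.2%,
#' # true OR 1.07 per SD urate
#' prospective_power(198598, 0.042, true_or = 1.07,
#'                   case_fraction = 65877 / 198598)
#' @export
prospective_power <- function(n, r2, true_effect = NULL, true_or = NULL,
                              case_fraction = NULL, alpha = 0.05) {
  if (is.null(true_effect)) {
    if (is.null(true_or)) {
      abort("supply true_effect or true_or", class = "mrpipe_parameter_error")
    }
    if (any(true_or <= 0)) {
      abort("true_or must be positive", class = "mrpipe_parameter_error")
    }
    true_effect <- log(true_or)
  }
  if (any(n <= 0)) abort("n must be positive", class = "mrpipe_parameter_error")
  if (any(r2 <= 0 | r2 >= 1)) {
    abort("r2 must be in (0, 1)", class = "mrpipe_parameter_error")
  }
  if (alpha <= 0 || alpha >= 1) {
    abort("alpha must be in (0, 1)", class = "mrpipe_parameter_error")
  }
  v <- 1
  if (!is.null(case_fraction)) {
    if (any(case_fraction <= 0 | case_fraction >= 1)) {
      abort("case_fraction must be in (0, 1)",
            class = "mrpipe_parameter_error")
    }
    v <- case_fraction * (1 - case_fraction)
  }
  z <- abs(true_effect) * sqrt(n * r2 * v)
  za <- qnorm(1 - alpha / 2)
  pnorm(z - za) + pnorm(-z - za)
}

#' Retrospective power at an estimated effect
#'
#' Power as the complement of the false rejection rate for the observed
#' effect size: `pnorm(-z_alpha + |beta_hat| / se) +
#' pnorm(-z_alpha - |beta_hat| / se)` with two-sided `alpha`.
#'
#' @param beta_hat Log-scale point estimate.
#' @param se Its standard error (> 0).
#' @param alpha Two-sided significance level.
#' @return Power in `[0, 1]`.
#' @examples
#' retrospective_power(log(1.05), ci_to_se(0.92, 1.20))
#' @export
retrospective_power <- function(beta_hat, se, alpha = 0.05) {
  if (any(se <= 0)) {
    abort("se must be positive", class = "mrpipe_parameter_error")
  }
  if (alpha <= 0 || alpha >= 1) {
    abort("alpha must be in (0, 1)", class = "mrpipe_parameter_error")
  }
  za <- qnorm(1 - alpha / 2)
  pnorm(-za + abs(beta_hat) / se) + pnorm(-za - abs(beta_hat) / se)
}
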