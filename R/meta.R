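#' Fixed-effects inverse-variance meta-analysis
#'
#' Pools effect estimates under a common-effect model with weights
#' `1 / se^2`: pooled beta `sum(w * b) / sum(w)`, pooled SE
#' `sqrt(1 / sum(w))`, Cochran heterogeneity `Q = sum(w * (b - pooled)^2)`
#' on `k - 1` df, and `I^2 = max(0, (Q - (k - 1)) / Q) * 100`.
#'
#' Used both to combine per-SNP estimates across publications and to pool
#' study-level observational estimates.
#'
#' @param data Data frame with one row per estimate.
#' @param beta,se Columns holding the effect estimates and their standard
#'   errors (tidy-eval; defaults `beta`, `se`).
#' @return A one-row tibble: `beta`, `se`, `k`, `q`, `q_df`, `q_p`, `i2`.
#' @examples
#' fixed_effect_meta(data.frame(beta = c(0.2, 0.4), se = c(0.1, 0.2)))
#' @export
fixed_effect_meta <- function(data, beta = beta, se = se) {
  b <- dplyr::pull(data, {{ beta }})
  s <- dplyr::pull(data, {{ se }})
  .fe_meta(b, s)
}

.fe_meta <- function(b, s) {
  if (length(b) != length(s)) {
    abort("beta and se must have equal length", class = "mrpipe_parameter_error")
  }
  if (length(b) == 0) {
    abort("meta-analysis needs at least one estimate",
          class = "mrpipe_parameter_error")
  }
  if (any(!is.finite(s) | s <= 0)) {
    abort("all standard errors must be positive and finite",
          class = "mrpipe_validation_error")
  }
  w <- 1 / s^2
  pooled <- sum(w * b) / sum(w)
  pooled_se <- sqrt(1 / sum(w))
  k <- length(b)
  q <- sum(w * (b - pooled)^2)
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
  tibble(
    beta = pooled,
    se = pooled_se,
    k = k,
    q = q,
    q_df = k - 1L,
    q_p = if (k > 1) pchisq(q, df = k - 1, lower.tail = FALSE) else NA_real_,
    i2 = i2
  )
}
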