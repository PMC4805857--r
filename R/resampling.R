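# Fast slope-only estimators used inside resampling loops. These apply the
# same weighted normal equations as mr_ivw()/mr_mvmr()/mr_egger() without
# object construction; equality with the full estimators is covered by tests.
.slope_ivw <- function(bx, by, w, BC = NULL) {
  sum(w * bx * by) / sum(w * bx^2)
}

.slope_egger <- function(bx, by, w, BC = NULL) {
  flip <- sign(bx)
  flip[flip == 0] <- 1
  x <- flip * bx
  y <- flip * by
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  sxx <- sum(w * (x - mx)^2)
  if (sxx == 0) return(NA_real_)
  sum(w * (x - mx) * (y - my)) / sxx
}

.slope_mvmr <- function(bx, by, w, BC) {
  X <- cbind(bx, BC)
  A <- crossprod(X, w * X)
  coef <- tryCatch(solve(A, crossprod(X, w * by)), error = function(e) NULL)
  if (is.null(coef)) return(NA_real_)
  coef[1]
}

.slope_fun <- function(method) {
  switch(method,
    ivw = .slope_ivw,
    egger = .slope_egger,
    mvmr = .slope_mvmr,
    abort(paste0("unknown method: ", method), class = "mrpipe_parameter_error")
  )
}

# Derives one sub-seed per replicate from the call seed so each replicate is
# an independent, parallelisation-order-free stream.
.replicate_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Empirical inference by resampling the summary statistics
#'
#' Rebuilds the sampling distribution of an MR estimate by resampling the
#' per-SNP summary statistics and recomputing the estimator each time,
#' avoiding reliance on the analytic standard error. Two schemes are
#' provided: `"parametric"` (default) perturbs every beta — exposure,
#' outcome, and covariates — by independent normal noise with that
#' statistic's reported SE; `"nonparametric"` draws J SNPs with replacement.
#' Confidence limits are empirical quantiles and the two-sided p-value is
#' sign-based, `2 * min(frac <= 0, frac >= 0)`, clamped to `[2/b, 1]`.
#'
#' @param instrument An `mr_instrument`.
#' @param method Estimator to resample: `"ivw"`, `"mvmr"`, or `"egger"`.
#' @param b Number of resamples (>= 100).
#' @param seed Integer seed; results are reproducible given
#'   `(seed, scheme, b)`.
#' @param scheme Resampling scheme (see Details).
#' @param level Confidence level for both the empirical and the reference
#'   normal-theory interval.
#' @param covariates Covariate labels for `method = "mvmr"`.
#' @return An `mr_resample` object: the point estimate and its normal-theory
#'   interval, the vector of resampled estimates, empirical `ci_low` /
#'   `ci_high`, `p_empirical`, and the count of resamples outside the
#'   normal-theory interval. Has [tidy()] and [glance()] methods.
#' @export
mr_bootstrap <- function(instrument, method = c("ivw", "mvmr", "egger"),
                         b = 10000, seed = 1,
                         scheme = c("parametric", "nonparametric"),
                         level = 0.95,
                         covariates = instrument_covariates(instrument)) {
  method <- match.arg(method)
  scheme <- match.arg(scheme)
  instrument <- as_instrument(instrument)
  if (b < 100) {
    abort("b must be at least 100", class = "mrpipe_parameter_error")
  }
  J <- nrow(instrument)
  if (method == "egger" && J < 3) {
    abort("Egger regression needs at least 3 SNPs",
          class = "mrpipe_insufficient_snps_error")
  }
  covariates <- if (method == "mvmr") as.character(covariates) else character()
  point <- .fit_method(instrument, method, covariates, level)
  z <- qnorm((1 + level) / 2)

  bx <- instrument$bx
  by <- instrument$by
  se_x <- instrument$se_x
  se_y <- instrument$se_y
  w <- 1 / se_y^2
  BC <- if (length(covariates) > 0) .cov_matrix(instrument, covariates) else NULL
  SEC <- if (length(covariates) > 0) {
    .cov_matrix(instrument, covariates, prefix = "se_c_")
  } else NULL
  slope <- .slope_fun(method)

  seeds <- .replicate_seeds(seed, b)
  est <- numeric(b)
  for (i in seq_len(b)) {
    set.seed(seeds[i])
    val <- NA_real_
    tries <- 0L
    while (!is.finite(val) && tries < 100L) {
      tries <- tries + 1L
      if (scheme == "parametric") {
        bx_i <- bx + rnorm(J) * se_x
        by_i <- by + rnorm(J) * se_y
        BC_i <- BC
        if (!is.null(BC)) {
          noise <- matrix(rnorm(length(BC)), nrow = J)
          fin <- is.finite(SEC)
          BC_i <- BC + ifelse(fin, noise * SEC, 0)
        }
        val <- slope(bx_i, by_i, w, BC_i)
      } else {
        idx <- sample.int(J, J, replace = TRUE)
        val <- slope(bx[idx], by[idx], w[idx],
                     if (is.null(BC)) NULL else BC[idx, , drop = FALSE])
      }
    }
    est[i] <- val
  }
  if (anyNA(est)) {
    abort("resampling failed to produce finite estimates",
          class = "mrpipe_resample_error")
  }

  qs <- unname(quantile(est, probs = c((1 - level) / 2, (1 + level) / 2),
                        type = 7))
  p_emp <- min(1, max(2 / b, 2 * min(mean(est <= 0), mean(est >= 0))))
  normal_ci <- c(point$beta - z * point$se, point$beta + z * point$se)
  structure(
    list(
      method = method, scheme = scheme, b = b, seed = seed, level = level,
      covariates = covariates,
      estimate = point$beta, se_normal = point$se,
      ci_normal_low = normal_ci[1], ci_normal_high = normal_ci[2],
      estimates = est,
      ci_low = qs[1], ci_high = qs[2], p_empirical = p_emp,
      n_outside_normal_ci = sum(est < normal_ci[1] | est > normal_ci[2])
    ),
    class = "mr_resample"
  )
}

#' @export
print.mr_resample <- function(x, ...) {
  cat(sprintf("Resampled %s estimate (%s scheme, b = %d, seed = %d)\n",
              x$method, x$scheme, x$b, x$seed))
  cat(sprintf("  point %.4f, empirical %d%% CI %.4f to %.4f, p = %.3g\n",
              x$estimate, round(100 * x$level), x$ci_low, x$ci_high,
              x$p_empirical))
  invisible(x)
}

#' @method tidy mr_resample
#' @export
tidy.mr_resample <- function(x, ...) {
  tibble(resample = seq_len(x$b), estimate = x$estimates)
}

#' @method glance mr_resample
#' @export
glance.mr_resample <- function(x, ...) {
  tibble(
    method = x$method, scheme = x$scheme, b = x$b, seed = x$seed,
    estimate = x$estimate, or = exp(x$estimate),
    ci_low = x$ci_low, ci_high = x$ci_high,
    or_ci_low = exp(x$ci_low), or_ci_high = exp(x$ci_high),
    p_empirical = x$p_empirical,
    n_outside_normal_ci = x$n_outside_normal_ci,
    level = x$level
  )
}

#' Leave-k-SNPs-out sensitivity scan
#'
#' Probes the stability of a summary causal estimate under instrument
#' perturbation: each replicate removes `k` distinct SNPs chosen uniformly
#' at random, re-estimates, and records whether the replicate estimate falls
#' outside the normal-theory confidence interval of the full-instrument
#' estimate. A result is flagged as sensitive to SNP selection when more
#' than 5% of replicate estimates fall outside that interval.
#'
#' @inheritParams mr_bootstrap
#' @param k Number of SNPs excluded per replicate (`0 <= k < J`).
#' @param n_reps Number of replicates (>= 100, or 1 when `k = 0`).
#' @return A one-row tibble: `method`, `k_excluded`, `n_reps`, `estimate`,
#'   `ci_low`, `ci_high`, `prop_outside`, `flagged`, `seed`. The replicate
#'   estimates are attached as the `"estimates"` attribute.
#' @export
leave_k_out_scan <- function(instrument, method = c("ivw", "mvmr", "egger"),
                             covariates = instrument_covariates(instrument),
                             k = 6, n_reps = 10000, seed = 1, level = 0.95) {
  method <- match.arg(method)
  instrument <- as_instrument(instrument)
  J <- nrow(instrument)
  if (k < 0 || k >= J) {
    abort("k must satisfy 0 <= k < number of SNPs",
          class = "mrpipe_parameter_error")
  }
  if (n_reps < 100 && k > 0) {
    abort("n_reps must be at least 100", class = "mrpipe_parameter_error")
  }
  covariates <- if (method == "mvmr") as.character(covariates) else character()
  point <- .fit_method(instrument, method, covariates, level)
  z <- qnorm((1 + level) / 2)
  lo <- point$beta - z * point$se
  hi <- point$beta + z * point$se

  bx <- instrument$bx
  by <- instrument$by
  w <- 1 / instrument$se_y^2
  BC <- if (length(covariates) > 0) .cov_matrix(instrument, covariates) else NULL
  slope <- .slope_fun(method)

  if (k == 0) {
    est <- rep(point$beta, max(1L, n_reps))
  } else {
    seeds <- .replicate_seeds(seed, n_reps)
    est <- numeric(n_reps)
    for (i in seq_len(n_reps)) {
      set.seed(seeds[i])
      keep <- sample.int(J, J - k)
      est[i] <- slope(bx[keep], by[keep], w[keep],
                      if (is.null(BC)) NULL else BC[keep, , drop = FALSE])
    }
    if (anyNA(est)) {
      abort("a replicate produced a degenerate fit; reduce k",
            class = "mrpipe_resample_error")
    }
  }
  prop <- mean(est < lo | est > hi)
  out <- tibble(
    method = method,
    k_excluded = as.integer(k),
    n_reps = length(est),
    estimate = point$beta,
    ci_low = lo,
    ci_high = hi,
    prop_outside = prop,
    flagged = prop > 0.05,
    seed = as.integer(seed)
  )
  attr(out, "estimates") <- est
  out
}
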