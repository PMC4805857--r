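#' Simulate a two-sample MR instrument with known causal ground truth
#'
#' Generates per-SNP summary statistics for a multilocus instrument under an
#' explicit structural model, so estimators and diagnostics can be validated
#' against a known truth. Per SNP j and covariate m the latent effects are
#'
#' \deqn{by_j = \theta \, bx_j + \sum_m \gamma_m \, bc_{jm} + \alpha_j}
#'
#' where `theta` is the causal effect of the exposure on the outcome,
#' `gamma` the covariate-to-outcome path coefficients (covariate-mediated
#' pleiotropy), and `alpha_j ~ N(mu_alpha, sigma_alpha)` a direct
#' (horizontal) pleiotropic effect drawn independently of instrument
#' strength, so the InSIDE condition holds by construction. Observed betas
#' add independent normal sampling noise at each statistic's SE; SEs follow
#' GWAS scaling `1 / sqrt(2 p (1-p) n)` (times `case_fraction *
#' (1 - case_fraction)` inside the root for the binary outcome) from
#' per-SNP allele frequencies drawn uniformly on (0.1, 0.9).
#'
#' Defaults emulate a urate-style design: 31 SNPs explaining 4.2% of
#' exposure variance, a binary outcome sample of 198,598 with 60,785
#' events, and four measured covariates (SBP, DBP, HDL, TG) of which a
#' random subset of SNPs (40%) carries covariate associations.
#'
#' @param j Number of SNPs.
#' @param theta True causal effect (log-OR per SD of exposure).
#' @param covariate_labels Labels for measured covariate phenotypes.
#' @param gamma Covariate-to-outcome path coefficients, one per label.
#' @param mu_alpha,sigma_alpha Mean and SD of the direct pleiotropic effect
#'   per SNP (`mu_alpha != 0` gives directional pleiotropy).
#' @param mu_c,sigma_c Mean and SD of nonzero SNP-covariate associations;
#'   a nonzero `mu_c` (with exposure effects oriented positive) makes the
#'   covariate-mediated pleiotropy directional, biasing unadjusted IVW.
#' @param prop_pleiotropic Fraction of SNPs carrying covariate associations.
#' @param r2 Exposure variance explained by the whole instrument.
#' @param n_exposure,n_outcome,n_covariate GWAS sample sizes behind the
#'   reported SEs.
#' @param case_fraction Case fraction of the binary outcome sample.
#' @param se_x_scale,se_y_scale Multipliers on the exposure/outcome SEs
#'   (> 0), for experiments that shrink or inflate sampling noise.
#' @param add_noise If `FALSE`, observed betas equal the latent values
#'   exactly (SEs are still reported); the deterministic limit used by
#'   exact-recovery tests.
#' @param seed Optional integer seed.
#' @return An `mr_simulation`: list with `instrument` (an
#'   `mr_instrument`), `truth` (the generating parameters), and the latent
#'   `true_bx`, `true_alpha`, `true_bc`.
#' @examples
#' sim <- simulate_instrument(seed = 1)
#' mr_ivw(sim$instrument)
#' @export
simulate_instrument <- function(j = 31,
                                theta = 0.17,
                                covariate_labels = c("SBP", "DBP", "HDL", "TG"),
                                gamma = setNames(rep(0, length(covariate_labels)),
                                                 covariate_labels),
                                mu_alpha = 0,
                                sigma_alpha = 0,
                                mu_c = 0,
                                sigma_c = 0.02,
                                prop_pleiotropic = 0.4,
                                r2 = 0.042,
                                n_exposure = 145000,
                                n_outcome = 198598,
                                n_covariate = 70000,
                                case_fraction = 60785 / 198598,
                                se_x_scale = 1,
                                se_y_scale = 1,
                                add_noise = TRUE,
                                seed = NULL) {
  if (j < 1) abort("j must be >= 1", class = "mrpipe_parameter_error")
  if (sigma_alpha < 0 || sigma_c < 0) {
    abort("sigma_alpha and sigma_c must be non-negative",
          class = "mrpipe_parameter_error")
  }
  if (se_x_scale <= 0 || se_y_scale <= 0) {
    abort("SE scales must be positive", class = "mrpipe_parameter_error")
  }
  m <- length(covariate_labels)
  if (length(gamma) != m) {
    abort("gamma must have one entry per covariate label",
          class = "mrpipe_parameter_error")
  }
  if (!is.null(seed)) set.seed(seed)

  eaf <- runif(j, 0.1, 0.9)
  het <- 2 * eaf * (1 - eaf)
  raw <- abs(rnorm(j))
  raw[raw < 0.05] <- 0.05  # keep every SNP a usable instrument
  true_bx <- raw * sqrt(r2 / sum(het * raw^2))
  se_x <- se_x_scale / sqrt(het * n_exposure)
  se_y <- se_y_scale /
    sqrt(het * n_outcome * case_fraction * (1 - case_fraction))
  se_c <- 1 / sqrt(het * n_covariate)

  true_bc <- matrix(0, nrow = j, ncol = m,
                    dimnames = list(NULL, covariate_labels))
  if (m > 0 && prop_pleiotropic > 0) {
    n_pleio <- max(1L, round(prop_pleiotropic * j))
    pleio <- sample.int(j, min(j, n_pleio))
    true_bc[pleio, ] <- rnorm(length(pleio) * m, mu_c, sigma_c)
  }
  true_alpha <- rnorm(j, mu_alpha, sigma_alpha)
  latent_by <- theta * true_bx + drop(true_bc %*% gamma) + true_alpha

  if (add_noise) {
    bx <- true_bx + rnorm(j) * se_x
    by <- latent_by + rnorm(j) * se_y
    bc <- true_bc + matrix(rnorm(j * m), j, m) * se_c
  } else {
    bx <- true_bx
    by <- latent_by
    bc <- true_bc
  }

  inst <- tibble(
    snp = paste0("rs", seq_len(j)),
    effect_allele = "A",
    other_allele = "G",
    eaf = eaf,
    bx = bx,
    se_x = se_x,
    by = by,
    se_y = se_y
  )
  for (lab in covariate_labels) {
    inst[[paste0("bc_", lab)]] <- bc[, lab]
    inst[[paste0("se_c_", lab)]] <- se_c
  }

  structure(
    list(
      instrument = as_instrument(inst, covariates = covariate_labels),
      truth = list(
        theta = theta, mu_alpha = mu_alpha, sigma_alpha = sigma_alpha,
        gamma = gamma, mu_c = mu_c, sigma_c = sigma_c,
        prop_pleiotropic = prop_pleiotropic,
        j = j, r2 = r2, n_exposure = n_exposure, n_outcome = n_outcome,
        n_covariate = n_covariate, case_fraction = case_fraction,
        se_x_scale = se_x_scale, se_y_scale = se_y_scale, seed = seed
      ),
      true_bx = true_bx,
      true_alpha = true_alpha,
      true_bc = true_bc
    ),
    class = "mr_simulation"
  )
}

#' @export
print.mr_simulation <- function(x, ...) {
  cat(sprintf("Simulated MR instrument: %d SNPs, theta = %g, R2 = %g\n",
              x$truth$j, x$truth$theta, x$truth$r2))
  cat(sprintf("  pleiotropy: mu_alpha = %g, sigma_alpha = %g; gamma = [%s]\n",
              x$truth$mu_alpha, x$truth$sigma_alpha,
              paste(signif(x$truth$gamma, 3), collapse = ", ")))
  invisible(x)
}

#' Export a simulation as per-trait summary tables
#'
#' Converts a simulated instrument into the long per-trait summary tables
#' that [read_summary_table()] produces and [harmonise()] consumes — the
#' file-facing view of the simulation. Optionally reports a random subset of
#' outcome rows on the opposite allele (beta negated, alleles swapped) to
#' exercise harmonisation.
#'
#' @param sim An `mr_simulation`.
#' @param scramble_alleles If `TRUE`, flip the reported allele orientation
#'   of `n_flip` random outcome rows.
#' @param n_flip Number of outcome rows to flip (default: half, rounded
#'   down).
#' @param seed Optional seed for the flip choice.
#' @return A list with `exposure`, `outcome` (summary tibbles) and
#'   `covariates` (named list of summary tibbles).
#' @export
as_summary_tables <- function(sim, scramble_alleles = FALSE, n_flip = NULL,
                              seed = NULL) {
  stopifnot(inherits(sim, "mr_simulation"))
  inst <- sim$instrument
  base <- function(beta, se, trait) {
    tibble(
      snp = inst$snp,
      effect_allele = inst$effect_allele,
      other_allele = inst$other_allele,
      beta = beta,
      se = se,
      trait = trait,
      source = "simulated",
      eaf = inst$eaf
    )
  }
  exposure <- base(inst$bx, inst$se_x, "exposure")
  outcome <- base(inst$by, inst$se_y, "outcome")
  if (scramble_alleles) {
    if (!is.null(seed)) set.seed(seed)
    if (is.null(n_flip)) n_flip <- nrow(inst) %/% 2
    flip <- sample.int(nrow(inst), n_flip)
    ea <- outcome$effect_allele[flip]
    outcome$effect_allele[flip] <- outcome$other_allele[flip]
    outcome$other_allele[flip] <- ea
    outcome$beta[flip] <- -outcome$beta[flip]
    outcome$eaf[flip] <- 1 - outcome$eaf[flip]
  }
  covariates <- lapply(instrument_covariates(inst), function(lab) {
    base(inst[[paste0("bc_", lab)]], inst[[paste0("se_c_", lab)]], lab)
  })
  names(covariates) <- instrument_covariates(inst)
  list(exposure = exposure, outcome = outcome, covariates = covariates)
}

#' Generate a suite of null datasets for size calibration
#'
#' Convenience generator for type-I-error studies: simulations with
#' `theta = 0` and `mu_alpha = 0` (no causal effect, no directional
#' pleiotropy), reproducible from one seed.
#'
#' @param n_datasets Number of datasets (>= 1).
#' @param seed Integer seed.
#' @param ... Further arguments to [simulate_instrument()] (e.g.
#'   `sigma_alpha` for balanced pleiotropy).
#' @return List of `mr_simulation` objects.
#' @export
generate_null_suite <- function(n_datasets, seed = 1, ...) {
  if (n_datasets < 1) {
    abort("n_datasets must be >= 1", class = "mrpipe_parameter_error")
  }
  dots <- list(...)
  if (any(c("theta", "mu_alpha", "seed") %in% names(dots))) {
    abort("theta, mu_alpha and seed are fixed by the null suite",
          class = "mrpipe_parameter_error")
  }
  seeds <- .replicate_seeds(seed, n_datasets)
  lapply(seeds, function(s) {
    simulate_instrument(theta = 0, mu_alpha = 0, seed = s, ...)
  })
}
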