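# Shared fixture builders and independent oracles.

# The 3-SNP worked example used across estimator and pipeline tests.
three_snp_instrument <- function() {
  as_instrument(tibble::tibble(
    snp = paste0("rs", 1:3),
    bx = c(0.1, 0.2, 0.3),
    se_x = 0.01,
    by = c(0.02, 0.05, 0.06),
    se_y = c(0.01, 0.02, 0.03)
  ))
}

# Random small instrument with optional covariates; betas and SEs on
# GWAS-plausible scales.
random_instrument <- function(j = NULL, m = NULL) {
  if (is.null(j)) j <- sample(3:12, 1)
  if (is.null(m)) m <- sample(0:2, 1)
  if (j < m + 2) j <- m + 2
  inst <- tibble::tibble(
    snp = paste0("rs", seq_len(j)),
    bx = rnorm(j, 0, 0.05) + 0.02 * sample(c(-1, 1), j, replace = TRUE),
    se_x = runif(j, 0.002, 0.01),
    by = rnorm(j, 0, 0.02),
    se_y = runif(j, 0.005, 0.03)
  )
  labels <- head(c("SBP", "HDL"), m)
  for (lab in labels) {
    inst[[paste0("bc_", lab)]] <- rnorm(j, 0, 0.02)
    inst[[paste0("se_c_", lab)]] <- runif(j, 0.002, 0.01)
  }
  as_instrument(inst)
}

# Independent weighted-least-squares oracle built on lm(); returns the
# coefficient vector, lm's dispersion-scaled SEs, and the fixed-effect SEs
# (lm SEs divided by the residual standard error).
wls_oracle <- function(formula_x, y, w, intercept = FALSE) {
  X <- as.matrix(formula_x)
  fit <- if (intercept) {
    stats::lm(y ~ X, weights = w)
  } else {
    stats::lm(y ~ 0 + X, weights = w)
  }
  sm <- summary(fit)
  sigma <- sm$sigma
  list(
    coef = unname(stats::coef(fit)),
    se_dispersion = unname(sm$coefficients[, "Std. Error"]),
    se_fixed = unname(sm$coefficients[, "Std. Error"]) / sigma,
    sigma = sigma
  )
}

# Writes a summary tibble to a temp file in a given delimiter/eol flavour.
write_flavoured <- function(tab, delim = "\t", eol = "\n") {
  path <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  cols <- c("snp", "effect_allele", "other_allele", "beta", "se")
  lines <- c(
    paste(cols, collapse = delim),
    apply(tab[cols], 1, paste, collapse = delim)
  )
  con <- file(path, open = "wb")
  writeLines(lines, con, sep = eol)
  close(con)
  path
}

simple_summary <- function(snp = c("rs1", "rs2", "rs3"),
                           ea = c("A", "C", "T"),
                           oa = c("G", "T", "C"),
                           beta = c(0.05, -0.02, 0.03),
                           se = c(0.01, 0.02, 0.015),
                           trait = "trait") {
  tibble::tibble(
    snp = snp, effect_allele = ea, other_allele = oa,
    beta = beta, se = se, trait = trait, source = "test"
  )
}
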