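test_that("summary tables parse identically across delimiters and line endings", {
  tab <- simple_summary()
  flavours <- list(
    c("\t", "\n"), c(",", "\n"), c("\t", "\r\n"), c(",", "\r\n")
  )
  parsed <- lapply(flavours, function(fl) {
    read_summary_table(write_flavoured(tab, fl[1], fl[2]), trait = "t")
  })
  for (p in parsed[-1]) {
    expect_equal(p[1:5], parsed[[1]][1:5])
  }
  expect_equal(nrow(parsed[[1]]), 3)
  expect_equal(parsed[[1]]$beta, tab$beta)
})

test_that("summary table round-trips through write_summary_table", {
  tab <- simple_summary()
  tab$eaf <- c(0.2, 0.5, 0.8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_table(tab, path)
  back <- read_summary_table(path, trait = "trait", source = "test")
  expect_equal(back[names(tab)], tab)
})

test_that("malformed inputs are rejected with informative errors", {
  tab <- simple_summary()
  # missing column
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tab[setdiff(names(tab), "se")], path)
  expect_error(read_summary_table(path), class = "mrpipe_format_error")
  # non-positive SE names the SNP
  bad <- tab
  bad$se[2] <- 0
  expect_error(
    read_summary_table(write_flavoured(bad)),
    regexp = "rs2", class = "mrpipe_validation_error"
  )
  # identical alleles
  bad <- tab
  bad$other_allele[1] <- bad$effect_allele[1]
  expect_error(
    read_summary_table(write_flavoured(bad)),
    class = "mrpipe_validation_error"
  )
  expect_error(read_summary_table(tempfile()), class = "mrpipe_io_error")
})

test_that("harmonise flips beta for swapped alleles and keeps matches", {
  exposure <- simple_summary(snp = "rs1", ea = "A", oa = "G",
                             beta = 0.05, se = 0.01)
  # swapped orientation: outcome effect allele is the exposure other allele
  outcome <- simple_summary(snp = "rs1", ea = "G", oa = "A",
                            beta = 0.02, se = 0.01)
  inst <- harmonise(exposure, outcome)
  expect_equal(inst$by, -0.02)
  # identical orientation: unchanged
  inst2 <- harmonise(exposure, simple_summary(snp = "rs1", ea = "A", oa = "G",
                                              beta = 0.02, se = 0.01))
  expect_equal(inst2$by, 0.02)
  # strand flip (complement letters): unchanged
  inst3 <- harmonise(exposure, simple_summary(snp = "rs1", ea = "T", oa = "C",
                                              beta = 0.02, se = 0.01))
  expect_equal(inst3$by, 0.02)
  # strand flip with swap: sign flipped
  inst4 <- harmonise(exposure, simple_summary(snp = "rs1", ea = "C", oa = "T",
                                              beta = 0.02, se = 0.01))
  expect_equal(inst4$by, -0.02)
})

test_that("palindromic SNPs with conflicting letters are dropped with a warning", {
  exposure <- simple_summary(snp = c("rs1", "rs2"), ea = c("A", "A"),
                             oa = c("T", "G"), beta = c(0.05, 0.04),
                             se = c(0.01, 0.01))
  outcome <- simple_summary(snp = c("rs1", "rs2"), ea = c("T", "A"),
                            oa = c("A", "G"), beta = c(0.02, 0.03),
                            se = c(0.01, 0.01))
  expect_warning(inst <- harmonise(exposure, outcome), regexp = "rs1")
  expect_equal(inst$snp, "rs2")
  expect_equal(attr(inst, "dropped")$snp, "rs1")
  # exact-letter palindromic match is retained unchanged
  same <- harmonise(
    simple_summary(snp = "rs1", ea = "A", oa = "T", beta = 0.05, se = 0.01),
    simple_summary(snp = "rs1", ea = "A", oa = "T", beta = 0.02, se = 0.01)
  )
  expect_equal(same$by, 0.02)
})

test_that("irreconcilable alleles and empty intersections error or drop", {
  exposure <- simple_summary(snp = "rs1", ea = "A", oa = "G",
                             beta = 0.05, se = 0.01)
  expect_error(
    harmonise(exposure, simple_summary(snp = "rs9", ea = "A", oa = "G",
                                       beta = 0.1, se = 0.1)),
    class = "mrpipe_empty_instrument_error"
  )
  # allele letters that cannot be reconciled at all
  expect_error(
    suppressWarnings(
      harmonise(exposure, simple_summary(snp = "rs1", ea = "A", oa = "C",
                                         beta = 0.1, se = 0.1))
    ),
    class = "mrpipe_empty_instrument_error"
  )
})

test_that("scrambled outcome alleles harmonise back to the ground truth", {
  sim <- simulate_instrument(seed = 11)
  tabs <- as_summary_tables(sim, scramble_alleles = TRUE, n_flip = 5,
                            seed = 12)
  inst <- harmonise(tabs$exposure, tabs$outcome, tabs$covariates)
  truth <- sim$instrument
  expect_equal(inst$by, truth$by, tolerance = 1e-12)
  expect_equal(inst$bx, truth$bx, tolerance = 1e-12)
  for (lab in instrument_covariates(truth)) {
    expect_equal(inst[[paste0("bc_", lab)]], truth[[paste0("bc_", lab)]],
                 tolerance = 1e-12)
  }
})

test_that("harmonisation is idempotent and sign flips are involutive", {
  sim <- simulate_instrument(seed = 21)
  tabs <- as_summary_tables(sim)
  once <- harmonise(tabs$exposure, tabs$outcome, tabs$covariates)
  # already-aligned tables pass through unchanged
  expect_equal(once$by, tabs$outcome$beta)
  # feeding the harmonised outcome back in changes nothing
  outcome2 <- tabs$outcome
  outcome2$beta <- once$by
  twice <- harmonise(tabs$exposure, outcome2, tabs$covariates)
  expect_equal(twice$by, once$by)
  # flipping all outcome alleles twice restores betas exactly
  flip <- function(tab) {
    tibble::tibble(
      snp = tab$snp, effect_allele = tab$other_allele,
      other_allele = tab$effect_allele, beta = -tab$beta, se = tab$se,
      trait = tab$trait, source = tab$source
    )
  }
  expect_equal(flip(flip(tabs$outcome))$beta, tabs$outcome$beta)
  flipped <- harmonise(tabs$exposure, flip(tabs$outcome))
  expect_equal(flipped$by, once$by)
})

test_that("missing covariate SNPs error by default and impute zero weight on request", {
  exposure <- simple_summary()
  outcome <- simple_summary(beta = c(0.01, 0.02, 0.03))
  cov_short <- simple_summary()[1:2, ]
  expect_error(
    harmonise(exposure, outcome, list(SBP = cov_short)),
    regexp = "rs3", class = "mrpipe_validation_error"
  )
  inst <- harmonise(exposure, outcome, list(SBP = cov_short),
                    allow_missing_covariates = TRUE)
  expect_equal(inst$bc_SBP[3], 0)
  expect_equal(inst$se_c_SBP[3], Inf)
})

test_that("instruments round-trip through the wide TSV layout", {
  sim <- simulate_instrument(seed = 31)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_instrument(sim$instrument, path)
  back <- read_instrument(path)
  expect_s3_class(back, "mr_instrument")
  expect_equal(instrument_covariates(back),
               instrument_covariates(sim$instrument))
  expect_equal(back$by, sim$instrument$by, tolerance = 1e-12)
})

test_that("ci_to_se and to_effect_with_ci are inverse and match hand values", {
  expect_equal(ci_to_se(1, 1), 0)
  # from a published OR interval 0.9191-1.1968
  expect_equal(ci_to_se(0.9191, 1.1968), 0.06735116, tolerance = 1e-6)
  expect_error(ci_to_se(-1, 2), class = "mrpipe_domain_error")
  eff <- to_effect_with_ci(0, 0.1)
  expect_equal(eff$or, 1)
  expect_equal(eff$ci_low, 0.8220152, tolerance = 1e-6)
  expect_equal(eff$ci_high, 1.2165235, tolerance = 1e-6)
  # printed OR and CI of a published estimate are mutually consistent
  eff2 <- to_effect_with_ci(log(1.1766), 0.04547)
  expect_equal(eff2$ci_low, 1.0763, tolerance = 5e-4)
  expect_equal(eff2$ci_high, 1.2861, tolerance = 5e-4)
  # zero SE collapses the interval
  eff3 <- to_effect_with_ci(0.3, 0)
  expect_equal(eff3$ci_low, eff3$or)
  expect_equal(eff3$ci_high, eff3$or)
  # round trip se -> interval -> se
  for (se in c(0.01, 0.5, 2)) {
    eff <- to_effect_with_ci(0.2, se, level = 0.9)
    expect_equal(ci_to_se(eff$ci_low, eff$ci_high, level = 0.9), se,
                 tolerance = 1e-10)
  }
})
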