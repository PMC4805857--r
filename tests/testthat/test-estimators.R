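test_that("Wald ratios follow by/bx with first-order SEs", {
  expect_equal(wald_ratio(1, 0.5, 0.2), tibble::tibble(ratio = 0.5, se = 0.2))
  expect_equal(wald_ratio(0.2, 0.05, 0.02),
               tibble::tibble(ratio = 0.25, se = 0.1))
  neg <- wald_ratio(-0.1, 0.03, 0.01)
  expect_equal(neg$ratio, -0.3)
  expect_equal(neg$se, 0.1)
  expect_error(wald_ratio(0, 1, 1), class = "mrpipe_domain_error")
})

test_that("IVW matches the hand-computed normal equations", {
  inst <- three_snp_instrument()
  fit <- mr_ivw(inst)
  expect_equal(fit$beta, 65 / 300, tolerance = 1e-9)
  expect_equal(fit$se, sqrt(1 / 300), tolerance = 1e-9)
  # a single SNP reduces to the Wald ratio
  single <- as_instrument(tibble::tibble(snp = "rs1", bx = 1, se_x = 0.1,
                                         by = 0.5, se_y = 1))
  expect_equal(mr_ivw(single)$beta, 0.5)
  expect_equal(mr_ivw(single)$se, 1)
  # all-zero exposure effects are singular
  zero <- as_instrument(tibble::tibble(snp = c("a", "b"), bx = 0, se_x = 0.1,
                                       by = c(0.1, 0.2), se_y = 0.1))
  expect_error(mr_ivw(zero), class = "mrpipe_singularity_error")
})

test_that("Egger regression recovers an exact line and tests its intercept", {
  # collinear points on by = 0.01 + 0.2 bx, equal weights
  line <- as_instrument(tibble::tibble(
    snp = paste0("rs", 1:3), bx = c(0.1, 0.2, 0.3), se_x = 0.01,
    by = 0.01 + 0.2 * c(0.1, 0.2, 0.3), se_y = 0.05
  ))
  fit <- mr_egger(line)
  expect_equal(fit$beta, 0.2, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.01, tolerance = 1e-10)
  # equal-weight fit matches the simple-regression closed form
  bx <- c(0.1, 0.2, 0.3)
  by <- c(0.04, 0.05, 0.08)
  slope <- sum((bx - mean(bx)) * (by - mean(by))) / sum((bx - mean(bx))^2)
  inst <- as_instrument(tibble::tibble(snp = paste0("rs", 1:3), bx = bx,
                                       se_x = 0.01, by = by, se_y = 0.05))
  fit2 <- mr_egger(inst)
  expect_equal(fit2$beta, slope, tolerance = 1e-10)
  expect_equal(fit2$intercept, mean(by) - slope * mean(bx), tolerance = 1e-10)
  expect_error(mr_egger(inst[1:2, ]), class = "mrpipe_insufficient_snps_error")
})

test_that("Egger estimates are invariant to reported allele orientation", {
  set.seed(7)
  inst <- random_instrument(j = 10, m = 0)
  flip <- sample(c(-1, 1), 10, replace = TRUE)
  flipped <- as_instrument(dplyr::mutate(tibble::as_tibble(inst),
                                         bx = bx * flip, by = by * flip))
  a <- mr_egger(inst)
  b <- mr_egger(flipped)
  expect_equal(a$beta, b$beta, tolerance = 1e-12)
  expect_equal(a$intercept, b$intercept, tolerance = 1e-12)
  expect_equal(a$intercept_p, b$intercept_p, tolerance = 1e-12)
})

test_that("MVMR generalises IVW and recovers noiseless path coefficients", {
  inst <- tibble::as_tibble(three_snp_instrument())
  inst$bc_SBP <- 0
  inst$se_c_SBP <- 0.01
  withcov <- as_instrument(inst)
  # an all-zero covariate column carries no information: the exposure
  # coefficient equals plain IVW exactly
  fit0 <- suppressMessages(mr_mvmr(withcov))
  expect_equal(fit0$beta, mr_ivw(withcov)$beta, tolerance = 1e-12)
  expect_equal(fit0$se, mr_ivw(withcov)$se, tolerance = 1e-12)
  # a duplicated regressor is genuinely rank deficient
  dup <- inst
  dup$bc_SBP <- dup$bx
  expect_error(mr_mvmr(as_instrument(dup)),
               class = "mrpipe_singularity_error")
  inst$bc_SBP <- c(0.01, -0.02, 0.015)
  inst$by <- 0.1 * inst$bx + 0.3 * inst$bc_SBP
  fit <- mr_mvmr(as_instrument(inst))
  expect_equal(fit$beta, 0.1, tolerance = 1e-10)
  gamma_hat <- tidy(fit)$estimate[tidy(fit)$term == "SBP"]
  expect_equal(gamma_hat, 0.3, tolerance = 1e-10)
  expect_error(mr_mvmr(as_instrument(inst), covariates = "HDL"),
               class = "mrpipe_parameter_error")
})

test_that("estimators agree with the lm() weighted-regression oracle", {
  set.seed(42)
  for (rep in 1:30) {
    inst <- random_instrument()
    w <- 1 / inst$se_y^2
    ivw <- mr_ivw(inst)
    o <- wls_oracle(cbind(inst$bx), inst$by, w)
    expect_equal(ivw$beta, o$coef[1], tolerance = 1e-8)
    expect_equal(ivw$se, o$se_fixed[1], tolerance = 1e-8)

    eg <- mr_egger(inst)
    oe <- wls_oracle(cbind(inst$bx), inst$by, w, intercept = TRUE)
    # orientation flip leaves these instruments' fits unchanged only when
    # bx > 0; restrict the check to the oracle on the re-oriented data
    flip <- sign(inst$bx)
    flip[flip == 0] <- 1
    oe <- wls_oracle(cbind(flip * inst$bx), flip * inst$by, w,
                     intercept = TRUE)
    expect_equal(eg$intercept, oe$coef[1], tolerance = 1e-8)
    expect_equal(eg$beta, oe$coef[2], tolerance = 1e-8)
    expect_equal(eg$intercept_se, oe$se_dispersion[1], tolerance = 1e-8)
    expect_equal(eg$se, oe$se_dispersion[2], tolerance = 1e-8)

    covs <- instrument_covariates(inst)
    if (length(covs) > 0) {
      mv <- mr_mvmr(inst)
      X <- cbind(inst$bx, as.matrix(inst[paste0("bc_", covs)]))
      om <- wls_oracle(X, inst$by, w)
      expect_equal(mv$beta, om$coef[1], tolerance = 1e-8)
      expect_equal(mv$se, om$se_fixed[1], tolerance = 1e-8)
    }
  }
})

test_that("IVW is the zero-covariate MVMR and the zero-intercept Egger", {
  set.seed(99)
  for (rep in 1:20) {
    inst <- random_instrument(m = 1)
    ivw <- mr_ivw(inst)
    # MVMR normal equations with an empty covariate block
    w <- 1 / inst$se_y^2
    expect_equal(ivw$beta, sum(w * inst$bx * inst$by) / sum(w * inst$bx^2),
                 tolerance = 1e-10)
    # Egger with its intercept forced to zero is the same constrained fit
    o <- wls_oracle(cbind(inst$bx), inst$by, w)
    expect_equal(ivw$beta, o$coef[1], tolerance = 1e-10)
  }
})

test_that("Cochran Q measures Wald-ratio heterogeneity on J-1 df", {
  # perfect homogeneity
  inst <- as_instrument(tibble::tibble(
    snp = paste0("rs", 1:4), bx = c(0.1, 0.2, 0.25, 0.4), se_x = 0.01,
    by = 0.3 * c(0.1, 0.2, 0.25, 0.4), se_y = 0.02
  ))
  q0 <- cochran_q(inst, theta = 0.3)
  expect_equal(q0$q, 0)
  expect_equal(q0$p, 1)
  # two ratios 0.2 and 0.4 with se 0.1 about theta 0.3
  two <- as_instrument(tibble::tibble(
    snp = c("rs1", "rs2"), bx = 1, se_x = 0.01,
    by = c(0.2, 0.4), se_y = 0.1
  ))
  qt <- cochran_q(two, theta = 0.3)
  expect_equal(qt$q, 2)
  expect_equal(qt$df, 1)
  expect_equal(qt$p, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(qt$p, 0.1573, tolerance = 1e-3)
})

test_that("tidy and glance return the documented tabular shapes", {
  inst <- three_snp_instrument()
  g <- glance(mr_ivw(inst))
  expect_s3_class(g, "tbl_df")
  expect_equal(nrow(g), 1)
  expect_true(all(c("method", "or", "ci_low", "ci_high", "p") %in% names(g)))
  expect_equal(g$or, exp(g$beta))

  td <- tidy(mr_egger(inst))
  expect_equal(td$term, c("intercept", "exposure"))

  all_tab <- mr_all(inst)
  expect_equal(all_tab$method, c("ivw", "egger"))
  expect_true(all(c("q", "q_df", "q_p") %in% names(all_tab)))
  expect_output(print(mr_egger(inst)), "Egger intercept")
})
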