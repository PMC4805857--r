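---
title: "Two-sample Mendelian randomization with mrpipe: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The estimation problem

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on an outcome from per-SNP summary statistics: for each of $J$
independent variants we observe the variant–exposure association $bx_j$
(per effect-allele copy, in SD units of the exposure) and the
variant–outcome association $by_j$ with standard error $se_{y,j}$ (log-odds
for a binary outcome). If a variant affects the outcome only through the
exposure, each per-SNP ratio $by_j / bx_j$ estimates the same causal slope
$\theta$, and the estimators in this package are different ways of pooling
that information under progressively weaker assumptions:

- **IVW** (`mr_ivw()`): weighted regression of $by$ on $bx$ constrained
  through the origin, weights $w_j = 1/se_{y,j}^2$. Valid when any
  pleiotropy is balanced. Equivalent to the inverse-variance-weighted mean
  of the Wald ratios, and to the summary-data instrumental-variable
  regression in which only outcome-side uncertainty enters the weights.
- **Multivariable MR** (`mr_mvmr()`): the same regression with the SNPs'
  associations with measured pleiotropic phenotypes as additional columns.
  The exposure coefficient is then the causal effect adjusted for those
  *measured* pathways.
- **MR-Egger** (`mr_egger()`): the weighted regression with an
  unconstrained intercept. The intercept estimates the mean directional
  pleiotropic effect; under the InSIDE condition (pleiotropy independent of
  instrument strength) the slope remains a consistent causal estimate even
  when pleiotropy is unbalanced.

Heterogeneity among the per-SNP ratios beyond their sampling error —
Cochran's $Q = \sum_j (r_j - \theta)^2 / se_{r,j}^2$ on $J-1$ df, with
first-order ratio SEs $se_{r,j} = se_{y,j}/|bx_j|$ (`cochran_q()`) — is the
standard alarm for invalid instruments.

All binary-outcome effects are held on the log-odds scale internally;
`to_effect_with_ci()` converts to odds ratios only at the presentation
boundary, and `ci_to_se()` inverts published OR intervals back to log-scale
SEs. Normal quantiles are always computed with `qnorm()`, never hard-coded.

## Inference conventions

Several small conventions matter for reproducibility and are fixed here as
package policy:

- **IVW standard error.** The fixed-effect form $\sqrt{1/\sum w_j bx_j^2}$
  with a normal p-value. A multiplicative-dispersion alternative (SE scaled
  by the weighted residual mean square, $t_{J-1}$ inference) is available
  via `dispersion = "multiplicative"` for instruments with substantial
  heterogeneity.
- **Egger inference.** The intercept is not invariant to which allele each
  SNP is reported on, so all SNPs are re-oriented to $bx_j \ge 0$ before
  fitting (the convention of the Egger-regression literature); a SNP with
  $bx_j = 0$ exactly is left unflipped. Slope and intercept use
  residual-dispersion-scaled SEs with $t_{J-2}$ inference — the standard
  small-sample weighted-regression convention.
- **Multivariable fits.** Solved by explicit weighted normal equations. A
  covariate column that is identically zero carries no adjustment
  information and is dropped from the design (with a message) so the fit
  degrades gracefully to IVW; genuinely collinear designs raise a
  singularity error naming the offending columns. The returned p-values use
  the normal approximation, matching IVW.
- **Empirical p-values.** `mr_bootstrap()` reports a sign-based two-sided
  p, $2\min(\hat F(0), 1-\hat F(0^-))$, clamped below at $2/b$ so that no
  resampled p is reported as exactly zero.

## Allele harmonisation

`harmonise()` aligns outcome and covariate studies to the exposure study's
effect allele per SNP: exact letter match is kept; swapped letters flip the
beta sign; complementary letters are treated as strand flips (kept or
sign-flipped accordingly). Palindromic SNPs (A/T, G/C) are strand-ambiguous
without allele-frequency information: they are kept only on an exact letter
match and dropped with a warning otherwise. This is a deliberately
conservative default — no frequency-based resolution is attempted — and
dropped SNPs are recorded in the instrument's `dropped` attribute and the
pipeline manifest. Covariate tables missing an instrument SNP are an error
by default; `allow_missing_covariates = TRUE` instead imputes a zero beta
with infinite SE, i.e. a cell that contributes no information to any
SE-weighted computation, because silently imputing an informative zero
would bias multivariable fits.

## Resampling and sensitivity

`mr_bootstrap()` implements two readings of "resampling the summary
statistics":

- **Parametric** (default): every beta — exposure, outcome, covariate — is
  perturbed by independent normal noise at its reported SE and the
  estimator recomputed. This propagates *all* summary-level uncertainty,
  including the exposure-side error the analytic SEs ignore, and works at
  any $J$.
- **Nonparametric**: $J$ SNPs drawn with replacement per resample;
  degenerate draws (e.g. a collinear Egger design) are rejected and
  redrawn.

Both were implemented because the phrase is genuinely ambiguous; the
parametric scheme is the default since it resamples the *distributions of
the summary statistics* rather than the SNP set. Each replicate derives its
own sub-seed from the call seed, so results are reproducible and
independent of any future parallelisation of the loop. Defaults are
$b = 10{,}000$ resamples — empirical quantiles of a smooth unimodal
distribution are stable at that size — and analyses wanting
publication-scale $b = 100{,}000$ simply pass it.

`leave_k_out_scan()` quantifies dependence of a result on SNP selection:
each replicate drops $k$ distinct SNPs uniformly at random (default
$k = 6$, about 20% of a 31-SNP instrument), re-estimates, and records
whether the replicate estimate leaves the full-data normal-theory CI. More
than 5% of estimates outside flags the result as sensitive. With $k = 0$
the estimate is invariant and the proportion is exactly zero.

## Observational-scale conversion and meta-analysis

Published observational contrasts of the top versus bottom exposure tertile
are placed on the per-SD scale using the normal-distribution fact that the
outer tertile means sit $3\varphi(\Phi^{-1}(2/3))$ SD either side of the
mean, so the contrast spans $6\varphi(\Phi^{-1}(2/3)) = 2.1816 \approx
2.18$ SD (`tertile_sd_factor()`, means convention; a medians convention
would give a smaller factor and is not used). `fixed_effect_meta()` pools
estimates with inverse-variance weights and reports Cochran $Q$ and
$I^2 = \max(0, (Q-(k-1))/Q) \cdot 100$, truncated at zero by the usual
convention.

## Power

`prospective_power()` uses the design-based approximation in which the
expected IVW test statistic is $|\beta|\sqrt{n R^2 v}$, with $v$ the
outcome variance factor — $cf(1-cf)$ for a binary outcome with case
fraction $cf$, and $1$ for a continuous outcome. With the CHD-scale inputs
(n = 198,598; 65,877 events; $R^2 = 0.042$; OR 1.07 per SD;
$\alpha = 0.05$) this returns 83% to the nearest percent, which the
acceptance script recomputes. `retrospective_power()` evaluates the same
complement-of-false-rejection quantity at an estimated effect and its SE,
with no bias correction: it describes the power the analysis *had* at the
observed effect size, and is itself noisy when the estimate is.

## What the synthetic generator emulates — and what it does not

`simulate_instrument()` draws a $J$-SNP instrument under the structural
model
$$by_j = \theta\,bx_j + \sum_m \gamma_m\,bc_{jm} + \alpha_j,$$
with sampling noise added to every observed beta at its SE. Defaults mirror
a urate–CHD-style design: $J = 31$; allele frequencies uniform on
$(0.1, 0.9)$; exposure effects scaled so the instrument explains exactly
$R^2 = 4.2\%$ of exposure variance; SEs following the GWAS scaling
$1/\sqrt{2p(1-p)\,n}$ with $n = 145{,}000$ (exposure), $198{,}598$ with a
30.6% case fraction (binary outcome), and $70{,}000$ (covariate GWAS);
four covariates labelled SBP, DBP, HDL, TG with a random 40% of SNPs
carrying covariate associations. Direct pleiotropy $\alpha_j \sim
N(\mu_\alpha, \sigma_\alpha)$ is drawn independently of instrument
strength, so InSIDE holds by construction; a nonzero mean makes it
directional. Covariate-mediated pleiotropy is switched on through
$\gamma$, and a nonzero mean SNP–covariate effect (`mu_c`) makes that
pathway directional too (exposure effects are oriented positive, so a mean
covariate effect correlates with the instrument across SNPs).

Deliberately **not** emulated: linkage disequilibrium between SNPs (the
design assumes an independent selection), winner's-curse inflation of the
published exposure effects, sample overlap between the two samples, strand
or imputation artefacts beyond simple allele flips, and non-normal
sampling error. Passing tests therefore demonstrate correctness of the
estimators and their calibration *under the stated model*, not robustness
to those real-data pathologies.

Two errors-in-variables effects surfaced by the generator are worth
knowing about, because they are properties of the methods, not bugs:
exposure-side sampling noise attenuates the Egger intercept toward zero
(so the intercept-recovery validation uses precisely estimated exposure
effects, and at GWAS-scale noise the test asserts only a clearly positive
intercept), and noise in the covariate betas attenuates multivariable
adjustment (so the MVMR-unbiasedness validation uses a large covariate
GWAS and strong covariate effects; with noisy covariate betas the
adjusted estimate lands between the crude and fully adjusted values).

## Validation suite: design and problem sizes

The test suite validates every operation against an independent route:
hand-computed normal equations for the worked 3-SNP example; `lm(weights=)`
as a weighted-least-squares oracle on 200 random instruments
($J \in 3..12$, tolerance $10^{-8}$); `metafor::rma(method = "FE")` for the
meta-analysis; numerical integration for the tertile factor; and
closed-form formulas for power. Statistical guarantees are checked by
simulation at sizes chosen to keep Monte-Carlo error well inside the
asserted bands: IVW recovery of $\theta = 0.17$ over 1,000 replicates
(bias within 3 MC SEs), Egger-versus-IVW bias ordering under directional
pleiotropy over 1,000 replicates, MVMR unbiasedness over 400 replicates,
type-I error of the IVW and Q tests over 2,000 null datasets
($0.05 \pm 0.02$), and parametric-bootstrap coverage over 500 outer
replicates of $b = 2{,}000$ resamples ($95\% \pm 2\%$).

## Known limitations

- Wald-ratio SEs are first order and ignore exposure-side uncertainty, as
  is standard for summary-data MR; the parametric bootstrap is the
  package's way to propagate it.
- Weak instruments bias IVW toward zero and Egger more so; no
  weak-instrument correction is implemented.
- No LD modelling: supplying correlated SNPs will understate SEs.
- Palindromic SNPs are dropped rather than frequency-resolved, which can
  shrink an instrument assembled from strand-inconsistent sources.
- Weighted-median and mode-based estimators are out of scope.
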