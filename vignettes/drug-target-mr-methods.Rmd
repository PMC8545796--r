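---
title: "Methods: drug-target two-sample Mendelian randomization in targetMR"
author: "targetMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug-target two-sample Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetMR)
```

# The model

Two-sample MR estimates the causal effect of an exposure (here: circulating
LDL-C in SD units, or its pharmacological modulation through a drug-target
gene) on a binary outcome (renal cell carcinoma, log-OR scale) from two
independent GWAS: per-variant exposure associations $(\hat\beta_{Xi},
\sigma_{Xi})$ and outcome associations $(\hat\beta_{Yi}, \sigma_{Yi})$. The
structural assumption is $\beta_{Yi} = \theta\,\beta_{Xi} + \alpha_i$ with
$\theta$ the causal log-OR per SD and $\alpha_i$ the variant's direct
(pleiotropic) effect, zero for valid instruments. The three instrumental
assumptions are relevance (strong SNP-exposure association), independence
from confounders, and exclusion restriction ($\alpha_i = 0$); the package's
diagnostics each probe one of these.

A *drug-target (cis) instrument* restricts variants to a window around the
gene encoding the drug's protein target, so the exposure contrast proxies
pharmacological modulation of that target rather than LDL-C at large.
Because cis variants are mutually correlated, estimation must carry the
signed LD matrix $\rho$.

## Estimators

* **Wald ratio** ($k \le 2$): $\hat\theta_i = \hat\beta_{Yi}/\hat\beta_{Xi}$
  with first-order SE $\sigma_{Yi}/|\hat\beta_{Xi}|$; two variants are
  pooled fixed-effect.
* **IVW** ($k \ge 3$): weighted regression of $\hat\beta_Y$ on
  $\hat\beta_X$ through the origin, weights $1/\sigma_Y^2$. The
  *multiplicative random-effects* model (the default) multiplies the
  fixed-effect SE by $\sqrt{\max(1, Q/(k-1))}$, where $Q$ is Cochran's
  heterogeneity statistic about the estimate. The floor at 1 means
  heterogeneity can only widen, never shrink, the interval — conventional
  and conservative.
* **LD-adjusted IVW**: generalized least squares with
  $\Omega = \mathrm{diag}(\sigma_Y)\,\rho\,\mathrm{diag}(\sigma_Y)$,
  $\hat\theta = (\beta_X^\top\Omega^{-1}\beta_X)^{-1}
  \beta_X^\top\Omega^{-1}\beta_Y$, with the GLS analogue of $Q$ feeding the
  same inflation. The default analysis path combines the LD correction
  with the random-effects model; a config switch
  (`estimator$ld_correction`) turns the correction off because the two are
  described separately in most applied work and their combination is a
  modelling choice, not a theorem.
* **MR-Egger**: the same regression *with* an intercept, each variant
  first oriented so $\hat\beta_{Xi} \ge 0$ (the fit is meaningless without
  this orientation; joint sign flips of $(\beta_X, \beta_Y)$ leave it
  invariant — when an LD matrix is supplied the corresponding rows of
  $\rho$ are sign-flipped too). The slope estimates $\theta$ under InSIDE;
  the intercept estimates average directional pleiotropy.
* **Weighted median / weighted mode**: order statistics of the per-variant
  ratios with weights $(\hat\beta_{Xi}/\sigma_{Yi})^2$. The median uses the
  cumulative-weight interpolation $p_i = \sum_{j\le i} w_j - w_i/2$; the
  mode maximizes a Gaussian-kernel weighted density with a
  modified-Silverman bandwidth $0.9\,\min(s, \mathrm{MAD})\,k^{-1/5}$
  scaled by `bandwidth_factor` (default 1). Both get parametric-bootstrap
  SEs (default 1000 draws) with a *mandatory* seed: no silent
  irreproducibility.
* **Multivariable MR**: weighted multiple regression of $\beta_Y$ on the
  matrix of exposure betas without intercept. Exposures whose betas are all
  zero at the shared variants carry no information and are dropped from the
  fit with an `NA` estimate rather than crashing the normal equations;
  genuinely collinear exposures raise an error naming them.

## Diagnostics

* **Cochran's Q** with $k-1$ (IVW) or $k-2$ (Egger) degrees of freedom;
  per-variant terms are returned so the sum can be audited.
* **$I^2_{GX}$** quantifies NOME violation (regression dilution of the
  Egger slope): $Q_{GX} = \sum \sigma_{Xi}^{-2}(|\beta_{Xi}| - \bar\beta)^2$
  about the precision-weighted mean of $|\beta_{Xi}|$ (the Egger
  orientation, matching the estimator the statistic diagnoses), and
  $I^2_{GX} = \max(0, (Q_{GX} - (k-1))/Q_{GX})$.
* **SIMEX** re-estimates the Egger slope after adding noise of variance
  $\lambda\sigma_{Xi}^2$ for $\lambda \in \{0, 0.5, 1, 1.5, 2\}$
  (quadratic extrapolation to $\lambda = -1$). Each pseudo-dataset draw is
  paired with its antithetic negation, halving the Monte-Carlo variance of
  the per-$\lambda$ means. The reported SE combines the jackknife-over-
  replicates simulation variance with the sampling SE of the underlying
  Egger slope: jackknife noise alone shrinks to zero as replicates grow and
  would badly understate the uncertainty of the extrapolated estimate.
  Quadratic extrapolation under-corrects severe dilution (the true
  attenuation is a rational, not quadratic, function of $\lambda$); the
  method is intended for the moderate-dilution regime flagged by
  $I^2_{GX}$ in roughly 0.7–0.9, which is where the test suite validates
  its improvement over the naive slope.
* **MR-PRESSO**: observed residual sum of squares of each outcome beta
  about its leave-one-out IVW prediction, with a parametric null in which
  outcome betas are redrawn from $N(\text{fitted}, \sigma_Y)$ and the
  leave-one-out machinery re-fitted per simulation (re-fitting keeps the
  global test calibrated; comparing simulated draws against fixed
  predictions is anticonservative). Empirical p-values use the
  $(r+1)/(n+1)$ convention, so they are bounded below by $1/(n_{sim}+1)$.
  Outliers are flagged at the Bonferroni-adjusted level; the distortion
  test compares the estimate shift after outlier removal against the shift
  from removing equally many random variants.

## Harmonization rules

Variants are matched by rsID; a missing outcome variant may be replaced by
a user-supplied proxy (logged `PROXY_SUBSTITUTED` while retained under the
index variant's identity — the drop log doubles as an event log, and the
conservation audit counts proxy records as retentions). Swapped alleles
negate the outcome beta and complement its frequency; strand flips are
resolved by base complementation. Palindromic variants cannot be resolved
by alleles alone: with minor-allele frequency in the window open at 0.4
and closed at 0.5 they are dropped (`PALINDROMIC_AMBIGUOUS`); outside the
window they are oriented by whichever strand assignment brings the two
studies' effect-allele frequencies closer, and dropped when either
frequency is missing. The window's frequency source is the outcome study
when available, else the exposure study. Palindromic filtering runs after
proxy substitution, so a proxy is subject to the same ambiguity rules as a
directly matched variant.

## Instrument selection

Greedy p-value-ranked clumping with deterministic tie-breaks (ascending
position, then lexical variant id) makes the retained set invariant to
input row order. The r² and distance conditions combine differently in the
two selection modes, mirroring how the criteria are stated: for the cis
window they are coupled ("r² ≤ 0.2 *and* 250 kb"), so a candidate is
discarded only when both near *and* correlated with a retained variant;
for genome-wide selection independence requires both ≥ 10 Mb separation
and r² ≤ 0.001, so either condition binding discards. Pairs absent from
the LD matrix count as uncorrelated — for genome-wide selection the
distance rule still protects against cryptic local correlation.

Instrument R² is the sum of per-variant values (variants in weak LD
treated as independent; the aggregation under residual r² up to 0.2 is not
uniquely defined, and summation is the standard convention). Variants with
missing effect-allele frequency are excluded from the sum and from $k$ for
strength reporting only. When a published table prints CIs instead of SEs,
SEs are recovered as $(\text{upper}-\text{lower})/(2 \times 1.96)$; the
constant 1.96 is used exactly throughout reporting and reconstruction,
matching convention.

# The synthetic generator

`simulateTwoSample()` emulates the statistical structure the estimators
assume — not a biological genome. Per variant: minor-allele frequency
$f \sim U(0.05, 0.5)$; exposure SE $1/\sqrt{2 n_{exp} f(1-f)}$ (SD-unit
trait); true effect $\gamma \sim N(0, 0.02^2)$ rejection-sampled until
$|\gamma|$ passes genome-wide significance at $n_{exp}$ — conditioning on
the *true* effect, so instrument selection is free of winner's curse
(winner's-curse bias itself is out of the package's scope); observed
$\hat\beta_X$ adds AR(1)-correlated noise; outcome SE
$1/\sqrt{2 n_{out} K(1-K) f(1-f)}$ (case-control log-OR scale, case
fraction $K$); $\hat\beta_Y \sim N(\theta\gamma + \alpha, \cdot)$ with the
same AR(1) correlation; an `invalid_fraction` of variants draw direct
effects $\alpha$ from the configured pleiotropy distribution; a
`palindromic_fraction` receives A/T or G/C alleles.

Defaults are the calibration conditions the package is validated under:
$k = 50$, $n_{exp} = 100{,}000$, $n_{out} = 20{,}000$, $\theta = 0.5$, no
pleiotropy, no LD. The case fraction defaults to 0.3, typical of
case-control cancer GWAS of this size (the renal cell carcinoma scans the
package is modelled on have case fractions near 0.28 and 0.39). What the
generator does *not* emulate: realistic allele-frequency spectra and LD
beyond AR(1), sample overlap between the two studies, winner's curse,
population stratification, and selection bias. Passing calibration tests
therefore demonstrates the estimators' statistical correctness under the
stated model, not robustness to those real-data pathologies.

`simulateDrugTargetRegion()` plants LD blocks of known within-block
correlation plus isolated significant variants, with p-values decreasing
in construction order, so the expected clump output — block sentinels plus
isolated variants, and whether the r² = 0.40 relaxation engages — is known
by construction rather than re-derived.

# Numerical choices

* GLS paths use Cholesky factorization of $\Omega$; a non-positive-definite
  LD matrix raises an error suggesting the explicit `ridge = TRUE` flag
  ($\rho + 10^{-6} I$) rather than regularizing silently — a singular LD
  matrix usually means duplicated or mis-specified variants.
* The weighted mode maximizes the closed-form weighted density by a
  512-point grid scan refined with `optimize()` in the winning cell;
  identical ratios (zero bandwidth) short-circuit to the common ratio.
* Significance conditioning in the generator caps rejection sampling at
  10,000 attempts per variant and errors with advice to raise `gamma_sd`.
* Seeded routines save and restore the caller's RNG state, and the
  pipeline derives per-cell child seeds from one master seed, so re-running
  a config byte-reproduces all outputs.
* Simulation sizes in the test suite (500 replicates for calibration
  properties, 200–300 for secondary ones, MR-PRESSO nulls at 300
  simulations) were chosen as the smallest sizes at which the binomial
  tolerances quoted in the tests are meaningful.

# Open design points

* The 18-test FDR family in the published analysis is not enumerated in
  the source; the pipeline defaults the family to all grid cells
  ({targets} × {strata} = 6 × 3 reproduces 18) and excludes
  positive-control cells, which are validation, not discovery.
* Whether the published sensitivity estimators consumed LD-adjusted inputs
  is unstated; `prewhitenSet()` (Cholesky-inverse transform) is provided
  for the median/mode estimators but is off the default path.
* The power calculation's effective versus total outcome N is unstated;
  `powerBinary()` takes whatever N the caller supplies.
* Printed instrument-level F ranges could not be unambiguously assigned to
  targets under any aggregation; the package treats the weak-instrument
  bar (F > 10 for every target) as the reproducible property, and the
  acceptance script reports the minimum F it computes.

# Limitations

Single-variant error handling is strict by design (a zero exposure beta in
a Wald ratio is an error, not an `NA`); no liftover between genome builds;
no LD computation from genotype panels (the matrix is an input); no
colocalization; proxies come from a user table, not a remote LD service.
The sex-difference z test assumes independent strata — it is not valid for
overlapping samples.
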