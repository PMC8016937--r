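---
title: "Family-based gene-environment kernel association testing: models and methods"
author: "fgeskat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based gene-environment kernel association testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgeskat)
```

## The model

For a quantitative trait measured on $n$ related individuals, the package
works with the linear mixed model

$$ y = X\alpha + h_1 + h_2 + b + \varepsilon, $$

where $X$ is the $n \times p$ fixed-effect design (intercept, age, sex,
medication, the environmental exposure itself, ...),
$h_1 \sim N(0, \tau_1 K_1)$ is a regional genetic random effect,
$h_2 \sim N(0, \tau_2 K_2)$ a regional gene-environment interaction random
effect, $b \sim N(0, \sigma_b^2 R)$ the polygenic family effect with
$R = 2\Phi$ twice the pedigree kinship matrix, and
$\varepsilon \sim N(0, \sigma_e^2 I_n)$.

The two kernels share a mixing weight $\rho \in [0, 1]$:

$$ K_1 = \rho\, G W W G^{\mathsf T}, \qquad
   K_2 = (1-\rho)\, E\, G W W G^{\mathsf T} E, $$

with $G$ the $n \times m$ window of (recoded) genotype dosages, $W$ the
diagonal matrix of variant weights, and $E$ the diagonal matrix of the
environmental factor (e.g. 0/1 smoking).  At $\rho = 1$ the combined kernel
$K = K_1 + K_2$ is the plain weighted linear kernel of family-based SKAT
(FFBSKAT); at $\rho = 0$ only the interaction similarity remains.  The
environment enters $E$ exactly as coded — it is not centred — and its main
effect must simultaneously sit in $X$, otherwise an environment main effect
masquerades as interaction.

## The score test

Under $H_0: \tau_1 = \tau_2 = 0$ the trait covariance is
$V = \sigma_b^2 R + \sigma_e^2 I_n$.  The variance components and
$\hat\alpha = (X^{\mathsf T}V^{-1}X)^{-1}X^{\mathsf T}V^{-1}y$ are
estimated once per trait by REML (the default; ordinary ML is available via
`method = "ml"` in `fitNull()`).  The score statistic for a window is the
quadratic form

$$ Q = \tfrac12\,(y - X\hat\alpha)^{\mathsf T} V^{-1} K V^{-1}
       (y - X\hat\alpha)\big|_{\hat\phi}, $$

which, because $\hat\alpha$ is the GLS solution, coincides with the doubly
projected form
$\tfrac12 y^{\mathsf T}P^{\mathsf T}V^{-1}PKP^{\mathsf T}V^{-1}Py$ with
$P = I_n - X(X^{\mathsf T}V^{-1}X)^{-1}X^{\mathsf T}V^{-1}$; the test suite
asserts this equality against a dense oracle rather than assuming it.  Under
$H_0$, $Q \sim \sum_i \lambda_i \chi^2_{1,i}$ where the $\lambda_i$ are the
nonzero eigenvalues of $\tfrac12 V^{-1/2} P K P^{\mathsf T} V^{-1/2}$.

Computationally everything flows through two factorisations:

* one eigendecomposition of $R$ per data set, reused across all $\theta$
  evaluations, permutation replicates and windows ($V = U\,\mathrm{diag}
  (\sigma_b^2 d + \sigma_e^2)\,U^{\mathsf T}$);
* the kernel's low-rank factor $B = [\sqrt{\rho}\,GW,\;
  \sqrt{1-\rho}\,E\,GW]$, so the eigenvalues come from an $r \times r$ Gram
  matrix with $r \le 2m \le 40$, never from an $n \times n$ problem (a dense
  path exists in the test oracles only).

REML maximises the profiled restricted likelihood over the single ratio
$\gamma = \sigma_b^2/\sigma_e^2$ on $\log\gamma \in [\log 10^{-6},
\log 10^{6}]$ with an explicit boundary check at $\gamma = 0$;
$\hat\sigma_e^2$ has a closed form at each $\gamma$.  A boundary fit
$\hat\sigma_b^2 = 0$ is a legitimate result.  When $R = I$ (no relatedness)
the two components are identified only through their sum; the package
returns the boundary fit with a warning instead of failing.

## p-values for the chi-square mixture

The default route is the Kuonen saddlepoint: the Lugannani–Rice tail
formula on the cumulant generating function
$K(\zeta) = -\tfrac12\sum_i \log(1 - 2\zeta\lambda_i)$, with the saddle
solved by safeguarded root finding on $\zeta < 1/(2\lambda_{\max})$ and the
removable singularity at $Q = \sum_i\lambda_i$ handled by its analytic
limit.  A second, essentially exact route inverts the characteristic
function numerically (an Imhof-type oscillatory integral, split at the
phase extremum and at the zeros of the integrand, with the alternating tail
summed by repeated averaging); against closed-form chi-square tails it is
accurate to about $10^{-13}$ absolute.  `method = "auto"` cross-checks the
two and falls back to the inversion when they disagree by more than
`tolFlag` relative.

A point worth stating plainly: the first-order saddlepoint is an
*approximation* with relative error of order a few percent for mixtures
dominated by one or two eigenvalues (measured directly in the test suite:
about 0.5% for a single $\chi^2_1$ at $p = 0.05$, up to ~7% for strongly
decaying spectra).  It is the field's standard because it is fast, stable
to $p \sim 10^{-300}$, and its relative error is far below the
between-window variability that matters in a scan.  Where exactness matters
— quantiles for the calibration oracle, cross-checks — the package uses the
inversion route.

## The decision rule over the rho grid

Each window is tested on the grid $\rho = 0, 0.1, \ldots, 1$ (11 values by
default).  The reported p-value is

$$ p_{\text{adj}} = \min\bigl(1,\; 2 \min_\rho p(\rho)\bigr). $$

The multiplier 2 accounts for the two joint hypotheses (gene, and
gene-by-environment) and deliberately does not grow with the grid size —
the grid is a hyper-parameter search, not a family of independent tests.
The factor is applied after the grid minimum and both the factor and the
grid are configurable.  The $\rho = 1$ entry is reported alongside as the
plain family-SKAT p-value.  Because $\min_\rho p$ over a strongly
correlated family of statistics is only slightly smaller than any single
$p(\rho)$, the doubling makes the combined test mildly conservative; the
permutation study below quantifies this.

## Variant weights, recoding, missing data

Weights follow the Beta$(1,25)$ density of the minor allele frequency,
$w_j = 25(1 - p_j)^{24}$, computed on the analysis sample after orienting
dosages to the literal minor allele (columns with alternate-allele
frequency above 0.5 are flipped).  Disease-model recoding (additive,
dominant, recessive) is applied to the window before weighting; weights use
the allele frequency, not the post-recoding carrier frequency, matching the
usual SKAT convention.  Missing dosages are mean-imputed per variant with a
10% missingness ceiling; entirely missing variants are dropped with a
warning, and monomorphic variants are retained (they carry weight but zero
signal) so window coordinates stay stable.  Traits are Blom-transformed by
default in the scan driver, $z_i = \Phi^{-1}\!\bigl((r_i - 3/8)/(n +
1/4)\bigr)$ with average ranks for ties; raw-trait analysis is a flag.

## What the simulator emulates — and what it does not

`simPedigrees()` builds three-generation families (founding couple,
children, married-in spouses, grandchildren); 20 families give roughly
650–850 individuals, matching the scale of the blood-pressure family study
the method targets (about 835 analysed individuals across 20 pedigrees).
`geneDrop()` assigns founder haplotypes and transmits them by Mendelian
rules; within an optional LD block, founder haplotypes come from a finite
pool (default 32) and are co-transmitted without recombination, so flanking
windows are in linkage disequilibrium with a causal variant they do not
contain.  Two deliberate design choices keep the *realised* study
conditions equal to the stated ones rather than merely equal in
expectation:

* pool haplotypes carry the exact rounded allele count per variant, and
* founder gametes draw pool rows in balanced (stratified) fashion,

because with free Bernoulli sampling the designated causal MAF of 0.25 can
drift to 0.15–0.37 in a cohort with a few hundred founders, which changes
its Beta$(1,25)$ weight by up to two orders of magnitude and makes
"saturated" power scenarios anything but.  The phenotype generator draws a
Bernoulli exposure (default prevalence 0.228, a typical adult smoking
rate) and a normal trait with SD 10 around one of four group means
(non-exposed/exposed × non-carrier/carrier), carrier status following the
generating disease model at the causal variant; under the additive model
the group means are interpolated linearly in dosage/2.

The default validation panel (`simStudyPanel()`) holds 50 variants — four
sliding windows of 20 with step 10 — with MAFs uniform on $[0.25, 0.5]$ and
the causal variant at index 16 (inside windows 1 and 2) pinned to MAF 0.25.
The common-variant range is intentional: with Beta$(1,25)$ weights, a
window mixing a MAF-0.25 causal variant with substantially rarer neighbours
weights the causal signal down by factors of $10^2$–$10^3$, and a
recessive 6-SD effect becomes undetectable no matter how real it is.  The
saturation scenarios probe the gene-environment machinery, not weight
misspecification; rare-variant spectra are exercised separately.  Two
realities of family data that these simulations *do* reproduce, and which a
reader should keep in mind when extrapolating to real cohorts: a recessive
signal carried by homozygotes concentrated in a handful of families is
partly absorbed by the polygenic term (power falls in small cohorts), and
windows whose variants share long haplotypes are mildly conservative at the
1% level under permutation — both also visible in published family-SKAT
permutation tables.  What the simulator does not emulate: realistic
coalescent haplotype diversity, the rare-variant site-frequency spectrum of
sequence data, longitudinal repeated measures, and ascertainment.

The permutation study (`permutationType1()`) permutes the phenotype vector
only, leaving genotypes, covariates and the family structure with the
individuals (a joint-row mode exists); each replicate refits the null model
and tests all windows with both decision rules.  The power study
(`powerStudy()`) regenerates phenotype and exposure each replicate on a
fixed gene-dropped panel (regenerating genotypes is a flag; fixed genotypes
are the default so replicates differ only in phenotype noise, and the
documented seed derivation makes partial reruns reproducible).

## Numerical choices

* REML convergence: golden-section search on $\log\gamma$ with tolerance
  $10^{-10}$ on the objective; results are start-value free by
  construction.  The profile identity (closed-form $\hat\sigma_e^2$
  maximises $l$ at fixed $\gamma$) is asserted numerically in the tests.
* Eigenvalues below $10^{-10}\lambda_{\max}$ are dropped from the mixture;
  p-values are floored at $10^{-300}$ so $-\log_{10} p$ exports stay
  finite.
* Saddlepoint root finding: bracketed on $(-\infty, 1/(2\lambda_{\max}))$
  with tolerance $10^{-14}$; $|w| < 10^{-6}$ switches to the analytic
  near-mean limit.
* Degenerate inputs are results, not crashes: an all-monomorphic window or
  a zero kernel reports $p = 1$ with a `"degenerate"` flag; a constant
  environment column is dropped from the fixed effects with a warning and
  the $\rho = 0$ entry is flagged.
* Half-founders are treated as having an implicit unique founder parent;
  individuals with data but absent from the pedigree are an error, never
  silently coerced into founders; kinship is always computed on the full
  pedigree and sub-matrixed to the analysis sample afterwards.

## Problem sizes used in the shipped studies

The package's own validation runs — the test suite and
`scripts/acceptance.R` — use the default 20-family cohort (n ≈ 650–850)
with 1,000 replicates for the permutation and power grids, a 10-family
(n ≈ 300) cohort with $10^5$ multivariate-normal draws for the
null-distribution calibration oracle at $\rho \in \{0, 0.5, 1\}$, and 500
replicates of a 50 × 4 sibship design for REML recovery of
$(\sigma_b^2, \sigma_e^2) = (4, 6)$.  These sizes were chosen so each study
estimates its quantity with a standard error comfortably inside the
assertion bands (binomial SE ≈ 0.007 at a 5% rate with 1,000 replicates).

## Known limitations

* One environmental factor at a time; multiple factors mean repeated runs
  and external multiplicity control.
* Quantitative traits only; no binary-trait GLMM or case-control
  imbalance corrections.
* The weighted linear kernel only (the kernel builder is the extension
  point for IBS or polynomial kernels).
* No analytic minimum-p distribution over the rho grid (SKAT-O style); the
  doubling rule is simple, validated by permutation, and mildly
  conservative.
* The genome-wide window count (and hence the Bonferroni threshold) is
  data-dependent; the published 834,030-window threshold is reproduced as
  arithmetic, not as a constant baked into the scan.
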