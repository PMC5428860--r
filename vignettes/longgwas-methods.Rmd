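---
title: "Random-regression functional GWAS for longitudinal traits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-regression functional GWAS for longitudinal traits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longgwas)
```

## The problem

Longitudinal traits — test-day milk yield, blood pressure, growth — are
measured repeatedly over time on the same individuals. Classical GWAS
pipelines collapse the trajectory into a single pseudo-phenotype per
individual (an accumulated estimated breeding value, a deregressed proof,
or an averaged residual) and regress it on each SNP. Collapsing discards
the time-dependence of the genetic signal and, depending on the
pseudo-phenotype, either inflates false positive rates (family information
leaks into the response) or wastes power (shrinkage attenuates the
signal).

`longgwas` instead scans SNPs inside the random regression (test-day)
model itself, giving every SNP its own effect *curve* over time. Two
parameterizations are provided:

* **fGWAS-C** — the SNP enters as a dosage covariate `x_i ∈ [0, 2]`
  multiplying a time curve: `x_i · SNP(t)`. Works for hard calls and
  imputed dosages; tests additivity directly.
* **fGWAS-F** — the SNP enters as a genotype factor with one curve per
  observed class. Tests additive and dominance deviations jointly at the
  cost of extra degrees of freedom.

## The model

For individual `i` at time `t`,

```
y_i(t) = mu(t) + [SNP term] + a_i(t) + pe_i(t) + e_it
```

with every time-varying term expanded in normalized Legendre polynomials
`phi_k(x(t))`, `x(t) = 2(t - t_min)/(t_max - t_min) - 1`:

* `mu(t) = sum_{k=0}^{nf} beta_k phi_k(t)` — population mean curve,
* `a_i(t) = sum_{k=0}^{nr1} a_ik phi_k(t)` — additive genetic curve,
  `var(a) = A ⊗ G` with `A` the pedigree numerator relationship matrix,
* `pe_i(t) = sum_{k=0}^{nr2} p_ik phi_k(t)` — permanent environment,
  `var(p) = I ⊗ P`,
* `e_it ~ N(0, sigma_e^2)` i.i.d.

"Order" always means the highest polynomial degree, so an order-`q` term
carries `q + 1` coefficients. The normalized ("Kirkpatrick") basis
`phi_k(x) = sqrt((2k+1)/2) P_k(x)` is the convention of random regression
animal models; normalization rescales coefficients but not fitted curves,
test statistics, or cumulative effects. All terms in one model share one
time domain, taken from the data unless overridden.

The SNP term uses the same order `nf` as the mean curve. For fGWAS-F the
lowest observed dosage class is the reference with zero curve — the same
behaviour as factor coding in standard mixed-model software. This choice
makes the genetic decomposition read exactly as written: with class curves
`SNP_AA(t)`, `SNP_Aa(t)`, `SNP_aa(t) = 0`,

```
add(t) = (SNP_AA(t) - SNP_aa(t)) / 2
dom(t) = SNP_Aa(t) - add(t)
sigma2_a,SNP(t) = 2 p q (add(t) + dom(t) (q - p))^2
```

and under reference coding the `dom(t)` line coincides with the textbook
midpoint convention `SNP_Aa - (SNP_AA + SNP_aa)/2`. A
`dom_convention = "midpoint"` switch is kept for class curves obtained
under other codings. A count-weighted sum-to-zero constraint was the main
alternative considered; it was rejected because the `dom(t)` contrast above
is not invariant to re-centering all class curves, so a deviation-coded fit
would report a dominance curve even for a purely additive locus.

## Hypothesis test

Each SNP is tested by the incremental Wald statistic

```
W = [R(full) - R(reduced)] / sigma_e^2
```

where `R(model)` is the reduction in sums of squares of the mixed-model
fit and `sigma_e^2` is the REML residual variance of the reduced (no-SNP)
model. `W` is chi-square with `nf + 1` df (fGWAS-C) or
`(number of observed classes - 1)(nf + 1)` df (fGWAS-F; `2(nf + 1)` when
all three genotypes occur). The pseudo-phenotype baselines all have 1 df.

`R(model)` is kept on the natural (unweighted) sums-of-squares scale,
`R = y'y - sigma_e^2 y'Py`, so that dividing the increment by
`sigma_e^2` yields the chi-square statistic; this matches the standard
mixed-model Wald construction and is verified against a dense GLS oracle
in the tests.

Variance components are *plug-in*: `(G, P, sigma_e^2)` are estimated once
by REML under the reduced model and reused for every SNP, which is the
standard genome-scan strategy when individual SNP effects are small. A
`per_snp_reml` flag re-estimates components under each SNP's full model
for single-locus studies.

## REML

The restricted likelihood is maximized by L-BFGS-B over an unconstrained
log-Cholesky parameterization of `(G, P, sigma_e^2)` — every iterate is
positive definite by construction, so no EM fallback or boundary repair is
needed. Convergence follows `optim`'s `factr = 1e7` relative-change rule
(about 1e-8 of the objective); a diagonal floor inside the
parameterization (1e-8 of the phenotypic variance, applied on the
standardized scale) keeps near-singular components from destabilizing the
mixed model equations. Phenotypes are standardized internally and the
components are scaled back on exit.

Two exact evaluation routes feed the optimizer:

* **Balanced recordings** (every phenotyped individual measured at the
  same times — the usual designed study): with `A_nn` the phenotyped block
  of `A` and `A_nn = U D U'`, rotating the data matrix by `U'` decouples
  individuals; a further joint diagonalization of the within-individual
  covariance reduces each likelihood evaluation to `O(n T)` elementwise
  work. The analytic gradient is computed in the same coordinates, so a
  full REML fit at `n = 500`, `T = 10` takes a fraction of a second.
* **General designs**: the likelihood is evaluated through a sparse
  Cholesky factorization of Henderson's mixed model equations using the
  determinant identity
  `log|V| + log|X'V^-1 X| = log|R| + log|A ⊗ G| + log|I ⊗ P| + log|C|`,
  with `log|A|` obtained for free from the Mendelian-sampling variances of
  the pedigree.

Both routes compute the same restricted likelihood; the test suite checks
their equality to 1e-8 on shared instances, and checks the analytic
gradient against central differences.

Initialization assigns half the phenotypic variance to the residual and
splits the remainder over diagonal `G` and `P`. Basis orders are selected
by `select_orders()`, which fits a candidate grid and minimizes BIC
(AIC reported alongside), breaking ties toward fewer parameters. The
information criteria count only the free covariance parameters,
`k = (nr1+1)(nr1+2)/2 + (nr2+1)(nr2+2)/2 + 1` — the REML convention;
because REML likelihoods are not comparable across different fixed
effects, candidates in one grid should share `nf`.

## Pedigree algebra

`A` is built by the tabular method with full inbreeding accounting
(`A_ii = 1 + F_i`), and `A^{-1}` directly from Henderson's rules with the
Quaas correction, using Mendelian sampling variances
`d_i = 1 - 0.25(A_ss + A_dd)`. The product `A A^{-1} = I` is exact to
round-off and is tested. Individuals present in the data but absent from
the pedigree are added as unrelated founders with a warning.

Reliabilities of accumulated EBVs use the prediction error variance of the
accumulation contrast `Q_c` from the inverse MME coefficient matrix:
`r2_i = 1 - Q_c' C^{aa}_i Q_c / (A_ii Q_c' G Q_c)`. The `A_ii` factor (1
for non-inbred individuals) makes the denominator the exact prior variance
under inbreeding.

## Pseudo-phenotype baselines

Five comparison strategies collapse the trajectory to one value per
individual and scan with a 1-df regression:

* **EBV (P/NP)** — the accumulated EBV `EBV_i = Q_c' a_hat_i`, with
  (`-P`) or without (`-NP`) a pedigree polygenic term
  `u ~ N(0, A sigma_a^2)` in the scan model.
* **DRP (P/NP)** — deregressed proofs. The package implements a
  single-step parent-average removal,
  `DRP_i = PA_i + (EBV_i - PA_i)/max(r2_i, 0.1)`: the family mean is
  stripped and the Mendelian-sampling deviation is de-shrunk by the
  reliability, with a floor of 0.1 capping variance inflation for weakly
  proven individuals. The full information-weighted deregression system
  was not reproduced — the published description delegates the details —
  but this form captures the property the comparison needs: parent-average
  information removed, within-family signal retained.
* **Residual** — the GRAMMAR-style scan: per-individual averaged residuals
  of the reduced model, tested by ordinary least squares. Because the
  response is a per-time mean, its regression coefficient is rescaled by
  the grid length when compared with cumulative effects.

These baselines reproduce their known pathologies in simulation: the
`-NP` variants inflate the false positive rate under family structure,
the residual scan is conservative and severely attenuates the effect
size, and all pseudo-phenotype methods underestimate the cumulative QTN
effect, while the two functional scans are near-unbiased.

## The simulator

`simulate_longitudinal()` emulates a pedigreed dairy-style design:

* Founder allele frequencies for 1,002 unlinked SNPs are drawn
  Uniform(0.1, 0.9) and drifted through 100 discrete Wright–Fisher
  generations of size 100 — enough drift to produce a realistic frequency
  spectrum and cohort-level relatedness without simulating a deep
  coalescent history; the methods under test use pedigree, not LD.
* A recent pedigree: `n_sires` males randomly chosen per generation, each
  mated to the previous generation's females, two offspring (one male,
  one female) per dam, four generations. Phenotyped cohort: all females
  of generations 1–4 (2,000 in the `paper` profile; 500 in the `desk`
  profile). Genotypes descend by Mendelian gene-dropping from founder
  haplotypes.
* One SNP is the causal QTN with a smooth order-2 Legendre effect curve
  whose **sum over the integer day grid 5..305 is fixed at 175.21**
  (the curve is scaled, so this holds exactly); one SNP is a null marker
  kept out of the phenotype; the remaining 1,000 SNPs carry random
  order-2 polygenic coefficient vectors and their genotypes are withheld
  from the output, forming the genetic background.
* Each phenotyped female gets 10 equally spaced records on days 5..305.
  Ten test-day-like records is the common dairy recording density; the
  exact scheme is configurable.
* Variance calibration: the QTN curve is fixed, so the total phenotypic
  variance is set to `var_QTN / h2_QTN`; the polygenic, permanent
  environment and residual components are then scaled to time-averaged
  shares `h2 - h2_QTN`, `pe` and `1 - h2 - pe` of it. Defaults
  `h2 = 0.3`, `pe = 0.2`, residual 0.5, with QTN heritabilities from
  0.1% to 2%; `pe = 0.2` is a typical repeatability-model split for
  production traits. With `h2_QTN = 0`, an explicit `phenotypic_var`
  anchors the scale. The realized additive share reproduces 0.30 within
  sampling error (checked in the tests).
* The population mean is a fixed lactation-like quadratic
  `mu(t) = 20 + 0.08 t - 2e-4 t^2`.

What the generator does **not** emulate: linkage and LD blocks (loci are
unlinked; drift supplies frequency variation only), selection, genotype
missingness or error, heterogeneous residual variance over time, and
non-genetic trends such as seasons or parity. Passing tests therefore
demonstrate correct statistical behaviour under a clean random-mating
pedigree — not robustness to LD structure or data-quality artifacts in
real data.

The QTN and null markers are required to segregate in the phenotyped
cohort; drift trajectories that approach fixation are redrawn (null
markers also resample their founder frequency), with a bounded retry count
and a warning on failure.

## Numerical choices and degenerate inputs

* Monomorphic or sub-MAF (default 0.01) SNPs are reported untestable with
  `W = 0`, `p = 1`, not dropped, so scan tables stay aligned.
* A SNP collinear with the mean curve raises a per-SNP rank error and the
  scan continues.
* fGWAS-F rejects fractional dosages explicitly and points to fGWAS-C;
  fGWAS-C mean-imputes missing calls, fGWAS-F drops the affected
  individuals for that SNP (falling back to the sparse-MME route, since
  dropping breaks the balanced rotation).
* `W` is clipped at zero; `R(full) >= R(reduced)` is guaranteed by nesting
  and asserted with a small numerical slack.
* Eigenvalues of `A_nn` are floored at 1e-10; basis matrices are built by
  the Bonnet recurrence (no explicit polynomial coefficients, stable to
  high orders).
* Storey q-values estimate pi0 by the smoother on lambda in 0.05..0.95,
  falling back to pi0 = 1 (= Benjamini–Hochberg) below 100 tests or when
  the smoother fails.

## Problem sizes used in checks

The packaged tests and the acceptance script run the `desk` profile: 500
phenotyped females (1,000 for the power target), 10 records each, with
50–200 replicates per quantity — sizes chosen so the whole study re-runs
in minutes on a laptop while keeping binomial noise on rates near one
percentage point. Calibration (type-I error), unbiasedness and the
bias/precision ranking of methods are scale-free and reproduce directly;
absolute power at the smallest QTN heritabilities is the one quantity that
genuinely needs the full 2,000-female, 1,000-replicate design, which the
`paper` profile provides for users with more patience.

## Known limitations

* REML likelihoods across different `nf` are not comparable (REML
  contrasts change); order selection should vary `nr1`/`nr2` within one
  `nf`.
* The deregression is the single-step parent-average form, not the full
  information-weighted system; reliabilities and DRPs for complex
  pedigrees with many progeny are approximate.
* Heterogeneous residual variance classes over time are not modeled
  (single `sigma_e^2`).
* The scan treats variance components as known (plug-in); p-values ignore
  their estimation error, as is standard for genome scans.
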