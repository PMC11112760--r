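---
title: "Methods: cell-type-specific MWAS of correlated risk variables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type-specific MWAS of correlated risk variables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctmwas)
```

# The analytical problem

Neonatal health indicators — gestational age, Apgar score, the three
body-size measures, maternal age, and the diagnoses jaundice,
preeclampsia and birth diagnosis — are strongly intercorrelated. A
methylome-wide association study (MWAS) run variable-by-variable
conflates two distinct kinds of biology: *common* effects shared
through latent dimensions of neonatal health, and *unique* effects
specific to one indicator. On top of that, blood is a mixed tissue:
a bulk methylation signal is a proportion-weighted average over cell
types, and effects confined to one cell type — or pointing in
opposite directions in two cell types — can be invisible in bulk.

`ctmwas` implements a two-phase pipeline that addresses both
problems, and a synthetic-data generator with known ground truth that
lets every stage be validated by parameter recovery and calibration
rather than by eyeballing.

# Phase 1: common and unique effects

Nine risk variables are decomposed by exploratory factor analysis of
their correlation matrix into two orthogonal factors — in the
reference structure a *size* factor (weight 0.95, height 0.82, head
size 0.74, gestational age 0.56) and a *disease* factor (jaundice
0.65, birth diagnosis 0.46, gestational age −0.42). A variable is
"assigned" to a factor when |loading| > 0.3 (the comparison is on the
absolute value: −0.42 counts). Downstream, an assigned variable's
analysis unit includes its factors as covariates, so its scan
isolates the *unique* effect; the factors themselves are analyzed as
their own units and carry the *common* effects.

Decisions taken where the method is underdetermined:

* **Extraction and rotation.** Maximum-likelihood factoring
  (`stats::factanal`) with varimax rotation. Orthogonal rotation is
  implied by the factors being modeled as independent; varimax is the
  standard orthogonal choice. The reference loading matrix is its own
  varimax solution (rotation matrix = identity), so the population
  target is rotation-stable.
* **Factor scores.** Regression (Thomson) scores,
  `F = Z R^{-1} Λ`. Their correlation with the true latent factor is
  bounded by the closed-form validity `sqrt(diag(Λ' R^{-1} Λ))` —
  about 0.97 for the size factor but only about 0.79 for the weakly
  determined disease factor. No scoring method can beat this bound;
  tests assert agreement with it rather than a uniform threshold.
* **Binary variables.** By default they enter the correlation matrix
  as Pearson correlations of the 0/1 coding, which is what a naive
  EFA on mixed data does — and which attenuates a loading like
  jaundice's 0.645 (prevalence 5.1%) to roughly 0.31, by the
  point-biserial factor `φ(τ)/sqrt(p(1−p)) ≈ 0.48`. Because the
  generator produces binaries by liability thresholding, the package
  also offers `cor_method = "latent"`: tetrachoric correlations
  (maximum likelihood, with a quadrature bivariate-normal CDF) for
  binary pairs and closed-form biserial correlations for
  binary–continuous pairs. The latent option recovers the generating
  loadings; the Pearson default reproduces what a practitioner's
  default analysis would see.
* **Degenerate inputs.** A singular correlation matrix is an error; a
  Heywood case (uniqueness at the boundary) is a warning, never
  silent. On data with *no* factor structure the ML solution is
  weakly identified and can park a near-unit loading on a single
  variable; the meaningful invariant — implied cross-correlations
  near zero — is what the tests check.

Missing phenotype values (only the four continuous size/gestation
variables are eligible) are imputed by seeded chained stochastic
regression: ten cycles over the targets, each refit on originally
observed rows against the other three size variables plus sex, with a
posterior-style Gaussian draw at the residual SD. Imputed gestational
ages are clipped to the plausible 154–301-day range. Exclusion rules
run first: gestational age below 224 days (32 weeks) drops the
sample; above 301 days (43 weeks) the value is treated as a clerical
error and set to missing. Every action is logged.

# Phase 2A: methylation-risk-score screening

Before any full scan, each analysis unit is screened for a
*cumulative* methylation signal with a k-fold cross-validated
methylation risk score: within each training fold the outcome and all
CpGs are residualized on the covariates, CpGs are ranked by the |t|
of their marginal association (ties broken by genomic position), and
each held-out sample receives the sum of sign-aligned standardized
residual methylation over the top-N CpGs. The out-of-fold scores are
Spearman-correlated with the covariate-residualized outcome. N runs
over a grid (default 50/500/5000/50000, capped at the panel size);
the best-N result is reported and flagged as grid-optimized. Units
with P < 0.05 pass the gate into Phase 2B.

**A calibration caveat that matters.** The default P-value is the
Spearman t-approximation treating the score as fixed. It is not:
folds share ~90% of their training samples, so they tend to select
the same CpGs, and the selection-induced dependence inflates the null
variance of the correlation roughly threefold (about 20–25%
rejection at nominal 5% in null simulations — reproduced by a
stand-alone oracle implementation, so it is a property of the
procedure, not of this code). The gate therefore uses a *knowingly
optimistic* statistic, which for a screening step mainly trades
specificity for sensitivity. For calibrated inference the package
provides `p_method = "permutation"`, which re-runs the *entire*
cross-validated selection pipeline on permuted (covariate-residualized,
Freedman–Lane) outcomes; its null rejection rate is at nominal level
by construction, and it is the variant used in the calibration
checks. Fold preparation is outcome-independent and cached, so a
permutation costs only one matrix–vector product per fold.

Two further details: scores are invariant to affine rescaling of any
CpG (standardization is internal), and a noiseless outcome equal to a
single CpG yields rho ≈ 0.9996 rather than exactly 1, because
standardization constants are estimated per training fold and ranks
can swap at fold boundaries.

# Phase 2B: bulk and cell-type-specific MWAS

For each passing unit, bulk association is per-CpG ordinary least
squares of methylation on the outcome plus covariates — sex, batch,
the first two methylation principal components (unmeasured
confounders), and the cell proportions themselves (one column, the
most abundant type granulocytes, dropped against the intercept since
rows sum to one).

The cell-type-specific scan fits, per CpG, one joint regression

    Y_bulk = Σ_c m_c P_c + Σ_c m_c^RV (RV × P_c) + covariates + E

with *no* global intercept — the six proportion columns span it.
Each interaction coefficient `m_c^RV` is the cell-type-specific
association, tested two-sided with df = n − rank. All six
interactions are fit jointly because the model is a single sum; a
one-type-at-a-time fit would misattribute shared variance.
Covariates enter additively, not interacted with proportions.

Numerical and design choices:

* All CpGs share one design matrix, so the scan is a single QR solve;
  classical SEs come from `(X'X)^{-1}` and the residual variance, and
  HC3 sandwich SEs from the shared hat diagonal — both verified
  against `lm()` and `sandwich::vcovHC` to 1e-10.
* An all-zero proportion column (absent cell type) carries no
  information and is dropped; a constant non-zero column is exactly
  collinear with the rest (row sums are one) and its cell type is
  flagged unidentifiable — unless it is the *only* type present, in
  which case the model collapses to the bulk regression, as it
  should. Passing an explicit intercept is refused with a
  rank-deficiency error.
* Constant-methylation CpGs get missing p and are excluded from FDR
  and lambda. Exact fits would give p = 0; p is clamped to the
  smallest positive double so q-values stay in (0, 1].
* "Robust" MWAS, used for rare binary outcomes such as jaundice,
  keeps the identical point estimates and swaps in HC3 SEs, with an
  optional seeded permutation p (outcome shuffled, within strata if
  given). Binary outcomes require at least 10 minor-class cases.
* FDR (Benjamini–Hochberg step-up, q < 0.1 for methylome-wide
  significance; P < 1e-6 for suggestive) is applied separately within
  each analysis unit × target, matching a per-column findings table;
  genomic inflation lambda is the median association chi-square over
  0.4549364. Under the generator's null, every cell type's type-I
  rate at α = 0.05 lands in [0.047, 0.053] and lambdas in
  [0.96, 1.04] at 20,000 CpGs.

# Phase 2C: genes and enrichment

CpGs below the suggestive threshold are linked to every gene whose
body ± 10 kb (configurable) contains the CpG position, strand
ignored since CpG methylation is strand-symmetric; unlinked CpGs are
reported intergenic. Enrichment against user-supplied GMT gene sets
is a one-sided hypergeometric test; the background universe is every
gene linkable to *any* assayed CpG — the tested universe, not the
whole annotation — and sets are intersected with it before testing.
The linking distance and background choice materially change term
lists and are deliberately explicit parameters.

# The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the
study conditions used throughout the tests:

* **Phenotypes.** n = 332. Independent standard-normal factors,
  variables formed as `Λ_v · F + e_v` with uniqueness
  `1 − Σ λ²`, rescaled to familiar units (gestational age 278 ± 12.6
  days, weight 3490 ± 526 g, ...). The three diagnoses are
  liability-thresholded at prevalences 5.1% (jaundice), 7.2%
  (preeclampsia), 29.8% (birth diagnosis) — thresholding preserves
  the latent loading structure for tetrachoric-style analysis. Sex is
  Bernoulli(0.575 male); batch has two levels.
* **Cell proportions.** Dirichlet rows centered at
  (B 0.08, Gran 0.39, Mono 0.18, NK 0.05, cT 0.15, Th 0.14),
  renormalized to sum exactly to one. Concentration 60: no single
  Dirichlet precision reproduces all six observed SDs (they imply
  values from ~36 to ~164), and 60 matches the dominant granulocyte
  SD scale (0.063 vs 0.08) while keeping the minor types close.
* **Methylation.** Per CpG, cell-type baselines `μ_c ~ N(5, 1)` on an
  arbitrary abundance scale (enrichment-sequencing coverage scales
  are study-specific and irrelevant to inference), bulk values
  `Σ_c P_c μ_c`, planted effects `β · RV · P_c` at configured
  CpG/cell-type pairs, per-CpG additive sex and batch effects, and a
  single global noise SD of 1 (heteroskedastic extension deferred).
  At a planted CpG the population interaction coefficient equals β
  exactly. The default demonstration effect size β = 8 gives
  per-CpG cell-type |t| of roughly 4–6 at n = 332 — the magnitude of
  a top methylome-wide finding. Values are not clipped at zero; the
  Gaussian tail can produce rare small negatives, which is harmless
  for linear modeling and keeps planted coefficients exact.
* **Missingness.** MCAR on the four continuous size/gestation
  variables only, at a rate quoted over all nine assessments
  (0.4% ≈ 12 of 2,988), never more than two per sample.
* **Seeding.** One master seed, split per operation by fixed offsets
  (phenotypes +101, proportions +211, methylation +307,
  missingness +401), so each stage is independently reproducible
  bit-for-bit.

What the generator does *not* emulate — and hence what passing tests
cannot certify about real data: read-level sequencing noise and QC
artifacts, genuine per-CpG variance heterogeneity, spatial
correlation between neighboring CpGs, cell-proportion estimation
error (proportions are taken as known inputs), nucleated red blood
cells, and genome-scale CpG counts (tests run desk-scale panels of
300–20,000 CpGs; the pipeline's shared-design algebra is linear in
CpG count).

# Problem sizes and runtime choices

The test and validation runs use: 20,000 null CpGs for calibration
(the lambda band is ~2.6 sampling SDs wide at 10,000 CpGs, so the
larger panel halves estimator noise without changing the quantity);
200 planted CpGs for recovery bias; 100 single-CpG replicates for the
opposite-sign design; n = 5000 cohorts for factor recovery; 100 null
replicates × 99 permutations for MRS calibration. Factor recovery is
asserted on the continuous liability scale, where the element-wise
0.1 bound holds with threefold margin; under thresholding the
attenuation-corrected latent fit is asserted to beat the Pearson fit
(tetrachoric sampling noise and rotation wobble make a fixed 0.1
element-wise bound seed-dependent there).

# Known limitations

* The default MRS gate P is optimistic (above); use the permutation
  option when the screen's error rate matters.
* Regression factor scores for weakly determined factors (disease
  factor validity ≈ 0.79) dilute "unique effect" adjustment: a
  variable's factor covariate removes only the estimable part of the
  common effect.
* The imputation is a single completed dataset (nothing downstream
  pools across imputations), appropriate at the ~0.4% missingness it
  is designed for, not at high missingness.
* FDR is per unit × target; a global option exists but counts in the
  findings table are per-column by design.
* Tetrachoric ML uses a continuity correction for empty cells, which
  can shrink extreme correlations at very low prevalence × small n.
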