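# ctmwas

Cell-type-specific methylome-wide association analysis of correlated
risk variables, with a factor-analytic decomposition into common and
unique effects, methylation-risk-score screening, and a fully seeded
synthetic-data generator for calibration and parameter-recovery
validation.

## The problem and who this is for

Epigenomics groups studying perinatal or other clinical phenotypes in
blood face two entangled problems. First, clinical risk variables
(gestational age, Apgar score, birth weight/height/head size,
maternal age, jaundice, preeclampsia, birth diagnosis) are heavily
intercorrelated, so per-variable association scans mix effects shared
across the phenotype panel with effects unique to one variable.
Second, whole blood is a mixture: the bulk methylation level of a CpG
is a proportion-weighted average over cell types, and a cell-type
confined effect — or two opposite-sign effects in different cell
types — can cancel into invisibility in bulk.

`ctmwas` addresses the first problem with exploratory factor analysis
(two orthogonal factors, size and disease; variables with |loading| >
0.3 get their factors as covariates so their scans isolate *unique*
effects) and the second with a statistical deconvolution regression.
For each CpG the bulk signal is fit jointly as

    Y_bulk = Σ_c m_c P_c + Σ_c m_c^RV (RV × P_c) + covariates + E

where `P_c` are the six leukocyte proportions (B, granulocytes,
monocytes, NK, cytotoxic T, T helper) and the interaction coefficient
`m_c^RV` tests the association of risk variable RV within cell type
`c`. There is no global intercept — the proportion columns span it.
Intermediate machinery includes cross-validated methylation risk
scores (screening gate P < 0.05), Benjamini–Hochberg FDR (q < 0.1
methylome-wide, P < 1e-6 suggestive), genomic-inflation lambdas, HC3
robust errors for rare binary outcomes, CpG-to-gene linking
(body ± 10 kb) and hypergeometric gene-set enrichment.

## Worked example

Simulate a 332-sample, 2,000-CpG cohort with 60 CpGs carrying a
T-helper-specific effect of the latent size factor, plus one CpG with
opposite-sign effects in monocytes and granulocytes calibrated to
cancel in bulk; then run the phases.

```r
library(ctmwas)

pm <- blood_cell_means()
effects <- rbind(
  data.frame(cpg = 1:60, cell_type = "Th", beta = 4),
  data.frame(cpg = c(61, 61), cell_type = c("Mono", "Gran"),
             beta = c(8, -8 * pm[["Mono"]] / pm[["Gran"]])))
cfg <- sim_config(n_samples = 332, n_cpgs = 2000, effect_map = effects,
                  effect_rv = "size_factor", seed = 42)
d <- simulate_dataset(cfg)

pheno <- impute_missing(apply_exclusions(d$phenotypes), seed = 42)
fm <- fit_factor_model(pheno)
rv   <- fm$scores[, "factor1"]            # recovered size factor
covs <- model.matrix(~ sex + batch, pheno)[, -1]

compute_mrs(d$meth, rv, covs, top_n_grid = c(50, 200), seed = 42,
            unit = "size_factor")
#> mrs_result [size_factor]: rho = 0.893, P = 1.54e-116
#>   (top 50 CpGs, grid-optimized), gate PASSED

ct <- celltype_mwas(d$meth, rv, d$proportions, covs, unit = "size_factor")
bk <- bulk_mwas(d$meth, rv, covs, d$proportions, unit = "size_factor")
```

The opposite-sign CpG (index 61) is invisible in bulk but decisively
recovered per cell type — the phenomenon the deconvolution exists
for:

```
     estimate     se     t        p        q
Mono     6.76 0.9800  6.90 2.86e-11 5.72e-08
Gran    -2.70 0.5780 -4.68 4.34e-06 8.68e-03
bulk    -0.06 0.0598 -1.00 3.17e-01 9.22e-01
```

The planted values were +8 in monocytes and −3.7 in granulocytes; the
bulk slope is null by mixture-weighted cancellation. The findings
table (`q < 0.1` / `P < 1e-6` per column) concentrates the planted
T-helper signal where it belongs:

```
         unit  bulk   B Gran Mono  NK  cT   Th
1 size_factor 64/60 0/0  3/0  1/1 0/0 0/0 50/4
```

(The same-sign Th effects are also visible in bulk, as expected; with
3% of CpGs carrying true signal the bulk and Th lambdas rise above 1
while the null cell types stay at ~0.93–1.0.)

The whole chain — simulation or TSV inputs, exclusions, imputation,
factor model, screening, scans, findings, optional gene enrichment,
plus a machine-readable JSON run report with every threshold and
seed — is driven by `run_pipeline(pipeline_config(...))`, with
content-hash caching of completed stages. A thin command-line
wrapper with `simulate`/`factors`/`screen`/`mwas`/`enrich`/`run`
subcommands ships at `inst/cli/ctmwas.R`.

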