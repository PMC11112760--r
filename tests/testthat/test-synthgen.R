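test_that("generator is seed-deterministic and validates its configuration", {
  cfg <- sim_config(n_samples = 40, n_cpgs = 30, seed = 9)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$phenotypes, d2$phenotypes)
  expect_identical(d1$meth$values, d2$meth$values)
  expect_identical(unclass(d1$proportions), unclass(d2$proportions))

  expect_error(sim_config(dirichlet_mean = c(0.5, 0.4)), "sum to 1")
  expect_error(sim_config(uniqueness = rep(-1, 9)), "positive")
  expect_error(sim_config(factor_loadings = matrix(0.1, 9, 3)), "2 columns")
  expect_error(sim_config(n_cpgs = 10,
                          effect_map = data.frame(cpg = 11, cell_type = "B",
                                                  beta = 1)),
               "1..n_cpgs", fixed = TRUE)
  expect_error(sim_config(n_cpgs = 10,
                          effect_map = data.frame(cpg = 1,
                                                  cell_type = "RBC",
                                                  beta = 1)),
               "unknown cell type")
})

test_that("phenotype correlations follow the factor model", {
  ## shared-factor structure: implied correlation is Lambda Lambda'
  cfg <- sim_config(n_samples = 5000, n_cpgs = 2, seed = 11,
                    binarize = FALSE)
  d <- simulate_phenotypes(cfg)
  r_wh <- cor(d$phenotypes$weight, d$phenotypes$height)
  expect_lt(abs(r_wh - 0.954 * 0.818), 0.05)

  L <- neonatal_loadings()
  implied <- L %*% t(L) + diag(1 - rowSums(L^2))
  emp <- cor(data.matrix(d$phenotypes[rownames(L)]))
  expect_lt(max(abs(emp - implied)), 3 / sqrt(5000))

  ## no shared factor: variables mutually uncorrelated
  L0 <- matrix(0, 9, 2, dimnames = list(rownames(L), NULL))
  cfg0 <- sim_config(n_samples = 5000, n_cpgs = 2, factor_loadings = L0,
                     uniqueness = rep(1, 9), binarize = FALSE, seed = 12)
  d0 <- simulate_phenotypes(cfg0)
  r0 <- cor(data.matrix(d0$phenotypes[rownames(L)]))
  expect_lt(max(abs(r0[upper.tri(r0)])), 0.05)

  ## binary prevalences near their liability cutpoints
  cfgb <- sim_config(n_samples = 5000, n_cpgs = 2, seed = 13)
  db <- simulate_phenotypes(cfgb)
  expect_lt(abs(mean(db$phenotypes$jaundice) - 0.051), 0.02)
  expect_lt(abs(mean(db$phenotypes$birth_diagnosis) - 0.298), 0.03)
})

test_that("cell proportions are Dirichlet with the configured mean", {
  cfg <- sim_config(n_samples = 5000, seed = 21)
  P <- simulate_cell_proportions(cfg)
  expect_true(all(P >= 0))
  expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  target <- c(B = 0.08, Gran = 0.39, Mono = 0.18, NK = 0.05,
              cT = 0.15, Th = 0.14)
  expect_lt(max(abs(colMeans(P) - target[colnames(P)])), 0.01)

  ## degenerate limit: huge concentration pins every row at the mean
  cfg_inf <- sim_config(n_samples = 50, dirichlet_concentration = 1e8,
                        seed = 22)
  P2 <- simulate_cell_proportions(cfg_inf)
  expect_lt(max(abs(sweep(unclass(P2), 2, blood_cell_means()))), 1e-3)

  P0 <- simulate_cell_proportions(cfg, n = 0)
  expect_equal(nrow(P0), 0)
  expect_equal(colnames(P0), names(blood_cell_means()))
})

test_that("methylation is the proportion-weighted mixture plus planted effects", {
  ## no effects, vanishing noise: Y equals the mixture of baselines
  cfg <- sim_config(n_samples = 30, n_cpgs = 50, noise_sd = 1e-9,
                    covariate_spec = list(sex_effect_sd = 0), seed = 31)
  ph <- simulate_phenotypes(cfg)
  P <- simulate_cell_proportions(cfg)
  me <- simulate_methylation(cfg, ph$phenotypes, P)
  expect_lt(max(abs(me$meth$values - unclass(P) %*% t(me$truth$mu))), 1e-6)
  expect_length(me$truth$null_cpg_set, 50)

  ## planted effect equals the interaction coefficient (OLS oracle)
  em <- data.frame(cpg = c(3, 7), cell_type = c("Mono", "Th"),
                   beta = c(8, -8))
  cfg2 <- sim_config(n_samples = 5000, n_cpgs = 10, effect_map = em,
                     effect_rv = "size_factor", seed = 32)
  d <- simulate_dataset(cfg2)
  rv <- d$truth$factor_scores[, "size_factor"]
  P2 <- unclass(d$proportions)
  for (i in 1:2) {
    XI <- P2 * rv
    colnames(XI) <- paste0("I_", colnames(P2))
    df <- data.frame(y = d$meth$values[, em$cpg[i]], P2, XI,
                     sex = d$phenotypes_complete$sex)
    fit <- lm(y ~ . - 1, data = df)
    est <- coef(fit)[paste0("I_", em$cell_type[i])]
    expect_lt(abs(est - em$beta[i]) / abs(em$beta[i]), 0.05)
  }
  expect_equal(sort(setdiff(c(3, 7), d$truth$null_cpg_set)), c(3, 7))
})

test_that("opposite-sign plants cancel in bulk but not per cell type", {
  pm <- blood_cell_means()
  delta <- 8
  em <- data.frame(cpg = c(1, 1), cell_type = c("Mono", "Gran"),
                   beta = c(delta, -delta * pm[["Mono"]] / pm[["Gran"]]))
  cfg <- sim_config(n_samples = 5000, n_cpgs = 5, effect_map = em,
                    effect_rv = "size_factor", seed = 41)
  d <- simulate_dataset(cfg)
  rv <- d$truth$factor_scores[, "size_factor"]
  ## marginal bulk slope ~ 0 by mixture-weighted cancellation
  bulk_fit <- lm(d$meth$values[, 1] ~ rv)
  expect_lt(abs(coef(bulk_fit)[["rv"]]), 0.15)
  ## cell-type-specific slopes are +/- nonzero (joint OLS oracle)
  P <- unclass(d$proportions)
  XI <- P * rv
  colnames(XI) <- paste0("I_", colnames(P))
  fit <- lm(d$meth$values[, 1] ~ . - 1, data = data.frame(P, XI))
  expect_gt(coef(fit)[["I_Mono"]], 2)
  expect_lt(coef(fit)[["I_Gran"]], -1)
})

test_that("MCAR missingness hits only eligible variables at the stated rate", {
  cfg <- sim_config(n_samples = 332, n_cpgs = 2, seed = 51)
  ph <- simulate_phenotypes(cfg)$phenotypes
  expect_identical(inject_missingness(ph, rate = 0), ph)
  expect_error(inject_missingness(ph, rate = 0.7), "0.5")

  out <- inject_missingness(ph, rate = 12 / 2988, seed = 5)
  mask <- attr(out, "missing_mask")
  expect_identical(colnames(mask),
                   c("gestational_age", "weight", "height", "head_size"))
  ## expected ~12 missing assessments; allow ~4 binomial SDs
  expect_gte(sum(mask), 2)
  expect_lte(sum(mask), 26)
  expect_lte(max(rowSums(mask)), 2)
  ## binary/diagnosis columns untouched
  expect_false(anyNA(out$jaundice))
  expect_false(anyNA(out$apgar))
  ## reproducible mask
  out2 <- inject_missingness(ph, rate = 12 / 2988, seed = 5)
  expect_identical(out, out2)
})
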