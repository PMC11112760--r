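test_that("methylation PCs are orthonormal, sign-fixed and flag degeneracy", {
  d <- small_sim(n = 60, p = 150, seed = 81)
  U <- methylation_pcs(d$meth, k = 3)
  G <- crossprod(U)
  expect_lt(max(abs(G - diag(3))), 1e-10)
  expect_false(any(attr(U, "degenerate")))

  ## rank-1 matrix: PC1 carries all variance, PC2 degenerate
  v <- rnorm(30); w <- rnorm(40)
  M1 <- outer(v, w) + 5
  U1 <- methylation_pcs(M1, k = 2, scale. = FALSE)
  expect_gt(attr(U1, "var_explained")[1], 1 - 1e-10)
  expect_true(attr(U1, "degenerate")[2])
  expect_error(methylation_pcs(M1[1:3, ], k = 2), "at least")
})

test_that("a planted batch confounder is captured by the leading PC", {
  cfg <- sim_config(n_samples = 150, n_cpgs = 1000,
                    covariate_spec = list(batch_effect_sd = 1), seed = 82)
  d <- simulate_dataset(cfg)
  U <- methylation_pcs(d$meth, k = 2)
  batch_num <- as.numeric(d$phenotypes_complete$batch)
  expect_gt(abs(cor(U[, 1], batch_num)), 0.8)
})

test_that("bulk and cell-type fits match per-CpG lm oracles to 1e-10", {
  set.seed(83)
  for (rep in 1:10) {
    n <- 40 + sample(0:20, 1)
    M <- matrix(rnorm(n * 3, 5), n, 3)
    rv <- rnorm(n)
    covs <- cbind(c1 = rnorm(n), c2 = rbinom(n, 1, 0.4))
    a <- matrix(rgamma(n * 6, shape = rep(blood_cell_means() * 50,
                                          each = n)), n, 6)
    P <- cell_proportions(a / rowSums(a))

    bk <- bulk_mwas(M, rv, covs, P)
    ct <- celltype_mwas(M, rv, P, covs)
    rb <- celltype_mwas(M, rv, P, covs, robust = TRUE)
    XI <- unclass(P) * rv
    colnames(XI) <- paste0("I_", colnames(P))
    for (j in 1:3) {
      f1 <- lm(M[, j] ~ rv + covs + unclass(P)[, -2])
      s1 <- coef(summary(f1))["rv", ]
      expect_lt(abs(s1[["Estimate"]] - bk$table$estimate[j]), 1e-10)
      expect_lt(abs(s1[["Std. Error"]] - bk$table$se[j]), 1e-10)
      expect_lt(abs(s1[["Pr(>|t|)"]] - bk$table$p[j]), 1e-10)

      df2 <- data.frame(y = M[, j], unclass(P), XI, covs)
      f2 <- lm(y ~ . - 1, data = df2)
      s2 <- coef(summary(f2))
      vc <- sandwich::vcovHC(f2, type = "HC3")
      for (cty in colnames(P)) {
        key <- paste0("I_", cty)
        expect_lt(abs(s2[key, "Estimate"] - ct[[cty]]$table$estimate[j]),
                  1e-10)
        expect_lt(abs(s2[key, "Std. Error"] - ct[[cty]]$table$se[j]),
                  1e-10)
        expect_lt(abs(sqrt(vc[key, key]) - rb[[cty]]$table$se[j]), 1e-9)
      }
    }
  }
})

test_that("noiseless outcomes are fit exactly and constants are skipped", {
  set.seed(84)
  n <- 50
  rv <- rnorm(n)
  sex <- rbinom(n, 1, 0.5)
  M <- cbind(2 * rv + 0.5 * sex + 3,       # exact linear CpG
             rnorm(n),
             rep(4, n))                    # constant CpG
  bk <- bulk_mwas(M, rv, covariates = cbind(sex = sex))
  expect_lt(abs(bk$table$estimate[1] - 2), 1e-8)
  expect_lt(bk$table$p[1], 1e-20)
  expect_true(is.na(bk$table$p[3]))
  expect_true(is.na(bk$table$q[3]))
  expect_equal(bk$n_skipped, 1)
})

test_that("cell-type model collapses to bulk when one proportion is 1", {
  set.seed(85)
  n <- 60
  M <- matrix(rnorm(2 * n, 5), n, 2)
  rv <- rnorm(n)
  P1 <- cell_proportions(cbind(B = rep(1, n), Gran = 0, Mono = 0,
                               NK = 0, cT = 0, Th = 0))
  expect_warning(ct <- celltype_mwas(M, rv, P1), "unidentifiable")
  expect_null(ct$Gran)
  expect_identical(attr(ct, "dropped_cell_types")[1], "Gran")
  ## remaining single-cell fit == plain bulk OLS of methylation on rv
  fit <- lm(M[, 1] ~ rv)
  expect_lt(abs(ct$B$table$estimate[1] - coef(fit)[["rv"]]), 1e-10)
})

test_that("a global intercept in the cell-type design is refused", {
  d <- small_sim(n = 50, p = 5, seed = 86)
  rv <- d$truth$factor_scores[, 1]
  expect_error(
    celltype_mwas(d$meth, rv, d$proportions,
                  covariates = cbind(intercept = rep(1, 50))),
    "intercept")
})

test_that("genomic lambda matches its definition and monotonicity", {
  expect_equal(genomic_lambda(rep(0.5, 200)), 1.0, tolerance = 1e-12)
  set.seed(87)
  u <- runif(1e5)
  expect_lt(abs(genomic_lambda(u) - 1), 0.01)
  expect_gt(genomic_lambda(u / 2), 1)
  expect_error(genomic_lambda(runif(50)), "100")
})

test_that("BH q-values match the step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  p_na <- c(0.01, NA, 0.5)
  q_na <- bh_fdr(p_na)
  expect_true(is.na(q_na[2]))
  expect_equal(q_na[c(1, 3)], bh_fdr(c(0.01, 0.5)))  # NA not counted in m
  expect_error(bh_fdr(c(0.5, 0)), "(0, 1]", fixed = TRUE)

  set.seed(88)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_lt(max(abs(bh_fdr(p) - bh_oracle(p))), 1e-12)
    expect_lt(max(abs(bh_fdr(p) - p.adjust(p, "BH"))), 1e-12)
  }
})

test_that("finding counts classify thresholds monotonically", {
  d <- small_sim(n = 80, p = 120, seed = 89)
  rv <- d$truth$factor_scores[, 1]
  res <- list(bulk = bulk_mwas(d$meth, rv, sexbatch(d$phenotypes_complete),
                               d$proportions, unit = "u1"),
              celltype_mwas(d$meth, rv, d$proportions,
                            sexbatch(d$phenotypes_complete), unit = "u1"))
  counts <- classify_findings(res)
  expect_equal(nrow(counts), 7)   # bulk + six cell types
  tight <- classify_findings(res, q_threshold = 0.01,
                             suggestive_p = 1e-8)
  expect_true(all(tight$n_significant <= counts$n_significant))
  expect_true(all(tight$n_suggestive <= counts$n_suggestive))
  layout <- findings_layout(counts)
  expect_identical(names(layout), c("unit", "bulk", "B", "Gran", "Mono",
                                    "NK", "cT", "Th"))
  ## all p = 1 -> all zero
  fake <- res$bulk
  fake$table$p[] <- 1
  fake$table$q[] <- 1
  expect_true(all(classify_findings(list(fake))[3:4] == 0))
})

test_that("robust errors agree with classical ones under homoskedasticity", {
  d <- small_sim(n = 200, p = 4000, seed = 90)
  rv <- d$truth$factor_scores[, 1]
  covs <- sexbatch(d$phenotypes_complete)
  cls <- bulk_mwas(d$meth, rv, covs, d$proportions)
  rob <- bulk_mwas(d$meth, rv, covs, d$proportions, robust = TRUE)
  lq_c <- sort(-log10(cls$table$p))
  lq_r <- sort(-log10(rob$table$p))
  slope <- coef(lm(lq_r ~ 0 + lq_c))[[1]]
  expect_gt(slope, 0.95)
  expect_lt(slope, 1.05)
})

test_that("robust MWAS guards rare binary outcomes and permutation nulls", {
  d <- small_sim(n = 80, p = 30, seed = 91)
  y_rare <- c(rep(1, 4), rep(0, 76))
  expect_error(robust_mwas(d$meth, y_rare, d$proportions), "10")

  y <- rbinom(80, 1, 0.4)
  res <- robust_mwas(d$meth, y, d$proportions,
                     covariates = sexbatch(d$phenotypes_complete),
                     mode = "bulk", n_perm = 200, seed = 7)
  expect_true("p_perm" %in% names(res$table))
  ## the least-associated CpG has permutation p near 1
  j <- which.min(abs(res$table$t))
  expect_gt(res$table$p_perm[j], 0.5)
})
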