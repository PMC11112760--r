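test_that("gestational-age exclusion rules drop, blank and log correctly", {
  ph <- data.frame(sample_id = c("a", "b", "c", "d"),
                   gestational_age = c(270, 310, 210, 280))
  out <- apply_exclusions(ph)
  log <- attr(out, "exclusion_log")
  expect_equal(nrow(out), 3)                  # c dropped (< 32 weeks)
  expect_true(is.na(out$gestational_age[out$sample_id == "b"]))
  expect_setequal(log$action, c("set_missing", "excluded"))
  expect_equal(log$sample_id[log$action == "excluded"], "c")

  ph_ok <- data.frame(sample_id = 1:3, gestational_age = c(250, 260, 270))
  out_ok <- apply_exclusions(ph_ok)
  expect_equal(out_ok$gestational_age, ph_ok$gestational_age)
  expect_equal(nrow(attr(out_ok, "exclusion_log")), 0)
})

test_that("chained imputation recovers collinear structure and stays in range", {
  set.seed(1)
  n <- 200
  height <- rnorm(n, 50, 2.4)
  ph <- data.frame(sample_id = seq_len(n),
                   gestational_age = rnorm(n, 278, 12),
                   weight = 2 * height,          # exact collinearity
                   height = height,
                   head_size = rnorm(n, 34.5, 1.7),
                   sex = rbinom(n, 1, 0.5))
  ph_m <- ph
  ph_m$weight[5] <- NA
  ## exact collinearity makes lm warn about a perfect fit; expected
  imp <- suppressWarnings(impute_missing(ph_m, seed = 3))
  expect_false(anyNA(imp$weight))
  expect_lt(abs(imp$weight[5] - 2 * height[5]), 0.5)

  ## untouched when nothing is missing
  expect_equal(impute_missing(ph, seed = 1)$weight, ph$weight)

  ## gestational age clipped to the plausible range
  ph_g <- ph
  ph_g$gestational_age[2] <- NA
  imp_g <- impute_missing(ph_g, seed = 4)
  expect_true(imp_g$gestational_age[2] >= 154 &&
              imp_g$gestational_age[2] <= 301)

  ph_bad <- ph
  ph_bad$head_size <- NA
  expect_error(impute_missing(ph_bad), "entirely missing")
})

test_that("imputation error is below the marginal SD on generator data", {
  cfg <- sim_config(n_samples = 332, n_cpgs = 2, missing_rate = 0.004,
                    seed = 61)
  d <- simulate_dataset(cfg)
  imp <- impute_missing(d$phenotypes, seed = 61)
  mask <- attr(d$phenotypes, "missing_mask")
  errs <- sds <- c()
  for (v in colnames(mask)) {
    if (!any(mask[, v])) next
    errs <- c(errs, imp[[v]][mask[, v]] -
                d$phenotypes_complete[[v]][mask[, v]])
    sds <- c(sds, rep(sd(d$phenotypes_complete[[v]]), sum(mask[, v])))
  }
  expect_gt(length(errs), 0)
  expect_lt(sqrt(mean((errs / sds)^2)), 1)   # RMSE below marginal SD
})

test_that("latent-scale correlations undo binary attenuation", {
  set.seed(2)
  n <- 4000
  z <- MASS::mvrnorm(n, c(0, 0), matrix(c(1, 0.5, 0.5, 1), 2))
  x <- as.integer(z[, 1] > qnorm(0.9))
  y <- as.integer(z[, 2] > qnorm(0.7))
  expect_lt(abs(ctmwas:::.tetrachoric(x, y) - 0.5), 0.08)
  ## biserial recovers the latent correlation from a thresholded pair
  yb <- as.integer(z[, 2] > qnorm(0.75))
  expect_lt(abs(ctmwas:::.biserial(z[, 1], yb) - 0.5), 0.06)
  ## Pearson on the same pair is attenuated well below 0.5
  expect_lt(cor(z[, 1], yb), 0.45)
})

test_that("factor model recovers the generating loadings and assignments", {
  L <- neonatal_loadings()
  ## continuous (liability-scale) indicators: recovery within 0.1
  cfg_c <- sim_config(n_samples = 5000, n_cpgs = 2, binarize = FALSE,
                      seed = 72)
  ph_c <- simulate_phenotypes(cfg_c)
  fm_c <- fit_factor_model(ph_c$phenotypes, cor_method = "pearson")
  expect_lt(max(abs(align_loadings(fm_c$loadings, L) - L)), 0.1)

  ## the > 0.3 assignment reproduces the expected pattern
  expect_length(fm_c$assignment$gestational_age, 2)  # both factors
  expect_length(fm_c$assignment$apgar, 0)            # neither
  expect_length(fm_c$assignment$weight, 1)           # size factor only
  ## weight's factor is the size factor: height loads high on it too
  expect_identical(fm_c$assignment$weight, fm_c$assignment$height)

  ## thresholded diagnoses (generator default): the latent-correlation
  ## fit corrects the Pearson attenuation of the binary loadings
  cfg <- sim_config(n_samples = 5000, n_cpgs = 2, seed = 71)
  ph <- simulate_phenotypes(cfg)
  fm_l <- fit_factor_model(ph$phenotypes, cor_method = "latent")
  fm_p <- fit_factor_model(ph$phenotypes, cor_method = "pearson")
  err_l <- max(abs(align_loadings(fm_l$loadings, L) - L))
  err_p <- max(abs(align_loadings(fm_p$loadings, L) - L))
  expect_lt(err_l, err_p)    # attenuation corrected
  expect_lt(err_l, 0.25)     # bounded despite tetrachoric noise
  expect_gt(err_p, 0.25)     # Pearson attenuation of jaundice (0.645)
})

test_that("independent variables imply no shared structure", {
  L0 <- matrix(0, 9, 2, dimnames = list(rownames(neonatal_loadings()), NULL))
  cfg <- sim_config(n_samples = 5000, n_cpgs = 2, factor_loadings = L0,
                    uniqueness = rep(1, 9), binarize = FALSE, seed = 73)
  ph <- simulate_phenotypes(cfg)
  fm <- suppressWarnings(fit_factor_model(ph$phenotypes))
  ## ML factoring of a near-identity correlation matrix is weakly
  ## identified and may inflate a single variable's loading (Heywood
  ## direction), but the implied SHARED effects must stay nil: every
  ## model-implied cross-correlation is tiny
  implied <- fm$loadings %*% t(fm$loadings)
  expect_lt(max(abs(implied[upper.tri(implied)])), 0.06)
})

test_that("rotation preserves communalities and scores track the truth", {
  cfg <- sim_config(n_samples = 5000, n_cpgs = 2, binarize = FALSE,
                    seed = 74)
  ph <- simulate_phenotypes(cfg)
  fm_v <- fit_factor_model(ph$phenotypes, rotation = "varimax")
  fm_n <- fit_factor_model(ph$phenotypes, rotation = "none")
  expect_lt(max(abs(rowSums(fm_v$loadings^2) - rowSums(fm_n$loadings^2))),
            1e-8)

  ## regression scores: match the closed-form validity and the truth
  L <- neonatal_loadings()
  R <- L %*% t(L) + diag(1 - rowSums(L^2))
  validity <- sqrt(diag(t(L) %*% solve(R) %*% L))
  Lal_idx <- apply(abs(cor(fm_v$loadings, L)), 2, which.max)
  obs <- abs(diag(cor(fm_v$scores[, Lal_idx], ph$truth$factor_scores)))
  expect_gt(obs[1], 0.9)                      # well-determined size factor
  expect_lt(max(abs(obs - validity)), 0.05)   # both match theory
})

test_that("degenerate correlation structures are reported, not silent", {
  set.seed(5)
  n <- 200
  base <- replicate(9, rnorm(n))
  colnames(base) <- rownames(neonatal_loadings())
  ph <- data.frame(sample_id = 1:n, base)
  ph$weight <- ph$height          # exact duplicate -> singular matrix
  expect_error(fit_factor_model(ph), "singular")
  expect_error(fit_factor_model(ph[1:30, ]), "50 samples")
  ph_na <- data.frame(sample_id = 1:n, base)
  ph_na$weight[1] <- NA
  expect_error(fit_factor_model(ph_na), "missing")
})

test_that("the analysis plan derives covariate factors from loadings alone", {
  cfg <- sim_config(n_samples = 2000, n_cpgs = 2, seed = 75)
  ph <- simulate_phenotypes(cfg)
  fm <- fit_factor_model(ph$phenotypes, cor_method = "latent")
  plan <- derive_analysis_plan(fm)
  expect_length(plan, 11)                     # 9 variables + 2 factors
  expect_length(plan$gestational_age$factor_covariates, 2)
  expect_length(plan$apgar$factor_covariates, 0)
  ## a factor is never its own covariate
  expect_length(plan$factor1$factor_covariates, 0)
  expect_length(plan$factor2$factor_covariates, 0)
  ## assignment is a pure function of loadings and threshold
  redo <- lapply(rownames(fm$loadings), function(v)
    colnames(fm$loadings)[abs(fm$loadings[v, ]) > fm$loading_threshold])
  expect_identical(unname(fm$assignment[rownames(fm$loadings)]), redo)
})
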