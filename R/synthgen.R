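## Synthetic-data generator: phenotypes from a two-factor model,
## Dirichlet cell proportions, bulk methylation as proportion-weighted
## mixtures of latent cell-type profiles with planted per-cell-type
## phenotype effects, and MCAR phenotype missingness.

## One shared seed, split per operation by fixed offsets so each
## generator stage is independently reproducible.
.SUBSTREAMS <- c(phenotypes = 101L, proportions = 211L,
                 methylation = 307L, missingness = 401L)

.substream <- function(seed, op) {
  set.seed(as.integer(seed) + .SUBSTREAMS[[op]])
}

#' Simulation configuration
#'
#' Bundles and validates every parameter of the synthetic-data
#' generator. Defaults reproduce the study conditions the pipeline is
#' designed for: 332 neonates, nine risk variables generated from the
#' two-factor loading structure in [neonatal_loadings()], six blood
#' cell types with Dirichlet-distributed proportions centered at
#' [blood_cell_means()], and 0.4% MCAR missingness among the four
#' continuous size/gestation variables.
#'
#' @param n_samples number of samples.
#' @param n_cpgs number of CpG sites.
#' @param factor_loadings numeric matrix (variables x 2) of factor
#'   loadings; rownames name the risk variables.
#' @param uniqueness per-variable residual variances; default
#'   `1 - rowSums(factor_loadings^2)` (unit-variance latents).
#' @param dirichlet_mean mean cell-type proportions (must sum to 1
#'   within 1e-12).
#' @param dirichlet_concentration Dirichlet precision; larger values
#'   concentrate proportions around the mean. Default 60 reproduces
#'   the granulocyte SD scale seen in neonatal blood.
#' @param effect_rv name of the variable whose planted methylation
#'   effects are generated (a phenotype column or a latent factor
#'   score column).
#' @param effect_map data.frame with columns `cpg` (1-based CpG
#'   index), `cell_type`, `beta`: per-cell-type effects to plant.
#'   `NULL` means a fully null methylome.
#' @param covariate_spec list with `male_prevalence`, `batch_levels`,
#'   `sex_effect_sd`, `batch_effect_sd`.
#' @param noise_sd residual SD of bulk methylation.
#' @param missing_rate MCAR missingness as a fraction of all
#'   assessments (9 per sample); applied to the four eligible
#'   continuous variables.
#' @param binarize threshold the diagnosis variables (jaundice,
#'   preeclampsia, birth diagnosis) at their liability cutpoints;
#'   `FALSE` keeps them continuous.
#' @param seed integer master seed; each generator operation uses a
#'   fixed offset substream of it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 332L,
                       n_cpgs = 10000L,
                       factor_loadings = neonatal_loadings(),
                       uniqueness = NULL,
                       dirichlet_mean = blood_cell_means(),
                       dirichlet_concentration = 60,
                       effect_rv = "size_factor",
                       effect_map = NULL,
                       covariate_spec = list(male_prevalence = 0.575,
                                             batch_levels = 2L,
                                             sex_effect_sd = 0.1,
                                             batch_effect_sd = 0),
                       noise_sd = 1,
                       missing_rate = 0.004,
                       binarize = TRUE,
                       seed = 1L) {
  factor_loadings <- as.matrix(factor_loadings)
  if (ncol(factor_loadings) != 2L)
    stop("factor_loadings must have exactly 2 columns")
  if (is.null(rownames(factor_loadings)))
    rownames(factor_loadings) <- paste0("rv", seq_len(nrow(factor_loadings)))
  if (is.null(colnames(factor_loadings)))
    colnames(factor_loadings) <- c("factor1", "factor2")
  if (is.null(uniqueness))
    uniqueness <- 1 - rowSums(factor_loadings^2)
  if (length(uniqueness) != nrow(factor_loadings))
    stop("uniqueness must have one entry per risk variable")
  if (any(uniqueness <= 0))
    stop("all uniqueness (residual) variances must be positive")
  if (abs(sum(dirichlet_mean) - 1) > 1e-12)
    stop("dirichlet_mean must sum to 1 (within 1e-12)")
  if (any(dirichlet_mean <= 0))
    stop("dirichlet_mean entries must be positive")
  if (dirichlet_concentration <= 0)
    stop("dirichlet_concentration must be positive")
  if (noise_sd <= 0)
    stop("noise_sd must be positive")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (is.null(names(dirichlet_mean)))
    names(dirichlet_mean) <- .CELL_TYPES[seq_along(dirichlet_mean)]
  if (!is.null(effect_map)) {
    effect_map <- as.data.frame(effect_map)
    if (!all(c("cpg", "cell_type", "beta") %in% names(effect_map)))
      stop("effect_map needs columns cpg, cell_type, beta")
    if (any(effect_map$cpg < 1 | effect_map$cpg > n_cpgs))
      stop("effect_map cpg indices must lie in 1..n_cpgs")
    bad <- setdiff(effect_map$cell_type, names(dirichlet_mean))
    if (length(bad))
      stop("effect_map references unknown cell type(s): ",
           paste(bad, collapse = ", "))
  }
  spec <- modifyList(list(male_prevalence = 0.575, batch_levels = 2L,
                          sex_effect_sd = 0.1, batch_effect_sd = 0),
                     covariate_spec)
  structure(list(n_samples = as.integer(n_samples),
                 n_cpgs = as.integer(n_cpgs),
                 factor_loadings = factor_loadings,
                 uniqueness = uniqueness,
                 dirichlet_mean = dirichlet_mean,
                 dirichlet_concentration = dirichlet_concentration,
                 effect_rv = effect_rv,
                 effect_map = effect_map,
                 covariate_spec = spec,
                 noise_sd = noise_sd,
                 missing_rate = missing_rate,
                 binarize = isTRUE(binarize),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate phenotypes from the two-factor model
#'
#' Draws independent standard-normal factor scores F and unique errors
#' e, forms each latent risk variable as `Lambda_v . F + e_v`,
#' standardizes, and maps onto observed scales: continuous variables
#' get the means/SDs of [neonatal_scales()] (where named there);
#' diagnosis variables are liability-thresholded at their stated
#' prevalences. Sex and a technical batch label are drawn as
#' covariates.
#'
#' @param config a [sim_config()].
#' @return list with `phenotypes` (data.frame: sample_id, risk
#'   variables, sex (1 = male), batch) and `truth` (list with
#'   `factor_scores`, an n x 2 matrix).
#' @export
simulate_phenotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  L <- config$factor_loadings
  psi <- config$uniqueness
  .substream(config$seed, "phenotypes")
  FS <- matrix(rnorm(n * 2L), n, 2L,
               dimnames = list(NULL, colnames(L)))
  E <- sweep(matrix(rnorm(n * nrow(L)), n, nrow(L)), 2L, sqrt(psi), "*")
  Z <- FS %*% t(L) + E
  Z <- sweep(Z, 2L, sqrt(rowSums(L^2) + psi), "/")  # exact unit variance
  colnames(Z) <- rownames(L)

  sc <- neonatal_scales()
  pheno <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                      stringsAsFactors = FALSE)
  for (v in colnames(Z)) {
    if (config$binarize && v %in% names(sc$prevalence)) {
      pheno[[v]] <- as.integer(Z[, v] > qnorm(1 - sc$prevalence[[v]]))
    } else if (v %in% names(sc$mean)) {
      pheno[[v]] <- sc$mean[[v]] + sc$sd[[v]] * Z[, v]
    } else {
      pheno[[v]] <- Z[, v]
    }
  }
  cs <- config$covariate_spec
  pheno$sex <- rbinom(n, 1L, cs$male_prevalence)
  pheno$batch <- factor(sample(seq_len(cs$batch_levels), n, replace = TRUE),
                        levels = seq_len(cs$batch_levels),
                        labels = paste0("batch", seq_len(cs$batch_levels)))
  list(phenotypes = pheno, truth = list(factor_scores = FS))
}

#' Simulate Dirichlet cell-type proportions
#'
#' Rows are independent Dirichlet draws with mean
#' `config$dirichlet_mean` and precision
#' `config$dirichlet_concentration` (gamma-ratio construction), so
#' every row is nonnegative and sums to one exactly.
#'
#' @param config a [sim_config()].
#' @param n number of samples (default `config$n_samples`).
#' @return A [cell_proportions()] matrix (n x number of cell types).
#' @export
simulate_cell_proportions <- function(config, n = config$n_samples) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$dirichlet_mean
  k <- length(m)
  if (n == 0L)
    return(cell_proportions(matrix(numeric(0), 0L, k,
                                   dimnames = list(NULL, names(m)))))
  .substream(config$seed, "proportions")
  alpha <- m * config$dirichlet_concentration
  G <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  P <- G / rowSums(G)
  colnames(P) <- names(m)
  rownames(P) <- sprintf("S%04d", seq_len(n))
  cell_proportions(P, tol = 1e-12)
}

## Synthetic CpG coordinates: contiguous blocks over chr1..chr22,
## 500 bp apart, already sorted by (chrom, position).
.make_cpg_coords <- function(n_cpgs, n_chrom = 22L, spacing = 500L) {
  n_chrom <- min(n_chrom, max(1L, n_cpgs))
  per <- ceiling(n_cpgs / n_chrom)
  chrom_idx <- rep(seq_len(n_chrom), each = per)[seq_len(n_cpgs)]
  within <- sequence(tabulate(chrom_idx))
  start <- 10000L + (within - 1L) * spacing
  data.frame(chrom = paste0("chr", sprintf("%02d", chrom_idx)),
             start = start, end = start + 2L,
             cpg = sprintf("cpg%06d", seq_len(n_cpgs)),
             stringsAsFactors = FALSE)
}

#' Simulate bulk methylation as a cell-type mixture
#'
#' Per-CpG, per-cell-type baseline abundances `mu_c ~ N(5, 1)` are
#' mixed by the sample's proportions, planted effects add
#' `beta * rv * P_c` at the configured CpG/cell-type pairs, additive
#' sex and batch effects are drawn per CpG, and homoskedastic Gaussian
#' noise is added. At a planted CpG the population coefficient of the
#' `rv x P_c` interaction column equals the planted `beta` exactly.
#'
#' @param config a [sim_config()].
#' @param phenotypes phenotype data.frame from [simulate_phenotypes()].
#' @param proportions cell-proportion matrix, row-aligned with
#'   `phenotypes`.
#' @param rv numeric vector driving the planted effects; defaults to
#'   the column of `phenotypes` named by `config$effect_rv`. Pass
#'   latent factor scores explicitly when planting on a factor. Used
#'   as given (no internal rescaling), so planted betas are per unit
#'   of `rv`.
#' @return list with `meth` (a [methylation_matrix()]) and `truth`
#'   (list: `effect_map`, `null_cpg_set`, `mu`).
#' @export
simulate_methylation <- function(config, phenotypes, proportions, rv = NULL) {
  stopifnot(inherits(config, "sim_config"))
  P <- unclass(proportions)
  n <- nrow(P)
  if (nrow(phenotypes) != n)
    stop("phenotype and proportion row counts do not match")
  em <- config$effect_map
  if (is.null(rv)) {
    if (!is.null(em) && nrow(em) > 0) {
      if (!config$effect_rv %in% names(phenotypes))
        stop(sprintf(paste0("effect_rv '%s' is not a phenotype column; ",
                            "pass rv explicitly (e.g. a factor score)"),
                     config$effect_rv))
      rv <- phenotypes[[config$effect_rv]]
    } else rv <- numeric(n)
  }
  stopifnot(length(rv) == n)
  p <- config$n_cpgs
  cs <- config$covariate_spec
  .substream(config$seed, "methylation")
  mu <- matrix(rnorm(p * ncol(P), mean = 5, sd = 1), p, ncol(P),
               dimnames = list(NULL, colnames(P)))
  Y <- P %*% t(mu)
  if (!is.null(em) && nrow(em) > 0) {
    for (i in seq_len(nrow(em))) {
      ct <- as.character(em$cell_type[i])
      j <- em$cpg[i]
      Y[, j] <- Y[, j] + em$beta[i] * rv * P[, ct]
    }
  }
  if (cs$sex_effect_sd > 0 && "sex" %in% names(phenotypes)) {
    d <- rnorm(p, 0, cs$sex_effect_sd)
    Y <- Y + outer(as.numeric(phenotypes$sex), d)
  }
  if (cs$batch_effect_sd > 0 && "batch" %in% names(phenotypes)) {
    b <- phenotypes$batch
    for (lev in levels(factor(b))[-1L]) {
      d <- rnorm(p, 0, cs$batch_effect_sd)
      Y <- Y + outer(as.numeric(b == lev), d)
    }
  }
  Y <- Y + matrix(rnorm(n * p, 0, config$noise_sd), n, p)
  coords <- .make_cpg_coords(p)
  meth <- methylation_matrix(Y, coords,
                             sample_ids = as.character(phenotypes$sample_id))
  planted <- if (is.null(em)) integer(0) else unique(em$cpg)
  list(meth = meth,
       truth = list(effect_map = em,
                    null_cpg_set = setdiff(seq_len(p), planted),
                    mu = mu))
}

#' Inject MCAR missingness into the continuous phenotype block
#'
#' Missing-completely-at-random mask over the four eligible variables
#' (gestational age, weight, height, head size). `rate` is quoted as a
#' fraction of all nine assessments per sample, so the per-eligible-cell
#' probability is `rate * 9 / 4`. No sample is left with more than two
#' missing values (excess masked cells are unmasked at random).
#'
#' @param phenotypes phenotype data.frame.
#' @param rate missingness fraction in `[0, 0.5)`.
#' @param seed integer seed for the mask.
#' @param max_per_sample cap on missing cells per sample.
#' @return The phenotype table with `NA`s injected; attribute
#'   `missing_mask` records the mask.
#' @export
inject_missingness <- function(phenotypes, rate = 0.004, seed = 1L,
                               max_per_sample = 2L) {
  if (rate < 0 || rate >= 0.5)
    stop("rate must lie in [0, 0.5)")
  if (rate == 0) return(phenotypes)
  eligible <- intersect(.RV_IMPUTABLE, names(phenotypes))
  if (!length(eligible)) return(phenotypes)
  n <- nrow(phenotypes)
  set.seed(as.integer(seed) + .SUBSTREAMS[["missingness"]])
  p_cell <- rate * length(.RV_NAMES) / length(eligible)
  mask <- matrix(runif(n * length(eligible)) < p_cell, n,
                 dimnames = list(NULL, eligible))
  over <- which(rowSums(mask) > max_per_sample)
  for (i in over) {
    on <- which(mask[i, ])
    keep <- sample(on, max_per_sample)
    mask[i, setdiff(on, keep)] <- FALSE
  }
  for (v in eligible) phenotypes[[v]][mask[, v]] <- NA
  attr(phenotypes, "missing_mask") <- mask
  phenotypes
}

#' Generate a complete synthetic dataset
#'
#' Runs the full generator: phenotypes, cell proportions, methylation
#' (planting on a phenotype column or a latent factor score, resolved
#' from `config$effect_rv`), and MCAR phenotype missingness.
#'
#' @param config a [sim_config()].
#' @return list: `meth`, `phenotypes` (with missingness),
#'   `phenotypes_complete` (pre-missingness), `proportions`, `truth`.
#' @export
simulate_dataset <- function(config) {
  ph <- simulate_phenotypes(config)
  P <- simulate_cell_proportions(config)
  rv <- NULL
  if (config$effect_rv %in% colnames(ph$truth$factor_scores))
    rv <- ph$truth$factor_scores[, config$effect_rv]
  me <- simulate_methylation(config, ph$phenotypes, P, rv = rv)
  pheno_missing <- inject_missingness(ph$phenotypes, config$missing_rate,
                                      seed = config$seed)
  list(meth = me$meth,
       phenotypes = pheno_missing,
       phenotypes_complete = ph$phenotypes,
       proportions = P,
       truth = c(ph$truth, me$truth))
}
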