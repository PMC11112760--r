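## Pipeline driver: configuration, stage chaining with content-hash
## caching, and a machine-readable run report.

#' Pipeline configuration
#'
#' Exactly one of `inputs` (paths to methylation TSV + BED sidecar,
#' phenotype TSV, proportion TSV, optional annotation and GMT) or
#' `simulation` (arguments for [sim_config()]) must be given.
#'
#' @param inputs named list: `methylation`, `bed`, `phenotypes`,
#'   `proportions`, optionally `annotation`, `gmt`.
#' @param simulation named list of [sim_config()] arguments.
#' @param gate_p MRS screening gate (nominal significance).
#' @param fdr methylome-wide significance FDR level.
#' @param suggestive_p suggestive significance threshold.
#' @param loading_threshold |loading| threshold for factor
#'   assignment.
#' @param flank CpG-to-gene linking window (bp).
#' @param n_pcs methylation PCs used as covariates.
#' @param n_folds,top_n_grid MRS cross-validation settings.
#' @param seed master seed for every stochastic step.
#' @param outdir output directory (created if absent).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs = NULL, simulation = NULL,
                            gate_p = 0.05, fdr = 0.1,
                            suggestive_p = 1e-6,
                            loading_threshold = 0.3,
                            flank = 10000L, n_pcs = 2L,
                            n_folds = 10L,
                            top_n_grid = c(50L, 500L, 5000L, 50000L),
                            seed = 1L, outdir = tempfile("ctmwas_run")) {
  if (is.null(inputs) == is.null(simulation))
    stop("exactly one of 'inputs' or 'simulation' must be given")
  for (th in c(gate_p, fdr, suggestive_p, loading_threshold))
    if (th <= 0 || th >= 1)
      stop("thresholds must lie strictly inside (0, 1)")
  if (!is.null(inputs)) {
    req <- c("methylation", "bed", "phenotypes", "proportions")
    if (!all(req %in% names(inputs)))
      stop("inputs must name: ", paste(req, collapse = ", "))
  }
  structure(list(inputs = inputs, simulation = simulation,
                 gate_p = gate_p, fdr = fdr,
                 suggestive_p = suggestive_p,
                 loading_threshold = loading_threshold,
                 flank = as.integer(flank), n_pcs = as.integer(n_pcs),
                 n_folds = as.integer(n_folds),
                 top_n_grid = as.integer(top_n_grid),
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with fields matching [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

## Content-hash stage cache: recompute only when the input hash
## changes; cached values live under <outdir>/cache as runtime RDS.
.stage_cached <- function(cache_dir, name, input_hash, compute) {
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  hfile <- file.path(cache_dir, paste0(name, ".hash"))
  rfile <- file.path(cache_dir, paste0(name, ".rds"))
  if (file.exists(hfile) && file.exists(rfile) &&
      identical(readLines(hfile, warn = FALSE), input_hash)) {
    val <- readRDS(rfile)
    attr(val, "cache_hit") <- TRUE
    return(val)
  }
  val <- compute()
  saveRDS(val, rfile, version = 2)
  writeLines(input_hash, hfile)
  attr(val, "cache_hit") <- FALSE
  val
}

#' Run the full two-phase pipeline
#'
#' Loads or simulates the inputs, then executes Phase 1 (exclusions,
#' imputation, factor model, analysis plan), Phase 2A (MRS screening;
#' only gate-passing units continue), Phase 2B (bulk and cell-type
#' MWAS per passing unit, robust HC3 errors for binary outcomes,
#' lambda diagnostics, FDR, findings counts) and Phase 2C (gene
#' linking and enrichment, when an annotation and gene sets are
#' configured). Every threshold, seed and count is recorded in a
#' machine-readable report written to `<outdir>/run_report.json`; the
#' run is fully deterministic given the seed. Stages are cached on a
#' content hash of their inputs and are not recomputed when unchanged.
#'
#' @param config a [pipeline_config()].
#' @return The report (list), invisibly also written as JSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  cache <- file.path(config$outdir, "cache")
  chash <- .hash_obj(config[setdiff(names(config), "outdir")])
  report <- list(config_hash = chash, seed = config$seed,
                 thresholds = config[c("gate_p", "fdr", "suggestive_p",
                                       "loading_threshold")],
                 stages = list())
  fail <- function(stage, e) {
    report$failed_stage <- stage
    report$error <- conditionMessage(e)
    jsonlite::write_json(report,
                         file.path(config$outdir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  ## ---- stage: data -------------------------------------------------
  data <- tryCatch({
    if (!is.null(config$simulation)) {
      sim <- do.call(sim_config,
                     c(config$simulation,
                       if (is.null(config$simulation$seed))
                         list(seed = config$seed)))
      .stage_cached(cache, "data", .hash_obj(sim), function() {
        d <- simulate_dataset(sim)
        write_methylation(d$meth,
                          file.path(config$outdir, "methylation.tsv"),
                          file.path(config$outdir, "cpgs.bed"),
                          seed = config$seed, config_hash = chash)
        write_phenotypes(d$phenotypes,
                         file.path(config$outdir, "phenotypes.tsv"),
                         seed = config$seed, config_hash = chash)
        write_proportions(d$proportions,
                          file.path(config$outdir, "proportions.tsv"),
                          seed = config$seed, config_hash = chash)
        write_truth(d$truth, file.path(config$outdir, "truth.json"))
        d
      })
    } else {
      ip <- config$inputs
      .stage_cached(cache, "data",
                    .hash_obj(lapply(unlist(ip), tools::md5sum)),
                    function() {
        meth <- read_methylation(ip$methylation, ip$bed)
        ph <- read_phenotypes(ip$phenotypes)
        pr <- read_proportions(ip$proportions)
        if (!identical(as.character(ph$sample_id), meth$sample_ids) ||
            !identical(rownames(pr), meth$sample_ids))
          stop("sample order differs between methylation, phenotype ",
               "and proportion inputs; refusing to reorder silently")
        list(meth = meth, phenotypes = ph, proportions = pr,
             truth = NULL)
      })
    }
  }, error = function(e) fail("data", e))
  report$stages$data <- list(n_samples = nrow(data$meth$values),
                             n_cpgs = ncol(data$meth$values))

  ## ---- stage: phase1 ----------------------------------------------
  phase1 <- tryCatch(.stage_cached(
    cache, "phase1",
    .hash_obj(list(data$phenotypes, config$loading_threshold,
                   config$seed)),
    function() {
      ph <- apply_exclusions(data$phenotypes)
      keep <- as.character(ph$sample_id)
      ph <- impute_missing(ph, seed = config$seed)
      fm <- fit_factor_model(ph,
                             loading_threshold = config$loading_threshold)
      plan <- derive_analysis_plan(fm)
      list(phenotypes = ph, keep = keep, model = fm, plan = plan,
           exclusion_log = attr(ph, "exclusion_log"))
    }), error = function(e) fail("phase1", e))
  keep_idx <- match(phase1$keep, data$meth$sample_ids)
  meth <- methylation_matrix(
    data$meth$values[keep_idx, , drop = FALSE], data$meth$coords,
    sample_ids = phase1$keep)
  props <- cell_proportions(
    unclass(data$proportions)[keep_idx, , drop = FALSE])
  loadings_df <- data.frame(variable = rownames(phase1$model$loadings),
                            phase1$model$loadings, check.names = FALSE)
  .write_tsv(loadings_df, file.path(config$outdir, "loadings.tsv"),
             config$seed, chash)
  .write_tsv(data.frame(sample_id = phase1$phenotypes$sample_id,
                        phase1$model$scores, check.names = FALSE),
             file.path(config$outdir, "factor_scores.tsv"),
             config$seed, chash)
  yaml::write_yaml(
    lapply(unname(phase1$plan), function(u)
      list(unit = u$unit, outcome_type = u$outcome_type,
           factor_covariates = as.list(u$factor_covariates))),
    file.path(config$outdir, "analysis_plan.yaml"))
  report$stages$phase1 <- list(
    n_excluded = nrow(data$phenotypes) - nrow(phase1$phenotypes),
    n_retained = nrow(phase1$phenotypes),
    n_imputed = sum(attr(phase1$phenotypes, "imputation_log")),
    assignment = lapply(phase1$model$assignment, as.list),
    n_units = length(phase1$plan))

  ## ---- stage: phase2a ---------------------------------------------
  screen <- tryCatch(.stage_cached(
    cache, "phase2a",
    .hash_obj(list(meth$values, phase1$model$loadings, config$gate_p,
                   config$n_folds, config$top_n_grid, config$seed)),
    function() {
      screen_units(phase1$plan, meth, phase1$phenotypes, props,
                   phase1$model, n_folds = config$n_folds,
                   top_n_grid = config$top_n_grid,
                   n_pcs = config$n_pcs, seed = config$seed,
                   gate_p = config$gate_p)
    }), error = function(e) fail("phase2a", e))
  .write_tsv(screen, file.path(config$outdir, "screening.tsv"),
             config$seed, chash)
  passing <- screen$unit[screen$passed_gate]
  report$stages$phase2a <- list(
    n_units = nrow(screen), n_passed = length(passing),
    passed = as.list(passing))

  ## ---- stage: phase2b ---------------------------------------------
  phase2b <- tryCatch(.stage_cached(
    cache, "phase2b",
    .hash_obj(list(meth$values, passing, config$fdr,
                   config$suggestive_p, config$seed)),
    function() {
      pcs <- methylation_pcs(meth, k = config$n_pcs)
      base <- .covariate_matrix(phase1$phenotypes,
                                attr(phase1$plan, "base_covariates"))
      results <- list()
      lambdas <- list()
      for (uname in passing) {
        u <- phase1$plan[[uname]]
        outcome <- if (u$outcome_type == "factor")
          phase1$model$scores[, u$outcome] else
          phase1$phenotypes[[u$outcome]]
        covs <- cbind(base, pcs)
        if (length(u$factor_covariates))
          covs <- cbind(covs, phase1$model$scores[, u$factor_covariates,
                                                  drop = FALSE])
        binary <- length(unique(outcome)) == 2L
        if (binary && min(table(outcome)) < 10) {
          results[[uname]] <- list(skipped = sprintf(
            "unit '%s': fewer than 10 minor-class cases", uname))
          next
        }
        bulk <- if (binary)
          robust_mwas(meth, outcome, props, covs, mode = "bulk",
                      seed = config$seed, unit = uname)
        else bulk_mwas(meth, outcome, covs, props, unit = uname)
        ct <- if (binary)
          robust_mwas(meth, outcome, props, covs, mode = "celltype",
                      seed = config$seed, unit = uname)
        else celltype_mwas(meth, outcome, props, covs, unit = uname)
        results[[uname]] <- c(list(bulk = bulk), ct)
        lambdas[[uname]] <- vapply(
          c(list(bulk = bulk), ct),
          function(r) if (is.null(r)) NA_real_ else r$lambda, 0)
      }
      list(results = results, lambdas = lambdas)
    }), error = function(e) fail("phase2b", e))
  counts <- classify_findings(phase2b$results,
                              q_threshold = config$fdr,
                              suggestive_p = config$suggestive_p)
  .write_tsv(counts, file.path(config$outdir, "findings_counts.tsv"),
             config$seed, chash)
  if (nrow(counts))
    .write_tsv(findings_layout(counts),
               file.path(config$outdir, "findings_layout.tsv"),
               config$seed, chash)
  for (uname in names(phase2b$results)) {
    rr <- phase2b$results[[uname]]
    if (!is.null(rr$skipped)) next
    for (tg in names(rr)) {
      r <- rr[[tg]]
      if (is.null(r) || !inherits(r, "mwas_result")) next
      write_mwas_result(r, file.path(
        config$outdir, sprintf("mwas_%s_%s.tsv", uname, tg)),
        config$seed, chash)
      .write_tsv(qq_table(r$table$p), file.path(
        config$outdir, sprintf("qq_%s_%s.tsv", uname, tg)),
        config$seed, chash)
    }
  }
  report$stages$phase2b <- list(
    lambdas = phase2b$lambdas,
    counts = if (nrow(counts)) counts else NULL)

  ## ---- stage: phase2c ---------------------------------------------
  if (!is.null(config$inputs$annotation) &&
      !is.null(config$inputs$gmt)) {
    phase2c <- tryCatch({
      annotation <- read_gene_annotation(config$inputs$annotation)
      sets <- read_gmt(config$inputs$gmt)
      enr <- list()
      for (uname in names(phase2b$results)) {
        rr <- phase2b$results[[uname]]
        if (!is.null(rr$skipped)) next
        for (tg in names(rr)) {
          r <- rr[[tg]]
          if (is.null(r) || !inherits(r, "mwas_result")) next
          e <- enrich_suggestive(r, meth, annotation, sets,
                                 flank = config$flank,
                                 suggestive_p = config$suggestive_p)
          key <- sprintf("%s_%s", uname, tg)
          if (!is.null(e$enrichment))
            .write_tsv(e$enrichment, file.path(
              config$outdir, sprintf("enrichment_%s.tsv", key)),
              config$seed, chash)
          enr[[key]] <- list(n_suggestive = e$n_suggestive,
                             n_query_genes = length(e$query_genes),
                             n_intergenic = e$n_intergenic)
        }
      }
      enr
    }, error = function(e) fail("phase2c", e))
    report$stages$phase2c <- phase2c
  } else {
    report$stages$phase2c <- "skipped (no annotation/gene sets configured)"
  }

  jsonlite::write_json(report,
                       file.path(config$outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
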