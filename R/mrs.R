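## Phase 2A: cross-validated methylation risk scores and the
## nominal-significance gate into the full-scale MWAS.

#' Cross-validated methylation risk score
#'
#' k-fold CV with seed-deterministic fold assignment. Within each
#' training fold, outcome and methylation are residualized on the
#' covariates (coefficients fitted on the training fold only), CpGs
#' are ranked by the |t| of their marginal association (ties broken by
#' genomic position, then column index), and each held-out sample's
#' score over the top-N CpGs is the sum of `sign(t_train)` times the
#' training-standardized residual methylation. The concatenated
#' out-of-fold scores are correlated (Spearman) with the
#' covariate-residualized outcome; P is the two-sided t approximation.
#' All grid sizes N are evaluated; the best (smallest-P) N is
#' reported, flagged as grid-optimized.
#'
#' @param meth [methylation_matrix()] or samples x CpGs matrix.
#' @param outcome numeric outcome vector.
#' @param covariates optional numeric covariate matrix.
#' @param n_folds number of CV folds (each fold must keep >= 3
#'   samples).
#' @param top_n_grid candidate numbers of top-ranked CpGs; capped at
#'   the number of CpGs.
#' @param seed fold-assignment seed.
#' @param gate_p nominal significance gate.
#' @param unit label for the analysis unit.
#' @param p_method `"asymptotic"` (t approximation) or
#'   `"permutation"` (recommended only for small n).
#' @param n_perm permutations when `p_method = "permutation"`.
#' @return Object of class `mrs_result`: `oof_scores` (at the
#'   selected N), `spearman_rho`, `p_value`, `selected_top_n`,
#'   `passed_gate`, the full `grid` table, and per-fold CpG
#'   selections.
#'
#' @details The asymptotic P treats the out-of-fold score as fixed.
#'   Because fold-specific CpG selections are built from heavily
#'   overlapping training sets, the score carries selection-induced
#'   dependence and the asymptotic P is optimistic under the null; it
#'   is retained as the (knowingly optimistic) screening statistic.
#'   `p_method = "permutation"` re-runs the entire cross-validated
#'   selection pipeline on permuted (covariate-residualized) outcomes
#'   and is calibrated by construction.
#' @export
compute_mrs <- function(meth, outcome, covariates = NULL, n_folds = 10L,
                        top_n_grid = c(50L, 500L, 5000L, 50000L),
                        seed = 1L, gate_p = 0.05, unit = "outcome",
                        p_method = c("asymptotic", "permutation"),
                        n_perm = 199L) {
  p_method <- match.arg(p_method)
  M <- .meth_values(meth)
  co <- .meth_coords(meth)
  n <- nrow(M)
  p <- ncol(M)
  stopifnot(length(outcome) == n)
  if (var(outcome) < 1e-12) stop("outcome is constant")
  if (n_folds < 2L) stop("n_folds must be at least 2")
  grid <- sort(unique(pmin(as.integer(top_n_grid), p)))
  C <- cbind(`(Intercept)` = rep(1, n),
             if (!is.null(covariates)) as.matrix(covariates))
  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(n_folds), n))
  if (min(table(fold)) < 3L)
    stop("each fold must contain at least 3 samples")
  ## tie-break key: genomic position if available, else column index
  tie1 <- if (!is.null(co)) as.integer(factor(co$chrom)) else
    rep(0L, p)
  tie2 <- if (!is.null(co)) co$start else seq_len(p)

  ## Per-fold preparation, outcome-independent: covariate projector,
  ## standardization constants and standardized test-fold residuals.
  ## After residualizing the outcome on the training covariates
  ## (intercept included), its inner product with the raw training
  ## methylation equals the one with the centered residualized
  ## methylation, so ranking correlations need only M[tr, ].
  prep <- lapply(seq_len(n_folds), function(f) {
    tr <- which(fold != f); te <- which(fold == f)
    qrC <- qr(C[tr, , drop = FALSE])
    Bm <- qr.coef(qrC, M[tr, , drop = FALSE])
    Rtr <- M[tr, , drop = FALSE] - C[tr, , drop = FALSE] %*% Bm
    mu <- colMeans(Rtr)
    sdv <- sqrt(colSums(sweep(Rtr, 2L, mu)^2) / (length(tr) - 1L))
    Rte <- M[te, , drop = FALSE] - C[te, , drop = FALSE] %*% Bm
    Zte <- sweep(sweep(Rte, 2L, mu), 2L, pmax(sdv, 1e-12), "/")
    list(tr = tr, te = te, qrC = qrC,
         denom = sdv * sqrt(length(tr) - 1L), sdv = sdv, Zte = Zte)
  })

  score_oof <- function(y, keep_selections = FALSE) {
    oof <- matrix(0, n, length(grid))
    selections <- if (keep_selections) vector("list", n_folds)
    for (f in seq_len(n_folds)) {
      pf <- prep[[f]]
      ytr <- y[pf$tr]
      ry <- ytr - as.vector(C[pf$tr, , drop = FALSE] %*%
                              qr.coef(pf$qrC, ytr))
      ss <- sqrt(sum(ry^2))
      r <- if (ss > 1e-12)
        as.vector(crossprod(ry, M[pf$tr, , drop = FALSE])) /
          (ss * pf$denom) else rep(NA_real_, p)
      r[pf$sdv <= 1e-12] <- NA_real_
      ord <- order(-abs(r), tie1, tie2, na.last = TRUE)
      ord <- ord[!is.na(r[ord])]
      if (keep_selections)
        selections[[f]] <- list(order = head(ord, max(grid)),
                                sign = sign(r[head(ord, max(grid))]))
      if (!length(ord)) next
      Z <- sweep(pf$Zte[, ord, drop = FALSE], 2L, sign(r[ord]), "*")
      for (g in seq_along(grid)) {
        N <- min(grid[g], length(ord))
        oof[pf$te, g] <- rowSums(Z[, seq_len(N), drop = FALSE])
      }
    }
    list(oof = oof, selections = selections)
  }

  y_hat <- as.vector(C %*% qr.coef(qr(C), outcome))
  y_res <- outcome - y_hat
  obs <- score_oof(outcome, keep_selections = TRUE)
  rho_of <- function(oof, yr) vapply(seq_along(grid), function(g) {
    s <- oof[, g]
    if (var(s) < 1e-12) NA_real_ else
      cor(s, yr, method = "spearman")
  }, 0)
  rho <- rho_of(obs$oof, y_res)
  if (p_method == "asymptotic") {
    tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    pval <- 2 * pt(-abs(tt), n - 2)
  } else {
    ## full-pipeline permutation: selection re-run per permuted
    ## outcome (Freedman-Lane: fitted covariate part + permuted
    ## residuals), so selection optimism is in the null distribution
    cnt <- rep(0L, length(grid))
    for (b in seq_len(n_perm)) {
      yr_b <- sample(y_res)
      rho_b <- rho_of(score_oof(y_hat + yr_b)$oof, yr_b)
      cnt <- cnt + (abs(rho_b) >= abs(rho) | is.na(rho))
    }
    pval <- (1 + cnt) / (n_perm + 1)
    pval[is.na(rho)] <- NA_real_
  }
  gridtab <- data.frame(top_n = grid, rho = rho, p = pval)
  oof <- obs$oof
  selections <- obs$selections
  if (all(is.na(gridtab$p))) {
    best <- 1L
  } else {
    best <- order(gridtab$p, -abs(gridtab$rho))[1L]  # ties: smaller N
  }
  structure(list(analysis_unit = unit,
                 oof_scores = oof[, best],
                 spearman_rho = gridtab$rho[best],
                 p_value = gridtab$p[best],
                 n_folds = n_folds,
                 top_n_grid = grid,
                 selected_top_n = grid[best],
                 passed_gate = isTRUE(gridtab$p[best] < gate_p),
                 gate_p = gate_p,
                 grid = gridtab,
                 grid_optimized = length(grid) > 1L,
                 p_method = p_method,
                 fold_assignment = fold,
                 fold_selections = selections),
            class = "mrs_result")
}

#' @export
print.mrs_result <- function(x, ...) {
  cat(sprintf(
    "mrs_result [%s]: rho = %.3f, P = %.3g (top %d CpGs%s), gate %s\n",
    x$analysis_unit, x$spearman_rho, x$p_value, x$selected_top_n,
    if (x$grid_optimized) ", grid-optimized" else "",
    if (x$passed_gate) "PASSED" else "not passed"))
  invisible(x)
}

#' Screen every analysis unit for cumulative methylation signal
#'
#' Runs [compute_mrs()] for each unit of the analysis plan, with the
#' standard covariate set: sex, batch dummies, the first methylation
#' PCs, cell proportions (reference dropped) and — for variables
#' loading high on a factor — the assigned factor scores. Units with
#' nominally significant out-of-fold Spearman correlation pass the
#' gate into the full-scale MWAS.
#'
#' @param plan [derive_analysis_plan()] result.
#' @param meth [methylation_matrix()].
#' @param phenotypes complete phenotype data.frame.
#' @param proportions cell-proportion matrix.
#' @param factor_model the fitted [fit_factor_model()] (source of
#'   factor scores).
#' @param n_pcs number of methylation PCs in the covariate set.
#' @param reference_cell proportion column dropped from covariates.
#' @param seed base seed; unit i uses `seed + i` for its folds.
#' @inheritParams compute_mrs
#' @return data.frame (unit, rho, p_value, selected_top_n,
#'   passed_gate) with the full `mrs_result` list in attribute
#'   `results`.
#' @export
screen_units <- function(plan, meth, phenotypes, proportions, factor_model,
                         n_folds = 10L,
                         top_n_grid = c(50L, 500L, 5000L, 50000L),
                         n_pcs = 2L, reference_cell = "Gran",
                         seed = 1L, gate_p = 0.05) {
  empty <- data.frame(unit = character(0), rho = numeric(0),
                      p_value = numeric(0), selected_top_n = integer(0),
                      passed_gate = logical(0))
  if (!length(plan)) return(empty)
  pcs <- methylation_pcs(meth, k = n_pcs)
  base <- .covariate_matrix(phenotypes,
                            attr(plan, "base_covariates") %||%
                              c("sex", "batch"))
  P <- unclass(proportions)
  prop_cov <- P[, setdiff(colnames(P), reference_cell), drop = FALSE]
  results <- list()
  rows <- list()
  for (i in seq_along(plan)) {
    u <- plan[[i]]
    outcome <- if (u$outcome_type == "factor")
      factor_model$scores[, u$outcome] else phenotypes[[u$outcome]]
    covs <- cbind(base, pcs, prop_cov)
    if (length(u$factor_covariates))
      covs <- cbind(covs,
                    factor_model$scores[, u$factor_covariates,
                                        drop = FALSE])
    res <- compute_mrs(meth, outcome, covariates = covs,
                       n_folds = n_folds, top_n_grid = top_n_grid,
                       seed = seed + i, gate_p = gate_p, unit = u$unit)
    results[[u$unit]] <- res
    rows[[u$unit]] <- data.frame(unit = u$unit, rho = res$spearman_rho,
                                 p_value = res$p_value,
                                 selected_top_n = res$selected_top_n,
                                 passed_gate = res$passed_gate,
                                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Numeric covariate matrix from phenotype columns (factors expanded
## to treatment-coded dummies).
.covariate_matrix <- function(phenotypes, cols) {
  cols <- intersect(cols, names(phenotypes))
  if (!length(cols)) return(NULL)
  fml <- stats::reformulate(cols)
  mm <- model.matrix(fml, data = phenotypes)
  mm[, setdiff(colnames(mm), "(Intercept)"), drop = FALSE]
}
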