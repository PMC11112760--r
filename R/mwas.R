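## Phase 2B: per-CpG bulk MWAS and joint cell-type interaction
## deconvolution, with methylation-PC covariates, HC3 robust option,
## genomic-inflation diagnostics, BH-FDR and findings classification.
##
## All per-CpG fits share one design matrix, so coefficients for every
## CpG come from a single QR solve; classical and HC3 standard errors
## are computed in closed form from the shared hat diagonal.

#' Principal components of the methylation matrix
#'
#' Top-k principal components of the column-centered, variance-scaled
#' methylation matrix, for use as covariates against unmeasured
#' confounders. Zero-variance CpGs are dropped before scaling. Each
#' returned column is a unit-norm left singular vector, sign-fixed so
#' the largest-|weight| CpG has a positive weight; components with a
#' (near-)zero singular value are flagged degenerate.
#'
#' @param meth [methylation_matrix()] or samples x CpGs matrix.
#' @param k number of components (default 2).
#' @param scale. scale CpGs to unit variance before the SVD.
#' @return n x k matrix of PC columns, with attributes `sdev`,
#'   `degenerate` and `var_explained`.
#' @export
methylation_pcs <- function(meth, k = 2L, scale. = TRUE) {
  M <- .meth_values(meth)
  n <- nrow(M)
  if (n < k + 2L)
    stop(sprintf("need at least %d samples for %d components", k + 2L, k))
  v <- apply(M, 2L, var)
  M <- M[, v > 1e-12, drop = FALSE]
  Z <- scale(M, center = TRUE, scale = scale.)
  sv <- svd(Z, nu = k, nv = k)
  U <- sv$u[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) U[, j] <- -U[, j]
  }
  colnames(U) <- paste0("mPC", seq_len(k))
  rownames(U) <- rownames(M)
  d <- sv$d[seq_len(k)]
  attr(U, "sdev") <- d / sqrt(max(1, n - 1))
  attr(U, "degenerate") <- d < 1e-8 * sv$d[1]
  attr(U, "var_explained") <- sv$d[seq_len(k)]^2 / sum(sv$d^2)
  U
}

## Shared-design least squares over many response columns.
## Y: n x p responses; X: n x q design; test_cols: design columns whose
## coefficients are tested. Returns per-CpG estimate/se/t/p for each
## test column. robust = HC3 sandwich SEs via the hat diagonal.
.fit_many <- function(Y, X, test_cols, robust = FALSE) {
  n <- nrow(X)
  QR <- qr(X)
  if (QR$rank < ncol(X)) {
    dep <- colnames(X)[QR$pivot[(QR$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dep, collapse = ", "))
  }
  df <- n - QR$rank
  if (df <= 0) stop("no residual degrees of freedom")
  B <- qr.coef(QR, Y)                       # q x p coefficients
  E <- Y - X %*% B                          # residuals
  Rmat <- qr.R(QR)
  XtXinv <- chol2inv(Rmat)
  piv <- QR$pivot
  XtXinv[piv, piv] <- XtXinv
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  const <- apply(Y, 2L, var) < 1e-12        # flagged, excluded from q/lambda
  out <- list()
  if (robust) {
    h <- rowSums(qr.Q(QR)^2)
    W <- E^2 / (1 - h)^2                    # n x p HC3 weights
  } else {
    sigma2 <- colSums(E^2) / df
  }
  for (cc in test_cols) {
    est <- B[cc, ]
    if (robust) {
      a <- XtXinv[cc, , drop = FALSE] %*% t(X)   # 1 x n projection row
      se <- sqrt(as.vector(a^2 %*% W))
    } else {
      se <- sqrt(XtXinv[cc, cc] * sigma2)
    }
    tt <- est / se
    ## exact fits give |t| = Inf; keep p inside (0, 1]
    p <- pmax(2 * pt(-abs(tt), df), .Machine$double.xmin)
    p[const] <- NA_real_
    tt[const] <- NA_real_
    out[[cc]] <- data.frame(estimate = est, se = se, t = tt,
                            df = df, p = p, row.names = NULL)
  }
  out
}

## Assemble an mwas_result object from a per-CpG stat table.
.mwas_result <- function(tab, meth, unit, target, robust,
                         q_threshold = 0.1, suggestive_p = 1e-6) {
  co <- .meth_coords(meth)
  if (!is.null(co)) {
    tab <- cbind(data.frame(cpg = co$cpg, chrom = co$chrom,
                            pos = co$start, stringsAsFactors = FALSE), tab)
  } else {
    tab <- cbind(data.frame(cpg = seq_len(nrow(tab))), tab)
  }
  tab$q <- bh_fdr(tab$p)
  ok <- !is.na(tab$p)
  lambda <- if (sum(ok) >= 100) genomic_lambda(tab$p[ok]) else NA_real_
  structure(list(unit = unit, target = target, robust = robust,
                 table = tab, lambda = lambda,
                 n_significant_q10 = sum(tab$q < q_threshold, na.rm = TRUE),
                 n_suggestive = sum(tab$p < suggestive_p, na.rm = TRUE),
                 n_skipped = sum(!ok)),
            class = "mwas_result")
}

#' @export
print.mwas_result <- function(x, ...) {
  cat(sprintf(
    "mwas_result [%s / %s%s]: %d CpGs, lambda = %.3f, q<0.1: %d, p<1e-6: %d\n",
    x$unit, x$target, if (x$robust) ", robust" else "",
    nrow(x$table), x$lambda, x$n_significant_q10, x$n_suggestive))
  invisible(x)
}

## Build the bulk covariate block: covariates plus all-but-reference
## proportion columns (rows sum to one, so the full set is collinear
## with the intercept).
.bulk_covariates <- function(covariates, proportions, reference_cell) {
  blocks <- list()
  if (!is.null(covariates)) blocks$cov <- as.matrix(covariates)
  if (!is.null(proportions)) {
    P <- unclass(proportions)
    if (!reference_cell %in% colnames(P))
      stop(sprintf("reference cell '%s' not among proportion columns",
                   reference_cell))
    blocks$prop <- P[, setdiff(colnames(P), reference_cell), drop = FALSE]
  }
  if (length(blocks)) do.call(cbind, blocks) else NULL
}

#' Bulk methylome-wide association scan
#'
#' Per CpG, ordinary least squares of methylation on the outcome plus
#' covariates, with cell proportions entered as covariates (one
#' proportion column dropped against the intercept; default reference
#' is the most abundant type, granulocytes). Two-sided t test on the
#' outcome coefficient. Constant-methylation CpGs get missing p and
#' are excluded from FDR and lambda.
#'
#' @param meth [methylation_matrix()] or samples x CpGs matrix.
#' @param outcome numeric outcome vector (the risk variable or factor
#'   score).
#' @param covariates optional numeric matrix of covariates (sex, batch
#'   dummies, methylation PCs, assigned factors).
#' @param proportions optional cell-proportion matrix entered as
#'   covariates.
#' @param reference_cell proportion column dropped to avoid exact
#'   collinearity with the intercept.
#' @param robust use HC3 heteroskedasticity-consistent standard
#'   errors.
#' @param unit label for the analysis unit.
#' @return An `mwas_result` (per-CpG estimate, se, t, df, p, q;
#'   genomic-inflation `lambda`; significant/suggestive counts).
#' @export
bulk_mwas <- function(meth, outcome, covariates = NULL, proportions = NULL,
                      reference_cell = "Gran", robust = FALSE,
                      unit = "outcome") {
  Y <- .meth_values(meth)
  n <- nrow(Y)
  stopifnot(length(outcome) == n)
  if (var(outcome) < 1e-12) stop("outcome is constant")
  Xc <- .bulk_covariates(covariates, proportions, reference_cell)
  X <- cbind(`(Intercept)` = 1, outcome = outcome, Xc)
  fit <- .fit_many(Y, X, "outcome", robust = robust)
  .mwas_result(fit$outcome, meth, unit, "bulk", robust)
}

#' Cell-type-specific MWAS by interaction deconvolution
#'
#' Per CpG, ONE joint regression of bulk methylation on the six
#' cell-type proportion columns, the six outcome-by-proportion
#' interaction columns, and additive covariates — with no global
#' intercept, since the proportion columns sum to one and span it.
#' Each interaction coefficient estimates the cell-type-specific
#' association and is tested two-sided from the joint fit. A
#' zero-variance proportion column makes its cell type unidentifiable
#' (its column plus the others is collinear): that cell type is
#' dropped, flagged, and the scan continues.
#'
#' @inheritParams bulk_mwas
#' @param proportions samples x cell types proportion matrix,
#'   row-aligned with `meth`.
#' @return Named list of `mwas_result`, one per cell type (entries for
#'   unidentifiable cell types are `NULL` and listed in the
#'   `dropped_cell_types` attribute).
#' @export
celltype_mwas <- function(meth, outcome, proportions, covariates = NULL,
                          robust = FALSE, unit = "outcome") {
  Y <- .meth_values(meth)
  n <- nrow(Y)
  P <- unclass(proportions)
  stopifnot(nrow(P) == n, length(outcome) == n)
  if (var(outcome) < 1e-12) stop("outcome is constant")
  cts <- colnames(P)
  pvar <- apply(P, 2L, var)
  pmean <- colMeans(P)
  ## absent cell types (all-zero column) carry no information; a
  ## constant nonzero column is collinear with the rest (rows sum to
  ## one) unless it is the only type present (single-type collapse)
  zero_col <- pmean < 1e-12
  const_col <- pvar < 1e-12 & !zero_col
  keep <- cts[!zero_col & !const_col]
  if (!length(keep) && any(const_col)) keep <- cts[const_col][1L]
  dropped <- setdiff(cts, keep)
  if (length(dropped))
    warning("proportion column(s) dropped as unidentifiable ",
            "(zero variance): ", paste(dropped, collapse = ", "))
  Pk <- P[, keep, drop = FALSE]
  XP <- Pk
  colnames(XP) <- paste0("P_", keep)
  XI <- Pk * outcome
  colnames(XI) <- paste0("RVxP_", keep)
  Xc <- if (!is.null(covariates)) as.matrix(covariates) else NULL
  if (!is.null(Xc)) {
    cvar <- apply(Xc, 2L, var)
    if (any(cvar < 1e-12))
      stop("covariate column(s) ", paste(colnames(Xc)[cvar < 1e-12],
           collapse = ", "),
           " are constant: a global intercept is not identifiable in the ",
           "cell-type design (the proportion columns already span it)")
  }
  X <- cbind(XP, XI, Xc)
  fit <- .fit_many(Y, X, paste0("RVxP_", keep), robust = robust)
  out <- setNames(vector("list", length(cts)), cts)
  for (ct in keep)
    out[[ct]] <- .mwas_result(fit[[paste0("RVxP_", ct)]], meth, unit, ct,
                              robust)
  attr(out, "dropped_cell_types") <- dropped
  out
}

#' Robust MWAS for (rare) binary outcomes
#'
#' Identical point estimates to the standard fit but HC3
#' heteroskedasticity-consistent standard errors, with optional seeded
#' permutation p-values. For a binary outcome at least 10 cases in
#' the minor class are required.
#'
#' @inheritParams celltype_mwas
#' @param mode `"celltype"` (deconvolution scan) or `"bulk"`.
#' @param n_perm number of outcome permutations for permutation
#'   p-values (0 = analytic HC3 p only).
#' @param strata optional factor; permutations shuffle the outcome
#'   within its levels.
#' @param seed permutation seed.
#' @return As [bulk_mwas()] / [celltype_mwas()]; with `n_perm > 0`
#'   each result table gains a `p_perm` column.
#' @export
robust_mwas <- function(meth, outcome, proportions = NULL,
                        covariates = NULL, mode = c("celltype", "bulk"),
                        n_perm = 0L, strata = NULL, seed = 1L,
                        unit = "outcome", reference_cell = "Gran") {
  mode <- match.arg(mode)
  u <- unique(outcome)
  if (length(u) == 2L) {
    n_cases <- min(table(outcome))
    if (n_cases < 10)
      stop(sprintf(paste0("only %d cases in the minor outcome class; ",
                          "at least 10 are required for adequate power"),
                   n_cases))
  }
  run <- function(y) {
    if (mode == "bulk")
      bulk_mwas(meth, y, covariates, proportions,
                reference_cell = reference_cell, robust = TRUE, unit = unit)
    else
      celltype_mwas(meth, y, proportions, covariates, robust = TRUE,
                    unit = unit)
  }
  res <- run(outcome)
  if (n_perm > 0L) {
    set.seed(as.integer(seed))
    perm_one <- function(y) {
      if (is.null(strata)) return(sample(y))
      out <- y
      for (s in split(seq_along(y), strata)) out[s] <- y[sample(s)]
      out
    }
    tstat <- function(r) if (inherits(r, "mwas_result")) list(all = r$table$t)
                         else lapply(r[!vapply(r, is.null, TRUE)],
                                     function(z) z$table$t)
    obs <- tstat(res)
    counts <- lapply(obs, function(tt) rep(0L, length(tt)))
    for (b in seq_len(n_perm)) {
      pb <- tstat(run(perm_one(outcome)))
      for (k in names(obs))
        counts[[k]] <- counts[[k]] +
          (abs(pb[[k]]) >= abs(obs[[k]]) | is.na(obs[[k]]))
    }
    addp <- function(r, k) {
      r$table$p_perm <- (1 + counts[[k]]) / (n_perm + 1)
      r
    }
    if (inherits(res, "mwas_result")) res <- addp(res, "all")
    else for (k in names(counts)) res[[k]] <- addp(res[[k]], k)
  }
  res
}

#' Genomic inflation factor
#'
#' Median of the 1-df chi-square quantiles of the p-values divided by
#' the 1-df chi-square median (0.4549364). Values near 1 indicate
#' calibrated tests.
#'
#' @param p_values vector of p-values (NAs ignored).
#' @return lambda, a positive scalar.
#' @export
genomic_lambda <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (length(p) < 100)
    stop("at least 100 non-missing p-values are required")
  chi <- qchisq(p, df = 1, lower.tail = FALSE)
  median(chi) / qchisq(0.5, df = 1)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up q-values `q_(i) = min_(j>=i) p_(j) * m / j` on the sorted
#' vector, mapped back to input order. Missing p-values propagate
#' missing q and do not count toward m.
#'
#' @param p_values p-values in (0, 1] (NA allowed).
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  q <- rep(NA_real_, length(p_values))
  ok <- which(!is.na(p_values))
  if (!length(ok)) return(q)
  p <- p_values[ok]
  if (any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p)
  qs <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q[ok[o]] <- qs
  q
}

#' Classify MWAS findings into a per-unit, per-target count table
#'
#' Counts methylome-wide significant (q below `q_threshold`) and
#' suggestive (p below `suggestive_p`) CpGs for every analysis unit and
#' target (bulk or one cell type).
#'
#' @param results list of `mwas_result` objects (flat, or nested lists
#'   as returned by [celltype_mwas()]).
#' @param q_threshold FDR significance threshold.
#' @param suggestive_p suggestive p-value threshold.
#' @return data.frame: unit, target, n_significant, n_suggestive.
#' @export
classify_findings <- function(results, q_threshold = 0.1,
                              suggestive_p = 1e-6) {
  flat <- list()
  add <- function(x) {
    if (inherits(x, "mwas_result")) flat[[length(flat) + 1L]] <<- x
    else if (is.list(x)) for (e in x) if (!is.null(e)) add(e)
  }
  add(results)
  if (!length(flat))
    return(data.frame(unit = character(0), target = character(0),
                      n_significant = integer(0), n_suggestive = integer(0)))
  data.frame(
    unit = vapply(flat, `[[`, "", "unit"),
    target = vapply(flat, `[[`, "", "target"),
    n_significant = vapply(flat, function(r)
      sum(r$table$q < q_threshold, na.rm = TRUE), 0L),
    n_suggestive = vapply(flat, function(r)
      sum(r$table$p < suggestive_p, na.rm = TRUE), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Reshape a findings table to the wide per-cell-type layout
#'
#' One row per analysis unit, one `sig/sugg` column per target in the
#' canonical order (bulk, then the six cell types).
#'
#' @param counts output of [classify_findings()].
#' @return Wide-format data.frame of "significant/suggestive" strings.
#' @export
findings_layout <- function(counts) {
  targets <- c("bulk", .CELL_TYPES)
  targets <- c(intersect(targets, counts$target),
               setdiff(unique(counts$target), targets))
  units <- unique(counts$unit)
  out <- data.frame(unit = units, stringsAsFactors = FALSE)
  for (tg in targets) {
    col <- vapply(units, function(u) {
      r <- counts[counts$unit == u & counts$target == tg, ]
      if (!nrow(r)) "-" else sprintf("%d/%d", r$n_significant[1],
                                     r$n_suggestive[1])
    }, "")
    out[[tg]] <- col
  }
  out
}

#' Quantile-quantile table for association p-values
#'
#' Expected vs observed -log10 p-values for QQ plotting.
#'
#' @param p_values vector of p-values (NAs dropped).
#' @return data.frame with `expected` and `observed` columns, sorted.
#' @export
qq_table <- function(p_values) {
  p <- sort(p_values[!is.na(p_values)])
  data.frame(expected = -log10(ppoints(length(p))),
             observed = -log10(p))
}
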