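## Phase 1: phenotype exclusions, chained-regression imputation,
## exploratory factor analysis, and the downstream analysis plan.

#' Apply gestational-age exclusion rules
#'
#' Samples with gestational age below `min_days` (extreme prematurity)
#' are dropped; implausibly long gestations above `max_days` are
#' treated as clerical errors and set to missing, with the sample
#' retained. Every action is recorded in the `exclusion_log`
#' attribute.
#'
#' @param phenotypes phenotype data.frame with a `gestational_age`
#'   column (days).
#' @param min_days exclusion threshold (default 224 days = 32 weeks).
#' @param max_days set-to-missing threshold (default 301 days = 43
#'   weeks).
#' @return Filtered phenotype table with attribute `exclusion_log`
#'   (data.frame: sample_id, action, value).
#' @export
apply_exclusions <- function(phenotypes, min_days = 224, max_days = 301) {
  if (!"gestational_age" %in% names(phenotypes))
    stop("phenotypes must contain a gestational_age column")
  ga <- phenotypes$gestational_age
  log <- data.frame(sample_id = character(0), action = character(0),
                    value = numeric(0), stringsAsFactors = FALSE)
  too_long <- which(!is.na(ga) & ga > max_days)
  if (length(too_long)) {
    log <- rbind(log, data.frame(
      sample_id = as.character(phenotypes$sample_id[too_long]),
      action = "set_missing", value = ga[too_long]))
    phenotypes$gestational_age[too_long] <- NA
  }
  too_short <- which(!is.na(ga) & ga < min_days)
  if (length(too_short)) {
    log <- rbind(log, data.frame(
      sample_id = as.character(phenotypes$sample_id[too_short]),
      action = "excluded", value = ga[too_short]))
    phenotypes <- phenotypes[-too_short, , drop = FALSE]
    rownames(phenotypes) <- NULL
  }
  attr(phenotypes, "exclusion_log") <- log
  phenotypes
}

#' Impute missing phenotype values by chained stochastic regression
#'
#' Single-dataset chained-equations imputation over the four
#' continuous size/gestation variables, using gestational age, birth
#' weight, birth height, head size and sex as predictors. Each cycle
#' refits a linear model per target on the originally observed rows
#' and replaces its missing values by the prediction plus a
#' posterior-style Gaussian draw with the residual SD. Imputed
#' gestational ages are clipped to the plausible range.
#'
#' @param phenotypes phenotype data.frame.
#' @param seed integer seed (draws are seed-deterministic).
#' @param n_iter number of chained cycles.
#' @param ga_range plausible gestational-age range (days) used to clip
#'   imputed values.
#' @return Completed phenotype table; attribute `imputation_log`
#'   counts imputed cells per variable.
#' @export
impute_missing <- function(phenotypes, seed = 1L, n_iter = 10L,
                           ga_range = c(154, 301)) {
  targets <- intersect(.RV_IMPUTABLE, names(phenotypes))
  predictors <- c(targets, intersect("sex", names(phenotypes)))
  if (!all(.RV_IMPUTABLE %in% names(phenotypes)))
    stop("the four size/gestation predictor variables must be present")
  miss <- lapply(setNames(targets, targets),
                 function(v) which(is.na(phenotypes[[v]])))
  n_miss <- vapply(miss, length, 0L)
  if (all(n_miss == 0L)) {
    attr(phenotypes, "imputation_log") <- n_miss
    return(phenotypes)
  }
  for (v in targets)
    if (n_miss[[v]] == nrow(phenotypes))
      stop(sprintf("variable '%s' is entirely missing; cannot impute", v))
  rate <- sum(n_miss) / (nrow(phenotypes) * length(targets))
  if (rate >= 0.10)
    stop(sprintf("missing rate %.1f%% exceeds the 10%% imputation limit",
                 100 * rate))
  set.seed(as.integer(seed))
  work <- phenotypes
  for (v in targets)  # mean initialization
    work[[v]][miss[[v]]] <- mean(phenotypes[[v]], na.rm = TRUE)
  for (it in seq_len(n_iter)) {
    for (v in targets) {
      if (!length(miss[[v]])) next
      rhs <- setdiff(predictors, v)
      fml <- stats::reformulate(rhs, response = v)
      obs <- which(!is.na(phenotypes[[v]]))
      fit <- lm(fml, data = work[obs, , drop = FALSE])
      sigma <- summary(fit)$sigma
      if (!is.finite(sigma)) sigma <- 0
      pred <- predict(fit, newdata = work[miss[[v]], , drop = FALSE])
      work[[v]][miss[[v]]] <- pred + rnorm(length(pred), 0, sigma)
    }
  }
  if ("gestational_age" %in% targets && length(miss$gestational_age))
    work$gestational_age[miss$gestational_age] <-
      pmin(pmax(work$gestational_age[miss$gestational_age],
                ga_range[1]), ga_range[2])
  attr(work, "imputation_log") <- n_miss
  attr(work, "missing_mask") <- attr(phenotypes, "missing_mask")
  work
}

## Bivariate normal CDF P(X < a, Y < b) under correlation rho, by
## one-dimensional quadrature; enough accuracy for ML tetrachorics.
.pbinorm <- function(a, b, rho) {
  if (abs(rho) > 0.9999) rho <- sign(rho) * 0.9999
  f <- function(x) dnorm(x) * pnorm((b - rho * x) / sqrt(1 - rho^2))
  integrate(f, -8, a, rel.tol = 1e-9)$value
}

## ML tetrachoric correlation from a 2x2 table of 0/1 variables.
.tetrachoric <- function(x, y) {
  n <- length(x)
  n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
  if (min(n11 + n10, n01 + n00, n11 + n01, n10 + n00) == 0)
    return(NA_real_)
  ## continuity correction for empty cells
  if (min(n11, n10, n01, n00) == 0) {
    n11 <- n11 + 0.5; n10 <- n10 + 0.5; n01 <- n01 + 0.5; n00 <- n00 + 0.5
    n <- n + 2
  }
  a <- qnorm((n01 + n00) / n)  # threshold on x latent
  b <- qnorm((n10 + n00) / n)  # threshold on y latent
  nll <- function(rho) {
    p00 <- .pbinorm(a, b, rho)
    p01 <- pnorm(a) - p00
    p10 <- pnorm(b) - p00
    p11 <- 1 - p00 - p01 - p10
    p <- pmax(c(p00, p01, p10, p11), 1e-12)
    -sum(c(n00, n01, n10, n11) * log(p))
  }
  optimize(nll, c(-0.999, 0.999))$minimum
}

## Biserial correlation from the point-biserial (closed form under the
## latent bivariate-normal model): r_bis = r_pb * sqrt(p q) / phi(tau).
.biserial <- function(cont, bin) {
  p <- mean(bin)
  if (p <= 0 || p >= 1) return(NA_real_)
  tau <- qnorm(1 - p)
  r <- cor(cont, bin) * sqrt(p * (1 - p)) / dnorm(tau)
  max(min(r, 0.999), -0.999)
}

## Correlation matrix over mixed continuous/binary columns.
## method "pearson": plain Pearson on 0/1 coding.
## method "latent": tetrachoric (binary-binary), biserial
## (binary-continuous), Pearson otherwise; nearest-PD repair by
## eigenvalue clipping when needed.
.mixed_cor <- function(X, method = "pearson") {
  if (method == "pearson") return(cor(X))
  is_bin <- vapply(seq_len(ncol(X)), function(j) {
    u <- unique(X[, j]); length(u) <= 2L
  }, logical(1))
  R <- cor(X)
  for (i in seq_len(ncol(X))) for (j in seq_len(ncol(X))) {
    if (j <= i) next
    r <- if (is_bin[i] && is_bin[j]) .tetrachoric(X[, i], X[, j])
         else if (is_bin[i]) .biserial(X[, j], X[, i])
         else if (is_bin[j]) .biserial(X[, i], X[, j])
         else R[i, j]
    if (!is.na(r)) R[i, j] <- R[j, i] <- r
  }
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-6) {
    vals <- pmax(ev$values, 1e-6)
    R <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    D <- diag(1 / sqrt(diag(R)))
    R <- D %*% R %*% D
    dimnames(R) <- list(colnames(X), colnames(X))
  }
  R
}

#' Fit the exploratory factor model
#'
#' Maximum-likelihood factor extraction from the risk-variable
#' correlation matrix, orthogonal (varimax) rotation, regression
#' (Thomson) factor scores, and the derived high-loading covariate
#' assignment at `loading_threshold` (compared on `|loading|`). The
#' sign convention fixes the largest-|loading| variable of each factor
#' to load positively.
#'
#' @param phenotypes complete (post-imputation) phenotype data.frame.
#' @param n_factors number of factors.
#' @param loading_threshold |loading| above which a variable is
#'   "assigned" to a factor (and the factor later enters that
#'   variable's covariate set).
#' @param cor_method `"pearson"` (default: Pearson on 0/1-coded
#'   binaries) or `"latent"` (tetrachoric/biserial correlations,
#'   appropriate when binaries arise by thresholding latent normals).
#' @param rotation `"varimax"` or `"none"`.
#' @param rv_names risk-variable columns to analyze; defaults to the
#'   nine neonatal variables present in `phenotypes`.
#' @return Object of class `factor_model`: loadings, uniquenesses,
#'   factor `scores`, `assignment` (variable -> factor names),
#'   correlation matrix and metadata (including the score method).
#' @export
fit_factor_model <- function(phenotypes, n_factors = 2L,
                             loading_threshold = 0.3,
                             cor_method = c("pearson", "latent"),
                             rotation = c("varimax", "none"),
                             rv_names = NULL) {
  cor_method <- match.arg(cor_method)
  rotation <- match.arg(rotation)
  if (is.null(rv_names))
    rv_names <- intersect(.RV_NAMES, names(phenotypes))
  if (length(rv_names) < 2L * n_factors + 1L)
    stop("too few risk variables for the requested number of factors")
  X <- data.matrix(phenotypes[rv_names])
  if (anyNA(X))
    stop("phenotypes contain missing values; impute before fitting")
  n <- nrow(X)
  if (n <= 50)
    stop("factor analysis requires more than 50 samples")
  R <- .mixed_cor(X, cor_method)
  if (!all(is.finite(R)) || abs(det(R)) < 1e-12)
    stop("singular correlation matrix; factor model not identifiable")
  fa <- factanal(covmat = R, factors = n_factors, rotation = "none",
                 n.obs = n)
  L <- unclass(fa$loadings)
  if (rotation == "varimax" && n_factors > 1L) {
    rot <- varimax(L)
    L <- unclass(rot$loadings)
  }
  uniq <- fa$uniquenesses
  if (any(uniq <= 0.005 + 1e-8))
    warning("Heywood case: uniqueness at boundary for ",
            paste(names(uniq)[uniq <= 0.005 + 1e-8], collapse = ", "))
  colnames(L) <- paste0("factor", seq_len(n_factors))
  ## sign convention: top-|loading| variable positive per factor
  for (j in seq_len(n_factors)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  Z <- scale(X)
  scores <- Z %*% solve(R, L)  # regression (Thomson) method
  colnames(scores) <- colnames(L)
  assignment <- lapply(setNames(rownames(L), rownames(L)), function(v) {
    colnames(L)[abs(L[v, ]) > loading_threshold]
  })
  structure(list(loadings = L,
                 uniquenesses = uniq,
                 scores = scores,
                 loading_threshold = loading_threshold,
                 assignment = assignment,
                 correlation = R,
                 cor_method = cor_method,
                 rotation = rotation,
                 score_method = "regression",
                 n = n),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("factor_model: %d variables, %d factors (%s, %s rotation)\n",
              nrow(x$loadings), ncol(x$loadings), x$cor_method, x$rotation))
  print(round(x$loadings, 3))
  high <- names(Filter(length, x$assignment))
  cat(sprintf("|loading| > %.2g: %s\n", x$loading_threshold,
              if (length(high)) paste(high, collapse = ", ") else "none"))
  invisible(x)
}

#' Derive the per-variable analysis plan
#'
#' One analysis unit per risk variable and one per factor. Units for
#' variables loading high (|loading| above the model's threshold) on a
#' factor include that factor as a covariate, isolating the variable's
#' unique effect; factor units never include a factor covariate.
#' Every unit additionally carries the standard covariate set (sex,
#' batch, methylation PCs, cell proportions), applied downstream.
#'
#' @param model a [fit_factor_model()] result.
#' @param base_covariates names of the phenotype covariate columns.
#' @return Object of class `analysis_plan`: list of units, each a
#'   list with `unit`, `outcome`, `outcome_type` ("risk_variable" or
#'   "factor") and `factor_covariates`.
#' @export
derive_analysis_plan <- function(model, base_covariates = c("sex", "batch")) {
  stopifnot(inherits(model, "factor_model"))
  units <- list()
  for (v in rownames(model$loadings)) {
    units[[v]] <- list(unit = v, outcome = v,
                       outcome_type = "risk_variable",
                       factor_covariates = model$assignment[[v]])
  }
  for (f in colnames(model$loadings)) {
    units[[f]] <- list(unit = f, outcome = f,
                       outcome_type = "factor",
                       factor_covariates = character(0))
  }
  structure(units, class = "analysis_plan",
            base_covariates = base_covariates,
            loading_threshold = model$loading_threshold)
}

#' @export
print.analysis_plan <- function(x, ...) {
  cat(sprintf("analysis_plan: %d units\n", length(x)))
  for (u in x)
    cat(sprintf("  %-16s [%s]%s\n", u$unit, u$outcome_type,
                if (length(u$factor_covariates))
                  paste0(" + ", paste(u$factor_covariates, collapse = ", "))
                else ""))
  invisible(x)
}

#' @export
as.data.frame.analysis_plan <- function(x, ...) {
  data.frame(unit = vapply(x, `[[`, "", "unit"),
             outcome_type = vapply(x, `[[`, "", "outcome_type"),
             factor_covariates = vapply(x, function(u)
               paste(u$factor_covariates, collapse = ","), ""),
             row.names = NULL, stringsAsFactors = FALSE)
}
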