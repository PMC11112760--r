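## Shared helpers for the test suite: all fixtures are built in code.

## Align an estimated loading matrix to a reference: for each
## reference column, pick the best-matching estimated column and flip
## its sign if needed.
align_loadings <- function(Lhat, Lref) {
  out <- matrix(NA_real_, nrow(Lref), ncol(Lref),
                dimnames = dimnames(Lref))
  for (j in seq_len(ncol(Lref))) {
    cc <- cor(Lref[, j], Lhat)
    k <- which.max(abs(cc))
    out[, j] <- Lhat[, k] * sign(cc[k])
  }
  out
}

## Small simulated dataset for unit tests.
small_sim <- function(n = 120, p = 200, seed = 1, ...) {
  simulate_dataset(sim_config(n_samples = n, n_cpgs = p, seed = seed, ...))
}

## sex/batch covariate matrix for a phenotype table.
sexbatch <- function(pheno) {
  ctmwas:::.covariate_matrix(pheno, c("sex", "batch"))
}

## Brute-force BH step-up q-values (independent min-over-suffix
## oracle).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(vapply(i:m, function(j) p[o[j]] * m / j, 0), 1)
  }
  q
}

## Exact hypergeometric upper tail by combinatorial enumeration.
hyper_tail_oracle <- function(overlap, set_size, bg_size, query_size) {
  if (overlap == 0) return(1)
  xs <- overlap:min(set_size, query_size)
  sum(choose(set_size, xs) * choose(bg_size - set_size, query_size - xs)) /
    choose(bg_size, query_size)
}
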