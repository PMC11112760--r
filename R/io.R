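## Format readers and writers. All tabular outputs are TSV (UTF-8,
## '.' decimal), prefixed with '#'-comment header lines carrying the
## run seed and config hash so every artifact is traceable to its run.

.hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  ## version 2 serialization is stable across R >= 3.5 sessions
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

.header_lines <- function(seed = NULL, config_hash = NULL) {
  c(sprintf("# ctmwas v%s",
            as.character(utils::packageVersion("ctmwas"))),
    if (!is.null(seed)) sprintf("# seed=%s", seed),
    if (!is.null(config_hash)) sprintf("# config=%s", config_hash))
}

.write_tsv <- function(df, path, seed = NULL, config_hash = NULL,
                       row_names = FALSE) {
  df <- as.data.frame(df)
  for (j in seq_along(df))  # 17 significant digits: doubles round-trip
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.header_lines(seed, config_hash), con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = row_names, col.names = TRUE)
}

.read_tsv <- function(path, ...) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write a methylation matrix as TSV plus BED sidecar
#'
#' The value file has one row per CpG (first column `cpg`, then one
#' column per sample); the sidecar is 4-column BED (chrom, start, end,
#' cpg; 0-based half-open), row-aligned with the value file.
#'
#' @param meth a [methylation_matrix()].
#' @param path_values output TSV path.
#' @param path_bed output BED path.
#' @param seed,config_hash recorded in the file headers.
#' @export
write_methylation <- function(meth, path_values, path_bed,
                              seed = NULL, config_hash = NULL) {
  stopifnot(inherits(meth, "MethylationMatrix"))
  df <- data.frame(cpg = meth$coords$cpg, t(meth$values),
                   check.names = FALSE)
  .write_tsv(df, path_values, seed, config_hash)
  bed <- meth$coords[c("chrom", "start", "end", "cpg")]
  con <- file(path_bed, "w", encoding = "UTF-8")
  writeLines(.header_lines(seed, config_hash), con)
  write.table(bed, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(c(path_values, path_bed))
}

#' Read a methylation matrix from TSV plus BED sidecar
#'
#' Validates that the BED rows align one-to-one with the value rows
#' (same count, same CpG ids in the same order), that intervals are
#' well formed, and that no position is duplicated. Malformed BED
#' lines are reported with their line number.
#'
#' @param path_values TSV of CpG rows x sample columns (first column
#'   `cpg`).
#' @param path_bed 3- or 4-column BED sidecar (0-based half-open).
#' @return A [methylation_matrix()].
#' @export
read_methylation <- function(path_values, path_bed) {
  vals <- .read_tsv(path_values)
  if (names(vals)[1] != "cpg")
    stop("methylation TSV must have 'cpg' as its first column")
  raw <- readLines(path_bed, encoding = "UTF-8")
  keep <- !grepl("^#", raw) & nzchar(raw)
  lineno <- which(keep)
  fields <- strsplit(raw[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("malformed BED line %d: fewer than 3 fields",
                 lineno[which(nf < 3L)[1]]))
  bed <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L))),
    end = suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L))),
    stringsAsFactors = FALSE)
  bad <- which(is.na(bed$start) | is.na(bed$end))
  if (length(bad))
    stop(sprintf("malformed BED line %d: non-numeric coordinates",
                 lineno[bad[1]]))
  bad <- which(bed$end <= bed$start)
  if (length(bad))
    stop(sprintf("malformed BED line %d: end <= start", lineno[bad[1]]))
  bed$cpg <- if (all(nf >= 4L)) vapply(fields, `[[`, "", 4L) else
    as.character(vals$cpg)
  if (nrow(bed) != nrow(vals))
    stop(sprintf("BED has %d rows but the value matrix has %d",
                 nrow(bed), nrow(vals)))
  if (!identical(as.character(bed$cpg), as.character(vals$cpg)))
    stop("CpG order differs between the BED sidecar and the value ",
         "matrix; refusing to reorder silently")
  values <- t(as.matrix(vals[, -1L, drop = FALSE]))
  methylation_matrix(values, bed, sample_ids = names(vals)[-1L])
}

#' Write / read a phenotype table
#' @param phenotypes phenotype data.frame.
#' @param path TSV path.
#' @param seed,config_hash recorded in the file header.
#' @export
write_phenotypes <- function(phenotypes, path, seed = NULL,
                             config_hash = NULL) {
  .write_tsv(phenotypes, path, seed, config_hash)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  ph <- .read_tsv(path)
  if ("batch" %in% names(ph)) ph$batch <- factor(ph$batch)
  ph
}

#' Write / read a cell-proportion table
#' @param proportions a [cell_proportions()] matrix.
#' @param path TSV path.
#' @param seed,config_hash recorded in the file header.
#' @export
write_proportions <- function(proportions, path, seed = NULL,
                              config_hash = NULL) {
  df <- data.frame(sample_id = rownames(proportions),
                   unclass(proportions), check.names = FALSE)
  .write_tsv(df, path, seed, config_hash)
  invisible(path)
}

#' @rdname write_proportions
#' @export
read_proportions <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  rownames(m) <- df$sample_id
  cell_proportions(m)
}

#' Write the generator ground truth as JSON
#' @param truth truth list from [simulate_dataset()].
#' @param path output JSON path.
#' @export
write_truth <- function(truth, path) {
  keep <- truth[setdiff(names(truth), "mu")]
  jsonlite::write_json(keep, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", matrix = "rowmajor")
  invisible(path)
}

#' Write an MWAS result table as TSV
#' @param result an `mwas_result`.
#' @param path output TSV path.
#' @param seed,config_hash recorded in the file header.
#' @export
write_mwas_result <- function(result, path, seed = NULL,
                              config_hash = NULL) {
  stopifnot(inherits(result, "mwas_result"))
  .write_tsv(result$table, path, seed, config_hash)
  invisible(path)
}
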