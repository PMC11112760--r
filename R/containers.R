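#' Methylation matrix container
#'
#' Couples a samples x CpGs value matrix with per-CpG genomic
#' coordinates (0-based, half-open, BED convention). Values are on an
#' arbitrary coverage-derived abundance scale; no missing values are
#' allowed. CpGs are kept sorted by (chromosome, position) and the
#' value columns are reordered along with the coordinates.
#'
#' @param values numeric matrix, samples in rows, CpGs in columns.
#' @param coords data.frame with columns `chrom`, `start`, `end` (and
#'   optionally `cpg` ids), one row per CpG, 0-based half-open.
#' @param sample_ids character vector of sample identifiers; defaults
#'   to `rownames(values)`.
#' @return An object of class `MethylationMatrix`: list with elements
#'   `values`, `coords`, `sample_ids`.
#' @export
methylation_matrix <- function(values, coords, sample_ids = rownames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("methylation values must be numeric")
  if (anyNA(values))
    stop("methylation values contain missing entries")
  coords <- as.data.frame(coords)
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(coords)))
    stop("coords must have columns chrom, start, end")
  if (nrow(coords) != ncol(values))
    stop(sprintf("coordinate rows (%d) do not match value columns (%d)",
                 nrow(coords), ncol(values)))
  if (any(coords$end <= coords$start))
    stop("BED intervals must satisfy start < end")
  if (is.null(coords$cpg)) {
    coords$cpg <- if (!is.null(colnames(values))) colnames(values) else
      sprintf("cpg%06d", seq_len(nrow(coords)))
  }
  if (anyDuplicated(coords[c("chrom", "start")]))
    stop("duplicate CpG positions are not allowed")
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%04d", seq_len(nrow(values)))
  if (length(sample_ids) != nrow(values))
    stop("sample_ids length does not match the number of rows")
  o <- order(coords$chrom, coords$start)
  if (is.unsorted(o)) {
    values <- values[, o, drop = FALSE]
    coords <- coords[o, , drop = FALSE]
    rownames(coords) <- NULL
  }
  colnames(values) <- coords$cpg
  rownames(values) <- sample_ids
  structure(list(values = values, coords = coords,
                 sample_ids = sample_ids),
            class = "MethylationMatrix")
}

#' @export
print.MethylationMatrix <- function(x, ...) {
  cat(sprintf("MethylationMatrix: %d samples x %d CpGs (%s..%s)\n",
              nrow(x$values), ncol(x$values),
              x$coords$chrom[1], x$coords$chrom[nrow(x$coords)]))
  invisible(x)
}

#' @export
dim.MethylationMatrix <- function(x) dim(x$values)

## Accept either a MethylationMatrix or a plain samples x CpGs matrix.
.meth_values <- function(meth) {
  if (inherits(meth, "MethylationMatrix")) meth$values else as.matrix(meth)
}

.meth_coords <- function(meth) {
  if (inherits(meth, "MethylationMatrix")) meth$coords else NULL
}

#' Cell-proportion container
#'
#' Validates a samples x cell-types fraction matrix: entries in `[0, 1]`,
#' rows summing to one within `tol`.
#'
#' @param values numeric matrix of fractions, samples in rows.
#' @param cell_types column (cell-type) names; defaults to the
#'   six-type blood panel.
#' @param tol row-sum tolerance.
#' @return Numeric matrix of class `CellProportions`.
#' @export
cell_proportions <- function(values, cell_types = NULL, tol = 1e-6) {
  values <- as.matrix(values)
  if (is.null(cell_types))
    cell_types <- if (!is.null(colnames(values))) colnames(values) else
      .CELL_TYPES[seq_len(ncol(values))]
  colnames(values) <- cell_types
  if (anyNA(values) || any(values < 0) || any(values > 1))
    stop("cell proportions must lie in [0, 1] with no missing values")
  if (nrow(values) > 0 && any(abs(rowSums(values) - 1) > tol))
    stop("cell-proportion rows must sum to 1")
  class(values) <- c("CellProportions", class(values))
  values
}
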