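## Phase 2C: CpG-to-gene linking and hypergeometric gene-set
## enrichment against user-supplied GMT sets.

#' Read a gene annotation (BED or GFF3)
#'
#' Thin wrapper over `rtracklayer::import()`. For GFF3, records of
#' type "gene" are kept and named from `gene_name`, `Name` or `ID`;
#' for BED the name column is used.
#'
#' @param path annotation file (`.bed`, `.gff`, `.gff3`).
#' @return A named `GRanges` of gene loci.
#' @export
read_gene_annotation <- function(path) {
  ext <- tolower(tools::file_ext(path))
  gr <- rtracklayer::import(path)
  if (ext %in% c("gff", "gff3", "gtf")) {
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(gr$type == "gene"))
      gr <- gr[gr$type == "gene"]
    nm <- S4Vectors::mcols(gr)
    name <- if ("gene_name" %in% names(nm)) nm$gene_name
            else if ("Name" %in% names(nm)) nm$Name
            else nm$ID
    names(gr) <- as.character(name)
  } else {
    names(gr) <- gr$name
  }
  if (anyNA(names(gr)) || any(names(gr) == ""))
    stop("annotation records must carry gene names")
  gr
}

## Coerce CpG input (MethylationMatrix, 0-based coords data.frame, or
## GRanges) to a GRanges of 1-based CpG positions.
.cpg_granges <- function(cpgs) {
  if (methods::is(cpgs, "GRanges")) return(cpgs)
  co <- if (inherits(cpgs, "MethylationMatrix")) cpgs$coords
        else as.data.frame(cpgs)
  GenomicRanges::GRanges(
    seqnames = co$chrom,
    ranges = IRanges::IRanges(start = co$start + 1L, end = co$start + 1L),
    cpg = if (!is.null(co$cpg)) co$cpg else
      sprintf("cpg%06d", seq_len(nrow(co))))
}

#' Link CpGs to genes within a flanking window
#'
#' A CpG links to every gene whose body, extended by `flank` bp on
#' both sides, contains its position; strand is ignored (CpG
#' methylation is strand-symmetric). CpGs linked to no gene are
#' labeled intergenic.
#'
#' @param cpgs a [methylation_matrix()], a 0-based coordinate
#'   data.frame (`chrom`, `start`, `end`), or a `GRanges`.
#' @param annotation named `GRanges` of gene loci (auto-sorted with a
#'   warning if unsorted).
#' @param flank flanking distance in bp (default 10000).
#' @return Named list, one character vector of gene names per CpG
#'   (empty = intergenic); attribute `intergenic` gives the labels of
#'   unlinked CpGs.
#' @export
link_cpgs_to_genes <- function(cpgs, annotation, flank = 10000L) {
  stopifnot(flank >= 0)
  q <- .cpg_granges(cpgs)
  if (!length(intersect(as.character(GenomeInfoDb::seqnames(q)),
                        as.character(GenomeInfoDb::seqnames(annotation)))))
    stop("no shared chromosome names between CpGs and annotation; ",
         "are they on the same assembly?")
  if (S4Vectors::isSorted(annotation) == FALSE) {
    warning("annotation was unsorted; sorting")
    annotation <- GenomicRanges::sort(annotation, ignore.strand = TRUE)
  }
  win <- suppressWarnings(GenomicRanges::resize(
    annotation, GenomicRanges::width(annotation) + 2L * flank,
    fix = "center"))
  GenomicRanges::start(win) <- pmax(GenomicRanges::start(win), 1L)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, win, ignore.strand = TRUE))
  ids <- if (!is.null(q$cpg)) as.character(q$cpg) else
    as.character(seq_along(q))
  links <- split(names(win)[S4Vectors::subjectHits(hits)],
                 factor(S4Vectors::queryHits(hits), levels = seq_along(q)))
  links <- lapply(links, function(g) sort(unique(g)))
  names(links) <- ids
  attr(links, "intergenic") <- ids[lengths(links) == 0L]
  links
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided (upper-tail) hypergeometric test of query-gene overlap
#' with each set, against a stated background universe. Sets are
#' intersected with the background before testing; sets with zero
#' overlap are reported with p = 1. q-values are Benjamini-Hochberg
#' across the tested sets.
#'
#' @param query_genes character vector of genes of interest (must be a
#'   subset of `background`).
#' @param gene_sets named list of character vectors (e.g. from
#'   `read_gmt()`).
#' @param background character vector: the gene universe (all genes
#'   linkable to any assayed CpG).
#' @return data.frame (set_name, overlap, set_size, query_size,
#'   background_size, p, q), sorted by p.
#' @export
enrichment_test <- function(query_genes, gene_sets, background) {
  query_genes <- unique(query_genes)
  background <- unique(background)
  if (!length(query_genes)) stop("empty query gene set")
  if (!length(background)) stop("empty background universe")
  extra <- setdiff(query_genes, background)
  if (length(extra))
    stop("query genes missing from the background: ",
         paste(head(extra, 5), collapse = ", "))
  N <- length(background)
  k <- length(query_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(unique(gene_sets[[nm]]), background)
    K <- length(s)
    ov <- length(intersect(s, query_genes))
    p <- if (ov == 0L) 1 else phyper(ov - 1L, K, N - K, k,
                                     lower.tail = FALSE)
    data.frame(set_name = nm, overlap = ov, set_size = K,
               query_size = k, background_size = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out[order(out$p, out$set_name), , drop = FALSE]
}

#' Link suggestive MWAS findings to genes and test enrichment
#'
#' Convenience wrapper for Phase 2C: collects CpGs with p below
#' `suggestive_p` from an `mwas_result`, links them to genes, and
#' tests enrichment against all gene sets, with the background taken
#' as every gene linkable to any assayed CpG.
#'
#' @param result an `mwas_result`.
#' @param meth the [methylation_matrix()] the scan was run on.
#' @param annotation named `GRanges` of gene loci.
#' @param gene_sets named list of gene sets.
#' @param flank linking window (bp).
#' @param suggestive_p suggestive threshold.
#' @return list: `query_genes`, `n_intergenic`, `enrichment`
#'   (data.frame, `NULL` when no suggestive CpG links to a gene).
#' @export
enrich_suggestive <- function(result, meth, annotation, gene_sets,
                              flank = 10000L, suggestive_p = 1e-6) {
  stopifnot(inherits(result, "mwas_result"))
  links_all <- link_cpgs_to_genes(meth, annotation, flank = flank)
  background <- sort(unique(unlist(links_all)))
  sel <- !is.na(result$table$p) & result$table$p < suggestive_p
  cpg_ids <- result$table$cpg[sel]
  links <- links_all[as.character(cpg_ids)]
  query <- sort(unique(unlist(links)))
  enr <- if (length(query))
    enrichment_test(query, gene_sets, background) else NULL
  list(query_genes = query,
       n_intergenic = sum(lengths(links) == 0L),
       n_suggestive = length(cpg_ids),
       background_size = length(background),
       enrichment = enr)
}
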