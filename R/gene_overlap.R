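#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

calls_granges <- function(calls) {
  GenomicRanges::GRanges(calls$chrom, IRanges::IRanges(calls$start, calls$end))
}

exons_granges <- function(genes) {
  GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(genes$start, genes$end))
}

#' Map CNV calls to the genes whose exons they impact
#'
#' A call impacts a gene when it overlaps at least one base pair of at
#' least one of the gene's exons (UTR exons count the same as coding
#' exons).
#'
#' @param calls CNV call data frame.
#' @param genes exon-level gene-model data frame.
#' @return data frame with one row per (call, gene) pair: `call_row` (row
#'   index into `calls`) and `gene_id`.
#' @export
cnv_gene_hits <- function(calls, genes) {
  if (!nrow(calls) || !nrow(genes))
    return(data.frame(call_row = integer(0), gene_id = character(0),
                      stringsAsFactors = FALSE))
  hits <- GenomicRanges::findOverlaps(calls_granges(calls), exons_granges(genes))
  pairs <- unique(data.frame(call_row = S4Vectors::queryHits(hits),
                             gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
                             stringsAsFactors = FALSE))
  rownames(pairs) <- NULL
  pairs[order(pairs$call_row, pairs$gene_id), , drop = FALSE]
}

#' Count impacted genes per CNV call
#'
#' @inheritParams cnv_gene_hits
#' @return integer vector parallel to the rows of `calls`: the number of
#'   genes with at least one exon overlapped by each call.
#' @export
cnv_gene_counts <- function(calls, genes) {
  hits <- cnv_gene_hits(calls, genes)
  counts <- integer(nrow(calls))
  if (nrow(hits)) {
    tab <- table(hits$call_row)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  counts
}
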