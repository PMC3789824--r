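mode_states <- function(mode = c("joint", "deletion", "duplication")) {
  mode <- match.arg(mode)
  switch(mode, joint = c("deletion", "duplication"), deletion = "deletion",
         duplication = "duplication")
}

#' Per-gene carrier counts and combined carrier frequency
#'
#' A sample carries gene `g` (in the selected copy-state mode) when at
#' least one of its in-mode calls overlaps at least one exon of `g`; a
#' sample is counted at most once per gene.  The combined frequency is
#' `(patient carriers + control carriers) / (n patients + n controls)`,
#' the denominator taken from the supplied sample table, which should hold
#' exactly the control set plus the patient group under analysis.
#'
#' @param calls filtered and merged CNV call data frame.
#' @param genes exon-level gene-model data frame.
#' @param samples sample data frame; samples whose `group` contains
#'   "control" are controls, all others are patients.
#' @param mode one of "joint", "deletion", "duplication".
#' @return data frame with one row per impacted gene: `gene_id`,
#'   `carriers_patients`, `carriers_controls`, `combined_frequency`;
#'   attributes `mode`, `n_patients`, `n_controls`.
#' @export
gene_carrier_counts <- function(calls, genes, samples,
                                mode = c("joint", "deletion", "duplication")) {
  mode <- match.arg(mode)
  missing <- setdiff(unique(calls$sample_id), samples$sample_id)
  if (length(missing))
    stop("calls reference samples absent from the manifest: ",
         paste(utils::head(missing, 5), collapse = ", "))
  is_control <- in_group(samples, "control")
  use <- calls[calls$copy_state %in% mode_states(mode), , drop = FALSE]
  hits <- cnv_gene_hits(use, genes)
  carriers <- unique(data.frame(sample_id = use$sample_id[hits$call_row],
                                gene_id = hits$gene_id,
                                stringsAsFactors = FALSE))
  ctrl_ids <- samples$sample_id[is_control]
  tab_all <- table(carriers$gene_id)
  tab_ctrl <- table(carriers$gene_id[carriers$sample_id %in% ctrl_ids])
  gene_id <- sort(names(tab_all))
  cc <- as.integer(tab_ctrl[gene_id]); cc[is.na(cc)] <- 0L
  cp <- as.integer(tab_all[gene_id]) - cc
  n_p <- sum(!is_control); n_c <- sum(is_control)
  out <- data.frame(gene_id = gene_id, carriers_patients = cp,
                    carriers_controls = cc,
                    combined_frequency = (cp + cc) / (n_p + n_c),
                    stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  attr(out, "n_patients") <- n_p
  attr(out, "n_controls") <- n_c
  out
}

#' Flag rare CNVs by the per-gene carrier-frequency rule
#'
#' A CNV is rare when at least one of the genes it impacts has a combined
#' patient+control carrier frequency strictly below `threshold` in the
#' matching copy-state mode.  Genes absent from the frequency table are
#' treated as frequency zero.
#'
#' @param calls CNV call data frame (in-mode calls; the caller is
#'   responsible for using a table computed in the same mode).
#' @param genes exon-level gene-model data frame.
#' @param freq_table result of [gene_carrier_counts()].
#' @param threshold strict upper frequency bound (default 0.01).
#' @return `calls` with an added logical column `rare`.
#' @export
flag_rare_cnvs <- function(calls, genes, freq_table, threshold = 0.01) {
  hits <- cnv_gene_hits(calls, genes)
  n_genes <- cnv_gene_counts(calls, genes)
  if (any(n_genes == 0))
    stop("CNV overlapping zero genes cannot be rarity-flagged (rows ",
         paste(utils::head(which(n_genes == 0), 5), collapse = ", "), ")")
  freq <- freq_table$combined_frequency[match(hits$gene_id, freq_table$gene_id)]
  freq[is.na(freq)] <- 0
  rare_rows <- unique(hits$call_row[freq < threshold])
  calls$rare <- seq_len(nrow(calls)) %in% rare_rows
  calls
}

#' Genes rare in the combined population
#'
#' @param freq_table result of [gene_carrier_counts()].
#' @param threshold strict upper frequency bound (default 0.01).
#' @return character vector of gene ids with combined frequency strictly
#'   below `threshold`.
#' @export
rare_gene_universe <- function(freq_table, threshold = 0.01) {
  freq_table$gene_id[freq_table$combined_frequency < threshold]
}
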