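#' @importFrom utils read.delim write.table
NULL

# All genomic intervals held in memory are 1-based inclusive.  Only BED I/O
# converts (BED files are 0-based half-open).  CNV lengths follow the
# end - start convention used throughout the reports (NOT end - start + 1),
# so chr5:116416478-120055246 has length 3.64 Mb.

#' Normalize chromosome names to the "chrN" form
#'
#' Adds a "chr" prefix where missing and maps the numeric sex-chromosome
#' codes 23 and 24 to chrX and chrY.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector of normalized names.
#' @export
normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  if (!length(chrom)) return(chrom)
  bare <- sub("^chr", "", chrom)
  bare[bare == "23"] <- "X"
  bare[bare == "24"] <- "Y"
  paste0("chr", bare)
}

cn_to_state <- function(cn) {
  # PennCNV HMM state for the common 6-state model
  c(`0` = 1L, `1` = 2L, `3` = 5L, `4` = 6L)[as.character(cn)]
}

#' Construct a CNV call table
#'
#' The central CNV container is a plain data frame with one row per call.
#' `length_bp` is always derived as `end - start`.
#'
#' @param sample_id,chrom,start,end,copy_number,n_snps,confidence vectors of
#'   equal length (recycled where length one).
#' @return data frame with columns `sample_id`, `chrom`, `start`, `end`,
#'   `copy_state`, `copy_number`, `n_snps`, `confidence`, `length_bp`.
#' @export
cnv_calls <- function(sample_id, chrom, start, end, copy_number,
                      n_snps = 10L, confidence = 100) {
  n <- max(length(sample_id), length(chrom), length(start), length(end),
           length(copy_number))
  df <- data.frame(
    sample_id = rep_len(as.character(sample_id), n),
    chrom = normalize_chrom(rep_len(chrom, n)),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    copy_number = rep_len(as.integer(copy_number), n),
    n_snps = rep_len(as.integer(n_snps), n),
    confidence = rep_len(as.numeric(confidence), n),
    stringsAsFactors = FALSE
  )
  if (any(df$copy_number == 2L))
    stop("copy-neutral call (cn=2) is not a CNV")
  if (!all(df$copy_number %in% c(0L, 1L, 3L, 4L)))
    stop("copy_number must be one of 0, 1, 3, 4")
  if (any(df$end <= df$start))
    stop("CNV end must exceed start (1-based inclusive coordinates)")
  if (any(df$n_snps < 1L)) stop("n_snps must be >= 1")
  df$copy_state <- ifelse(df$copy_number <= 1L, "deletion", "duplication")
  df$length_bp <- df$end - df$start
  df[, c("sample_id", "chrom", "start", "end", "copy_state", "copy_number",
         "n_snps", "confidence", "length_bp")]
}

#' Read PennCNV-style CNV calls
#'
#' Parses the single-sample `rawcnv` dialect, one call per line:
#' `chrN:start-end numsnp=K length=L state S,cn=C <sample> conf=X`.
#' Tokens are whitespace separated; `startsnp=`/`endsnp=` tokens are
#' accepted and ignored; other unknown `key=value` tokens are ignored with
#' a warning.  Copy-neutral lines (`cn=2`) are rejected.
#'
#' @param path path to a text file in the dialect above.
#' @return CNV call data frame (see [cnv_calls()]).
#' @export
read_penncnv_calls <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(cnv_calls(character(0), character(0), integer(0), integer(0),
                     integer(0))[0, ])
  }
  known <- c("numsnp", "length", "startsnp", "endsnp", "conf")
  parse_line <- function(line, lineno) {
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    loc <- regmatches(toks[1],
                      regexec("^(chr)?([0-9XYxy]+):([0-9]+)-([0-9]+)$", toks[1]))[[1]]
    if (!length(loc))
      stop("malformed PennCNV line ", lineno, ": bad locus token '", toks[1], "'")
    fields <- list(chrom = loc[3], start = as.integer(loc[4]),
                   end = as.integer(loc[5]), sample = NA_character_,
                   numsnp = NA_integer_, conf = NA_real_, cn = NA_integer_)
    for (tok in toks[-1]) {
      if (grepl("^state[0-9]+,cn=[0-9]+$", tok)) {
        fields$cn <- as.integer(sub("^state[0-9]+,cn=", "", tok))
      } else if (grepl("=", tok, fixed = TRUE)) {
        key <- sub("=.*$", "", tok)
        val <- sub("^[^=]*=", "", tok)
        if (key == "numsnp") fields$numsnp <- as.integer(val)
        else if (key == "conf") fields$conf <- as.numeric(val)
        else if (!key %in% known)
          warning("line ", lineno, ": ignoring unknown token '", tok, "'")
      } else if (is.na(fields$sample)) {
        fields$sample <- tok
      }
    }
    if (is.na(fields$cn))
      stop("malformed PennCNV line ", lineno, ": missing state/cn token")
    if (fields$cn == 2L)
      stop("copy-neutral call (cn=2) at line ", lineno)
    if (is.na(fields$sample))
      stop("malformed PennCNV line ", lineno, ": missing sample identifier")
    if (is.na(fields$numsnp))
      stop("malformed PennCNV line ", lineno, ": missing numsnp")
    fields
  }
  parsed <- lapply(seq_along(lines), function(i) parse_line(lines[i], i))
  cnv_calls(
    sample_id = vapply(parsed, `[[`, "", "sample"),
    chrom = vapply(parsed, `[[`, "", "chrom"),
    start = vapply(parsed, `[[`, 0L, "start"),
    end = vapply(parsed, `[[`, 0L, "end"),
    copy_number = vapply(parsed, `[[`, 0L, "cn"),
    n_snps = vapply(parsed, `[[`, 0L, "numsnp"),
    confidence = vapply(parsed, function(p) {
      if (is.na(p$conf)) 0 else p$conf
    }, 0)
  )
}

#' Write CNV calls in the PennCNV dialect
#'
#' Inverse of [read_penncnv_calls()]: `read(write(x))` reproduces `x`.
#'
#' @param calls CNV call data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_penncnv_calls <- function(calls, path) {
  lines <- sprintf(
    "%s:%d-%d numsnp=%d length=%s state%d,cn=%d %s conf=%s",
    calls$chrom, calls$start, calls$end, calls$n_snps,
    formatC(calls$length_bp, format = "d", big.mark = ","),
    cn_to_state(calls$copy_number), calls$copy_number, calls$sample_id,
    format(calls$confidence, trim = TRUE, digits = 15, scientific = FALSE)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a BED-like annotation file
#'
#' Rows are `chrom<TAB>start<TAB>end<TAB>gene_id`, one exon (UTRs included)
#' per row, declared 0-based half-open; coordinates are converted to
#' 1-based inclusive on read.  Exons are grouped by gene, sorted, and
#' overlapping exons of the same gene are collapsed.
#'
#' @param path path to the annotation file.
#' @return exon-level data frame with columns `gene_id`, `chrom`, `start`,
#'   `end` (1-based inclusive), one row per normalized exon.
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("gene BED needs >= 4 columns (chrom, start, end, gene_id)")
  names(df)[1:4] <- c("chrom", "start", "end", "gene_id")
  if (any(df$start < 0) || any(df$end < 0)) stop("negative coordinate in BED")
  if (any(df$end <= df$start)) stop("BED exon with end <= start")
  gene_models(gene_id = df$gene_id, chrom = df$chrom,
              start = df$start + 1L, end = df$end)
}

#' Construct a normalized gene-model table
#'
#' @param gene_id,chrom,start,end parallel vectors, one exon per element,
#'   1-based inclusive coordinates.
#' @return exon-level data frame sorted by gene then position, with
#'   overlapping or book-ended exons of the same gene collapsed.
#' @export
gene_models <- function(gene_id, chrom, start, end) {
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = normalize_chrom(chrom),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (any(df$end < df$start)) stop("exon end < start")
  if (anyNA(df)) stop("NA in gene model fields")
  chrom_per_gene <- tapply(df$chrom, df$gene_id, function(x) length(unique(x)))
  if (any(chrom_per_gene > 1)) stop("a gene spans multiple chromosomes")
  if (!nrow(df)) return(df)
  # collapse overlapping/book-ended exons per gene in one vectorized pass,
  # using the gene id as the sequence name
  gr <- GenomicRanges::GRanges(df$gene_id, IRanges::IRanges(df$start, df$end))
  red <- GenomicRanges::reduce(gr)
  gid <- as.character(GenomicRanges::seqnames(red))
  chrom_of <- df$chrom[!duplicated(df$gene_id)]
  names(chrom_of) <- df$gene_id[!duplicated(df$gene_id)]
  out <- data.frame(gene_id = gid, chrom = unname(chrom_of[gid]),
                    start = GenomicRanges::start(red),
                    end = GenomicRanges::end(red), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write gene models as a BED-like annotation file
#'
#' Inverse of [read_gene_bed()] (coordinates converted back to 0-based
#' half-open).
#'
#' @param genes exon-level gene-model data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  write.table(
    data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene_id),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read a sample manifest
#'
#' Tab-separated with a header; required columns `sample_id` and `group`
#' (multiple group labels separated by ";"), optional QC-metric and trio
#' columns (`ethnicity`, `call_rate`, `lrr_sd`, `gcwf`, `cnv_call_count`,
#' `father_id`, `mother_id`).
#'
#' @param path path to the manifest.
#' @return sample data frame.
#' @export
read_sample_manifest <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("sample manifest needs 'sample_id' and 'group' columns")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in manifest")
  if ("call_rate" %in% names(df) &&
      any(df$call_rate < 0 | df$call_rate > 1, na.rm = TRUE))
    stop("call_rate must lie in [0, 1]")
  df
}

#' Test group membership of samples
#'
#' @param samples sample data frame.
#' @param group group label, e.g. "control".
#' @return logical vector, TRUE where the sample's ";"-separated `group`
#'   field contains `group`.
#' @export
in_group <- function(samples, group) {
  vapply(strsplit(samples$group, ";", fixed = TRUE),
         function(g) group %in% g, NA)
}

#' Read a labeled region file (BED)
#'
#' For blacklists of polymorphic regions and catalogs of known disease
#' regions: `chrom<TAB>start<TAB>end[<TAB>name]`, 0-based half-open.
#'
#' @param path path to the BED file.
#' @return data frame with `chrom`, `start`, `end` (1-based inclusive) and
#'   `name`.
#' @export
read_regions_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  df$name <- if (ncol(df) >= 4) as.character(df[[4]]) else
    sprintf("region_%04d", seq_len(nrow(df)))
  if (any(df$end <= df$start)) stop("region with end <= start")
  data.frame(chrom = normalize_chrom(df$chrom), start = df$start + 1L,
             end = df$end, name = df$name, stringsAsFactors = FALSE)
}

#' Read a reference CNV list
#'
#' Tab-separated with header columns `cnv_id`, `chrom`, `start`, `end`,
#' `copy_state`, `genes` (";"-separated gene ids; must be non-empty for
#' gene-based overlap).
#'
#' @param path path to the reference list.
#' @return data frame of reference CNVs.
#' @export
read_reference_cnvs <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("cnv_id", "chrom", "start", "end", "copy_state", "genes")
  if (!all(need %in% names(df)))
    stop("reference CNV list needs columns: ", paste(need, collapse = ", "))
  if (any(!nzchar(df$genes)))
    stop("reference CNV with empty gene list: ",
         paste(df$cnv_id[!nzchar(df$genes)], collapse = ", "))
  df$chrom <- normalize_chrom(df$chrom)
  df
}

#' Write an analysis report as tab-separated text
#'
#' Writes a header even for empty inputs.  Numeric columns are emitted
#' with 15 significant digits so that re-reading reproduces them to within
#' 1e-9.  Row order is taken as given; report builders sort their output
#' deterministically before calling this.
#'
#' @param results data frame (possibly zero rows).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  out <- results
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- format(out[[j]], digits = 15, trim = TRUE, scientific = TRUE)
  }
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write report to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path path to the TSV report.
#' @return data frame.
#' @export
read_report <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
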