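# qPCR relative quantification (delta-delta-Ct), copy-state calling
# against the 0.7 / 1.3 thresholds, and trio inheritance classification.
#
# A panel is a long-format data frame of raw Ct values with columns:
#   sample_id   individual measured in the well (test sample or calibrator)
#   locus_id    CNV locus under test
#   assay       primer-pair id (target) or reference-gene name
#   assay_class "target" or "reference"
#   role        "test" or "calibrator"
#   replicate   1..3
#   ct          cycle-threshold value

#' Relative quantities by the delta-delta-Ct method
#'
#' For every combination of target primer pair, reference gene and
#' calibrator individual: `dCt_sample = mean Ct(target) - mean
#' Ct(reference)` in the test sample, the same in the calibrator, and
#' `RQ = 2^-(dCt_sample - dCt_calibrator)`.  With at least 2 primers, 2
#' reference genes and 2 calibrators this yields at least 8 RQ values.
#'
#' @param panel long-format Ct data frame (see above) for one (sample,
#'   locus).
#' @return data frame with one row per (primer, reference, calibrator)
#'   combination and an `rq` column.
#' @export
compute_rq <- function(panel) {
  need <- c("sample_id", "locus_id", "assay", "assay_class", "role",
            "replicate", "ct")
  if (!all(need %in% names(panel)))
    stop("panel needs columns: ", paste(need, collapse = ", "))
  if (anyNA(panel$ct)) {
    bad <- panel[is.na(panel$ct), ]
    stop("missing Ct in well ",
         paste(bad$sample_id, bad$assay, bad$replicate, sep = "/",
               collapse = ", "))
  }
  counts <- table(paste(panel$sample_id, panel$assay, sep = "\r"))
  if (any(counts < 3)) {
    bad <- names(counts)[counts < 3]
    stop("missing replicate for well ",
         paste(gsub("\r", "/", bad), collapse = ", "))
  }
  primers <- sort(unique(panel$assay[panel$assay_class == "target"]))
  refs <- sort(unique(panel$assay[panel$assay_class == "reference"]))
  cals <- sort(unique(panel$sample_id[panel$role == "calibrator"]))
  test_id <- unique(panel$sample_id[panel$role == "test"])
  if (length(test_id) != 1) stop("panel must contain exactly one test sample")
  if (length(primers) < 2 || length(refs) < 2 || length(cals) < 2)
    stop("panel needs >= 2 primers, >= 2 reference genes, >= 2 calibrators")
  if (length(cals) > 4) stop("panel allows at most 4 calibrators")
  mean_ct <- function(id, assay)
    mean(panel$ct[panel$sample_id == id & panel$assay == assay])
  grid <- expand.grid(primer = primers, reference = refs, calibrator = cals,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$rq <- mapply(function(p, r, cal) {
    dct_s <- mean_ct(test_id, p) - mean_ct(test_id, r)
    dct_c <- mean_ct(cal, p) - mean_ct(cal, r)
    2^(-(dct_s - dct_c))
  }, grid$primer, grid$reference, grid$calibrator)
  grid$sample_id <- test_id
  grid$locus_id <- panel$locus_id[1]
  grid
}

#' Copy-state call from a set of RQ values
#'
#' The 95% confidence interval of the mean RQ uses the t distribution
#' (small n).  The call is `normal` when the interval lies inside
#' (`lower`, `upper`) = (0.7, 1.3), `deletion` when entirely below the
#' lower threshold, `duplication` when entirely above the upper one, and
#' `inconclusive` when the interval straddles a threshold.
#'
#' @param rqs numeric vector of at least 8 RQ values.
#' @param lower,upper RQ thresholds (defaults 0.7 and 1.3).
#' @return list with `rq_values`, `mean_rq`, `ci_low`, `ci_high`, `call`.
#' @export
call_copy_state <- function(rqs, lower = 0.7, upper = 1.3) {
  n <- length(rqs)
  if (n < 8) stop("insufficient replicates: need >= 8 RQ values, got ", n)
  m <- mean(rqs)
  half <- qt(0.975, n - 1) * sd(rqs) / sqrt(n)
  lo <- m - half; hi <- m + half
  call <- if (lo > lower && hi < upper) "normal"
  else if (hi < lower) "deletion"
  else if (lo > upper) "duplication"
  else "inconclusive"
  list(rq_values = rqs, mean_rq = m, ci_low = lo, ci_high = hi, call = call)
}

#' Trio inheritance classification of a qPCR-tested CNV
#'
#' A child called `normal` means the array call was not confirmed
#' (`false_positive`).  A confirmed (non-normal) child call is `de_novo`
#' when both parents were tested and called normal, `inherited` when at
#' least one parent shares the same non-normal state, and
#' `not_determined` otherwise (a parent missing or inconclusive, or
#' conclusive parents that neither share the state nor are both normal).
#'
#' @param child result of [call_copy_state()] for the child.
#' @param father,mother results for the parents, or NULL when no DNA was
#'   available.
#' @return one of `de_novo`, `inherited`, `not_determined`,
#'   `false_positive`.
#' @export
classify_inheritance <- function(child, father = NULL, mother = NULL) {
  cc <- child$call
  if (cc == "normal") return("false_positive")
  if (cc == "inconclusive") return("not_determined")
  pcalls <- c(if (!is.null(father)) father$call else NA_character_,
              if (!is.null(mother)) mother$call else NA_character_)
  if (any(!is.na(pcalls) & pcalls == cc)) return("inherited")
  if (!anyNA(pcalls) && all(pcalls == "normal")) return("de_novo")
  "not_determined"
}
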