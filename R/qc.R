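#' Post-imputation variant filters
#'
#' Keeps variants with minor allele frequency strictly above `maf_min` and
#' imputation INFO score strictly above `info_min` (boundary values are
#' removed). Kept and removed counts are recorded in the `qc_counts`
#' attribute and always sum to the input count; applying the filter twice is
#' a no-op.
#'
#' @param matrix a `genotype_matrix`.
#' @param maf_min minor-allele-frequency cutoff (default 0.01).
#' @param info_min INFO-score cutoff (default 0.9).
#' @return the filtered `genotype_matrix` with attribute
#'   `qc_counts = c(kept, removed_maf, removed_info, removed)`.
#' @export
filter_variants <- function(matrix, maf_min = 0.01, info_min = 0.9) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (ncol(matrix$dosage) == 0L) stop("empty genotype matrix", call. = FALSE)
  v <- matrix$variants
  pass_maf <- v$maf > maf_min
  pass_info <- v$info > info_min
  keep <- pass_maf & pass_info
  if (!any(keep)) {
    stop(sprintf(
      "all %d variants removed by MAF > %g / INFO > %g filtering; scoring impossible",
      nrow(v), maf_min, info_min), call. = FALSE)
  }
  out <- new_genotype_matrix(matrix$dosage[, keep, drop = FALSE],
                             v[keep, , drop = FALSE])
  # preserve MAF as originally computed rather than recomputing on the subset
  out$variants$maf <- v$maf[keep]
  attr(out, "qc_counts") <- c(kept = sum(keep),
                              removed_maf = sum(!pass_maf),
                              removed_info = sum(!pass_info),
                              removed = sum(!keep))
  out
}

#' Per-sample genotype call rates
#'
#' Call rate is the fraction of non-missing genotypes per sample. Samples
#' below the flag threshold (default 95%) are flagged but never removed
#' here: low-call-rate samples are retained by default, and exclusion is
#' only available through the explicit [drop_flagged_samples()] step.
#'
#' @param matrix a `genotype_matrix`.
#' @param flag_below flag threshold on the call rate (strict `<`).
#' @return a `sample_qc` data.frame: sample_id, call_rate, flagged.
#' @export
compute_sample_call_rates <- function(matrix, flag_below = 0.95) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (ncol(matrix$dosage) == 0L) stop("empty genotype matrix", call. = FALSE)
  cr <- rowMeans(!is.na(matrix$dosage))
  structure(
    data.frame(sample_id = matrix$sample_ids, call_rate = cr,
               flagged = cr < flag_below,
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("sample_qc", "data.frame"), flag_below = flag_below)
}

#' Remove flagged samples (explicit opt-in)
#'
#' @param matrix a `genotype_matrix`.
#' @param report a `sample_qc` report from [compute_sample_call_rates()].
#' @return the `genotype_matrix` restricted to unflagged samples.
#' @export
drop_flagged_samples <- function(matrix, report) {
  stopifnot(inherits(matrix, "genotype_matrix"),
            inherits(report, "sample_qc"))
  keep <- matrix$sample_ids %in% report$sample_id[!report$flagged]
  out <- new_genotype_matrix(matrix$dosage[keep, , drop = FALSE],
                             matrix$variants)
  out$variants$maf <- matrix$variants$maf
  out
}
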