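#' Align summary-statistic effect alleles with genotype dosages
#'
#' Joins variants between a summary-statistic set and a genotype matrix (by
#' ID, falling back to chromosome/position with matching allele pairs) and
#' orients every dosage column to the effect allele: where the effect allele
#' is the VCF ALT the dosage is used as-is, where it is the REF the dosage
#' is replaced by `2 - dosage`. Published weights are never sign-flipped.
#' Strand-ambiguous variants (A/T or C/G) cannot be matched across datasets
#' without strand metadata and are dropped by default; allele pairs that
#' match neither orientation are always dropped. A report of
#' matched/flipped/dropped counts is attached.
#'
#' @param sumstats a `summary_stats` object.
#' @param matrix a `genotype_matrix`.
#' @param drop_ambiguous drop A/T and C/G variants (default `TRUE`). Only
#'   disable when both datasets are known to share a strand convention, e.g.
#'   for data simulated in this package.
#' @return a `harmonized` object: list with `dosage` (samples x variants,
#'   effect-allele oriented), `weights`, `p_values`, `variants` and `report`
#'   (n_matched, n_flipped, n_dropped_ambiguous, n_dropped_mismatch,
#'   n_unmatched).
#' @export
harmonize <- function(sumstats, matrix, drop_ambiguous = TRUE) {
  stopifnot(inherits(sumstats, "summary_stats"),
            inherits(matrix, "genotype_matrix"))
  v <- matrix$variants
  idx <- match(sumstats$id, v$id)
  # positional fallback for variants unmatched by ID
  if (anyNA(idx)) {
    key_ss <- paste(sumstats$chrom, sumstats$pos)
    key_gm <- paste(v$chrom, v$pos)
    fall <- is.na(idx)
    idx[fall] <- match(key_ss[fall], key_gm)
  }
  matched <- !is.na(idx)
  n_unmatched <- sum(!matched)
  ss <- sumstats[matched, , drop = FALSE]
  gv <- v[idx[matched], , drop = FALSE]

  same <- ss$effect_allele == gv$alt & ss$other_allele == gv$ref
  flip <- ss$effect_allele == gv$ref & ss$other_allele == gv$alt
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ambiguous <- ss$effect_allele == comp[ss$other_allele]
  mismatch <- !(same | flip)

  keep <- (same | flip) & !(drop_ambiguous & ambiguous)
  if (!any(keep)) {
    stop("no variants could be harmonized between summary statistics and genotypes",
         call. = FALSE)
  }
  report <- list(
    n_matched = sum(keep),
    n_flipped = sum(flip & keep),
    n_dropped_ambiguous = sum((same | flip) & ambiguous & drop_ambiguous),
    n_dropped_mismatch = sum(mismatch),
    n_unmatched = n_unmatched)
  ss <- ss[keep, , drop = FALSE]
  gv <- gv[keep, , drop = FALSE]
  flip <- flip[keep]
  dos <- matrix$dosage[, idx[matched][keep], drop = FALSE]
  dos[, flip] <- 2 - dos[, flip]
  colnames(dos) <- ss$id

  structure(
    list(dosage = dos,
         weights = stats::setNames(ss$beta, ss$id),
         p_values = stats::setNames(ss$p_value, ss$id),
         variants = data.frame(
           id = ss$id, chrom = ss$chrom, pos = ss$pos,
           effect_allele = ss$effect_allele, other_allele = ss$other_allele,
           flipped = flip, info = gv$info, maf = gv$maf,
           stringsAsFactors = FALSE),
         sample_ids = matrix$sample_ids,
         trait_label = attr(sumstats, "trait_label"),
         report = report),
    class = "harmonized")
}

#' @export
print.harmonized <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "harmonized '%s': %d variants (%d flipped); dropped %d ambiguous, %d mismatched; %d unmatched\n",
    x$trait_label %||% "trait", r$n_matched, r$n_flipped,
    r$n_dropped_ambiguous, r$n_dropped_mismatch, r$n_unmatched))
  invisible(x)
}
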