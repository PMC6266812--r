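# Small in-code fixture builders shared across test files.

# Toy summary-statistic set from explicit vectors (bypasses file IO).
toy_sumstats <- function(id, beta, p, eaf = rep(0.3, length(id)),
                         effect_allele = rep("A", length(id)),
                         other_allele = rep("G", length(id)),
                         chrom = rep("1", length(id)),
                         pos = seq_along(id) * 100L,
                         trait = "toy") {
  prscross:::new_summary_stats(
    data.frame(id = id, chrom = chrom, pos = pos,
               effect_allele = effect_allele, other_allele = other_allele,
               beta = beta, p_value = p, eaf = eaf,
               stringsAsFactors = FALSE),
    trait_label = trait)
}

# Toy genotype matrix: dosage is samples x variants; ref/alt defaults put
# the effect allele of toy_sumstats() on the ALT side.
toy_genotypes <- function(dosage, ids = NULL,
                          ref = NULL, alt = NULL,
                          info = NULL, maf = NULL,
                          chrom = NULL, pos = NULL) {
  m <- ncol(dosage)
  ids <- ids %||% sprintf("v%d", seq_len(m))
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("s%02d", seq_len(nrow(dosage)))
  }
  colnames(dosage) <- ids
  variants <- data.frame(
    id = ids, chrom = chrom %||% rep("1", m),
    pos = pos %||% (seq_len(m) * 100L),
    ref = ref %||% rep("G", m), alt = alt %||% rep("A", m),
    info = info %||% rep(1, m), maf = maf %||% NA_real_,
    stringsAsFactors = FALSE)
  prscross:::new_genotype_matrix(dosage, variants)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent double-loop PRS accumulation oracle (never vectorized).
brute_force_prs <- function(dosage, weights) {
  out <- numeric(nrow(dosage))
  for (i in seq_len(nrow(dosage))) {
    acc <- 0
    for (j in seq_len(ncol(dosage))) {
      acc <- acc + weights[j] * dosage[i, j]
    }
    out[i] <- acc
  }
  out
}

# Write a minimal VCF from explicit body lines.
write_toy_vcf <- function(path, samples, body_lines,
                          format_defs = c("GT", "DS")) {
  fmt <- c(
    GT = "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    DS = "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">")
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation quality\">",
    fmt[format_defs],
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body_lines), path)
  path
}

# Standardized-delta of a simulated genotype cohort under a frequency shift;
# the lean inner loop of the Monte-Carlo recovery checks.
observed_delta <- function(sumstats, shift, config) {
  cohort <- simulate_cohort_genotypes(sumstats, shift, config)
  harm <- harmonize(sumstats, cohort$genotypes, drop_ambiguous = FALSE)
  sc <- standardize_scores(compute_raw_prs(harm))
  mean(sc$std_score[cohort$is_case]) - mean(sc$std_score[!cohort$is_case])
}
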