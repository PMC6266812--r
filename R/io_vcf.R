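# Internal constructor: dosage is a samples x variants matrix of
# effect/ALT-allele counts in [0, 2] with NA as the missing marker.
new_genotype_matrix <- function(dosage, variants) {
  stopifnot(is.matrix(dosage), nrow(variants) == ncol(dosage))
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  required <- c("id", "chrom", "pos", "ref", "alt", "info", "maf")
  missing <- setdiff(required, names(variants))
  if (length(missing)) {
    stop("variant table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(variants$maf)) {
    alt_freq <- colMeans(dosage, na.rm = TRUE) / 2
    variants$maf <- pmin(alt_freq, 1 - alt_freq)
  }
  rownames(variants) <- NULL
  structure(list(dosage = dosage, variants = variants,
                 sample_ids = rownames(dosage)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants, %.2f%% missing\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Read a dosage VCF into a genotype matrix
#'
#' Loads biallelic records from a VCF, taking the ALT-allele dose from the
#' `DS` FORMAT field (fractional imputed dosages preserved) or converting
#' hard `GT` calls to 0/1/2. Missing genotypes (`./.`) become the missing
#' marker. The per-variant imputation quality is read from a named INFO key
#' when present, else set to 1.0. MAF is computed from the non-missing
#' dosages. Multiallelic records are skipped with a warning.
#'
#' @param path VCF path (plain or gzipped).
#' @param dosage_field `"DS"` or `"GT"`.
#' @param info_key name of the INFO key carrying the imputation quality
#'   score.
#' @return a `genotype_matrix`: list with `dosage` (samples x variants),
#'   `variants` (id, chrom, pos, ref, alt, info, maf) and `sample_ids`.
#' @export
read_genotypes_vcf <- function(path, dosage_field = c("DS", "GT"),
                               info_key = "INFO") {
  dosage_field <- match.arg(dosage_field)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0L) stop("empty VCF: ", path, call. = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warning(sprintf("%s: skipped %d multiallelic record(s)",
                    basename(path), sum(multi)), call. = FALSE)
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
    if (nrow(fix) == 0L) stop("no biallelic records in ", path, call. = FALSE)
  }
  if (dosage_field == "DS") {
    d <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    g <- vcfR::extract.gt(vcf, element = "GT")
    d <- gt_to_dosage(g)
  }
  d <- t(d)  # vcfR returns variants x samples
  storage.mode(d) <- "double"
  info <- suppressWarnings(
    vcfR::extract.info(vcf, element = info_key, as.numeric = TRUE))
  if (is.null(info)) info <- rep(NA_real_, nrow(fix))
  info[is.na(info)] <- 1.0
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- sprintf(
    "%s:%s", fix$CHROM[is.na(ids) | ids == "."],
    fix$POS[is.na(ids) | ids == "."])
  colnames(d) <- ids
  variants <- data.frame(
    id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, info = info, maf = NA_real_,
    stringsAsFactors = FALSE)
  new_genotype_matrix(d, variants)
}

# Convert biallelic GT strings ("0/1", "1|1", "./.") to ALT counts.
gt_to_dosage <- function(g) {
  clean <- gsub("|", "/", g, fixed = TRUE)
  out <- matrix(NA_real_, nrow = nrow(g), ncol = ncol(g),
                dimnames = dimnames(g))
  out[clean %in% c("0/0", "0")] <- 0
  out[clean %in% c("0/1", "1/0")] <- 1
  out[clean %in% c("1/1", "1")] <- 2
  out
}

#' Write a genotype matrix as a dosage VCF
#'
#' Emits one biallelic record per variant with `GT:DS` FORMAT fields: DS
#' carries the stored ALT dosage, GT the corresponding hard call when the
#' dosage is integral (`./.` otherwise or when missing). The imputation
#' quality is written under a named INFO key. [read_genotypes_vcf()] on the
#' result reproduces the matrix.
#'
#' @param gm a `genotype_matrix`.
#' @param path output path (plain text).
#' @param info_key INFO key name for the imputation quality score.
#' @return the path, invisibly.
#' @export
write_genotypes_vcf <- function(gm, path, info_key = "INFO") {
  stopifnot(inherits(gm, "genotype_matrix"))
  v <- gm$variants
  d <- gm$dosage
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"Imputation quality score\">",
            info_key),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Effect (ALT) allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$sample_ids), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(j) {
    dj <- d[, j]
    gt <- rep("./.", length(dj))
    hard <- !is.na(dj) & dj %in% c(0, 1, 2)
    gt[hard] <- c("0/0", "0/1", "1/1")[dj[hard] + 1]
    ds <- ifelse(is.na(dj), ".", sprintf("%.17g", dj))
    cells <- paste(gt, ds, sep = ":")
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j], ".", "PASS",
            sprintf("%s=%.17g", info_key, v$info[j]), "GT:DS", cells),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
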