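# Internal constructor shared by the reader and the simulator: validates the
# canonical column set and sorts by (chrom, pos).
new_summary_stats <- function(df, trait_label = "trait",
                              n_dropped = c(bad_p = 0L, bad_allele = 0L,
                                            duplicate_id = 0L)) {
  required <- c("id", "chrom", "pos", "effect_allele", "other_allele",
                "beta", "p_value", "eaf")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("summary statistics lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$id)) {
    stop("summary-statistic variant IDs must be unique", call. = FALSE)
  }
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("summary_stats", "data.frame"),
            trait_label = trait_label, n_dropped = n_dropped)
}

#' Default summary-statistic column map
#'
#' The common SNP/CHR/BP/A1/A2/BETA(OR)/P/FRQ header convention. Published
#' GWAS files differ, so every entry can be overridden in
#' [read_summary_stats()].
#'
#' @return named character vector mapping canonical fields to file columns.
#' @export
default_column_map <- function() {
  c(id = "SNP", chrom = "CHR", pos = "BP", effect_allele = "A1",
    other_allele = "A2", beta = "BETA", or = "OR", p_value = "P",
    eaf = "FRQ")
}

#' Read GWAS summary statistics
#'
#' Reads a tab-delimited summary-statistic file into the canonical per-variant
#' form: ID, chromosome, position, effect/other allele, per-allele weight on
#' the log-odds (or linear) scale, P-value and effect-allele frequency.
#' Odds-ratio effect columns are log-transformed exactly once, at ingest.
#' Rows with P outside (0, 1], non-ACGT or identical alleles, or a variant ID
#' already seen (first occurrence kept) are dropped; drop counts are recorded
#' in the `n_dropped` attribute and surfaced as one warning.
#'
#' @param path path to a tab-delimited file with a header row.
#' @param column_map named character vector overriding entries of
#'   [default_column_map()].
#' @param effect_scale `"beta"` for effects already on the log-odds/linear
#'   scale, `"or"` for odds-ratio columns (log-transformed on read).
#' @param trait_label label attached to the set.
#' @return a `summary_stats` object: a data.frame sorted by (chrom, pos) with
#'   attributes `trait_label` and `n_dropped`.
#' @export
read_summary_stats <- function(path, column_map = NULL,
                               effect_scale = c("beta", "or"),
                               trait_label = NULL) {
  effect_scale <- match.arg(effect_scale)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  map <- default_column_map()
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  effect_col <- if (effect_scale == "or") map[["or"]] else map[["beta"]]
  mandatory <- c(id = map[["id"]], chrom = map[["chrom"]], pos = map[["pos"]],
                 effect_allele = map[["effect_allele"]],
                 other_allele = map[["other_allele"]],
                 effect = effect_col, p_value = map[["p_value"]])
  absent <- mandatory[!mandatory %in% names(raw)]
  if (length(absent)) {
    stop(sprintf("mandatory column(s) missing from %s: %s", path,
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  eff <- as.numeric(raw[[effect_col]])
  beta <- if (effect_scale == "or") log(eff) else eff
  df <- data.frame(
    id = as.character(raw[[map[["id"]]]]),
    chrom = as.character(raw[[map[["chrom"]]]]),
    pos = as.integer(raw[[map[["pos"]]]]),
    effect_allele = toupper(as.character(raw[[map[["effect_allele"]]]])),
    other_allele = toupper(as.character(raw[[map[["other_allele"]]]])),
    beta = beta,
    p_value = as.numeric(raw[[map[["p_value"]]]]),
    eaf = if (map[["eaf"]] %in% names(raw)) as.numeric(raw[[map[["eaf"]]]])
          else NA_real_,
    stringsAsFactors = FALSE)

  bad_p <- is.na(df$p_value) | df$p_value <= 0 | df$p_value > 1
  valid_allele <- function(a) a %in% c("A", "C", "G", "T")
  bad_allele <- !valid_allele(df$effect_allele) |
    !valid_allele(df$other_allele) |
    df$effect_allele == df$other_allele
  keep <- !(bad_p | bad_allele)
  df <- df[keep, , drop = FALSE]
  dup <- duplicated(df$id)
  n_dropped <- c(bad_p = sum(bad_p), bad_allele = sum(bad_allele & !bad_p),
                 duplicate_id = sum(dup))
  df <- df[!dup, , drop = FALSE]
  if (nrow(df) == 0L) {
    stop("no valid summary-statistic rows survive validation in ", path,
         call. = FALSE)
  }
  if (sum(n_dropped) > 0) {
    warning(sprintf(
      "%s: dropped %d row(s) (%d bad P, %d bad alleles, %d duplicate IDs)",
      basename(path), sum(n_dropped), n_dropped[["bad_p"]],
      n_dropped[["bad_allele"]], n_dropped[["duplicate_id"]]),
      call. = FALSE)
  }
  new_summary_stats(df,
                    trait_label = trait_label %||%
                      tools::file_path_sans_ext(basename(path)),
                    n_dropped = n_dropped)
}

#' Write summary statistics in the canonical TSV layout
#'
#' Inverse of [read_summary_stats()] under the default column map; effects
#' are written on the beta (log-odds) scale at full double precision so
#' write-then-read round-trips are exact.
#'
#' @param sumstats a `summary_stats` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_summary_stats <- function(sumstats, path) {
  stopifnot(inherits(sumstats, "summary_stats"))
  out <- data.frame(SNP = sumstats$id, CHR = sumstats$chrom,
                    BP = sumstats$pos, A1 = sumstats$effect_allele,
                    A2 = sumstats$other_allele, BETA = sumstats$beta,
                    P = sumstats$p_value, FRQ = sumstats$eaf,
                    stringsAsFactors = FALSE)
  write_tsv_full(out, path)
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("summary_stats '%s': %d variants on %d chromosome(s)\n",
              attr(x, "trait_label"), nrow(x),
              length(unique(x$chrom))))
  nd <- attr(x, "n_dropped")
  if (!is.null(nd) && sum(nd) > 0) {
    cat("  dropped at read:",
        paste(sprintf("%s=%d", names(nd), nd), collapse = ", "), "\n")
  }
  NextMethod()
}
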