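# Internal score-set constructor.
new_score_set <- function(sample_id, raw_score, std_score = NULL,
                          trait_label = "trait", threshold = NA_real_,
                          n_snps = NA_integer_) {
  df <- data.frame(sample_id = sample_id, raw_score = raw_score,
                   stringsAsFactors = FALSE)
  if (!is.null(std_score)) df$std_score <- std_score
  structure(df, class = c("score_set", "data.frame"),
            trait_label = trait_label, threshold = threshold,
            n_snps = as.integer(n_snps))
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("score_set '%s' (P_T < %s): %d samples, %s SNPs%s\n",
              attr(x, "trait_label"), format(attr(x, "threshold")),
              nrow(x), format(attr(x, "n_snps")),
              if ("std_score" %in% names(x)) ", standardized" else ""))
  NextMethod()
}

#' The study's P-value threshold grid
#'
#' @return the default SNP-inclusion grid
#'   `{0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1}`.
#' @export
default_pt_grid <- function() c(0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1)

#' Select variants below a P-value threshold
#'
#' Inclusion is strict (`p_value < p_threshold`), matching the `P_T < x`
#' convention; at `p_threshold = 1` rows with P exactly 1 are excluded. An
#' empty selection is returned as a zero-row set (the grid runner records
#' `n_snps = 0` and skips the cell), never an error.
#'
#' @param sumstats a `summary_stats` object.
#' @param p_threshold threshold in (0, 1].
#' @return the `summary_stats` subset.
#' @export
select_snps <- function(sumstats, p_threshold) {
  stopifnot(inherits(sumstats, "summary_stats"))
  if (!(is.numeric(p_threshold) && length(p_threshold) == 1L &&
        p_threshold > 0 && p_threshold <= 1)) {
    stop("`p_threshold` must be a single value in (0, 1]", call. = FALSE)
  }
  out <- sumstats[sumstats$p_value < p_threshold, , drop = FALSE]
  attr(out, "trait_label") <- attr(sumstats, "trait_label")
  attr(out, "n_dropped") <- attr(sumstats, "n_dropped")
  class(out) <- class(sumstats)
  out
}

#' Additive weighted polygenic score
#'
#' Computes the raw PRS of each sample as the weighted sum of effect-allele
#' dosages, `raw_i = sum_j w_j d_ij`, over the harmonized variants passing
#' an optional P-value threshold. Missing dosages are handled by
#' `missing_policy`: `"mean_impute"` (default) substitutes the variant's
#' mean non-missing dosage, `"zero"` contributes nothing, `"exclude"` drops
#' any variant with a missing value for any sample. Variants with all
#' dosages missing are dropped with a warning under mean imputation.
#'
#' @param harmonized a `harmonized` object from [harmonize()].
#' @param p_threshold optional strict P-value cutoff applied to the
#'   harmonized variants (see [select_snps()]).
#' @param missing_policy `"mean_impute"`, `"zero"` or `"exclude"`.
#' @return a `score_set` with raw scores and an `n_snps` attribute equal to
#'   the number of variants actually summed.
#' @export
compute_raw_prs <- function(harmonized, p_threshold = NULL,
                            missing_policy = c("mean_impute", "zero",
                                               "exclude")) {
  stopifnot(inherits(harmonized, "harmonized"))
  missing_policy <- match.arg(missing_policy)
  keep <- if (is.null(p_threshold)) {
    rep(TRUE, length(harmonized$weights))
  } else {
    harmonized$p_values < p_threshold
  }
  d <- harmonized$dosage[, keep, drop = FALSE]
  w <- harmonized$weights[keep]
  if (ncol(d) == 0L) {
    return(new_score_set(harmonized$sample_ids,
                         raw_score = rep(0, length(harmonized$sample_ids)),
                         trait_label = harmonized$trait_label,
                         threshold = p_threshold %||% NA_real_, n_snps = 0L))
  }
  if (anyNA(d)) {
    if (missing_policy == "mean_impute") {
      mu <- colMeans(d, na.rm = TRUE)
      dead <- !is.finite(mu)
      if (any(dead)) {
        warning(sprintf("dropped %d variant(s) with all dosages missing",
                        sum(dead)), call. = FALSE)
        d <- d[, !dead, drop = FALSE]
        w <- w[!dead]
        mu <- mu[!dead]
      }
      na_idx <- which(is.na(d), arr.ind = TRUE)
      d[na_idx] <- mu[na_idx[, 2]]
    } else if (missing_policy == "zero") {
      d[is.na(d)] <- 0
    } else {
      complete <- colSums(is.na(d)) == 0L
      d <- d[, complete, drop = FALSE]
      w <- w[complete]
    }
  }
  raw <- as.numeric(d %*% w)
  new_score_set(harmonized$sample_ids, raw_score = raw,
                trait_label = harmonized$trait_label,
                threshold = p_threshold %||% NA_real_,
                n_snps = ncol(d))
}

#' Standardize polygenic scores
#'
#' Centres and scales raw scores to mean 0 and SD 1 over the scored cohort
#' (cases and reference together by default; pass a logical `reference`
#' mask to centre on the reference subjects only). The sample SD (n - 1
#' denominator) convention is used throughout. Standardization is
#' idempotent and invariant to positive affine transforms of the raw score.
#'
#' @param scores a `score_set`.
#' @param reference optional logical vector marking the subset whose mean
#'   and SD define the transformation; default is the whole cohort.
#' @return the `score_set` with a `std_score` column added/replaced.
#' @export
standardize_scores <- function(scores, reference = NULL) {
  stopifnot(inherits(scores, "score_set"))
  if (nrow(scores) < 2L) {
    stop("standardization needs at least 2 samples", call. = FALSE)
  }
  x <- scores$raw_score
  ref <- if (is.null(reference)) rep(TRUE, length(x)) else reference
  stopifnot(length(ref) == length(x), sum(ref) >= 2L)
  s <- stats::sd(x[ref])
  if (!is.finite(s) || s == 0) {
    stop("raw scores are constant over the standardization set: zero variance",
         call. = FALSE)
  }
  scores$std_score <- (x - mean(x[ref])) / s
  scores
}

#' Score every (trait, threshold) cell of a PRS grid
#'
#' Harmonizes each trait's summary statistics against the genotype matrix
#' once, then scores and standardizes at every P-value threshold of the
#' grid. Cells whose threshold selects no variants are recorded with
#' `n_snps = 0` and a `NULL` score set. Ordering is deterministic: traits in
#' input order, thresholds ascending.
#'
#' @param matrix a (QC-filtered) `genotype_matrix`.
#' @param sumstats_by_trait named list of `summary_stats`, one per trait.
#' @param thresholds P-value threshold grid; defaults to
#'   [default_pt_grid()].
#' @param missing_policy passed to [compute_raw_prs()].
#' @param standardize_with `"combined"` (default) or `"reference"`; the
#'   latter requires `is_case`.
#' @param is_case optional logical case mask (needed for reference-only
#'   standardization).
#' @param drop_ambiguous passed to [harmonize()].
#' @return a `score_grid`: list with `cells` (list of `score_set` or
#'   `NULL`), `summary` (data.frame trait/threshold/n_snps) and
#'   `harmonization` reports per trait.
#' @export
score_grid <- function(matrix, sumstats_by_trait,
                       thresholds = default_pt_grid(),
                       missing_policy = "mean_impute",
                       standardize_with = c("combined", "reference"),
                       is_case = NULL,
                       drop_ambiguous = TRUE) {
  stopifnot(inherits(matrix, "genotype_matrix"),
            length(sumstats_by_trait) >= 1L)
  standardize_with <- match.arg(standardize_with)
  if (standardize_with == "reference" && is.null(is_case)) {
    stop("reference-only standardization requires `is_case`", call. = FALSE)
  }
  if (is.null(names(sumstats_by_trait))) {
    names(sumstats_by_trait) <- vapply(sumstats_by_trait,
                                       attr, "", "trait_label")
  }
  thresholds <- sort(thresholds)
  cells <- list()
  rows <- list()
  reports <- list()
  for (trait in names(sumstats_by_trait)) {
    harm <- harmonize(sumstats_by_trait[[trait]], matrix,
                      drop_ambiguous = drop_ambiguous)
    harm$trait_label <- trait
    reports[[trait]] <- harm$report
    for (pt in thresholds) {
      key <- sprintf("%s@%g", trait, pt)
      n_snps <- sum(harm$p_values < pt)
      if (n_snps == 0L) {
        cells[key] <- list(NULL)  # keep the skipped cell visible
        rows[[key]] <- data.frame(trait = trait, threshold = pt,
                                  n_snps = 0L, stringsAsFactors = FALSE)
        next
      }
      ss <- compute_raw_prs(harm, p_threshold = pt,
                            missing_policy = missing_policy)
      ss <- standardize_scores(
        ss, reference = if (standardize_with == "reference") !is_case)
      cells[[key]] <- ss
      rows[[key]] <- data.frame(trait = trait, threshold = pt,
                                n_snps = attr(ss, "n_snps"),
                                stringsAsFactors = FALSE)
    }
  }
  structure(list(cells = cells,
                 summary = do.call(rbind, c(rows, make.row.names = FALSE)),
                 harmonization = reports,
                 thresholds = thresholds),
            class = "score_grid")
}

#' @export
print.score_grid <- function(x, ...) {
  cat(sprintf("score_grid: %d traits x %d thresholds (%d scored cells)\n",
              length(x$harmonization), length(x$thresholds),
              sum(!vapply(x$cells, is.null, TRUE))))
  print(x$summary)
  invisible(x)
}

#' Export a score grid as a long TSV
#'
#' One row per (sample, trait, threshold) with raw and standardized scores
#' and the number of SNPs in the cell.
#'
#' @param grid a `score_grid`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_score_table <- function(grid, path) {
  stopifnot(inherits(grid, "score_grid"))
  rows <- lapply(grid$cells, function(cell) {
    if (is.null(cell)) return(NULL)
    data.frame(sample_id = cell$sample_id,
               trait = attr(cell, "trait_label"),
               threshold = attr(cell, "threshold"),
               raw_score = cell$raw_score,
               std_score = cell$std_score,
               n_snps = attr(cell, "n_snps"),
               stringsAsFactors = FALSE)
  })
  write_tsv_full(do.call(rbind, c(rows, make.row.names = FALSE)), path)
}
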