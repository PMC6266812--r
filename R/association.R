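# Pull the analysis score: standardized when available, else raw.
analysis_score <- function(scores) {
  if ("std_score" %in% names(scores)) scores$std_score else scores$raw_score
}

#' Case/reference t-test on polygenic scores
#'
#' Two-sample t-test of the mean standardized PRS difference between cases
#' and the reference set. The classic pooled-variance (equal variance) test
#' is the default; Welch's correction is available via `var_equal = FALSE`.
#'
#' @param scores a `score_set` (standardized scores used when present).
#' @param is_case logical vector aligned with the score rows.
#' @param var_equal pooled-variance test if `TRUE` (default).
#' @return list with `delta` (mean case minus mean reference, SD units),
#'   `t_stat`, `t_p` (two-sided) and group sizes.
#' @export
ttest_case_control <- function(scores, is_case, var_equal = TRUE) {
  stopifnot(inherits(scores, "score_set"),
            length(is_case) == nrow(scores), is.logical(is_case))
  x <- analysis_score(scores)
  if (sum(is_case) < 2L || sum(!is_case) < 2L) {
    stop("each group needs at least 2 samples for the t-test", call. = FALSE)
  }
  tt <- stats::t.test(x[is_case], x[!is_case], var.equal = var_equal)
  list(delta = mean(x[is_case]) - mean(x[!is_case]),
       t_stat = unname(tt$statistic),
       t_p = tt$p.value,
       n_case = sum(is_case), n_control = sum(!is_case))
}

#' Logistic odds ratio per SD of PRS
#'
#' Maximum-likelihood logistic regression of case status on the
#' (standardized) score with an intercept. The reported odds ratio,
#' `exp(slope)`, is the multiplicative change in odds of being a case per
#' one standard deviation of PRS; 95% confidence bounds are Wald
#' (`exp(slope +/- 1.96 SE)`) with a two-sided Wald P. Non-convergence and
#' (quasi-)complete separation are flagged in `status` with `NA` CI/P
#' rather than fabricated intervals.
#'
#' @param scores a `score_set`.
#' @param is_case logical case mask.
#' @return list with `or_per_sd`, `ci_low`, `ci_high`, `wald_p`, `slope`,
#'   `slope_se`, `status` ("ok", "no_convergence" or "separation").
#' @export
logistic_or_per_sd <- function(scores, is_case) {
  stopifnot(inherits(scores, "score_set"),
            length(is_case) == nrow(scores), is.logical(is_case))
  if (!any(is_case) || all(is_case)) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  x <- analysis_score(scores)
  fit <- suppressWarnings(
    stats::glm(is_case ~ x, family = stats::binomial()))
  co <- summary(fit)$coefficients
  slope <- co["x", "Estimate"]
  se <- co["x", "Std. Error"]
  status <- "ok"
  if (!fit$converged) status <- "no_convergence"
  # quasi-complete separation: fitted probabilities pinned at 0/1 or an
  # exploding Wald SE
  pinned <- any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
  if (fit$boundary || se > 100 || (abs(slope) > 10 && pinned)) {
    status <- "separation"
  }
  if (status == "ok") {
    list(or_per_sd = exp(slope),
         ci_low = exp(slope - 1.96 * se),
         ci_high = exp(slope + 1.96 * se),
         wald_p = 2 * stats::pnorm(-abs(slope / se)),
         slope = slope, slope_se = se, status = status)
  } else {
    list(or_per_sd = exp(slope), ci_low = NA_real_, ci_high = NA_real_,
         wald_p = NA_real_, slope = slope, slope_se = se, status = status)
  }
}

#' Full case/reference association for one score set
#'
#' Combines [ttest_case_control()] and [logistic_or_per_sd()] into one
#' association row for a (trait, threshold) cell.
#'
#' @param scores a `score_set`.
#' @param is_case logical case mask.
#' @param var_equal passed to the t-test layer.
#' @return a one-row `association_result` data.frame: trait, threshold,
#'   n_snps, n_case, n_control, delta, t_stat, t_p, or_per_sd, ci_low,
#'   ci_high, wald_p, status.
#' @export
associate_case_control <- function(scores, is_case, var_equal = TRUE) {
  tt <- ttest_case_control(scores, is_case, var_equal = var_equal)
  lr <- logistic_or_per_sd(scores, is_case)
  structure(
    data.frame(trait = attr(scores, "trait_label"),
               threshold = attr(scores, "threshold"),
               n_snps = attr(scores, "n_snps"),
               n_case = tt$n_case, n_control = tt$n_control,
               delta = tt$delta, t_stat = tt$t_stat, t_p = tt$t_p,
               or_per_sd = lr$or_per_sd, ci_low = lr$ci_low,
               ci_high = lr$ci_high, wald_p = lr$wald_p,
               status = lr$status, stringsAsFactors = FALSE),
    class = c("association_result", "data.frame"))
}

#' Association over every scored cell of a grid
#'
#' @param grid a `score_grid`.
#' @param is_case logical case mask aligned with the genotype samples.
#' @param var_equal passed to the t-test layer.
#' @return data.frame of `association_result` rows; skipped (empty) cells
#'   are omitted.
#' @export
association_grid <- function(grid, is_case, var_equal = TRUE) {
  stopifnot(inherits(grid, "score_grid"))
  rows <- lapply(grid$cells, function(cell) {
    if (is.null(cell)) return(NULL)
    associate_case_control(cell, is_case, var_equal = var_equal)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("association_result", "data.frame")
  out
}

#' Per-symptom ANOVA of PRS against follow-up phenotypes
#'
#' For each binary symptom, a one-way ANOVA compares the mean PRS of
#' subjects positive versus negative for the symptom (equivalent to the
#' squared pooled t-test at two levels). Missing symptom values are
#' excluded per symptom. Symptoms observed at a single level get status
#' `"untestable"` instead of an error. No multiple-testing correction is
#' applied by default (nominal P < 0.05 convention for correlated allergic
#' outcomes); `correction = "bonferroni"` adds an adjusted column.
#'
#' @param scores a `score_set` for the followed-up subjects; subjects are
#'   matched to the phenotype table by ID.
#' @param phenotypes a `phenotype_table`.
#' @param correction `"none"` (default) or `"bonferroni"`.
#' @return a `symptom_association` data.frame: symptom, domain, n_yes, n_no,
#'   mean_prs_yes, mean_prs_no, f_stat, p_value, status (and p_adjusted
#'   under Bonferroni).
#' @export
symptom_association <- function(scores, phenotypes,
                                correction = c("none", "bonferroni")) {
  stopifnot(inherits(scores, "score_set"),
            inherits(phenotypes, "phenotype_table"))
  correction <- match.arg(correction)
  idx <- match(phenotypes$subject_id, scores$sample_id)
  if (all(is.na(idx))) {
    stop("no phenotype subject matches a scored sample", call. = FALSE)
  }
  x_all <- analysis_score(scores)[idx]
  symptoms <- attr(phenotypes, "symptoms")
  domains <- attr(phenotypes, "domains")
  rows <- lapply(symptoms, function(s) {
    y <- phenotypes[[s]]
    ok <- !is.na(y) & !is.na(x_all)
    y <- y[ok]; x <- x_all[ok]
    n_yes <- sum(y == 1L); n_no <- sum(y == 0L)
    base <- data.frame(symptom = s, domain = unname(domains[[s]]),
                       n_yes = n_yes, n_no = n_no,
                       mean_prs_yes = if (n_yes) mean(x[y == 1L]) else NA_real_,
                       mean_prs_no = if (n_no) mean(x[y == 0L]) else NA_real_,
                       f_stat = NA_real_, p_value = NA_real_,
                       status = "untestable", stringsAsFactors = FALSE)
    if (n_yes >= 1L && n_no >= 1L && length(x) >= 3L &&
        stats::var(x) > 0) {
      av <- stats::anova(stats::aov(x ~ factor(y)))
      base$f_stat <- av[["F value"]][1]
      base$p_value <- av[["Pr(>F)"]][1]
      base$status <- "ok"
    }
    base
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (correction == "bonferroni") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "bonferroni")
  }
  structure(out, class = c("symptom_association", "data.frame"))
}

#' Prevalence summary of a follow-up phenotype table
#'
#' Per symptom: positive count, number of non-missing responses, percent of
#' non-missing, grouped by domain. When some responses are missing the
#' denominator differs from the subject count; such rows are flagged.
#'
#' @param phenotypes a `phenotype_table`.
#' @return data.frame: domain, symptom, n_positive, n_responded, percent,
#'   denominator_differs.
#' @export
summarize_phenotypes <- function(phenotypes) {
  stopifnot(inherits(phenotypes, "phenotype_table"))
  if (nrow(phenotypes) == 0L) stop("empty phenotype table", call. = FALSE)
  symptoms <- attr(phenotypes, "symptoms")
  domains <- attr(phenotypes, "domains")
  n <- nrow(phenotypes)
  rows <- lapply(symptoms, function(s) {
    y <- phenotypes[[s]]
    n_resp <- sum(!is.na(y))
    n_pos <- sum(y == 1L, na.rm = TRUE)
    data.frame(domain = unname(domains[[s]]), symptom = s,
               n_positive = n_pos, n_responded = n_resp,
               percent = if (n_resp) round(100 * n_pos / n_resp, 1) else NA_real_,
               denominator_differs = n_resp != n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[order(match(out$domain, unique(domains))), , drop = FALSE]
}
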