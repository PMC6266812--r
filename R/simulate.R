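#' Simulation settings for a synthetic PRS study
#'
#' Bundles every knob of the synthetic-data generator into one validated
#' object. Defaults reproduce the design of the motivating study: 22 allergic
#' cases against 307 population reference subjects, with a target
#' standardized PRS shift of 0.41 SD in cases.
#'
#' @param n_snps number of simulated variants.
#' @param n_cases number of case samples.
#' @param n_controls number of reference samples.
#' @param n_gwas effective sample size of the emulated GWAS; controls the
#'   standard error `1 / sqrt(2 f (1 - f) n_gwas)` of reported effects.
#' @param causal_fraction proportion of variants with a nonzero true effect.
#' @param effect_sd standard deviation of true per-allele effects
#'   (log-odds scale).
#' @param maf_range length-2 numeric, lower/upper bound of the uniform
#'   effect-allele frequency distribution; both in (0, 0.5].
#' @param delta_target target case-vs-reference mean standardized PRS shift,
#'   in SD units.
#' @param missing_rate per-genotype missingness probability in [0, 1).
#' @param seed integer RNG seed; identical config + seed reproduces
#'   byte-identical output.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_snps = 2000L,
                              n_cases = 22L,
                              n_controls = 307L,
                              n_gwas = 20000L,
                              causal_fraction = 0.1,
                              effect_sd = 0.05,
                              maf_range = c(0.05, 0.5),
                              delta_target = 0.41,
                              missing_rate = 0.02,
                              seed = 1L) {
  stopifnot(n_snps >= 1, n_cases >= 1, n_controls >= 1, n_gwas >= 1)
  if (!(is.numeric(causal_fraction) && causal_fraction >= 0 && causal_fraction <= 1)) {
    stop("`causal_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (!(length(maf_range) == 2L && maf_range[1] > 0 &&
        maf_range[1] <= maf_range[2] && maf_range[2] <= 0.5)) {
    stop("`maf_range` must satisfy 0 < low <= high <= 0.5", call. = FALSE)
  }
  if (!(missing_rate >= 0 && missing_rate < 1)) {
    stop("`missing_rate` must lie in [0, 1)", call. = FALSE)
  }
  stopifnot(effect_sd >= 0, is.finite(delta_target))
  structure(
    list(n_snps = as.integer(n_snps), n_cases = as.integer(n_cases),
         n_controls = as.integer(n_controls), n_gwas = as.double(n_gwas),
         causal_fraction = causal_fraction, effect_sd = effect_sd,
         maf_range = as.double(maf_range), delta_target = delta_target,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "simulation_config: %d SNPs, %d cases / %d controls, n_gwas = %g\n",
    x$n_snps, x$n_cases, x$n_controls, x$n_gwas))
  cat(sprintf(
    "  causal fraction %.3g, effect SD %.3g, MAF in [%.3g, %.3g]\n",
    x$causal_fraction, x$effect_sd, x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  delta target %.3g SD, missing rate %.3g, seed %d\n",
              x$delta_target, x$missing_rate, x$seed))
  invisible(x)
}

#' Simulate a GWAS summary-statistic set
#'
#' Fabricates per-variant association results with realistic sampling
#' structure: a `causal_fraction` of variants receives true effects drawn
#' from Normal(0, `effect_sd`^2) on the log-odds scale, the rest are null.
#' The reported effect adds estimation noise with standard error
#' `se = 1 / sqrt(2 f (1 - f) n_gwas)` and the reported P-value is the
#' two-sided normal P of `reported / se`. Under `causal_fraction = 0` the
#' P-values are therefore exactly Uniform(0, 1).
#'
#' @param config a [simulation_config()].
#' @param trait_label label attached to the resulting set.
#' @return a `summary_stats` object (see [read_summary_stats()]).
#' @export
simulate_summary_stats <- function(config, trait_label = "trait") {
  stopifnot(inherits(config, "simulation_config"))
  m <- config$n_snps
  with_seed(config$seed + 0L, {
    chrom <- sample(1:22, m, replace = TRUE)
    pos <- sample.int(1e8L, m, replace = TRUE)
    o <- order(as.character(chrom), pos)  # match the constructor's sort
    chrom <- chrom[o]; pos <- pos[o]
    bases <- c("A", "C", "G", "T")
    ea <- character(m); oa <- character(m)
    pick <- matrix(sample(4L, 2L * m, replace = TRUE), ncol = 2L)
    clash <- pick[, 1] == pick[, 2]
    while (any(clash)) {
      pick[clash, 2] <- sample(4L, sum(clash), replace = TRUE)
      clash <- pick[, 1] == pick[, 2]
    }
    ea <- bases[pick[, 1]]; oa <- bases[pick[, 2]]
    f <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    causal <- stats::runif(m) < config$causal_fraction
    true_beta <- ifelse(causal, stats::rnorm(m, 0, config$effect_sd), 0)
    se <- 1 / sqrt(2 * f * (1 - f) * config$n_gwas)
    beta_hat <- true_beta + stats::rnorm(m, 0, se)
    p <- 2 * stats::pnorm(-abs(beta_hat / se))
    p <- pmax(p, .Machine$double.xmin)  # keep P in (0, 1]
    df <- data.frame(
      id = sprintf("rs%07d", seq_len(m)),
      chrom = as.character(chrom), pos = pos,
      effect_allele = ea, other_allele = oa,
      beta = beta_hat, p_value = p, eaf = f,
      stringsAsFactors = FALSE)
    ss <- new_summary_stats(df, trait_label = trait_label)
    # rows are pre-sorted, so true effects stay aligned with the table
    attr(ss, "true_beta") <- true_beta
    ss
  })
}

#' Case allele-frequency tilt realizing a target PRS shift
#'
#' Solves the inverse problem of choosing case effect-allele frequencies so
#' the expected case-vs-reference raw-score mean difference equals a target
#' number of score standard deviations. With weights `w_j`, reference
#' frequencies `f_j` and independent variants, case frequencies are tilted as
#' `f'_j = f_j + lambda w_j f_j (1 - f_j)` with
#' `lambda = delta_target / sqrt(sum_j w_j^2 2 f_j (1 - f_j))`,
#' the closed-form solution of
#' `sum_j w_j 2 (f'_j - f_j) = delta_target * sd_raw`. Tilted frequencies
#' are clipped into `[epsilon, 1 - epsilon]`; the number of clipped variants
#' is reported (clipping biases the realized shift slightly toward zero).
#'
#' @param sumstats a `summary_stats` object supplying weights, P-values and
#'   reference effect-allele frequencies.
#' @param threshold P-value threshold selecting the variants that will enter
#'   the score (strict `<`).
#' @param delta_target target standardized shift, SD units.
#' @param epsilon clipping bound keeping frequencies valid Binomial
#'   parameters.
#' @return an object of class `frequency_shift` with elements `lambda`,
#'   `variant_id`, `control_freq`, `case_freq`, `n_clipped`.
#' @export
calibrate_frequency_shift <- function(sumstats, threshold = 1,
                                      delta_target = 0.41,
                                      epsilon = 1e-4) {
  stopifnot(inherits(sumstats, "summary_stats"), is.finite(delta_target))
  keep <- sumstats$p_value < threshold
  if (!any(keep)) stop("no variant passes the P-value threshold", call. = FALSE)
  w <- sumstats$beta[keep]
  f <- sumstats$eaf[keep]
  if (any(is.na(f))) {
    stop("effect-allele frequencies are required to calibrate a shift",
         call. = FALSE)
  }
  s2 <- sum(w^2 * 2 * f * (1 - f))
  if (s2 <= 0) {
    stop("all selected weights are zero: no solvable frequency tilt",
         call. = FALSE)
  }
  lambda <- delta_target / sqrt(s2)
  fprime <- f + lambda * w * f * (1 - f)
  clipped <- fprime < epsilon | fprime > 1 - epsilon
  fprime <- pmin(pmax(fprime, epsilon), 1 - epsilon)
  structure(
    list(lambda = lambda,
         variant_id = sumstats$id[keep],
         control_freq = f,
         case_freq = fprime,
         n_clipped = sum(clipped),
         delta_target = delta_target,
         threshold = threshold),
    class = "frequency_shift")
}

#' @export
print.frequency_shift <- function(x, ...) {
  cat(sprintf(
    "frequency_shift: lambda = %.6g over %d variants (target delta %.3g SD, %d clipped)\n",
    x$lambda, length(x$variant_id), x$delta_target, x$n_clipped))
  invisible(x)
}

#' Simulate a case/control genotype cohort
#'
#' Draws hard-call dosages independently per variant: reference subjects from
#' Binomial(2, f) at the summary-statistic effect-allele frequency, cases
#' from Binomial(2, f') at the tilted frequency of a [calibrate_frequency_shift()]
#' object (variants outside the shift keep f). About half the variants are
#' stored with the effect allele as VCF REF rather than ALT, so downstream
#' harmonization has genuine flips to perform. Genotypes are masked missing
#' uniformly at `missing_rate`, and each variant gets an imputation INFO
#' score drawn uniformly in (0.5, 1] so quality filters see both outcomes.
#'
#' @param sumstats the `summary_stats` the cohort is simulated under.
#' @param shift optional `frequency_shift`; `NULL` means no case enrichment.
#' @param config a [simulation_config()]; its seed (offset from the
#'   summary-statistic stream) drives all draws here.
#' @return a list with `genotypes` (a `genotype_matrix`) and `is_case`
#'   (logical vector aligned with its samples).
#' @export
simulate_cohort_genotypes <- function(sumstats, shift = NULL, config) {
  stopifnot(inherits(sumstats, "summary_stats"),
            inherits(config, "simulation_config"))
  if (!is.null(shift)) stopifnot(inherits(shift, "frequency_shift"))
  m <- nrow(sumstats)
  n_case <- config$n_cases
  n_ctrl <- config$n_controls
  f_ctrl <- sumstats$eaf
  f_case <- f_ctrl
  if (!is.null(shift)) {
    idx <- match(shift$variant_id, sumstats$id)
    if (anyNA(idx)) {
      stop("frequency shift refers to variants absent from `sumstats`",
           call. = FALSE)
    }
    f_case[idx] <- shift$case_freq
  }
  with_seed(config$seed + 1L, {
    d_case <- matrix(stats::rbinom(n_case * m, 2L, rep(f_case, each = n_case)),
                     nrow = n_case)
    d_ctrl <- matrix(stats::rbinom(n_ctrl * m, 2L, rep(f_ctrl, each = n_ctrl)),
                     nrow = n_ctrl)
    dos <- rbind(d_case, d_ctrl) * 1.0
    if (config$missing_rate > 0) {
      dos[stats::runif(length(dos)) < config$missing_rate] <- NA_real_
    }
    info <- stats::runif(m, 0.5, 1)
    # orient ~half the variants with the effect allele on the REF side
    eff_is_alt <- stats::runif(m) < 0.5
    ref <- ifelse(eff_is_alt, sumstats$other_allele, sumstats$effect_allele)
    alt <- ifelse(eff_is_alt, sumstats$effect_allele, sumstats$other_allele)
    dos[, !eff_is_alt] <- 2 - dos[, !eff_is_alt]
    sample_ids <- c(sprintf("case_%02d", seq_len(n_case)),
                    sprintf("ctrl_%03d", seq_len(n_ctrl)))
    rownames(dos) <- sample_ids
    colnames(dos) <- sumstats$id
    variants <- data.frame(
      id = sumstats$id, chrom = sumstats$chrom, pos = sumstats$pos,
      ref = ref, alt = alt, info = info, maf = NA_real_,
      stringsAsFactors = FALSE)
    gm <- new_genotype_matrix(dos, variants)
    list(genotypes = gm,
         is_case = c(rep(TRUE, n_case), rep(FALSE, n_ctrl)))
  })
}

#' Simulate standardized-score cohorts directly
#'
#' Score-level shortcut for testing the association layer in isolation:
#' reference scores are Normal(0, 1) and case scores Normal(`delta`, 1).
#' Scores are returned unstandardized so the association layer may apply its
#' own standardization.
#'
#' @param delta case mean shift in SD units.
#' @param n_case,n_control group sizes (each at least 2 for downstream
#'   tests; smaller values are accepted here and rejected downstream).
#' @param seed integer RNG seed.
#' @return list with `scores` (a `score_set` with raw scores) and `is_case`.
#' @export
simulate_score_cohort <- function(delta, n_case = 22L, n_control = 307L,
                                  seed = 1L) {
  stopifnot(is.finite(delta), n_case >= 1, n_control >= 1)
  with_seed(seed, {
    raw <- c(stats::rnorm(n_case, mean = delta, sd = 1),
             stats::rnorm(n_control, mean = 0, sd = 1))
    ids <- c(sprintf("case_%02d", seq_len(n_case)),
             sprintf("ctrl_%03d", seq_len(n_control)))
    scores <- new_score_set(sample_id = ids, raw_score = raw,
                            trait_label = "simulated",
                            threshold = NA_real_, n_snps = NA_integer_)
    list(scores = scores,
         is_case = c(rep(TRUE, n_case), rep(FALSE, n_control)))
  })
}

#' Canonical symptom-to-domain map of the follow-up questionnaire
#'
#' Thirteen-column follow-up questionnaires in this package use twelve
#' canonical binary symptom columns grouped into four allergic-disorder
#' domains (asthma, allergic rhinitis, atopic dermatitis, food allergy).
#'
#' @return named character vector mapping symptom column to domain.
#' @export
default_symptom_domains <- function() {
  c(wheezing = "asthma",
    dyspnoea = "asthma",
    coughing_at_night = "asthma",
    asthma_diagnosed = "asthma",
    asthma_medication = "asthma",
    irritated_nasal_mucosa = "allergic_rhinitis",
    irritated_eyes = "allergic_rhinitis",
    rhinitis_diagnosed = "allergic_rhinitis",
    rhinitis_medication = "allergic_rhinitis",
    eczema = "atopic_dermatitis",
    topical_steroids = "atopic_dermatitis",
    food_allergy = "food_allergy")
}

#' Default per-symptom base rates
#'
#' Prevalences observed at the six-year follow-up of the 19-child former
#' cow's-milk-allergy cohort the generator emulates (e.g. nightly coughing
#' 5/19 = 26.3%, topical steroid use 6/19 = 31.6%).
#'
#' @return named numeric vector of probabilities, one per canonical symptom.
#' @export
default_base_rates <- function() {
  c(wheezing = 4 / 19,
    dyspnoea = 4 / 19,
    coughing_at_night = 5 / 19,
    asthma_diagnosed = 6 / 18,
    asthma_medication = 6 / 18,
    irritated_nasal_mucosa = 6 / 18,
    irritated_eyes = 3 / 19,
    rhinitis_diagnosed = 1 / 19,
    rhinitis_medication = 5 / 19,
    eczema = 7 / 19,
    topical_steroids = 6 / 19,
    food_allergy = 3 / 19)
}

#' Simulate prospective follow-up symptom tables
#'
#' Generates binary symptom indicators whose probability depends on each
#' subject's PRS through a logistic link:
#' `P(symptom_ij = 1) = plogis(qlogis(base_rate_j) + effect_j * score_i)`.
#' With all effects zero, prevalences match the base rates in expectation.
#'
#' @param scores a `score_set`; standardized scores are used when present.
#' @param symptom_effects named log-odds-per-SD effects, one per symptom;
#'   defaults to zero everywhere.
#' @param base_rates named per-symptom probabilities in (0, 1); defaults to
#'   [default_base_rates()].
#' @param seed integer RNG seed.
#' @return a `phenotype_table` with one row per score-set sample.
#' @export
simulate_followup_phenotypes <- function(scores, symptom_effects = NULL,
                                         base_rates = default_base_rates(),
                                         seed = 1L) {
  stopifnot(inherits(scores, "score_set"))
  domains <- default_symptom_domains()
  symptoms <- names(domains)
  if (is.null(symptom_effects)) {
    symptom_effects <- stats::setNames(rep(0, length(symptoms)), symptoms)
  }
  if (!all(symptoms %in% names(base_rates)) ||
      !all(symptoms %in% names(symptom_effects))) {
    stop("`base_rates` and `symptom_effects` must cover every canonical symptom",
         call. = FALSE)
  }
  for (s in symptoms) assert_scalar_prob(base_rates[[s]], paste0("base_rates$", s))
  x <- if ("std_score" %in% names(scores)) scores$std_score else scores$raw_score
  with_seed(seed, {
    cols <- lapply(symptoms, function(s) {
      p <- stats::plogis(stats::qlogis(base_rates[[s]]) + symptom_effects[[s]] * x)
      stats::rbinom(length(x), 1L, p)
    })
    names(cols) <- symptoms
    df <- data.frame(subject_id = scores$sample_id, cols,
                     stringsAsFactors = FALSE)
    new_phenotype_table(df, domains = domains)
  })
}

#' Synthetic reconstruction of the six-year follow-up table
#'
#' A deterministic 19-subject table whose margins match the published
#' follow-up characteristics of the former cow's-milk-allergy cohort: 6
#' female / 13 male, two IgE-positive subjects in the first 2.5 years (IgE
#' data available for 16 of 19), and the per-symptom counts such as nightly
#' coughing 5 (26.3%) or eczema 7 (36.8%). Three symptoms (diagnosed asthma,
#' asthma medication, irritated nasal mucosa) carry one missing response,
#' giving 6 positives of 18 respondents (33.3%). Which individual subject is
#' positive for which symptom is an arbitrary synthetic assignment; only the
#' margins are anchored.
#'
#' @return a `phenotype_table` with sex, age and IgE metadata columns.
#' @export
followup_reference_table <- function() {
  n <- 19L
  counts <- c(wheezing = 4L, dyspnoea = 4L, coughing_at_night = 5L,
              asthma_diagnosed = 6L, asthma_medication = 6L,
              irritated_nasal_mucosa = 6L, irritated_eyes = 3L,
              rhinitis_diagnosed = 1L, rhinitis_medication = 5L,
              eczema = 7L, topical_steroids = 6L, food_allergy = 3L)
  incomplete <- c("asthma_diagnosed", "asthma_medication",
                  "irritated_nasal_mucosa")
  cols <- lapply(seq_along(counts), function(k) {
    v <- integer(n)
    # staggered deterministic assignment so symptom splits are not nested
    pos <- ((seq_len(counts[[k]]) - 1L + 3L * (k - 1L)) %% n) + 1L
    v[pos] <- 1L
    v
  })
  names(cols) <- names(counts)
  for (s in incomplete) {
    v <- cols[[s]]
    na_at <- max(which(v == 0L))  # keep 6 positives over 18 respondents
    v[na_at] <- NA_integer_
    cols[[s]] <- v
  }
  df <- data.frame(
    subject_id = sprintf("cma_%02d", seq_len(n)),
    sex = c(rep("F", 6L), rep("M", 13L)),
    age = 7.0,
    ige_positive = c(1L, 1L, rep(0L, 14L), rep(NA_integer_, 3L)),
    cols, stringsAsFactors = FALSE)
  new_phenotype_table(df, domains = default_symptom_domains())
}
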