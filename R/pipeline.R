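#' Assemble and validate a pipeline configuration
#'
#' The configuration is one hierarchical, fully serializable object; the
#' resolved form is written as YAML next to each run's outputs.
#'
#' @param sumstats named list, one entry per trait: either a path or a list
#'   with `path` and optional `effect_scale` ("beta"/"or") and `column_map`.
#' @param genotypes path to the dosage VCF, or a list with `path` and
#'   optional `dosage_field` ("DS"/"GT") and `info_key`.
#' @param out_dir run output directory (created if absent).
#' @param phenotypes optional path to a follow-up phenotype CSV.
#' @param case_pattern regex on sample IDs identifying cases (default
#'   `"^case_"`); ignored when `case_ids` is given.
#' @param case_ids optional explicit character vector of case sample IDs.
#' @param thresholds P-value threshold grid.
#' @param qc list: `maf_min`, `info_min`, `call_rate_flag`, `drop_flagged`.
#' @param scoring list: `missing_policy`, `standardize_with`,
#'   `drop_ambiguous`.
#' @param association list: `var_equal`, `correction`, `symptom_cells`
#'   (list of `list(trait =, threshold =)` cells to test against the
#'   phenotypes; `NULL` = first trait at the smallest and largest
#'   thresholds).
#' @param seed integer seed recorded with the run (the analysis itself is
#'   deterministic).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(sumstats, genotypes, out_dir,
                            phenotypes = NULL,
                            case_pattern = "^case_", case_ids = NULL,
                            thresholds = default_pt_grid(),
                            qc = list(), scoring = list(),
                            association = list(), seed = 1L) {
  norm_entry <- function(x, defaults) {
    if (is.character(x)) x <- list(path = x)
    stopifnot(is.list(x), !is.null(x$path))
    utils::modifyList(defaults, x)
  }
  stopifnot(length(sumstats) >= 1L)
  if (is.null(names(sumstats)) || any(names(sumstats) == "")) {
    stop("`sumstats` must be a named list (one entry per trait)",
         call. = FALSE)
  }
  cfg <- list(
    sumstats = lapply(sumstats, norm_entry,
                      defaults = list(path = NULL, effect_scale = "beta",
                                      column_map = NULL)),
    genotypes = norm_entry(genotypes,
                           defaults = list(path = NULL, dosage_field = "DS",
                                           info_key = "INFO")),
    phenotypes = phenotypes,
    case_pattern = case_pattern,
    case_ids = case_ids,
    out_dir = out_dir,
    thresholds = sort(as.numeric(thresholds)),
    qc = utils::modifyList(list(maf_min = 0.01, info_min = 0.9,
                                call_rate_flag = 0.95,
                                drop_flagged = FALSE), qc),
    scoring = utils::modifyList(list(missing_policy = "mean_impute",
                                     standardize_with = "combined",
                                     drop_ambiguous = TRUE), scoring),
    association = utils::modifyList(list(var_equal = TRUE,
                                         correction = "none",
                                         symptom_cells = NULL), association),
    seed = as.integer(seed))
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  stopifnot(is.list(cfg))
  for (field in c("sumstats", "genotypes", "out_dir", "thresholds", "qc",
                  "scoring", "association", "seed")) {
    if (is.null(cfg[[field]])) {
      stop("pipeline config is missing field `", field, "`", call. = FALSE)
    }
  }
  if (any(cfg$thresholds <= 0 | cfg$thresholds > 1)) {
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  }
  if (!cfg$scoring$missing_policy %in% c("mean_impute", "zero", "exclude")) {
    stop("unknown missing policy: ", cfg$scoring$missing_policy,
         call. = FALSE)
  }
  if (!cfg$scoring$standardize_with %in% c("combined", "reference")) {
    stop("unknown standardization scope: ", cfg$scoring$standardize_with,
         call. = FALSE)
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [pipeline_config()]; relative
#'   input paths are resolved against the YAML file's directory.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  raw$sumstats <- lapply(raw$sumstats, function(x) {
    if (is.character(x)) x <- list(path = x)
    x$path <- resolve(x$path)
    x
  })
  if (is.character(raw$genotypes)) raw$genotypes <- list(path = raw$genotypes)
  raw$genotypes$path <- resolve(raw$genotypes$path)
  raw$phenotypes <- resolve(raw$phenotypes)
  if (is.null(raw$out_dir)) raw$out_dir <- file.path(base, "run")
  do.call(pipeline_config, raw[intersect(names(raw),
                                         names(formals(pipeline_config)))])
}

#' Run the full PRS pipeline
#'
#' Executes read, sample/variant QC, harmonization, grid scoring and the
#' association layers, writing all result tables, a log and the resolved
#' configuration into the run directory. Identical configuration yields
#' byte-identical outputs. Stages: `"qc"` stops after quality control,
#' `"score"` after grid scoring, `"associate"`/`"run"` execute everything
#' (the symptom layer runs only when phenotypes are configured).
#'
#' @param config a `pipeline_config` (or YAML path).
#' @param stage last stage to execute.
#' @param verbose print log lines as they are produced.
#' @return invisibly, a list with the run directory, log, and in-memory
#'   results of each executed stage.
#' @export
run_full_pipeline <- function(config, stage = c("run", "qc", "score",
                                                "associate"),
                              verbose = FALSE) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
  }
  finish <- function(results) {
    writeLines(log_lines, file.path(config$out_dir, "run.log"))
    yaml::write_yaml(unclass(config),
                     file.path(config$out_dir, "resolved_config.yaml"))
    invisible(c(results, list(out_dir = config$out_dir, log = log_lines)))
  }

  # --- read ---------------------------------------------------------------
  sumstats <- lapply(names(config$sumstats), function(trait) {
    entry <- config$sumstats[[trait]]
    ss <- read_summary_stats(entry$path, column_map = entry$column_map,
                             effect_scale = entry$effect_scale,
                             trait_label = trait)
    say("read %d variants for trait '%s' from %s (dropped: %s)",
        nrow(ss), trait, entry$path,
        paste(sprintf("%s=%d", names(attr(ss, "n_dropped")),
                      attr(ss, "n_dropped")), collapse = " "))
    ss
  })
  names(sumstats) <- names(config$sumstats)
  gm <- read_genotypes_vcf(config$genotypes$path,
                           dosage_field = config$genotypes$dosage_field,
                           info_key = config$genotypes$info_key)
  say("read genotype matrix: %d samples x %d variants",
      nrow(gm$dosage), ncol(gm$dosage))
  is_case <- if (!is.null(config$case_ids)) {
    gm$sample_ids %in% config$case_ids
  } else {
    grepl(config$case_pattern, gm$sample_ids)
  }
  say("cohort: %d cases, %d reference samples", sum(is_case), sum(!is_case))
  if (sum(is_case) == 0L) {
    stop("pipeline stage 'read': no case samples identified", call. = FALSE)
  }

  # --- qc -----------------------------------------------------------------
  qc_report <- compute_sample_call_rates(gm, config$qc$call_rate_flag)
  write_tsv_full(as.data.frame(qc_report),
                 file.path(config$out_dir, "qc_samples.tsv"))
  say("sample call rates: mean %.4f, %d flagged below %.2f (%s)",
      mean(qc_report$call_rate), sum(qc_report$flagged),
      config$qc$call_rate_flag,
      if (config$qc$drop_flagged) "dropped" else "retained")
  if (config$qc$drop_flagged && any(qc_report$flagged)) {
    gm <- drop_flagged_samples(gm, qc_report)
    is_case <- is_case[!qc_report$flagged]
  }
  gm_f <- filter_variants(gm, config$qc$maf_min, config$qc$info_min)
  cnt <- attr(gm_f, "qc_counts")
  say("variant QC (MAF > %g, INFO > %g): kept %d of %d (removed %d)",
      config$qc$maf_min, config$qc$info_min, cnt[["kept"]],
      cnt[["kept"]] + cnt[["removed"]], cnt[["removed"]])
  write_tsv_full(data.frame(rule = names(cnt), count = as.integer(cnt)),
                 file.path(config$out_dir, "qc_variants.tsv"))
  if (stage == "qc") {
    return(finish(list(genotypes = gm_f, sample_qc = qc_report,
                       is_case = is_case)))
  }

  # --- score --------------------------------------------------------------
  grid <- score_grid(gm_f, sumstats, thresholds = config$thresholds,
                     missing_policy = config$scoring$missing_policy,
                     standardize_with = config$scoring$standardize_with,
                     is_case = is_case,
                     drop_ambiguous = config$scoring$drop_ambiguous)
  for (trait in names(grid$harmonization)) {
    r <- grid$harmonization[[trait]]
    say("harmonized '%s': matched %d (flipped %d), dropped %d ambiguous + %d mismatched, %d unmatched",
        trait, r$n_matched, r$n_flipped, r$n_dropped_ambiguous,
        r$n_dropped_mismatch, r$n_unmatched)
  }
  for (i in seq_len(nrow(grid$summary))) {
    say("cell %s @ P_T < %g: n_snps = %d", grid$summary$trait[i],
        grid$summary$threshold[i], grid$summary$n_snps[i])
  }
  write_score_table(grid, file.path(config$out_dir, "scores.tsv"))
  if (stage == "score") {
    return(finish(list(genotypes = gm_f, sample_qc = qc_report,
                       is_case = is_case, grid = grid)))
  }

  # --- associate ----------------------------------------------------------
  assoc <- association_grid(grid, is_case,
                            var_equal = config$association$var_equal)
  write_association_table(assoc, file.path(config$out_dir,
                                           "associations.tsv"))
  say("association grid: %d cells written", nrow(assoc))

  symptoms <- NULL
  if (!is.null(config$phenotypes)) {
    ph <- read_phenotypes(config$phenotypes)
    cells <- config$association$symptom_cells
    if (is.null(cells)) {
      trait1 <- names(sumstats)[1]
      cells <- list(list(trait = trait1, threshold = min(config$thresholds)),
                    list(trait = trait1, threshold = max(config$thresholds)))
    }
    symptoms <- list()
    for (cell in cells) {
      key <- sprintf("%s@%g", cell$trait, cell$threshold)
      scores <- grid$cells[[key]]
      if (is.null(scores)) {
        say("symptom layer: cell %s empty, skipped", key)
        next
      }
      sa <- symptom_association(scores, ph,
                                correction = config$association$correction)
      out <- file.path(config$out_dir, sprintf("symptoms_%s_%g.tsv",
                                               cell$trait, cell$threshold))
      write_tsv_full(sa, out)
      say("symptom associations for %s: %d symptoms (%d testable)",
          key, nrow(sa), sum(sa$status == "ok"))
      symptoms[[key]] <- sa
    }
    write_tsv_full(summarize_phenotypes(ph),
                   file.path(config$out_dir, "phenotype_prevalence.tsv"))
  }
  finish(list(genotypes = gm_f, sample_qc = qc_report, is_case = is_case,
              grid = grid, associations = assoc, symptoms = symptoms))
}

#' Write a complete synthetic study to disk
#'
#' Generates five trait-specific GWAS summary-statistic files, one
#' case/control dosage VCF over the union of their variant panels, a
#' follow-up phenotype CSV for the first 19 cases, a sample sheet and a
#' ready-to-run pipeline YAML. Per-trait case enrichment is realized through
#' [calibrate_frequency_shift()]; by default only the asthma panel carries a
#' shift (0.58 SD) and asthma-domain symptoms depend on the asthma PRS.
#'
#' @param out_dir output directory.
#' @param config a [simulation_config()]; per-trait seeds are derived from
#'   its seed.
#' @param trait_deltas named numeric vector of per-trait standardized shift
#'   targets.
#' @param symptom_effects passed to [simulate_followup_phenotypes()];
#'   default: +0.8 log-odds per SD on the five asthma-domain symptoms.
#' @param n_followup number of cases with follow-up phenotypes.
#' @return invisibly, the list of written file paths.
#' @export
simulate_study_files <- function(out_dir,
                                 config = simulation_config(),
                                 trait_deltas = c(asthma = 0.58, asd = 0,
                                                  atopic_dermatitis = 0,
                                                  ibd = 0,
                                                  rheumatoid_arthritis = 0),
                                 symptom_effects = NULL,
                                 n_followup = 19L) {
  stopifnot(inherits(config, "simulation_config"),
            length(trait_deltas) >= 1L, !is.null(names(trait_deltas)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  dosages <- list()
  variant_tabs <- list()
  is_case <- NULL
  first_harm_scores <- NULL
  for (k in seq_along(trait_deltas)) {
    trait <- names(trait_deltas)[k]
    cfg_k <- config
    cfg_k$seed <- config$seed + 101L * k
    ss <- simulate_summary_stats(cfg_k, trait_label = trait)
    # disjoint ID space per trait panel
    ss$id <- sprintf("%s_%s", trait, ss$id)
    shift <- if (trait_deltas[[k]] != 0) {
      calibrate_frequency_shift(ss, threshold = 1,
                                delta_target = trait_deltas[[k]])
    } else NULL
    cohort <- simulate_cohort_genotypes(ss, shift, cfg_k)
    is_case <- cohort$is_case
    dosages[[trait]] <- cohort$genotypes$dosage
    variant_tabs[[trait]] <- cohort$genotypes$variants
    p <- file.path(out_dir, sprintf("%s_sumstats.tsv", trait))
    write_summary_stats(ss, p)
    paths[[sprintf("sumstats_%s", trait)]] <- p
    if (k == 1L) {
      harm <- harmonize(ss, cohort$genotypes, drop_ambiguous = FALSE)
      sc <- standardize_scores(compute_raw_prs(harm, p_threshold = 1))
      first_harm_scores <- sc
    }
  }
  gm <- new_genotype_matrix(do.call(cbind, dosages),
                            do.call(rbind, c(variant_tabs,
                                             make.row.names = FALSE)))
  vcf_path <- file.path(out_dir, "genotypes.vcf")
  write_genotypes_vcf(gm, vcf_path)
  paths$genotypes <- vcf_path

  case_scores <- first_harm_scores[is_case, , drop = FALSE]
  class(case_scores) <- class(first_harm_scores)
  attr(case_scores, "trait_label") <- names(trait_deltas)[1]
  n_followup <- min(n_followup, nrow(case_scores))
  fu <- case_scores[seq_len(n_followup), , drop = FALSE]
  class(fu) <- class(case_scores)
  if (is.null(symptom_effects)) {
    domains <- default_symptom_domains()
    symptom_effects <- stats::setNames(
      ifelse(domains == "asthma", 0.8, 0), names(domains))
  }
  ph <- simulate_followup_phenotypes(fu, symptom_effects = symptom_effects,
                                     seed = config$seed + 7L)
  ph_path <- file.path(out_dir, "phenotypes.csv")
  write_phenotypes(ph, ph_path)
  paths$phenotypes <- ph_path

  samples_path <- file.path(out_dir, "samples.csv")
  utils::write.csv(data.frame(sample_id = gm$sample_ids, is_case = is_case),
                   samples_path, row.names = FALSE)
  paths$samples <- samples_path

  cfg_yaml <- file.path(out_dir, "pipeline.yaml")
  yaml::write_yaml(list(
    sumstats = stats::setNames(
      lapply(names(trait_deltas),
             function(t) list(path = sprintf("%s_sumstats.tsv", t),
                              effect_scale = "beta")),
      names(trait_deltas)),
    genotypes = list(path = "genotypes.vcf", dosage_field = "DS",
                     info_key = "INFO"),
    phenotypes = "phenotypes.csv",
    case_pattern = "^case_",
    out_dir = file.path(out_dir, "run"),
    seed = config$seed), cfg_yaml)
  paths$config <- cfg_yaml
  invisible(paths)
}
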