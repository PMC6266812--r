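make_scores <- function(x) {
  prscross:::new_score_set(sprintf("s%02d", seq_along(x)), raw_score = x,
                           std_score = x, trait_label = "toy",
                           threshold = 1, n_snps = 1L)
}

test_that("the case/reference t-test matches hand calculations", {
  # identical groups: no mean difference at all
  sc <- make_scores(c(1, 2, 3, 1, 2, 3))
  tt <- ttest_case_control(sc, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(tt$delta, 0)
  expect_equal(tt$t_stat, 0)
  expect_equal(tt$t_p, 1)
  # textbook instance {1,2,3} vs {2,3,4}: pooled s = 1, se = sqrt(2/3)
  sc2 <- make_scores(c(1, 2, 3, 2, 3, 4))
  tt2 <- ttest_case_control(sc2, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(tt2$delta, -1)
  expect_equal(tt2$t_stat, -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tt2$t_p, 2 * stats::pt(-sqrt(3 / 2), df = 4),
               tolerance = 1e-12)
  # Welch variant is available by flag
  tw <- ttest_case_control(sc2, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                           var_equal = FALSE)
  expect_equal(tw$delta, tt2$delta)
})

test_that("the delta estimator is unbiased at the study's sample sizes", {
  deltas <- vapply(1:600, function(s) {
    sim <- simulate_score_cohort(0.41, 22, 307, seed = 2000 + s)
    std <- standardize_scores(sim$scores)
    ttest_case_control(std, sim$is_case)$delta
  }, numeric(1))
  expect_lt(abs(mean(deltas) - 0.41), 0.02)
})

test_that("logistic OR per SD is null-calibrated and flags separation", {
  sim <- simulate_score_cohort(0, 2000, 2000, seed = 41)
  std <- standardize_scores(sim$scores)
  lr <- logistic_or_per_sd(std, sim$is_case)
  expect_equal(lr$or_per_sd, 1, tolerance = 0.15)
  expect_true(lr$ci_low < 1 && lr$ci_high > 1)
  expect_identical(lr$status, "ok")
  # complete separation: flagged, no fabricated interval
  xs <- make_scores(c(5, 6, 7, -5, -6, -7))
  sep <- logistic_or_per_sd(xs, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(sep$status, "separation")
  expect_true(is.na(sep$ci_low) && is.na(sep$wald_p))
  expect_error(logistic_or_per_sd(make_scores(1:4), rep(TRUE, 4)),
               "both outcome classes")
})

test_that("OR, CI and P are internally consistent Wald quantities", {
  for (s in 1:25) {
    sim <- simulate_score_cohort(stats::runif(1, -0.8, 0.8), 40, 80,
                                 seed = 500 + s)
    lr <- logistic_or_per_sd(standardize_scores(sim$scores), sim$is_case)
    if (lr$status != "ok") next
    expect_true(lr$ci_low <= lr$or_per_sd & lr$or_per_sd <= lr$ci_high)
    expect_gt(lr$or_per_sd, 0)
    excludes_one <- lr$ci_low > 1 || lr$ci_high < 1
    expect_identical(lr$wald_p < 0.05, excludes_one)
  }
})

test_that("delta and log-OR agree in sign on non-degenerate cells", {
  for (s in 1:10) {
    sim <- simulate_score_cohort(c(-0.6, 0.6)[1 + s %% 2], 50, 100,
                                 seed = 900 + s)
    res <- associate_case_control(standardize_scores(sim$scores),
                                  sim$is_case)
    expect_identical(sign(res$delta), sign(log(res$or_per_sd)))
  }
})

test_that("two-level ANOVA equals the squared pooled t-test", {
  x <- c(0.3, -1.2, 0.8, 1.9, -0.4, 0.2, 1.1, -0.9, 0.5, 1.4)
  y <- c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L, 0L)
  sc <- make_scores(x)
  ph <- prscross:::new_phenotype_table(
    data.frame(subject_id = sc$sample_id, wheezing = y,
               stringsAsFactors = FALSE),
    domains = default_symptom_domains())
  sa <- symptom_association(sc, ph)
  t2 <- stats::t.test(x[y == 1], x[y == 0], var.equal = TRUE)$statistic^2
  expect_equal(sa$f_stat[sa$symptom == "wheezing"], unname(t2),
               tolerance = 1e-12)
})

test_that("single-level symptoms are untestable, not errors", {
  sc <- make_scores(stats::rnorm(8))
  ph <- prscross:::new_phenotype_table(
    data.frame(subject_id = sc$sample_id,
               wheezing = rep(1L, 8),          # everyone positive
               eczema = c(1L, rep(0L, 7)),
               food_allergy = c(NA, NA, 1L, 0L, 1L, 0L, 0L, 1L),
               stringsAsFactors = FALSE),
    domains = default_symptom_domains())
  sa <- symptom_association(sc, ph)
  expect_identical(sa$status[sa$symptom == "wheezing"], "untestable")
  expect_true(is.na(sa$f_stat[sa$symptom == "wheezing"]))
  expect_identical(sa$status[sa$symptom == "eczema"], "ok")
  # missing responses are excluded pairwise
  expect_identical(sa$n_yes[sa$symptom == "food_allergy"] +
                     sa$n_no[sa$symptom == "food_allergy"], 6L)
  # optional Bonferroni column appears only on request
  expect_false("p_adjusted" %in% names(sa))
  sab <- symptom_association(sc, ph, correction = "bonferroni")
  expect_true(all(sab$p_adjusted >= sab$p_value, na.rm = TRUE))
})

test_that("symptoms driven by the PRS show higher mean scores in positives", {
  gaps <- vapply(1:25, function(s) {
    set.seed(700 + s)
    sc <- make_scores(stats::rnorm(60))
    eff <- stats::setNames(rep(0, 12), names(default_symptom_domains()))
    eff["coughing_at_night"] <- 1
    ph <- simulate_followup_phenotypes(sc, symptom_effects = eff, seed = s)
    sa <- symptom_association(sc, ph)
    row <- sa[sa$symptom == "coughing_at_night", ]
    if (row$status != "ok") return(NA_real_)
    row$mean_prs_yes - row$mean_prs_no
  }, numeric(1))
  expect_gt(mean(gaps, na.rm = TRUE), 0)
  expect_gt(mean(gaps > 0, na.rm = TRUE), 0.9)
})

test_that("prevalence summaries report percent of non-missing and flag gaps", {
  ph <- followup_reference_table()
  tab <- summarize_phenotypes(ph)
  expect_equal(tab$percent[tab$symptom == "coughing_at_night"], 26.3)
  expect_equal(tab$percent[tab$symptom == "topical_steroids"], 31.6)
  # one missing response: 6 of 18 responders, denominator flagged
  row <- tab[tab$symptom == "asthma_diagnosed", ]
  expect_equal(row$percent, 33.3)
  expect_identical(row$n_responded, 18L)
  expect_true(row$denominator_differs)
  expect_false(tab$denominator_differs[tab$symptom == "wheezing"])
  # zero positives give 0.0%
  ph0 <- prscross:::new_phenotype_table(
    data.frame(subject_id = sprintf("s%d", 1:19), wheezing = 0L,
               stringsAsFactors = FALSE),
    domains = default_symptom_domains())
  expect_equal(summarize_phenotypes(ph0)$percent, 0)
  expect_identical(unique(tab$domain),
                   c("asthma", "allergic_rhinitis", "atopic_dermatitis",
                     "food_allergy"))
})
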