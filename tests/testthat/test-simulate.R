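test_that("simulation config validates its invariants", {
  expect_error(simulation_config(n_snps = 0), "n_snps")
  expect_error(simulation_config(causal_fraction = 1.2), "causal_fraction")
  expect_error(simulation_config(maf_range = c(0.4, 0.2)), "maf_range")
  expect_error(simulation_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(simulation_config(missing_rate = 1), "missing_rate")
})

test_that("identical config + seed reproduces identical outputs", {
  cfg <- simulation_config(n_snps = 200, seed = 11)
  ss1 <- simulate_summary_stats(cfg)
  ss2 <- simulate_summary_stats(cfg)
  expect_identical(ss1, ss2)
  sh <- calibrate_frequency_shift(ss1, 1, 0.41)
  coh1 <- simulate_cohort_genotypes(ss1, sh, cfg)
  coh2 <- simulate_cohort_genotypes(ss1, sh, cfg)
  expect_identical(coh1, coh2)
  sc1 <- simulate_score_cohort(0.41, seed = 5)
  sc2 <- simulate_score_cohort(0.41, seed = 5)
  expect_identical(sc1, sc2)
  ph1 <- simulate_followup_phenotypes(sc1$scores, seed = 5)
  ph2 <- simulate_followup_phenotypes(sc2$scores, seed = 5)
  expect_identical(ph1, ph2)
})

test_that("null GWAS P-values are uniform", {
  # with no causal variants, reported z is exactly standard normal
  for (seed in 1:5) {
    cfg <- simulation_config(n_snps = 2000, causal_fraction = 0, seed = seed)
    ss <- simulate_summary_stats(cfg)
    ks <- suppressWarnings(stats::ks.test(ss$p_value, "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("reported effects converge to true effects as n_gwas grows", {
  dev <- vapply(c(1e5, 1e7), function(n) {
    cfg <- simulation_config(n_snps = 500, causal_fraction = 1,
                             n_gwas = n, seed = 21)
    ss <- simulate_summary_stats(cfg)
    max(abs(ss$beta - attr(ss, "true_beta")))
  }, numeric(1))
  expect_lt(dev[2], dev[1])
  # max |noise| scales ~ 1/sqrt(n_gwas): 100x sample size, ~10x shrinkage
  expect_lt(dev[2], dev[1] / 5)
  expect_gt(dev[2], dev[1] / 20)
})

test_that("zero delta target produces a null frequency shift", {
  ss <- simulate_summary_stats(simulation_config(n_snps = 100, seed = 2))
  sh <- calibrate_frequency_shift(ss, 1, 0)
  expect_identical(sh$lambda, 0)
  expect_equal(sh$case_freq, sh$control_freq)
  expect_identical(sh$n_clipped, 0L)
})

test_that("single-variant tilt matches a numeric root-finder oracle", {
  for (d in c(0.2, 0.41, -0.3)) {
    ss <- toy_sumstats("v1", beta = 1, p = 0.5, eaf = 0.5)
    sh <- calibrate_frequency_shift(ss, 1, d)
    # oracle: solve E[raw diff](lambda) = d * sd_raw by 1-D root finding
    f <- 0.5; w <- 1
    sd_raw <- sqrt(w^2 * 2 * f * (1 - f))
    g <- function(l) w * 2 * (f + l * w * f * (1 - f) - f) - d * sd_raw
    lambda_oracle <- stats::uniroot(g, c(-50, 50), tol = 1e-12)$root
    expect_equal(sh$lambda, lambda_oracle, tolerance = 1e-8)
    expect_equal(sh$case_freq, f + sh$lambda * w * f * (1 - f))
  }
})

test_that("degenerate calibration inputs are rejected", {
  ss <- toy_sumstats(c("a", "b"), beta = c(0, 0), p = c(0.2, 0.4))
  expect_error(calibrate_frequency_shift(ss, 1, 0.4), "zero")
  ss2 <- toy_sumstats("a", beta = 1, p = 0.5)
  expect_error(calibrate_frequency_shift(ss2, 0.001, 0.4), "threshold")
})

test_that("extreme tilts are clipped and counted", {
  ss <- toy_sumstats(c("a", "b"), beta = c(5, 5), p = c(0.1, 0.1),
                     eaf = c(0.99, 0.99))
  sh <- calibrate_frequency_shift(ss, 1, 3)
  expect_true(all(sh$case_freq >= 1e-4 & sh$case_freq <= 1 - 1e-4))
  expect_gte(sh$n_clipped, 1L)
})

test_that("cohort genotypes honour missingness and frequency settings", {
  cfg0 <- simulation_config(n_snps = 150, missing_rate = 0, seed = 9)
  ss <- simulate_summary_stats(cfg0)
  coh <- simulate_cohort_genotypes(ss, NULL, cfg0)
  expect_false(anyNA(coh$genotypes$dosage))
  cr <- compute_sample_call_rates(coh$genotypes)
  expect_true(all(cr$call_rate == 1))
  expect_identical(sum(coh$is_case), cfg0$n_cases)
  expect_true(all(coh$genotypes$variants$info > 0.5 &
                  coh$genotypes$variants$info <= 1))

  # binomial expectation: f = 0.3 gives mean effect-allele dosage ~ 2f
  ss2 <- toy_sumstats(c("x1", "x2"), beta = c(0.1, -0.2), p = c(0.5, 0.5),
                      eaf = c(0.3, 0.3))
  cfg_big <- simulation_config(n_snps = 2, n_cases = 1, n_controls = 10000,
                               missing_rate = 0, seed = 4)
  coh2 <- simulate_cohort_genotypes(ss2, NULL, cfg_big)
  harm <- harmonize(ss2, coh2$genotypes, drop_ambiguous = FALSE)
  expect_equal(unname(colMeans(harm$dosage[!coh2$is_case, ])),
               c(0.6, 0.6), tolerance = 0.034)
})

test_that("null tilt leaves case and control dosage means exchangeable", {
  cfg <- simulation_config(n_snps = 1000, n_cases = 150, n_controls = 150,
                           missing_rate = 0, seed = 13)
  ss <- simulate_summary_stats(cfg)
  coh <- simulate_cohort_genotypes(ss, NULL, cfg)
  d <- coh$genotypes$dosage
  p <- vapply(seq_len(ncol(d)), function(j) {
    stats::t.test(d[coh$is_case, j], d[!coh$is_case, j])$p.value
  }, numeric(1))
  # per-variant two-sample t at alpha = 0.001: rejections stay near 0.1%
  expect_lte(sum(p < 0.001, na.rm = TRUE), 6)
})

test_that("score-level cohorts carry the requested shift", {
  sim <- simulate_score_cohort(0.41, 22, 307, seed = 3)
  expect_identical(nrow(sim$scores), 329L)
  expect_identical(sum(sim$is_case), 22L)
  # n_case = 1 is accepted here and rejected by the downstream t-test
  tiny <- simulate_score_cohort(0.5, n_case = 1, n_control = 10, seed = 1)
  expect_identical(sum(tiny$is_case), 1L)
  std <- standardize_scores(tiny$scores)
  expect_error(ttest_case_control(std, tiny$is_case), "at least 2")
})

test_that("follow-up phenotypes track base rates and PRS effects", {
  big <- simulate_score_cohort(0, 1000, 1000, seed = 8)
  std <- standardize_scores(big$scores)
  ph <- simulate_followup_phenotypes(std, seed = 8)
  expect_identical(attr(ph, "symptoms"), names(default_symptom_domains()))
  # null effects: prevalence within a 4-sigma binomial band of each base rate
  br <- default_base_rates()
  for (s in c("coughing_at_night", "eczema", "rhinitis_diagnosed")) {
    phat <- mean(ph[[s]])
    se <- sqrt(br[[s]] * (1 - br[[s]]) / nrow(ph))
    expect_lt(abs(phat - br[[s]]), 4 * se)
  }
  # positive effect on one symptom: positives have higher mean PRS
  eff <- stats::setNames(rep(0, 12), names(default_symptom_domains()))
  eff["coughing_at_night"] <- 1
  gaps <- vapply(1:20, function(s) {
    p2 <- simulate_followup_phenotypes(std, symptom_effects = eff, seed = s)
    x <- std$std_score
    mean(x[p2$coughing_at_night == 1]) - mean(x[p2$coughing_at_night == 0])
  }, numeric(1))
  expect_gt(mean(gaps), 0)
  expect_true(all(gaps > 0))
  expect_error(
    simulate_followup_phenotypes(std, base_rates = stats::setNames(
      c(1.2, br[-1]), names(br))), "base_rates")
})

test_that("the bundled follow-up reconstruction has the published margins", {
  ph <- followup_reference_table()
  expect_identical(nrow(ph), 19L)
  expect_identical(sum(ph$sex == "F"), 6L)
  expect_identical(sum(ph$sex == "M"), 13L)
  expect_identical(sum(ph$ige_positive, na.rm = TRUE), 2L)
  expect_identical(sum(!is.na(ph$ige_positive)), 16L)
  expect_identical(sum(ph$coughing_at_night), 5L)
  expect_identical(sum(ph$asthma_diagnosed, na.rm = TRUE), 6L)
  expect_identical(sum(!is.na(ph$asthma_diagnosed)), 18L)
  expect_identical(sum(ph$topical_steroids), 6L)
  expect_identical(sum(ph$eczema), 7L)
})
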