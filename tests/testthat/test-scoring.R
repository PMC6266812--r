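test_that("threshold selection is strict and monotone", {
  ss <- toy_sumstats(c("a", "b", "c", "d"), beta = rep(0.1, 4),
                     p = c(0.0005, 0.002, 0.5, 1))
  expect_identical(select_snps(ss, 0.001)$id, "a")
  # P = 1 rows are excluded even at the loosest threshold
  expect_identical(select_snps(ss, 1)$id, c("a", "b", "c"))
  counts <- vapply(default_pt_grid(), function(pt) nrow(select_snps(ss, pt)),
                   integer(1))
  brute <- vapply(default_pt_grid(),
                  function(pt) sum(ss$p_value < pt), integer(1))
  expect_identical(counts, brute)
  expect_true(all(diff(counts) >= 0))
  expect_error(select_snps(ss, 0), "0, 1")
  expect_identical(nrow(select_snps(ss, 1e-6)), 0L)
})

test_that("raw scores are the weighted dosage sums", {
  ss <- toy_sumstats("v1", beta = 0.3, p = 0.5)
  gm <- toy_genotypes(matrix(c(0, 1, 2), 3, 1), ids = "v1")
  sc <- compute_raw_prs(harmonize(ss, gm))
  expect_equal(sc$raw_score, c(0, 0.3, 0.6))
  expect_identical(attr(sc, "n_snps"), 1L)
  ss0 <- toy_sumstats(c("v1", "v2"), beta = c(0, 0), p = c(0.5, 0.5))
  gm0 <- toy_genotypes(matrix(rbinom(10, 2, 0.5), 5, 2))
  expect_equal(compute_raw_prs(harmonize(ss0, gm0))$raw_score, rep(0, 5))
})

test_that("missing-dosage policies behave as documented", {
  ss <- toy_sumstats(c("v1", "v2"), beta = c(1, 10), p = c(0.5, 0.5))
  d <- matrix(c(0, 2, NA, 1, 1, 1), nrow = 3)
  gm <- toy_genotypes(d)
  h <- harmonize(ss, gm)
  # mean imputation: missing v1 entry becomes mean(0, 2) = 1
  expect_equal(compute_raw_prs(h)$raw_score, c(10, 12, 11))
  expect_equal(compute_raw_prs(h, missing_policy = "zero")$raw_score,
               c(10, 12, 10))
  expect_equal(compute_raw_prs(h, missing_policy = "exclude")$raw_score,
               c(10, 10, 10))
  # a variant with no observed dosages is dropped with a warning
  d2 <- matrix(c(NA, NA, NA, 1, 1, 1), nrow = 3)
  h2 <- harmonize(ss, toy_genotypes(d2))
  expect_warning(sc2 <- compute_raw_prs(h2), "all dosages missing")
  expect_equal(sc2$raw_score, c(10, 10, 10))
  expect_identical(attr(sc2, "n_snps"), 1L)
})

test_that("scoring is linear in the weight vector", {
  cfg <- simulation_config(n_snps = 30, missing_rate = 0, seed = 19)
  ss <- simulate_summary_stats(cfg)
  coh <- simulate_cohort_genotypes(ss, NULL, cfg)
  w2 <- stats::rnorm(nrow(ss))
  ss_b <- ss; ss_b$beta <- w2
  ss_sum <- ss; ss_sum$beta <- ss$beta + w2
  s_a <- compute_raw_prs(harmonize(ss, coh$genotypes, drop_ambiguous = FALSE))
  s_b <- compute_raw_prs(harmonize(ss_b, coh$genotypes, drop_ambiguous = FALSE))
  s_ab <- compute_raw_prs(harmonize(ss_sum, coh$genotypes,
                                    drop_ambiguous = FALSE))
  expect_equal(s_a$raw_score + s_b$raw_score, s_ab$raw_score,
               tolerance = 1e-12)
})

test_that("standardization yields exact moments, idempotence, affine invariance", {
  sim <- simulate_score_cohort(0.41, 22, 307, seed = 23)
  std <- standardize_scores(sim$scores)
  expect_lt(abs(mean(std$std_score)), 1e-9)
  expect_lt(abs(stats::sd(std$std_score) - 1), 1e-9)
  # idempotence: standardizing an already standardized score changes nothing
  again <- sim$scores
  again$raw_score <- std$std_score
  expect_equal(standardize_scores(again)$std_score, std$std_score,
               tolerance = 1e-12)
  # invariance under positive affine transforms of the raw score
  affine <- sim$scores
  affine$raw_score <- 3.7 * sim$scores$raw_score - 42
  expect_equal(standardize_scores(affine)$std_score, std$std_score,
               tolerance = 1e-12)
  flat <- sim$scores
  flat$raw_score <- rep(1, nrow(flat))
  expect_error(standardize_scores(flat), "zero variance")
})

test_that("reference-only standardization centres the reference set", {
  sim <- simulate_score_cohort(0.5, 50, 200, seed = 31)
  std <- standardize_scores(sim$scores, reference = !sim$is_case)
  expect_lt(abs(mean(std$std_score[!sim$is_case])), 1e-9)
  expect_lt(abs(stats::sd(std$std_score[!sim$is_case]) - 1), 1e-9)
  expect_gt(mean(std$std_score[sim$is_case]), 0)
})

test_that("the score grid matches independent single-cell pipelines", {
  cfg <- simulation_config(n_snps = 400, seed = 17)
  traits <- lapply(1:5, function(k) {
    ck <- cfg; ck$seed <- cfg$seed + k
    simulate_summary_stats(ck, trait_label = sprintf("trait%d", k))
  })
  names(traits) <- vapply(traits, attr, "", "trait_label")
  coh <- simulate_cohort_genotypes(traits[[1]], NULL, cfg)
  grid <- score_grid(coh$genotypes, traits)
  expect_identical(nrow(grid$summary), 35L)  # 5 traits x 7 thresholds
  expect_identical(length(grid$cells), 35L)
  # n_snps is non-decreasing in the threshold within each trait
  for (tr in names(traits)) {
    ns <- grid$summary$n_snps[grid$summary$trait == tr]
    expect_true(all(diff(ns) >= 0))
  }
  # compositional equality against the single-call pipeline
  for (key in c("trait2@0.05", "trait4@1")) {
    cell <- grid$cells[[key]]
    if (is.null(cell)) next
    tr <- sub("@.*", "", key); pt <- as.numeric(sub(".*@", "", key))
    h <- harmonize(traits[[tr]], coh$genotypes)
    single <- standardize_scores(compute_raw_prs(h, p_threshold = pt))
    expect_equal(cell$std_score, single$std_score, tolerance = 1e-12)
    expect_identical(attr(cell, "n_snps"), attr(single, "n_snps"))
  }
})
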