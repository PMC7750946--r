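test_that("genotype dosages respect the Hardy-Weinberg support and MAF", {
  cfg <- sim_config(n_individuals = 10000, n_variants = 3,
                    maf_range = c(0.3, 0.3), seed = 11)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$dosages %in% 0:2))
  # binomial SE for the allele frequency: sqrt(p(1-p)/(2n))
  se <- sqrt(0.3 * 0.7 / (2 * 10000))
  expect_true(all(abs(g$variants$eaf - 0.3) < 4 * se))

  # MAF fixed at 0.5: mean dosage symmetric around 1
  g5 <- simulate_genotypes(sim_config(n_individuals = 20000, n_variants = 2,
                                      maf_range = c(0.5, 0.5), seed = 2))
  expect_true(all(abs(colMeans(g5$dosages) - 1) < 4 * sqrt(0.5 / (2 * 20000))))

  # rare variants still live on {0,1,2}
  g_rare <- simulate_genotypes(sim_config(n_individuals = 500, n_variants = 1,
                                          maf_range = c(0.001, 0.001), seed = 3))
  expect_true(all(g_rare$dosages %in% 0:2))
})

test_that("degenerate MAF ranges are rejected", {
  expect_error(sim_config(maf_range = c(0, 0.3)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_silent(sim_config(maf_range = c(0.2, 0.2)))
})

test_that("exposure variance decomposition matches the target h2", {
  cfg <- sim_config(n_individuals = 100000, n_variants = 50,
                    h2_exposure = 0.02, seed = 21, n_relative_pairs = 0)
  g <- simulate_genotypes(cfg)
  xo <- simulate_exposure_outcome(cfg, g)
  gcomp <- drop(g$dosages %*% xo$true_params$gamma)
  ratio <- var(gcomp) / var(xo$cohort$exposure)
  expect_lt(abs(ratio - 0.02), 0.005)
})

test_that("realized prevalence is calibrated to the target", {
  cfg <- sim_config(n_individuals = 10000, n_variants = 20,
                    baseline_prevalence = 0.09, seed = 5,
                    n_relative_pairs = 0)
  g <- simulate_genotypes(cfg)
  xo <- simulate_exposure_outcome(cfg, g)
  se <- sqrt(0.09 * 0.91 / 10000)
  expect_lt(abs(mean(xo$cohort$disease) - 0.09), 3 * se)
})

test_that("infeasible variance budgets are reported as calibration failures", {
  cfg <- sim_config(n_individuals = 100, n_variants = 5,
                    h2_exposure = 0.9, confounder_effect_x = 0.5, seed = 1)
  g <- simulate_genotypes(cfg)
  expect_error(simulate_exposure_outcome(cfg, g), "standardized exposure")
})

test_that("pleiotropy modes shape the direct variant-outcome effects", {
  g <- simulate_genotypes(sim_config(n_individuals = 100, n_variants = 200,
                                     seed = 4))
  for (mode in c("none", "balanced", "directional")) {
    cfg <- sim_config(n_individuals = 100, n_variants = 200,
                      pleiotropy_mode = mode, pleiotropy_sd = 0.05, seed = 4)
    a <- simulate_exposure_outcome(cfg, g)$true_params$alpha
    if (mode == "none") expect_true(all(a == 0))
    if (mode == "balanced") expect_lt(abs(mean(a)), 3 * 0.05 / sqrt(200))
    if (mode == "directional") expect_true(all(a >= 0))
  }
})

test_that("code assignment follows the stated sensitivity and specificity", {
  # perfect coding: derived primary cases equal latent cases exactly
  sim <- quick_sim(n = 2000, seed = 31, code_sensitivity = 1,
                   code_specificity = 1, p_meds_controls = 0,
                   p_endoscopy_controls = 0)
  st <- derive_gord(sim$cohort)
  expect_identical(st$primary == "case", sim$cohort$disease == 1L)

  # zero sensitivity, perfect specificity: no cases derived at all
  sim0 <- quick_sim(n = 1000, seed = 32, code_sensitivity = 0,
                    code_specificity = 1, p_surgery = 0)
  expect_equal(sum(derive_gord(sim0$cohort)$primary == "case"), 0)

  # closed-form expectation for the self-report code count:
  # n * (prev * sens + (1 - prev) * (1 - spec))
  cfg <- sim_config(n_individuals = 10000, n_variants = 10,
                    code_sensitivity = 0.8, code_specificity = 0.99,
                    baseline_prevalence = 0.09, seed = 33,
                    n_relative_pairs = 0)
  sim3 <- simulate_cohort(cfg)
  prev <- mean(sim3$cohort$disease)
  expected <- 10000 * (prev * 0.8 + (1 - prev) * 0.01)
  observed <- sum(sim3$cohort$self_report_codes == "1138")
  expect_lt(abs(observed - expected), 4 * sqrt(expected))
})

test_that("relatedness pairs are distinct, feasible and reproducible", {
  cfg0 <- sim_config(n_individuals = 100, n_relative_pairs = 0, seed = 1)
  expect_equal(nrow(simulate_relatedness(cfg0)), 0)

  expect_error(sim_config(n_individuals = 5, n_relative_pairs = 11),
               "exceeds")

  cfg <- sim_config(n_individuals = 50, n_variants = 5,
                    n_relative_pairs = 30, seed = 9)
  p1 <- simulate_relatedness(cfg)
  p2 <- simulate_relatedness(cfg)
  expect_identical(p1, p2)
  expect_true(all(p1$id1 != p1$id2))
  key <- paste(pmin(p1$id1, p1$id2), pmax(p1$id1, p1$id2))
  expect_false(any(duplicated(key)))
  expect_true(all(p1$kinship_degree %in% 1:3))
})

test_that("the whole simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_individuals = 500, n_variants = 10,
                    n_relative_pairs = 20, seed = 77)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$dosages, s2$dosages)
  expect_identical(s1$true_params, s2$true_params)
  expect_identical(s1$related_pairs, s2$related_pairs)
})

test_that("cohort files round-trip through the plain-text writers", {
  sim <- quick_sim(n = 50, m = 4, seed = 13)
  dir <- tempfile("cohort")
  paths <- write_cohort(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read.delim(paths["cohort"], stringsAsFactors = FALSE)
  expect_equal(nrow(back), 50)
  dos <- as.matrix(read.delim(paths["dosages"]))
  expect_equal(unname(dos), unname(sim$dosages))
  tp <- jsonlite::read_json(paths["params"])
  expect_equal(length(tp$gamma), 4)
  unlink(dir, recursive = TRUE)
})
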