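mk_instruments <- function(ids, ea, oa, beta) {
  data.frame(variant_id = ids, effect_allele = ea, other_allele = oa,
             beta = beta, stringsAsFactors = FALSE)
}

test_that("allele harmonization flips swapped variants and is idempotent", {
  ins <- mk_instruments("v1", "A", "G", 0.1)
  panel_swapped <- data.frame(variant_id = "v1", effect_allele = "G",
                              other_allele = "A", eaf = 0.7)
  h <- harmonize_instruments(ins, panel_swapped)
  expect_true(h$instruments$flip)
  expect_equal(h$instruments$panel_eaf, 0.3)

  panel_same <- data.frame(variant_id = "v1", effect_allele = "A",
                           other_allele = "G", eaf = 0.3)
  h2 <- harmonize_instruments(ins, panel_same)
  expect_false(h2$instruments$flip)

  # harmonizing the already-aligned table again changes nothing
  h3 <- harmonize_instruments(h2$instruments[, 1:4], panel_same)
  expect_identical(h3$instruments$flip, h2$instruments$flip)
})

test_that("incompatible allele pairs are dropped with a warning", {
  ins <- mk_instruments(c("v1", "v2"), c("A", "C"), c("G", "T"),
                        c(0.1, 0.2))
  panel <- data.frame(variant_id = c("v1", "v2"),
                      effect_allele = c("A", "C"),
                      other_allele = c("G", "A"))
  expect_warning(h <- harmonize_instruments(ins, panel), "dropped")
  expect_identical(h$instruments$variant_id, "v1")
  expect_equal(h$n_dropped, 1)
})

test_that("strand-ambiguous variants are flagged, and dropped in strict mode", {
  ins <- mk_instruments(c("v1", "v2"), c("A", "C"), c("T", "G"),
                        c(0.1, 0.2))
  panel <- data.frame(variant_id = c("v1", "v2"),
                      effect_allele = c("A", "C"),
                      other_allele = c("T", "G"))
  h <- harmonize_instruments(ins, panel)
  expect_identical(h$instruments$ambiguous, c(TRUE, TRUE))
  expect_warning(hs <- harmonize_instruments(ins, panel, strict = TRUE))
  expect_equal(nrow(hs$instruments), 0)
})

test_that("scores after harmonization equal scores on a hand-aligned copy", {
  set.seed(42)
  m <- 10
  ids <- paste0("v", 1:m)
  dos <- matrix(sample(0:2, 50 * m, replace = TRUE), 50, m,
                dimnames = list(NULL, ids))
  beta <- runif(m, 0.01, 0.3)
  # panel states alleles; instruments swap alleles for variants 2, 5, 9
  swap <- c(2, 5, 9)
  ins_ea <- rep("A", m); ins_oa <- rep("G", m)
  ins_ea[swap] <- "G"; ins_oa[swap] <- "A"
  ins <- mk_instruments(ids, ins_ea, ins_oa, beta)
  panel <- data.frame(variant_id = ids, effect_allele = "A",
                      other_allele = "G", eaf = colMeans(dos) / 2)
  h <- harmonize_instruments(ins, panel)
  ws <- grs_score(dos, h)
  # oracle: align by hand (recode the swapped dosage columns), plain loop
  dos_hand <- dos
  dos_hand[, swap] <- 2 - dos_hand[, swap]
  ws_hand <- numeric(50)
  for (i in 1:50) ws_hand[i] <- sum(beta * dos_hand[i, ])
  expect_equal(unname(as.numeric(ws)), ws_hand, tolerance = 1e-12)
})

test_that("the weighted score is the exact weighted allele sum", {
  # individual 1 carries dosages (1, 2), individual 2 carries (0, 0)
  d <- matrix(c(1, 0, 2, 0), 2, 2, dimnames = list(NULL, c("v1", "v2")))
  ins <- mk_instruments(c("v1", "v2"), "A", "G", c(0.1, 0.3))
  ws <- grs_score(d, ins)
  expect_equal(unname(ws[1]), 0.1 * 1 + 0.3 * 2)  # 0.7
  expect_equal(unname(ws[2]), 0)

  one <- grs_score(matrix(2, 1, 1, dimnames = list(NULL, "v1")),
                   mk_instruments("v1", "A", "G", 0.05))
  expect_equal(unname(as.numeric(one)), 0.10)
})

test_that("missing dosages are mean-imputed to 2*eaf and counted", {
  d <- matrix(c(NA, 2, 1, 1), 2, 2, dimnames = list(NULL, c("v1", "v2")))
  ins <- mk_instruments(c("v1", "v2"), "A", "G", c(0.5, 1))
  ws <- grs_score(d, ins)
  # v1 column mean among observed: dosage 2 -> eaf 1, imputed value 2
  expect_equal(unname(ws[1]), 0.5 * 2 + 1 * 1)
  expect_equal(attr(ws, "n_imputed"), 1)

  all_na <- matrix(NA_real_, 2, 1, dimnames = list(NULL, "v1"))
  expect_error(grs_score(all_na, mk_instruments("v1", "A", "G", 1)),
               "missing")
})

test_that("rescaling yields the trait-raising allele count scale", {
  ins <- mk_instruments(c("v1", "v2"), "A", "G", c(0.1, 0.3))
  expect_equal(grs_rescale(0.7, ins), 0.7 * 2 / 0.4)  # 3.5
  expect_equal(grs_rescale(0, ins), 0)

  # equal weights: rescaled score is the raw allele count
  d <- matrix(c(2, 1, 0, 1), 2, 2, dimnames = list(NULL, c("v1", "v2")))
  eq <- mk_instruments(c("v1", "v2"), "A", "G", c(0.2, 0.2))
  expect_equal(grs_rescale(grs_score(d, eq), eq), rowSums(d))

  # invariance to positive rescaling of all weights
  ins2 <- ins; ins2$beta <- ins$beta * 7.3
  d2 <- matrix(sample(0:2, 20, TRUE), 10, 2,
               dimnames = list(NULL, c("v1", "v2")))
  expect_equal(grs_rescale(grs_score(d2, ins), ins),
               grs_rescale(grs_score(d2, ins2), ins2), tolerance = 1e-12)

  zero <- mk_instruments(c("v1", "v2"), "A", "G", c(0.3, -0.3))
  expect_error(grs_rescale(1, zero), "zero")
})

test_that("instrument strength recovers the generative variance explained", {
  cfg <- sim_config(n_individuals = 100000, n_variants = 50,
                    h2_exposure = 0.02, seed = 91, n_relative_pairs = 0)
  g <- simulate_genotypes(cfg)
  xo <- simulate_exposure_outcome(cfg, g)
  score <- drop(g$dosages %*% xo$true_params$gamma)
  s <- grs_strength(score, xo$cohort$exposure)
  expect_lt(abs(s$r2 - 0.02), 0.005)
  expect_gt(s$f_stat, 1000)

  # independent score: R^2 near zero
  s0 <- grs_strength(rnorm(5000), rnorm(5000))
  expect_lt(s0$r2, 0.005)

  # degenerate perfect fit reported as such
  x <- rnorm(100)
  sp <- suppressWarnings(grs_strength(x, x))
  expect_equal(sp$r2, 1, tolerance = 1e-10)

  expect_error(grs_strength(rep(1, 10), rnorm(10)), "constant")
})
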