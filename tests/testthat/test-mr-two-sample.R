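mk_stats <- function(beta_x, beta_y, se_y, se_x = 0.01) {
  data.frame(variant_id = paste0("v", seq_along(beta_x)),
             beta_x = beta_x, se_x = se_x, beta_y = beta_y, se_y = se_y,
             stringsAsFactors = FALSE)
}

test_that("Wald ratio and its first-order SE follow the closed form", {
  w <- wald_ratio(0.1, 0.02, 0.01)
  expect_equal(w$estimate, 0.2)
  expect_equal(w$se, 0.01 / 0.1)
  expect_equal(wald_ratio(0.1, 0, 0.05)$estimate, 0)
  # delta-method oracle: d(by/bx)/d(by) = 1/bx, so se = se_y * |1/bx|
  expect_equal(wald_ratio(-0.25, 0.1, 0.03)$se, 0.03 / 0.25)
  expect_error(wald_ratio(0, 0.1, 0.01), "zero")
})

test_that("IVW equals the weight-averaged Wald ratios and detects homogeneity", {
  # all variants share the exact ratio c: estimate c, Q = 0
  bx <- c(0.1, 0.2, 0.05, 0.3)
  ss <- mk_stats(bx, 0.4 * bx, se_y = c(0.01, 0.05, 0.02, 0.04))
  est <- mr_ivw(ss)
  expect_equal(est$estimate, 0.4, tolerance = 1e-12)
  expect_equal(est$diagnostics$Q, 0, tolerance = 1e-20)

  # direct-summation oracle on an arbitrary fixture
  ss2 <- mk_stats(c(0.12, -0.08, 0.2, 0.05, 0.31),
                  c(0.03, -0.01, 0.09, 0.04, 0.02),
                  c(0.015, 0.02, 0.05, 0.01, 0.03))
  w <- ss2$beta_x^2 / ss2$se_y^2
  theta <- ss2$beta_y / ss2$beta_x
  expect_equal(mr_ivw(ss2)$estimate, sum(w * theta) / sum(w),
               tolerance = 1e-12)

  # one variant reduces to the Wald ratio
  one <- mr_ivw(mk_stats(0.1, 0.02, 0.01))
  expect_equal(one$estimate, 0.2)
  expect_equal(one$se, 0.1)
  expect_match(one$notes, "Wald")

  expect_error(mr_ivw(mk_stats(c(0, 0), c(0.1, 0.2), c(0.1, 0.1))),
               "zero")
})

test_that("random-effects IVW inflates the SE only under heterogeneity", {
  bx <- c(0.1, 0.2, 0.15, 0.25, 0.12)
  ss_hom <- mk_stats(bx, 0.3 * bx, se_y = rep(0.05, 5))
  expect_equal(mr_ivw(ss_hom, "random")$se, mr_ivw(ss_hom, "fixed")$se)

  set.seed(5)
  ss_het <- mk_stats(bx, 0.3 * bx + rnorm(5, 0, 0.2), se_y = rep(0.01, 5))
  expect_gt(mr_ivw(ss_het, "random")$se, mr_ivw(ss_het, "fixed")$se)
  Q <- mr_ivw(ss_het)$diagnostics$Q
  expect_equal(mr_ivw(ss_het, "random")$se,
               mr_ivw(ss_het, "fixed")$se * sqrt(Q / 4))
})

test_that("Egger fits exact lines and recovers injected constant pleiotropy", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  # points exactly on a line through the origin
  e0 <- mr_egger(mk_stats(bx, 0.5 * bx, se_y = c(0.01, 0.02, 0.01, 0.03)))
  expect_equal(e0$estimate, 0.5, tolerance = 1e-10)
  expect_equal(e0$diagnostics$intercept, 0, tolerance = 1e-10)

  # constant offset in every outcome effect lands in the intercept
  e1 <- mr_egger(mk_stats(bx, 0.5 * bx + 0.07,
                          se_y = c(0.01, 0.02, 0.01, 0.03)))
  expect_equal(e1$estimate, 0.5, tolerance = 1e-10)
  expect_equal(e1$diagnostics$intercept, 0.07, tolerance = 1e-10)

  expect_error(mr_egger(mk_stats(c(0.1, 0.2), c(0, 0), c(0.1, 0.1))),
               "at least 3")
})

test_that("estimators are invariant to joint allele-orientation flips", {
  set.seed(7)
  ss <- mk_stats(rnorm(8, 0.1, 0.05), rnorm(8, 0.03, 0.02),
                 runif(8, 0.01, 0.05), se_x = runif(8, 0.005, 0.02))
  flip <- c(2, 5, 7)
  ss2 <- ss
  ss2$beta_x[flip] <- -ss2$beta_x[flip]
  ss2$beta_y[flip] <- -ss2$beta_y[flip]
  expect_equal(mr_ivw(ss)$estimate, mr_ivw(ss2)$estimate, tolerance = 1e-12)
  expect_equal(mr_egger(ss)$estimate, mr_egger(ss2)$estimate,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(ss, 50, seed = 2)$estimate,
               mr_weighted_median(ss2, 50, seed = 2)$estimate,
               tolerance = 1e-12)
})

test_that("the weighted median reduces correctly in degenerate cases", {
  # all ratios identical: that ratio, whatever the weights
  bx <- c(0.1, 0.2, 0.4)
  wm <- mr_weighted_median(mk_stats(bx, 0.25 * bx,
                                    se_y = c(0.01, 0.05, 0.02)), 50, 1)
  expect_equal(wm$estimate, 0.25, tolerance = 1e-12)

  # equal weights, odd k: the simple median of the ratios
  bx <- rep(0.2, 5)
  by <- c(0.01, 0.05, 0.03, 0.09, 0.07)
  wm2 <- mr_weighted_median(mk_stats(bx, by, se_y = rep(0.02, 5)), 50, 1)
  expect_equal(wm2$estimate, median(by / bx), tolerance = 1e-12)

  expect_error(mr_weighted_median(mk_stats(0.1, 0.1, 0.1), 10, 1),
               "at least 3")
})

test_that("the weighted median resists directional pleiotropy better than IVW", {
  # 40% of variants get a large directional outcome offset
  set.seed(11)
  reps <- 200; k <- 25; theta <- 0.3
  bias_ivw <- bias_wm <- numeric(reps)
  for (r in seq_len(reps)) {
    bx <- runif(k, 0.05, 0.2)
    alpha <- ifelse(seq_len(k) <= 0.4 * k, 0.1, 0)
    se_y <- runif(k, 0.005, 0.015)
    ss <- mk_stats(rnorm(k, bx, 0.005),
                   rnorm(k, theta * bx + alpha, se_y), se_y,
                   se_x = 0.005)
    bias_ivw[r] <- mr_ivw(ss)$estimate - theta
    bias_wm[r] <- mr_weighted_median(ss, 1, seed = r)$estimate - theta
  }
  expect_lt(abs(mean(bias_wm)), 0.5 * abs(mean(bias_ivw)))
})

test_that("the association scan recovers generative effects and is exact", {
  set.seed(21)
  n <- 2000
  g <- matrix(rbinom(n, 2, 0.3), n, 1, dimnames = list(NULL, "v1"))
  y <- 0.2 * g[, 1] + rnorm(n)
  sc <- gwas_scan(g, y)
  expect_lt(abs(sc$beta - 0.2), 3 * sc$se)
  # agrees with lm to numerical precision
  fit <- summary(lm(y ~ g[, 1]))$coefficients
  expect_equal(sc$beta, fit[2, 1], tolerance = 1e-10)
  expect_equal(sc$se, fit[2, 2], tolerance = 1e-10)

  # binary scan agrees with glm
  yb <- rbinom(n, 1, plogis(-2 + 0.3 * g[, 1]))
  scb <- gwas_scan(g, yb, trait_type = "binary")
  fitb <- summary(glm(yb ~ g[, 1], family = binomial()))$coefficients
  expect_equal(scb$beta, fitb[2, 1], tolerance = 1e-6)
  expect_equal(scb$se, fitb[2, 2], tolerance = 1e-6)

  # covariate adjustment matches the full model
  age <- rnorm(n)
  sca <- gwas_scan(g, y, covariates = data.frame(age = age))
  fita <- summary(lm(y ~ age + g[, 1]))$coefficients
  expect_equal(sca$beta, fita[3, 1], tolerance = 1e-10)
})

test_that("null scans give uniform p-values and monomorphic variants drop", {
  set.seed(22)
  n <- 500
  g <- matrix(rbinom(n * 200, 2, 0.3), n, 200,
              dimnames = list(NULL, paste0("v", 1:200)))
  y <- rnorm(n)
  sc <- gwas_scan(g, y)
  ks <- suppressWarnings(ks.test(sc$p, "punif"))
  expect_gt(ks$p.value, 0.001)

  g2 <- cbind(g[, 1:3], mono = 1L)
  expect_message(sc2 <- gwas_scan(g2, y), "monomorphic")
  expect_equal(nrow(sc2), 3)

  # determinism: identical inputs, identical output
  expect_identical(gwas_scan(g[, 1:5], y), gwas_scan(g[, 1:5], y))
})

test_that("summary statistics merge and validate", {
  ex <- data.frame(variant_id = c("a", "b"), beta = c(0.1, 0.2),
                   se = c(0.01, 0.02))
  oc <- data.frame(variant_id = c("b", "a"), beta = c(0.05, 0.03),
                   se = c(0.02, 0.01))
  ss <- make_summary_stats(ex, oc)
  expect_equal(ss$beta_y[ss$variant_id == "b"], 0.05)
  expect_true(attr(ss, "same_cohort"))
  oc_bad <- oc; oc_bad$se[1] <- 0
  expect_error(make_summary_stats(ex, oc_bad), "positive")
})
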