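# Independent re-implementations used as oracles. These deliberately take
# the most literal route (per-individual loops, exhaustive enumeration)
# and share no code with the package internals.

# phenotype rules, one individual at a time
oracle_derive <- function(cohort) {
  n <- nrow(cohort)
  primary <- sa1 <- sa2 <- sa3 <- character(n)
  for (i in seq_len(n)) {
    sr <- strsplit(cohort$self_report_codes[i], ",", fixed = TRUE)[[1]]
    ic <- strsplit(cohort$icd10_codes[i], ",", fixed = TRUE)[[1]]
    op <- strsplit(cohort$opcs4_codes[i], ",", fixed = TRUE)[[1]]
    self_ev <- "1138" %in% sr
    icd_ev <- any(c("K21.9", "K21.0") %in% ic)
    k210 <- "K21.0" %in% ic
    surg <- any(c("G24", "G25") %in% op)
    case <- self_ev || icd_ev || surg
    primary[i] <- if (case) "case" else "control"
    if (case) {
      sa1[i] <- if (self_ev && !icd_ev && !surg) "excluded" else "case"
      sa2[i] <- if (sa1[i] == "case" && k210) "case" else "excluded"
      sa3[i] <- if (sa2[i] == "case" && surg && (self_ev || icd_ev))
        "case" else "excluded"
    } else {
      excl <- cohort$on_acid_suppressant[i] || cohort$had_endoscopy_g45[i]
      sa1[i] <- sa2[i] <- sa3[i] <- if (excl) "excluded" else "control"
    }
  }
  data.frame(id = cohort$id, primary = primary, sa1 = sa1, sa2 = sa2,
             sa3 = sa3, stringsAsFactors = FALSE)
}

# exhaustive maximum independent set for graphs with <= ~16 nodes:
# every node subset is a bitmask; a subset is independent iff it contains
# no edge's two endpoints
oracle_max_independent_set <- function(ids, edges) {
  n <- length(ids)
  masks <- 0:(2^n - 1)
  ok <- rep(TRUE, length(masks))
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      em <- 2^(match(edges$id1[e], ids) - 1) +
        2^(match(edges$id2[e], ids) - 1)
      ok <- ok & bitwAnd(masks, em) != em
    }
  }
  sizes <- vapply(masks[ok], function(m) sum(bitwAnd(m, 2^(0:(n - 1))) > 0),
                  numeric(1))
  max(sizes)
}

is_independent_set <- function(retained, edges) {
  if (!nrow(edges)) return(TRUE)
  !any(edges$id1 %in% retained & edges$id2 %in% retained)
}

random_graph <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  ids <- LETTERS[seq_len(n_nodes)]
  combs <- t(combn(ids, 2))
  pick <- runif(nrow(combs)) < p_edge
  data.frame(id1 = combs[pick, 1], id2 = combs[pick, 2],
             stringsAsFactors = FALSE)
}

# variant filter, one record at a time
oracle_filter <- function(variants, info_min, maf_min, p_max) {
  keep <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    maf <- min(variants$eaf[i], 1 - variants$eaf[i])
    keep[i] <- variants$info[i] >= info_min && maf >= maf_min &&
      variants$p[i] < p_max
  }
  variants[keep, , drop = FALSE]
}

# summary statistics drawn under a null of no directional pleiotropy:
# beta_y = theta * beta_x + noise, precise exposure side
null_summary_stats <- function(k = 30, theta = 0.2, seed = 1) {
  set.seed(seed)
  bx <- runif(k, 0.03, 0.10)
  se_x <- rep(0.004, k)
  se_y <- runif(k, 0.03, 0.06)
  data.frame(variant_id = paste0("v", seq_len(k)),
             beta_x = rnorm(k, bx, se_x), se_x = se_x,
             beta_y = rnorm(k, theta * bx, se_y), se_y = se_y,
             stringsAsFactors = FALSE)
}

# small cohort simulated directly through the package generator stages
quick_sim <- function(n = 2000, m = 20, seed = 1, ...) {
  simulate_cohort(sim_config(n_individuals = n, n_variants = m,
                             n_relative_pairs = 0, seed = seed, ...))
}

# one parameter-recovery replicate: simulate a cohort, fit the one-sample
# two-stage IV and the same-cohort two-sample IVW, and compute the
# same-data oracle IVW (true variant-exposure effects, estimated outcome
# scan), which is the estimand the CIs should cover
recovery_replicate <- function(n, m, h2, causal_beta, seed) {
  cfg <- sim_config(n_individuals = n, n_variants = m, h2_exposure = h2,
                    causal_beta = causal_beta, pleiotropy_mode = "none",
                    n_relative_pairs = 0, seed = seed)
  g <- simulate_genotypes(cfg)
  xo <- simulate_exposure_outcome(cfg, g)
  score <- drop(g$dosages %*% xo$true_params$gamma)
  est1 <- suppressWarnings(
    mr_two_stage(score, xo$cohort$exposure, xo$cohort$disease))
  ex <- gwas_scan(g$dosages, inverse_normal(xo$cohort$exposure))
  oc <- gwas_scan(g$dosages, xo$cohort$disease, trait_type = "binary")
  est2 <- mr_ivw(make_summary_stats(ex, oc))
  oracle <- mr_ivw(data.frame(beta_x = unname(xo$true_params$gamma),
                              beta_y = oc$beta, se_y = oc$se))$estimate
  list(two_stage = est1, ivw = est2, oracle = oracle)
}

# Monte-Carlo power of the two-stage IV under a clean generative model
mc_power <- function(n, r2, or, case_fraction, reps, seed_base) {
  rej <- 0L
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_individuals = n, n_variants = 20,
                      h2_exposure = r2, causal_beta = log(or),
                      confounder_effect_x = 0, confounder_effect_y = 0,
                      baseline_prevalence = case_fraction,
                      n_relative_pairs = 0, seed = seed_base + r)
    g <- simulate_genotypes(cfg)
    xo <- simulate_exposure_outcome(cfg, g)
    score <- drop(g$dosages %*% xo$true_params$gamma)
    est <- suppressWarnings(
      mr_two_stage(score, xo$cohort$exposure, xo$cohort$disease))
    if (est$p < 0.05) rej <- rej + 1L
  }
  rej / reps
}

# the 12-point power grid: case fraction and effect sizes mirror the
# study's setting (9% cases, MR odds ratios near 1.2)
power_grid <- expand.grid(n = c(2000, 5000), r2 = c(0.01, 0.02, 0.05),
                          or = c(1.2, 1.3))
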