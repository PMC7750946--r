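#' Simulate biallelic genotype dosages under Hardy-Weinberg equilibrium
#'
#' Each variant is assigned a minor-allele frequency drawn uniformly from
#' \code{config$maf_range} and dosages are drawn as Binomial(2, MAF)
#' counts of the effect allele, independently across variants (no linkage
#' disequilibrium). Effect/other alleles, the empirical allele frequency
#' and an imputation-quality (INFO) placeholder of 1 are recorded per
#' variant.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{dosages} (n x m integer matrix, values 0/1/2,
#'   columns named by variant id) and \code{variants} (data frame:
#'   \code{variant_id}, \code{effect_allele}, \code{other_allele},
#'   \code{maf} generative, \code{eaf} empirical, \code{info}).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, .seed_offsets[["genotypes"]]))
  n <- config$n_individuals
  m <- config$n_variants
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  dos <- vapply(maf, function(p) stats::rbinom(n, 2L, p), integer(n))
  dim(dos) <- c(n, m)
  ids <- sprintf("rs%05d", seq_len(m))
  colnames(dos) <- ids
  # random non-identical allele pairs; some A/T and C/G pairs arise, which
  # downstream harmonization must flag as strand-ambiguous
  bases <- c("A", "C", "G", "T")
  ea <- sample(bases, m, replace = TRUE)
  oa <- vapply(ea, function(b) sample(setdiff(bases, b), 1L), character(1))
  variants <- data.frame(
    variant_id = ids,
    effect_allele = ea,
    other_allele = oa,
    maf = maf,
    eaf = colMeans(dos) / 2,
    info = rep(1.0, m),
    stringsAsFactors = FALSE
  )
  list(dosages = dos, variants = variants)
}

# Calibrate the logistic intercept by bisection so that the mean simulated
# case probability hits the target prevalence to +/- tol. No closed form
# exists once the linear predictor mixes genetic, exposure and confounder
# terms.
calibrate_intercept <- function(eta, target, tol = 1e-3, max_iter = 200L) {
  f <- function(a) mean(stats::plogis(a + eta)) - target
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0) {
    stop("prevalence calibration failed: target unreachable", call. = FALSE)
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (abs(f(mid)) <= tol || (hi - lo) < 1e-12) return(mid)
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Simulate exposure, confounder, covariates and disease outcome
#'
#' The exposure is built as genetic component + confounder + noise with the
#' genetic share of variance calibrated to \code{h2_exposure}; the binary
#' outcome follows a logistic model in the standardized exposure, the
#' confounder and any direct (pleiotropic) variant effects, with the
#' intercept calibrated by bisection so the realized prevalence matches the
#' target. Age, sex, assessment centre, genotyping platform and four
#' ancestry principal components are simulated independently of everything
#' else, mirroring covariates that are adjusted for but carry no signal.
#'
#' @param config A \code{\link{sim_config}}.
#' @param genotypes Result of \code{\link{simulate_genotypes}}.
#' @return List with \code{cohort} (data frame, one row per individual) and
#'   \code{true_params} (per-variant exposure slopes \code{gamma},
#'   pleiotropic log-ORs \code{alpha}, \code{causal_beta}, confounder
#'   slopes, calibrated intercept, and the latent confounder kept for
#'   oracle checks).
#' @export
simulate_exposure_outcome <- function(config, genotypes) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, .seed_offsets[["exposure"]]))
  dos <- genotypes$dosages
  n <- nrow(dos); m <- ncol(dos)
  h2 <- config$h2_exposure
  cx <- config$confounder_effect_x
  if (h2 + cx^2 >= 1) {
    stop(sprintf("h2_exposure (%.3f) plus squared confounder effect (%.3f) must be < 1 on the standardized exposure scale",
                 h2, cx^2), call. = FALSE)
  }
  # raw per-variant slopes, then rescaled so the genetic component has
  # variance h2 when the total exposure variance is 1
  gamma_raw <- stats::rnorm(m)
  gcomp_raw <- drop(dos %*% gamma_raw)
  sd_raw <- stats::sd(gcomp_raw)
  if (h2 > 0 && sd_raw < .Machine$double.eps) {
    stop("h2_exposure infeasible: genetic component has zero variance",
         call. = FALSE)
  }
  gamma <- if (h2 > 0) gamma_raw * sqrt(h2) / sd_raw else numeric(m)
  gcomp <- if (h2 > 0) gcomp_raw * sqrt(h2) / sd_raw else numeric(n)

  U <- stats::rnorm(n)
  eps_sd <- sqrt(1 - h2 - cx^2)
  X <- gcomp + cx * U + stats::rnorm(n, sd = eps_sd)
  X_std <- (X - mean(X)) / stats::sd(X)

  alpha <- switch(config$pleiotropy_mode,
    none        = numeric(m),
    balanced    = stats::rnorm(m, 0, config$pleiotropy_sd),
    directional = abs(stats::rnorm(m, 0, config$pleiotropy_sd))
  )
  eta <- config$causal_beta * X_std +
    config$confounder_effect_y * U +
    drop(dos %*% alpha)
  a0 <- calibrate_intercept(eta, config$baseline_prevalence)
  Y <- stats::rbinom(n, 1L, stats::plogis(a0 + eta))

  cohort <- data.frame(
    id = sprintf("ID%06d", seq_len(n)),
    age = sample(40:69, n, replace = TRUE),
    sex = stats::rbinom(n, 1L, 0.46),
    centre = sample(paste0("C", 1:10), n, replace = TRUE),
    platform = sample(c("axiom", "bileve"), n, replace = TRUE,
                      prob = c(0.9, 0.1)),
    pc1 = stats::rnorm(n), pc2 = stats::rnorm(n),
    pc3 = stats::rnorm(n), pc4 = stats::rnorm(n),
    exposure = X,
    disease = Y,
    stringsAsFactors = FALSE
  )
  true_params <- list(
    gamma = stats::setNames(gamma, colnames(dos)),
    alpha = stats::setNames(alpha, colnames(dos)),
    causal_beta = config$causal_beta,
    confounder_effect_x = config$confounder_effect_x,
    confounder_effect_y = config$confounder_effect_y,
    intercept = a0,
    confounder = U
  )
  list(cohort = cohort, true_params = true_params)
}

#' Attach diagnosis, procedure, self-report and medication codes
#'
#' Maps the latent disease status to the code families a hospital-records
#' phenotype algorithm consumes. True cases receive, independently with
#' probability \code{code_sensitivity}, a self-report code 1138 and an
#' ICD10 reflux code (K21.0 with probability \code{p_esophagitis}, else
#' K21.9), and with probability \code{p_surgery} an anti-reflux operation
#' code (G24, occasionally G25). Non-cases receive each family at rate
#' \code{1 - code_specificity}. A fraction of non-cases is flagged as
#' taking acid-suppressant medication or as having had an upper-GI
#' endoscopy (G45), the groups the stricter control definitions exclude.
#'
#' @param cohort Data frame from \code{\link{simulate_exposure_outcome}}
#'   (needs column \code{disease}).
#' @param config A \code{\link{sim_config}}.
#' @return The cohort with columns \code{self_report_codes},
#'   \code{icd10_codes}, \code{opcs4_codes} (comma-separated strings, empty
#'   when absent), \code{on_acid_suppressant} and \code{had_endoscopy_g45}.
#' @export
simulate_codes <- function(cohort, config) {
  stopifnot(inherits(config, "sim_config"), "disease" %in% names(cohort))
  set.seed(child_seed(config$seed, .seed_offsets[["codes"]]))
  n <- nrow(cohort)
  case <- cohort$disease == 1L
  sens <- config$code_sensitivity
  fpr <- 1 - config$code_specificity

  hit <- function(p_case, p_ctrl) {
    stats::runif(n) < ifelse(case, p_case, p_ctrl)
  }
  self_rep <- hit(sens, fpr)
  icd <- hit(sens, fpr)
  icd_k210 <- icd & (stats::runif(n) < config$p_esophagitis)
  surgery <- hit(config$p_surgery, fpr * config$p_surgery)
  surgery_rev <- surgery & (stats::runif(n) < 0.1)

  cohort$self_report_codes <- ifelse(self_rep, "1138", "")
  cohort$icd10_codes <- ifelse(icd, ifelse(icd_k210, "K21.0", "K21.9"), "")
  cohort$opcs4_codes <- ifelse(surgery,
                               ifelse(surgery_rev, "G24,G25", "G24"), "")
  # medication/endoscopy flags: common in true cases, present in a stated
  # fraction of non-cases (undiagnosed or treated reflux)
  cohort$on_acid_suppressant <- hit(0.6, config$p_meds_controls)
  cohort$had_endoscopy_g45 <- hit(0.3, config$p_endoscopy_controls)
  ge <- cohort$had_endoscopy_g45
  cohort$opcs4_codes <- ifelse(ge,
    ifelse(cohort$opcs4_codes == "", "G45",
           paste0(cohort$opcs4_codes, ",G45")),
    cohort$opcs4_codes)
  cohort
}

#' Simulate third-degree-or-closer relative pairs
#'
#' Draws \code{n_relative_pairs} distinct undirected pairs. With
#' probability \code{p_chain} a new pair reuses an individual already
#' involved in one, producing chains (A-B, A-C) so that the greedy
#' unrelated-selection rule is exercised, not just simple pairs.
#'
#' @param config A \code{\link{sim_config}}.
#' @return Data frame with columns \code{id1}, \code{id2},
#'   \code{kinship_degree} (1-3); zero rows when no pairs were requested.
#' @export
simulate_relatedness <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, .seed_offsets[["relatedness"]]))
  ids <- sprintf("ID%06d", seq_len(config$n_individuals))
  k <- config$n_relative_pairs
  out <- data.frame(id1 = character(0), id2 = character(0),
                    kinship_degree = integer(0), stringsAsFactors = FALSE)
  if (k == 0L) return(out)
  seen <- character(0)   # ids already in some pair
  keys <- character(0)   # canonical "a|b" keys of emitted pairs
  id1 <- id2 <- character(k); deg <- integer(k)
  for (j in seq_len(k)) {
    repeat {
      if (length(seen) > 0 && stats::runif(1) < config$p_chain) {
        a <- sample(seen, 1L)
      } else {
        a <- sample(ids, 1L)
      }
      b <- sample(setdiff(ids, a), 1L)
      key <- paste(sort(c(a, b)), collapse = "|")
      if (!key %in% keys) break
    }
    keys <- c(keys, key)
    seen <- union(seen, c(a, b))
    id1[j] <- a; id2[j] <- b
    deg[j] <- sample(1:3, 1L)
  }
  data.frame(id1 = id1, id2 = id2, kinship_degree = deg,
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic cohort
#'
#' Runs the four generator stages (genotypes; exposure and outcome; coded
#' phenotype fields; relatedness) under one configuration. Each stage uses
#' a fixed child seed of \code{config$seed}, so re-running any stage, or
#' the whole cohort, is byte-identical.
#'
#' @param config A \code{\link{sim_config}}.
#' @return Object of class \code{"sim_cohort"}: list with \code{config},
#'   \code{cohort} (data frame), \code{dosages} (matrix), \code{variants}
#'   (data frame), \code{true_params}, \code{related_pairs}.
#' @examples
#' sim <- simulate_cohort(sim_config(n_individuals = 300, n_variants = 5,
#'                                   n_relative_pairs = 10, seed = 42))
#' sim
#' @export
simulate_cohort <- function(config = sim_config()) {
  geno <- simulate_genotypes(config)
  xo <- simulate_exposure_outcome(config, geno)
  cohort <- simulate_codes(xo$cohort, config)
  pairs <- simulate_relatedness(config)
  structure(list(
    config = config,
    cohort = cohort,
    dosages = geno$dosages,
    variants = geno$variants,
    true_params = xo$true_params,
    related_pairs = pairs
  ), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d individuals x %d variants\n",
              nrow(x$cohort), ncol(x$dosages)))
  cat(sprintf("  latent cases: %d (%.1f%%)   relative pairs: %d\n",
              sum(x$cohort$disease), 100 * mean(x$cohort$disease),
              nrow(x$related_pairs)))
  cat(sprintf("  pleiotropy: %s   causal log-OR/SD: %.4f\n",
              x$config$pleiotropy_mode, x$config$causal_beta))
  invisible(x)
}

#' Write a simulated cohort to plain-text files
#'
#' Emits the per-individual table and relative pairs as tab-separated
#' files, the dosage matrix as a tab-separated table with a header row of
#' variant ids, and the generative parameters as JSON.
#'
#' @param sim A \code{"sim_cohort"}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    cohort = file.path(dir, "cohort.tsv"),
    dosages = file.path(dir, "dosages.tsv"),
    variants = file.path(dir, "variants.tsv"),
    pairs = file.path(dir, "related_pairs.tsv"),
    params = file.path(dir, "true_params.json")
  )
  utils::write.table(sim$cohort, paths["cohort"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$dosages, paths["dosages"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$variants, paths["variants"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$related_pairs, paths["pairs"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tp <- sim$true_params
  tp$confounder <- NULL  # latent vector is bulky; kept in memory only
  jsonlite::write_json(tp, paths["params"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
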