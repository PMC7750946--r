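#' Simulation configuration for a synthetic biobank cohort
#'
#' Collects and validates every parameter of the cohort generator. The
#' defaults describe a cohort with the statistical structure the package's
#' analyses assume: a common binary disease (baseline prevalence 9\%), a
#' continuous exposure of which a polygenic score explains a few percent of
#' the variance, an unmeasured confounder acting on both exposure and
#' outcome, optional horizontal pleiotropy, imperfect diagnostic coding and
#' a sprinkling of close-relative pairs.
#'
#' @param n_individuals Number of individuals (>= 2).
#' @param n_variants Number of independent biallelic variants.
#' @param maf_range Length-2 numeric, lower/upper minor-allele frequency in
#'   (0, 0.5]. A zero-width range fixes every MAF.
#' @param h2_exposure Fraction of exposure variance explained by the genetic
#'   instruments jointly (on the standardized exposure scale).
#' @param confounder_effect_x Per-SD effect of the latent confounder on the
#'   exposure (standardized scale).
#' @param confounder_effect_y Log-odds-ratio per SD of the confounder on the
#'   outcome.
#' @param causal_beta Causal log-odds-ratio per SD of the exposure.
#' @param pleiotropy_mode One of \code{"none"}, \code{"balanced"},
#'   \code{"directional"}: direct variant-to-outcome effects are absent,
#'   drawn from a centred normal, or drawn from a half-normal.
#' @param pleiotropy_sd Scale (per-allele log-OR) of the pleiotropic draws.
#' @param baseline_prevalence Target marginal case fraction in (0, 1).
#' @param code_sensitivity Probability that a true case receives each
#'   diagnostic code family (self-report; hospital ICD10).
#' @param code_specificity Probability that a non-case receives no code from
#'   a family (codes appear in non-cases at rate \code{1 - code_specificity}).
#' @param p_esophagitis Among ICD10-coded cases, probability the code is
#'   K21.0 (reflux with esophagitis) rather than K21.9.
#' @param p_surgery Probability a true case carries an anti-reflux operation
#'   code (G24, or G25 for a revision).
#' @param p_meds_controls Fraction of non-cases flagged as taking
#'   acid-suppressant medication.
#' @param p_endoscopy_controls Fraction of non-cases with an upper-GI
#'   endoscopy code (G45).
#' @param n_relative_pairs Number of third-degree-or-closer relative pairs
#'   to inject.
#' @param p_chain Probability that a new relative pair reuses an individual
#'   already in a pair, creating chains (A-B, A-C) that exercise the greedy
#'   unrelated-selection rule.
#' @param seed Integer seed; fans out to fixed per-stage child seeds.
#'
#' @return An object of class \code{"sim_config"} (a validated list).
#' @examples
#' cfg <- sim_config(n_individuals = 500, n_variants = 10, seed = 7)
#' cfg
#' @export
sim_config <- function(n_individuals = 20000,
                       n_variants = 50,
                       maf_range = c(0.05, 0.45),
                       h2_exposure = 0.02,
                       confounder_effect_x = 0.2,
                       confounder_effect_y = 0.2,
                       causal_beta = log(1.2),
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_sd = 0.05,
                       baseline_prevalence = 0.09,
                       code_sensitivity = 0.8,
                       code_specificity = 0.99,
                       p_esophagitis = 0.48,
                       p_surgery = 0.03,
                       p_meds_controls = 0.10,
                       p_endoscopy_controls = 0.05,
                       n_relative_pairs = round(0.08 * n_individuals),
                       p_chain = 0.3,
                       seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot_scalar(n_individuals, "n_individuals")
  stopifnot_scalar(n_variants, "n_variants")
  stopifnot_scalar(seed, "seed")
  if (n_individuals < 2) stop("'n_individuals' must be >= 2", call. = FALSE)
  if (n_variants < 1) stop("'n_variants' must be >= 1", call. = FALSE)
  if (length(maf_range) != 2L || any(!is.finite(maf_range))) {
    stop("'maf_range' must be two finite frequencies", call. = FALSE)
  }
  if (maf_range[1] > maf_range[2]) maf_range <- rev(maf_range)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop("'maf_range' must lie in (0, 0.5]; zero frequencies are degenerate",
         call. = FALSE)
  }
  fracs <- c(h2_exposure = h2_exposure,
             baseline_prevalence = baseline_prevalence,
             code_sensitivity = code_sensitivity,
             code_specificity = code_specificity,
             p_esophagitis = p_esophagitis, p_surgery = p_surgery,
             p_meds_controls = p_meds_controls,
             p_endoscopy_controls = p_endoscopy_controls,
             p_chain = p_chain)
  bad <- names(fracs)[!is.finite(fracs) | fracs < 0 | fracs > 1]
  if (length(bad)) {
    stop("fractions must be in [0, 1]: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (baseline_prevalence <= 0 || baseline_prevalence >= 1) {
    stop("'baseline_prevalence' must be in (0, 1)", call. = FALSE)
  }
  if (n_relative_pairs < 0) stop("'n_relative_pairs' must be >= 0", call. = FALSE)
  max_pairs <- n_individuals * (n_individuals - 1) / 2
  if (n_relative_pairs > max_pairs) {
    stop(sprintf("'n_relative_pairs' (%d) exceeds the %g distinct pairs %d individuals support",
                 n_relative_pairs, max_pairs, n_individuals), call. = FALSE)
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_variants = as.integer(n_variants),
    maf_range = as.numeric(maf_range),
    h2_exposure = h2_exposure,
    confounder_effect_x = confounder_effect_x,
    confounder_effect_y = confounder_effect_y,
    causal_beta = causal_beta,
    pleiotropy_mode = pleiotropy_mode,
    pleiotropy_sd = pleiotropy_sd,
    baseline_prevalence = baseline_prevalence,
    code_sensitivity = code_sensitivity,
    code_specificity = code_specificity,
    p_esophagitis = p_esophagitis,
    p_surgery = p_surgery,
    p_meds_controls = p_meds_controls,
    p_endoscopy_controls = p_endoscopy_controls,
    n_relative_pairs = as.integer(n_relative_pairs),
    p_chain = p_chain,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  individuals: %d   variants: %d   MAF in [%.3f, %.3f]\n",
              x$n_individuals, x$n_variants, x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  h2(exposure) = %.3f   causal log-OR/SD = %.4f   prevalence = %.3f\n",
              x$h2_exposure, x$causal_beta, x$baseline_prevalence))
  cat(sprintf("  confounder slopes (x, y) = (%.2f, %.2f)   pleiotropy: %s (sd %.3f)\n",
              x$confounder_effect_x, x$confounder_effect_y,
              x$pleiotropy_mode, x$pleiotropy_sd))
  cat(sprintf("  coding sens/spec = %.2f/%.2f   relative pairs: %d   seed: %d\n",
              x$code_sensitivity, x$code_specificity,
              x$n_relative_pairs, x$seed))
  invisible(x)
}
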