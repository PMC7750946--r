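---
title: "Models and methods behind grsmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind grsmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grsmr)
```

# The scientific problem

Observational associations between modifiable exposures (adiposity,
smoking, coffee) and common diseases such as gastro-oesophageal reflux
disease (GORD) are prone to confounding and reverse causation. Mendelian
randomization (MR) addresses this by using genetic variants as
instrumental variables: because alleles are assigned at conception,
a score built from exposure-associated variants is an unconfounded proxy
for the exposure. `grsmr` implements the full analysis stack such a study
needs — phenotype derivation from health-record codes, relatedness
pruning, weighted genetic risk scores (GRS), observational models,
one-sample two-stage instrumental-variable analysis, and two-sample
summary-statistic MR — together with a cohort simulator that provides
ground truth for every stage.

# The synthetic cohort generator

`sim_config()` / `simulate_cohort()` generate a cohort with the structure
a biobank MR analysis assumes:

* **Genotypes.** `n_variants` independent biallelic variants under
  Hardy–Weinberg equilibrium, MAF drawn uniformly from `maf_range`
  (default 0.05–0.45). Linkage disequilibrium and population structure
  are deliberately out of scope; an INFO column of 1 is carried so that
  variant-filter plumbing is exercised.
* **Exposure.** $X = \sum_i \gamma_i g_i + c_x U + \varepsilon$, with the
  raw per-variant slopes rescaled so the genetic component explains
  exactly `h2_exposure` of the unit total variance (default 0.02, a
  typical GRS-explained fraction for an anthropometric trait; the
  trait-specific values live in supplementary material we do not
  reproduce, so this default is a documented placeholder). $U$ is a
  standard-normal latent confounder with slopes `confounder_effect_x`
  and `confounder_effect_y` (defaults 0.2 each — strong enough to bias a
  naive regression noticeably, weak enough to keep the outcome model
  well conditioned).
* **Outcome.** $Y \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(\alpha_0 +
  \beta X_{std} + c_y U + \sum_i \alpha_i g_i))$. The exposure is
  standardized before the causal slope is applied so that `causal_beta`
  (default $\log 1.2$) reads as a log-odds ratio per SD, matching how MR
  effects are reported. The intercept $\alpha_0$ is calibrated by
  bisection to hit `baseline_prevalence` (default 0.09, the case
  fraction of a large reflux cohort) within ±0.001; no closed form
  exists once the linear predictor mixes genetic, exposure and
  confounder terms.
* **Pleiotropy.** Direct variant–outcome effects $\alpha_i$ are zero
  (`none`), centred normal (`balanced`, satisfying the IVW
  random-effects assumption that pleiotropic effects average to zero),
  or half-normal (`directional`, violating it — the scenario MR-Egger
  and the weighted median are designed for).
* **Diagnostic codes.** The latent disease status is mapped to the code
  families a hospital-records phenotype algorithm consumes (self-report
  1138; ICD10 K21.9/K21.0; OPCS4 G24/G25/G45; medication flags). Each
  family is assigned with `code_sensitivity` (default 0.8) in cases and
  at `1 − code_specificity` (default 0.99) in non-cases. Among
  ICD-coded cases, 48% receive the esophagitis code K21.0 and 3% a
  surgery code — proportions chosen to produce nested definition counts
  with the same order-of-magnitude attrition as published reflux
  flowcharts (roughly half of hospital-coded cases carrying the
  esophagitis code, surgery rare).
* **Relatedness.** `n_relative_pairs` undirected pairs of kinship degree
  ≤ 3 (default 8% of n, giving an excluded fraction comparable to a
  European-ancestry biobank); with probability `p_chain` a new pair
  reuses an existing member, producing the A–B/A–C chains the greedy
  pruning rule must handle.

One global seed fans out to fixed per-stage child seeds, so any stage can
be re-run byte-identically on its own.

What the generator does **not** emulate: linkage disequilibrium,
ancestry stratification, genotyping batch effects, informative
missingness, date-resolved diagnoses, and covariates that actually
influence the outcome (age, sex, centre, platform and the principal
components are simulated independently and act as adjustment plumbing
only). Tests passing on this simulator therefore validate the
*estimators and rules*, not robustness to those real-data complications.

# Phenotype derivation

`derive_gord()` implements four nested case definitions: the primary one
(any of self-report 1138, ICD10 K21.9/K21.0, OPCS4 G24/G25), then three
sensitivity levels that successively drop self-report-only cases and
controls with acid-suppressant use or endoscopy (level 1), cases without
the esophagitis code K21.0 (level 2), and finally keep only surgical
cases with at least one other confirming code (level 3). Two design
choices were genuinely open:

* level 3's "other confirmation" is interpreted as any of
  {1138, K21.9, K21.0} in addition to the operation code, and level 3 is
  evaluated within the level-2 case set so that the four case sets nest
  strictly — the nesting invariant is enforced in `tabulate_flowchart()`;
* medication exclusion consumes a boolean flag rather than a drug
  dictionary; mapping drug codes to classes is the caller's concern.

An incident-case restriction is supported only as a caller-supplied flag;
no date-window algorithm is invented.

# Risk scores and instrument strength

With per-allele weights $\beta_i$ from a discovery GWAS, the raw score is
$W_s = \sum_i \beta_i \, SNP_i$ and the rescaled score
$WGRS = W_s \, n / \sum_i \beta_i$ reads as a count of trait-raising
alleles; it is invariant to multiplying all weights by a positive
constant, and the two-stage estimator is invariant to affine rescaling of
the score, so no further standardization is applied. Harmonization
recodes dosages $g \to 2 - g$ where the weight file's effect allele is
the panel's other allele, drops incompatible allele pairs with a warning,
and flags palindromic (A/T, C/G) variants, which a strict mode drops.
Missing dosages are mean-imputed to $2 \cdot EAF$ (counted and reported).
Instrument strength is the incremental $R^2$ of the score given the
covariates and the corresponding partial F statistic.

# Observational models

Continuous exposures are inverse-normalized with the Blom offset,
$\Phi^{-1}((r - 3/8)/(m + 1/4))$ with average ranks for ties (the offset
choice is recorded in the function documentation; the alternative
constants differ negligibly at biobank scale), so odds ratios read per
SD. Associations are maximum-likelihood logistic fits, complete-case per
model, with separation detected (boundary fitted probabilities or
non-convergence) and the estimate withheld in that case. On an
unadjusted 2×2 table the fitted odds ratio equals the cross-product
ratio, which the tests exploit as a closed-form oracle.

# One-sample MR

`mr_two_stage()` regresses the inverse-normalized exposure on the score
(stage 1) and the binary outcome on the stage-1 fitted values (stage 2,
logistic), with identical covariates in both stages. The reported SE is
the stage-2 model SE — it ignores first-stage uncertainty and is flagged
as such; with first-stage F in the hundreds the neglected term is
negligible, and a seeded nonparametric bootstrap is available when it is
not. `rescale_per_unit()` converts a per-SD odds ratio into per-unit
terms given the units-per-SD correlation scale, e.g. a 1.19 odds ratio
per SD of waist-hip-ratio with 4.2 cm of waist per SD becomes 1.23 per
5 cm. The units-per-SD input is supplied by the caller, not computed
internally.

`mr_power()` uses the normal approximation with non-centrality
$\sqrt{n r^2 \phi (1-\phi)}\,|\ln OR|$: the score–outcome Wald statistic
for a score explaining $r^2$ of an exposure with causal log-odds ratio
$\ln OR$ and case fraction $\phi$. The package validates it against a
Monte-Carlo oracle (simulate, run the two-stage IV, count rejections) on
a 12-point grid with $n \in \{2000, 5000\}$,
$r^2 \in \{0.01, 0.02, 0.05\}$, $OR \in \{1.2, 1.3\}$ and $\phi = 0.09$
— effect sizes bracketing the odds ratios a reflux MR study reports and
the case fraction it observes. The approximation's known bias grows with
$|\ln OR|$ (logistic non-collapsibility attenuates the two-stage
estimate), so agreement to ±0.03 should not be extrapolated to odds
ratios far above ~1.5.

# Two-sample MR

`gwas_scan()` supplies both halves of the summary statistics by plain
per-variant linear or logistic regression with covariates — a
deliberately simple association scan; mixed-model (relatedness-aware)
GWAS is out of scope, so two-sample analyses on simulated data should be
run on the unrelated subset or interpreted accordingly.

The estimators follow their standard forms:

* **Wald ratio** $\hat\theta_j = \hat\beta_{y,j}/\hat\beta_{x,j}$ with
  first-order SE $se_{y,j}/|\hat\beta_{x,j}|$; second-order terms are
  omitted, matching the canonical implementations.
* **IVW**: weights $w_j = \beta_{x,j}^2/se_{y,j}^2$;
  $\hat\theta = \sum w_j \hat\theta_j / \sum w_j$, fixed-effects
  $se = (\sum w_j)^{-1/2}$, Cochran's
  $Q = \sum w_j (\hat\theta_j - \hat\theta)^2$ on $k-1$ df, and the
  random-effects SE multiplies by $\sqrt{\max(1, Q/(k-1))}$.
* **MR-Egger**: weighted regression of $\hat\beta_y$ on $\hat\beta_x$
  with a free intercept, all variants oriented to $\hat\beta_x > 0$
  first; inference uses the weighted-least-squares t-tests with freely
  estimated residual dispersion, which keeps the intercept test exact
  under the generating model (the alternative of flooring the dispersion
  at 1 makes the test conservative).
* **Weighted median**: ratios ordered, normalized weights accumulated,
  estimate interpolated where the cumulative weight crosses 0.5; SE from
  a seeded parametric bootstrap (default B = 1000) resampling
  $(\hat\beta_x, \hat\beta_y)$ from their reported SEs.

A flag on the summary-statistics table records whether both halves come
from one cohort (the one-cohort two-sample design) or two, since sample
overlap changes weak-instrument behaviour.

# Numerical and validation choices

* Prevalence calibration: bisection on $[-30, 30]$ to ±0.001.
* Greedy unrelated selection removes a maximum-degree individual per
  round; simple pairs drop one member at random (seeded), residual ties
  break on lowest id. Exhaustive maximum-independent-set enumeration on
  small graphs bounds the greedy solution in tests.
* Variant filters use strict exclusion semantics: keep INFO ≥ 0.9,
  minor-allele frequency = min(EAF, 1−EAF) ≥ 0.001, p < 5×10⁻⁸.
* Parameter-recovery validation runs 100 cohorts of 20 000 individuals
  and 50 variants (h² = 0.02, causal OR 1.2). At this size the
  per-variant instruments are individually weak (F ≈ 8), so the
  two-sample scan's estimand differs slightly from the generative
  constant; the recovery check therefore measures CI coverage of a
  *same-data oracle IVW* — the IVW computed with the true
  variant–exposure effects and the estimated outcome scan — which is the
  appropriate referent for the estimators' sampling distributions. At
  biobank scale (10× larger n) the distinction all but vanishes.
  Coverage of the generative constant is reported alongside for
  reference. The problem sizes here and in the power grid are the
  package's validation defaults, chosen to make the whole suite run
  comfortably on a laptop.

# Known limitations

* No LD-aware instrument selection or clumping; instruments are assumed
  independent, as the simulator generates them.
* The two-stage SE is uncorrected by default (see above).
* The power approximation ignores covariate adjustment and
  non-collapsibility; it is a planning tool, not an inferential one.
* The phenotype module consumes pre-extracted code lists; parsing raw
  hospital-episode extracts and drug-name mapping are out of scope.

# A worked example

```{r example, eval = FALSE}
run <- run_pipeline(sim_config(n_individuals = 20000, n_variants = 50,
                               seed = 7))
cat(make_report(run))
```

The report juxtaposes the observational odds ratio with the one-sample
IV and the three two-sample estimates per SD of exposure, all computed on
the same simulated cohort, along with the nested phenotype counts.
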