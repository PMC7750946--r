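# grsmr

Genetic risk scores and Mendelian randomization for coded biobank
phenotypes.

## What problem this solves

Whether an exposure such as central adiposity *causes* a common disease
such as gastro-oesophageal reflux disease (GORD) cannot be settled by
observational association alone: confounding and reverse causation cut
both ways. Mendelian randomization (MR) uses genetic variants associated
with the exposure as instrumental variables — alleles are fixed at
conception, so a genetic risk score (GRS) is an unconfounded proxy for
the exposure. `grsmr` is aimed at analysts building such studies on
biobank-style data (EHR diagnosis/procedure codes, self-report,
genotype dosages) and at methodologists who want every stage testable
against simulated ground truth.

The package implements:

- **Phenotype derivation** — nested case/control definitions from
  ICD10 / OPCS4 / self-report code lists with control exclusions
  (`derive_gord`, `tabulate_flowchart`);
- **Cohort QC** — greedy unrelated-subset selection from kinship pairs,
  variant filters on INFO, MAF and exposure p-value
  (`select_unrelated`, `filter_variants`);
- **Risk scores** — allele harmonization, weighted score
  `Ws = Σ βᵢ·SNPᵢ`, rescaled score `WGRS = Ws·n/Σβᵢ` on the
  trait-raising-allele scale, instrument-strength R²/F
  (`harmonize_instruments`, `grs_score`, `grs_rescale`, `grs_strength`);
- **Observational models** — Blom inverse-normal transform,
  covariate-adjusted logistic associations, Table-1-style summaries
  (`inverse_normal`, `logistic_assoc`, `summarize_cohort`);
- **One-sample MR** — two-stage IV with binary outcome, per-unit
  rescaling of per-SD odds ratios, analytic power
  (`mr_two_stage`, `rescale_per_unit`, `mr_power`);
- **Two-sample MR** — per-variant association scan, Wald ratios, IVW
  (fixed/random effects with Cochran's Q), MR-Egger, weighted median
  (`gwas_scan`, `mr_ivw`, `mr_egger`, `mr_weighted_median`);
- **A cohort simulator** with known causal structure — confounding,
  balanced/directional pleiotropy, imperfect diagnostic coding,
  relative pairs (`sim_config`, `simulate_cohort`) — and an end-to-end
  pipeline (`run_pipeline`, `make_report`).

Estimators return a classed `mr_estimate` with `print`, `coef`,
`confint` and `summary` methods. The core identities, in standard
notation: per-variant Wald ratio `θ̂ⱼ = β̂y,ⱼ / β̂x,ⱼ`; IVW estimate
`θ̂ = Σwⱼθ̂ⱼ / Σwⱼ` with `wⱼ = β̂²x,ⱼ/se²y,ⱼ`; MR-Egger fits
`β̂y = α + θ·β̂x` weighted by `1/se²y`, a non-zero `α` indicating
directional pleiotropy; the weighted median interpolates the
weight-ordered ratios at cumulative weight 0.5.

## Worked example

```r
library(grsmr)
run <- run_pipeline(sim_config(n_individuals = 20000, n_variants = 50,
                               seed = 7))
cat(make_report(run))
```

Output (seed 7):

```
# Cohort analysis report

Seed 7; 20000 individuals simulated, 18862 analyzed; 50 variants.

## Phenotype definitions

| level | cases | controls | excluded |
|---|---|---|---|
| primary | 1934 | 16928 | 0 |
| sa1 | 1495 | 14434 | 2933 |
| sa2 | 704 | 14434 | 3724 |
| sa3 | 18 | 14434 | 4410 |

## Instrument strength

Score explains R^2 = 0.0202 of the exposure; first-stage F = 388.7.

## Exposure-disease estimates (OR per SD, 95% CI)

| method | OR (95% CI) |
|---|---|
| Observational | 1.24 (1.19-1.30) |
| One-sample IV | 1.37 (0.98-1.90) |
| IVW | 1.35 (0.97-1.88) |
| MR-Egger | 1.07 (0.62-1.87) |
| Weighted median | 1.14 (0.72-1.83) |
```

Reading it: 1138 individuals were removed as third-degree-or-closer
relatives; the four phenotype definitions nest (1934 → 18 cases) as the
diagnostic certainty tightens; the score recovers the configured 2% of
exposure variance with a strong first stage (F ≈ 389); and with a
generative causal odds ratio of 1.2 per SD, the observational and
MR estimates agree in direction, the MR confidence intervals being wider
because only 2% of exposure variance is instrumented.

Single operations work standalone:

```r
rescale_per_unit(1.19, units_per_sd = 4.2, target_units = 5)
#> 1.23009  — a 1.19 OR per SD re-expressed per 5 units
assoc_from_counts(19971, 8093, 221046, 71128)$or
#> 0.7940514 — crude 2x2 odds ratio (equals the cross-product ad/bc)
```

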