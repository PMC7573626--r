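# cnamlrisk

Genotype risk stratification and post-remission outcome modelling for
de novo cytogenetically normal acute myeloid leukemia (CN-AML) in younger
adults (18–60 years).

In CN-AML prognosis must be inferred from gene mutations. This package
implements, as tested reusable R functions, the analysis machinery for that
problem:

* **Genotype rules** — the five NPM1 × FLT3-ITD × DNMT3A combination
  categories (Category 1: NPM1 only; 2: all three wild type; 3: NPM1 +
  FLT3-ITD; 4: FLT3-ITD only; 5: any DNMT3A mutation), FLT3-ITD burden from
  the allelic ratio $AR = \mathrm{VAF}/(1-\mathrm{VAF})$ (high when
  $\mathrm{VAF} \ge 1/3$, i.e. $AR \ge 0.5$), gene-only ELN 2017 risk, and
  a DNMT3A-modified ELN risk in which any DNMT3A mutation is adverse.
* **Clonal architecture** — dominant / co-dominant / subclone calls from
  variant allele frequencies (clone fraction $\min(1, 2\,\mathrm{VAF})$,
  relative tier threshold 0.67), canonical clonal-subtype keys and their
  cohort-level enumeration (bubble-diagram data).
* **Survival core** — LFS / EFS / OS endpoint construction with optional
  censoring at transplantation, and self-contained Kaplan–Meier (Greenwood
  variance), log-rank (hypergeometric covariance) and Cox regression
  (Newton–Raphson on the Breslow partial likelihood).
* **Multistate model** — cause-specific exponential or Weibull hazards on
  CR1 → RELAPSE, CR1 → TRM, RELAPSE → DEATH, with covariates (genotype
  category, age, sex, log white cell count, HSCT-at-CR1), per-patient
  state-occupancy ("sediment plot") prediction, and HSCT-at-CR1 versus
  no-HSCT strategy comparison at 2 and 5 years.
* **Evaluation** — Harrell's concordance index with paired bootstrap
  against the ordinal ELN baseline, and a train/validation workflow with
  the refractory-HSCT exclusion.
* **Synthetic cohorts** — a seeded generator emulating mutation marginal
  frequencies, pairwise co-occurrence, VAF structure (dominant clones near
  VAF 0.40–0.50, heterogeneous subclones) and genotype-dependent multistate
  event histories, so every stage is testable against known ground truth.

See the methods vignette (`vignettes/cnaml-prognosis.Rmd`) for the models,
assumptions, parameter defaults and limitations.

## Worked example

```r
library(cnamlrisk)

cfg    <- default_generator_config(n_patients = 500, seed = 2026)
cohort <- generate_cohort(cfg)
cohort
#> <aml_cohort> 500 patients, 884 mutation calls (synthetic)
#>   patients with >=1 detectable mutation: 418
#>   achieved CR1: 458; relapsed: 357; died: 474

cls <- classify_cohort(cohort)
table(cls$category)
#>   1   2   3   4   5
#>  73 157  37  48 185
```

Category 5 (DNMT3A-mutated) is the largest group because DNMT3A mutation
overrides NPM1/FLT3 status. The DNMT3A-modified ELN stratification
separates leukemia-free survival clearly in this cohort:

```r
rec <- derive_endpoints(cohort, endpoints = "LFS")
grp <- cls$eln_dnmt3a[match(rec$patient_id, cls$patient_id)]
logrank_test(rec, group = grp)
#> Log-rank test: chi-square = 18.6423, df = 2, p = 8.951e-05
#>              observed expected
#> adverse           211   167.48
#> favorable          85   102.45
#> intermediate      149   175.07
```

Fit the post-remission multistate model and compare transplant strategies
for a 25-year-old woman, white cell count 10 × 10⁹/L, genotype Category 1:

```r
model <- fit_multistate(cohort)
compare_strategies(model, list(age = 25, sex = "female", wcc = 10, category = 1))
#>   horizon strategy     p_cr1 p_death_relapse
#> 1      24 hsct_cr1 0.7487764      0.05641009
#> 2      24  no_hsct 0.5773531      0.14085909
#> 3      60 hsct_cr1 0.4851548      0.20808068
#> 4      60  no_hsct 0.2532816      0.45834939
```

`p_cr1` is the predicted leukemia-free survival (probability of still being
in CR1) at 2 and 5 years under each strategy; `p_death_relapse` the
probability of having died in relapse. Under this synthetic cohort's fitted
hazards, transplantation at CR1 raises 2-year leukemia-free survival from
58% to 75% for this profile. `predict_occupancy()` returns the full
sediment-plot curves behind these numbers.

The whole chain (simulate → classify → clones → survival → fit → predict →
evaluate) runs reproducibly via:

```r
run_pipeline(default_run_config(seed = 7), "out/")
```

which writes per-stage TSV/JSON outputs and a `manifest.json` of md5 hashes;
the same seed reproduces identical hashes.

Real cohorts enter through `read_cohort(clinical, mutations)` (TSV/CSV
schemas documented in `?new_cohort`, plus a MAF adapter
`maf_to_mutations()`).

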