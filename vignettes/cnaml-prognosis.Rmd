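---
title: "Prognostic modelling of cytogenetically normal AML: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prognostic modelling of cytogenetically normal AML: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnamlrisk)
```

# The problem

About half of adult acute myeloid leukemia presents with a normal karyotype
(CN-AML), so prognosis must be read from recurrent gene mutations rather
than chromosomes. For younger adults (18–60 years) treated with
anthracycline/cytarabine induction, the central post-remission decision is
whether to consolidate with allogeneic hematopoietic stem cell
transplantation (allo-HSCT) at first complete remission (CR1): transplant
lowers relapse risk but adds treatment-related mortality (TRM).

`cnamlrisk` packages the analysis machinery for this question:

1. deterministic genotype classification — the five NPM1 × FLT3-ITD ×
   DNMT3A combination categories, gene-only ELN 2017 risk, and a
   DNMT3A-modified ELN risk;
2. clonal-architecture calls (dominant / co-dominant / subclone) from
   variant allele frequencies (VAF), and cohort-level clonal subtype
   enumeration;
3. survival endpoints (LFS / EFS / OS, optional censoring at HSCT) with
   self-contained Kaplan–Meier, log-rank and Cox estimation;
4. a parametric cause-specific multistate model of post-remission outcomes
   that produces per-patient state-occupancy ("sediment plot") curves under
   HSCT-at-CR1 versus no-HSCT strategies;
5. concordance-index evaluation of that model against an ordinal ELN
   baseline, with paired bootstrap;
6. a synthetic cohort generator providing ground truth for all of the
   above, and a pipeline driver tying the stages together.

Patient-level data behind this class of study are typically not public, so
every quantitative claim the package tests is made on synthetic cohorts
with known generating truth, plus hand-computed oracles on tiny worked
examples.

# Genotype rules

**FLT3-ITD burden.** The allelic ratio (mutant over wild-type allele
quantity) relates to VAF by $AR = \mathrm{VAF}/(1-\mathrm{VAF})$; the
conventional cut between low and high ITD burden, $AR \ge 0.5$, corresponds
to $\mathrm{VAF} \ge 1/3$. `classify_flt3_itd()` uses the maximum ITD VAF
when several ITD calls exist, because the clinical question is whether a
high-burden ITD clone is present. FLT3-TKD calls never count as ITD.

**The five categories.** Any DNMT3A mutation (R882 or not) dominates and
assigns Category 5; otherwise the NPM1-mutation × ITD-presence table gives
Categories 1–4. Two deliberate readings, both testable through the exported
rule configuration:

* "All wild type" (Category 2) means wild type for the three index genes
  only — other genes may be mutated. This is forced by the package's own
  Category-2 subgroup flag for IDH1-R132H, which presupposes mutations
  inside Category 2.
* Categories 3/4 condition on ITD *presence*, not burden; the burden cut
  feeds only the ELN classifier.

**ELN 2017, gene-only.** The cohort is cytogenetically normal by
definition, so only the mutation rows of the ELN table are encoded:
favorable = NPM1-mutant with ITD absent/low, or biallelic CEBPA; adverse =
NPM1-wild-type with ITD-high, or RUNX1/ASXL1/TP53 mutation; everything else
intermediate. The guideline's caveat that RUNX1/ASXL1 should not be used as
adverse markers when they co-occur with a favorable-defining lesion is on
by default and switchable (`eln_rules(runx1_asxl1_yield = FALSE)`), since
published analyses are often silent about whether they applied it. TP53
never yields. The DNMT3A modification (`classify_eln_dnmt3a()`) moves every
DNMT3A-mutated patient to adverse and touches no one else.

# Clonal architecture

Under a heterozygous autosomal assumption the clone fraction of a mutation
is $\min(1, 2\,\mathrm{VAF})$. Calls whose clone fraction reaches
`rel_threshold` (default 0.67) times the patient's maximum form the
dominant tier: one member → dominant, several → co-dominant; the rest are
subclones. The default threshold places a 0.45/0.12 VAF pair in
dominant/subclone and 0.47/0.44 in co-dominance, reproducing the
qualitative architectures described for this disease; it is fully
configurable because published assignment procedures rarely state their
cut. Consequences worth knowing:

* the rule is *relative*, so multiplying all of a patient's VAFs by a
  common factor preserves statuses — exactly true while clone fractions
  stay below the clip at 1 (VAF ≤ 0.5); copy-number events and hemizygous
  loci that push VAF beyond 0.5 are out of scope;
* patients with zero panel mutations have no architecture and are excluded
  from the clonal-subtype denominator;
* the clonal subtype key is canonical ("dominant set | subclone set",
  tokens sorted, `-` for an empty subclone set), so counting distinct keys
  is permutation-invariant. The distinct-subtype count of a cohort is
  threshold-dependent and should be reported with the threshold.

# Survival endpoints and estimation

Times are months from diagnosis. OS runs from diagnosis to death or last
follow-up; LFS from CR1 to relapse, death or last follow-up (defined only
for CR1 patients); EFS from diagnosis to induction failure, relapse or
death. EFS needs an interpretation because induction failure has no
canonical time stamp: patients who never reach CR1 are scored as failure
events at a configurable induction-assessment time (default 2 months), or
at death if earlier. Loss to follow-up and administrative censoring are
treated identically as `last_followup`. CR and CRi are pooled. The
censor-at-HSCT option censors any endpoint at `hsct_time` when HSCT
precedes the event — the complementary view to modelling HSCT as a
covariate.

The estimators are self-contained and oracle-tested: Kaplan–Meier with
Greenwood variance (events precede censorings at tied times), the log-rank
test with the multivariate hypergeometric covariance on $K-1$ groups, and
Cox regression by Newton–Raphson on the Breslow-ties partial likelihood
(convergence at max $|$score$| < 10^{-8}$, 50 iterations, step-halving so
the accepted log-likelihood never decreases). Breslow ties were chosen over
Efron to keep the brute-force risk-set oracle exact. Wald confidence
intervals are reported (published reports rarely say which flavour they
used); a likelihood-ratio p-value covers the whole model. Coefficients that
drift beyond $|\beta| > 10$ flag a monotone likelihood (separation) rather
than failing silently. No multiplicity correction is applied anywhere,
matching the exploratory presentation style of the field; subgroup p-values
should be read accordingly.

# The multistate model

Post-remission outcomes are modelled on the DAG

```
CR1 --> RELAPSE --> DEATH_RELAPSE
  \--> TRM
```

with CR1 and RELAPSE transient and the other two absorbing. Each
transition $k$ carries a proportional cause-specific hazard
$\lambda_{0k}\,\gamma_k t^{\gamma_k-1} e^{x^\top\beta_k}$ (exponential when
$\gamma_k = 1$). Covariates: genotype-category indicators (Category 1
reference), age in years centered at 49 (the typical cohort median), sex,
$\log_{10}$ white cell count centered at $10\times10^9$/L, and an
HSCT-at-CR1 indicator (excluded from the post-relapse transition by
default). The published model this machinery emulates is described only as
"machine learning"; a covariate-adjusted parametric multistate model is the
simplest family able to produce the same sediment curves and strategy
comparisons, and it is isolated behind `fit_multistate()` so another
learner could be swapped in.

Design choices that matter:

* **Entry at CR1.** The model is post-remission decision support; the
  pre-CR part of the outcome tree is summarized by the generator's logistic
  CR model and is not part of the fitted likelihood.
* **Clock reset at relapse.** The RELAPSE → DEATH hazard runs on time since
  relapse (semi-Markov). For the exponential family this is
  indistinguishable from a shared clock; for Weibull it is a modelling
  choice, stated here.
* **HSCT as a time-fixed covariate from CR1.** This imports a small
  immortal-time distortion: patients must survive in remission to the
  transplant date to be recorded as transplanted. The generator mirrors the
  same simplification (the effect applies from CR1, `hsct_time` is recorded
  at `cr1 + hsct_delay_months` only if still in remission), and
  parameter-recovery experiments set the recording delay to 0 so the
  recorded covariate equals the generating one — i.e. they test the fitter
  in a correctly specified regime. With the default 4-month delay the
  time-fixed fit acquires a protective-side bias of order 0.05–0.1 on the
  HSCT coefficient; the censor-at-HSCT endpoint view is provided as the
  complementary analysis.
* **Estimation.** Cause-specific likelihoods are maximized per transition,
  censoring competing transitions. The exponential family profiles the
  baseline ($\hat\lambda_0 = D / \sum_i t_i e^{x_i^\top\beta}$) inside
  Newton steps — numerically identical to a Poisson regression with
  log-exposure offset, which the test suite uses as an independent oracle.
  Weibull fits run Newton with step-halving on
  $(\log\lambda_0, \log\gamma, \beta)$. Covariates constant in a cohort are
  dropped from that transition (reported with coefficient 0); a transition
  with zero events gets hazard 0 and a flag.
* **Prediction.** State occupancies solve the forward equations:
  closed forms for the exponential family;
  for Weibull, adaptive quadrature of
  $P_{TRM}(t)=\int_0^t S_{12}(u)h_2(u)\,du$ and the convolution integrals
  for RELAPSE / DEATH_RELAPSE at absolute tolerance $10^{-8}$. All four
  occupancies are computed independently — none as one minus the others —
  so the conservation check $\sum_s P_s(t) = 1$ is informative. The default
  grid is 0–120 months in 0.5-month steps.

Risk scores for evaluation are $1 - P_{CR1}(h)$ at horizon $h$ (default 60
months): the predicted probability of leaving remission, available in
closed form for both families.

# Evaluation

Harrell's C is computed over comparable pairs (the earlier time is an
event; tied times are not comparable), with half credit for tied scores —
deliberate, because the ELN baseline is an ordinal 0/1/2 score with heavy
ties. Censoring-weighted variants (Uno) are out of scope. The ELN baseline
encodes favorable/intermediate/adverse as 0/1/2. `compare_models()` runs a
paired bootstrap over patients (both C's recomputed on the same resample;
two-sided add-one-smoothed p-value), and `train_validate()` fits on the
training cohort only, applies the refractory-HSCT exclusion (transplant
without recorded CR1) to the validation cohort, and reports both absolute
and relative concordance differences — published "x% higher concordance"
claims are ambiguous between the two.

# What the synthetic generator does and does not emulate

The generator is the package's study population, and its defaults are fixed
conditions, not tuning knobs.

* **Genotypes.** Fourteen recurrent lesions with marginal frequencies
  qualitatively ranked as in CN-AML spectra (NPM1 ≈ 0.35 and DNMT3A ≈ 0.30
  most frequent, FLT3-ITD 0.25, down to TP53 0.02; shipped as an editable
  YAML config because published circos ribbons print no usable numbers).
  Pairwise co-occurrence is a Gibbs-sampled pairwise binary model (50
  sweeps per cohort), chosen over a full Bayesian network because only
  pairwise co-occurrence is ever reported: positive tilts for NPM1–DNMT3A
  and NPM1–FLT3-ITD, near-exclusivity for NPM1 with CEBPA/RUNX1/TP53.
* **VAFs.** The first-drawn mutation of a patient is always clonal.
  Dominant-clone VAF is truncated-normal around 0.445 (sd 0.035), matching
  the 40–50% range typical of founding heterozygous mutations; subclonal
  VAF is uniform on 0.10–0.30. Subclone propensity is per-lesion, highest
  for FLT3-ITD (0.55) which occurs most often subclonally, lowest for NPM1
  (0.05).
* **Clinical course.** Age 18–60 with median near 49 (scaled Beta), WCC
  log-normal with median 10, 96% 7+3 induction, CR/CRi after first
  induction from a logistic model calibrated to ≈65% at baseline with
  dose-90, NPM1 and CEBPA advantages and RUNX1/ASXL1 disadvantages; salvage
  converts 74% of failures; never-CR patients follow a refractory death
  clock. Post-remission events are competing exponential clocks with
  category, age, WCC and HSCT effects (relapse baseline 0.022/month, TRM
  0.004, post-relapse death 0.055); HSCT assignment probability rises with
  the DNMT3A-modified ELN group (0.20/0.45/0.60). Administrative censoring
  at 120 months.
* **Not emulated:** sequencing reads and calling error, variable accrual
  and loss to follow-up (censoring is purely administrative),
  non-proportional or time-varying hazards, cytogenetics, measurable
  residual disease, and any attempt to match a specific cohort's fitted
  survival curves. Passing tests therefore demonstrate correctness of the
  machinery under a known, simplified data-generating process — not
  clinical calibration of the default parameters.

# Numerical and testing choices

* Exponential/Weibull Newton solvers: convergence at gradient norm
  $10^{-8}$ / $10^{-6}$, 200 iterations, step-halving; Weibull Hessian by
  central differences of the analytic gradient (step $10^{-5}$).
* Quadrature: `integrate()` at absolute tolerance $10^{-10}$ per
  subinterval; occupancy conservation is asserted at $10^{-8}$.
* Ties: KM and log-rank place events before censorings at equal times; Cox
  uses Breslow; equal occupancy denominators $|a - \lambda_3| < 10^{-10}$
  switch to the limiting form $\lambda_1 t e^{-at}$.
* Serialization writes numbers at 17 significant digits so write/read
  round-trips are bit-exact.
* Test problem sizes were chosen to make Monte-Carlo noise small relative
  to the asserted tolerances while keeping the default suite around five
  minutes: 20,000 subjects for the exponential-survival band, 50,000 for
  marginal-frequency fidelity (±0.01 ≈ 5 binomial SE), 100 cohorts of
  1,000 for multistate recovery, 200 cohorts of 500 for Cox bias/coverage,
  100 replicates of 400 for the model-vs-ELN comparison. Parameter-recovery
  experiments refit the generating covariate specification; padding
  transitions with null covariates puts ~10 events behind some coefficients,
  where small-sample ML bias is expected and would measure the experiment,
  not the fitter.
* Per-stage pipeline sub-seeds come from an FNV-1a hash of the stage name
  combined with the global seed, so inserting a stage never shifts another
  stage's random stream.

# Known limitations

* The multistate family is a stand-in for an unspecified published
  learner; its virtue is transparency, not flexibility.
* HSCT handling (time-fixed from CR1, fixed assignment delay) understates
  immortal-time subtleties; a time-dependent covariate or a waiting-time
  state is future work.
* The clonal-architecture rule is a single-threshold heuristic on bulk
  VAF; it does not infer phylogenies or cluster cancer-cell fractions.
* The ELN encoding covers the gene-only rows relevant to CN disease;
  karyotype-driven rows are intentionally absent.
* Default generator parameters are plausible, not fitted; conclusions
  about real cohorts require re-running the machinery on real tables via
  `read_cohort()`.
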