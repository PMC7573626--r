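# Default mutation spectrum for the synthetic CN-AML cohort generator.
# Marginal lesion frequencies are qualitatively ranked (NPM1 and DNMT3A most
# frequent, FLT3-ITD next, rare tumor suppressors least) and are
# configuration, not cohort estimates. Lesion labels of the form GENE-SUFFIX
# map to gene GENE with the suffix selecting the subtype family.
gene_freqs:
  NPM1: 0.35
  DNMT3A: 0.30
  FLT3-ITD: 0.25
  NRAS: 0.12
  TET2: 0.10
  IDH2: 0.10
  FLT3-TKD: 0.08
  IDH1: 0.07
  CEBPA-DM: 0.06
  WT1: 0.06
  RUNX1: 0.05
  ASXL1: 0.04
  KRAS: 0.04
  TP53: 0.02
# Probability that a non-founding occurrence of the lesion is subclonal.
# FLT3-ITD and signalling mutations are most often subclonal; NPM1 almost
# never is.
p_subclone_default: 0.25
p_subclone:
  NPM1: 0.05
  FLT3-ITD: 0.55
  FLT3-TKD: 0.50
  NRAS: 0.50
  KRAS: 0.50
  WT1: 0.40
  CEBPA-DM: 0.10
# Pairwise log-odds tilts for co-occurrence (symmetric); NPM1 co-occurs with
# DNMT3A and FLT3-ITD and is near-exclusive with CEBPA-DM/RUNX1/TP53.
cooccurrence_log_odds:
  - [NPM1, DNMT3A, 0.9]
  - [NPM1, FLT3-ITD, 0.6]
  - [NPM1, CEBPA-DM, -2.0]
  - [NPM1, RUNX1, -2.0]
  - [NPM1, TP53, -1.0]
  - [DNMT3A, IDH2, 0.4]
  - [RUNX1, ASXL1, 0.8]
# Variant subtype label distribution within each lesion.
subtypes:
  NPM1: {typeA: 0.80, typeB: 0.08, typeD: 0.06, other: 0.06}
  DNMT3A: {R882: 0.60, non-R882: 0.40}
  FLT3-ITD: {ITD: 1.0}
  FLT3-TKD: {TKD-D835: 0.75, TKD-nonD835: 0.25}
  IDH1: {R132H: 0.50, R132C: 0.20, R132S: 0.10, R132L: 0.10, R132G: 0.10}
  IDH2: {R140Q: 0.75, R172K: 0.25}
  CEBPA-DM: {biallelic: 1.0}
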