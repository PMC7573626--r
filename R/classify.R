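# Genotype classification: FLT3-ITD burden, the five NPM1/FLT3-ITD/DNMT3A
# combination categories, gene-only ELN 2017 risk for cytogenetically normal
# disease, and the DNMT3A-modified ELN risk.

#' Convert a variant allele frequency to an allelic ratio
#'
#' The allelic ratio (mutant over wild-type allele quantity) is
#' `AR = VAF / (1 - VAF)`. A FLT3-ITD VAF of 1/3 corresponds to AR 0.5, the
#' conventional cut between low and high ITD burden.
#'
#' @param vaf numeric vector of variant allele frequencies in `[0, 1)`.
#' @return Numeric vector of allelic ratios (unitless, `>= 0`), strictly
#'   increasing in `vaf`.
#' @examples
#' vaf_to_allelic_ratio(1/3) # 0.5
#' vaf_to_allelic_ratio(0.5) # 1
#' @export
vaf_to_allelic_ratio <- function(vaf) {
  if (any(!is.finite(vaf) | vaf < 0 | vaf >= 1)) {
    stop("allelic ratio is undefined unless 0 <= vaf < 1", call. = FALSE)
  }
  vaf / (1 - vaf)
}

is_itd <- function(gene, subtype) {
  gene == "FLT3" & grepl("ITD", subtype, ignore.case = TRUE)
}

is_cebpa_biallelic <- function(gene, subtype) {
  gene == "CEBPA" & grepl("^(biallelic|dm)$", subtype, ignore.case = TRUE)
}

#' Classify FLT3-ITD burden for one patient
#'
#' A FLT3 call whose subtype label contains "ITD" counts as an internal
#' tandem duplication; FLT3-TKD calls never do. With multiple ITD calls the
#' maximum VAF decides: `high` when max VAF >= 0.33 (allelic ratio >= 0.5),
#' `low` below, `absent` with no ITD call.
#'
#' @param mutations data frame of one patient's mutation calls
#'   (columns `gene`, `subtype`, `vaf`); may have zero rows.
#' @param vaf_high high-burden VAF threshold (default 0.33).
#' @return `"absent"`, `"low"` or `"high"`.
#' @export
classify_flt3_itd <- function(mutations, vaf_high = 0.33) {
  itd <- is_itd(mutations$gene, mutations$subtype)
  if (!any(itd)) return("absent")
  if (max(mutations$vaf[itd]) >= vaf_high) "high" else "low"
}

#' Assign the five-category genotype label for one patient
#'
#' Categories are defined on NPM1 mutation, FLT3-ITD presence (any burden)
#' and DNMT3A mutation (any subtype); mutations in other genes never change
#' the category:
#' \describe{
#'   \item{1}{NPM1 mutated, no FLT3-ITD, no DNMT3A}
#'   \item{2}{wild type for all three (other genes may be mutated)}
#'   \item{3}{NPM1 mutated with FLT3-ITD, no DNMT3A}
#'   \item{4}{FLT3-ITD only (NPM1 wild type), no DNMT3A}
#'   \item{5}{DNMT3A mutated, irrespective of NPM1 and FLT3 status}
#' }
#'
#' @inheritParams classify_flt3_itd
#' @return Integer in `1:5`.
#' @export
classify_category <- function(mutations) {
  has_dnmt3a <- any(mutations$gene == "DNMT3A")
  if (has_dnmt3a) return(5L)
  has_npm1 <- any(mutations$gene == "NPM1")
  has_itd <- any(is_itd(mutations$gene, mutations$subtype))
  if (has_npm1 && !has_itd) 1L
  else if (!has_npm1 && !has_itd) 2L
  else if (has_npm1 && has_itd) 3L
  else 4L
}

#' ELN 2017 rule configuration
#'
#' The gene-only ELN 2017 table is exposed as data so alternative readings
#' are testable: which genes are always adverse, which adverse markers yield
#' to a co-occurring favorable-defining lesion, and the high-ITD VAF cut.
#'
#' @param adverse_genes genes whose mutation is adverse.
#' @param yield_genes subset of `adverse_genes` whose adverse status is
#'   ignored when a favorable-defining lesion (NPM1-mutant without high ITD,
#'   or biallelic CEBPA) co-occurs.
#' @param runx1_asxl1_yield if `FALSE`, `yield_genes` is emptied so
#'   RUNX1/ASXL1 stay adverse regardless of co-occurring lesions.
#' @param itd_high_vaf VAF threshold defining high FLT3-ITD burden.
#' @return A list of class `eln_rules`.
#' @export
eln_rules <- function(adverse_genes = c("RUNX1", "ASXL1", "TP53"),
                      yield_genes = c("RUNX1", "ASXL1"),
                      runx1_asxl1_yield = TRUE,
                      itd_high_vaf = 0.33) {
  if (!runx1_asxl1_yield) yield_genes <- character(0)
  structure(list(adverse_genes = adverse_genes,
                 yield_genes = intersect(yield_genes, adverse_genes),
                 itd_high_vaf = itd_high_vaf),
            class = "eln_rules")
}

#' Gene-only ELN 2017 risk for cytogenetically normal AML, one patient
#'
#' Favorable: NPM1-mutant with ITD absent or low, or biallelic CEBPA
#' (subtype `"biallelic"`/`"DM"`). Adverse: NPM1-wild-type with high ITD, or
#' any mutation in the configured adverse genes (RUNX1/ASXL1 by default
#' yield to a co-occurring favorable-defining lesion; TP53 never yields).
#' Everything else — including NPM1-mutant with high ITD — is intermediate.
#' Karyotype is assumed normal; no cytogenetic input is taken.
#'
#' @inheritParams classify_flt3_itd
#' @param flt3_itd_level result of [classify_flt3_itd()]; computed when `NULL`.
#' @param rules an [eln_rules()] configuration.
#' @return `"favorable"`, `"intermediate"` or `"adverse"`.
#' @export
classify_eln2017 <- function(mutations, flt3_itd_level = NULL,
                             rules = eln_rules()) {
  if (is.null(flt3_itd_level)) {
    flt3_itd_level <- classify_flt3_itd(mutations, rules$itd_high_vaf)
  }
  has_npm1 <- any(mutations$gene == "NPM1")
  cebpa_bi <- any(is_cebpa_biallelic(mutations$gene, mutations$subtype))
  favorable_lesion <- (has_npm1 && flt3_itd_level != "high") || cebpa_bi

  hit <- intersect(unique(mutations$gene), rules$adverse_genes)
  non_yielding <- setdiff(hit, rules$yield_genes)
  adverse_marker <- length(non_yielding) > 0 ||
    (length(hit) > 0 && !favorable_lesion)
  adverse <- adverse_marker || (!has_npm1 && flt3_itd_level == "high")

  if (adverse) "adverse"
  else if (favorable_lesion) "favorable"
  else "intermediate"
}

#' DNMT3A-modified ELN risk, one patient
#'
#' Re-stratification in which any DNMT3A mutation (R882 or not) is an
#' unfavorable risk factor: DNMT3A-mutated patients are adverse; everyone
#' else keeps their ELN 2017 group.
#'
#' @inheritParams classify_flt3_itd
#' @param eln2017 the patient's [classify_eln2017()] group.
#' @return `"favorable"`, `"intermediate"` or `"adverse"`.
#' @export
classify_eln_dnmt3a <- function(mutations, eln2017) {
  if (any(mutations$gene == "DNMT3A")) "adverse" else eln2017
}

#' Classify every patient in a cohort
#'
#' Applies [classify_flt3_itd()], [classify_category()], [classify_eln2017()]
#' and [classify_eln_dnmt3a()] patient-wise, and sets the `idh1_r132h` flag
#' used for the Category-2 subgroup analysis.
#'
#' @param cohort an `aml_cohort`.
#' @param rules an [eln_rules()] configuration.
#' @return A data frame with one row per patient: `patient_id`, `category`,
#'   `flt3_itd_level`, `eln2017`, `eln_dnmt3a`, `flags` (comma-separated,
#'   empty if none).
#' @export
classify_cohort <- function(cohort, rules = eln_rules()) {
  stopifnot(inherits(cohort, "aml_cohort"))
  classify_patient_set(cohort$mutations, cohort$clinical$patient_id, rules)
}

# Workhorse for classify_cohort, usable before a full cohort object exists
# (the generator classifies genotypes while histories are being simulated).
classify_patient_set <- function(mutations, ids, rules = eln_rules()) {
  by_pt <- split(mutations, factor(mutations$patient_id, levels = ids))
  res <- lapply(by_pt, function(mu) {
    itd <- classify_flt3_itd(mu, rules$itd_high_vaf)
    eln <- classify_eln2017(mu, itd, rules)
    flags <- character(0)
    if (any(mu$gene == "IDH1" & grepl("R132H", mu$subtype, ignore.case = TRUE))) {
      flags <- c(flags, "idh1_r132h")
    }
    data.frame(
      category = classify_category(mu),
      flt3_itd_level = itd,
      eln2017 = eln,
      eln_dnmt3a = classify_eln_dnmt3a(mu, eln),
      flags = paste(flags, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out <- cbind(patient_id = ids, out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
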