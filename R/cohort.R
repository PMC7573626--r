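# Cohort schema: domain tables, validation, and delimited-text I/O.
#
# A cohort is a pair of data frames sharing a patient_id key:
#   * clinical — one row per patient (covariates + event history)
#   * mutations — one row per gene-level mutation call (gene, subtype, VAF)
# Times are months from diagnosis (diagnosis is time 0). Missing times are NA
# (serialized as empty cells).

CLINICAL_COLUMNS <- c(
  "patient_id", "age", "sex", "wcc", "dauno_dose", "regimen",
  "induction_given", "cr1_time", "cr1_via_salvage", "relapse_time",
  "hsct_time", "death_time", "death_context", "last_followup"
)

MUTATION_COLUMNS <- c("patient_id", "gene", "subtype", "vaf")

DEATH_CONTEXTS <- c("TRM_in_remission", "death_in_relapse", "death_refractory", "none")

#' Construct a cohort from clinical and mutation tables
#'
#' Bundles a per-patient clinical table and a per-call mutation table into a
#' validated `aml_cohort` object, the container consumed by every analysis
#' function in the package. Gene symbols are upper-cased on ingest; mutation
#' subtype labels are case-preserved.
#'
#' @param clinical data frame with columns `patient_id`, `age` (years), `sex`
#'   (`"male"`/`"female"`), `wcc` (presenting white cell count, 1e9/L),
#'   `dauno_dose` (`"60"`, `"90"`, `"other"`, `"none"`), `regimen`,
#'   `induction_given` (logical), `cr1_time`, `cr1_via_salvage` (logical),
#'   `relapse_time`, `hsct_time`, `death_time` (months from diagnosis, NA if
#'   the event did not occur), `death_context` (one of `TRM_in_remission`,
#'   `death_in_relapse`, `death_refractory`, `none`), `last_followup` (months).
#' @param mutations data frame with columns `patient_id`, `gene`, `subtype`
#'   (free-text variant label, e.g. `"ITD"`, `"R882"`, `"typeA"`,
#'   `"biallelic"`), `vaf` (variant allele frequency in `[0, 1]`). Patients
#'   absent from this table are treated as all-wild-type.
#' @param provenance list with at least `$source` (`"synthetic"` or
#'   `"imported"`); synthetic cohorts also carry `$config_hash`.
#' @param validate enforce all schema invariants (default `TRUE`). Disabling
#'   is intended only for deliberately malformed fixtures in tests.
#' @return An object of class `aml_cohort`: a list with elements `clinical`,
#'   `mutations` and `provenance`.
#' @seealso [read_cohort()], [generate_cohort()], [validate_cohort()]
#' @export
new_cohort <- function(clinical, mutations,
                       provenance = list(source = "imported"),
                       validate = TRUE) {
  clinical <- as.data.frame(clinical, stringsAsFactors = FALSE)
  mutations <- as.data.frame(mutations, stringsAsFactors = FALSE)
  missing_clin <- setdiff(CLINICAL_COLUMNS, names(clinical))
  if (length(missing_clin) > 0) {
    stop("clinical table is missing required column(s): ",
         paste(missing_clin, collapse = ", "), call. = FALSE)
  }
  missing_mut <- setdiff(MUTATION_COLUMNS, names(mutations))
  if (length(missing_mut) > 0) {
    stop("mutation table is missing required column(s): ",
         paste(missing_mut, collapse = ", "), call. = FALSE)
  }
  clinical <- clinical[, CLINICAL_COLUMNS]
  mutations <- mutations[, MUTATION_COLUMNS]
  clinical$patient_id <- as.character(clinical$patient_id)
  mutations$patient_id <- as.character(mutations$patient_id)
  mutations$gene <- toupper(as.character(mutations$gene))
  mutations$subtype <- as.character(mutations$subtype)
  for (col in c("age", "wcc", "cr1_time", "relapse_time", "hsct_time",
                "death_time", "last_followup")) {
    clinical[[col]] <- as.numeric(clinical[[col]])
  }
  for (col in c("induction_given", "cr1_via_salvage")) {
    clinical[[col]] <- as.logical(clinical[[col]])
  }
  for (col in c("sex", "dauno_dose", "regimen", "death_context")) {
    clinical[[col]] <- as.character(clinical[[col]])
  }
  mutations$vaf <- as.numeric(mutations$vaf)
  rownames(clinical) <- NULL
  rownames(mutations) <- NULL
  cohort <- structure(
    list(clinical = clinical, mutations = mutations, provenance = provenance),
    class = "aml_cohort"
  )
  if (validate) validate_cohort(cohort)
  cohort
}

#' Validate an `aml_cohort` against the schema invariants
#'
#' Checks every documented invariant: VAF bounds, non-negative finite age and
#' white cell count, controlled vocabularies, event-history ordering
#' (relapse after CR1, HSCT at or after CR1, all times within follow-up,
#' death time equal to last follow-up), the equivalence of `death_context`
#' and `death_time`, mutation rows keyed to known patients, and patient_id
#' uniqueness. Violations raise an error naming the offending patient(s) and
#' the rule.
#'
#' @param cohort an `aml_cohort`.
#' @return Invisibly `TRUE` if the cohort is valid; otherwise an error.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "aml_cohort"))
  cl <- cohort$clinical
  mu <- cohort$mutations
  problems <- character(0)
  fail <- function(ids, rule) {
    if (length(ids) > 0) {
      problems <<- c(problems, sprintf(
        "patient(s) %s violate rule: %s",
        paste(utils::head(unique(ids), 5), collapse = ", "), rule))
    }
  }

  if (nrow(cl) == 0) {
    stop("cohort validation failed: clinical table has zero rows", call. = FALSE)
  }
  dup <- cl$patient_id[duplicated(cl$patient_id)]
  fail(dup, "patient_id unique within cohort")

  bad <- cl$patient_id[!is.finite(cl$age) | cl$age < 0]
  fail(bad, "age finite and non-negative")
  bad <- cl$patient_id[!is.finite(cl$wcc) | cl$wcc < 0]
  fail(bad, "wcc finite and non-negative")
  bad <- cl$patient_id[!cl$sex %in% c("male", "female")]
  fail(bad, "sex in {male, female}")
  bad <- cl$patient_id[!cl$dauno_dose %in% c("60", "90", "other", "none")]
  fail(bad, "dauno_dose in {60, 90, other, none}")
  bad <- cl$patient_id[!cl$death_context %in% DEATH_CONTEXTS]
  fail(bad, paste("death_context in {", paste(DEATH_CONTEXTS, collapse = ", "), "}"))
  bad <- cl$patient_id[is.na(cl$last_followup) | cl$last_followup < 0]
  fail(bad, "last_followup present and >= 0")

  within_fu <- function(x) is.na(x) | (x >= 0 & x <= cl$last_followup)
  fail(cl$patient_id[!within_fu(cl$cr1_time)], "0 <= cr1_time <= last_followup")
  fail(cl$patient_id[!within_fu(cl$relapse_time)], "0 <= relapse_time <= last_followup")
  fail(cl$patient_id[!within_fu(cl$hsct_time)], "0 <= hsct_time <= last_followup")
  bad <- cl$patient_id[!is.na(cl$death_time) & cl$death_time != cl$last_followup]
  fail(bad, "death_time equals last_followup when present")
  bad <- cl$patient_id[xor(cl$death_context != "none", !is.na(cl$death_time))]
  fail(bad, "death_context != none if and only if death_time present")
  bad <- cl$patient_id[!is.na(cl$relapse_time) &
                         (is.na(cl$cr1_time) | cl$relapse_time <= cl$cr1_time)]
  fail(bad, "relapse_time present requires cr1_time present and relapse_time > cr1_time")
  bad <- cl$patient_id[!is.na(cl$hsct_time) &
                         (is.na(cl$cr1_time) | cl$hsct_time < cl$cr1_time)]
  fail(bad, "hsct_time present requires cr1_time present and hsct_time >= cr1_time (HSCT at CR1 only)")

  if (nrow(mu) > 0) {
    bad <- mu$patient_id[!mu$patient_id %in% cl$patient_id]
    fail(bad, "mutation rows must reference a known patient_id")
    bad <- mu$patient_id[is.na(mu$vaf) | mu$vaf < 0 | mu$vaf > 1]
    fail(bad, "0 <= vaf <= 1")
    bad <- mu$patient_id[is.na(mu$gene) | mu$gene == ""]
    fail(bad, "gene is non-empty")
  }

  if (length(problems) > 0) {
    stop("cohort validation failed:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(TRUE)
}

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a cohort from delimited text files
#'
#' Reads the clinical and mutation tables (TSV or CSV, autodetected from the
#' file extension; `.csv` is comma-delimited, anything else tab-delimited),
#' validates all schema invariants and returns an [new_cohort()] object.
#' Empty cells encode missing values. Patients with no mutation rows are
#' retained as all-wild-type.
#'
#' @param clinical_path,mutations_path paths to delimited text files with
#'   header rows; required columns as documented in [new_cohort()].
#' @return A validated `aml_cohort` with provenance `imported`.
#' @export
read_cohort <- function(clinical_path, mutations_path) {
  for (p in c(clinical_path, mutations_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  clinical <- utils::read.table(clinical_path, header = TRUE,
                                sep = delim_for(clinical_path),
                                colClasses = "character",
                                na.strings = "", quote = "\"",
                                stringsAsFactors = FALSE)
  mutations <- utils::read.table(mutations_path, header = TRUE,
                                 sep = delim_for(mutations_path),
                                 colClasses = "character",
                                 na.strings = "", quote = "\"",
                                 stringsAsFactors = FALSE)
  # death_context NA (empty cell) means "none"
  if ("death_context" %in% names(clinical)) {
    clinical$death_context[is.na(clinical$death_context)] <- "none"
  }
  new_cohort(clinical, mutations, provenance = list(source = "imported"))
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a cohort to delimited text files
#'
#' Serializes the clinical and mutation tables so that
#' `read_cohort(write_cohort(c))` reproduces `c` exactly: numeric times are
#' written with 17 significant digits and missing values as empty cells.
#'
#' @param cohort an `aml_cohort`.
#' @param clinical_path,mutations_path destination paths; the delimiter is
#'   chosen from each extension as in [read_cohort()].
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, clinical_path, mutations_path) {
  stopifnot(inherits(cohort, "aml_cohort"))
  cl <- cohort$clinical
  for (col in c("age", "wcc", "cr1_time", "relapse_time", "hsct_time",
                "death_time", "last_followup")) {
    cl[[col]] <- fmt_num(cl[[col]])
  }
  mu <- cohort$mutations
  mu$vaf <- fmt_num(mu$vaf)
  write_one <- function(df, path) {
    ok <- tryCatch({
      utils::write.table(df, path, sep = delim_for(path), na = "",
                         row.names = FALSE, quote = FALSE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) {
      stop("failed to write ", path, ": ", conditionMessage(ok), call. = FALSE)
    }
  }
  write_one(cl, clinical_path)
  write_one(mu, mutations_path)
  invisible(c(clinical_path, mutations_path))
}

#' Convert a MAF-style mutation table to the package's mutation schema
#'
#' Convenience adapter for Mutation Annotation Format exports:
#' maps `Tumor_Sample_Barcode` to `patient_id`, `Hugo_Symbol` to `gene`,
#' and computes `vaf = t_alt_count / t_depth`. The variant subtype label is
#' taken from `Protein_Change` if present, otherwise empty.
#'
#' @param maf data frame with columns `Tumor_Sample_Barcode`, `Hugo_Symbol`,
#'   `t_alt_count`, `t_depth` (and optionally `Protein_Change`).
#' @return A data frame with the package's mutation columns.
#' @export
maf_to_mutations <- function(maf) {
  need <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "t_alt_count", "t_depth")
  missing <- setdiff(need, names(maf))
  if (length(missing) > 0) {
    stop("MAF table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  depth <- as.numeric(maf$t_depth)
  if (any(!is.finite(depth) | depth <= 0)) {
    stop("t_depth must be positive for all rows", call. = FALSE)
  }
  data.frame(
    patient_id = as.character(maf$Tumor_Sample_Barcode),
    gene = toupper(as.character(maf$Hugo_Symbol)),
    subtype = if ("Protein_Change" %in% names(maf))
      as.character(maf$Protein_Change) else "",
    vaf = as.numeric(maf$t_alt_count) / depth,
    stringsAsFactors = FALSE
  )
}

#' @export
print.aml_cohort <- function(x, ...) {
  cat(sprintf("<aml_cohort> %d patients, %d mutation calls (%s)\n",
              nrow(x$clinical), nrow(x$mutations),
              x$provenance$source %||% "unknown"))
  n_mut <- length(unique(x$mutations$patient_id))
  cat(sprintf("  patients with >=1 detectable mutation: %d\n", n_mut))
  cat(sprintf("  achieved CR1: %d; relapsed: %d; died: %d\n",
              sum(!is.na(x$clinical$cr1_time)),
              sum(!is.na(x$clinical$relapse_time)),
              sum(!is.na(x$clinical$death_time))))
  invisible(x)
}

# Split the mutation table by patient, including all-wild-type patients
# (empty data frames), in clinical-table order.
mutations_by_patient <- function(cohort) {
  ids <- cohort$clinical$patient_id
  mu <- cohort$mutations
  split(mu, factor(mu$patient_id, levels = ids))
}
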