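# Clonal architecture from variant allele frequencies: dominant /
# co-dominant / subclone calls per mutation, canonical per-patient clonal
# subtype keys, and cohort-level subtype enumeration (the bubble-diagram
# computation).

#' Call clonality of each mutation of one patient
#'
#' Under a heterozygous autosomal assumption each call's clone fraction is
#' `min(1, 2 * VAF)`. Calls whose clone fraction is at least
#' `rel_threshold` times the patient's maximum clone fraction form the
#' dominant tier: a single-member tier is `dominant`, a multi-member tier is
#' `co_dominant`; every other call is a `subclone`. The rule is relative, so
#' rescaling all VAFs of a patient by a common factor leaves statuses
#' unchanged.
#'
#' @param mutations data frame of one patient's calls (columns `gene`,
#'   `subtype`, `vaf`), at least one row.
#' @param rel_threshold dominant-tier cut as a fraction of the maximum clone
#'   fraction (default 0.67, which places a 0.45/0.12 VAF pair in
#'   dominant/subclone and a 0.47/0.44 pair in co-dominance).
#' @param tol reserved for absolute comparisons; unused by the default rule.
#' @return The input data frame with columns `clone_fraction` and `status`
#'   (`"dominant"`, `"co_dominant"` or `"subclone"`) appended.
#' @export
call_clonality <- function(mutations, rel_threshold = 0.67, tol = 0.10) {
  if (is.null(mutations) || nrow(mutations) == 0) {
    stop("call_clonality requires at least one mutation; ",
         "all-wild-type patients have no clonal architecture", call. = FALSE)
  }
  cf <- pmin(1, 2 * mutations$vaf)
  f_max <- max(cf)
  tier <- cf >= rel_threshold * f_max
  status <- ifelse(tier,
                   if (sum(tier) == 1L) "dominant" else "co_dominant",
                   "subclone")
  out <- mutations
  out$clone_fraction <- cf
  out$status <- status
  out
}

#' Canonical clonal-subtype key for one patient
#'
#' Builds an order-invariant key `"dominant-set | subclone-set"`: gene:subtype
#' tokens sorted lexicographically within each set, joined by `+`, with `-`
#' for an empty subclone set. Two patients with the same genes but swapped
#' dominant/subclone roles get different keys.
#'
#' @param calls output of [call_clonality()] for one patient.
#' @return A single string.
#' @export
subtype_key <- function(calls) {
  token <- paste0(calls$gene, ":", calls$subtype)
  dom <- sort(unique(token[calls$status %in% c("dominant", "co_dominant")]))
  sub <- sort(unique(token[calls$status == "subclone"]))
  paste(paste(dom, collapse = "+"),
        if (length(sub) > 0) paste(sub, collapse = "+") else "-",
        sep = " | ")
}

#' Enumerate distinct clonal subtypes across a cohort
#'
#' Calls clonality for every patient with at least one detectable mutation,
#' reduces each to a canonical [subtype_key()], and tabulates. Prevalences
#' are fractions of the mutated-patient denominator (all-wild-type patients
#' are excluded), so counts sum to that denominator.
#'
#' @param cohort an `aml_cohort` with at least one mutated patient.
#' @inheritParams call_clonality
#' @return A data frame (`key`, `count`, `prevalence`) sorted by count
#'   descending, key ascending as tie-break.
#' @export
enumerate_subtypes <- function(cohort, rel_threshold = 0.67) {
  stopifnot(inherits(cohort, "aml_cohort"))
  by_pt <- mutations_by_patient(cohort)
  by_pt <- Filter(function(mu) nrow(mu) > 0, by_pt)
  if (length(by_pt) == 0) {
    stop("enumerate_subtypes requires at least one mutated patient",
         call. = FALSE)
  }
  keys <- vapply(by_pt, function(mu) {
    subtype_key(call_clonality(mu, rel_threshold))
  }, character(1))
  tab <- table(keys)
  out <- data.frame(key = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$prevalence <- out$count / length(keys)
  out <- out[order(-out$count, out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-mutation clonality table for a whole cohort
#'
#' @param cohort an `aml_cohort`.
#' @inheritParams call_clonality
#' @return The cohort mutation table with `clone_fraction` and `status`
#'   columns, in clinical-table patient order; zero-mutation patients
#'   contribute no rows.
#' @export
call_clonality_cohort <- function(cohort, rel_threshold = 0.67) {
  stopifnot(inherits(cohort, "aml_cohort"))
  by_pt <- mutations_by_patient(cohort)
  res <- lapply(by_pt, function(mu) {
    if (nrow(mu) == 0) NULL else call_clonality(mu, rel_threshold)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Bubble-diagram export of the cohort's clonal architecture
#'
#' Serializes [enumerate_subtypes()] output as a list ready for JSON export:
#' one element per subtype with the outer-bubble (dominant/co-dominant set
#' with cohort prevalence) and inner-bubble (subclone set with mean clone
#' size relative to the dominant tier) information.
#'
#' @inheritParams enumerate_subtypes
#' @return A list of subtype descriptors.
#' @export
bubble_diagram_data <- function(cohort, rel_threshold = 0.67) {
  stopifnot(inherits(cohort, "aml_cohort"))
  by_pt <- mutations_by_patient(cohort)
  by_pt <- Filter(function(mu) nrow(mu) > 0, by_pt)
  calls <- lapply(by_pt, call_clonality, rel_threshold = rel_threshold)
  keys <- vapply(calls, subtype_key, character(1))
  out <- lapply(unique(keys), function(k) {
    members <- calls[keys == k]
    one <- members[[1]]
    dom_cf <- max(one$clone_fraction)
    rel_sizes <- vapply(members, function(cc) {
      sub <- cc$clone_fraction[cc$status == "subclone"]
      if (length(sub) == 0) 0 else mean(sub) / max(cc$clone_fraction)
    }, numeric(1))
    list(
      key = k,
      outer = sort(unique(paste0(one$gene, ":", one$subtype)[
        one$status != "subclone"])),
      inner = sort(unique(paste0(one$gene, ":", one$subtype)[
        one$status == "subclone"])),
      prevalence = length(members) / length(calls),
      inner_relative_size = mean(rel_sizes)
    )
  })
  out[order(-vapply(out, `[[`, numeric(1), "prevalence"),
            vapply(out, `[[`, character(1), "key"))]
}
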