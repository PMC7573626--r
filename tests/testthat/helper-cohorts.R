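# Shared fixture builders. Everything is constructed in code; no binary data.

# One clinical row with sensible defaults, overridable per field.
clinical_row <- function(patient_id, ...) {
  row <- list(
    patient_id = patient_id, age = 45, sex = "female", wcc = 10,
    dauno_dose = "60", regimen = "7+3", induction_given = TRUE,
    cr1_time = NA_real_, cr1_via_salvage = FALSE, relapse_time = NA_real_,
    hsct_time = NA_real_, death_time = NA_real_, death_context = "none",
    last_followup = 60
  )
  over <- list(...)
  row[names(over)] <- over
  as.data.frame(row, stringsAsFactors = FALSE)
}

mutation_rows <- function(patient_id, genes, subtypes, vafs) {
  data.frame(patient_id = patient_id, gene = genes, subtype = subtypes,
             vaf = vafs, stringsAsFactors = FALSE)
}

empty_mutations <- function() {
  data.frame(patient_id = character(0), gene = character(0),
             subtype = character(0), vaf = numeric(0),
             stringsAsFactors = FALSE)
}

# A mutation data frame for single-patient classification helpers.
muts <- function(...) {
  calls <- list(...)
  do.call(rbind, lapply(calls, function(x) {
    data.frame(patient_id = "P1", gene = x[[1]], subtype = x[[2]],
               vaf = as.numeric(x[[3]]), stringsAsFactors = FALSE)
  })) %||% empty_mutations()
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Small generator config with co-occurrence tilts removed for speed unless
# requested; other defaults untouched.
quick_config <- function(n, seed, keep_cooccurrence = FALSE, ...) {
  cfg <- default_generator_config(n_patients = n, seed = seed, ...)
  if (!keep_cooccurrence) {
    cfg$cooccurrence_log_odds <- cfg$cooccurrence_log_odds[0, , drop = FALSE]
  }
  cfg
}

# Manual multistate model object for prediction-side tests: exponential or
# weibull, with named beta vectors over the package's covariate set.
make_ms_model <- function(l1, l2, l3,
                          beta1 = numeric(0), beta2 = numeric(0),
                          beta3 = numeric(0),
                          family = "exponential",
                          gamma = c(1, 1, 1)) {
  tr <- function(l, g, b) {
    list(family = family, lambda0 = l, gamma = g, beta = b, dropped = character(0),
         loglik = NA_real_, iterations = 0L, grad_norm = 0,
         zero_events = FALSE, converged = TRUE, n = NA_integer_,
         events = NA_integer_)
  }
  structure(list(
    family = family,
    transitions = list(cr1_relapse = tr(l1, gamma[1], beta1),
                       cr1_trm = tr(l2, gamma[2], beta2),
                       relapse_death = tr(l3, gamma[3], beta3)),
    covariate_spec = list(cr1_relapse = names(beta1),
                          cr1_trm = names(beta2),
                          relapse_death = names(beta3))
  ), class = "aml_multistate")
}

# Independent pair-by-pair concordance oracle (quadratic loop, no sharing
# with the package implementation).
exhaustive_c <- function(scores, time, event) {
  num <- den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (time[i] < time[j] && event[i]) {
        den <- den + 1
        if (scores[i] > scores[j]) num <- num + 1
        else if (scores[i] == scores[j]) num <- num + 0.5
      }
    }
  }
  num / den
}

random_profile <- function() {
  list(age = sample(18:60, 1),
       sex = sample(c("male", "female"), 1),
       wcc = round(stats::rlnorm(1, log(10), 1), 1),
       category = sample(1:5, 1))
}
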