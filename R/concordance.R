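# Concordance-index evaluation and paired model comparison.
#
# Harrell's C over comparable pairs: a pair (i, j) is comparable when the
# smaller of the two follow-up times carries an event (tied times are not
# comparable). The pair is concordant when the earlier-failing patient has
# the higher risk score; tied scores earn half credit.

harrell_c_counts <- function(scores, time, event) {
  n <- length(time)
  dt <- outer(time, time, "-")            # dt[i,j] = t_i - t_j
  earlier <- dt < 0 & matrix(event, n, n) # i fails first and is an event
  ds <- outer(scores, scores, "-")        # ds[i,j] = s_i - s_j
  comparable <- sum(earlier)
  concordant <- sum(earlier & ds > 0)
  tied <- sum(earlier & ds == 0)
  list(comparable = comparable, concordant = concordant, tied = tied,
       c = if (comparable == 0) NA_real_
       else (concordant + 0.5 * tied) / comparable)
}

#' Harrell concordance index with bootstrap standard error
#'
#' @param scores per-patient risk scores (higher = higher predicted risk),
#'   aligned with `records`.
#' @param records survival records: a data frame with columns `time` and
#'   `event` (e.g. one endpoint of [derive_endpoints()]).
#' @param n_boot number of patient-level bootstrap resamples for the
#'   standard error (default 1000; 0 skips the bootstrap and reports `NA`).
#' @param seed integer seed for the bootstrap.
#' @return An object of class `aml_concordance`: `c_index`,
#'   `n_comparable_pairs`, `bootstrap_se`, `n_boot`, `seed`.
#' @export
concordance_index <- function(scores, records, n_boot = 1000, seed = 1L) {
  time <- records$time
  event <- as.logical(records$event)
  stopifnot(length(scores) == length(time))
  base <- harrell_c_counts(scores, time, event)
  if (base$comparable == 0) {
    stop("no comparable pairs: concordance is undefined", call. = FALSE)
  }
  se <- NA_real_
  if (n_boot > 0) {
    set.seed(seed)
    n <- length(time)
    cs <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      harrell_c_counts(scores[idx], time[idx], event[idx])$c
    }, numeric(1))
    se <- stats::sd(cs, na.rm = TRUE)
  }
  structure(list(c_index = base$c,
                 n_comparable_pairs = base$comparable,
                 bootstrap_se = se, n_boot = n_boot, seed = seed),
            class = "aml_concordance")
}

#' @export
print.aml_concordance <- function(x, ...) {
  cat(sprintf("Harrell C = %.4f (%d comparable pairs%s)\n",
              x$c_index, x$n_comparable_pairs,
              if (is.na(x$bootstrap_se)) ""
              else sprintf(", bootstrap SE %.4f", x$bootstrap_se)))
  invisible(x)
}

#' Encode ELN-style risk groups as ordinal baseline scores
#'
#' @param risk character vector of `"favorable"`, `"intermediate"`,
#'   `"adverse"`.
#' @return Numeric scores 0, 1, 2 (ties expected; the concordance
#'   computation half-credits them).
#' @export
eln_baseline_scores <- function(risk) {
  unname(c(favorable = 0, intermediate = 1, adverse = 2)[risk])
}

#' Paired comparison of two risk-score vectors on the same patients
#'
#' Computes both concordances and their difference, with a paired bootstrap
#' over patients: each resample recomputes both C's on the same resampled
#' patients, and the two-sided p-value is the (add-one smoothed) fraction of
#' bootstrap deltas crossing zero.
#'
#' @param model_scores,baseline_scores aligned risk-score vectors (e.g.
#'   [ms_risk_score()] and [eln_baseline_scores()]); names, when present on
#'   both, must agree.
#' @param records survival records as in [concordance_index()].
#' @param n_boot paired bootstrap resamples (default 1000; 0 skips
#'   uncertainty and reports `NA` for SE and p).
#' @param seed integer seed.
#' @return An object of class `aml_model_comparison`: `c_model`,
#'   `c_baseline`, `delta` (absolute difference), `delta_relative`,
#'   `delta_se`, `p_value`, `n_boot`, `seed`.
#' @export
compare_models <- function(model_scores, baseline_scores, records,
                           n_boot = 1000, seed = 1L) {
  if (!is.null(names(model_scores)) && !is.null(names(baseline_scores))) {
    if (!identical(sort(names(model_scores)), sort(names(baseline_scores)))) {
      stop("model and baseline scores cover different patient sets",
           call. = FALSE)
    }
    baseline_scores <- baseline_scores[names(model_scores)]
  }
  if (length(model_scores) != length(baseline_scores)) {
    stop("model and baseline scores cover different patient sets",
         call. = FALSE)
  }
  time <- records$time
  event <- as.logical(records$event)
  stopifnot(length(model_scores) == length(time))
  c_m <- harrell_c_counts(model_scores, time, event)$c
  c_b <- harrell_c_counts(baseline_scores, time, event)$c
  delta <- c_m - c_b
  delta_se <- p_value <- NA_real_
  if (n_boot > 0) {
    set.seed(seed)
    n <- length(time)
    deltas <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      harrell_c_counts(model_scores[idx], time[idx], event[idx])$c -
        harrell_c_counts(baseline_scores[idx], time[idx], event[idx])$c
    }, numeric(1))
    deltas <- deltas[is.finite(deltas)]
    B <- length(deltas)
    delta_se <- stats::sd(deltas)
    p_value <- min(1, 2 * min((1 + sum(deltas <= 0)) / (B + 1),
                              (1 + sum(deltas >= 0)) / (B + 1)))
  }
  structure(list(c_model = c_m, c_baseline = c_b, delta = delta,
                 delta_relative = delta / c_b,
                 delta_se = delta_se, p_value = p_value,
                 n_boot = n_boot, seed = seed),
            class = "aml_model_comparison")
}

#' @export
print.aml_model_comparison <- function(x, ...) {
  cat(sprintf("C(model) = %.4f, C(baseline) = %.4f, delta = %+.4f",
              x$c_model, x$c_baseline, x$delta))
  if (!is.na(x$p_value)) cat(sprintf(" (paired bootstrap p = %.4g)", x$p_value))
  cat("\n")
  invisible(x)
}

#' Train/validation workflow: multistate model versus ELN baseline
#'
#' Fits the multistate model on the training cohort only, scores both
#' cohorts with the model-predicted probability of leaving CR1 by `horizon`
#' months, scores the ELN 2017 baseline ordinally
#' (favorable 0 / intermediate 1 / adverse 2), and compares the two on the
#' chosen endpoint in each cohort. Patients transplanted without a recorded
#' CR1 (refractory-stage HSCT) are excluded from the validation cohort
#' before evaluation; a validation cohort empty after filtering is an error.
#'
#' @param train,validate disjoint `aml_cohort`s with identical schemas.
#' @param family baseline hazard family for [fit_multistate()].
#' @param covariate_spec covariate specification for [fit_multistate()].
#' @param endpoint endpoint for concordance (default `"LFS"`, measured from
#'   CR1; only CR1 patients are evaluable).
#' @param horizon risk-score horizon in months (default 60).
#' @param n_boot,seed passed to [compare_models()].
#' @return A list of class `aml_train_validate`: `model`, plus
#'   `train` and `validation` [compare_models()] results.
#' @export
train_validate <- function(train, validate, family = "exponential",
                           covariate_spec = default_covariate_spec(),
                           endpoint = "LFS", horizon = 60,
                           n_boot = 1000, seed = 1L) {
  stopifnot(inherits(train, "aml_cohort"), inherits(validate, "aml_cohort"))
  validate <- filter_refractory_hsct(validate)
  if (nrow(validate$clinical) == 0) {
    stop("validation cohort is empty after the refractory-HSCT exclusion",
         call. = FALSE)
  }
  model <- fit_multistate(train, family = family,
                          covariate_spec = covariate_spec)
  eval_one <- function(cohort, which_seed) {
    cls <- classify_cohort(cohort)
    scores <- ms_risk_score(model, cohort, horizon = horizon)
    eln <- stats::setNames(eln_baseline_scores(cls$eln2017), cls$patient_id)
    rec <- derive_endpoints(cohort, endpoints = endpoint)
    rec <- rec[match(names(scores), rec$patient_id), , drop = FALSE]
    rec <- rec[!is.na(rec$time), , drop = FALSE]
    scores <- scores[rec$patient_id]
    compare_models(scores, eln[rec$patient_id], rec,
                   n_boot = n_boot, seed = which_seed)
  }
  structure(list(model = model,
                 train = eval_one(train, seed),
                 validation = eval_one(validate, derive_seed(seed, "validation"))),
            class = "aml_train_validate")
}

#' Drop patients transplanted without a recorded CR1
#'
#' The refractory-stage HSCT exclusion applied to external validation
#' cohorts: any patient with `hsct_time` present but `cr1_time` absent, or
#' with HSCT before CR1, is removed (together with their mutation rows).
#' Schema-conformant cohorts pass through unchanged.
#'
#' @param cohort an `aml_cohort`.
#' @return The filtered `aml_cohort`.
#' @export
filter_refractory_hsct <- function(cohort) {
  cl <- cohort$clinical
  refractory <- !is.na(cl$hsct_time) &
    (is.na(cl$cr1_time) | cl$hsct_time < cl$cr1_time)
  if (!any(refractory)) return(cohort)
  keep_ids <- cl$patient_id[!refractory]
  new_cohort(cl[!refractory, , drop = FALSE],
             cohort$mutations[cohort$mutations$patient_id %in% keep_ids, ,
                              drop = FALSE],
             provenance = cohort$provenance, validate = FALSE)
}
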