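# Endpoint construction: leukemia-free, event-free and overall survival
# records, with optional censoring at HSCT.
#
# Definitions (times in months):
#  * OS  — diagnosis to death or last follow-up; event = death.
#  * LFS — CR1 to the earliest of relapse, death, last follow-up; defined
#    only for patients who achieved CR1.
#  * EFS — diagnosis to the earliest of induction failure, relapse, death,
#    last follow-up. Patients who never reach CR1 are failure events at the
#    induction assessment time (default 2 months) or at death if earlier.
# With censor_at_hsct, any record whose event/censor time lies after the
# patient's HSCT is censored at HSCT instead (the complementary view to
# treating HSCT as a covariate).

#' Derive survival endpoint records for a cohort
#'
#' @param cohort an `aml_cohort`.
#' @param endpoints subset of `c("OS", "LFS", "EFS")`.
#' @param censor_at_hsct censor every endpoint at `hsct_time` when HSCT
#'   precedes the event/censoring time (default `FALSE`).
#' @param assessment_time months from diagnosis at which induction failure is
#'   scored as an EFS event for patients who never achieve CR1 (default 2).
#' @return A data frame with columns `patient_id`, `endpoint`, `time`
#'   (months, from CR1 for LFS and from diagnosis otherwise), `event`
#'   (logical) and `censored_at_hsct` (logical; `TRUE` where the HSCT rule
#'   actually censored the record). Patients without CR1 contribute no LFS
#'   record.
#' @export
derive_endpoints <- function(cohort, endpoints = c("OS", "LFS", "EFS"),
                             censor_at_hsct = FALSE, assessment_time = 2) {
  stopifnot(inherits(cohort, "aml_cohort"))
  endpoints <- match.arg(endpoints, c("OS", "LFS", "EFS"), several.ok = TRUE)
  cl <- cohort$clinical
  out <- list()

  hsct_censor <- function(df) {
    # df has absolute end time `abs_end`; censor records whose end lies
    # strictly after HSCT
    df$censored_at_hsct <- FALSE
    if (!censor_at_hsct) return(df)
    cut <- !is.na(df$hsct_time) & df$hsct_time < df$abs_end
    df$abs_end[cut] <- df$hsct_time[cut]
    df$event[cut] <- FALSE
    df$censored_at_hsct <- cut
    df
  }

  if ("OS" %in% endpoints) {
    df <- data.frame(
      patient_id = cl$patient_id,
      abs_end = ifelse(is.na(cl$death_time), cl$last_followup, cl$death_time),
      event = !is.na(cl$death_time),
      hsct_time = cl$hsct_time,
      stringsAsFactors = FALSE
    )
    df <- hsct_censor(df)
    out$OS <- data.frame(patient_id = df$patient_id, endpoint = "OS",
                         time = df$abs_end, event = df$event,
                         censored_at_hsct = df$censored_at_hsct,
                         stringsAsFactors = FALSE)
  }

  if ("LFS" %in% endpoints) {
    has_cr <- !is.na(cl$cr1_time)
    sub <- cl[has_cr, , drop = FALSE]
    abs_end <- pmin(sub$relapse_time, sub$death_time, sub$last_followup,
                    na.rm = TRUE)
    event <- (!is.na(sub$relapse_time) & sub$relapse_time <= abs_end) |
      (!is.na(sub$death_time) & sub$death_time <= abs_end)
    df <- data.frame(patient_id = sub$patient_id, abs_end = abs_end,
                     event = event, hsct_time = sub$hsct_time,
                     stringsAsFactors = FALSE)
    df <- hsct_censor(df)
    out$LFS <- data.frame(patient_id = df$patient_id, endpoint = "LFS",
                          time = df$abs_end - sub$cr1_time, event = df$event,
                          censored_at_hsct = df$censored_at_hsct,
                          stringsAsFactors = FALSE)
  }

  if ("EFS" %in% endpoints) {
    has_cr <- !is.na(cl$cr1_time)
    abs_end <- ifelse(
      has_cr,
      pmin(cl$relapse_time, cl$death_time, cl$last_followup, na.rm = TRUE),
      pmin(assessment_time, cl$death_time, cl$last_followup, na.rm = TRUE)
    )
    event <- ifelse(
      has_cr,
      (!is.na(cl$relapse_time) & cl$relapse_time <= abs_end) |
        (!is.na(cl$death_time) & cl$death_time <= abs_end),
      TRUE  # never-CR1: induction failure (or earlier death) is the event
    )
    df <- data.frame(patient_id = cl$patient_id, abs_end = abs_end,
                     event = event, hsct_time = cl$hsct_time,
                     stringsAsFactors = FALSE)
    df <- hsct_censor(df)
    out$EFS <- data.frame(patient_id = df$patient_id, endpoint = "EFS",
                          time = df$abs_end, event = df$event,
                          censored_at_hsct = df$censored_at_hsct,
                          stringsAsFactors = FALSE)
  }

  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
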