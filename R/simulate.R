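# Synthetic CN-AML cohort generator.
#
# Emulates the statistical structure the downstream analyses assume:
#  * genotypes drawn gene-by-gene from marginal lesion frequencies tilted by
#    pairwise co-occurrence log-odds (Gibbs sweeps over a pairwise model);
#  * dominant-clone VAF concentrated near 0.40-0.50 (truncated normal) with
#    heterogeneous subclonal VAF from a uniform range; the first-drawn
#    mutation of a patient is always clonal;
#  * post-diagnosis event histories (CR/CRi, relapse, treatment-related
#    mortality, death in relapse, HSCT at CR1) simulated with competing
#    exponential clocks whose per-transition hazards are
#    lambda0 * exp(sum beta * covariate).

MS_COVARIATES <- c("cat2", "cat3", "cat4", "cat5", "age_c", "male",
                   "log_wcc", "hsct")
CR_COVARIATES <- c("dose90", "age_c", "npm1", "cebpa", "runx1", "asxl1")
MS_TRANSITIONS <- c("cr1_relapse", "cr1_trm", "relapse_death")

#' Default configuration for the synthetic cohort generator
#'
#' Returns a `generator_config` list whose mutation spectrum (marginal
#' lesion frequencies, subtype label distributions, subclone propensities and
#' pairwise co-occurrence tilts) is read from the packaged
#' `generator_defaults.yaml`, and whose clinical and event-history parameters
#' default to values a CN-AML cohort of 18-60 year-olds treated with 7+3
#' induction would plausibly show (about 65% CR/CRi after first induction,
#' relapse dominating treatment-related mortality, administrative censoring
#' at 120 months). All elements can be overridden via `...` or by modifying
#' the returned list.
#'
#' @param n_patients cohort size.
#' @param seed integer; fully determines the generated cohort.
#' @param ... named overrides for any top-level config element.
#' @return A list of class `generator_config` with elements documented in
#'   [generate_cohort()].
#' @export
default_generator_config <- function(n_patients = 500, seed = 1L, ...) {
  path <- system.file("extdata", "generator_defaults.yaml",
                      package = "cnamlrisk", mustWork = TRUE)
  spectrum <- yaml::read_yaml(path)
  cooc <- spectrum$cooccurrence_log_odds %||% list()
  cooc <- if (length(cooc) > 0) {
    data.frame(
      a = vapply(cooc, function(x) as.character(x[[1]]), character(1)),
      b = vapply(cooc, function(x) as.character(x[[2]]), character(1)),
      log_odds = vapply(cooc, function(x) as.numeric(x[[3]]), numeric(1)),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(a = character(0), b = character(0), log_odds = numeric(0))
  }
  config <- list(
    n_patients = as.integer(n_patients),
    seed = as.integer(seed),
    gene_freqs = unlist(spectrum$gene_freqs),
    p_subclone_default = spectrum$p_subclone_default %||% 0.25,
    p_subclone = unlist(spectrum$p_subclone %||% list()),
    subtypes = spectrum$subtypes %||% list(),
    cooccurrence_log_odds = cooc,
    gibbs_sweeps = 50L,
    vaf_dominant = c(mean = 0.445, sd = 0.035),
    vaf_subclone = c(low = 0.10, high = 0.30),
    # clinical covariates
    age_range = c(18, 60),
    age_beta_shape = c(2.8, 1.2),   # right-shifted: median near 49 years
    wcc_meanlog = log(10),          # presenting WCC ~ lognormal, median 10e9/L
    wcc_sdlog = 1.0,
    p_male = 0.5,
    p_dose90 = 0.40,
    p_dose_other = 0.03,
    p_regimen_73 = 0.96,
    induction_prob = 0.95,
    # induction response
    cr_probability = c(intercept = 0.65, dose90 = 0.5, age_c = -0.012,
                       npm1 = 0.4, cebpa = 0.6, runx1 = -0.6, asxl1 = -0.6),
    p_salvage_cr = 0.74,
    cr_time_range = c(0.9, 1.8),          # months, CR after first induction
    salvage_cr_time_range = c(2.5, 4.5),  # months, CR after salvage
    assessment_time = 2,                  # induction assessment, months
    refractory_death_rate = 0.09,         # per month, never-CR patients
    # post-remission multistate structure (per month baseline hazards)
    transition_hazards = c(cr1_relapse = 0.022, cr1_trm = 0.004,
                           relapse_death = 0.055),
    covariate_effects = list(
      cr1_relapse = c(cat2 = 0.45, cat3 = 0.65, cat4 = 0.95, cat5 = 1.15,
                      age_c = 0.010, log_wcc = 0.35, hsct = -0.75),
      cr1_trm = c(age_c = 0.03, hsct = 0.9),
      relapse_death = c(cat5 = 0.40, age_c = 0.015)
    ),
    hsct_policy = c(favorable = 0.20, intermediate = 0.45, adverse = 0.60),
    hsct_delay_months = 4,
    followup_max = 120
  )
  overrides <- list(...)
  if (length(overrides) > 0) {
    unknown <- setdiff(names(overrides), names(config))
    if (length(unknown) > 0) {
      stop("unknown generator config element(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    config[names(overrides)] <- overrides
  }
  structure(config, class = "generator_config")
}

validate_generator_config <- function(config) {
  p <- config$gene_freqs
  if (length(p) == 0 || any(!is.finite(p) | p < 0 | p > 1)) {
    stop("gene_freqs must be probabilities in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(config$transition_hazards) | config$transition_hazards < 0)) {
    stop("transition_hazards must be non-negative rates", call. = FALSE)
  }
  missing_tr <- setdiff(MS_TRANSITIONS, names(config$transition_hazards))
  if (length(missing_tr) > 0) {
    stop("transition_hazards missing: ", paste(missing_tr, collapse = ", "),
         call. = FALSE)
  }
  for (tr in names(config$covariate_effects)) {
    if (!tr %in% MS_TRANSITIONS) {
      stop("covariate_effects names an unknown transition: ", tr, call. = FALSE)
    }
    unknown <- setdiff(names(config$covariate_effects[[tr]]), MS_COVARIATES)
    if (length(unknown) > 0) {
      stop("covariate_effects[", tr, "] names unknown covariate(s): ",
           paste(unknown, collapse = ", "),
           " (allowed: ", paste(MS_COVARIATES, collapse = ", "), ")",
           call. = FALSE)
    }
  }
  unknown <- setdiff(names(config$cr_probability),
                     c("intercept", CR_COVARIATES))
  if (length(unknown) > 0) {
    stop("cr_probability names unknown covariate(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

lesion_gene <- function(label) sub("-(ITD|TKD|DM)$", "", label)

# Draw genotype indicator matrix (n x n_lesions) from the pairwise model.
draw_genotypes <- function(config, n) {
  labels <- names(config$gene_freqs)
  L <- length(labels)
  p <- as.numeric(config$gene_freqs)
  W <- matrix(0, L, L, dimnames = list(labels, labels))
  cooc <- config$cooccurrence_log_odds
  if (nrow(cooc) > 0) {
    for (i in seq_len(nrow(cooc))) {
      a <- cooc$a[i]; b <- cooc$b[i]
      if (!a %in% labels || !b %in% labels) next
      W[a, b] <- W[a, b] + cooc$log_odds[i]
      W[b, a] <- W[b, a] + cooc$log_odds[i]
    }
  }
  Z <- matrix(stats::runif(n * L) < rep(p, each = n), n, L,
              dimnames = list(NULL, labels))
  if (any(W != 0)) {
    # Gibbs sweeps over the pairwise binary model; marginals of degenerate
    # lesions (p 0 or 1) are preserved exactly.
    eta0 <- stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12))
    storage.mode(Z) <- "double"
    for (s in seq_len(config$gibbs_sweeps)) {
      for (j in seq_len(L)) {
        if (p[j] %in% c(0, 1)) { Z[, j] <- p[j]; next }
        eta <- eta0[j] + as.numeric(Z %*% W[, j])
        Z[, j] <- as.double(stats::runif(n) < stats::plogis(eta))
      }
    }
    Z <- Z > 0.5
  }
  Z
}

draw_subtype <- function(config, label, k) {
  dist <- config$subtypes[[label]]
  if (is.null(dist)) return(rep("mut", k))
  sample(names(dist), k, replace = TRUE, prob = as.numeric(unlist(dist)))
}

# Build the mutation table for a genotype matrix.
draw_mutations <- function(config, Z, ids) {
  hits <- which(Z, arr.ind = TRUE)
  if (nrow(hits) == 0) {
    return(data.frame(patient_id = character(0), gene = character(0),
                      subtype = character(0), vaf = numeric(0),
                      stringsAsFactors = FALSE))
  }
  labels <- colnames(Z)
  lab <- labels[hits[, 2]]
  pid <- ids[hits[, 1]]
  # the first-drawn mutation per patient is always clonal: shuffle calls
  # within patient and mark the first
  draw_order <- stats::runif(nrow(hits))
  first <- !duplicated(hits[order(hits[, 1], draw_order), 1])
  founder <- logical(nrow(hits))
  founder[order(hits[, 1], draw_order)] <- first
  p_sub <- rep(config$p_subclone_default, nrow(hits))
  named <- config$p_subclone
  override <- lab %in% names(named)
  p_sub[override] <- as.numeric(named[lab[override]])
  subclonal <- !founder & stats::runif(nrow(hits)) < p_sub
  vd <- config$vaf_dominant
  vs <- config$vaf_subclone
  vaf <- numeric(nrow(hits))
  vaf[!subclonal] <- pmin(1, pmax(0, stats::rnorm(sum(!subclonal),
                                                  vd[["mean"]], vd[["sd"]])))
  vaf[subclonal] <- stats::runif(sum(subclonal), vs[["low"]], vs[["high"]])
  subtype <- character(nrow(hits))
  for (l in unique(lab)) {
    sel <- lab == l
    subtype[sel] <- draw_subtype(config, l, sum(sel))
  }
  out <- data.frame(patient_id = pid, gene = lesion_gene(lab),
                    subtype = subtype, vaf = vaf, stringsAsFactors = FALSE)
  out[order(match(out$patient_id, ids)), , drop = FALSE]
}

# Multistate covariate matrix (columns MS_COVARIATES) from clinical +
# classification + an HSCT indicator.
build_ms_covariates <- function(clinical, classification, hsct) {
  cat <- classification$category
  cbind(
    cat2 = as.numeric(cat == 2),
    cat3 = as.numeric(cat == 3),
    cat4 = as.numeric(cat == 4),
    cat5 = as.numeric(cat == 5),
    age_c = clinical$age - 49,
    male = as.numeric(clinical$sex == "male"),
    log_wcc = log10(pmax(clinical$wcc, 0.1)) - 1,
    hsct = as.numeric(hsct)
  )
}

lin_pred <- function(X, beta) {
  if (length(beta) == 0) return(rep(0, nrow(X)))
  as.numeric(X[, names(beta), drop = FALSE] %*% beta)
}

#' Generate a synthetic CN-AML cohort
#'
#' Draws genotypes, VAF-resolved mutation calls, clinical covariates and a
#' post-diagnosis event history for `config$n_patients` patients. Event
#' histories follow the clinical outcome tree: induction (CR/CRi by a
#' logistic model, salvage for first-induction failures, refractory death
#' otherwise), then competing exponential clocks from CR1 for relapse and
#' treatment-related mortality and from relapse for death, with
#' per-transition hazards `lambda0 * exp(sum(beta * covariate))`. HSCT at
#' CR1 is assigned by `hsct_policy` (probability per DNMT3A-modified ELN
#' group) and acts as a time-fixed covariate from CR1; `hsct_time` is
#' recorded at `cr1 + hsct_delay_months` when the patient is still in
#' remission then. Administrative censoring at `followup_max` months.
#'
#' The same seed always yields the identical cohort.
#'
#' @param config a [default_generator_config()] list (possibly modified).
#' @return A validated `aml_cohort` with provenance
#'   `list(source = "synthetic", config_hash = ...)`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config") || is.list(config))
  validate_generator_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("P%04d", seq_len(n))

  # clinical covariates
  ar <- config$age_range; sh <- config$age_beta_shape
  age <- round(ar[1] + (ar[2] - ar[1]) * stats::rbeta(n, sh[1], sh[2]))
  sex <- ifelse(stats::runif(n) < config$p_male, "male", "female")
  wcc <- round(stats::rlnorm(n, config$wcc_meanlog, config$wcc_sdlog), 1)
  induction_given <- stats::runif(n) < config$induction_prob
  u <- stats::runif(n)
  dauno <- ifelse(!induction_given, "none",
                  ifelse(u < config$p_dose90, "90",
                         ifelse(u < config$p_dose90 + config$p_dose_other,
                                "other", "60")))
  regimen <- ifelse(!induction_given, "none",
                    ifelse(stats::runif(n) < config$p_regimen_73, "7+3", "5+2"))

  # genotype and mutation calls
  Z <- draw_genotypes(config, n)
  mutations <- draw_mutations(config, Z, ids)
  classification <- classify_patient_set(mutations, ids)

  # induction response
  gene_of <- function(g) {
    ids %in% mutations$patient_id[mutations$gene == g]
  }
  cebpa_bi <- ids %in% mutations$patient_id[
    is_cebpa_biallelic(mutations$gene, mutations$subtype)]
  Xcr <- cbind(dose90 = as.numeric(dauno == "90"), age_c = age - 49,
               npm1 = as.numeric(gene_of("NPM1")),
               cebpa = as.numeric(cebpa_bi),
               runx1 = as.numeric(gene_of("RUNX1")),
               asxl1 = as.numeric(gene_of("ASXL1")))
  beta_cr <- config$cr_probability
  eta <- beta_cr[["intercept"]] +
    lin_pred(Xcr, beta_cr[setdiff(names(beta_cr), "intercept")])
  p_cr <- stats::plogis(eta)
  cr_first <- induction_given & stats::runif(n) < p_cr
  salvage <- induction_given & !cr_first & stats::runif(n) < config$p_salvage_cr
  has_cr <- cr_first | salvage
  cr1_time <- rep(NA_real_, n)
  cr1_time[cr_first] <- stats::runif(sum(cr_first), config$cr_time_range[1],
                                     config$cr_time_range[2])
  cr1_time[salvage] <- stats::runif(sum(salvage),
                                    config$salvage_cr_time_range[1],
                                    config$salvage_cr_time_range[2])

  fu_max <- config$followup_max
  relapse_time <- hsct_time <- death_time <- rep(NA_real_, n)
  death_context <- rep("none", n)
  last_followup <- rep(fu_max, n)

  # never-CR patients: refractory course from the induction assessment
  nc <- which(!has_cr)
  if (length(nc) > 0) {
    t_death <- config$assessment_time +
      stats::rexp(length(nc)) / config$refractory_death_rate
    died <- t_death <= fu_max
    death_time[nc[died]] <- t_death[died]
    death_context[nc[died]] <- "death_refractory"
    last_followup[nc[died]] <- t_death[died]
  }

  # post-remission multistate simulation
  cr <- which(has_cr)
  if (length(cr) > 0) {
    cl_cr <- data.frame(age = age[cr], sex = sex[cr], wcc = wcc[cr])
    cls_cr <- classification[cr, , drop = FALSE]
    p_hsct <- config$hsct_policy[cls_cr$eln_dnmt3a]
    hsct_assigned <- stats::runif(length(cr)) < as.numeric(p_hsct)
    X <- build_ms_covariates(cl_cr, cls_cr, hsct_assigned)
    h0 <- config$transition_hazards
    be <- config$covariate_effects
    rate_rel <- h0[["cr1_relapse"]] * exp(lin_pred(X, be$cr1_relapse))
    rate_trm <- h0[["cr1_trm"]] * exp(lin_pred(X, be$cr1_trm))
    rate_dth <- h0[["relapse_death"]] * exp(lin_pred(X, be$relapse_death))
    t_rel <- stats::rexp(length(cr)) / rate_rel
    t_trm <- stats::rexp(length(cr)) / rate_trm
    t_dth <- stats::rexp(length(cr)) / rate_dth
    avail <- fu_max - cr1_time[cr]
    first <- pmin(t_rel, t_trm)

    trm_first <- t_trm <= t_rel & t_trm <= avail
    idx <- cr[trm_first]
    death_time[idx] <- cr1_time[idx] + t_trm[trm_first]
    death_context[idx] <- "TRM_in_remission"
    last_followup[idx] <- death_time[idx]

    rel_first <- t_rel < t_trm & t_rel <= avail
    idx <- cr[rel_first]
    relapse_time[idx] <- cr1_time[idx] + t_rel[rel_first]
    t_total <- t_rel[rel_first] + t_dth[rel_first]
    died <- cr1_time[idx] + t_total <= fu_max
    death_time[idx[died]] <- cr1_time[idx[died]] + t_total[died]
    death_context[idx[died]] <- "death_in_relapse"
    last_followup[idx[died]] <- death_time[idx[died]]

    gets_hsct <- hsct_assigned & first > config$hsct_delay_months &
      config$hsct_delay_months <= avail
    hsct_time[cr[gets_hsct]] <- cr1_time[cr[gets_hsct]] +
      config$hsct_delay_months
  }

  clinical <- data.frame(
    patient_id = ids, age = age, sex = sex, wcc = wcc,
    dauno_dose = dauno, regimen = regimen,
    induction_given = induction_given,
    cr1_time = cr1_time, cr1_via_salvage = salvage,
    relapse_time = relapse_time, hsct_time = hsct_time,
    death_time = death_time, death_context = death_context,
    last_followup = last_followup,
    stringsAsFactors = FALSE
  )
  new_cohort(clinical, mutations,
             provenance = list(source = "synthetic",
                               config_hash = config_hash(unclass(config))))
}

#' Ground-truth linear predictor for generated patients
#'
#' Returns the generator's CR1-to-relapse linear predictor
#' `sum(beta * covariate)` for every patient of a cohort generated under
#' `config`, using each patient's realized covariates (category, age, sex,
#' white cell count, recorded HSCT). This is the oracle against which risk
#' scores from fitted models are compared in parameter-recovery tests.
#'
#' @param config the `generator_config` the cohort was generated under.
#' @param cohort an `aml_cohort`.
#' @return Named numeric vector (patient_id -> linear predictor), monotone in
#'   each coefficient.
#' @export
true_risk_score <- function(config, cohort) {
  classification <- classify_cohort(cohort)
  X <- build_ms_covariates(cohort$clinical, classification,
                           !is.na(cohort$clinical$hsct_time))
  lp <- lin_pred(X, config$covariate_effects$cr1_relapse)
  stats::setNames(lp, cohort$clinical$patient_id)
}
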