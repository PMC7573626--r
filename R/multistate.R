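# Parametric cause-specific multistate model of post-remission outcomes.
#
# State space (directed acyclic): CR1 (transient) -> RELAPSE (transient)
# and CR1 -> TRM (absorbing); RELAPSE -> DEATH_RELAPSE (absorbing). Patients
# enter at CR1 (time 0 on the CR1 clock); the RELAPSE -> DEATH_RELAPSE clock
# is reset at relapse (semi-Markov; indistinguishable from clock-forward for
# the default exponential family). Each transition k carries a proportional
# hazard lambda0_k * gamma_k * t^(gamma_k - 1) * exp(x' beta_k) with
# gamma_k = 1 for the exponential family. Covariates: genotype-category
# indicators (Category 1 reference), age (years, centered at 49), sex
# (male = 1), log10 white cell count (centered at 10e9/L), and an
# HSCT-at-CR1 indicator (time-fixed, excluded from the post-relapse
# transition by default).

MS_STATES <- c("CR1", "RELAPSE", "DEATH_RELAPSE", "TRM")

default_covariate_spec <- function() {
  list(
    cr1_relapse = MS_COVARIATES,
    cr1_trm = MS_COVARIATES,
    relapse_death = setdiff(MS_COVARIATES, "hsct")
  )
}

# Per-transition (time, event, X) data from a cohort.
ms_transition_data <- function(cohort, covariate_spec = default_covariate_spec(),
                               classification = NULL) {
  cl <- cohort$clinical
  if (is.null(classification)) classification <- classify_cohort(cohort)
  has_cr <- !is.na(cl$cr1_time)
  sub <- cl[has_cr, , drop = FALSE]
  cls <- classification[has_cr, , drop = FALSE]
  hsct <- !is.na(sub$hsct_time)
  X <- build_ms_covariates(sub, cls, hsct)

  exit <- pmin(sub$relapse_time, sub$death_time, sub$last_followup, na.rm = TRUE)
  t_cr1 <- exit - sub$cr1_time
  relapsed <- !is.na(sub$relapse_time)
  trm <- !relapsed & !is.na(sub$death_time)

  rel_sub <- sub[relapsed, , drop = FALSE]
  t_rel <- ifelse(is.na(rel_sub$death_time), rel_sub$last_followup,
                  rel_sub$death_time) - rel_sub$relapse_time
  died_rel <- !is.na(rel_sub$death_time)

  pick <- function(Xfull, covs) Xfull[, covs, drop = FALSE]
  list(
    cr1_relapse = list(time = t_cr1, event = relapsed,
                       X = pick(X, covariate_spec$cr1_relapse),
                       patient_id = sub$patient_id),
    cr1_trm = list(time = t_cr1, event = trm,
                   X = pick(X, covariate_spec$cr1_trm),
                   patient_id = sub$patient_id),
    relapse_death = list(time = t_rel, event = died_rel,
                         X = pick(X[relapsed, , drop = FALSE],
                                  covariate_spec$relapse_death),
                         patient_id = rel_sub$patient_id)
  )
}

# Exponential PH MLE with profiled baseline: given beta the baseline rate is
# events / sum(t * exp(x beta)); Newton iterations on the profile likelihood.
fit_exponential_ph <- function(time, event, X, max_iter = 200, tol = 1e-8) {
  D <- sum(event)
  X <- as.matrix(X)
  keep <- apply(X, 2, function(col) length(unique(col)) > 1)
  dropped <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]
  p <- ncol(X)
  profile_ll <- function(beta) {
    T_ <- sum(time * exp(as.numeric(X %*% beta)))
    sum((X %*% beta)[event]) + D * log(D / T_) - D
  }
  beta <- rep(0, p)
  ll <- if (D > 0) profile_ll(beta) else 0
  iter <- 0
  grad_norm <- 0
  if (p > 0 && D > 0) {
    repeat {
      iter <- iter + 1
      w <- time * exp(as.numeric(X %*% beta))
      T_ <- sum(w)
      m1 <- colSums(X * w) / T_
      g <- colSums(X[event, , drop = FALSE]) - D * m1
      grad_norm <- max(abs(g))
      if (grad_norm < tol || iter > max_iter) break
      M2 <- crossprod(X, X * w) / T_
      H <- D * (M2 - tcrossprod(m1))
      step <- tryCatch(solve(H, g), error = function(e) g / (diag(H) + 1e-12))
      repeat {
        cand <- beta + step
        cand_ll <- profile_ll(cand)
        if (is.finite(cand_ll) && cand_ll >= ll - 1e-12) break
        step <- step / 2
        if (max(abs(step)) < 1e-14) break
      }
      beta <- beta + step
      ll <- cand_ll
    }
  }
  lambda0 <- if (D == 0) 0 else D / sum(time * exp(as.numeric(X %*% beta)))
  full_beta <- stats::setNames(rep(0, length(keep)), names(keep))
  full_beta[keep] <- beta
  list(family = "exponential", lambda0 = lambda0, gamma = 1,
       beta = full_beta, dropped = dropped, loglik = ll,
       iterations = iter, grad_norm = grad_norm,
       zero_events = D == 0, converged = D == 0 || grad_norm < tol)
}

# Weibull PH MLE on (log lambda0, log gamma, beta): Newton with
# step-halving, Hessian from central differences of the analytic gradient.
fit_weibull_ph <- function(time, event, X, max_iter = 200, tol = 1e-6) {
  D <- sum(event)
  X <- as.matrix(X)
  keep <- apply(X, 2, function(col) length(unique(col)) > 1)
  dropped <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]
  p <- ncol(X)
  if (D == 0) {
    full_beta <- stats::setNames(rep(0, length(keep)), names(keep))
    return(list(family = "weibull", lambda0 = 0, gamma = 1, beta = full_beta,
                dropped = dropped, loglik = 0, iterations = 0, grad_norm = 0,
                zero_events = TRUE, converged = TRUE))
  }
  pos <- time > 0
  ll_fun <- function(th) {
    l0 <- exp(th[1]); g <- exp(th[2]); b <- th[-(1:2)]
    eta <- as.numeric(X %*% b)
    cum <- l0 * time[pos]^g * exp(eta[pos])
    sum((log(l0) + log(g) + (g - 1) * log(time[event]) + eta[event])) - sum(cum)
  }
  grad_fun <- function(th) {
    l0 <- exp(th[1]); g <- exp(th[2]); b <- th[-(1:2)]
    eta <- as.numeric(X %*% b)
    cum <- l0 * time[pos]^g * exp(eta[pos])
    lt <- log(time[pos])
    d_l0 <- D - sum(cum)                       # wrt log lambda0
    d_g <- g * (sum(1 / g + log(time[event])) - sum(cum * lt))  # wrt log gamma
    d_b <- colSums(X[event, , drop = FALSE]) - colSums(X[pos, , drop = FALSE] * cum)
    c(d_l0, d_g, d_b)
  }
  th <- c(log(D / sum(time)), 0, rep(0, p))
  ll <- ll_fun(th)
  iter <- 0
  repeat {
    iter <- iter + 1
    g <- grad_fun(th)
    grad_norm <- max(abs(g))
    if (grad_norm < tol || iter > max_iter) break
    # numerical Hessian of the analytic gradient
    k <- length(th)
    H <- matrix(0, k, k)
    h <- 1e-5
    for (j in seq_len(k)) {
      e <- rep(0, k); e[j] <- h
      H[, j] <- (grad_fun(th + e) - grad_fun(th - e)) / (2 * h)
    }
    H <- (H + t(H)) / 2
    step <- tryCatch(solve(-H, g), error = function(e) g / max(abs(diag(H)), 1))
    repeat {
      cand <- th + step
      cand_ll <- ll_fun(cand)
      if (is.finite(cand_ll) && cand_ll >= ll - 1e-12) break
      step <- step / 2
      if (max(abs(step)) < 1e-14) break
    }
    th <- th + step
    ll <- cand_ll
  }
  if (iter > max_iter && grad_norm >= tol) {
    stop("Weibull transition fit did not converge after ", max_iter,
         " iterations (gradient norm ", signif(grad_norm, 3), ")",
         call. = FALSE)
  }
  full_beta <- stats::setNames(rep(0, length(keep)), names(keep))
  full_beta[keep] <- th[-(1:2)]
  list(family = "weibull", lambda0 = exp(th[1]), gamma = exp(th[2]),
       beta = full_beta, dropped = dropped, loglik = ll,
       iterations = iter, grad_norm = grad_norm,
       zero_events = FALSE, converged = grad_norm < tol)
}

#' Fit the post-remission multistate model
#'
#' Maximizes, independently for each of the three transitions (CR1 to
#' relapse, CR1 to treatment-related mortality, relapse to death), the
#' cause-specific likelihood in which competing transitions censor. The
#' exponential family profiles the baseline rate (events over
#' rate-weighted exposure); the Weibull family is fitted by Newton with
#' step-halving. Covariates constant in the cohort are dropped from the
#' affected transition (coefficient reported as 0). A transition with zero
#' observed events gets hazard 0 and a `zero_events` flag with a warning.
#'
#' @param cohort an `aml_cohort`; patients enter the model at CR1.
#' @param family `"exponential"` (default) or `"weibull"` baseline hazard.
#' @param covariate_spec named list giving, per transition, the covariate
#'   names to include (subset of `cat2, cat3, cat4, cat5, age_c, male,
#'   log_wcc, hsct`); default includes all, minus `hsct` post-relapse.
#' @return An object of class `aml_multistate`: per-transition parameter
#'   lists (`lambda0`, `gamma`, `beta`, diagnostics) plus the covariate spec.
#' @export
fit_multistate <- function(cohort, family = c("exponential", "weibull"),
                           covariate_spec = default_covariate_spec()) {
  family <- match.arg(family)
  stopifnot(inherits(cohort, "aml_cohort"))
  bad <- setdiff(unlist(covariate_spec), MS_COVARIATES)
  if (length(bad) > 0) {
    stop("unknown covariate(s) in covariate_spec: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  dat <- ms_transition_data(cohort, covariate_spec)
  fits <- lapply(names(dat), function(tr) {
    d <- dat[[tr]]
    fit <- if (family == "exponential") {
      fit_exponential_ph(d$time, d$event, d$X)
    } else {
      fit_weibull_ph(d$time, d$event, d$X)
    }
    if (fit$zero_events) {
      warning("transition ", tr, " has zero observed events; ",
              "its hazard is set to 0", call. = FALSE)
    }
    fit$n <- length(d$time)
    fit$events <- sum(d$event)
    fit
  })
  names(fits) <- names(dat)
  structure(list(family = family, transitions = fits,
                 covariate_spec = covariate_spec),
            class = "aml_multistate")
}

# Rate multiplier exp(x' beta) for one covariate profile.
ms_rate_multiplier <- function(model, transition, x_row) {
  beta <- model$transitions[[transition]]$beta
  if (length(beta) == 0) return(1)
  exp(sum(beta * x_row[names(beta)]))
}

# Covariate row (named numeric over MS_COVARIATES) from a patient profile.
ms_profile_row <- function(covariates, hsct) {
  clin <- data.frame(age = covariates$age, sex = covariates$sex,
                     wcc = covariates$wcc)
  cls <- data.frame(category = covariates$category)
  drop(build_ms_covariates(clin, cls, hsct))
}

# Cumulative hazard of transition k at times t for multiplier m.
ms_cumhaz <- function(fit, t, m) fit$lambda0 * t^fit$gamma * m

# Instantaneous hazard.
ms_haz <- function(fit, t, m) {
  fit$lambda0 * fit$gamma * t^(fit$gamma - 1) * m
}

#' Predict state-occupancy ("sediment plot") curves for one patient
#'
#' Solves the forward equations of the post-remission DAG for a single
#' covariate profile under a treatment strategy. For the exponential family
#' the four occupancies have closed forms; for the Weibull family the
#' absorbing and transient relapse occupancies are computed by adaptive
#' quadrature (absolute tolerance 1e-8). The leukemia-free survival curve is
#' the CR1 occupancy.
#'
#' @param model an [fit_multistate()] object.
#' @param covariates list or one-row data frame with `age` (years), `sex`
#'   (`"male"`/`"female"`), `wcc` (1e9/L) and `category` (1-5).
#' @param strategy `"hsct_cr1"` (HSCT-at-CR1 indicator on) or `"no_hsct"`.
#' @param grid time grid in months from CR1, starting at 0
#'   (default `seq(0, 120, by = 0.5)`).
#' @return An object of class `aml_occupancy`: data frame with columns
#'   `time`, `CR1`, `RELAPSE`, `DEATH_RELAPSE`, `TRM`, with attribute
#'   `strategy`; rows sum to 1.
#' @export
predict_occupancy <- function(model, covariates,
                              strategy = c("hsct_cr1", "no_hsct"),
                              grid = seq(0, 120, by = 0.5)) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(model, "aml_multistate"), grid[1] == 0,
            !is.unsorted(grid))
  x <- ms_profile_row(covariates, hsct = strategy == "hsct_cr1")
  tr <- model$transitions
  m1 <- ms_rate_multiplier(model, "cr1_relapse", x)
  m2 <- ms_rate_multiplier(model, "cr1_trm", x)
  m3 <- ms_rate_multiplier(model, "relapse_death", x)

  if (model$family == "exponential") {
    l1 <- tr$cr1_relapse$lambda0 * m1
    l2 <- tr$cr1_trm$lambda0 * m2
    l3 <- tr$relapse_death$lambda0 * m3
    a <- l1 + l2
    p_cr1 <- exp(-a * grid)
    if (a < 1e-14) {
      p_trm <- p_rel <- p_dr <- rep(0, length(grid))
    } else {
      p_trm <- (l2 / a) * (1 - exp(-a * grid))
      if (abs(a - l3) > 1e-10) {
        p_rel <- l1 * (exp(-l3 * grid) - exp(-a * grid)) / (a - l3)
      } else {
        p_rel <- l1 * grid * exp(-a * grid)
      }
      p_dr <- (l1 / a) * (1 - exp(-a * grid)) - p_rel
    }
  } else {
    H12 <- function(u) ms_cumhaz(tr$cr1_relapse, u, m1) +
      ms_cumhaz(tr$cr1_trm, u, m2)
    S12 <- function(u) exp(-H12(u))
    h1 <- function(u) ms_haz(tr$cr1_relapse, u, m1)
    h2 <- function(u) ms_haz(tr$cr1_trm, u, m2)
    S3 <- function(u) exp(-ms_cumhaz(tr$relapse_death, u, m3))
    quad <- function(f, lower, upper) {
      if (upper <= lower) return(0)
      stats::integrate(f, lower, upper, abs.tol = 1e-10,
                       rel.tol = 1e-10, stop.on.error = TRUE)$value
    }
    p_cr1 <- S12(grid)
    # TRM accumulates; integrate increments between grid points
    inc <- vapply(seq_along(grid)[-1], function(i) {
      quad(function(u) S12(u) * h2(u), grid[i - 1], grid[i])
    }, numeric(1))
    p_trm <- c(0, cumsum(inc))
    p_rel <- vapply(grid, function(t) {
      if (t == 0) return(0)
      quad(function(u) S12(u) * h1(u) * S3(t - u), 0, t)
    }, numeric(1))
    p_dr <- vapply(grid, function(t) {
      if (t == 0) return(0)
      quad(function(u) S12(u) * h1(u) * (1 - S3(t - u)), 0, t)
    }, numeric(1))
  }
  bad <- !is.finite(p_cr1) | !is.finite(p_rel) | !is.finite(p_dr) |
    !is.finite(p_trm)
  if (any(bad)) {
    stop("non-finite occupancy at t = ", grid[which(bad)[1]],
         "; check transition hazards", call. = FALSE)
  }
  out <- data.frame(time = grid, CR1 = p_cr1, RELAPSE = p_rel,
                    DEATH_RELAPSE = p_dr, TRM = p_trm)
  attr(out, "strategy") <- strategy
  class(out) <- c("aml_occupancy", "data.frame")
  out
}

#' Compare HSCT-at-CR1 against no-HSCT at fixed horizons
#'
#' Evaluates [predict_occupancy()] under both strategies and reports the
#' leukemia-free survival probability (CR1 occupancy) at each requested
#' horizon together with the probability of having died in relapse.
#'
#' @param model an [fit_multistate()] object.
#' @param covariates patient profile as in [predict_occupancy()].
#' @param horizons months from CR1 (default 24 and 60, i.e. 2 and 5 years).
#' @return Data frame with columns `horizon`, `strategy`, `p_cr1`
#'   (leukemia-free survival) and `p_death_relapse`.
#' @export
compare_strategies <- function(model, covariates, horizons = c(24, 60)) {
  grid <- sort(unique(c(0, horizons)))
  rows <- lapply(c("hsct_cr1", "no_hsct"), function(s) {
    occ <- predict_occupancy(model, covariates, strategy = s, grid = grid)
    idx <- match(horizons, occ$time)
    data.frame(horizon = horizons, strategy = s,
               p_cr1 = occ$CR1[idx],
               p_death_relapse = occ$DEATH_RELAPSE[idx],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$horizon, out$strategy), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Model-based risk scores for a cohort
#'
#' The risk score used for concordance evaluation: the predicted probability
#' of leaving CR1 (relapse or treatment-related death) by `horizon` months,
#' `1 - P_CR1(horizon)`, evaluated at each patient's own covariates with the
#' HSCT indicator at its observed value. Available in closed form for both
#' baseline families since `P_CR1` only involves cumulative hazards.
#'
#' @param model an [fit_multistate()] object.
#' @param cohort an `aml_cohort`; only patients with CR1 receive scores.
#' @param horizon months from CR1 (default 60).
#' @return Named numeric vector (patient_id -> risk score in `[0, 1]`).
#' @export
ms_risk_score <- function(model, cohort, horizon = 60) {
  stopifnot(inherits(model, "aml_multistate"))
  cl <- cohort$clinical
  cls <- classify_cohort(cohort)
  has_cr <- !is.na(cl$cr1_time)
  sub <- cl[has_cr, , drop = FALSE]
  X <- build_ms_covariates(sub, cls[has_cr, , drop = FALSE],
                           !is.na(sub$hsct_time))
  tr <- model$transitions
  mult <- function(transition) {
    beta <- tr[[transition]]$beta
    if (length(beta) == 0) rep(1, nrow(X))
    else exp(as.numeric(X[, names(beta), drop = FALSE] %*% beta))
  }
  H <- tr$cr1_relapse$lambda0 * horizon^tr$cr1_relapse$gamma * mult("cr1_relapse") +
    tr$cr1_trm$lambda0 * horizon^tr$cr1_trm$gamma * mult("cr1_trm")
  stats::setNames(1 - exp(-H), sub$patient_id)
}

#' @export
print.aml_multistate <- function(x, ...) {
  cat(sprintf("<aml_multistate> %s baseline, transitions:\n", x$family))
  for (tr in names(x$transitions)) {
    f <- x$transitions[[tr]]
    cat(sprintf("  %-14s lambda0 = %.5f, gamma = %.3f, events = %d/%d%s\n",
                tr, f$lambda0, f$gamma, f$events %||% NA, f$n %||% NA,
                if (isTRUE(f$zero_events)) " [zero events]" else ""))
  }
  invisible(x)
}
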