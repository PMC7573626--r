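# Product-limit estimation and the log-rank test, self-contained.
# Tie convention: at equal times, events precede censorings (the risk set at
# an event time includes subjects censored at that time).

#' Kaplan-Meier product-limit estimate
#'
#' @param time numeric vector of follow-up times (months, `>= 0`), or a
#'   record data frame from [derive_endpoints()] (columns `time`, `event`).
#' @param event logical/0-1 event indicators (ignored when `time` is a data
#'   frame).
#' @return An object of class `aml_km`: a data frame of the distinct event
#'   times with columns `time`, `n_risk`, `n_event`, `n_censor`, `surv`
#'   (the step value of S just after `time`), `var_greenwood` and `std_err`
#'   (Greenwood standard error of S). `S(0) = 1` is implicit.
#' @export
km_estimate <- function(time, event = NULL) {
  if (is.data.frame(time)) {
    event <- time$event
    time <- time$time
  }
  if (length(time) == 0) stop("km_estimate requires at least one record",
                              call. = FALSE)
  stopifnot(length(time) == length(event), all(time >= 0))
  event <- as.logical(event)
  ut <- sort(unique(time))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event), numeric(1))
  n_censor <- vapply(ut, function(t) sum(time == t & !event), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  # Greenwood: Var(S) = S^2 * cumsum(d / (n (n - d)))
  gw_term <- ifelse(n_risk > n_event,
                    n_event / (n_risk * (n_risk - n_event)), 0)
  var_g <- surv^2 * cumsum(gw_term)
  out <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                    n_censor = n_censor, surv = surv,
                    var_greenwood = var_g, std_err = sqrt(var_g))
  keep <- n_event > 0 | n_censor > 0
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("aml_km", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param km an `aml_km` object.
#' @param t numeric vector of times.
#' @return `S(t)` as a right-continuous step function with `S(0) = 1`.
#' @export
km_survival_at <- function(km, t) {
  step_eval(km$time, km$surv, t, v0 = 1)
}

#' Log-rank test for two or more groups
#'
#' Standard log-rank statistic with the hypergeometric variance: at each
#' distinct event time the observed minus expected events per group are
#' accumulated along with their covariance, and the chi-square statistic is
#' formed on the first `K - 1` groups.
#'
#' @param time,event follow-up times and event indicators (or a record data
#'   frame as in [km_estimate()] for `time`).
#' @param group group labels, at least two non-empty groups.
#' @return A list of class `aml_logrank`: `statistic`, `df` (groups - 1),
#'   `p_value`, plus per-group `observed` and `expected` counts.
#' @export
logrank_test <- function(time, event = NULL, group = NULL) {
  if (is.data.frame(time)) {
    if (is.null(group)) group <- event
    event <- time$event
    time <- time$time
  }
  stopifnot(length(time) == length(event), length(time) == length(group))
  event <- as.logical(event)
  group <- factor(group)
  K <- nlevels(group)
  if (K < 2) stop("logrank_test requires at least two groups", call. = FALSE)
  ut <- sort(unique(time[event]))
  O <- E <- stats::setNames(numeric(K), levels(group))
  V <- matrix(0, K, K)
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(time == t & event)
    n_g <- vapply(levels(group), function(g) sum(at_risk & group == g),
                  numeric(1))
    d_g <- vapply(levels(group), function(g) sum(time == t & event & group == g),
                  numeric(1))
    e_g <- d * n_g / n
    O <- O + d_g
    E <- E + e_g
    if (n > 1) {
      # multivariate hypergeometric covariance
      mult <- d * (n - d) / (n - 1)
      Vt <- mult * (diag(n_g / n, K) - tcrossprod(n_g / n))
      V <- V + Vt
    }
  }
  u <- (O - E)[-K]
  Vsub <- V[-K, -K, drop = FALSE]
  stat <- if (all(abs(u) < 1e-12)) 0 else {
    as.numeric(t(u) %*% solve(Vsub, u))
  }
  structure(list(statistic = stat, df = K - 1,
                 p_value = stats::pchisq(stat, K - 1, lower.tail = FALSE),
                 observed = O, expected = E),
            class = "aml_logrank")
}

#' @export
print.aml_logrank <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  print(data.frame(observed = x$observed, expected = round(x$expected, 2)))
  invisible(x)
}
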