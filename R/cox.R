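# Cox proportional hazards with Breslow tie-handling, fitted by
# Newton-Raphson with step-halving on the log partial likelihood.

cox_loglik_parts <- function(beta, time, event, X) {
  ord <- order(-time)
  t_s <- time[ord]
  e_s <- event[ord]
  Xs <- X[ord, , drop = FALSE]
  p <- ncol(X)
  eta <- as.numeric(Xs %*% beta)
  r <- exp(eta)
  S0 <- cumsum(r)
  S1 <- apply(Xs * r, 2, cumsum)
  if (p == 1) S1 <- matrix(S1, ncol = 1)
  # risk-set index for each subject: last position sharing its time
  # (descending order => all positions 1..ridx have time >= t)
  ridx <- stats::ave(seq_along(t_s), t_s, FUN = max)
  ev <- which(e_s)
  ll <- sum(eta[ev]) - sum(log(S0[ridx[ev]]))
  mu <- S1[ridx[ev], , drop = FALSE] / S0[ridx[ev]]
  score <- colSums(Xs[ev, , drop = FALSE]) - colSums(mu)
  info <- matrix(0, p, p)
  # S2 via pairwise cumulative sums; p is small
  for (j in seq_len(p)) {
    for (k in j:p) {
      s2 <- cumsum(Xs[, j] * Xs[, k] * r)
      v <- sum(s2[ridx[ev]] / S0[ridx[ev]] - mu[, j] * mu[, k])
      info[j, k] <- info[k, j] <- v
    }
  }
  list(loglik = ll, score = score, info = info)
}

#' Fit a Cox proportional hazards model
#'
#' Maximizes the Breslow-ties partial likelihood by Newton-Raphson with
#' step-halving, declaring convergence when the maximum absolute score
#' component falls below `tol` (default 1e-8) or after `max_iter` iterations.
#' Reports coefficients, hazard ratios, Wald 95% confidence intervals and
#' p-values, a likelihood-ratio p-value for the whole model, and diagnostics
#' (iterations, score norm, a monotone-likelihood/separation flag).
#'
#' @param time,event follow-up times and event indicators, or a record data
#'   frame from [derive_endpoints()] as `time`.
#' @param X numeric covariate matrix (rows aligned with `time`); columns must
#'   be named and non-constant.
#' @param max_iter,tol Newton-Raphson controls.
#' @param conf_level confidence level for Wald intervals (default 0.95).
#' @return An object of class `aml_cox` with elements `coef`, `se`,
#'   `hazard_ratio`, `ci_lower`, `ci_upper`, `wald_p`, `lr_statistic`,
#'   `lr_p`, `loglik`, `loglik_null`, `iterations`, `converged`,
#'   `score_norm`, `separation_flag`, `loglik_trace`.
#' @export
cox_fit <- function(time, event = NULL, X, max_iter = 50, tol = 1e-8,
                    conf_level = 0.95) {
  if (is.data.frame(time)) {
    event <- time$event
    time <- time$time
  }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  event <- as.logical(event)
  stopifnot(length(time) == length(event), nrow(X) == length(time))
  const <- apply(X, 2, function(col) length(unique(col)) == 1)
  if (any(const)) {
    stop("constant covariate(s): ", paste(colnames(X)[const], collapse = ", "),
         call. = FALSE)
  }
  p <- ncol(X)
  if (sum(event) < p) {
    stop("fewer events (", sum(event), ") than covariates (", p, ")",
         call. = FALSE)
  }

  beta <- rep(0, p)
  parts <- cox_loglik_parts(beta, time, event, X)
  loglik_null <- parts$loglik
  trace <- parts$loglik
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    if (max(abs(parts$score)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(parts$info, parts$score),
                     error = function(e) parts$score / (diag(parts$info) + 1e-12))
    halvings <- 0
    repeat {
      cand <- beta + step
      cand_parts <- cox_loglik_parts(cand, time, event, X)
      if (is.finite(cand_parts$loglik) && cand_parts$loglik >= parts$loglik - 1e-12) break
      step <- step / 2
      halvings <- halvings + 1
      if (halvings > 30) break
    }
    beta <- beta + step
    parts <- cand_parts
    trace <- c(trace, parts$loglik)
  }
  if (!converged && max(abs(parts$score)) < tol) converged <- TRUE
  # a coefficient drifting beyond |beta| = 10 (HR > 2e4) signals a monotone
  # partial likelihood: the "converged" score can still vanish in the limit
  separation <- max(abs(beta)) > 10
  if (separation) {
    warning("possible monotone partial likelihood (separation); ",
            "estimates are unreliable", call. = FALSE)
  }

  cov_beta <- tryCatch(solve(parts$info), error = function(e) {
    matrix(NA_real_, p, p)
  })
  se <- sqrt(pmax(diag(cov_beta), 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  wald_z <- beta / se
  lr_stat <- 2 * (parts$loglik - loglik_null)
  structure(list(
    coef = stats::setNames(beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    hazard_ratio = stats::setNames(exp(beta), colnames(X)),
    ci_lower = stats::setNames(exp(beta - z * se), colnames(X)),
    ci_upper = stats::setNames(exp(beta + z * se), colnames(X)),
    wald_p = stats::setNames(2 * stats::pnorm(-abs(wald_z)), colnames(X)),
    lr_statistic = lr_stat,
    lr_p = stats::pchisq(lr_stat, p, lower.tail = FALSE),
    loglik = parts$loglik,
    loglik_null = loglik_null,
    iterations = iter,
    converged = converged,
    score_norm = max(abs(parts$score)),
    separation_flag = separation,
    loglik_trace = trace
  ), class = "aml_cox")
}

#' @export
print.aml_cox <- function(x, ...) {
  tab <- data.frame(
    coef = round(x$coef, 4),
    HR = round(x$hazard_ratio, 3),
    ci_lower = round(x$ci_lower, 3),
    ci_upper = round(x$ci_upper, 3),
    p = signif(x$wald_p, 3)
  )
  cat(sprintf("Cox model (Breslow ties): %d iterations, %s\n",
              x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  print(tab)
  cat(sprintf("Likelihood ratio test: %.3f, p = %.4g\n",
              x$lr_statistic, x$lr_p))
  invisible(x)
}
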