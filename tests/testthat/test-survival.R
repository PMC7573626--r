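test_that("endpoint definitions follow the LFS/EFS/OS arithmetic", {
  cl <- rbind(
    clinical_row("A", cr1_time = 1, relapse_time = 13, death_time = 20,
                 death_context = "death_in_relapse", last_followup = 20),
    clinical_row("B", cr1_time = 1, hsct_time = 5, relapse_time = 13,
                 last_followup = 60),
    clinical_row("C", death_time = 2, death_context = "death_refractory",
                 last_followup = 2)
  )
  co <- new_cohort(cl, empty_mutations())

  rec <- derive_endpoints(co)
  a <- rec[rec$patient_id == "A", ]
  expect_equal(a$time[a$endpoint == "LFS"], 12)
  expect_true(a$event[a$endpoint == "LFS"])
  expect_equal(a$time[a$endpoint == "OS"], 20)
  expect_true(a$event[a$endpoint == "OS"])
  expect_equal(a$time[a$endpoint == "EFS"], 13)

  # no LFS record without CR1; refractory death is an EFS event
  c_rec <- rec[rec$patient_id == "C", ]
  expect_false("LFS" %in% c_rec$endpoint)
  expect_equal(c_rec$time[c_rec$endpoint == "OS"], 2)
  expect_true(c_rec$event[c_rec$endpoint == "OS"])
  expect_true(c_rec$event[c_rec$endpoint == "EFS"])
  expect_equal(c_rec$time[c_rec$endpoint == "EFS"], 2)

  # censoring at HSCT
  rec_h <- derive_endpoints(co, censor_at_hsct = TRUE)
  b <- rec_h[rec_h$patient_id == "B" & rec_h$endpoint == "LFS", ]
  expect_equal(b$time, 4)
  expect_false(b$event)
  expect_true(b$censored_at_hsct)
  # without the flag the same patient relapses at 12 months post-CR
  b0 <- rec[rec$patient_id == "B" & rec$endpoint == "LFS", ]
  expect_equal(b0$time, 12)
  expect_true(b0$event)
})

test_that("never-CR patients without death are EFS events at the assessment time", {
  co <- new_cohort(clinical_row("X", last_followup = 40), empty_mutations())
  rec <- derive_endpoints(co, endpoints = "EFS", assessment_time = 2)
  expect_equal(rec$time, 2)
  expect_true(rec$event)
})

test_that("product-limit estimate matches hand computation and edge cases", {
  # all censored
  km <- km_estimate(c(3, 7, 9), c(FALSE, FALSE, FALSE))
  expect_true(all(km$surv == 1))
  # n = 4, one event
  km <- km_estimate(c(5, 6, 7, 8), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(km_survival_at(km, 5), 0.75)
  # five-subject worked set {1e, 2c, 3e, 4e, 5c}: hand product-limit
  km <- km_estimate(c(1, 2, 3, 4, 5), c(TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(km_survival_at(km, c(1, 3, 4)), c(4/5, 4/5 * 2/3, 4/5 * 2/3 * 1/2))
  expect_equal(km_survival_at(km, 0.5), 1)
  # Greenwood variance, hand accumulation of d / (n (n - d))
  v_hand <- c(
    (4/5)^2 * (1 / (5 * 4)),
    (8/15)^2 * (1 / (5 * 4) + 1 / (3 * 2)),
    (4/15)^2 * (1 / (5 * 4) + 1 / (3 * 2) + 1 / (2 * 1))
  )
  expect_equal(km$var_greenwood[km$n_event > 0], v_hand)
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(41)
  for (i in 1:10) {
    t <- round(rexp(40, 0.1), 2)
    km <- km_estimate(t, rep(TRUE, 40))
    grid <- seq(0, max(t), length.out = 17)
    expect_equal(km_survival_at(km, grid),
                 vapply(grid, function(u) mean(t > u), numeric(1)))
  }
})

test_that("KM agrees with survival::survfit on censored data", {
  skip_if_not_installed("survival")
  set.seed(42)
  t <- round(rexp(200, 0.05), 1)
  e <- runif(200) < 0.7
  km <- km_estimate(t, e)
  sf <- survival::survfit(survival::Surv(t, e) ~ 1)
  s <- summary(sf, times = sort(unique(t)))
  expect_equal(km_survival_at(km, s$time), s$surv, tolerance = 1e-12)
  # Greenwood standard errors agree at event times while S > 0
  ev <- km$n_event > 0 & km$surv > 0
  s_ev <- summary(sf, times = km$time[ev])
  expect_equal(km$std_err[ev], s_ev$std.err, tolerance = 1e-10)
})

test_that("log-rank matches a hand hypergeometric computation and survdiff", {
  # two identical groups
  t <- c(2, 4, 6, 8)
  e <- c(TRUE, TRUE, FALSE, TRUE)
  lr <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 4))
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p_value, 1)

  # six-subject worked set, hand O-E / V accumulation over 2x2 risk tables
  time <- c(1, 3, 5, 2, 4, 6)
  event <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  grp <- rep(c("g1", "g2"), each = 3)
  hand <- local({
    U <- 0; V <- 0
    for (tt in sort(unique(time[event]))) {
      at <- time >= tt
      n <- sum(at); n1 <- sum(at & grp == "g1")
      d <- sum(time == tt & event)
      d1 <- sum(time == tt & event & grp == "g1")
      U <- U + d1 - d * n1 / n
      if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    c(stat = U^2 / V, U = U, V = V)
  })
  lr <- logrank_test(time, event, grp)
  expect_equal(lr$statistic, unname(hand["stat"]))
  expect_equal(unname(lr$observed["g1"] - lr$expected["g1"]),
               unname(hand["U"]))

  skip_if_not_installed("survival")
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  expect_equal(lr$statistic, sd$chisq, tolerance = 1e-12)

  # three groups: df = 2, invariant under relabeling, matches survdiff
  set.seed(43)
  t3 <- round(rexp(90, 0.08), 1)
  e3 <- runif(90) < 0.8
  g3 <- sample(c("x", "y", "z"), 90, replace = TRUE)
  lr3 <- logrank_test(t3, e3, g3)
  expect_equal(lr3$df, 2)
  relab <- c(x = "q", y = "r", z = "p")[g3]
  expect_equal(logrank_test(t3, e3, relab)$statistic, lr3$statistic,
               tolerance = 1e-10)
  sd3 <- survival::survdiff(survival::Surv(t3, e3) ~ g3)
  expect_equal(lr3$statistic, sd3$chisq, tolerance = 1e-10)
})

test_that("Cox partial likelihood matches a brute-force risk-set product", {
  # five subjects with a tie; Breslow ties
  time <- c(2, 2, 4, 5, 7)
  event <- c(TRUE, TRUE, TRUE, FALSE, TRUE)
  x <- c(1, 0, 1, 0, 0)
  brute <- function(beta) {
    ll <- 0
    for (i in which(event)) {
      rs <- time >= time[i]
      ll <- ll + x[i] * beta - log(sum(exp(x[rs] * beta)))
    }
    ll
  }
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
  for (beta in seq(-2, 2, by = 0.25)) {
    expect_equal(
      cnamlrisk:::cox_loglik_parts(beta, time, event, X)$loglik,
      brute(beta), tolerance = 1e-12)
  }
  fit <- cox_fit(time, event, X)
  expect_true(fit$converged)
  expect_lt(fit$score_norm, 1e-6)
  # the fitted beta beats every grid point
  expect_true(all(fit$loglik >= sapply(seq(-2, 2, 0.25), brute) - 1e-10))
  expect_true(all(diff(fit$loglik_trace) >= -1e-12))
})

test_that("Cox estimates agree with survival::coxph under Breslow ties", {
  skip_if_not_installed("survival")
  set.seed(44)
  n <- 300
  X <- cbind(a = rbinom(n, 1, 0.4), b = rnorm(n))
  t <- round(rexp(n, 0.05 * exp(0.6 * X[, "a"] - 0.3 * X[, "b"])), 1)
  e <- runif(n) < 0.75
  fit <- cox_fit(t, e, X)
  ref <- survival::coxph(survival::Surv(t, e) ~ X, ties = "breslow")
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
})

test_that("Cox recovers a null and a twofold hazard ratio", {
  set.seed(45)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  t_null <- rexp(n, 0.05)
  fit0 <- cox_fit(pmin(t_null, 60), t_null <= 60,
                  matrix(x, ncol = 1, dimnames = list(NULL, "x")))
  expect_lt(abs(fit0$coef), 0.1)
  expect_true(fit0$ci_lower < 1 && fit0$ci_upper > 1)

  t2 <- rexp(n, 0.05 * exp(log(2) * x))
  fit2 <- cox_fit(pmin(t2, 60), t2 <= 60,
                  matrix(x, ncol = 1, dimnames = list(NULL, "x")))
  expect_lt(abs(fit2$coef - log(2)), 0.1)
})

test_that("Cox parameter recovery: bias and coverage over repeated cohorts", {
  set.seed(46)
  n <- 500
  betas <- numeric(200)
  covered <- logical(200)
  for (r in 1:200) {
    x <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.04 * exp(log(2) * x))
    cens <- runif(n, 10, 80)
    fit <- cox_fit(pmin(t, cens), t <= cens,
                   matrix(x, ncol = 1, dimnames = list(NULL, "x")))
    betas[r] <- fit$coef
    covered[r] <- fit$ci_lower <= 2 && 2 <= fit$ci_upper
  }
  expect_lt(abs(mean(betas) - log(2)), 0.02)
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})

test_that("degenerate Cox inputs are rejected or flagged", {
  expect_error(cox_fit(c(1, 2, 3), c(TRUE, TRUE, FALSE),
                       matrix(1, 3, 1, dimnames = list(NULL, "k"))),
               "constant covariate")
  expect_error(cox_fit(c(1, 2, 3), c(TRUE, FALSE, FALSE),
                       cbind(a = c(1, 0, 1), b = c(0, 1, 1))),
               "fewer events")
  # perfect separation: the lone covariate perfectly orders events
  t <- c(1, 2, 3, 4, 10, 11, 12, 13)
  e <- rep(TRUE, 8)
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_warning(
    fit <- cox_fit(t, e, matrix(x, ncol = 1, dimnames = list(NULL, "x"))),
    "separation")
  expect_true(fit$separation_flag)
})
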