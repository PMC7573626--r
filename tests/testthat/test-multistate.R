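test_that("no-covariate exponential fit equals events over person-time", {
  cfg <- quick_config(
    1000, seed = 51,
    transition_hazards = c(cr1_relapse = 0.02, cr1_trm = 0.005,
                           relapse_death = 0.06),
    covariate_effects = list(),
    cr_probability = c(intercept = 50), induction_prob = 1,
    hsct_policy = c(favorable = 0, intermediate = 0, adverse = 0)
  )
  co <- generate_cohort(cfg)
  fit <- fit_multistate(co, covariate_spec = list(
    cr1_relapse = character(0), cr1_trm = character(0),
    relapse_death = character(0)))
  cl <- co$clinical
  exit <- pmin(cl$relapse_time, cl$death_time, cl$last_followup, na.rm = TRUE)
  exposure <- sum(exit - cl$cr1_time)
  relapses <- sum(!is.na(cl$relapse_time))
  expect_equal(fit$transitions$cr1_relapse$lambda0, relapses / exposure,
               tolerance = 1e-12)
  expect_equal(fit$transitions$cr1_relapse$lambda0, 0.02, tolerance = 0.1)
  expect_equal(fit$transitions$cr1_trm$lambda0, 0.005, tolerance = 0.2)
})

test_that("exponential covariate fits match the Poisson-GLM oracle", {
  co <- generate_cohort(quick_config(800, seed = 52, keep_cooccurrence = TRUE,
                                     hsct_delay_months = 0))
  fit <- fit_multistate(co)
  dat <- cnamlrisk:::ms_transition_data(co)
  for (tr in c("cr1_relapse", "cr1_trm")) {
    d <- dat[[tr]]
    keep <- apply(d$X, 2, function(col) length(unique(col)) > 1)
    glm_fit <- stats::glm(d$event ~ d$X[, keep] + offset(log(d$time)),
                          family = stats::poisson())
    beta_hat <- fit$transitions[[tr]]$beta[keep]
    expect_equal(unname(beta_hat), unname(coef(glm_fit)[-1]), tolerance = 1e-5)
    expect_equal(log(fit$transitions[[tr]]$lambda0),
                 unname(coef(glm_fit)[1]), tolerance = 1e-5)
  }
})

test_that("the HSCT effect on relapse is recovered from generated cohorts", {
  est <- vapply(1:4, function(seed) {
    cfg <- quick_config(
      2000, seed = seed,
      covariate_effects = list(cr1_relapse = c(hsct = -0.7)),
      hsct_delay_months = 0,
      hsct_policy = c(favorable = 0.5, intermediate = 0.5, adverse = 0.5)
    )
    co <- generate_cohort(cfg)
    fit <- fit_multistate(co, covariate_spec = list(
      cr1_relapse = "hsct", cr1_trm = "hsct", relapse_death = character(0)))
    fit$transitions$cr1_relapse$beta[["hsct"]]
  }, numeric(1))
  expect_lt(abs(mean(est) - (-0.7)), 0.15)
})

test_that("a transition without events gets hazard zero and a flag", {
  cfg <- quick_config(
    300, seed = 54,
    transition_hazards = c(cr1_relapse = 0, cr1_trm = 0.004,
                           relapse_death = 0.05),
    cr_probability = c(intercept = 50), induction_prob = 1
  )
  co <- generate_cohort(cfg)
  expect_warning(
    expect_warning(fit <- fit_multistate(co), "cr1_relapse"),
    "relapse_death")
  expect_equal(fit$transitions$cr1_relapse$lambda0, 0)
  expect_true(fit$transitions$cr1_relapse$zero_events)
  occ <- predict_occupancy(fit, list(age = 40, sex = "male", wcc = 10,
                                     category = 2), "no_hsct")
  expect_true(all(occ$RELAPSE == 0))
})

test_that("null-hazard models occupy CR1 forever", {
  m <- make_ms_model(0, 0, 0)
  occ <- predict_occupancy(m, random_profile(), "no_hsct",
                           grid = seq(0, 60, 1))
  expect_true(all(occ$CR1 == 1))
  expect_true(all(occ$RELAPSE == 0 & occ$TRM == 0 & occ$DEATH_RELAPSE == 0))
})

test_that("exponential occupancies match the competing-risk closed forms", {
  set.seed(55)
  grid <- seq(0, 120, by = 0.5)
  for (i in 1:25) {
    l <- runif(3, 0.001, 0.08)
    m <- make_ms_model(l[1], l[2], l[3])
    occ <- predict_occupancy(m, random_profile(), "no_hsct", grid = grid)
    a <- l[1] + l[2]
    expect_equal(occ$CR1, exp(-a * grid), tolerance = 1e-12)
    expect_equal(occ$TRM, l[2] / a * (1 - exp(-a * grid)), tolerance = 1e-12)
    expect_equal(occ$RELAPSE,
                 l[1] * (exp(-l[3] * grid) - exp(-a * grid)) / (a - l[3]),
                 tolerance = 1e-10)
    expect_true(all(abs(rowSums(occ[, -1]) - 1) < 1e-8))
  }
})

test_that("quadrature and closed-form routes agree on gamma = 1 hazards", {
  set.seed(56)
  for (i in 1:5) {
    l <- runif(3, 0.002, 0.05)
    beta1 <- c(age_c = 0.02, cat5 = 0.8)
    exp_model <- make_ms_model(l[1], l[2], l[3], beta1 = beta1)
    wei_model <- make_ms_model(l[1], l[2], l[3], beta1 = beta1,
                               family = "weibull")
    prof <- random_profile()
    grid <- seq(0, 96, by = 4)
    occ_e <- predict_occupancy(exp_model, prof, "no_hsct", grid = grid)
    occ_w <- predict_occupancy(wei_model, prof, "no_hsct", grid = grid)
    for (s in c("CR1", "RELAPSE", "DEATH_RELAPSE", "TRM")) {
      expect_lt(max(abs(occ_e[[s]] - occ_w[[s]])), 1e-6)
    }
  }
})

test_that("occupancy curves conserve probability and are monotone", {
  set.seed(57)
  grid <- seq(0, 120, by = 2)
  for (i in 1:100) {
    l <- runif(3, 1e-4, 0.1)
    m <- make_ms_model(l[1], l[2], l[3],
                       beta1 = c(age_c = rnorm(1, 0, 0.02),
                                 log_wcc = rnorm(1, 0, 0.3),
                                 hsct = rnorm(1, 0, 0.5)),
                       beta2 = c(age_c = rnorm(1, 0, 0.02)),
                       beta3 = c(cat5 = rnorm(1, 0, 0.4)))
    occ <- predict_occupancy(
      m, random_profile(),
      strategy = sample(c("hsct_cr1", "no_hsct"), 1), grid = grid)
    expect_true(all(abs(rowSums(occ[, -1]) - 1) < 1e-8))
    expect_true(all(diff(occ$CR1) <= 1e-12))
    expect_true(all(diff(occ$TRM) >= -1e-12))
    expect_true(all(diff(occ$DEATH_RELAPSE) >= -1e-12))
    expect_equal(occ$CR1[1], 1)
  }
})

test_that("strategy comparison responds to the HSCT coefficient as expected", {
  prof <- list(age = 30, sex = "female", wcc = 10, category = 1)
  null_m <- make_ms_model(0.02, 0.004, 0.05,
                          beta1 = c(hsct = 0), beta2 = c(hsct = 0))
  tab <- compare_strategies(null_m, prof)
  wide <- split(tab, tab$strategy)
  expect_equal(wide$hsct_cr1$p_cr1, wide$no_hsct$p_cr1)

  prot <- make_ms_model(0.02, 0.004, 0.05, beta1 = c(hsct = -0.7))
  tab2 <- compare_strategies(prot, prof, horizons = c(12, 24, 60))
  w2 <- split(tab2, tab2$strategy)
  expect_true(all(w2$hsct_cr1$p_cr1 > w2$no_hsct$p_cr1))
  # direct closed-form check of the no-HSCT column
  expect_equal(w2$no_hsct$p_cr1, exp(-(0.02 + 0.004) * c(12, 24, 60)),
               tolerance = 1e-12)
  expect_equal(w2$hsct_cr1$p_cr1,
               exp(-(0.02 * exp(-0.7) + 0.004) * c(12, 24, 60)),
               tolerance = 1e-12)
})

test_that("Weibull fits recover shape one on exponential data and match survreg", {
  cfg <- quick_config(
    1500, seed = 58,
    transition_hazards = c(cr1_relapse = 0.03, cr1_trm = 0.002,
                           relapse_death = 0.05),
    covariate_effects = list(cr1_relapse = c(male = 0.5)),
    cr_probability = c(intercept = 50), induction_prob = 1,
    hsct_policy = c(favorable = 0, intermediate = 0, adverse = 0)
  )
  co <- generate_cohort(cfg)
  fit <- fit_multistate(co, family = "weibull", covariate_spec = list(
    cr1_relapse = "male", cr1_trm = character(0),
    relapse_death = character(0)))
  tr <- fit$transitions$cr1_relapse
  expect_lt(abs(tr$gamma - 1), 0.08)
  expect_lt(abs(tr$beta[["male"]] - 0.5), 0.15)

  skip_if_not_installed("survival")
  dat <- cnamlrisk:::ms_transition_data(co)$cr1_relapse
  keep <- dat$time > 0
  sr <- survival::survreg(
    survival::Surv(dat$time[keep], dat$event[keep]) ~ dat$X[keep, "male"],
    dist = "weibull")
  gamma_ref <- 1 / sr$scale
  lambda_ref <- exp(-coef(sr)[1] / sr$scale)
  beta_ref <- -coef(sr)[2] / sr$scale
  expect_equal(tr$gamma, gamma_ref, tolerance = 1e-3)
  expect_equal(tr$lambda0, unname(lambda_ref), tolerance = 1e-3)
  expect_equal(tr$beta[["male"]], unname(beta_ref), tolerance = 1e-3)
})

test_that("model-based risk scores equal one minus the closed-form CR1 occupancy", {
  co <- generate_cohort(quick_config(200, seed = 59, keep_cooccurrence = TRUE))
  fit <- fit_multistate(co)
  sc <- ms_risk_score(fit, co, horizon = 60)
  cl <- co$clinical
  has_cr <- !is.na(cl$cr1_time)
  expect_equal(length(sc), sum(has_cr))
  expect_true(all(sc >= 0 & sc <= 1))
  # cross-check one patient against predict_occupancy
  pid <- names(sc)[1]
  i <- match(pid, cl$patient_id)
  cls <- classify_cohort(co)
  occ <- predict_occupancy(
    fit,
    list(age = cl$age[i], sex = cl$sex[i], wcc = cl$wcc[i],
         category = cls$category[i]),
    strategy = if (!is.na(cl$hsct_time[i])) "hsct_cr1" else "no_hsct",
    grid = c(0, 60))
  expect_equal(unname(sc[pid]), 1 - occ$CR1[2], tolerance = 1e-12)
})
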