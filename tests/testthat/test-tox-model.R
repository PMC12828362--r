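test_that("intercept-only fit to one cohort matches the closed form", {
  co <- make_cohorts(n = 10, events = 3, dose = 80)
  fit <- fit_logistic(co, covariates = character(0))
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)[["intercept"]]), qlogis(0.3),
               tolerance = 1e-7)
  expect_equal(fit$logLik, 3 * log(0.3) + 7 * log(0.7), tolerance = 1e-10)
})

test_that("MLE matches the brute-force likelihood grid search", {
  # 6-unit toy set mixing Bernoulli patients and binomial cohorts
  p <- make_patients(dose = c(40, 95, 150), event = c(0, 0, 1))
  co <- make_cohorts(n = c(8, 12, 5), events = c(1, 4, 1),
                     dose = c(60, 110, 85))
  fit <- fit_logistic(list(p, co), covariates = "dose")
  units <- list(dose = c(40, 95, 150, 60, 110, 85),
                n = c(1, 1, 1, 8, 12, 5), y = c(0, 0, 1, 1, 4, 1))
  oracle <- grid_search_mle(units$dose, units$n, units$y)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)[["intercept"]]), unname(oracle[["intercept"]]),
               tolerance = 2e-3)
  expect_equal(unname(coef(fit)[["dose"]]), unname(oracle[["dose"]]),
               tolerance = 2e-3)
  expect_gte(fit$logLik, oracle[["logLik"]] - 1e-6)
})

test_that("fit agrees with glm on both granularities", {
  set.seed(11)
  dose <- runif(300, 10, 200)
  chemo <- rbinom(300, 1, 0.4)
  ev <- rbinom(300, 1, plogis(-6 + 0.04 * dose + 1.5 * chemo))
  if (sum(ev) == 0) ev[1] <- 1
  p <- make_patients(dose, ev, chemo = chemo)
  fit <- fit_logistic(p, c("dose", "chemo"))
  ref <- glm(ev ~ dose + chemo, family = binomial)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(diag(vcov(fit))), unname(diag(vcov(ref))),
               tolerance = 1e-4)

  co <- make_cohorts(n = c(30, 40, 25, 20), events = c(2, 9, 12, 3),
                     dose = c(50, 90, 130, 80), chemo = c(0, 0.5, 1, 1))
  fitc <- fit_logistic(co, c("dose", "chemo"))
  refc <- glm(cbind(events, n - events) ~ cdmax_rep + chemo_fraction,
              family = binomial, data = co)
  expect_equal(unname(coef(fitc)), unname(coef(refc)), tolerance = 1e-6)
})

test_that("a cohort is likelihood-equivalent to its expanded patients", {
  co <- make_cohorts(n = c(20, 15), events = c(3, 6), dose = c(70, 120),
                     chemo = c(0, 1))
  p <- make_patients(dose = rep(co$cdmax_rep, co$n),
                     event = unlist(mapply(function(n, e)
                       c(rep(1, e), rep(0, n - e)), co$n, co$events)),
                     chemo = rep(co$chemo_fraction, co$n),
                     study = rep(co$study_id, co$n))
  f1 <- fit_logistic(co, c("dose", "chemo"))
  f2 <- fit_logistic(p, c("dose", "chemo"))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-10)
  expect_equal(vcov(f1), vcov(f2), tolerance = 1e-8)
})

test_that("shifting all doses by c reparameterises only the intercept", {
  co <- make_cohorts(n = c(30, 40, 25, 50), events = c(2, 9, 12, 5),
                     dose = c(50, 90, 130, 70))
  f0 <- fit_logistic(co, "dose")
  co2 <- co
  co2$cdmax_rep <- co2$cdmax_rep + 25
  f1 <- fit_logistic(co2, "dose")
  bd <- coef(f0)[["dose"]]
  expect_equal(coef(f1)[["dose"]], bd, tolerance = 1e-7)
  expect_equal(coef(f1)[["intercept"]],
               coef(f0)[["intercept"]] - 25 * bd, tolerance = 1e-6)
})

test_that("complete separation is flagged, not silently returned", {
  p <- make_patients(dose = c(10, 20, 30, 150, 160, 170),
                     event = c(0, 0, 0, 1, 1, 1))
  fit <- fit_logistic(p, "dose")
  expect_false(fit$converged)
  expect_match(fit$diagnostic, "separation|iterations")
  expect_error(wald_p(fit, "dose"), "converge")
})

test_that("degenerate outcomes and missing covariates are handled", {
  expect_error(fit_logistic(make_patients(dose = c(10, 20), event = c(0, 0)),
                            "dose"), "at least one event")
  expect_error(fit_logistic(make_patients(dose = c(10, 20), event = c(1, 1)),
                            "dose"), "at least one event")
  p <- make_patients(dose = c(30, 60, 90, 120), event = c(0, 0, 1, 1),
                     chemo = c(NA, 0, 1, NA))
  fit <- fit_logistic(p, c("dose", "chemo"))
  expect_equal(fit$n_dropped, 2)
  expect_equal(fit$n_units, 2)
})

test_that("Wald p-values follow the normal reference", {
  m <- tox_model(c(intercept = -5, dose = 0),
                 vcov = diag(c(1, 0.01)))
  expect_equal(wald_p(m, "dose"), 1)
  m2 <- tox_model(c(intercept = -5, dose = 1.959964 * 0.1),
                  vcov = diag(c(1, 0.01)))
  expect_equal(wald_p(m2, "dose"), 0.05, tolerance = 1e-6)
  expect_error(wald_p(m2, "chemo"), "not in model")
})

test_that("univariable screen selects real effects and gates nulls", {
  # intervals share one distribution across studies so the null predictor
  # is not confounded by between-study clustering
  d <- simulation_design(n_studies = 12, study_sizes = rep(80, 12),
                         true_beta = c(intercept = -5, dose = 0.04,
                                       chemo = 0),
                         study_intervals = rep(15.5, 12),
                         seed = 21)
  p <- simulate_patients(d)
  sc <- screen_univariable(p, candidates = c("dose", "interval"), gate = 0.2)
  expect_true("dose" %in% sc$selected)
  expect_false("interval" %in% sc$selected)
  # a gate of 1 admits every fittable candidate
  sc_all <- screen_univariable(p, candidates = c("dose", "interval"),
                               gate = 1)
  expect_setequal(sc_all$selected, c("dose", "interval"))
  # a failing candidate is reported, not fatal
  p$chemo <- NA_real_
  sc_err <- screen_univariable(p, candidates = c("dose", "chemo"))
  expect_true("dose" %in% sc_err$selected)
  expect_false(is.na(sc_err$table$error[sc_err$table$candidate == "chemo"]))
})

test_that("LOOCV fold scores match hand computation on two cohorts", {
  co <- make_cohorts(n = c(10, 10), events = c(3, 5), dose = c(80, 80))
  cv <- loocv_by_cohort(co, list(intercept = character(0)))
  # training on the other cohort gives p = its event rate; the held-out
  # score is that cohort's binomial NLL kernel at the training rate
  nll <- function(e, n, p) -(e * log(p) + (n - e) * log(1 - p))
  expect_equal(unname(cv$folds[, 1]),
               c(nll(3, 10, 0.5), nll(5, 10, 0.3)), tolerance = 1e-7)
  expect_equal(cv$summary$total_nll, sum(cv$folds[, 1]), tolerance = 1e-10)
  expect_error(loocv_by_cohort(co[1, ], list("dose")), "at least 2")
})

test_that("LOOCV prefers the generating model when chemo matters", {
  d <- simulation_design(n_studies = 8, study_sizes = rep(60, 8), seed = 5)
  p <- simulate_patients(d)
  cv <- loocv_by_cohort(p, list(dose = "dose",
                                dose_chemo = c("dose", "chemo")))
  expect_equal(cv$summary$spec[1], "dose_chemo")
  expect_equal(cv$summary$rank, c(1, 2))
})
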