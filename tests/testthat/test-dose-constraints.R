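test_that("inversion round trip and monotonicity hold", {
  m <- published_oesophageal_model()
  for (cc in c(0, 1)) {
    p <- seq(0.01, 0.5, by = 0.01)
    d <- invert_dose(m, p, chemo = cc)
    expect_equal(unname(predict_prob(m, d, chemo = cc)), p,
                 tolerance = 1e-10)
    expect_true(all(diff(d) > 0))  # increasing in target rate
  }
  # intercept fixed point: target = expit(beta0) inverts to dose 0
  expect_equal(invert_dose(m, plogis(coef(m)[["intercept"]]), chemo = 0), 0,
               tolerance = 1e-10)
  expect_error(invert_dose(m, 1.2), "\\(0, 1\\)")
  expect_error(invert_dose(m, 0), "\\(0, 1\\)")
  m0 <- tox_model(c(intercept = -3, dose = 0))
  expect_error(invert_dose(m0, 0.05), "zero")
})

test_that("chemotherapy shifts the curve by a constant beta_c/beta_d", {
  m <- published_oesophageal_model()
  expect_equal(chemo_dose_shift(m), 2.2065 / 0.0431, tolerance = 1e-12)
  expect_equal(round(chemo_dose_shift(m), 1), 51.2)
  for (p in c(0.02, 0.05, 0.2, 0.4))
    expect_equal(invert_dose(m, p, 0) - invert_dose(m, p, 1),
                 chemo_dose_shift(m), tolerance = 1e-10)
  m_nochemo <- tox_model(c(intercept = -5, dose = 0.05, chemo = 0))
  expect_equal(chemo_dose_shift(m_nochemo), 0)
})

test_that("delta-method interval has the Wald structure", {
  vc <- matrix(c(0.5, -0.004, -0.1,
                 -0.004, 4e-5, 8e-4,
                 -0.1, 8e-4, 0.3), 3, 3,
               dimnames = rep(list(c("intercept", "dose", "chemo")), 2))
  m <- tox_model(c(intercept = -7, dose = 0.043, chemo = 2.2), vcov = vc)
  ci <- wald_ci_dose(m, 0.05, chemo = 0)
  d <- invert_dose(m, 0.05, 0)
  expect_lte(ci[["lower"]], d)
  expect_gte(ci[["upper"]], d)
  # width scales with the normal quantile
  ci68 <- wald_ci_dose(m, 0.05, chemo = 0, level = 0.68)
  expect_equal(unname(diff(ci) / diff(ci68)),
               qnorm(0.975) / qnorm(0.84), tolerance = 1e-9)
  # zero covariance collapses to the point estimate
  m0 <- tox_model(c(intercept = -7, dose = 0.043, chemo = 2.2))
  ci0 <- wald_ci_dose(m0, 0.05, chemo = 1)
  expect_equal(unname(ci0), rep(invert_dose(m0, 0.05, 1), 2))
})

test_that("delta-method intervals reach nominal coverage on simulation", {
  # moderate-size check: 150 simulated patient-level datasets
  truth <- c(intercept = -6, dose = 0.045, chemo = 1.8)
  true_d5 <- (qlogis(0.05) - truth[["intercept"]]) / truth[["dose"]]
  d <- simulation_design(n_studies = 15, study_sizes = rep(100, 15),
                         true_beta = truth)
  hits <- 0L
  for (s in 1:150) {
    p <- simulate_patients(d, seed = 1000 + s)
    fit <- fit_logistic(p, c("dose", "chemo"))
    if (!fit$converged) next
    ci <- wald_ci_dose(fit, 0.05, chemo = 0)
    hits <- hits + (ci[["lower"]] <= true_d5 && true_d5 <= ci[["upper"]])
  }
  expect_gte(hits / 150, 0.90)
  expect_lte(hits / 150, 0.99)
})

test_that("block bootstrap is seed-deterministic and audited", {
  fx <- builtin_fixture()
  dc1 <- block_bootstrap_ci(fx$cohorts, B = 100, seed = 42)
  dc2 <- block_bootstrap_ci(fx$cohorts, B = 100, seed = 42)
  expect_identical(as.data.frame(dc1), as.data.frame(dc2))
  dc3 <- block_bootstrap_ci(fx$cohorts, B = 100, seed = 43)
  expect_false(identical(dc1$boot_lower, dc3$boot_lower))
  # ML and Wald columns do not depend on the seed
  expect_identical(dc1$dose_ml, dc3$dose_ml)
  expect_identical(dc1$wald_lower, dc3$wald_lower)
  # replicate accounting
  expect_equal(attr(dc1, "n_replicates_requested"), 100)
  expect_lte(attr(dc1, "n_replicates_converged"), 100)
  expect_equal(attr(dc1, "seed"), 42)
  # interval bounds bracket the converged replicates' percentiles
  expect_true(all(dc1$boot_lower <= dc1$boot_upper))
  expect_error(block_bootstrap_ci(fx$cohorts[1, ], B = 10), "at least 2")
})

test_that("bootstrap intervals are not truncated at zero", {
  # steep chemo effect pushes the 5% with-chemo dose near/below zero
  co <- make_cohorts(n = rep(30, 6), events = c(0, 1, 2, 8, 12, 18),
                     dose = c(20, 50, 80, 110, 140, 170),
                     chemo = c(0, 0, 1, 1, 1, 1))
  dc <- block_bootstrap_ci(co, B = 300, seed = 9,
                           target_rates = 0.05, chemo_levels = 1)
  expect_true(is.finite(dc$boot_lower))
  # negative bounds are reported as such when they occur
  if (dc$boot_lower < 0) expect_lt(dc$boot_lower, 0)
})
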