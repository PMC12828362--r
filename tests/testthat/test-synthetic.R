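test_that("simulation is seed-deterministic and leaves the RNG alone", {
  d <- simulation_design(n_studies = 6, seed = 17)
  p1 <- simulate_patients(d)
  set.seed(123); before <- runif(1)
  set.seed(123)
  p2 <- simulate_patients(d)
  after <- runif(1)
  expect_identical(p1, p2)
  expect_identical(before, after)   # caller RNG stream untouched
  expect_false(identical(p1, simulate_patients(d, seed = 18)))
})

test_that("generated data respect the design's constraints", {
  d <- simulation_design(n_studies = 12, patients_per_study = c(1, 60),
                         dose_range = c(0, 250),
                         interval_range = c(1, 162), seed = 2)
  p <- simulate_patients(d)
  expect_equal(length(unique(p$study_id)), 12)
  sizes <- table(p$study_id)
  expect_true(all(sizes >= 1 & sizes <= 60))
  expect_true(all(p$cdmax >= 0 & p$cdmax <= 250))
  expect_true(all(p$interval_months >= 1 & p$interval_months <= 162))
  expect_true(all(p$chemo %in% c(0, 1)))
  expect_true(all(p$event %in% c(0, 1)))
  expect_error(simulation_design(n_studies = 0), ">= 1")
})

test_that("intercept-only and extreme designs give the expected rates", {
  # beta_dose = beta_chemo = 0: event rate is expit(beta0)
  d <- simulation_design(n_studies = 10, study_sizes = rep(1000, 10),
                         true_beta = c(intercept = qlogis(0.3), dose = 0,
                                       chemo = 0), seed = 8)
  p <- simulate_patients(d)
  expect_lt(abs(mean(p$event) - 0.3), 0.012)
  # essentially -infinity intercept: no events
  d0 <- simulation_design(n_studies = 5, study_sizes = rep(200, 5),
                          true_beta = c(intercept = -50, dose = 0,
                                        chemo = 0), seed = 8)
  expect_equal(sum(simulate_patients(d0)$event), 0)
})

test_that("event rate at the inverted 5% dose is 5%", {
  # fix every dose at the no-chemo 5% iso-risk dose of the published model
  m <- published_oesophageal_model()
  d5 <- invert_dose(m, 0.05, chemo = 0)
  d <- simulation_design(n_studies = 10, study_sizes = rep(2000, 10),
                         study_dose_medians = rep(d5, 10),
                         dose_sdlog_within = 1e-12,
                         study_chemo_probs = rep(0, 10), seed = 31)
  p <- simulate_patients(d)
  expect_equal(unique(round(p$cdmax, 6)), round(d5, 6))
  expect_lt(abs(mean(p$event) - 0.05), 0.006)  # ~4 binomial SEs
})

test_that("aggregation conserves counts and reduces to medians", {
  p <- make_patients(dose = c(10, 30, 50, 70, 90), event = c(0, 0, 1, 0, 1),
                     chemo = c(0, 0, 1, 1, 1), study = "S1")
  co <- aggregate_to_cohorts(p)
  expect_equal(co$n, 5)
  expect_equal(co$events, 2)
  expect_equal(co$cdmax_rep, 50)     # hand-computed median
  expect_equal(co$chemo_fraction, 0.6)
  # single-patient study collapses to that patient
  one <- make_patients(dose = 84.8, event = 1, chemo = 1, study = "solo")
  co1 <- aggregate_to_cohorts(one)
  expect_equal(co1$cdmax_rep, 84.8)
  expect_equal(co1$events, 1)
  # conservation on a simulated multi-study set
  sim <- simulate_patients(simulation_design(n_studies = 9, seed = 4))
  agg <- aggregate_to_cohorts(sim)
  expect_equal(sum(agg$events), sum(sim$event))
  expect_equal(sum(agg$n), nrow(sim))
})

test_that("mixed granularity partitions studies without losing units", {
  d <- simulation_design(n_studies = 7, granularity = "mixed", seed = 12)
  mix <- simulate_dataset(d)
  expect_named(mix, c("patients", "cohorts"))
  expect_equal(length(unique(mix$patients$study_id)) + nrow(mix$cohorts), 7)
  full <- simulate_patients(d)
  expect_equal(nrow(mix$patients) + sum(mix$cohorts$n), nrow(full))
  expect_equal(sum(mix$patients$event) + sum(mix$cohorts$events),
               sum(full$event))
})

test_that("fixture-like preset reproduces the packaged study shapes", {
  d <- design_fixture_like(seed = 6)
  fx <- builtin_fixture()
  p <- simulate_patients(d)
  agg <- aggregate_to_cohorts(p)
  expect_equal(nrow(agg), 21)
  expect_equal(sum(agg$n), 505)
  # simulated study S<i> mirrors the i-th packaged study: same size, and an
  # all-or-none chemo policy is kept exactly
  expect_equal(agg$n, fx$cohorts$n)
  pol <- fx$cohorts$chemo_fraction
  fixed <- !is.na(pol) & pol %in% c(0, 1)
  expect_equal(agg$chemo_fraction[fixed], pol[fixed])
})

test_that("fitting large simulated data recovers the true coefficients", {
  truth <- c(intercept = -7.0065, dose = 0.0431, chemo = 2.2065)
  d <- simulation_design(n_studies = 20, study_sizes = rep(500, 20),
                         true_beta = truth, seed = 77)
  fit <- fit_logistic(simulate_patients(d), c("dose", "chemo"))
  se <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(coef(fit) - truth) < 3 * se))
})

test_that("designs round-trip through YAML and JSON config files", {
  fy <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_studies: 4", "seed: 9",
               "true_beta: {intercept: -6.0, dose: 0.05, chemo: 1.0}"), fy)
  dy <- read_simulation_design(fy)
  expect_equal(dy$n_studies, 4)
  expect_equal(dy$true_beta[["dose"]], 0.05)
  fj <- withr::local_tempfile(fileext = ".json")
  writeLines('{"n_studies": 4, "seed": 9,
               "true_beta": {"intercept": -6.0, "dose": 0.05, "chemo": 1.0}}',
             fj)
  dj <- read_simulation_design(fj)
  expect_equal(dj$true_beta, dy$true_beta)
  expect_identical(simulate_patients(dy), simulate_patients(dj))
  writeLines("bogus_field: 3", fy)
  expect_error(read_simulation_design(fy), "unknown design field")
})
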