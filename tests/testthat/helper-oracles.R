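# Independent oracles and small data builders shared across tests.

# Brute-force maximum-likelihood search for an intercept + dose logistic
# model on a tiny unit set: successively refined grids by direct likelihood
# evaluation only, independent of the package's Newton-Raphson path. With
# doses of order 100 Gy the likelihood has a long intercept/slope ridge, so
# each stage's window must cover the discretisation error of the previous
# slope step times the dose scale, and the final slope step must be far
# below 0.001 for the intercept to be pinned to 3 decimals.
grid_search_mle <- function(dose, n, y,
                            b0_range = c(-10, 10), bd_range = c(-1, 1)) {
  eval_grid <- function(b0s, bds) {
    best <- c(NA, NA, -Inf)
    for (b0 in b0s) {
      eta <- outer(dose, bds) + b0      # units x bd grid
      ll <- colSums(y * plogis(eta, log.p = TRUE) +
                      (n - y) * plogis(-eta, log.p = TRUE))
      j <- which.max(ll)
      if (ll[j] > best[3]) best <- c(b0, bds[j], ll[j])
    }
    best
  }
  b <- eval_grid(seq(b0_range[1], b0_range[2], by = 0.05),
                 seq(bd_range[1], bd_range[2], by = 0.005))
  b <- eval_grid(seq(b[1] - 0.8, b[1] + 0.8, by = 0.005),
                 seq(b[2] - 0.01, b[2] + 0.01, by = 0.0005))
  b <- eval_grid(seq(b[1] - 0.1, b[1] + 0.1, by = 0.001),
                 seq(b[2] - 0.001, b[2] + 0.001, by = 0.00001))
  c(intercept = b[1], dose = b[2], logLik = b[3])
}

# Exact two-sided Fisher p by hypergeometric enumeration over all 2x2
# tables with the observed margins: sum of probabilities of tables no more
# probable than the observed one.
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  N <- r1 + r2
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(a_range, function(a)
    exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(N, c1)), numeric(1))
  p_obs <- probs[a_range == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# tiny patient-level builder
make_patients <- function(dose, event, chemo = 0, study = "S1",
                          interval = 12) {
  k <- length(dose)
  validate_patients(data.frame(
    patient_id = sprintf("p%03d", seq_len(k)),
    study_id = rep_len(study, k), cdmax = dose,
    chemo = rep_len(chemo, k), interval_months = rep_len(interval, k),
    event = event,
    event_timing = ifelse(event == 1, "late", "none"),
    event_grade = ifelse(event == 1, 3, NA_real_)))
}

make_cohorts <- function(n, events, dose, chemo = 0, interval = 12,
                         study = NULL) {
  k <- length(n)
  if (is.null(study)) study <- sprintf("C%02d", seq_len(k))
  validate_cohorts(data.frame(
    study_id = study, n = n, events = events, cdmax_rep = dose,
    chemo_fraction = rep_len(chemo, k),
    interval_rep = rep_len(interval, k), followup_rep = NA_real_))
}
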