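# Model diagnostics: decile calibration, threshold discrimination and
# median-split contingency testing.

#' Decile calibration of a fitted model
#'
#' Sorts the complete-case units by their modelled toxicity risk, cuts them
#' into \code{n_bins} (default 10) equal-count bins — cases are not grouped
#' into pre-specified risk bands — and compares the mean predicted rate with
#' the observed event rate per bin. Agreement is summarised by the Pearson
#' correlation over the (predicted, observed) pairs, tested against zero
#' with the t distribution on \code{n_bins - 2} degrees of freedom.
#'
#' When the unit count is not a multiple of \code{n_bins}, the remainder is
#' spread one extra unit each over the lowest-risk bins. Ties in predicted
#' risk (common for grouped data, where all of a study's patients share one
#' prediction) are broken by a stable sort on (predicted risk, unit id), so
#' binning is deterministic.
#'
#' @param model a converged \code{tox_model}.
#' @param data as in [fit_logistic()]; at least 10 complete-case units.
#' @param n_bins number of risk bins (default 10).
#' @param cohort_chemo see [fit_logistic()].
#' @return an object of class \code{"decile_calibration"}: list with
#'   \code{bins} (bin_index, n_units, n_patients, events, predicted_rate,
#'   observed_rate), \code{pearson_r}, \code{pearson_p}.
#' @examples
#' fx <- builtin_fixture()
#' fit <- fit_logistic(fx$patients, covariates = c("dose", "chemo"))
#' decile_calibration(fit, fx$patients)
#' @export
decile_calibration <- function(model, data, n_bins = 10,
                               cohort_chemo = c("fraction", "dichotomized")) {
  cohort_chemo <- match.arg(cohort_chemo)
  stopifnot(inherits(model, "tox_model"))
  units <- as_unit_table(data, cohort_chemo)
  keep <- rep(TRUE, nrow(units))
  for (v in model$covariates) keep <- keep & !is.na(units[[v]])
  units <- units[keep, , drop = FALSE]
  if (nrow(units) < n_bins)
    stop("need at least ", n_bins, " complete-case units", call. = FALSE)
  pred <- predict_prob(model, dose = units$dose,
                       chemo = ifelse(is.na(units$chemo), 0, units$chemo),
                       interval = ifelse(is.na(units$interval), 0,
                                         units$interval))
  if (length(unique(pred)) == 1L)
    stop("all predicted risks identical; cannot form risk bins",
         call. = FALSE)
  ord <- order(pred, units$unit_id, method = "radix")
  units <- units[ord, , drop = FALSE]
  pred <- pred[ord]
  N <- nrow(units)
  base <- N %/% n_bins
  sizes <- rep(base, n_bins) + c(rep(1, N %% n_bins), rep(0, n_bins - N %% n_bins))
  bin <- rep(seq_len(n_bins), times = sizes)
  bins <- data.frame(
    bin_index = seq_len(n_bins),
    n_units = as.vector(tapply(rep(1, N), bin, sum)),
    n_patients = as.vector(tapply(units$n, bin, sum)),
    events = as.vector(tapply(units$events, bin, sum)),
    predicted_rate = as.vector(tapply(pred * units$n, bin, sum) /
                                 tapply(units$n, bin, sum)),
    observed_rate = as.vector(tapply(units$events, bin, sum) /
                                tapply(units$n, bin, sum))
  )
  ct <- stats::cor.test(bins$predicted_rate, bins$observed_rate,
                        method = "pearson")
  structure(list(bins = bins, pearson_r = unname(ct$estimate),
                 pearson_p = ct$p.value),
            class = "decile_calibration")
}

#' @export
print.decile_calibration <- function(x, ...) {
  cat("Risk-decile calibration\n")
  print(x$bins, row.names = FALSE, digits = 3)
  cat(sprintf("Pearson r = %.3f (p = %.4g)\n", x$pearson_r, x$pearson_p))
  invisible(x)
}

#' @export
plot.decile_calibration <- function(x, ...) {
  lim <- range(0, x$bins$predicted_rate, x$bins$observed_rate)
  graphics::plot(x$bins$predicted_rate, x$bins$observed_rate, xlim = lim,
                 ylim = lim, xlab = "Predicted toxicity rate",
                 ylab = "Observed toxicity rate",
                 main = "Risk-decile calibration", pch = 19, ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Observed toxicity rates above and below a dose cutoff
#'
#' Splits patient-level records at a candidate dose constraint (strictly
#' above versus at-or-below) and reports the observed grade >=3 toxicity
#' rate in each group — the discrimination check for a proposed cutoff. An
#' empty group's rate is reported as \code{NA} (undefined), never as zero.
#'
#' @param patients a \code{patient_records} data frame with non-missing
#'   doses.
#' @param cutoff dose cutoff in Gy EQD2.
#' @return a list with \code{rate_above}, \code{rate_below}, \code{n_above},
#'   \code{n_below}, \code{events_above}, \code{events_below} and
#'   \code{cutoff}, classed \code{"threshold_validation"}.
#' @export
threshold_validation <- function(patients, cutoff) {
  p <- validate_patients(patients)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L)
  above <- p$cdmax > cutoff
  n_above <- sum(above)
  n_below <- sum(!above)
  ev_above <- sum(p$event[above])
  ev_below <- sum(p$event[!above])
  structure(list(
    cutoff = cutoff,
    rate_above = if (n_above > 0) ev_above / n_above else NA_real_,
    rate_below = if (n_below > 0) ev_below / n_below else NA_real_,
    n_above = n_above, n_below = n_below,
    events_above = ev_above, events_below = ev_below
  ), class = "threshold_validation")
}

#' @export
print.threshold_validation <- function(x, ...) {
  fmt <- function(r) if (is.na(r)) "undefined" else sprintf("%.1f%%", 100 * r)
  cat(sprintf("Grade >=3 toxicity above %.1f Gy: %s (%d/%d); at or below: %s (%d/%d)\n",
              x$cutoff, fmt(x$rate_above), x$events_above, x$n_above,
              fmt(x$rate_below), x$events_below, x$n_below))
  invisible(x)
}

#' 2x2 contingency test with automatic test choice
#'
#' Cross-tabulates a binary predictor (e.g. a [median_split()] label)
#' against a binary outcome and tests association with the chi-squared test
#' (no continuity correction) when all expected cell counts are >= 5, and
#' Fisher's exact test otherwise — the conventional switching rule. A table
#' with a zero margin carries no information about association and returns
#' Fisher's p = 1 with a warning.
#'
#' @param predictor_labels binary vector/factor, or a 2x2 count matrix (in
#'   which case \code{outcomes} is omitted).
#' @param outcomes binary vector of the same length.
#' @return an object of class \code{"contingency_result"}: list with
#'   \code{table}, \code{test} ("chi_squared" or "fisher_exact"),
#'   \code{statistic} (NA for Fisher) and \code{p_value}.
#' @examples
#' contingency_test(matrix(c(5, 5, 5, 5), 2))        # independence, p = 1
#' @export
contingency_test <- function(predictor_labels, outcomes = NULL) {
  if (is.matrix(predictor_labels)) {
    tab <- predictor_labels
    if (any(dim(tab) != 2) || any(tab < 0) || any(tab != round(tab)))
      stop("count matrix must be 2x2 with nonnegative integers", call. = FALSE)
  } else {
    if (is.null(outcomes))
      stop("'outcomes' required when labels are a vector", call. = FALSE)
    keep <- !is.na(predictor_labels) & !is.na(outcomes)
    tab <- table(factor(predictor_labels[keep]), factor(outcomes[keep]))
    if (any(dim(tab) > 2))
      stop("both variables must be binary", call. = FALSE)
    tab <- as.matrix(tab)
  }
  if (sum(tab) < 1) stop("empty table", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin: association untestable; returning Fisher p = 1",
            call. = FALSE)
    return(structure(list(table = tab, test = "fisher_exact",
                          statistic = NA_real_, p_value = 1),
                     class = "contingency_result"))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(dim(tab) < 2) || any(expected < 5)) {
    ft <- stats::fisher.test(tab)
    res <- list(table = tab, test = "fisher_exact", statistic = NA_real_,
                p_value = ft$p.value)
  } else {
    ct <- stats::chisq.test(tab, correct = FALSE)
    res <- list(table = tab, test = "chi_squared",
                statistic = unname(ct$statistic), p_value = ct$p.value)
  }
  structure(res, class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("%s test: p = %.4g%s\n",
              if (x$test == "chi_squared") "Chi-squared" else "Fisher's exact",
              x$p_value,
              if (is.na(x$statistic)) "" else sprintf(" (X^2 = %.3f)",
                                                      x$statistic)))
  print(x$table)
  invisible(x)
}

#' Plot fitted dose-response curves with study-level observations
#'
#' Draws the modelled probability of grade >=3 toxicity against cumulative
#' EQD2 dose, one curve per chemotherapy level, overlaid with study-level
#' observed rates (point area proportional to study size).
#'
#' @param model a converged \code{tox_model} with a dose term.
#' @param data optional data (as in [fit_logistic()]) to overlay.
#' @param chemo_levels chemotherapy levels to draw curves for.
#' @param dose_range x-axis dose range in Gy EQD2.
#' @param cohort_chemo see [fit_logistic()].
#' @return invisibly, NULL.
#' @export
plot_dose_response <- function(model, data = NULL, chemo_levels = c(0, 1),
                               dose_range = c(0, 250),
                               cohort_chemo = c("fraction", "dichotomized")) {
  cohort_chemo <- match.arg(cohort_chemo)
  stopifnot(inherits(model, "tox_model"))
  dd <- seq(dose_range[1], dose_range[2], length.out = 200)
  graphics::plot(NA, xlim = dose_range, ylim = c(0, 1),
                 xlab = "Cumulative dose (Gy EQD2)",
                 ylab = "P(grade >=3 toxicity)",
                 main = "Logistic dose-response")
  for (i in seq_along(chemo_levels))
    graphics::lines(dd, predict_prob(model, dd, chemo = chemo_levels[i]),
                    lty = i, col = i)
  if (!is.null(data)) {
    units <- as_unit_table(data, cohort_chemo)
    agg <- stats::aggregate(cbind(n, events) ~ study_id + dose, data = units,
                            FUN = sum)
    graphics::points(agg$dose, agg$events / agg$n, cex = sqrt(agg$n) / 2,
                     pch = 21, bg = "grey")
  }
  graphics::legend("topleft", legend = paste("chemo =", chemo_levels),
                   lty = seq_along(chemo_levels), col = seq_along(chemo_levels),
                   bty = "n")
  invisible(NULL)
}
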