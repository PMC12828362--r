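# Inversion of a fitted logistic dose-response model to iso-risk dose
# constraints, with delta-method ("Wald") and study-level block-bootstrap
# confidence intervals.

.check_invertible <- function(model) {
  stopifnot(inherits(model, "tox_model"))
  if (!"dose" %in% model$covariates)
    stop("model has no dose term; cannot invert", call. = FALSE)
  if (model$coefficients[["dose"]] == 0)
    stop("dose coefficient is zero; no iso-risk dose exists", call. = FALSE)
  if (!isTRUE(model$converged))
    stop("model did not converge (", model$diagnostic, ")", call. = FALSE)
}

#' Iso-risk dose for a target toxicity rate
#'
#' Closed-form inversion of the logistic model: the cumulative dose at which
#' the model predicts toxicity probability \code{target_rate},
#' \deqn{CD = \frac{\mathrm{logit}(p) - \beta_0 - \beta_c CC}{\beta_d}.}
#' This is the model-based dose constraint: e.g. the 5\% iso-risk dose
#' without chemotherapy is the cumulative EQD2 at which a 5\% grade >=3
#' toxicity rate is predicted.
#'
#' @param model a converged \code{tox_model} containing a dose term.
#' @param target_rate target toxicity probability/ies in (0, 1).
#' @param chemo chemotherapy covariate value (0 or 1 for a patient-level
#'   constraint).
#' @return iso-risk dose(s) in Gy EQD2 (may be negative for extreme targets;
#'   never truncated).
#' @examples
#' m <- published_oesophageal_model()
#' invert_dose(m, 0.05, chemo = 0)   # ~94.2 Gy_3
#' invert_dose(m, 0.05, chemo = 1)   # ~43.1 Gy_3
#' @export
invert_dose <- function(model, target_rate, chemo = 0) {
  .check_invertible(model)
  if (any(!is.finite(target_rate)) || any(target_rate <= 0) ||
      any(target_rate >= 1))
    stop("'target_rate' must lie in (0, 1)", call. = FALSE)
  b <- model$coefficients
  bc <- if ("chemo" %in% names(b)) b[["chemo"]] else 0
  (stats::qlogis(target_rate) - b[["intercept"]] - bc * chemo) / b[["dose"]]
}

#' Delta-method confidence interval for an iso-risk dose
#'
#' Propagates the coefficient covariance through the closed-form inversion
#' \eqn{CD(\beta) = (\mathrm{logit}(p) - \beta_0 - \beta_c CC)/\beta_d}:
#' with gradient \eqn{g = (-1, -CD, -CC)/\beta_d} with respect to
#' \eqn{(\beta_0, \beta_d, \beta_c)}, the interval is
#' \eqn{CD \pm z_{1-\alpha/2}\sqrt{g^\top \Sigma g}}.
#'
#' @inheritParams invert_dose
#' @param level confidence level (default 0.95).
#' @return named vector \code{c(lower, upper)} in Gy EQD2.
#' @export
wald_ci_dose <- function(model, target_rate, chemo = 0, level = 0.95) {
  .check_invertible(model)
  stopifnot(length(target_rate) == 1L, level > 0, level < 1)
  dose <- invert_dose(model, target_rate, chemo)
  b <- model$coefficients
  bd <- b[["dose"]]
  g <- stats::setNames(numeric(length(b)), names(b))
  g["intercept"] <- -1 / bd
  g["dose"] <- -dose / bd
  if ("chemo" %in% names(b)) g["chemo"] <- -chemo / bd
  if ("interval" %in% names(b)) g["interval"] <- 0
  vc <- model$vcov
  if (any(!is.finite(vc)))
    stop("model covariance is singular or unavailable", call. = FALSE)
  v <- drop(g %*% vc %*% g)
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(lower = dose - z * sqrt(v), upper = dose + z * sqrt(v))
}

#' Horizontal dose shift due to concurrent chemotherapy
#'
#' The logistic model with a chemotherapy indicator implies two parallel
#' dose-response curves; their constant horizontal offset is
#' \eqn{\beta_c / \beta_d} Gy — the reduction in iso-risk dose caused by
#' concurrent chemotherapy, identical at every target rate.
#'
#' @param model a \code{tox_model} containing dose and chemo terms.
#' @return the shift in Gy EQD2.
#' @examples
#' chemo_dose_shift(published_oesophageal_model())  # ~51.2 Gy
#' @export
chemo_dose_shift <- function(model) {
  stopifnot(inherits(model, "tox_model"))
  if (!all(c("dose", "chemo") %in% model$covariates))
    stop("model must contain dose and chemo terms", call. = FALSE)
  bd <- model$coefficients[["dose"]]
  if (bd == 0) stop("dose coefficient is zero", call. = FALSE)
  model$coefficients[["chemo"]] / bd
}

# run expr with a temporarily seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Iso-risk dose constraints with study-level block-bootstrap intervals
#'
#' Builds the dose-constraint table for a set of target toxicity rates and
#' chemotherapy levels: the maximum-likelihood iso-risk dose and delta-method
#' interval from the model fitted to the observed data, plus a block
#' bootstrap over studies. Whole study cohorts are resampled with
#' replacement (resample size = observed number of studies), chosen over a
#' unit-level bootstrap because it preserves the between-study clustering
#' and hence the overdispersion of multi-study toxicity data. The model is
#' refitted and re-inverted on each of \code{B} resamples and the central
#' \code{level} percentile interval is taken (the lowest and highest 2.5\%
#' of predictions are excluded at the default level). Replicates that fail
#' to converge or separate are dropped from the percentiles and counted;
#' more than 50\% failed replicates is an error. Intervals are never
#' truncated at zero: a negative lower bound is reported as such.
#'
#' @param data as in [fit_logistic()] (>= 2 studies).
#' @param covariates model specification, as in [fit_logistic()]; must
#'   include \code{"dose"}.
#' @param target_rates target toxicity probabilities (default 5, 10, 20,
#'   30\%).
#' @param chemo_levels chemotherapy indicator values to tabulate (default 0
#'   and 1; use 0 alone for a model without a chemo term).
#' @param B number of bootstrap resamples (default 2000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed for the resampling; recorded in the output.
#' @param cohort_chemo see [fit_logistic()].
#' @return a \code{dose_constraints} data frame: one row per (target_rate,
#'   chemo) with \code{dose_ml}, \code{wald_lower}, \code{wald_upper},
#'   \code{boot_lower}, \code{boot_upper}; attributes
#'   \code{n_replicates_requested}, \code{n_replicates_converged},
#'   \code{seed} and \code{model} (the observed-data fit).
#' @examples
#' fx <- builtin_fixture()
#' dc <- block_bootstrap_ci(fx$cohorts, B = 200, seed = 1)
#' dc
#' @export
block_bootstrap_ci <- function(data, covariates = c("dose", "chemo"),
                               target_rates = c(0.05, 0.10, 0.20, 0.30),
                               chemo_levels = c(0, 1), B = 2000,
                               level = 0.95, seed = 1,
                               cohort_chemo = c("fraction", "dichotomized")) {
  cohort_chemo <- match.arg(cohort_chemo)
  if (!"dose" %in% covariates)
    stop("'covariates' must include \"dose\"", call. = FALSE)
  units <- as_unit_table(data, cohort_chemo)
  keep <- rep(TRUE, nrow(units))
  for (v in covariates) keep <- keep & !is.na(units[[v]])
  units <- units[keep, , drop = FALSE]
  studies <- unique(units$study_id)
  n_studies <- length(studies)
  if (n_studies < 2)
    stop("block bootstrap needs at least 2 studies", call. = FALSE)
  fit <- fit_logistic(data, covariates = covariates,
                      cohort_chemo = cohort_chemo)
  by_study <- split(units, units$study_id)[studies]

  grid <- expand.grid(target_rate = target_rates, chemo = chemo_levels,
                      KEEP.OUT.ATTRS = FALSE)
  qt <- stats::qlogis(grid$target_rate)

  boot_doses <- .with_seed(seed, {
    out <- matrix(NA_real_, B, nrow(grid))
    for (b in seq_len(B)) {
      pick <- sample.int(n_studies, n_studies, replace = TRUE)
      du <- do.call(rbind, by_study[pick])
      if (sum(du$events) == 0 || sum(du$n - du$events) == 0) next
      X <- .design_matrix(du, covariates)
      f <- tryCatch(.irls(X, du$n, du$events), error = function(e) NULL)
      if (is.null(f) || !f$converged) next
      beta <- stats::setNames(f$beta, c("intercept", covariates))
      if (beta[["dose"]] == 0) next
      bc <- if ("chemo" %in% covariates) beta[["chemo"]] else 0
      out[b, ] <- (qt - beta[["intercept"]] - bc * grid$chemo) / beta[["dose"]]
    }
    out
  })
  converged <- sum(stats::complete.cases(boot_doses))
  if (converged < B / 2)
    stop(sprintf("block bootstrap failed: only %d of %d replicates converged",
                 converged, B), call. = FALSE)

  alpha <- (1 - level) / 2
  res <- grid
  res$dose_ml <- invert_dose(fit, grid$target_rate, grid$chemo)
  wald <- t(mapply(function(p, cc) wald_ci_dose(fit, p, cc, level),
                   grid$target_rate, grid$chemo))
  res$wald_lower <- wald[, "lower"]
  res$wald_upper <- wald[, "upper"]
  res$boot_lower <- apply(boot_doses, 2, stats::quantile, probs = alpha,
                          na.rm = TRUE, names = FALSE)
  res$boot_upper <- apply(boot_doses, 2, stats::quantile, probs = 1 - alpha,
                          na.rm = TRUE, names = FALSE)
  structure(res,
            n_replicates_requested = B, n_replicates_converged = converged,
            seed = seed, level = level, model = fit,
            class = c("dose_constraints", "data.frame"))
}

#' Maximum-likelihood dose-constraint table (no bootstrap)
#'
#' Tabulates iso-risk doses and delta-method intervals for a fitted model
#' without resampling; see [block_bootstrap_ci()] for the full table with
#' bootstrap intervals.
#'
#' @inheritParams invert_dose
#' @param target_rates target toxicity probabilities.
#' @param chemo_levels chemotherapy indicator values to tabulate.
#' @param level confidence level.
#' @return a data frame with \code{target_rate, chemo, dose_ml, wald_lower,
#'   wald_upper}.
#' @export
dose_constraint_table <- function(model, target_rates = c(0.05, 0.10, 0.20, 0.30),
                                  chemo_levels = c(0, 1), level = 0.95) {
  .check_invertible(model)
  grid <- expand.grid(target_rate = target_rates, chemo = chemo_levels,
                      KEEP.OUT.ATTRS = FALSE)
  grid$dose_ml <- invert_dose(model, grid$target_rate, grid$chemo)
  wald <- t(mapply(function(p, cc) wald_ci_dose(model, p, cc, level),
                   grid$target_rate, grid$chemo))
  grid$wald_lower <- wald[, "lower"]
  grid$wald_upper <- wald[, "upper"]
  grid
}

#' @export
print.dose_constraints <- function(x, ...) {
  cat(sprintf("Iso-risk dose constraints (Gy EQD2); %d/%d bootstrap replicates converged, seed %s\n",
              attr(x, "n_replicates_converged"),
              attr(x, "n_replicates_requested"),
              format(attr(x, "seed"))))
  df <- as.data.frame(x)
  dose_cols <- setdiff(names(df), c("target_rate", "chemo"))
  df[dose_cols] <- lapply(df[dose_cols], round, digits = 1)
  print(df, row.names = FALSE)
  invisible(x)
}
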