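# Maximum-likelihood logistic dose-response fitting on mixed
# Bernoulli/binomial data. The likelihood unit is either one patient
# (event ~ Bernoulli at the patient's own covariates) or one study
# (events ~ Binomial(n) at the study's representative dose and fractional
# chemotherapy rate). The log-likelihood is the kernel (no binomial
# coefficient), so a cohort of n identical patients has literally the same
# log-likelihood as the n patient records.

.COVARIATES <- c("dose", "chemo", "interval")

# Normalise patients / cohorts / a list of both into one unit table with
# columns: unit_id, study_id, n, events, dose, chemo, interval, granularity.
as_unit_table <- function(data, cohort_chemo = c("fraction", "dichotomized")) {
  cohort_chemo <- match.arg(cohort_chemo)
  if (is.data.frame(data)) data <- list(data)
  parts <- lapply(data, function(d) {
    if (inherits(d, "patient_records") ||
        (is.data.frame(d) && "cdmax" %in% names(d))) {
      d <- validate_patients(d)
      data.frame(unit_id = d$patient_id, study_id = d$study_id, n = 1,
                 events = d$event, dose = d$cdmax, chemo = d$chemo,
                 interval = d$interval_months, granularity = "patient",
                 stringsAsFactors = FALSE)
    } else if (inherits(d, "cohort_summaries") ||
               (is.data.frame(d) && "cdmax_rep" %in% names(d))) {
      d <- validate_cohorts(d)
      chemo <- d$chemo_fraction
      if (cohort_chemo == "dichotomized")
        chemo <- as.numeric(chemo >= 0.5)
      data.frame(unit_id = d$study_id, study_id = d$study_id, n = d$n,
                 events = d$events, dose = d$cdmax_rep, chemo = chemo,
                 interval = d$interval_rep, granularity = "cohort",
                 stringsAsFactors = FALSE)
    } else {
      stop("unrecognised data element: expected patient_records or cohort_summaries",
           call. = FALSE)
    }
  })
  units <- do.call(rbind, parts)
  if (is.null(units) || nrow(units) == 0L)
    stop("no data units supplied", call. = FALSE)
  rownames(units) <- NULL
  units
}

# intercept + covariate columns for a unit table
.design_matrix <- function(units, covariates) {
  X <- matrix(1, nrow(units), 1L)
  for (v in covariates) X <- cbind(X, units[[v]])
  colnames(X) <- c("intercept", covariates)
  X
}

# Binomial log-likelihood kernel, numerically stable in eta.
.ll_kernel <- function(eta, n, y) {
  sum(y * stats::plogis(eta, log.p = TRUE) +
        (n - y) * stats::plogis(-eta, log.p = TRUE))
}

# Newton-Raphson / IRLS with step halving. X includes the intercept column.
.irls <- function(X, n, y, tol = 1e-8, max_iter = 100L, beta_max = 50) {
  p <- ncol(X)
  beta <- numeric(p)
  ll <- .ll_kernel(drop(X %*% beta), n, y)
  converged <- FALSE
  diagnostic <- NA_character_
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(X, y - n * mu))
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    if (iter > max_iter) { diagnostic <- "max iterations reached"; break }
    w <- n * mu * (1 - mu)
    H <- crossprod(X * w, X)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) { diagnostic <- "singular information matrix"; break }
    # damped Newton: halve until the likelihood does not decrease
    lam <- 1
    repeat {
      cand <- beta + lam * step
      ll_new <- .ll_kernel(drop(X %*% cand), n, y)
      if (ll_new >= ll - 1e-12 || lam < 1e-10) break
      lam <- lam / 2
    }
    beta <- cand
    ll <- ll_new
    if (max(abs(beta)) > beta_max) { diagnostic <- "separation"; break }
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  # complete separation: the score can underflow below tol while every
  # fitted probability is saturated at 0/1 and the true MLE sits at infinity
  if (converged && ncol(X) > 1 && all(pmin(mu, 1 - mu) < 1e-6)) {
    converged <- FALSE
    diagnostic <- "separation"
  }
  H <- crossprod(X * (n * mu * (1 - mu)), X)
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p, p))
  list(beta = beta, vcov = vc, logLik = .ll_kernel(eta, n, y),
       converged = converged, diagnostic = diagnostic, iterations = iter)
}

.data_hash <- function(units) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(units, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Construct a fitted-model object from known coefficients
#'
#' Builds a \code{tox_model} directly from logit-scale coefficients (and
#' optionally their covariance), e.g. to work with a published model whose
#' coefficient vector is reported but whose raw data are not available.
#'
#' @param coefficients named numeric vector: \code{intercept} plus any of
#'   \code{dose} (per Gy EQD2), \code{chemo}, \code{interval} (per month).
#' @param vcov optional covariance matrix matching \code{coefficients}.
#' @return an object of class \code{"tox_model"}.
#' @examples
#' m <- tox_model(c(intercept = -7.0065, dose = 0.0431, chemo = 2.2065))
#' predict_prob(m, dose = 94.2, chemo = 0)
#' @export
tox_model <- function(coefficients, vcov = NULL) {
  if (is.null(names(coefficients)) || names(coefficients)[1] != "intercept" ||
      !all(names(coefficients)[-1] %in% .COVARIATES))
    stop("'coefficients' must be named: 'intercept' then any of ",
         paste(.COVARIATES, collapse = ", "), call. = FALSE)
  k <- length(coefficients)
  if (is.null(vcov)) vcov <- matrix(0, k, k)
  if (!is.matrix(vcov) || any(dim(vcov) != k))
    stop("'vcov' dimensions must match 'coefficients'", call. = FALSE)
  dimnames(vcov) <- list(names(coefficients), names(coefficients))
  structure(
    list(coefficients = coefficients, vcov = vcov, logLik = NA_real_,
         n_units = NA_integer_, n_patients = NA_integer_,
         n_events = NA_real_, n_dropped = NA_integer_, converged = TRUE,
         diagnostic = NA_character_, covariates = names(coefficients)[-1],
         cohort_chemo = NA_character_, iterations = NA_integer_,
         data_hash = NA_character_),
    class = "tox_model"
  )
}

#' Fit a logistic dose-response model to mixed-granularity data
#'
#' Maximum-likelihood logistic regression of grade >=3 toxicity on cumulative
#' EQD2 dose, concurrent chemotherapy and/or interval, where patient-level
#' records contribute Bernoulli likelihood terms at their own covariates and
#' study-level summaries contribute Binomial(n, events) terms at the study's
#' representative (median) dose and fractional chemotherapy rate. Fitting is
#' damped Newton-Raphson on the exact likelihood (gradient-norm tolerance
#' \code{tol}); the covariance is the inverse observed information.
#'
#' Units missing any requested covariate are dropped (complete-case; the
#' count is recorded in \code{n_dropped} — no imputation). Complete
#' separation is detected as coefficient divergence (any |beta| > 50) and
#' flagged via \code{converged = FALSE} with a diagnostic; coefficients are
#' not silently returned as estimates in that case.
#'
#' @param data a \code{patient_records} data frame, a \code{cohort_summaries}
#'   data frame, or a list mixing both (see [read_patients()],
#'   [read_cohorts()]).
#' @param covariates character subset of \code{c("dose", "chemo",
#'   "interval")}; empty for an intercept-only model.
#' @param cohort_chemo how study-level chemotherapy enters the linear
#'   predictor: as the fraction of patients treated (default) or
#'   dichotomised at 0.5.
#' @param tol convergence tolerance on the max absolute score (default 1e-8).
#' @param max_iter maximum Newton iterations (default 100).
#' @return an object of class \code{"tox_model"}: list with
#'   \code{coefficients} (logit scale; dose per Gy), \code{vcov},
#'   \code{logLik} (kernel, no binomial coefficient), \code{n_units},
#'   \code{n_patients}, \code{n_events}, \code{n_dropped}, \code{converged},
#'   \code{diagnostic}, \code{iterations} and a \code{data_hash} provenance
#'   token.
#' @examples
#' fx <- builtin_fixture()
#' fit <- fit_logistic(fx$cohorts, covariates = c("dose", "chemo"))
#' coef(fit)
#' @export
fit_logistic <- function(data, covariates = c("dose", "chemo"),
                         cohort_chemo = c("fraction", "dichotomized"),
                         tol = 1e-8, max_iter = 100L) {
  cohort_chemo <- match.arg(cohort_chemo)
  covariates <- as.character(covariates)
  if (!all(covariates %in% .COVARIATES))
    stop("covariates must be a subset of: ",
         paste(.COVARIATES, collapse = ", "), call. = FALSE)
  units <- as_unit_table(data, cohort_chemo)
  keep <- rep(TRUE, nrow(units))
  for (v in covariates) keep <- keep & !is.na(units[[v]])
  n_dropped <- sum(!keep)
  units <- units[keep, , drop = FALSE]
  if (nrow(units) == 0L)
    stop("no complete-case units for covariates: ",
         paste(covariates, collapse = ", "), call. = FALSE)
  if (sum(units$events) == 0 || sum(units$n - units$events) == 0)
    stop("need at least one event and one non-event to fit", call. = FALSE)
  X <- .design_matrix(units, covariates)
  fit <- .irls(X, units$n, units$events, tol = tol, max_iter = max_iter)
  beta <- stats::setNames(fit$beta, colnames(X))
  vc <- fit$vcov
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(
    list(coefficients = beta, vcov = vc, logLik = fit$logLik,
         n_units = nrow(units), n_patients = sum(units$n),
         n_events = sum(units$events), n_dropped = n_dropped,
         converged = fit$converged, diagnostic = fit$diagnostic,
         covariates = covariates, cohort_chemo = cohort_chemo,
         iterations = fit$iterations, data_hash = .data_hash(units)),
    class = "tox_model"
  )
}

#' @export
coef.tox_model <- function(object, ...) object$coefficients

#' @export
vcov.tox_model <- function(object, ...) object$vcov

#' @export
logLik.tox_model <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients),
            nobs = object$n_units, class = "logLik")
}

#' @export
print.tox_model <- function(x, ...) {
  cat("Logistic dose-response model (grade >=3 toxicity)\n")
  cat("Covariates:",
      if (length(x$covariates)) paste(x$covariates, collapse = ", ")
      else "(intercept only)", "\n")
  print(round(x$coefficients, 4))
  if (!is.na(x$logLik))
    cat(sprintf("log-likelihood %.3f on %d units (%s patients, %s events; %d dropped)\n",
                x$logLik, x$n_units, x$n_patients, x$n_events, x$n_dropped))
  if (!x$converged)
    cat("WARNING: not converged:", x$diagnostic, "\n")
  invisible(x)
}

#' @export
summary.tox_model <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(estimate = object$coefficients, std_error = se, z = z,
               p_value = 2 * stats::pnorm(-abs(z)))
  structure(list(model = object, coefficients = tab),
            class = "summary.tox_model")
}

#' @export
print.summary.tox_model <- function(x, ...) {
  print(x$model)
  cat("\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' Predicted toxicity probability
#'
#' Evaluates the fitted logistic model
#' \eqn{p = 1 / (1 + \exp(-(\beta_0 + \beta_d CD + \beta_c CC + \ldots)))}
#' at cumulative dose \code{dose} (Gy EQD2) and chemotherapy indicator
#' \code{chemo}.
#'
#' @param model a \code{tox_model}.
#' @param dose cumulative dose(s) in Gy EQD2.
#' @param chemo concurrent-chemotherapy covariate (0/1, or a fraction for
#'   study-level prediction); ignored if the model has no chemo term.
#' @param interval interval in months; ignored if the model has no interval
#'   term.
#' @return vector of probabilities.
#' @export
predict_prob <- function(model, dose, chemo = 0, interval = 0) {
  stopifnot(inherits(model, "tox_model"))
  b <- model$coefficients
  eta <- b[["intercept"]]
  vals <- list(dose = dose, chemo = chemo, interval = interval)
  for (v in model$covariates) eta <- eta + b[[v]] * vals[[v]]
  stats::plogis(eta)
}

#' Wald test for one coefficient
#'
#' Two-sided normal test of coefficient / standard error from the observed
#' information.
#'
#' @param model a converged \code{tox_model}.
#' @param covariate name of the coefficient to test (\code{"dose"},
#'   \code{"chemo"}, \code{"interval"} or \code{"intercept"}).
#' @return two-sided p-value.
#' @export
wald_p <- function(model, covariate) {
  stopifnot(inherits(model, "tox_model"))
  if (!covariate %in% names(model$coefficients))
    stop("covariate '", covariate, "' not in model", call. = FALSE)
  if (!isTRUE(model$converged))
    stop("model did not converge (", model$diagnostic, ")", call. = FALSE)
  se <- sqrt(model$vcov[covariate, covariate])
  2 * stats::pnorm(-abs(model$coefficients[[covariate]] / se))
}

#' Univariable covariate screen
#'
#' Fits one univariable logistic model per candidate predictor and selects
#' those with Wald p below the gate (default 0.2), the inclusion rule for
#' multivariable modelling. Candidates whose fit fails are reported with
#' the error message and not selected, without aborting the screen.
#'
#' @param data as in [fit_logistic()].
#' @param candidates character vector of candidate covariates.
#' @param gate p-value gate for inclusion (default 0.2).
#' @param cohort_chemo see [fit_logistic()].
#' @return a list with \code{table} (candidate, estimate, se, p_value,
#'   selected, error) and \code{selected} (character vector), classed
#'   \code{"univariable_screen"}.
#' @export
screen_univariable <- function(data, candidates = c("dose", "chemo", "interval"),
                               gate = 0.2,
                               cohort_chemo = c("fraction", "dichotomized")) {
  cohort_chemo <- match.arg(cohort_chemo)
  rows <- lapply(candidates, function(v) {
    fit <- tryCatch(fit_logistic(data, covariates = v,
                                 cohort_chemo = cohort_chemo),
                    error = function(e) e)
    if (inherits(fit, "error"))
      return(data.frame(candidate = v, estimate = NA_real_, se = NA_real_,
                        p_value = NA_real_, selected = FALSE,
                        error = conditionMessage(fit),
                        stringsAsFactors = FALSE))
    if (!fit$converged)
      return(data.frame(candidate = v, estimate = NA_real_, se = NA_real_,
                        p_value = NA_real_, selected = FALSE,
                        error = paste("not converged:", fit$diagnostic),
                        stringsAsFactors = FALSE))
    p <- wald_p(fit, v)
    data.frame(candidate = v, estimate = fit$coefficients[[v]],
               se = sqrt(fit$vcov[v, v]), p_value = p,
               selected = p < gate, error = NA_character_,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab, selected = tab$candidate[tab$selected],
                 gate = gate),
            class = "univariable_screen")
}

#' @export
print.univariable_screen <- function(x, ...) {
  cat(sprintf("Univariable screen (Wald p < %g gate)\n", x$gate))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Leave-one-study-out cross-validation
#'
#' Scores candidate model specifications by leave-one-cohort-out
#' cross-validation: for each study, the model is fitted to the remaining
#' studies and the held-out study is scored by its negative log-likelihood
#' under that fit. Fold scores are summed; the lowest total identifies the
#' model that generalises best across studies. Folds where any
#' specification's training fit fails or does not converge are recorded and
#' excluded identically across all specifications, so totals stay
#' comparable.
#'
#' @param data as in [fit_logistic()]; must contain at least 2 studies.
#' @param specs a list of covariate character vectors, one per candidate
#'   specification (e.g. \code{list(dose = "dose", dose_chemo = c("dose",
#'   "chemo"))}).
#' @param cohort_chemo see [fit_logistic()].
#' @return an object of class \code{"loocv_result"}: list with
#'   \code{summary} (spec, total held-out NLL, folds used, rank; ordered
#'   best first), \code{folds} (per-study scores per spec) and
#'   \code{excluded_folds}.
#' @export
loocv_by_cohort <- function(data, specs,
                            cohort_chemo = c("fraction", "dichotomized")) {
  cohort_chemo <- match.arg(cohort_chemo)
  if (is.character(specs)) specs <- list(specs)
  if (is.null(names(specs)) || any(names(specs) == ""))
    names(specs) <- vapply(specs, function(s)
      if (length(s)) paste(s, collapse = "+") else "intercept", character(1))
  units <- as_unit_table(data, cohort_chemo)
  studies <- unique(units$study_id)
  if (length(studies) < 2)
    stop("leave-one-study-out needs at least 2 studies", call. = FALSE)
  score <- matrix(NA_real_, length(studies), length(specs),
                  dimnames = list(studies, names(specs)))
  for (j in seq_along(specs)) {
    cov_j <- specs[[j]]
    for (i in seq_along(studies)) {
      train <- units[units$study_id != studies[i], , drop = FALSE]
      test <- units[units$study_id == studies[i], , drop = FALSE]
      keep_tr <- keep_te <- TRUE
      for (v in cov_j) {
        keep_tr <- keep_tr & !is.na(train[[v]])
        keep_te <- keep_te & !is.na(test[[v]])
      }
      train <- train[keep_tr, , drop = FALSE]
      test <- test[keep_te, , drop = FALSE]
      if (nrow(test) == 0L) next  # fold has no scorable units for this spec
      fit <- tryCatch({
        if (sum(train$events) == 0 || sum(train$n - train$events) == 0)
          stop("degenerate training outcomes")
        .irls(.design_matrix(train, cov_j), train$n, train$events)
      }, error = function(e) NULL)
      if (is.null(fit) || !fit$converged) next
      Xt <- .design_matrix(test, cov_j)
      score[i, j] <- -.ll_kernel(drop(Xt %*% fit$beta), test$n, test$events)
    }
  }
  ok <- stats::complete.cases(score)
  totals <- colSums(score[ok, , drop = FALSE])
  summary <- data.frame(spec = names(specs),
                        covariates = vapply(specs, paste, character(1),
                                            collapse = "+"),
                        total_nll = totals, folds_used = sum(ok),
                        stringsAsFactors = FALSE)
  summary <- summary[order(summary$total_nll), ]
  summary$rank <- seq_len(nrow(summary))
  rownames(summary) <- NULL
  structure(list(summary = summary, folds = score,
                 excluded_folds = studies[!ok], specs = specs),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat("Leave-one-study-out cross-validation (held-out negative log-likelihood;\nlower is better)\n")
  print(x$summary, row.names = FALSE, digits = 5)
  if (length(x$excluded_folds))
    cat("Folds excluded for all specs:",
        paste(x$excluded_folds, collapse = ", "), "\n")
  invisible(x)
}

#' Coefficients of the published multi-study oesophageal model
#'
#' Convenience constructor for the multivariable logistic model of grade >=3
#' oesophageal toxicity reported by the published 21-study thoracic
#' re-irradiation analysis: logit(p) = -7.0065 + 0.0431 CD + 2.2065 CC,
#' with CD the cumulative oesophageal D_max in EQD2 Gy (alpha/beta = 3) and
#' CC the concurrent-chemotherapy indicator. Only the coefficient vector was
#' published, so the covariance is zero and Wald intervals are unavailable
#' for this object.
#'
#' @return a \code{tox_model}.
#' @examples
#' invert_dose(published_oesophageal_model(), 0.05, chemo = 0)  # ~94.2 Gy
#' @export
published_oesophageal_model <- function() {
  tox_model(c(intercept = -7.0065, dose = 0.0431, chemo = 2.2065))
}
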