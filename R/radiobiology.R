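#' Treatment course
#'
#' Describes one course of fractionated radiotherapy as input to EQD2
#' conversion. Exactly two of \code{total_dose}, \code{dose_per_fraction} and
#' \code{n_fractions} determine the third; all three may be given if they are
#' consistent to within rounding tolerance.
#'
#' @param total_dose total physical dose in Gy (>= 0).
#' @param dose_per_fraction dose per fraction in Gy (> 0 when
#'   \code{total_dose} > 0).
#' @param n_fractions positive integer number of fractions.
#' @param timing toxicity-timing class the dose will be related to:
#'   \code{"late"} (events after 3 months, alpha/beta = 3 Gy) or
#'   \code{"acute"} (events within 3 months, alpha/beta = 10 Gy).
#' @return an object of class \code{"treatment_course"}.
#' @examples
#' treatment_course(60, n_fractions = 30)             # 2 Gy/fraction
#' treatment_course(54, dose_per_fraction = 18)       # SABR-like course
#' @seealso [eqd2()], [cumulative_eqd2()]
#' @export
treatment_course <- function(total_dose, dose_per_fraction = NULL,
                             n_fractions = NULL,
                             timing = c("late", "acute")) {
  timing <- match.arg(timing)
  if (!is.numeric(total_dose) || length(total_dose) != 1L || is.na(total_dose))
    stop("'total_dose' must be a single number", call. = FALSE)
  if (total_dose < 0)
    stop("'total_dose' must be >= 0", call. = FALSE)

  if (total_dose == 0) {
    dose_per_fraction <- if (is.null(dose_per_fraction)) 2 else dose_per_fraction
    n_fractions <- 0L
  } else {
    if (is.null(dose_per_fraction) && is.null(n_fractions))
      stop("give 'dose_per_fraction' or 'n_fractions'", call. = FALSE)
    if (is.null(dose_per_fraction))
      dose_per_fraction <- total_dose / n_fractions
    if (is.null(n_fractions))
      n_fractions <- round(total_dose / dose_per_fraction)
    if (dose_per_fraction <= 0)
      stop("'dose_per_fraction' must be > 0", call. = FALSE)
    if (n_fractions < 1 || n_fractions != round(n_fractions))
      stop("'n_fractions' must be a positive integer", call. = FALSE)
    if (abs(total_dose - dose_per_fraction * n_fractions) > 1e-6 * max(1, total_dose))
      stop("total_dose != dose_per_fraction * n_fractions", call. = FALSE)
  }
  structure(
    list(total_dose = total_dose, dose_per_fraction = dose_per_fraction,
         n_fractions = as.integer(n_fractions), timing = timing),
    class = "treatment_course"
  )
}

#' @export
print.treatment_course <- function(x, ...) {
  cat(sprintf("Treatment course: %.4g Gy in %d x %.4g Gy fractions (%s timing)\n",
              x$total_dose, x$n_fractions, x$dose_per_fraction, x$timing))
  invisible(x)
}

#' Alpha/beta ratio for a toxicity-timing class
#'
#' Acute (within 3 months) oesophageal effects use alpha/beta = 10 Gy; late
#' effects use 3 Gy, the convention for late-responding normal tissue.
#'
#' @param timing \code{"late"} or \code{"acute"}.
#' @return alpha/beta ratio in Gy.
#' @export
alpha_beta_for <- function(timing = c("late", "acute")) {
  timing <- match.arg(timing)
  c(late = 3, acute = 10)[[timing]]
}

#' EQD2 dose object
#'
#' A dose in equivalent 2-Gy fractions, annotated with the alpha/beta ratio
#' used so that Gy_3 and Gy_10 quantities are never silently mixed: addition
#' and subtraction of two \code{eqd2_dose} values with different alpha/beta
#' is an error.
#'
#' @param value nonnegative dose(s) in Gy EQD2.
#' @param alpha_beta positive alpha/beta ratio in Gy.
#' @return numeric vector of class \code{"eqd2_dose"} with an
#'   \code{"alpha_beta"} attribute.
#' @export
eqd2_dose <- function(value, alpha_beta) {
  if (!is.numeric(value) || any(is.na(value)) || any(value < 0))
    stop("EQD2 value must be nonnegative", call. = FALSE)
  if (!is.numeric(alpha_beta) || length(alpha_beta) != 1L || alpha_beta <= 0)
    stop("'alpha_beta' must be a single positive number", call. = FALSE)
  structure(as.numeric(value), alpha_beta = alpha_beta, class = "eqd2_dose")
}

#' @export
format.eqd2_dose <- function(x, digits = 1, ...) {
  sprintf("%.*f Gy_%g EQD2", digits, unclass(x), attr(x, "alpha_beta"))
}

#' @export
print.eqd2_dose <- function(x, ...) {
  cat(format(x, ...), sep = "\n")
  invisible(x)
}

#' @export
Ops.eqd2_dose <- function(e1, e2) {
  if (.Generic %in% c("+", "-") && inherits(e1, "eqd2_dose") &&
      inherits(e2, "eqd2_dose")) {
    ab1 <- attr(e1, "alpha_beta")
    ab2 <- attr(e2, "alpha_beta")
    if (!isTRUE(all.equal(ab1, ab2)))
      stop(sprintf("cannot combine EQD2 doses with different alpha/beta (Gy_%g vs Gy_%g)",
                   ab1, ab2), call. = FALSE)
    return(eqd2_dose(get(.Generic)(unclass(e1), unclass(e2)), ab1))
  }
  get(.Generic)(unclass(e1), unclass(e2))
}

#' Convert a fractionated course to EQD2
#'
#' Linear-quadratic conversion of a physical fractionated dose to the
#' equivalent dose in 2-Gy fractions:
#' \deqn{EQD2 = D \cdot \frac{d + \alpha/\beta}{2 + \alpha/\beta}}
#' where \eqn{D} is the total dose and \eqn{d} the dose per fraction. A
#' course delivered at exactly 2 Gy/fraction is a fixed point (EQD2 equals
#' the physical dose) for every alpha/beta.
#'
#' @param course a [treatment_course()].
#' @param alpha_beta alpha/beta ratio in Gy; defaults to the value implied by
#'   the course's timing class (late 3, acute 10).
#' @return an [eqd2_dose()].
#' @examples
#' eqd2(treatment_course(60, n_fractions = 30), alpha_beta = 3)   # 60 Gy_3
#' eqd2(treatment_course(54, n_fractions = 3), alpha_beta = 3)    # 226.8 Gy_3
#' @export
eqd2 <- function(course, alpha_beta = NULL) {
  if (!inherits(course, "treatment_course"))
    stop("'course' must be a treatment_course", call. = FALSE)
  if (is.null(alpha_beta)) alpha_beta <- alpha_beta_for(course$timing)
  if (!is.numeric(alpha_beta) || length(alpha_beta) != 1L || alpha_beta <= 0)
    stop("'alpha_beta' must be a single positive number", call. = FALSE)
  d <- course$dose_per_fraction
  if (d <= 0 && course$total_dose > 0)
    stop("'dose_per_fraction' must be > 0", call. = FALSE)
  value <- course$total_dose * (d + alpha_beta) / (2 + alpha_beta)
  eqd2_dose(value, alpha_beta)
}

#' Cumulative EQD2 over several courses
#'
#' Sums per-course EQD2 values at a common alpha/beta; order-independent.
#' No repopulation/time-factor correction and no recovery discount for the
#' inter-course interval is applied: doses add directly, and interval enters
#' the analysis only as a candidate regression covariate.
#'
#' @param courses a list of [treatment_course()] objects.
#' @param alpha_beta common alpha/beta ratio in Gy (default 3, the
#'   late-toxicity convention in which the headline dose constraints are
#'   expressed).
#' @return an [eqd2_dose()] with the summed value.
#' @examples
#' crs <- list(treatment_course(60, n_fractions = 30),
#'             treatment_course(54, n_fractions = 3))
#' cumulative_eqd2(crs, alpha_beta = 3)   # 286.8 Gy_3
#' @export
cumulative_eqd2 <- function(courses, alpha_beta = 3) {
  if (inherits(courses, "treatment_course")) courses <- list(courses)
  if (length(courses) == 0L) {
    warning("empty course list; cumulative EQD2 is 0", call. = FALSE)
    return(eqd2_dose(0, alpha_beta))
  }
  vals <- vapply(courses, function(cr) unclass(eqd2(cr, alpha_beta)), numeric(1))
  eqd2_dose(sum(vals), alpha_beta)
}
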