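# Seeded generator of multi-study re-irradiation datasets with the
# statistical structure the analysis assumes: ~20 studies of 1-60 patients,
# per-study clustered cumulative EQD2 doses, per-study chemotherapy
# policies, and binary grade >=3 toxicity drawn from a true logistic model
# in dose and chemotherapy.

#' Simulation design for synthetic multi-study cohorts
#'
#' Describes the data-generating process for [simulate_patients()]. Dose
#' heterogeneity is modelled hierarchically: each study draws a log-normal
#' location, and its patients draw log-normal doses around it, truncated to
#' \code{dose_range} — reproducing the between-study dose clustering that
#' the study-level block bootstrap exists to handle. Each study draws a
#' chemotherapy probability from a Beta distribution (bimodal by default,
#' since real study policies are mostly all-or-none), and each patient's
#' event is Bernoulli with
#' \eqn{p = \mathrm{expit}(\beta_0 + \beta_d \cdot dose + \beta_c \cdot chemo)}.
#'
#' Study-level fields (\code{study_sizes}, \code{study_dose_medians},
#' \code{study_chemo_probs}, \code{study_intervals}) may be fixed explicitly
#' to emulate a concrete set of studies; otherwise they are drawn from the
#' distributions given.
#'
#' @param n_studies number of studies (default 21).
#' @param patients_per_study inclusive size range to draw study sizes from
#'   (default 1-60).
#' @param true_beta named logit-scale coefficients of the generating model:
#'   \code{intercept}, \code{dose} (per Gy EQD2), \code{chemo}. Defaults to
#'   the coefficients of the published multi-study oesophageal model.
#' @param dose_meanlog,dose_sdlog_between mean and SD of the per-study
#'   log-dose locations (defaults: location log(84.8), between-study SD 0.5,
#'   matching the observed spread of study median doses).
#' @param dose_sdlog_within within-study log-dose SD (default 0.35).
#' @param dose_range truncation range in Gy EQD2 (default 0-250, spanning
#'   the observed 3.7-220.6).
#' @param chemo_shape Beta(a, b) parameters for per-study chemotherapy
#'   probability (default c(0.3, 0.3): mass near 0 and 1).
#' @param interval_meanlog,interval_sdlog,interval_range log-normal
#'   parameters and truncation for intervals in months (defaults: median
#'   15.5 months, range 1-162).
#' @param study_sizes,study_dose_medians,study_chemo_probs,study_intervals
#'   optional explicit per-study vectors (length \code{n_studies})
#'   overriding the random draws.
#' @param granularity \code{"patient"}, \code{"grouped"} or \code{"mixed"} —
#'   how [simulate_dataset()] presents the data.
#' @param seed default RNG seed used when none is passed to the simulator.
#' @return an object of class \code{"simulation_design"}.
#' @export
simulation_design <- function(n_studies = 21,
                              patients_per_study = c(1, 60),
                              true_beta = c(intercept = -7.0065,
                                            dose = 0.0431, chemo = 2.2065),
                              dose_meanlog = log(84.8),
                              dose_sdlog_between = 0.5,
                              dose_sdlog_within = 0.35,
                              dose_range = c(0, 250),
                              chemo_shape = c(0.3, 0.3),
                              interval_meanlog = log(15.5),
                              interval_sdlog = 0.6,
                              interval_range = c(1, 162),
                              study_sizes = NULL,
                              study_dose_medians = NULL,
                              study_chemo_probs = NULL,
                              study_intervals = NULL,
                              granularity = c("patient", "grouped", "mixed"),
                              seed = 1L) {
  granularity <- match.arg(granularity)
  if (n_studies < 1) stop("'n_studies' must be >= 1", call. = FALSE)
  if (!all(c("intercept", "dose", "chemo") %in% names(true_beta)))
    stop("'true_beta' needs intercept, dose and chemo components",
         call. = FALSE)
  for (v in list(study_sizes, study_dose_medians, study_chemo_probs,
                 study_intervals))
    if (!is.null(v) && length(v) != n_studies)
      stop("explicit per-study vectors must have length n_studies",
           call. = FALSE)
  if (!is.null(study_chemo_probs) &&
      any(study_chemo_probs < 0 | study_chemo_probs > 1, na.rm = TRUE))
    stop("'study_chemo_probs' must lie in [0, 1]", call. = FALSE)
  structure(mget(names(formals())), class = "simulation_design")
}

# truncated log-normal draw by rejection (falls back to clamping if the
# acceptance region is tiny)
.rtrunc_lnorm <- function(n, meanlog, sdlog, range) {
  x <- stats::rlnorm(n, meanlog, sdlog)
  for (i in 1:50) {
    bad <- x < range[1] | x > range[2]
    if (!any(bad)) return(x)
    x[bad] <- stats::rlnorm(sum(bad), meanlog, sdlog)
  }
  pmin(pmax(x, range[1]), range[2])
}

#' Simulate patient-level records from a design
#'
#' Draws a full multi-study patient-level dataset from the generating model
#' in the design. Identical (design, seed) pairs give identical datasets;
#' the caller's RNG state is untouched. Simulated events are recorded with
#' timing \code{"late"} and grade 3 (the model concerns the binary event
#' only; timing/grade are filled for schema completeness).
#'
#' @param design a [simulation_design()].
#' @param seed RNG seed (default \code{design$seed}).
#' @return a \code{patient_records} data frame.
#' @examples
#' d <- simulation_design(n_studies = 5, seed = 42)
#' head(simulate_patients(d))
#' @export
simulate_patients <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "simulation_design"))
  d <- design
  .with_seed(seed, {
    sizes <- if (!is.null(d$study_sizes)) as.integer(d$study_sizes)
             else sample(seq(d$patients_per_study[1], d$patients_per_study[2]),
                         d$n_studies, replace = TRUE)
    dose_loc <- if (!is.null(d$study_dose_medians)) log(d$study_dose_medians)
                else stats::rnorm(d$n_studies, d$dose_meanlog,
                                  d$dose_sdlog_between)
    chemo_p <- if (!is.null(d$study_chemo_probs)) d$study_chemo_probs
               else stats::rbeta(d$n_studies, d$chemo_shape[1],
                                 d$chemo_shape[2])
    interval_loc <- if (!is.null(d$study_intervals)) log(d$study_intervals)
                    else stats::rnorm(d$n_studies, d$interval_meanlog,
                                      d$interval_sdlog / 2)
    parts <- lapply(seq_len(d$n_studies), function(i) {
      n <- sizes[i]
      dose <- .rtrunc_lnorm(n, dose_loc[i], d$dose_sdlog_within, d$dose_range)
      chemo <- if (is.na(chemo_p[i])) rep(NA_real_, n)
               else stats::rbinom(n, 1, chemo_p[i])
      interval <- if (is.na(interval_loc[i])) rep(NA_real_, n)
                  else .rtrunc_lnorm(n, interval_loc[i], d$interval_sdlog / 2,
                                     d$interval_range)
      eta <- d$true_beta[["intercept"]] + d$true_beta[["dose"]] * dose +
        d$true_beta[["chemo"]] * ifelse(is.na(chemo), 0, chemo)
      event <- stats::rbinom(n, 1, stats::plogis(eta))
      data.frame(patient_id = sprintf("S%02d_%03d", i, seq_len(n)),
                 study_id = sprintf("S%02d", i),
                 cdmax = dose, chemo = chemo, interval_months = interval,
                 event = event,
                 event_timing = ifelse(event == 1, "late", "none"),
                 event_grade = ifelse(event == 1, 3, NA_real_),
                 stringsAsFactors = FALSE)
    })
    validate_patients(do.call(rbind, parts))
  })
}

#' Aggregate patient records to study-level summaries
#'
#' Collapses patient-level records to one row per study: patient count,
#' grouped event count, the study median dose as the representative dose,
#' the mean chemotherapy flag as the chemo fraction and the median interval
#' — i.e. exactly how grouped studies enter the mixed likelihood.
#'
#' @param patients a \code{patient_records} data frame.
#' @return a \code{cohort_summaries} data frame.
#' @export
aggregate_to_cohorts <- function(patients) {
  p <- validate_patients(patients)
  if (nrow(p) == 0L) stop("no patients to aggregate", call. = FALSE)
  med_or_na <- function(x) if (all(is.na(x))) NA_real_ else
    stats::median(x, na.rm = TRUE)
  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else
    mean(x, na.rm = TRUE)
  parts <- lapply(split(p, p$study_id), function(g)
    data.frame(study_id = g$study_id[1], n = nrow(g), events = sum(g$event),
               cdmax_rep = med_or_na(g$cdmax),
               chemo_fraction = mean_or_na(g$chemo),
               interval_rep = med_or_na(g$interval_months),
               followup_rep = NA_real_, stringsAsFactors = FALSE))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  validate_cohorts(out[order(out$study_id), ])
}

#' Simulate a dataset at the design's granularity
#'
#' Presents a simulated multi-study dataset the way mixed-source literature
#' data arrive: fully patient-level, fully grouped (study summaries only),
#' or mixed, where alternating studies are reduced to grouped summaries and
#' the rest stay patient-level.
#'
#' @inheritParams simulate_patients
#' @return for \code{granularity = "patient"}, a \code{patient_records}
#'   data frame; for \code{"grouped"}, a \code{cohort_summaries} data frame;
#'   for \code{"mixed"}, a list of the patient-level part and the grouped
#'   part.
#' @export
simulate_dataset <- function(design, seed = design$seed) {
  patients <- simulate_patients(design, seed)
  switch(design$granularity,
         patient = patients,
         grouped = aggregate_to_cohorts(patients),
         mixed = {
           ids <- unique(patients$study_id)
           grouped_ids <- ids[seq_along(ids) %% 2 == 0]
           list(patients = validate_patients(
                  patients[!patients$study_id %in% grouped_ids, ]),
                cohorts = aggregate_to_cohorts(
                  patients[patients$study_id %in% grouped_ids, ]))
         })
}

#' Design emulating the packaged 21-study dataset
#'
#' A preset [simulation_design()] whose study sizes, median doses,
#' chemotherapy rates and intervals are fixed at the values of the packaged
#' multi-study dataset, so simulated data have the same realistic shapes
#' (tiny single-patient studies, all-or-none chemotherapy policies, doses
#' from 19 to 136 Gy) as the literature data the analysis targets.
#'
#' @param ... overrides passed to [simulation_design()].
#' @return a \code{simulation_design}.
#' @export
design_fixture_like <- function(...) {
  co <- builtin_fixture()$cohorts
  args <- list(n_studies = nrow(co), study_sizes = co$n,
               study_dose_medians = co$cdmax_rep,
               study_chemo_probs = co$chemo_fraction,
               study_intervals = co$interval_rep,
               dose_sdlog_within = 0.2)
  override <- list(...)
  args[names(override)] <- override
  do.call(simulation_design, args)
}

#' Read a simulation design from a YAML or JSON file
#'
#' @param path file whose top-level keys are [simulation_design()] argument
#'   names (format chosen by extension: .json is JSON, anything else YAML).
#' @return a \code{simulation_design}.
#' @export
read_simulation_design <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  bad <- setdiff(names(vals), names(formals(simulation_design)))
  if (length(bad))
    stop("unknown design field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(vals$true_beta)) vals$true_beta <- unlist(vals$true_beta)
  do.call(simulation_design, vals)
}
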