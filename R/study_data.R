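# Data model and delimited-file I/O for patient-level and study-level
# re-irradiation records. Files are comma-separated, UTF-8, header row
# required, "." decimal separator; "NA" and "NR" are read as missing.

.NA_STRINGS <- c("NA", "NR", "")

.patient_file_cols <- c(patient_id = "patient_id", study_id = "study_id",
                        cdmax = "cdmax_gy_eqd2", chemo = "chemo",
                        interval_months = "interval_months", event = "event",
                        event_timing = "event_timing",
                        event_grade = "event_grade")

.cohort_file_cols <- c(study_id = "study_id", n = "n", events = "events",
                       cdmax_rep = "cdmax_rep_gy_eqd2",
                       chemo_fraction = "chemo_fraction",
                       interval_rep = "interval_rep_months",
                       followup_rep = "followup_rep_months")

.row_fail <- function(bad, msg) {
  if (any(bad, na.rm = TRUE))
    stop(sprintf("%s (row%s %s)", msg,
                 if (sum(bad, na.rm = TRUE) > 1) "s" else "",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
}

.read_schema <- function(path, file_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, na.strings = .NA_STRINGS,
                        stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(unname(file_cols), names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  out <- df[, unname(file_cols), drop = FALSE]
  names(out) <- names(file_cols)
  out
}

.check_numeric <- function(x, what) {
  if (is.numeric(x) || is.logical(x)) return(as.numeric(x))
  sup <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(sup)
  .row_fail(bad, paste("non-numeric", what))
  sup
}

#' Validate patient-level records
#'
#' Checks the invariants of the patient schema: doses nonnegative, event a
#' 0/1 flag, event timing and grade consistent with the flag, chemo coded
#' 0/1 or missing. Violations are reported with row numbers.
#'
#' @param patients a data frame in the patient schema (see [read_patients()]).
#' @return the validated data frame, classed \code{"patient_records"}.
#' @export
validate_patients <- function(patients) {
  p <- as.data.frame(patients, stringsAsFactors = FALSE)
  need <- names(.patient_file_cols)
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  p <- p[, need, drop = FALSE]
  p$cdmax <- .check_numeric(p$cdmax, "dose")
  p$chemo <- .check_numeric(p$chemo, "chemo flag")
  p$interval_months <- .check_numeric(p$interval_months, "interval")
  p$event <- .check_numeric(p$event, "event flag")
  .row_fail(!is.na(p$cdmax) & p$cdmax < 0, "negative dose")
  .row_fail(is.na(p$cdmax), "missing dose")
  .row_fail(!is.na(p$chemo) & !p$chemo %in% c(0, 1),
            "chemo must be 0, 1 or missing")
  .row_fail(!is.na(p$interval_months) & p$interval_months < 0,
            "negative interval")
  .row_fail(is.na(p$event) | !p$event %in% c(0, 1), "event must be 0 or 1")
  p$event_timing <- as.character(p$event_timing)
  p$event_timing[is.na(p$event_timing)] <- "none"
  .row_fail(!p$event_timing %in% c("none", "acute", "late", "both"),
            "event_timing must be none/acute/late/both")
  .row_fail((p$event == 1) != (p$event_timing != "none"),
            "event flag inconsistent with event_timing")
  p$event_grade <- .check_numeric(p$event_grade, "event grade")
  .row_fail(!is.na(p$event_grade) & !p$event_grade %in% c(3, 4, 5),
            "event_grade must be 3, 4, 5 or missing")
  .row_fail(p$event == 1 & is.na(p$event_grade),
            "event without event_grade")
  .row_fail(p$event == 0 & !is.na(p$event_grade),
            "event_grade on a non-event")
  class(p) <- c("patient_records", "data.frame")
  p
}

#' Validate study-level cohort summaries
#'
#' @param cohorts a data frame in the cohort schema (see [read_cohorts()]).
#' @return the validated data frame, classed \code{"cohort_summaries"}.
#' @export
validate_cohorts <- function(cohorts) {
  ch <- as.data.frame(cohorts, stringsAsFactors = FALSE)
  need <- names(.cohort_file_cols)
  miss <- setdiff(need, names(ch))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ch <- ch[, need, drop = FALSE]
  for (v in c("n", "events", "cdmax_rep", "chemo_fraction", "interval_rep",
              "followup_rep"))
    ch[[v]] <- .check_numeric(ch[[v]], v)
  nonint <- function(x) abs(x - round(x)) > 1e-8
  .row_fail(is.na(ch$n) | ch$n < 1 | nonint(ch$n),
            "n must be a positive integer")
  .row_fail(is.na(ch$events) | ch$events < 0 | ch$events > ch$n |
              nonint(ch$events),
            "events must be an integer in [0, n]")
  ch$n <- round(ch$n)
  ch$events <- round(ch$events)
  .row_fail(is.na(ch$cdmax_rep) | ch$cdmax_rep < 0,
            "cdmax_rep must be a nonnegative dose")
  .row_fail(!is.na(ch$chemo_fraction) &
              (ch$chemo_fraction < 0 | ch$chemo_fraction > 1),
            "chemo_fraction must lie in [0, 1]")
  .row_fail(!is.na(ch$interval_rep) & ch$interval_rep < 0,
            "negative interval")
  .row_fail(duplicated(ch$study_id), "duplicated study_id")
  class(ch) <- c("cohort_summaries", "data.frame")
  ch
}

#' Read patient-level records from CSV
#'
#' Expects columns \code{patient_id, study_id, cdmax_gy_eqd2, chemo,
#' interval_months, event, event_timing, event_grade}. \code{cdmax_gy_eqd2}
#' is the patient's cumulative oesophageal maximal dose in EQD2 Gy summed
#' over both radiotherapy courses; \code{chemo} flags concurrent
#' chemotherapy with re-irradiation; \code{event} flags grade >=3
#' oesophageal toxicity. "NA"/"NR" are read as missing; no imputation is
#' ever performed (complete-case filtering happens per model downstream).
#'
#' @param path path to a CSV file.
#' @return a \code{patient_records} data frame (columns \code{patient_id,
#'   study_id, cdmax, chemo, interval_months, event, event_timing,
#'   event_grade}).
#' @seealso [read_cohorts()], [builtin_fixture()], [write_patients()]
#' @export
read_patients <- function(path) {
  validate_patients(.read_schema(path, .patient_file_cols))
}

#' Read study-level cohort summaries from CSV
#'
#' Expects columns \code{study_id, n, events, cdmax_rep_gy_eqd2,
#' chemo_fraction, interval_rep_months, followup_rep_months}: per study the
#' number of patients, the grouped count of grade >=3 events, the
#' representative (median) cumulative dose, the fraction on concurrent
#' chemotherapy and representative interval/follow-up in months.
#'
#' @param path path to a CSV file.
#' @return a \code{cohort_summaries} data frame (columns \code{study_id, n,
#'   events, cdmax_rep, chemo_fraction, interval_rep, followup_rep}).
#' @export
read_cohorts <- function(path) {
  validate_cohorts(.read_schema(path, .cohort_file_cols))
}

#' Write patient-level records / cohort summaries to CSV
#'
#' Inverse of [read_patients()] / [read_cohorts()]: writes the documented
#' file schema so that a write-read round trip preserves all fields.
#'
#' @param x a validated \code{patient_records} or \code{cohort_summaries}
#'   data frame.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_patients <- function(x, path) {
  x <- validate_patients(x)
  out <- x
  names(out) <- unname(.patient_file_cols[names(x)])
  utils::write.csv(out, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_patients
#' @export
write_cohorts <- function(x, path) {
  x <- validate_cohorts(x)
  out <- x
  names(out) <- unname(.cohort_file_cols[names(x)])
  utils::write.csv(out, path, row.names = FALSE, na = "NA")
  invisible(path)
}

# Expand one study's grouped events into per-patient (timing, grade) pairs,
# using the itemised event rows. dual = raw events - grouped events patients
# experienced both an acute and a late event; pairs are formed on the
# highest grades first, deterministically.
.expand_event_patients <- function(grouped_events, ev_rows) {
  if (grouped_events == 0L) return(NULL)
  acute <- sort(rep(ev_rows$grade[ev_rows$timing == "acute"],
                    ev_rows$count[ev_rows$timing == "acute"]),
                decreasing = TRUE)
  late <- sort(rep(ev_rows$grade[ev_rows$timing == "late"],
                   ev_rows$count[ev_rows$timing == "late"]),
               decreasing = TRUE)
  raw <- length(acute) + length(late)
  if (raw == 0L) {  # study has a rate-derived count but no itemised rows
    return(data.frame(event_timing = rep("late", grouped_events),
                      event_grade = rep(3, grouped_events)))
  }
  dual <- raw - grouped_events
  stopifnot(dual >= 0, dual <= min(length(acute), length(late)))
  out <- data.frame(event_timing = character(0), event_grade = numeric(0))
  if (dual > 0)
    out <- rbind(out, data.frame(event_timing = "both",
                                 event_grade = pmax(acute[seq_len(dual)],
                                                    late[seq_len(dual)])))
  drop_dual <- function(x) if (dual > 0) x[-seq_len(dual)] else x
  if (length(acute) > dual)
    out <- rbind(out, data.frame(event_timing = "acute",
                                 event_grade = drop_dual(acute)))
  if (length(late) > dual)
    out <- rbind(out, data.frame(event_timing = "late",
                                 event_grade = drop_dual(late)))
  out
}

#' Packaged multi-study re-irradiation dataset
#'
#' Returns the study-level dataset transcribed from 21 published thoracic
#' re-irradiation reports (505 patients, 49 grouped grade >=3 oesophageal
#' toxicity events from 57 raw events; eight patients had both an acute and
#' a late event), together with the itemised toxicity-event rows and a
#' pseudo patient-level expansion.
#'
#' The expansion assigns every patient of a study the study's representative
#' (median) dose and interval, distributes concurrent chemotherapy to match
#' the study's chemo fraction, and spreads the grouped events evenly across
#' the study's rows: it is a reconstruction for exercising patient-level
#' code paths, not observed individual data, and is flagged as such via the
#' \code{"reconstructed"} attribute. See the packaged file
#' \code{fixture_notes.md} for transcription conventions and known
#' source-table discrepancies.
#'
#' @return a list with components \code{cohorts} (\code{cohort_summaries},
#'   21 rows), \code{events} (itemised event rows: \code{study_id, timing,
#'   grade, category, count}), and \code{patients} (reconstructed
#'   \code{patient_records}, 505 rows).
#' @examples
#' fx <- builtin_fixture()
#' sum(fx$cohorts$n)        # 505
#' sum(fx$events$count)     # 57
#' sum(fx$cohorts$events)   # 49
#' @export
builtin_fixture <- function() {
  cohorts <- read_cohorts(system.file("extdata", "reirradiation_studies.csv",
                                      package = "reirrtox", mustWork = TRUE))
  events <- utils::read.csv(system.file("extdata", "toxicity_events.csv",
                                        package = "reirrtox", mustWork = TRUE),
                            na.strings = .NA_STRINGS,
                            stringsAsFactors = FALSE)
  patients <- do.call(rbind, lapply(seq_len(nrow(cohorts)), function(i) {
    co <- cohorts[i, ]
    n <- co$n
    ev <- .expand_event_patients(co$events,
                                 events[events$study_id == co$study_id, ])
    p <- data.frame(
      patient_id = sprintf("%s_%02d", co$study_id, seq_len(n)),
      study_id = co$study_id,
      cdmax = co$cdmax_rep,
      chemo = NA_real_,
      interval_months = co$interval_rep,
      event = 0,
      event_timing = "none",
      event_grade = NA_real_,
      stringsAsFactors = FALSE
    )
    if (!is.na(co$chemo_fraction))
      p$chemo <- as.numeric(seq_len(n) <= round(n * co$chemo_fraction))
    if (co$events > 0) {
      idx <- unique(round(seq(1, n, length.out = co$events)))
      stopifnot(length(idx) == co$events)
      p$event[idx] <- 1
      p$event_timing[idx] <- ev$event_timing
      p$event_grade[idx] <- ev$event_grade
    }
    p
  }))
  patients <- validate_patients(patients)
  attr(patients, "reconstructed") <- TRUE
  list(cohorts = cohorts, events = events, patients = patients)
}

#' Split values at their median
#'
#' Labels each value as at-or-below versus above the median of the
#' non-missing values, the dichotomisation used to screen candidate
#' predictors in 2x2 contingency tests.
#'
#' @param values numeric vector with at least 2 non-missing values.
#' @return a factor with levels \code{"<=median"} and \code{">median"}
#'   (missing values stay \code{NA}), with attributes \code{median} and
#'   \code{n_missing}. A degenerate split (all values equal) warns.
#' @examples
#' median_split(c(1, 2, 3, 4))
#' @export
median_split <- function(values) {
  if (!is.numeric(values)) stop("'values' must be numeric", call. = FALSE)
  ok <- !is.na(values)
  if (sum(ok) < 2)
    stop("need at least 2 non-missing values", call. = FALSE)
  m <- stats::median(values[ok])
  lab <- ifelse(values <= m, "<=median", ">median")
  lab[!ok] <- NA
  f <- factor(lab, levels = c("<=median", ">median"))
  if (all(f[ok] == "<=median"))
    warning("degenerate split: no values above the median", call. = FALSE)
  attr(f, "median") <- m
  attr(f, "n_missing") <- sum(!ok)
  f
}
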