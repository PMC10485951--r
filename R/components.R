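# The five binary surveillance components, evaluated on a day-index scale
# anchored at the surgery. Component functions take one surgery and the
# cohort-level event tables; `extract_components()` applies them to a whole
# cohort after splitting events by patient once.

.component_names <- c("admissions", "reoperation", "radiology", "antibiotics",
                      "microbiology")

#' Day index of an event relative to a surgery
#'
#' The surgery day is day 1: an event on the surgery date has index 1, one day
#' later index 2, one day before index 0. All component windows are expressed
#' on this scale; the follow-up window is day 1 through `fu_days`.
#'
#' @param event_date,surgery_date `Date` vectors (recycled).
#' @return Integer vector of day indices; values `<= 0` are pre-surgery.
#' @examples
#' day_index(as.Date("2019-05-02"), as.Date("2019-05-01"))  # 2
#' @export
day_index <- function(event_date, surgery_date) {
  as.integer(event_date - surgery_date) + 1L
}

.one_row <- function(surgery) {
  if (is.data.frame(surgery)) {
    stopifnot(nrow(surgery) == 1L)
    as.list(surgery)
  } else {
    surgery
  }
}

.patient_events <- function(events, patient_id) {
  events[events$patient_id == patient_id, , drop = FALSE]
}

#' Admissions component: prolonged stay, readmission or in-hospital death
#'
#' True when any of three arms holds within the follow-up window: (a) the
#' index admission (the earliest episode whose interval contains the surgery
#' date) keeps the patient in hospital at least `los_threshold_days` days past
#' the surgery, or has no discharge, or discharges only after the follow-up
#' window closes; (b) a later episode readmits the patient to the original
#' department between day 1 and `fu_days`; (c) an in-hospital death, dated by
#' its episode's discharge date, falls between day 1 and `fu_days`. With
#' `los_from = "admission"` arm (a) counts from the index admission date
#' instead of the surgery date.
#'
#' When no episode contains the surgery date, arms (b) and (c) are still
#' evaluated and a condition of class `ssi_no_index_admission` is signalled.
#'
#' @param surgery A single surgery: one-row data frame or named list with
#'   `patient_id`, `surgery_date`, `department`.
#' @param admissions Admission episodes table (any patients; filtered
#'   internally).
#' @param config A [surveillance_config()].
#' @return `TRUE` or `FALSE`.
#' @export
admissions_component <- function(surgery, admissions, config = surveillance_config()) {
  s <- .one_row(surgery)
  ep <- .patient_events(admissions, s$patient_id)
  fu <- config$fu_days
  sd <- s$surgery_date

  contains <- !is.na(ep$admit_date) & ep$admit_date <= sd &
    (is.na(ep$discharge_date) | ep$discharge_date >= sd)
  idx <- which(contains)
  if (length(idx) > 1L) idx <- idx[which.min(as.integer(ep$admit_date[idx]))]

  if (length(idx) == 1L) {
    disch <- ep$discharge_date[idx]
    start <- if (config$los_from == "admission") ep$admit_date[idx] else sd
    if (is.na(disch)) return(TRUE)                 # still admitted: open stay
    if (day_index(disch, sd) > fu) return(TRUE)    # discharged after FU close
    if (as.integer(disch - start) >= config$los_threshold_days) return(TRUE)
  } else {
    rlang::warn(
      sprintf("no admission episode contains surgery on %s for patient '%s'",
              sd, s$patient_id),
      class = "ssi_no_index_admission")
  }

  later <- setdiff(seq_len(nrow(ep)), idx)
  if (length(later) > 0L) {
    adm_day <- day_index(ep$admit_date[later], sd)
    if (any(ep$department[later] == s$department & adm_day >= 1L & adm_day <= fu,
            na.rm = TRUE)) {
      return(TRUE)
    }
  }

  died <- isTRUE_v(ep$died_in_hospital) & !is.na(ep$discharge_date)
  if (any(died)) {
    death_day <- day_index(ep$discharge_date[died], sd)
    if (any(death_day >= 1L & death_day <= fu)) return(TRUE)
  }
  FALSE
}

#' Reoperation component
#'
#' True when the patient has at least one reoperation by the original surgery
#' specialty strictly after the surgery day (day index 2 through `fu_days`).
#' The index procedure itself never counts; a genuine same-day reoperation is
#' not representable at day resolution.
#'
#' @inheritParams admissions_component
#' @param reoperations Reoperations table.
#' @return `TRUE` or `FALSE`.
#' @export
reoperation_component <- function(surgery, reoperations, config = surveillance_config()) {
  s <- .one_row(surgery)
  re <- .patient_events(reoperations, s$patient_id)
  if (nrow(re) == 0L) return(FALSE)
  d <- day_index(re$procedure_date, s$surgery_date)
  any(re$specialty == s$specialty & d >= 2L & d <= config$fu_days, na.rm = TRUE)
}

#' Radiology component
#'
#' True when at least one imaging order with a modality in
#' `config$radiology_modalities` (default CT) falls on day 1 through
#' `fu_days`. Pre-operative orders (day index `<= 0`) never count.
#'
#' @inheritParams admissions_component
#' @param radiology Radiology orders table.
#' @return `TRUE` or `FALSE`.
#' @export
radiology_component <- function(surgery, radiology, config = surveillance_config()) {
  s <- .one_row(surgery)
  ra <- .patient_events(radiology, s$patient_id)
  if (nrow(ra) == 0L) return(FALSE)
  d <- day_index(ra$order_date, s$surgery_date)
  any(ra$modality %in% config$radiology_modalities & d >= 1L & d <= config$fu_days,
      na.rm = TRUE)
}

# Qualifying-run test on a set of distinct day indices: does any run of
# `min_len` consecutive administered days lie entirely inside
# [earliest_start, fu]? Days outside that window contribute nothing, so a
# course is truncated at the window edges before the length test, and adding
# administrations can never disqualify (monotonicity).
.has_qualifying_run <- function(days, min_len, earliest_start, fu) {
  days <- sort(unique(days[days >= earliest_start & days <= fu]))
  if (length(days) < min_len) return(FALSE)
  run_id <- cumsum(c(1L, diff(days) != 1L))
  any(tabulate(run_id) >= min_len)
}

#' Antibiotics component
#'
#' True when the patient received systemic antibacterials (ATC code matching
#' the `J01` prefix) on at least `abx_min_consecutive_days` consecutive
#' calendar days lying entirely after the surgery day and inside the
#' follow-up window, i.e. some run of `abx_min_consecutive_days` consecutive
#' administered days within day `abx_earliest_start_day` through `fu_days`.
#' Administrations are reduced to distinct day indices: dose counts and
#' routes are ignored. Administrations on the surgery day or earlier are read
#' as perioperative prophylaxis and contribute nothing (so a 3-day course
#' starting on the surgery day does not qualify, while a course running from
#' the surgery day through day 4 does, via days 2-4); a course running past
#' `fu_days` is truncated at `fu_days` before the length test.
#'
#' @inheritParams admissions_component
#' @param antibiotics Antibiotic administrations table.
#' @return `TRUE` or `FALSE`.
#' @export
antibiotics_component <- function(surgery, antibiotics, config = surveillance_config()) {
  s <- .one_row(surgery)
  ab <- .patient_events(antibiotics, s$patient_id)
  ab <- ab[startsWith(ab$atc_code, config$abx_atc_prefix), , drop = FALSE]
  if (nrow(ab) == 0L) return(FALSE)
  d <- day_index(ab$administration_date, s$surgery_date)
  .has_qualifying_run(d, config$abx_min_consecutive_days,
                      config$abx_earliest_start_day, config$fu_days)
}

#' Microbiology component
#'
#' True when at least one culture from a relevant body site falls on day
#' `culture_earliest_day` (default 1: the surgery day counts) through
#' `fu_days`. Cultures from any day before the surgery day never count.
#'
#' @inheritParams admissions_component
#' @param microbiology Microbiology cultures table.
#' @return `TRUE` or `FALSE`.
#' @export
microbiology_component <- function(surgery, microbiology, config = surveillance_config()) {
  s <- .one_row(surgery)
  mb <- .patient_events(microbiology, s$patient_id)
  if (nrow(mb) == 0L) return(FALSE)
  d <- day_index(mb$sample_date, s$surgery_date)
  any(isTRUE_v(mb$relevant_site) & d >= config$culture_earliest_day &
        d <= config$fu_days)
}

#' Extract the five-component profile for every surgery in a cohort
#'
#' Applies the five component functions to each surgery and assembles the
#' binary profile plus the component count. Surgeries with no admission
#' episode containing the surgery date are evaluated on the readmission and
#' mortality arms only; one summarizing warning lists how many such surgeries
#' were seen.
#'
#' @param cohort An [ssi_cohort()].
#' @param config A [surveillance_config()].
#' @return A tibble with one row per surgery, in the roster order:
#'   `surgery_id`, logical columns `admissions`, `reoperation`, `radiology`,
#'   `antibiotics`, `microbiology`, and integer `count` (0-5).
#' @export
extract_components <- function(cohort, config = surveillance_config()) {
  stopifnot(inherits(cohort, "ssi_cohort"))
  surg <- cohort$surgeries
  n <- nrow(surg)
  by_patient <- function(tab) split(tab, tab$patient_id)
  ev <- lapply(cohort[c("admissions", "reoperations", "radiology",
                        "antibiotics", "microbiology")], by_patient)
  empty <- lapply(c("admissions", "reoperations", "radiology", "antibiotics",
                    "microbiology"), .empty_table)
  names(empty) <- names(ev)

  flags <- matrix(FALSE, nrow = n, ncol = 5L,
                  dimnames = list(NULL, .component_names))
  n_no_index <- 0L
  for (i in seq_len(n)) {
    s <- as.list(surg[i, c("surgery_id", "patient_id", "surgery_date",
                           "specialty", "department")])
    pid <- s$patient_id
    get <- function(tab) {
      hit <- ev[[tab]][[pid]]
      if (is.null(hit)) empty[[tab]] else hit
    }
    flags[i, "admissions"] <- withCallingHandlers(
      admissions_component(s, get("admissions"), config),
      ssi_no_index_admission = function(cnd) {
        n_no_index <<- n_no_index + 1L
        rlang::cnd_muffle(cnd)
      })
    flags[i, "reoperation"] <- reoperation_component(s, get("reoperations"), config)
    flags[i, "radiology"] <- radiology_component(s, get("radiology"), config)
    flags[i, "antibiotics"] <- antibiotics_component(s, get("antibiotics"), config)
    flags[i, "microbiology"] <- microbiology_component(s, get("microbiology"), config)
  }
  if (n_no_index > 0L) {
    warning(sprintf(
      "%d surgeries had no admission episode containing the surgery date; their admissions component used the readmission and mortality arms only.",
      n_no_index), call. = FALSE)
  }
  tibble::tibble(
    surgery_id = surg$surgery_id,
    admissions = flags[, "admissions"],
    reoperation = flags[, "reoperation"],
    radiology = flags[, "radiology"],
    antibiotics = flags[, "antibiotics"],
    microbiology = flags[, "microbiology"],
    count = as.integer(rowSums(flags))
  )
}
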