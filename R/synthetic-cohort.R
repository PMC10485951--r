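# Synthetic validation cohorts: sample per-surgery deep-SSI status and the
# five component indicators from a calibrated conditional model, then realize
# the indicators as event-level EHR streams (plus non-qualifying distractor
# events) so that component extraction on the realized events reproduces the
# planted indicators exactly.

.default_marginals <- c(admissions = 0.387, reoperation = 0.178,
                        radiology = 0.476, antibiotics = 0.413,
                        microbiology = 0.311)

# P(component | deep SSI), calibrated by least squares under the
# exact-marginal constraint so that the expected operating characteristics of
# the two built-in rules approximate the validation study's.
.default_given_ssi <- c(admissions = 0.8326, reoperation = 0.4151,
                        radiology = 0.9359, antibiotics = 0.8626,
                        microbiology = 0.8309)

.default_distractors <- list(
  prophylactic_abx = 0.5,      # perioperative J01 course starting day <= 1
  scattered_abx = 0.2,         # 1-2 isolated J01 days, never 3 consecutive
  non_j01_abx = 0.2,           # antifungal (J02) course: fails the ATC filter
  preop_culture = 0.2,         # relevant-site culture strictly before surgery
  nonrelevant_culture = 0.25,  # in-window culture from a non-relevant site
  non_ct_order = 0.3,          # MR/US/XR order in window
  preop_ct = 0.1,              # CT strictly before surgery
  other_dept_readmission = 0.15,
  wrong_specialty_reop = 0.1,
  late_reop = 0.05             # same specialty but after the FU window
)

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the composition of the validation cohort: 225 colorectal
#' surgeries, 18.2% deep-SSI prevalence, and component marginal prevalences
#' of 38.7% (admissions), 17.8% (reoperation), 47.6% (radiology), 41.3%
#' (antibiotics) and 31.1% (microbiology). Components are modelled as
#' conditionally independent given SSI status; `component_given_ssi` holds
#' P(component | deep SSI), calibrated so the expected sensitivity and
#' specificity of the two built-in rules approximate the validation study,
#' and `component_given_no_ssi` is derived from the marginal constraint
#' `m = p * q1 + (1 - p) * q0` unless supplied explicitly.
#'
#' @param n_surgeries Cohort size (default 225).
#' @param ssi_prevalence P(deep SSI) (default 0.182).
#' @param component_marginals Named vector of the five marginal component
#'   prevalences (used to derive `component_given_no_ssi` when that is
#'   `NULL`).
#' @param component_given_ssi Named vector of P(component | SSI).
#' @param component_given_no_ssi Named vector of P(component | no SSI), or
#'   `NULL` to derive it from the marginals.
#' @param distractor_rates Named list of rates of non-qualifying events
#'   emitted for surgeries whose indicator is false (prophylactic day-1
#'   antibiotic courses, scattered single antibiotic days, non-J01 courses,
#'   pre-operative cultures, non-relevant-site cultures, non-CT imaging,
#'   pre-operative CT, readmissions to another department, reoperations by
#'   another specialty, reoperations after the window).
#' @param admissions_arms Probabilities with which a true admissions
#'   indicator is realized as prolonged stay, same-department readmission, or
#'   in-hospital death (must sum to 1). The default death share makes the
#'   cohort-level in-hospital mortality about 2%.
#' @param annotator_disagreement Per-item flip probability for
#'   [simulate_second_annotator()] (default 0.05).
#' @param period Character vector `c(start, end)` from which surgery dates are
#'   drawn uniformly (default the study inclusion period 2015-01-01 to
#'   2020-08-31).
#' @return An object of class `ssi_gen_config`.
#' @export
generator_config <- function(n_surgeries = 225L,
                             ssi_prevalence = 0.182,
                             component_marginals = .default_marginals,
                             component_given_ssi = .default_given_ssi,
                             component_given_no_ssi = NULL,
                             distractor_rates = .default_distractors,
                             admissions_arms = c(los = 0.60, readmission = 0.35,
                                                 death = 0.05),
                             annotator_disagreement = 0.05,
                             period = c("2015-01-01", "2020-08-31")) {
  p <- ssi_prevalence
  stopifnot(n_surgeries >= 1, p >= 0, p <= 1)
  m <- component_marginals[.component_names]
  q1 <- component_given_ssi[.component_names]
  if (any(is.na(q1)) || any(q1 < 0) || any(q1 > 1)) {
    rlang::abort("`component_given_ssi` must name all five components with proportions in [0, 1].")
  }
  if (is.null(component_given_no_ssi)) {
    if (any(is.na(m)) || any(m < 0) || any(m > 1)) {
      rlang::abort("`component_marginals` must name all five components with proportions in [0, 1].")
    }
    q0 <- if (p < 1) (m - p * q1) / (1 - p) else q1
    if (any(q0 < -1e-9 | q0 > 1 + 1e-9)) {
      bad <- .component_names[q0 < -1e-9 | q0 > 1 + 1e-9]
      rlang::abort(sprintf(
        "Marginals and conditionals are incompatible: implied P(%s | no SSI) falls outside [0, 1].",
        paste(bad, collapse = ", ")))
    }
    q0 <- pmin(pmax(q0, 0), 1)
  } else {
    q0 <- component_given_no_ssi[.component_names]
    if (any(is.na(q0)) || any(q0 < 0) || any(q0 > 1)) {
      rlang::abort("`component_given_no_ssi` must name all five components with proportions in [0, 1].")
    }
    m <- p * q1 + (1 - p) * q0
  }
  dr <- utils::modifyList(.default_distractors, as.list(distractor_rates))
  if (any(unlist(dr) < 0) || any(unlist(dr) > 1)) {
    rlang::abort("Distractor rates must be proportions in [0, 1].")
  }
  arms <- admissions_arms[c("los", "readmission", "death")]
  if (any(is.na(arms)) || abs(sum(arms) - 1) > 1e-9) {
    rlang::abort("`admissions_arms` must name los/readmission/death and sum to 1.")
  }
  if (annotator_disagreement < 0 || annotator_disagreement > 1) {
    rlang::abort("`annotator_disagreement` must be a proportion.")
  }
  structure(list(
    n_surgeries = as.integer(n_surgeries),
    ssi_prevalence = p,
    component_marginals = stats::setNames(as.numeric(m), .component_names),
    component_given_ssi = stats::setNames(as.numeric(q1), .component_names),
    component_given_no_ssi = stats::setNames(as.numeric(q0), .component_names),
    distractor_rates = dr,
    admissions_arms = stats::setNames(as.numeric(arms), names(arms)),
    annotator_disagreement = annotator_disagreement,
    period = as.Date(period)
  ), class = "ssi_gen_config")
}

#' @export
print.ssi_gen_config <- function(x, ...) {
  cat("<ssi_gen_config>\n")
  cat(sprintf("  n = %d surgeries, deep-SSI prevalence %.1f%%\n",
              x$n_surgeries, 100 * x$ssi_prevalence))
  cat("  component marginals:",
      paste(sprintf("%s %.1f%%", .component_names, 100 * x$component_marginals),
            collapse = ", "), "\n")
  invisible(x)
}

# Independent substreams: each event stream draws under its own seed derived
# from the master seed, so adding a stream never perturbs the others.
.stream_seed <- function(seed, id) {
  s <- (as.double(seed) %% 2147483647) * 2147483 + as.double(id) * 7919
  as.integer(s %% 2147483629 + 1)
}

# Uniform integer draw on [lo, hi], vectorized over lo/hi.
.rint <- function(n, lo, hi) {
  lo <- rep_len(as.integer(lo), n)
  hi <- rep_len(as.integer(hi), n)
  stopifnot(all(hi >= lo))
  lo + as.integer(floor(stats::runif(n) * (hi - lo + 1L)))
}

#' Sample a planted cohort (deep-SSI status and component indicators)
#'
#' Draws, per surgery, deep-SSI status as Bernoulli(`ssi_prevalence`) and the
#' five component indicators as conditionally independent Bernoullis given
#' that status, plus surgery metadata and descriptive covariates matched to
#' the validation cohort's published medians and proportions (age, sex, BMI,
#' ASA class, wound class, duration, stoma, primary/open/malignancy flags).
#' Covariates are passthrough realism only: no algorithm reads them.
#'
#' @param config A [generator_config()].
#' @param seed Integer master seed; the same seed reproduces the cohort
#'   exactly.
#' @return A tibble of class `ssi_planted`, one row per surgery: surgery
#'   metadata and covariates, `deep_ssi`, and the five logical indicator
#'   columns named as the components.
#' @export
sample_cohort <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "ssi_gen_config"))
  n <- config$n_surgeries

  set.seed(.stream_seed(seed, 1L))
  deep_ssi <- stats::runif(n) < config$ssi_prevalence
  q <- t(ifelse(matrix(rep(deep_ssi, 5L), ncol = 5L),
                matrix(rep(config$component_given_ssi, each = n), ncol = 5L),
                matrix(rep(config$component_given_no_ssi, each = n), ncol = 5L)))
  ind <- matrix(stats::runif(5L * n) < q, nrow = 5L,
                dimnames = list(.component_names, NULL))

  set.seed(.stream_seed(seed, 2L))
  span <- as.integer(config$period[2L] - config$period[1L])
  surgery_date <- config$period[1L] + .rint(n, 0L, span)
  department <- sample(c("surgery A", "surgery B"), n, replace = TRUE)
  age <- pmin(pmax(round(stats::rnorm(n, 66, 14.8)), 18), 99)
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.489, 0.511))
  bmi <- round(stats::rlnorm(n, log(25.6), 0.205), 1)
  asa_class <- sample(1:4, n, replace = TRUE, prob = c(0.15, 0.485, 0.31, 0.055))
  wound_class <- sample(c("clean-contaminated", "contaminated", "dirty-infected"),
                        n, replace = TRUE, prob = c(0.76, 0.15, 0.09))
  duration_minutes <- round(stats::rlnorm(n, log(316), 0.54))
  stoma <- stats::runif(n) < 0.418
  primary <- stats::runif(n) < 0.636
  open <- stats::runif(n) < 0.773
  malignancy <- stats::runif(n) < 0.769

  out <- tibble::tibble(
    surgery_id = sprintf("S%05d", seq_len(n)),
    patient_id = sprintf("P%05d", seq_len(n)),
    surgery_date = surgery_date,
    specialty = "colorectal surgery",
    department = department,
    age = age, sex = sex, bmi = bmi, asa_class = asa_class,
    wound_class = wound_class, duration_minutes = duration_minutes,
    stoma = stoma, primary = primary, open = open, malignancy = malignancy,
    deep_ssi = deep_ssi,
    admissions = ind["admissions", ],
    reoperation = ind["reoperation", ],
    radiology = ind["radiology", ],
    antibiotics = ind["antibiotics", ],
    microbiology = ind["microbiology", ]
  )
  class(out) <- c("ssi_planted", class(out))
  out
}

#' Realize a planted cohort as event-level EHR streams
#'
#' Emits, for every true indicator, events satisfying the corresponding
#' component predicate (dates drawn uniformly within their legal windows),
#' and for every false indicator only non-qualifying distractor events at the
#' configured rates: perioperative antibiotic courses starting on or before
#' the surgery day, isolated antibiotic days, non-J01 courses, pre-operative
#' or non-relevant-site cultures, non-CT or pre-operative imaging,
#' readmissions to another department, reoperations by another specialty or
#' after the window. An index admission containing the surgery date is always
#' emitted. By construction, [extract_components()] on the result reproduces
#' the planted indicators exactly.
#'
#' @param planted An `ssi_planted` tibble from [sample_cohort()].
#' @param config The [generator_config()] used to sample it.
#' @param seed Integer master seed (use the same value as for
#'   [sample_cohort()] or a different one; event realization draws from its
#'   own substreams either way).
#' @return An [ssi_cohort()] including the reference-standard annotations of
#'   the first annotator (`icp1`), whose labels equal the planted truth.
#' @export
realize_events <- function(planted, config = generator_config(), seed = 1L) {
  stopifnot(inherits(planted, "ssi_planted"))
  n <- nrow(planted)
  pid <- planted$patient_id
  sd <- planted$surgery_date
  fu <- 45L  # realized windows match the default surveillance window
  dr <- config$distractor_rates

  # --- admissions (always an index episode) ------------------------------
  set.seed(.stream_seed(seed, 3L))
  admit_offset <- .rint(n, 0L, 3L)
  arm <- rep("none", n)
  on <- which(planted$admissions)
  if (length(on) > 0L) {
    arm[on] <- sample(names(config$admissions_arms), length(on), replace = TRUE,
                      prob = config$admissions_arms)
  }
  disch_after <- .rint(n, 3L, 10L)
  disch_after[arm == "los"] <- .rint(sum(arm == "los"), 14L, 35L)
  disch_after[arm == "death"] <- .rint(sum(arm == "death"), 2L, fu - 1L)
  admissions <- tibble::tibble(
    patient_id = pid,
    admit_date = sd - admit_offset,
    discharge_date = sd + disch_after,
    department = planted$department,
    died_in_hospital = arm == "death"
  )
  re_i <- which(arm == "readmission")
  if (length(re_i) > 0L) {
    r_admit <- .rint(length(re_i), disch_after[re_i] + 1L, fu - 1L)
    admissions <- dplyr::bind_rows(admissions, tibble::tibble(
      patient_id = pid[re_i],
      admit_date = sd[re_i] + r_admit,
      discharge_date = sd[re_i] + r_admit + .rint(length(re_i), 2L, 10L),
      department = planted$department[re_i],
      died_in_hospital = FALSE
    ))
  }
  od_i <- which(arm == "none" & stats::runif(n) < dr$other_dept_readmission)
  if (length(od_i) > 0L) {
    o_admit <- .rint(length(od_i), disch_after[od_i] + 1L, fu - 1L)
    admissions <- dplyr::bind_rows(admissions, tibble::tibble(
      patient_id = pid[od_i],
      admit_date = sd[od_i] + o_admit,
      discharge_date = sd[od_i] + o_admit + .rint(length(od_i), 2L, 10L),
      department = "internal medicine",
      died_in_hospital = FALSE
    ))
  }

  # --- reoperations ------------------------------------------------------
  set.seed(.stream_seed(seed, 4L))
  on <- which(planted$reoperation)
  reoperations <- tibble::tibble(
    patient_id = pid[on],
    procedure_date = sd[on] + .rint(length(on), 1L, fu - 1L),
    specialty = planted$specialty[on]
  )
  off <- which(!planted$reoperation)
  ws_i <- off[stats::runif(length(off)) < dr$wrong_specialty_reop]
  lt_i <- off[stats::runif(length(off)) < dr$late_reop]
  reoperations <- dplyr::bind_rows(
    reoperations,
    tibble::tibble(patient_id = pid[ws_i],
                   procedure_date = sd[ws_i] + .rint(length(ws_i), 1L, fu - 1L),
                   specialty = "orthopaedic surgery"),
    tibble::tibble(patient_id = pid[lt_i],
                   procedure_date = sd[lt_i] + .rint(length(lt_i), fu, fu + 15L),
                   specialty = planted$specialty[lt_i])
  )

  # --- radiology ---------------------------------------------------------
  set.seed(.stream_seed(seed, 5L))
  on <- which(planted$radiology)
  radiology <- tibble::tibble(
    patient_id = pid[on],
    order_date = sd[on] + .rint(length(on), 0L, fu - 1L),
    modality = "CT"
  )
  off <- which(!planted$radiology)
  nc_i <- off[stats::runif(length(off)) < dr$non_ct_order]
  pc_i <- off[stats::runif(length(off)) < dr$preop_ct]
  radiology <- dplyr::bind_rows(
    radiology,
    tibble::tibble(patient_id = pid[nc_i],
                   order_date = sd[nc_i] + .rint(length(nc_i), 0L, fu - 1L),
                   modality = sample(c("MR", "US", "XR"), length(nc_i),
                                     replace = TRUE)),
    tibble::tibble(patient_id = pid[pc_i],
                   order_date = sd[pc_i] - .rint(length(pc_i), 1L, 30L),
                   modality = "CT")
  )

  # --- antibiotics -------------------------------------------------------
  set.seed(.stream_seed(seed, 6L))
  j01 <- c("J01CA04", "J01CR02", "J01DH02", "J01MA02", "J01XD01")
  abx_run <- function(idx, start_after, len, codes) {
    if (length(idx) == 0L) {
      return(tibble::tibble(patient_id = character(),
                            administration_date = as.Date(character()),
                            atc_code = character()))
    }
    tibble::tibble(
      patient_id = rep(pid[idx], len),
      administration_date = rep(sd[idx] + start_after, len) +
        (sequence(len) - 1L),
      atc_code = rep(codes, len)
    )
  }
  on <- which(planted$antibiotics)
  len_on <- .rint(length(on), 3L, 7L)
  start_on <- .rint(length(on), 1L, fu - len_on)
  antibiotics <- abx_run(on, start_on, len_on,
                         sample(j01, length(on), replace = TRUE))
  off <- which(!planted$antibiotics)
  # prophylaxis: 1-3 days ending no later than day index 3, so at most two
  # administered days fall after the surgery day -- never a qualifying run,
  # even when merged with a scattered distractor day (those sit >= 3 apart)
  pr_i <- off[stats::runif(length(off)) < dr$prophylactic_abx]
  antibiotics <- dplyr::bind_rows(antibiotics, abx_run(
    pr_i, .rint(length(pr_i), -1L, 0L), .rint(length(pr_i), 1L, 3L),
    sample(j01, length(pr_i), replace = TRUE)))
  sc_i <- off[stats::runif(length(off)) < dr$scattered_abx]
  if (length(sc_i) > 0L) {
    grid <- seq(2L, fu - 1L, by = 3L)  # pairwise gaps >= 3 days: no runs
    k <- .rint(length(sc_i), 1L, 2L)
    days <- lapply(seq_along(sc_i), function(i) sample(grid, k[i]))
    antibiotics <- dplyr::bind_rows(antibiotics, tibble::tibble(
      patient_id = rep(pid[sc_i], k),
      administration_date = rep(sd[sc_i], k) + unlist(days),
      atc_code = sample(j01, sum(k), replace = TRUE)
    ))
  }
  nj_i <- off[stats::runif(length(off)) < dr$non_j01_abx]
  len_nj <- .rint(length(nj_i), 3L, 5L)
  antibiotics <- dplyr::bind_rows(antibiotics, abx_run(
    nj_i, .rint(length(nj_i), 2L, fu - 6L), len_nj,
    rep("J02AC01", length(nj_i))))

  # --- microbiology ------------------------------------------------------
  set.seed(.stream_seed(seed, 7L))
  on <- which(planted$microbiology)
  microbiology <- tibble::tibble(
    patient_id = pid[on],
    sample_date = sd[on] + .rint(length(on), 0L, fu - 1L),
    body_site = sample(default_relevant_sites(), length(on), replace = TRUE),
    relevant_site = TRUE
  )
  off <- which(!planted$microbiology)
  po_i <- off[stats::runif(length(off)) < dr$preop_culture]
  nr_i <- off[stats::runif(length(off)) < dr$nonrelevant_culture]
  microbiology <- dplyr::bind_rows(
    microbiology,
    tibble::tibble(patient_id = pid[po_i],
                   sample_date = sd[po_i] - .rint(length(po_i), 1L, 5L),
                   body_site = sample(default_relevant_sites(), length(po_i),
                                      replace = TRUE),
                   relevant_site = TRUE),
    tibble::tibble(patient_id = pid[nr_i],
                   sample_date = sd[nr_i] + .rint(length(nr_i), 0L, fu - 1L),
                   body_site = sample(c("urine", "nasopharynx", "sputum"),
                                      length(nr_i), replace = TRUE),
                   relevant_site = FALSE)
  )

  covs <- intersect(names(.ssi_schema$surgeries$optional), names(planted))
  surgeries <- planted[, c("surgery_id", "patient_id", "surgery_date",
                           "specialty", "department", covs)]
  reference <- tibble::tibble(
    surgery_id = planted$surgery_id,
    deep_ssi = planted$deep_ssi,
    annotator_id = "icp1"
  )
  ssi_cohort(surgeries = surgeries, admissions = admissions,
             reoperations = reoperations, radiology = radiology,
             antibiotics = antibiotics, microbiology = microbiology,
             reference = reference)
}

#' Simulate a full synthetic cohort (events plus planted truth)
#'
#' Convenience wrapper: [sample_cohort()] then [realize_events()].
#'
#' @inheritParams sample_cohort
#' @return A list with elements `cohort` (an [ssi_cohort()]) and `truth` (the
#'   `ssi_planted` tibble).
#' @export
simulate_cohort <- function(config = generator_config(), seed = 1L) {
  truth <- sample_cohort(config, seed)
  list(cohort = realize_events(truth, config, seed), truth = truth)
}

#' Simulate a second annotator for the double-annotated overlap
#'
#' Flips each reference label independently with the given disagreement
#' probability, emulating the second infection-control practitioner in a
#' double-annotation reliability exercise.
#'
#' @param reference Tibble with `surgery_id` and `deep_ssi`.
#' @param disagreement Per-item flip probability.
#' @param seed Integer seed.
#' @param annotator_id Label for the simulated annotator.
#' @return A tibble like `reference` with flipped labels and the new
#'   `annotator_id`.
#' @export
simulate_second_annotator <- function(reference, disagreement = 0.05,
                                      seed = 1L, annotator_id = "icp2") {
  stopifnot(disagreement >= 0, disagreement <= 1)
  ref <- tibble::as_tibble(reference)
  set.seed(.stream_seed(seed, 8L))
  flip <- stats::runif(nrow(ref)) < disagreement
  tibble::tibble(
    surgery_id = ref$surgery_id,
    deep_ssi = xor(ref$deep_ssi, flip),
    annotator_id = annotator_id
  )
}
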