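cfg <- surveillance_config()
d0 <- as.Date("2019-03-01")

empty_admissions <- tibble::tibble(
  patient_id = character(), admit_date = as.Date(character()),
  discharge_date = as.Date(character()), department = character(),
  died_in_hospital = logical())

adm <- function(patient = "P1", admit, discharge, department = "surgery A",
                died = FALSE) {
  tibble::tibble(patient_id = patient, admit_date = d0 + admit,
                 discharge_date = if (is.na(discharge)) as.Date(NA) else d0 + discharge,
                 department = department, died_in_hospital = died)
}

test_that("day_index anchors the surgery day at 1", {
  expect_identical(day_index(d0, d0), 1L)
  expect_identical(day_index(d0 + 44, d0), 45L)
  expect_identical(day_index(d0 - 1, d0), 0L)
})

test_that("admissions component: prolonged stay, open stays and window edges", {
  s <- fixture_surgery(date = d0)
  # discharge 20 days after surgery: prolonged stay
  expect_true(admissions_component(s, adm(admit = -1, discharge = 20), cfg))
  # discharge 5 days after surgery, nothing else
  expect_false(admissions_component(s, adm(admit = -1, discharge = 5), cfg))
  # exactly at the threshold counts
  expect_true(admissions_component(s, adm(admit = 0, discharge = 14), cfg))
  expect_false(admissions_component(s, adm(admit = 0, discharge = 13), cfg))
  # open discharge = still admitted
  expect_true(admissions_component(s, adm(admit = -1, discharge = NA), cfg))
  # counting from admission instead of surgery shifts the threshold
  cfg_adm <- surveillance_config(los_from = "admission")
  expect_true(admissions_component(s, adm(admit = -2, discharge = 12), cfg_adm))
  expect_false(admissions_component(s, adm(admit = -2, discharge = 12), cfg))
})

test_that("admissions component: readmission arm requires the original department", {
  s <- fixture_surgery(date = d0)
  same <- dplyr::bind_rows(adm(admit = -1, discharge = 5),
                           adm(admit = 12, discharge = 18))
  other <- dplyr::bind_rows(adm(admit = -1, discharge = 5),
                            adm(admit = 12, discharge = 18,
                                department = "internal medicine"))
  late <- dplyr::bind_rows(adm(admit = -1, discharge = 5),
                           adm(admit = 45, discharge = 50))  # day index 46
  expect_true(admissions_component(s, same, cfg))
  expect_false(admissions_component(s, other, cfg))
  expect_false(admissions_component(s, late, cfg))
})

test_that("admissions component: in-hospital death inside the window", {
  s <- fixture_surgery(date = d0)
  expect_true(admissions_component(s, adm(admit = -1, discharge = 9, died = TRUE), cfg))
  # death after the follow-up window is ignored (other department, so the
  # readmission arm stays quiet too)
  died_late <- adm(admit = 40, discharge = 50, died = TRUE,
                   department = "internal medicine")
  early <- dplyr::bind_rows(adm(admit = -1, discharge = 5), died_late)
  expect_false(admissions_component(s, early, cfg))
})

test_that("missing index admission warns and still evaluates the other arms", {
  s <- fixture_surgery(date = d0)
  readmit_only <- adm(admit = 10, discharge = 12)
  expect_warning(res <- admissions_component(s, readmit_only, cfg),
                 class = "ssi_no_index_admission")
  expect_true(res)
  expect_warning(res2 <- admissions_component(s, empty_admissions, cfg),
                 class = "ssi_no_index_admission")
  expect_false(res2)
})

test_that("reoperation component matches specialty and the day 2..45 window", {
  s <- fixture_surgery(date = d0)
  reop <- function(day, spec = "colorectal surgery") {
    tibble::tibble(patient_id = "P1", procedure_date = d0 + day, specialty = spec)
  }
  expect_true(reoperation_component(s, reop(8), cfg))     # day index 9
  expect_false(reoperation_component(s, reop(8, "orthopaedic surgery"), cfg))
  expect_false(reoperation_component(s, reop(45), cfg))   # day index 46
  expect_true(reoperation_component(s, reop(44), cfg))    # day index 45
  expect_false(reoperation_component(s, reop(0), cfg))    # the index procedure
})

test_that("radiology component needs a configured modality inside day 1..45", {
  s <- fixture_surgery(date = d0)
  ord <- function(day, modality = "CT") {
    tibble::tibble(patient_id = "P1", order_date = d0 + day, modality = modality)
  }
  expect_true(radiology_component(s, ord(2), cfg))
  expect_true(radiology_component(s, ord(0), cfg))          # surgery day = day 1
  expect_false(radiology_component(s, ord(2, "MR"), cfg))
  expect_false(radiology_component(s, ord(-1), cfg))        # pre-op
  expect_false(radiology_component(s, ord(45), cfg))        # day index 46
  cfg_mr <- surveillance_config(radiology_modalities = c("CT", "MR"))
  expect_true(radiology_component(s, ord(2, "MR"), cfg_mr))
})

test_that("antibiotics component: courses, prophylaxis exclusion, gaps, ATC filter", {
  s <- fixture_surgery(date = d0)
  abx <- function(days, atc = "J01CA04") {
    tibble::tibble(patient_id = "P1", administration_date = d0 + days,
                   atc_code = atc)
  }
  expect_true(antibiotics_component(s, abx(1:3), cfg))     # days 2-4
  expect_false(antibiotics_component(s, abx(0:2), cfg))    # starts on day 1
  expect_true(antibiotics_component(s, abx(0:3), cfg))     # days 2-4 remain
  expect_false(antibiotics_component(s, abx(c(1, 3, 5)), cfg))  # gaps
  expect_false(antibiotics_component(s, abx(1:3, "J02AC01"), cfg))
  # duplicate administrations on the same day still count once
  expect_true(antibiotics_component(s, abx(c(1, 1, 2, 2, 3)), cfg))
  # a later course qualifies even with prophylaxis present
  expect_true(antibiotics_component(s, abx(c(0, 1, 9, 10, 11)), cfg))
  # course straddling day 45 is truncated before the length test
  expect_true(antibiotics_component(s, abx(42:46), cfg))   # days 43-45 remain
  expect_false(antibiotics_component(s, abx(43:46), cfg))  # only 44-45 remain
})

test_that("antibiotics run detection agrees with a naive day-by-day scan", {
  set.seed(71)
  s <- fixture_surgery(date = d0)
  for (i in 1:1000) {
    days <- sort(sample(0:50, sample(0:12, 1)))
    tab <- tibble::tibble(patient_id = "P1",
                          administration_date = d0 + days - 1,  # day index = offset + 1
                          atc_code = "J01CA04")
    expect_identical(antibiotics_component(s, tab, cfg),
                     abx_scan_oracle(days),
                     info = paste(days, collapse = ","))
  }
})

test_that("microbiology component keeps the surgery day and drops earlier cultures", {
  s <- fixture_surgery(date = d0)
  cult <- function(day, relevant = TRUE) {
    tibble::tibble(patient_id = "P1", sample_date = d0 + day,
                   body_site = "abdominal", relevant_site = relevant)
  }
  expect_true(microbiology_component(s, cult(0), cfg))    # surgery day = day 1
  expect_false(microbiology_component(s, cult(-1), cfg))  # day 0
  expect_false(microbiology_component(s, cult(9, relevant = FALSE), cfg))
  expect_true(microbiology_component(s, cult(44), cfg))
  expect_false(microbiology_component(s, cult(45), cfg))
})

test_that("extract_components assembles per-component decisions with consistent counts", {
  cohort <- fixture_cohort()
  prof <- extract_components(cohort, cfg)
  expect_identical(prof$surgery_id, cohort$surgeries$surgery_id)
  # S1: prolonged stay, same-specialty reop day 10, CT day 4, J01 days 2-4,
  # abdominal culture day 6 -> all five
  expect_identical(unlist(prof[1, 2:6]), c(admissions = TRUE, reoperation = TRUE,
                                           radiology = TRUE, antibiotics = TRUE,
                                           microbiology = TRUE))
  # S2: 5-day stay, MR only -> nothing
  expect_identical(prof$count[2], 0L)
  # S3: 5-day stay, non-relevant culture -> nothing
  expect_identical(prof$count[3], 0L)
  expect_identical(prof$count, as.integer(rowSums(as.matrix(prof[2:6]))))
})

test_that("components are invariant under a common date translation", {
  sim <- simulate_cohort(generator_config(n_surgeries = 30L), seed = 5L)
  shift <- 370L
  shifted <- sim$cohort
  shifted$surgeries$surgery_date <- shifted$surgeries$surgery_date + shift
  shifted$admissions$admit_date <- shifted$admissions$admit_date + shift
  shifted$admissions$discharge_date <- shifted$admissions$discharge_date + shift
  shifted$reoperations$procedure_date <- shifted$reoperations$procedure_date + shift
  shifted$radiology$order_date <- shifted$radiology$order_date + shift
  shifted$antibiotics$administration_date <- shifted$antibiotics$administration_date + shift
  shifted$microbiology$sample_date <- shifted$microbiology$sample_date + shift
  expect_identical(extract_components(sim$cohort, cfg),
                   extract_components(shifted, cfg))
})

test_that("adding events never turns a true component false (monotonicity)", {
  sim <- simulate_cohort(generator_config(n_surgeries = 25L), seed = 9L)
  before <- extract_components(sim$cohort, cfg)
  more <- sim$cohort
  set.seed(13)
  pick <- sample(sim$cohort$surgeries$patient_id, 10)
  extra_days <- sample(0:44, 10, replace = TRUE)
  more$radiology <- dplyr::bind_rows(more$radiology, tibble::tibble(
    patient_id = pick,
    order_date = sim$cohort$surgeries$surgery_date[
      match(pick, sim$cohort$surgeries$patient_id)] + extra_days,
    modality = sample(c("CT", "MR"), 10, replace = TRUE)))
  more$microbiology <- dplyr::bind_rows(more$microbiology, tibble::tibble(
    patient_id = pick,
    sample_date = sim$cohort$surgeries$surgery_date[
      match(pick, sim$cohort$surgeries$patient_id)] + extra_days,
    body_site = "drain", relevant_site = TRUE))
  after <- extract_components(more, cfg)
  for (comp in c("admissions", "reoperation", "radiology", "antibiotics",
                 "microbiology")) {
    expect_true(all(after[[comp]] >= before[[comp]]), info = comp)
  }
})
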