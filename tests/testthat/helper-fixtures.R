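# A tiny hand-crafted cohort: three surgeries with contrasting event
# histories, used by the data-model and pipeline tests.

fixture_surgery <- function(id = "S1", patient = "P1", date = "2019-03-01",
                            specialty = "colorectal surgery",
                            department = "surgery A") {
  list(surgery_id = id, patient_id = patient, surgery_date = as.Date(date),
       specialty = specialty, department = department)
}

fixture_cohort <- function() {
  d0 <- as.Date("2019-03-01")
  surgeries <- tibble::tibble(
    surgery_id = c("S1", "S2", "S3"),
    patient_id = c("P1", "P2", "P3"),
    surgery_date = d0 + c(0, 10, 20),
    specialty = "colorectal surgery",
    department = c("surgery A", "surgery A", "surgery B")
  )
  admissions <- tibble::tibble(
    patient_id = c("P1", "P2", "P3"),
    admit_date = d0 + c(-1, 9, 19),
    discharge_date = d0 + c(20, 15, 25),   # P1 stays 20 days post-surgery
    department = c("surgery A", "surgery A", "surgery B"),
    died_in_hospital = FALSE
  )
  reoperations <- tibble::tibble(
    patient_id = "P1", procedure_date = d0 + 9,
    specialty = "colorectal surgery"
  )
  radiology <- tibble::tibble(
    patient_id = c("P1", "P2"), order_date = d0 + c(3, 12),
    modality = c("CT", "MR")
  )
  antibiotics <- tibble::tibble(
    patient_id = rep("P1", 3),
    administration_date = d0 + 1:3,        # days 2-4: qualifying course
    atc_code = "J01CA04"
  )
  microbiology <- tibble::tibble(
    patient_id = c("P1", "P3"), sample_date = d0 + c(5, 19),
    body_site = c("abdominal", "urine"),
    relevant_site = c(TRUE, FALSE)
  )
  reference <- tibble::tibble(
    surgery_id = c("S1", "S2", "S3"),
    deep_ssi = c(TRUE, FALSE, FALSE),
    annotator_id = "icp1"
  )
  ssi_cohort(surgeries, admissions, reoperations, radiology, antibiotics,
             microbiology, reference)
}

expect_cohort_equal <- function(a, b) {
  for (tab in names(a)) {
    testthat::expect_equal(as.data.frame(a[[tab]]), as.data.frame(b[[tab]]),
                           info = tab)
  }
}
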