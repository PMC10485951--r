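# Tabular data model: one tibble per record type, bundled in an `ssi_cohort`.
# All tables are keyed on opaque string identifiers and day-resolution dates.

.ssi_tables <- c("surgeries", "admissions", "reoperations", "radiology",
                 "antibiotics", "microbiology", "reference")

.ssi_schema <- list(
  surgeries = list(
    required = c(surgery_id = "character", patient_id = "character",
                 surgery_date = "Date", specialty = "character",
                 department = "character"),
    optional = c(age = "numeric", sex = "character", bmi = "numeric",
                 asa_class = "integer", wound_class = "character",
                 duration_minutes = "numeric", stoma = "logical",
                 primary = "logical", open = "logical", malignancy = "logical")
  ),
  admissions = list(
    required = c(patient_id = "character", admit_date = "Date",
                 discharge_date = "Date", department = "character",
                 died_in_hospital = "logical"),
    optional = c()
  ),
  reoperations = list(
    required = c(patient_id = "character", procedure_date = "Date",
                 specialty = "character"),
    optional = c()
  ),
  radiology = list(
    required = c(patient_id = "character", order_date = "Date",
                 modality = "character"),
    optional = c()
  ),
  antibiotics = list(
    required = c(patient_id = "character", administration_date = "Date",
                 atc_code = "character"),
    optional = c()
  ),
  microbiology = list(
    required = c(patient_id = "character", sample_date = "Date",
                 body_site = "character", relevant_site = "logical"),
    optional = c()
  ),
  reference = list(
    required = c(surgery_id = "character", deep_ssi = "logical",
                 annotator_id = "character"),
    optional = c()
  )
)

#' Body sites whose cultures count as relevant by default
#'
#' The microbiology component requires a culture "from a relevant body site".
#' The source rule sets do not enumerate these sites, so the package ships an
#' editable default: sites plausibly sampled when a deep or organ/space
#' infection after colorectal surgery is suspected. Cultures from any other
#' site are kept in the data but never satisfy the component unless their
#' `relevant_site` flag is set explicitly in the input.
#'
#' @return A character vector of body-site labels.
#' @export
default_relevant_sites <- function() {
  c("abdominal", "pelvic", "wound", "drain", "blood")
}

.coerce_col <- function(x, type) {
  switch(type,
    character = as.character(x),
    Date = if (inherits(x, "Date")) x else as.Date(x, format = "%Y-%m-%d"),
    logical = if (is.logical(x)) x else as.logical(x),
    integer = as.integer(x),
    numeric = as.numeric(x),
    x
  )
}

.coerce_table <- function(df, name) {
  sch <- .ssi_schema[[name]]
  df <- tibble::as_tibble(df)
  missing <- setdiff(names(sch$required), names(df))
  if (name == "microbiology" && "relevant_site" %in% missing &&
      "body_site" %in% names(df)) {
    df$relevant_site <- tolower(df$body_site) %in% default_relevant_sites()
    missing <- setdiff(missing, "relevant_site")
  }
  if (length(missing) > 0L) {
    rlang::abort(sprintf("Table `%s` is missing required column(s): %s",
                         name, paste(missing, collapse = ", ")))
  }
  for (col in names(sch$required)) {
    df[[col]] <- .coerce_col(df[[col]], sch$required[[col]])
  }
  for (col in intersect(names(sch$optional), names(df))) {
    df[[col]] <- .coerce_col(df[[col]], sch$optional[[col]])
  }
  df
}

.empty_table <- function(name) {
  sch <- .ssi_schema[[name]]
  cols <- lapply(sch$required, function(type) {
    switch(type, character = character(), Date = as.Date(character()),
           logical = logical(), integer = integer(), numeric = numeric())
  })
  tibble::as_tibble(cols)
}

#' Assemble a surveillance cohort from its component tables
#'
#' Bundles the surgery roster, the six event streams and the reference-standard
#' annotations into a single validated container. Column types are coerced
#' (ISO-8601 strings to dates, 0/1 or TRUE/FALSE to logicals); structural
#' problems such as a missing required column raise immediately, while
#' record-level invariant violations are reported by [validate_ssi_cohort()].
#'
#' @param surgeries Data frame of index surgeries: `surgery_id`, `patient_id`,
#'   `surgery_date`, `specialty`, `department`, plus optional descriptive
#'   covariates (`age`, `sex`, `bmi`, `asa_class`, `wound_class`,
#'   `duration_minutes`, `stoma`, `primary`, `open`, `malignancy`). Covariates
#'   are carried through untouched; no computation uses them.
#' @param admissions Hospital episodes: `patient_id`, `admit_date`,
#'   `discharge_date` (may be `NA` for an open stay), `department`,
#'   `died_in_hospital`. An in-hospital death is dated by the episode's
#'   discharge date.
#' @param reoperations `patient_id`, `procedure_date`, `specialty`.
#' @param radiology `patient_id`, `order_date`, `modality`.
#' @param antibiotics `patient_id`, `administration_date`, `atc_code`.
#' @param microbiology `patient_id`, `sample_date`, `body_site`,
#'   `relevant_site` (derived from `body_site` via
#'   [default_relevant_sites()] when absent).
#' @param reference Reference-standard annotations: `surgery_id`, `deep_ssi`,
#'   `annotator_id`.
#'
#' @return An object of class `ssi_cohort`: a named list of tibbles.
#' @seealso [read_ssi_cohort()], [validate_ssi_cohort()]
#' @export
ssi_cohort <- function(surgeries,
                       admissions = .empty_table("admissions"),
                       reoperations = .empty_table("reoperations"),
                       radiology = .empty_table("radiology"),
                       antibiotics = .empty_table("antibiotics"),
                       microbiology = .empty_table("microbiology"),
                       reference = .empty_table("reference")) {
  tables <- list(surgeries = surgeries, admissions = admissions,
                 reoperations = reoperations, radiology = radiology,
                 antibiotics = antibiotics, microbiology = microbiology,
                 reference = reference)
  tables <- Map(.coerce_table, tables, names(tables))
  structure(tables, class = "ssi_cohort")
}

#' @export
print.ssi_cohort <- function(x, ...) {
  cat("<ssi_cohort>\n")
  cat(sprintf("  %d surgeries (%d patients), %d reference annotations\n",
              nrow(x$surgeries), length(unique(x$surgeries$patient_id)),
              nrow(x$reference)))
  for (tab in c("admissions", "reoperations", "radiology", "antibiotics",
                "microbiology")) {
    cat(sprintf("  %-12s %d events\n", tab, nrow(x[[tab]])))
  }
  invisible(x)
}

.issue <- function(severity, table, row, field, message) {
  tibble::tibble(severity = severity, table = table, row = as.integer(row),
                 field = field, message = message)
}

#' Check a cohort against its record-level invariants
#'
#' Returns issues rather than raising, so a data manager can review every
#' problem in one pass. Checked invariants: unique non-missing surgery
#' identifiers and valid surgery dates; discharge on or after admission; dated
#' in-hospital deaths; non-empty ATC codes; valid event dates; every event
#' `patient_id` and every reference `surgery_id` resolvable against the
#' surgery roster; at most one annotation per surgery and annotator.
#'
#' The result is independent of the row order of the input tables (issues are
#' sorted by table, row and field).
#'
#' @param cohort An [ssi_cohort()].
#' @return A tibble with columns `severity` (`"error"` or `"warning"`),
#'   `table`, `row`, `field`, `message`; zero rows when the cohort is valid.
#' @export
validate_ssi_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "ssi_cohort"))
  issues <- list()
  add <- function(...) issues[[length(issues) + 1L]] <<- .issue(...)

  surg <- cohort$surgeries
  dup <- which(duplicated(surg$surgery_id))
  for (i in dup) {
    add("error", "surgeries", i, "surgery_id",
        sprintf("duplicate surgery_id '%s'", surg$surgery_id[i]))
  }
  for (i in which(is.na(surg$surgery_id) | !nzchar(surg$surgery_id))) {
    add("error", "surgeries", i, "surgery_id", "missing surgery_id")
  }
  for (i in which(is.na(surg$surgery_date))) {
    add("error", "surgeries", i, "surgery_date", "invalid or missing surgery_date")
  }

  adm <- cohort$admissions
  bad <- which(!is.na(adm$discharge_date) & !is.na(adm$admit_date) &
                 adm$discharge_date < adm$admit_date)
  for (i in bad) {
    add("error", "admissions", i, "discharge_date",
        sprintf("discharge_date %s precedes admit_date %s",
                adm$discharge_date[i], adm$admit_date[i]))
  }
  for (i in which(isTRUE_v(adm$died_in_hospital) & is.na(adm$discharge_date))) {
    add("warning", "admissions", i, "discharge_date",
        "in-hospital death without a discharge (death) date; mortality arm cannot date it")
  }

  abx <- cohort$antibiotics
  for (i in which(is.na(abx$atc_code) | !nzchar(abx$atc_code))) {
    add("error", "antibiotics", i, "atc_code", "empty atc_code")
  }

  date_cols <- c(admissions = "admit_date", reoperations = "procedure_date",
                 radiology = "order_date", antibiotics = "administration_date",
                 microbiology = "sample_date")
  for (tab in names(date_cols)) {
    col <- date_cols[[tab]]
    for (i in which(is.na(cohort[[tab]][[col]]))) {
      add("error", tab, i, col, sprintf("invalid or missing %s", col))
    }
  }

  known_patients <- unique(surg$patient_id)
  for (tab in c("admissions", "reoperations", "radiology", "antibiotics",
                "microbiology")) {
    pid <- cohort[[tab]]$patient_id
    for (i in which(!pid %in% known_patients)) {
      add("error", tab, i, "patient_id",
          sprintf("patient_id '%s' matches no surgery", pid[i]))
    }
  }

  ref <- cohort$reference
  for (i in which(!ref$surgery_id %in% surg$surgery_id)) {
    add("error", "reference", i, "surgery_id",
        sprintf("annotation for unknown surgery_id '%s'", ref$surgery_id[i]))
  }
  key <- paste(ref$surgery_id, ref$annotator_id, sep = "\r")
  for (i in which(duplicated(key))) {
    add("error", "reference", i, "surgery_id",
        sprintf("duplicate annotation for surgery '%s' by annotator '%s'",
                ref$surgery_id[i], ref$annotator_id[i]))
  }

  if (length(issues) == 0L) {
    return(.issue(character(0), character(0), integer(0), character(0),
                  character(0))[0, ])
  }
  out <- dplyr::bind_rows(issues)
  dplyr::arrange(out, .data$table, .data$row, .data$field)
}

isTRUE_v <- function(x) !is.na(x) & x

.cohort_filenames <- c(surgeries = "surgeries.csv", admissions = "admissions.csv",
                       reoperations = "reoperations.csv", radiology = "radiology.csv",
                       antibiotics = "antibiotics.csv",
                       microbiology = "microbiology.csv", reference = "reference.csv")

.read_table_csv <- function(path, name) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Required input file not found: %s", path))
  }
  sch <- .ssi_schema[[name]]
  types <- c(sch$required, sch$optional)
  hdr <- names(readr::read_csv(path, n_max = 0,
                               col_types = readr::cols(.default = readr::col_character()),
                               progress = FALSE))
  types <- types[intersect(names(types), hdr)]
  spec <- do.call(readr::cols, c(
    lapply(types, function(type) {
      switch(type,
        character = readr::col_character(),
        Date = readr::col_date(format = "%Y-%m-%d"),
        logical = readr::col_logical(),
        integer = readr::col_integer(),
        numeric = readr::col_double())
    }),
    list(.default = readr::col_character())
  ))
  df <- readr::read_csv(path, col_types = spec, progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0L) {
    p <- probs[1L, ]
    rlang::abort(sprintf(
      "Malformed row in %s: line %d, column %d (expected %s, got '%s'); %d problem(s) in total.",
      path, p$row, p$col, p$expected, p$actual, nrow(probs)))
  }
  df
}

#' Read a surveillance cohort from CSV tables
#'
#' Reads the seven standard tables (`surgeries.csv`, `admissions.csv`,
#' `reoperations.csv`, `radiology.csv`, `antibiotics.csv`, `microbiology.csv`,
#' `reference.csv`) from a directory, validates them, and returns an
#' [ssi_cohort()]. Files are UTF-8 CSV with a header row and ISO-8601 dates.
#' A missing file or a malformed row is fatal; record-level invariant
#' violations of severity `"error"` abort with the full issue listing.
#'
#' An optional `deaths.csv` (`patient_id`, `death_date`) is folded into the
#' admission episodes: the episode containing the death date gets
#' `died_in_hospital = TRUE` and its discharge date set to the death date,
#' since the mortality arm dates a death by its episode's discharge.
#'
#' @param dir Directory containing the CSV tables.
#' @param paths Optional named character vector overriding individual file
#'   locations (names among `surgeries`, `admissions`, `reoperations`,
#'   `radiology`, `antibiotics`, `microbiology`, `reference`, `deaths`).
#' @return A validated `ssi_cohort`.
#' @export
read_ssi_cohort <- function(dir = ".", paths = NULL) {
  locs <- file.path(dir, .cohort_filenames)
  names(locs) <- names(.cohort_filenames)
  death_path <- file.path(dir, "deaths.csv")
  if (!is.null(paths)) {
    for (nm in names(paths)) {
      if (nm == "deaths") death_path <- paths[[nm]] else locs[[nm]] <- paths[[nm]]
    }
  }
  tables <- Map(.read_table_csv, locs, names(locs))
  if (file.exists(death_path)) {
    deaths <- readr::read_csv(
      death_path,
      col_types = readr::cols(patient_id = readr::col_character(),
                              death_date = readr::col_date(format = "%Y-%m-%d")),
      progress = FALSE)
    tables$admissions <- .join_deaths(tables$admissions, deaths)
  }
  cohort <- do.call(ssi_cohort, tables)
  issues <- validate_ssi_cohort(cohort)
  errs <- issues[issues$severity == "error", ]
  if (nrow(errs) > 0L) {
    msgs <- sprintf("%s row %d [%s]: %s", errs$table, errs$row, errs$field,
                    errs$message)
    rlang::abort(c("Cohort validation failed:",
                   stats::setNames(utils::head(msgs, 10L),
                                   rep("x", min(nrow(errs), 10L)))))
  }
  cohort
}

.join_deaths <- function(admissions, deaths) {
  for (i in seq_len(nrow(deaths))) {
    pid <- deaths$patient_id[i]
    dd <- deaths$death_date[i]
    cand <- which(admissions$patient_id == pid &
                    admissions$admit_date <= dd &
                    (is.na(admissions$discharge_date) |
                       admissions$discharge_date >= dd))
    if (length(cand) == 0L) {
      warning(sprintf("death of patient '%s' on %s matches no admission episode",
                      pid, dd), call. = FALSE)
      next
    }
    j <- cand[which.max(as.integer(admissions$admit_date[cand]))]
    admissions$died_in_hospital[j] <- TRUE
    admissions$discharge_date[j] <- dd
  }
  admissions
}

#' Write a surveillance cohort to CSV tables
#'
#' Inverse of [read_ssi_cohort()]: writes the seven standard CSV tables into
#' `dir`. `read_ssi_cohort(dir)` on the result reproduces the cohort
#' field-for-field.
#'
#' @param cohort An [ssi_cohort()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_ssi_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ssi_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(.cohort_filenames)) {
    readr::write_csv(cohort[[nm]], file.path(dir, .cohort_filenames[[nm]]),
                     na = "")
  }
  invisible(dir)
}
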