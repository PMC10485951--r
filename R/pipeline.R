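# End-to-end orchestration: read -> extract -> classify (each rule) ->
# evaluate -> render. Each stage is an exported function with a CSV contract,
# so any stage can be run and inspected on its own; rounding happens only at
# render time.

#' Configure a surveillance pipeline run
#'
#' @param input_dir Directory holding the cohort CSV tables (see
#'   [read_ssi_cohort()]).
#' @param output_dir Directory for artifacts (`components.csv`,
#'   `classifications.csv`, `report.json`, `report.md`); `NULL` writes
#'   nothing and only returns the reports.
#' @param rules List of rules: [ssi_rule()] objects, built-in names
#'   (`"original"`, `"adapted"`), or paths to rule files. At least one.
#' @param window A [surveillance_config()].
#' @param level Confidence level for Wilson intervals (default 0.95).
#' @param annotator Reference annotator to score against; `NULL` picks the
#'   annotator covering the most surgeries (ties broken alphabetically).
#' @return An object of class `ssi_pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir = NULL,
                            rules = list("original", "adapted"),
                            window = surveillance_config(), level = 0.95,
                            annotator = NULL) {
  if (length(rules) < 1L) {
    rlang::abort("At least one classification rule is required.")
  }
  resolve <- function(r) {
    if (inherits(r, "ssi_rule")) return(r)
    if (is.character(r) && length(r) == 1L) {
      if (file.exists(r) && grepl("\\.(ya?ml|json)$", r)) return(read_rule(r))
      return(builtin_rule(r))
    }
    rlang::abort("Each rule must be an ssi_rule, a built-in name, or a rule file path.")
  }
  rules <- lapply(rules, resolve)
  nms <- vapply(rules, function(r) r$name, character(1))
  if (anyDuplicated(nms)) rlang::abort("Rule names must be unique.")
  stopifnot(inherits(window, "ssi_config"), level > 0, level < 1)
  structure(list(input_dir = input_dir, output_dir = output_dir, rules = rules,
                 window = window, level = level, annotator = annotator),
            class = "ssi_pipeline_config")
}

.pick_annotator <- function(reference, annotator = NULL) {
  if (nrow(reference) == 0L) {
    rlang::abort("The reference table is empty; nothing to evaluate against.")
  }
  if (is.null(annotator)) {
    tab <- sort(table(reference$annotator_id), decreasing = TRUE)
    annotator <- names(tab)[tab == max(tab)]
    annotator <- sort(annotator)[1L]
  }
  out <- reference[reference$annotator_id == annotator, , drop = FALSE]
  if (nrow(out) == 0L) {
    rlang::abort(sprintf("No reference annotations by annotator '%s'.", annotator))
  }
  out
}

#' Run the full surveillance pipeline
#'
#' Reads and validates the cohort, extracts the five-component profiles,
#' classifies every surgery under each configured rule, and scores each rule
#' against the reference standard. With an `output_dir`, writes
#' `components.csv`, `classifications.csv`, `report.json` (full precision)
#' and `report.md` (rendered table). Repeated runs on identical inputs
#' produce byte-identical artifacts.
#'
#' @param config An [pipeline_config()] object.
#' @return A named list of [diagnostic_performance()] reports, one per rule,
#'   invisibly when `output_dir` is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ssi_pipeline_config"))
  cohort <- read_ssi_cohort(config$input_dir)
  profiles <- extract_components(cohort, config$window)
  ref <- .pick_annotator(cohort$reference, config$annotator)

  classifications <- list()
  reports <- list()
  for (rule in config$rules) {
    cls <- classify_surgeries(profiles, rule)
    classifications[[rule$name]] <- cls
    counts <- confusion_matrix(cls, ref[, c("surgery_id", "deep_ssi")])
    reports[[rule$name]] <- diagnostic_performance(counts, config$level,
                                                   algorithm = rule$name)
  }

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(profiles, file.path(config$output_dir, "components.csv"))
    readr::write_csv(dplyr::bind_rows(classifications),
                     file.path(config$output_dir, "classifications.csv"))
    rendered <- render_report(reports)
    writeLines(rendered$json, file.path(config$output_dir, "report.json"))
    writeLines(rendered$text, file.path(config$output_dir, "report.md"))
    return(invisible(reports))
  }
  reports
}

.fmt_pct <- function(x, digits = 1) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"),
                                 round_half_up(100 * x, digits)))
}

#' Render performance reports as a table and JSON
#'
#' The text table carries one row per algorithm with the confusion counts,
#' the four metrics as `point (lower-upper)` percentages rounded half up to
#' one decimal, and the percent workload reduction. The JSON document carries
#' the same quantities at full double precision; rounding happens only in the
#' text rendering.
#'
#' @param reports A list of [diagnostic_performance()] objects.
#' @return A list with `text` (character vector of lines, markdown table) and
#'   `json` (a JSON string).
#' @export
render_report <- function(reports) {
  if (inherits(reports, "ssi_performance")) reports <- list(reports)
  if (length(reports) < 1L) rlang::abort("Need at least one performance report.")
  stopifnot(all(vapply(reports, inherits, logical(1), "ssi_performance")))

  ci_cell <- function(met, nm) {
    row <- met[met$metric == nm, ]
    if (row$undefined) return("undefined")
    sprintf("%s (%s–%s)", .fmt_pct(row$estimate), .fmt_pct(row$lower),
            .fmt_pct(row$upper))
  }
  level_pct <- .fmt_pct(reports[[1L]]$level, 0)
  header <- c("Algorithm", "TP", "FP", "FN", "TN",
              sprintf("Sensitivity, %% (%s%%CI)", level_pct),
              sprintf("Specificity, %% (%s%%CI)", level_pct),
              sprintf("PPV, %% (%s%%CI)", level_pct),
              sprintf("NPV, %% (%s%%CI)", level_pct),
              "% workload reduction")
  rows <- lapply(reports, function(r) {
    c(r$algorithm, r$counts$tp, r$counts$fp, r$counts$fn, r$counts$tn,
      ci_cell(r$metrics, "sensitivity"), ci_cell(r$metrics, "specificity"),
      ci_cell(r$metrics, "ppv"), ci_cell(r$metrics, "npv"),
      .fmt_pct(r$workload_reduction))
  })
  mat <- do.call(rbind, c(list(header), rows))
  widths <- apply(nchar(mat, type = "width"), 2L, max)
  pad <- function(v) paste(mapply(formatC, v, width = widths,
                                  MoreArgs = list(flag = "-")), collapse = " | ")
  text <- c(paste("|", pad(header), "|"),
            paste("|", paste(mapply(strrep, "-", widths), collapse = " | "), "|"),
            vapply(rows, function(r) paste("|", pad(r), "|"), character(1)))

  json_payload <- lapply(reports, function(r) {
    list(
      algorithm = r$algorithm,
      counts = list(tp = r$counts$tp, fp = r$counts$fp, fn = r$counts$fn,
                    tn = r$counts$tn, n = r$counts$n),
      metrics = lapply(split(r$metrics, r$metrics$metric)[unique(r$metrics$metric)],
                       function(m) list(estimate = m$estimate, lower = m$lower,
                                        upper = m$upper,
                                        undefined = m$undefined)),
      workload_reduction = r$workload_reduction,
      level = r$level
    )
  })
  names(json_payload) <- NULL
  json <- jsonlite::toJSON(json_payload, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null", pretty = TRUE)
  list(text = text, json = as.character(json))
}
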