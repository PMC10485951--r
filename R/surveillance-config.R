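#' Surveillance window configuration
#'
#' Bundles every temporal parameter of the component definitions. All windows
#' are expressed on a day-index scale anchored at the surgery: the surgery day
#' is day 1, the day before surgery is day 0, and the follow-up (FU) window
#' runs from day 1 through `fu_days` inclusive.
#'
#' @param fu_days Length of the follow-up window in days (default 45): the
#'   last day index on which an event can still contribute to a component.
#' @param ssi_window_days Reference-standard window in days (default 30).
#'   Documentation only: the chart-review outcome is annotated within this
#'   window, but no component computation uses it.
#' @param los_threshold_days Minimum surgery-to-discharge stay, in days, for
#'   the prolonged length-of-stay arm of the admissions component (default 14).
#' @param abx_min_consecutive_days Minimum number of consecutive calendar days
#'   of systemic antibiotic administration for the antibiotics component
#'   (default 3).
#' @param abx_earliest_start_day Earliest day index on which a qualifying
#'   antibiotic course may start (default 2, i.e. strictly after the surgery
#'   day; courses starting on or before the surgery day are read as
#'   perioperative prophylaxis and never qualify).
#' @param culture_earliest_day Earliest day index of a qualifying microbiology
#'   culture (default 1: the surgery day counts, any earlier day does not).
#' @param abx_atc_prefix ATC code prefix identifying systemic antibacterials
#'   (default `"J01"`); matching is by prefix.
#' @param radiology_modalities Character vector of imaging modalities that
#'   satisfy the radiology component (default `"CT"`).
#' @param los_from Whether the length-of-stay arm counts days from the
#'   `"surgery"` date (default) or from the index `"admission"` date. The
#'   source rule sets do not state which anchor was used; surveillance here is
#'   anchored at the surgery.
#'
#' @return An object of class `ssi_config` (a named list).
#' @examples
#' cfg <- surveillance_config()
#' cfg$fu_days
#' @export
surveillance_config <- function(fu_days = 45L,
                                ssi_window_days = 30L,
                                los_threshold_days = 14L,
                                abx_min_consecutive_days = 3L,
                                abx_earliest_start_day = 2L,
                                culture_earliest_day = 1L,
                                abx_atc_prefix = "J01",
                                radiology_modalities = "CT",
                                los_from = c("surgery", "admission")) {
  los_from <- match.arg(los_from)
  cfg <- list(
    fu_days = as.integer(fu_days),
    ssi_window_days = as.integer(ssi_window_days),
    los_threshold_days = as.integer(los_threshold_days),
    abx_min_consecutive_days = as.integer(abx_min_consecutive_days),
    abx_earliest_start_day = as.integer(abx_earliest_start_day),
    culture_earliest_day = as.integer(culture_earliest_day),
    abx_atc_prefix = as.character(abx_atc_prefix),
    radiology_modalities = as.character(radiology_modalities),
    los_from = los_from
  )
  day_fields <- c("fu_days", "ssi_window_days", "los_threshold_days",
                  "abx_min_consecutive_days", "abx_earliest_start_day",
                  "culture_earliest_day")
  for (f in day_fields) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 0L) {
      rlang::abort(sprintf("`%s` must be a single non-negative day count.", f))
    }
  }
  if (cfg$fu_days < cfg$ssi_window_days) {
    rlang::abort("`fu_days` must be at least `ssi_window_days`.")
  }
  if (!nzchar(cfg$abx_atc_prefix)) {
    rlang::abort("`abx_atc_prefix` must be a non-empty string.")
  }
  if (length(cfg$radiology_modalities) < 1L) {
    rlang::abort("`radiology_modalities` must name at least one modality.")
  }
  structure(cfg, class = "ssi_config")
}

#' @export
print.ssi_config <- function(x, ...) {
  cat("<ssi_config>\n")
  cat(sprintf("  follow-up window: day 1..%d (surgery day = day 1)\n", x$fu_days))
  cat(sprintf("  LOS threshold: >= %d days from %s\n", x$los_threshold_days, x$los_from))
  cat(sprintf("  antibiotics: >= %d consecutive days, ATC '%s*', start day >= %d\n",
              x$abx_min_consecutive_days, x$abx_atc_prefix, x$abx_earliest_start_day))
  cat(sprintf("  cultures: relevant site, day >= %d\n", x$culture_earliest_day))
  cat(sprintf("  radiology modalities: %s\n", paste(x$radiology_modalities, collapse = ", ")))
  invisible(x)
}

#' Read or write a surveillance configuration as YAML
#'
#' @param path File path; format is YAML (a JSON file parses too, since JSON
#'   is a YAML subset).
#' @return `read_surveillance_config()` returns an `ssi_config`;
#'   `write_surveillance_config()` returns `path` invisibly.
#' @export
read_surveillance_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(surveillance_config))
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0L) {
    rlang::abort(sprintf("Unknown surveillance config field(s): %s",
                         paste(extra, collapse = ", ")))
  }
  do.call(surveillance_config, vals)
}

#' @rdname read_surveillance_config
#' @param config An `ssi_config` object.
#' @export
write_surveillance_config <- function(config, path) {
  stopifnot(inherits(config, "ssi_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
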