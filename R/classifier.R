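# Declarative high/low probability rules over component profiles. A rule is
# (required set, optional set, minimum optional count): high iff every
# required component is present and at least `min_optional` of the optional
# components are present. Both published rule sets are expressible this way.

#' Define a classification rule
#'
#' A surgery is classified *high probability* of deep SSI when all `required`
#' components are present and at least `min_optional` of the `optional`
#' components are present; otherwise *low probability*. Low-probability
#' surgeries are exempt from manual record review in the semi-automated
#' design, so the rule trades sensitivity against review workload.
#'
#' @param name Rule name (used in outputs).
#' @param required Character vector of components that must all be present.
#' @param optional Character vector of components counted toward
#'   `min_optional`; must be disjoint from `required`.
#' @param min_optional Minimum number of present optional components
#'   (`0 <= min_optional <= length(optional)`).
#' @return An object of class `ssi_rule`.
#' @seealso [builtin_rule()] for the two shipped rule sets.
#' @examples
#' ssi_rule("culture_plus_one", required = "microbiology",
#'          optional = c("admissions", "reoperation", "radiology", "antibiotics"),
#'          min_optional = 1)
#' @export
ssi_rule <- function(name, required = character(), optional = character(),
                     min_optional = 0L) {
  required <- as.character(required)
  optional <- as.character(optional)
  min_optional <- as.integer(min_optional)
  bad <- setdiff(c(required, optional), .component_names)
  if (length(bad) > 0L) {
    rlang::abort(sprintf("Unknown component name(s): %s. Components are: %s.",
                         paste(bad, collapse = ", "),
                         paste(.component_names, collapse = ", ")))
  }
  if (length(intersect(required, optional)) > 0L) {
    rlang::abort("`required` and `optional` must be disjoint.")
  }
  if (anyDuplicated(required) || anyDuplicated(optional)) {
    rlang::abort("Component names may not repeat within a set.")
  }
  if (is.na(min_optional) || min_optional < 0L || min_optional > length(optional)) {
    rlang::abort(sprintf(
      "`min_optional` must lie in 0..%d (the size of `optional`); got %s.",
      length(optional), min_optional))
  }
  structure(list(name = as.character(name), required = required,
                 optional = optional, min_optional = min_optional),
            class = "ssi_rule")
}

#' @export
print.ssi_rule <- function(x, ...) {
  fmt <- function(v) if (length(v) == 0L) "(none)" else paste(v, collapse = ", ")
  cat(sprintf("<ssi_rule> %s\n  required: %s\n  optional (>= %d of): %s\n",
              x$name, fmt(x$required), x$min_optional, fmt(x$optional)))
  invisible(x)
}

#' The two built-in classification rules
#'
#' `"original"` requires the microbiology component (a relevant-site culture)
#' plus at least one of the other four components; microbiology is thereby
#' necessary but not sufficient. `"adapted"` drops the microbiology component
#' entirely and requires at least two of the remaining four. The exact branch
#' structure of the source flow diagrams is not published as a formula; these
#' threshold forms reproduce the classifications the validation study reports
#' (in particular, SSI cases with 2-3 components but no culture are high
#' under the adapted rule and low under the original, and a zero-component
#' case is low under both). Users who need a different branch structure can
#' encode it via [ssi_rule()] or a rule file.
#'
#' @param name `"original"` or `"adapted"`.
#' @return An `ssi_rule`.
#' @export
builtin_rule <- function(name) {
  others <- setdiff(.component_names, "microbiology")
  switch(name,
    original = ssi_rule("original", required = "microbiology",
                        optional = others, min_optional = 1L),
    adapted = ssi_rule("adapted", required = character(),
                       optional = others, min_optional = 2L),
    rlang::abort(sprintf(
      "Unknown rule '%s'. Available built-in rules: original, adapted.", name))
  )
}

.as_rule <- function(rule) {
  if (inherits(rule, "ssi_rule")) rule
  else if (is.character(rule) && length(rule) == 1L) builtin_rule(rule)
  else rlang::abort("`rule` must be an ssi_rule or a built-in rule name.")
}

#' Read a classification rule from a YAML or JSON file
#'
#' The file carries `name`, `required`, `optional` and `min_optional`, e.g.
#' `{name: custom, required: [microbiology], optional: [radiology], min_optional: 1}`.
#'
#' @param path File path.
#' @return An `ssi_rule`.
#' @export
read_rule <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- c("name", "required", "optional", "min_optional")
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0L) {
    rlang::abort(sprintf("Unknown rule field(s): %s", paste(extra, collapse = ", ")))
  }
  if (is.null(vals$name)) rlang::abort("Rule file must carry a `name`.")
  do.call(ssi_rule, vals)
}

#' Classify one component profile
#'
#' @param profile A one-row data frame or named list with logical entries for
#'   the five components (`admissions`, `reoperation`, `radiology`,
#'   `antibiotics`, `microbiology`).
#' @param rule An [ssi_rule()] or built-in rule name.
#' @return `"high"` or `"low"`.
#' @export
classify_profile <- function(profile, rule) {
  rule <- .as_rule(rule)
  p <- .one_row(profile)
  vals <- vapply(.component_names, function(nm) isTRUE(p[[nm]]), logical(1))
  req_ok <- all(vals[rule$required])
  opt_ok <- sum(vals[rule$optional]) >= rule$min_optional
  if (req_ok && opt_ok) "high" else "low"
}

#' Classify every surgery in a component table
#'
#' Applies a rule to each row of a component table (as produced by
#' [extract_components()]), preserving the input order.
#'
#' @param profiles Tibble with `surgery_id` and the five logical component
#'   columns.
#' @param rule An [ssi_rule()] or built-in rule name (`"original"`,
#'   `"adapted"`).
#' @return A tibble `surgery_id`, `algorithm`, `probability_class`
#'   (factor with levels `low`, `high`).
#' @export
classify_surgeries <- function(profiles, rule) {
  rule <- .as_rule(rule)
  profiles <- tibble::as_tibble(profiles)
  need <- c("surgery_id", .component_names)
  missing <- setdiff(need, names(profiles))
  if (length(missing) > 0L) {
    rlang::abort(sprintf("`profiles` is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(profiles$surgery_id)) {
    dup <- unique(profiles$surgery_id[duplicated(profiles$surgery_id)])
    rlang::abort(sprintf("Duplicate surgery_id in profiles: %s",
                         paste(utils::head(dup, 5L), collapse = ", ")))
  }
  n <- nrow(profiles)
  req_ok <- rep(TRUE, n)
  for (nm in rule$required) req_ok <- req_ok & isTRUE_v(profiles[[nm]])
  opt_n <- rep(0L, n)
  for (nm in rule$optional) opt_n <- opt_n + as.integer(isTRUE_v(profiles[[nm]]))
  high <- req_ok & opt_n >= rule$min_optional
  tibble::tibble(
    surgery_id = profiles$surgery_id,
    algorithm = rule$name,
    probability_class = factor(ifelse(high, "high", "low"),
                               levels = c("low", "high"))
  )
}
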