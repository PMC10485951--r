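# Diagnostic performance of a high/low classification against the
# chart-review reference standard: confusion counts, sensitivity /
# specificity / PPV / NPV with Wilson score intervals, workload reduction,
# and two-rater agreement (Cohen's kappa) for the annotation overlap.

#' Wilson score confidence interval for a binomial proportion
#'
#' Inverts the score test: with `phat = k/n` and `z` the standard-normal
#' quantile at `(1 + level)/2`, the interval is
#' `(phat + z^2/2n)/(1 + z^2/n)  +/-  z * sqrt(phat(1-phat)/n + z^2/4n^2)/(1 + z^2/n)`.
#' Unlike the Wald interval it is well behaved near 0 and 1; the bounds are
#' clamped so `k = 0` gives a lower bound of exactly 0 and `k = n` an upper
#' bound of exactly 1. The quantile is used at full double precision, not
#' rounded to 1.96.
#'
#' @param successes,n Integer vectors (recycled): number of successes and
#'   number of trials; `0 <= successes <= n`, `n >= 1`.
#' @param level Confidence level (default 0.95).
#' @return A tibble with columns `estimate`, `lower`, `upper`, one row per
#'   input element.
#' @examples
#' wilson_interval(34, 41)
#' @export
wilson_interval <- function(successes, n, level = 0.95) {
  k <- as.numeric(successes)
  n <- as.numeric(n)
  if (length(level) != 1L || is.na(level) || level <= 0 || level >= 1) {
    rlang::abort("`level` must be a single value strictly between 0 and 1.")
  }
  m <- max(length(k), length(n))
  k <- rep_len(k, m)
  n <- rep_len(n, m)
  if (any(is.na(k) | is.na(n)) || any(n < 1) || any(k < 0) || any(k > n)) {
    rlang::abort("Require 0 <= successes <= n and n >= 1.")
  }
  z <- stats::qnorm((1 + level) / 2)
  phat <- k / n
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  lower <- pmax(0, center - half)
  upper <- pmin(1, center + half)
  lower[k == 0] <- 0  # boundary closure: the score interval is exact here,
  upper[k == n] <- 1  # but floating point can land an ulp inside
  tibble::tibble(estimate = phat, lower = lower, upper = upper)
}

#' Confusion counts for a high/low classification
#'
#' "Positive" is the high-probability class; "truth" is the reference-standard
#' deep-SSI annotation. `confusion_counts()` builds the object from four
#' counts; `confusion_matrix()` tabulates classifications against a reference
#' table, erroring when the two surgery sets differ.
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return An object of class `ssi_confusion` with fields `tp`, `fp`, `fn`,
#'   `tn` and `n`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  vals <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(vals)) || any(vals < 0) || any(vals != as.integer(vals))) {
    rlang::abort("tp, fp, fn, tn must be non-negative integers.")
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
                 tn = as.integer(tn), n = as.integer(tp + fp + fn + tn)),
            class = "ssi_confusion")
}

#' @export
print.ssi_confusion <- function(x, ...) {
  cat(sprintf("<ssi_confusion> TP %d  FP %d  FN %d  TN %d  (n = %d)\n",
              x$tp, x$fp, x$fn, x$tn, x$n))
  invisible(x)
}

#' @rdname confusion_counts
#' @param classifications Tibble from [classify_surgeries()]: `surgery_id`,
#'   `probability_class`.
#' @param reference Tibble with `surgery_id` and logical `deep_ssi` (one row
#'   per surgery; filter to a single annotator first if several annotated).
#' @export
confusion_matrix <- function(classifications, reference) {
  cls <- tibble::as_tibble(classifications)
  ref <- tibble::as_tibble(reference)
  if (anyDuplicated(ref$surgery_id)) {
    rlang::abort("`reference` must carry one annotation per surgery; filter to a single annotator first.")
  }
  only_cls <- setdiff(cls$surgery_id, ref$surgery_id)
  only_ref <- setdiff(ref$surgery_id, cls$surgery_id)
  if (length(only_cls) > 0L || length(only_ref) > 0L) {
    rlang::abort(c(
      "Classified and reference surgery sets differ.",
      if (length(only_cls) > 0L)
        stats::setNames(sprintf("classified only: %s",
                                paste(utils::head(only_cls, 5L), collapse = ", ")), "x"),
      if (length(only_ref) > 0L)
        stats::setNames(sprintf("reference only: %s",
                                paste(utils::head(only_ref, 5L), collapse = ", ")), "x")))
  }
  merged <- dplyr::inner_join(cls, ref, by = "surgery_id")
  high <- merged$probability_class == "high"
  ssi <- isTRUE_v(merged$deep_ssi)
  confusion_counts(sum(high & ssi), sum(high & !ssi),
                   sum(!high & ssi), sum(!high & !ssi))
}

#' Fraction of records exempted from manual review
#'
#' The share of surgeries classified low probability, i.e. `(tn + fn) / n`:
#' these records are accepted as non-cases without chart review, so the
#' complement `(tp + fp) / n` is the share still reviewed manually.
#'
#' @param counts An `ssi_confusion` (or anything [confusion_counts()] accepts
#'   as a list with `tp`, `fp`, `fn`, `tn`).
#' @return A proportion in `[0, 1]`.
#' @export
workload_reduction <- function(counts) {
  stopifnot(inherits(counts, "ssi_confusion"))
  if (counts$n == 0L) rlang::abort("Workload reduction is undefined on an empty cohort.")
  (counts$tn + counts$fn) / counts$n
}

#' Diagnostic performance of a classification rule
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive
#' predictive value `tp/(tp+fp)` and negative predictive value `tn/(tn+fn)`,
#' each with a Wilson score interval on its own denominator, plus the
#' workload reduction. A metric whose denominator is zero is reported as
#' missing with `undefined = TRUE`, never silently as 0 or 1. All stored
#' values are full precision; rounding happens only when rendering.
#'
#' @param counts An `ssi_confusion` from [confusion_counts()] or
#'   [confusion_matrix()].
#' @param level Confidence level for the Wilson intervals (default 0.95).
#' @param algorithm Optional algorithm name carried into the report.
#' @return An object of class `ssi_performance`: list with `algorithm`,
#'   `counts`, `metrics` (tibble `metric`, `numerator`, `denominator`,
#'   `estimate`, `lower`, `upper`, `undefined`), `workload_reduction`,
#'   `level`.
#' @export
diagnostic_performance <- function(counts, level = 0.95, algorithm = NULL) {
  stopifnot(inherits(counts, "ssi_confusion"))
  if (counts$n == 0L) rlang::abort("Performance is undefined on an empty cohort.")
  spec <- list(
    sensitivity = c(counts$tp, counts$tp + counts$fn),
    specificity = c(counts$tn, counts$tn + counts$fp),
    ppv = c(counts$tp, counts$tp + counts$fp),
    npv = c(counts$tn, counts$tn + counts$fn)
  )
  rows <- lapply(names(spec), function(nm) {
    num <- spec[[nm]][1L]
    den <- spec[[nm]][2L]
    if (den == 0L) {
      tibble::tibble(metric = nm, numerator = num, denominator = den,
                     estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                     undefined = TRUE)
    } else {
      ci <- wilson_interval(num, den, level)
      tibble::tibble(metric = nm, numerator = num, denominator = den,
                     estimate = ci$estimate, lower = ci$lower, upper = ci$upper,
                     undefined = FALSE)
    }
  })
  structure(list(
    algorithm = algorithm %||% "unnamed",
    counts = counts,
    metrics = dplyr::bind_rows(rows),
    workload_reduction = workload_reduction(counts),
    level = level
  ), class = "ssi_performance")
}

#' @export
print.ssi_performance <- function(x, ...) {
  cat(render_report(list(x))$text, sep = "\n")
  invisible(x)
}

#' Round half up (decimal rounding used for display)
#'
#' Base `round()` rounds half to even; reported percentages here round half
#' away from zero, which is the convention clinical tables use.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Two-rater agreement on binary annotations
#'
#' Percent agreement and Cohen's kappa for two annotators labelling the same
#' items, as used to report the reliability of a double-annotated chart-review
#' overlap. Kappa is `(p_o - p_e) / (1 - p_e)` with `p_e` the chance agreement
#' from the marginal label frequencies. When both raters are constant and
#' identical (`p_e = 1`), kappa is undefined and reported as `NA` with
#' `undefined = TRUE`.
#'
#' @param a,b Logical (or two-level) vectors of equal length: the two raters'
#'   labels, item-aligned.
#' @return An object of class `ssi_agreement`: list with `n_items`,
#'   `percent_agreement`, `kappa`, `undefined`.
#' @examples
#' cohens_kappa(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b)) rlang::abort("`a` and `b` must be item-aligned.")
  if (length(a) == 0L) rlang::abort("Agreement is undefined on zero items.")
  a <- as.logical(a)
  b <- as.logical(b)
  if (any(is.na(a)) || any(is.na(b))) rlang::abort("Labels must not be missing.")
  n <- length(a)
  p_o <- mean(a == b)
  p_e <- mean(a) * mean(b) + mean(!a) * mean(!b)
  undefined <- p_e > 1 - 1e-12
  kappa <- if (undefined) NA_real_ else (p_o - p_e) / (1 - p_e)
  structure(list(n_items = n, percent_agreement = p_o, kappa = kappa,
                 undefined = undefined),
            class = "ssi_agreement")
}

#' @export
print.ssi_agreement <- function(x, ...) {
  cat(sprintf("<ssi_agreement> n = %d, agreement %.1f%%, kappa %s\n",
              x$n_items, 100 * x$percent_agreement,
              if (x$undefined) "undefined (both raters constant)"
              else sprintf("%.3f", x$kappa)))
  invisible(x)
}
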