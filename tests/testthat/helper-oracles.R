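# Independent oracles, deliberately coded differently from the package paths
# they cross-check.

# Wilson interval as the two roots of (p - phat)^2 = z^2 p (1 - p) / n,
# solved with the quadratic formula.
wilson_quadratic <- function(k, n, level = 0.95) {
  z2 <- stats::qnorm((1 + level) / 2)^2
  phat <- k / n
  a <- 1 + z2 / n
  b <- -(2 * phat + z2 / n)
  cc <- phat^2
  disc <- sqrt(b^2 - 4 * a * cc)
  c(lower = (-b - disc) / (2 * a), upper = (-b + disc) / (2 * a))
}

# Rule decision by brute-force subset enumeration over the optional set.
rule_oracle <- function(profile, rule) {
  vals <- vapply(c("admissions", "reoperation", "radiology", "antibiotics",
                   "microbiology"), function(nm) isTRUE(profile[[nm]]),
                 logical(1))
  if (!all(vals[rule$required])) return("low")
  if (rule$min_optional == 0L) return("high")
  subsets <- utils::combn(rule$optional, rule$min_optional, simplify = FALSE)
  for (s in subsets) if (all(vals[s])) return("high")
  "low"
}

# All 32 component profiles as a tibble.
all_profiles <- function() {
  grid <- expand.grid(admissions = c(FALSE, TRUE), reoperation = c(FALSE, TRUE),
                      radiology = c(FALSE, TRUE), antibiotics = c(FALSE, TRUE),
                      microbiology = c(FALSE, TRUE))
  tibble::as_tibble(cbind(surgery_id = sprintf("S%02d", seq_len(nrow(grid))),
                          grid))
}

# Naive day-by-day scan for a qualifying antibiotic course: some start day s
# in the window such that min_len consecutive days from s onward were all
# administered and all lie inside the window.
abx_scan_oracle <- function(days, min_len = 3L, earliest = 2L, fu = 45L) {
  days <- unique(days)
  for (s in seq(earliest, fu - min_len + 1L)) {
    if (all((s:(s + min_len - 1L)) %in% days)) return(TRUE)
  }
  FALSE
}
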