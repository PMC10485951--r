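comps <- c("admissions", "reoperation", "radiology", "antibiotics",
           "microbiology")

test_that("generator configuration validates and derives the no-SSI conditionals", {
  cfg <- generator_config()
  expect_identical(cfg$n_surgeries, 225L)
  expect_equal(cfg$ssi_prevalence, 0.182)
  # marginal constraint: p * q1 + (1-p) * q0 reproduces the marginals exactly
  implied <- cfg$ssi_prevalence * cfg$component_given_ssi +
    (1 - cfg$ssi_prevalence) * cfg$component_given_no_ssi
  expect_equal(unname(implied),
               c(0.387, 0.178, 0.476, 0.413, 0.311), tolerance = 1e-3)
  # incompatible marginals are rejected
  expect_error(
    generator_config(component_marginals = c(admissions = 0.05, reoperation = 0.178,
                                             radiology = 0.476, antibiotics = 0.413,
                                             microbiology = 0.311)),
    "incompatible")
})

test_that("sampling is reproducible and prevalence behaves at the extremes", {
  cfg <- generator_config()
  a <- sample_cohort(cfg, seed = 21L)
  b <- sample_cohort(cfg, seed = 21L)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- sample_cohort(cfg, seed = 22L)
  expect_false(identical(a$deep_ssi, c2$deep_ssi))
  expect_identical(nrow(a), 225L)

  none <- sample_cohort(generator_config(ssi_prevalence = 0), seed = 3L)
  expect_identical(sum(none$deep_ssi), 0L)
  # with zero prevalence there can be no false negatives under any rule
  cohort <- realize_events(none, generator_config(ssi_prevalence = 0), seed = 3L)
  prof <- extract_components(cohort)
  for (r in c("original", "adapted")) {
    cm <- confusion_matrix(classify_surgeries(prof, r),
                           cohort$reference[, c("surgery_id", "deep_ssi")])
    expect_identical(cm$fn, 0L)
    expect_identical(cm$tp, 0L)
  }
})

test_that("realized events reproduce the planted indicators exactly", {
  cfg <- generator_config()
  for (seed in 1:3) {
    sim <- simulate_cohort(cfg, seed = seed)
    prof <- extract_components(sim$cohort)
    expect_identical(as.data.frame(prof[comps]),
                     as.data.frame(sim$truth[comps]),
                     info = paste("seed", seed))
  }
})

test_that("distractor-only patients never trip a component", {
  # all indicators forced off: realized streams hold only distractors
  cfg <- generator_config(
    ssi_prevalence = 0,
    component_marginals = c(admissions = 0, reoperation = 0, radiology = 0,
                            antibiotics = 0, microbiology = 0),
    component_given_ssi = c(admissions = 0, reoperation = 0, radiology = 0,
                            antibiotics = 0, microbiology = 0),
    distractor_rates = list(prophylactic_abx = 1, scattered_abx = 1,
                            non_j01_abx = 1, preop_culture = 1,
                            nonrelevant_culture = 1, non_ct_order = 1,
                            preop_ct = 1, other_dept_readmission = 1,
                            wrong_specialty_reop = 1, late_reop = 1))
  for (seed in 1:5) {
    sim <- simulate_cohort(cfg, seed = seed)
    prof <- extract_components(sim$cohort)
    expect_identical(sum(prof$count), 0L, info = paste("seed", seed))
  }
})

test_that("empirical marginals recover the configured ones", {
  cfg <- generator_config(n_surgeries = 20000L)
  planted <- sample_cohort(cfg, seed = 8L)
  m_hat <- colMeans(as.matrix(planted[comps]))
  m <- cfg$component_marginals
  se <- sqrt(m * (1 - m) / nrow(planted))
  expect_true(all(abs(m_hat - m) <= 3 * se))
  p_hat <- mean(planted$deep_ssi)
  expect_lt(abs(p_hat - 0.182), 3 * sqrt(0.182 * 0.818 / nrow(planted)))
})

test_that("a null configuration makes both rules uninformative", {
  # P(c|SSI) = P(c|no SSI) = marginal: components carry no signal, so the
  # high-probability rate is the same in SSI and non-SSI strata
  m <- c(admissions = 0.387, reoperation = 0.178, radiology = 0.476,
         antibiotics = 0.413, microbiology = 0.311)
  cfg <- generator_config(n_surgeries = 20000L, component_given_ssi = m,
                          component_given_no_ssi = m)
  planted <- sample_cohort(cfg, seed = 14L)
  for (r in c("original", "adapted")) {
    cls <- classify_surgeries(planted, r)
    high <- cls$probability_class == "high"
    sens <- mean(high[planted$deep_ssi])
    fpr <- mean(high[!planted$deep_ssi])  # 1 - specificity
    expect_lt(abs(sens - fpr), 0.03)
  }
})

test_that("the simulated second annotator flips labels at the configured rate", {
  ref <- tibble::tibble(surgery_id = sprintf("S%02d", 1:20),
                        deep_ssi = rep(c(TRUE, FALSE), 10))
  same <- simulate_second_annotator(ref, disagreement = 0, seed = 4L)
  expect_identical(same$deep_ssi, ref$deep_ssi)
  expect_identical(cohens_kappa(ref$deep_ssi, same$deep_ssi)$kappa, 1)

  flipped <- simulate_second_annotator(ref, disagreement = 1, seed = 4L)
  expect_identical(cohens_kappa(ref$deep_ssi, flipped$deep_ssi)$percent_agreement, 0)

  agree <- vapply(1:400, function(s) {
    second <- simulate_second_annotator(ref, disagreement = 0.05, seed = s)
    mean(second$deep_ssi == ref$deep_ssi)
  }, numeric(1))
  expect_lt(abs(mean(agree) - 0.95), 0.01)
})

test_that("event substreams are seed-stable per stream", {
  cfg <- generator_config(n_surgeries = 50L)
  planted <- sample_cohort(cfg, seed = 31L)
  a <- realize_events(planted, cfg, seed = 31L)
  b <- realize_events(planted, cfg, seed = 31L)
  expect_cohort_equal(a, b)
  c2 <- realize_events(planted, cfg, seed = 32L)
  expect_false(identical(as.data.frame(a$antibiotics),
                         as.data.frame(c2$antibiotics)))
})
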