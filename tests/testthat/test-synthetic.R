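test_that("generation is seed-deterministic at every level", {
  prof <- cohort_profile(n = 8, seed = 55)
  g1 <- generate_patient_bundle(prof, 3)
  g2 <- generate_patient_bundle(prof, 3)
  expect_identical(g1$bundle, g2$bundle)
  expect_identical(g1$truth, g2$truth)

  ds1 <- generate_triage_dataset(prof)
  ds2 <- generate_triage_dataset(prof)
  expect_identical(ds1, ds2)

  s1 <- generate_local_store(prof)
  s2 <- generate_local_store(prof)
  expect_identical(s1, s2)
})

test_that("forced constructions pin the oracle's corner behavior", {
  # prevalence 1 with certain orders and deranged temperature floor > 37.5:
  # every patient must screen in unless temperature is missing
  hot <- cohort_profile(
    n = 30, sepsis_prevalence = 1,
    order_probabilities = list(septic = c(blood_culture = 1,
                                          antibiotics = 1, vasopressor = 0),
                               nonseptic = c(blood_culture = 0,
                                             antibiotics = 0,
                                             vasopressor = 0)),
    lab_missingness = 0, vital_missingness = 0, seed = 61)
  gi <- generate_sepsis_inputs(hot)
  screened <- gi$truth$expected_screen_flag
  expect_identical(screened, gi$inputs$body_temperature > 37.5)
  expect_gt(mean(screened), 0.7)  # deranged temps sit mostly above 37.5

  # total lab missingness floors the four lab-fed organs at zero
  blind <- cohort_profile(n = 10, sepsis_prevalence = 1,
                          lab_missingness = 1, vital_missingness = 0,
                          seed = 62)
  gb <- generate_sepsis_inputs(blind)
  expect_true(all(is.na(gb$inputs$platelets)))
  for (i in seq_len(nrow(gb$inputs))) {
    r <- gb$inputs[i, ]
    si <- input_from_row(r)
    sofa <- compute_sofa(si)
    expect_true(all(c("respiration", "coagulation", "liver", "renal") %in%
                      sofa$missing_organs))
    expect_identical(unname(sofa$organ_subscores["coagulation"]), 0L)
  }
})

test_that("the empirical septic fraction respects the binomial bound", {
  prof <- cohort_profile(n = 200, sepsis_prevalence = 0.3, seed = 7)
  gi <- generate_sepsis_inputs(prof)
  expect_identical(nrow(gi$truth), 200L)
  k <- sum(gi$truth$septic)
  se <- sqrt(200 * 0.3 * 0.7)
  expect_true(abs(k - 60) <= 3 * se)

  single <- generate_cohort(cohort_profile(n = 1, seed = 9))
  expect_length(single$bundles, 1)
  expect_identical(nrow(single$truth), 1L)
})

test_that("engine scores agree with the generation-time oracle on a cohort", {
  prof <- cohort_profile(n = 400, seed = 17)
  gi <- generate_sepsis_inputs(prof)
  for (i in seq_len(nrow(gi$inputs))) {
    si <- input_from_row(gi$inputs[i, ])
    expect_identical(compute_qsofa(si)$score,
                     as.integer(gi$truth$expected_qsofa[i]))
    expect_identical(compute_sofa(si)$total,
                     as.integer(gi$truth$expected_sofa[i]))
    expect_identical(isTRUE(as.logical(screen_suspected_sepsis(si))),
                     gi$truth$expected_screen_flag[i])
  }
})

test_that("generated bundles reproduce their own ground truth through the full pipeline", {
  prof <- cohort_profile(n = 40, seed = 23)
  co <- generate_cohort(prof)
  eng <- sepsis3_engine()
  for (i in seq_along(co$bundles)) {
    rec <- extract_features(co$bundles[[i]], eng$descriptor,
                            co$truth$reference_time[i])
    a <- eng$fn(rec)
    expect_identical(a$suspected_infection,
                     co$truth$expected_screen_flag[i], info = i)
    expect_identical(a$qsofa$score, as.integer(co$truth$expected_qsofa[i]),
                     info = i)
    expect_identical(a$sofa$total, as.integer(co$truth$expected_sofa[i]),
                     info = i)
  }
})

test_that("generated stores respect the antibiotic mixture and integrity", {
  prof <- cohort_profile(n = 500, seed = 29,
                         antibiotic_mixture = c(`1777806` = 0.6,
                                                `1771162` = 0.4))
  store <- generate_local_store(prof)
  # all foreign keys resolve (local_store() re-validates, so construction
  # succeeding is the integrity check); spot-check anyway
  expect_true(all(store$drug_exposure$person_id %in% store$person$person_id))
  expect_true(all(store$death$person_id %in% store$person$person_id))

  counts <- table(store$drug_exposure$drug_concept_id)
  n_abx <- sum(counts)
  for (drug in names(counts)) {
    p <- c(`1777806` = 0.6, `1771162` = 0.4)[[drug]]
    se <- sqrt(n_abx * p * (1 - p))
    expect_true(abs(counts[[drug]] - n_abx * p) <= 3 * se)
  }

  empty <- generate_local_store(cohort_profile(n = 1, sepsis_prevalence = 0,
                                               seed = 1,
                                               order_probabilities = list(
                                                 septic = c(blood_culture = 0,
                                                            antibiotics = 0,
                                                            vasopressor = 0),
                                                 nonseptic = c(
                                                   blood_culture = 0,
                                                   antibiotics = 0,
                                                   vasopressor = 0))))
  expect_identical(nrow(empty$drug_exposure), 0L)
  expect_true(all(c("person_id", "drug_concept_id") %in%
                    names(empty$drug_exposure)))
})

test_that("triage outcome prevalence matches the logistic model within 3 SE", {
  # with all slopes zeroed the prevalence must be sigmoid(intercept)
  coefs <- list(mortality = c("(Intercept)" = -2.0),
                critical_care = c("(Intercept)" = -1.0),
                hospitalization = c("(Intercept)" = 0.0))
  prof <- cohort_profile(n = 1500, seed = 37, triage_coefficients = coefs)
  ds <- generate_triage_dataset(prof)
  for (oc in names(coefs)) {
    p <- stats::plogis(coefs[[oc]][["(Intercept)"]])
    se <- sqrt(p * (1 - p) / nrow(ds))
    expect_true(abs(mean(ds[[oc]]) - p) <= 3 * se, info = oc)
    expect_true(all(ds[[oc]] %in% c(0L, 1L)))
  }
})
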