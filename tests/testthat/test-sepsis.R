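test_that("the suspected-sepsis screen applies the strict 37.5 degC rule", {
  expect_true(screen_suspected_sepsis(
    sepsis_input(body_temperature = 38.0, blood_culture_ordered = TRUE)))
  # boundary is strict: exactly 37.5 does not screen in
  expect_false(as.logical(screen_suspected_sepsis(
    sepsis_input(body_temperature = 37.5, blood_culture_ordered = TRUE))))
  # order clause required
  expect_false(as.logical(screen_suspected_sepsis(
    sepsis_input(body_temperature = 39.0))))
  # antibiotics order suffices in place of the culture
  expect_true(screen_suspected_sepsis(
    sepsis_input(body_temperature = 37.6, antibiotics_ordered = TRUE)))
  # missing temperature screens out with a note
  out <- screen_suspected_sepsis(sepsis_input(blood_culture_ordered = TRUE))
  expect_false(as.logical(out))
  expect_match(attr(out, "note"), "missing")
})

test_that("screening equals brute-force truth-table evaluation on a grid", {
  temps <- seq(36.0, 40.0, by = 0.5)
  for (temp in temps) {
    for (bc in c(TRUE, FALSE)) {
      for (abx in c(TRUE, FALSE)) {
        got <- as.logical(screen_suspected_sepsis(sepsis_input(
          body_temperature = temp, blood_culture_ordered = bc,
          antibiotics_ordered = abx)))
        expect_identical(got, temp > 37.5 && (bc || abx))
      }
    }
  }
})

test_that("qSOFA scores the three components with one point each", {
  r0 <- compute_qsofa(sepsis_input(sbp = 120, resp_rate = 16, gcs = 15))
  expect_identical(r0$score, 0L)
  expect_false(r0$positive)

  r3 <- compute_qsofa(sepsis_input(sbp = 90, resp_rate = 24, gcs = 13))
  expect_identical(r3$score, 3L)
  expect_true(r3$positive)
  expect_true(all(r3$components))

  # cutoff boundaries: <=100, >=22, <15
  expect_identical(
    compute_qsofa(sepsis_input(sbp = 100, resp_rate = 22, gcs = 14))$score, 3L)
  expect_identical(
    compute_qsofa(sepsis_input(sbp = 101, resp_rate = 21, gcs = 15))$score, 0L)
})

test_that("qSOFA equals popcount over the exhaustive 2^3 component grid", {
  sbp_vals <- c(90, 120)    # TRUE / FALSE for low_sbp
  rr_vals <- c(24, 16)      # TRUE / FALSE for high_resp_rate
  gcs_vals <- c(13, 15)     # TRUE / FALSE for altered_mentation
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    r <- compute_qsofa(sepsis_input(sbp = sbp_vals[i], resp_rate = rr_vals[j],
                                    gcs = gcs_vals[k]))
    expected <- sum(i == 1, j == 1, k == 1)
    expect_identical(r$score, as.integer(expected))
    expect_identical(sum(r$components), as.integer(expected))
    expect_identical(r$positive, expected >= 2)
  }
})

test_that("missing qSOFA components contribute zero and are recorded", {
  r <- compute_qsofa(sepsis_input(sbp = 90))
  expect_identical(r$score, 1L)
  expect_setequal(r$missing, c("high_resp_rate", "altered_mentation"))
})

test_that("SOFA spans its floor and ceiling", {
  normal <- sepsis_input(pao2 = 94.5, fio2 = 0.21, platelets = 250,
                         total_bilirubin = 0.5, sbp = 120, dbp = 75,
                         gcs = 15, creatinine = 0.8)
  r <- compute_sofa(normal)
  expect_identical(r$total, 0L)
  expect_true(all(r$organ_subscores == 0))
  expect_length(r$missing_organs, 0)

  worst <- sepsis_input(pao2 = 60, fio2 = 1.0, platelets = 10,
                        total_bilirubin = 15, sbp = 60, dbp = 40,
                        gcs = 3, creatinine = 6,
                        vasopressor_ordered = TRUE)
  w <- compute_sofa(worst)
  # the vasopressor boolean caps the cardiovascular branch at 3
  expect_identical(unname(w$organ_subscores["cardiovascular"]), 3L)
  expect_identical(w$total, 23L)
  expect_true(all(w$organ_subscores[names(w$organ_subscores) !=
                                      "cardiovascular"] == 4L))
})

test_that("missing organ inputs score zero and are listed, never raise", {
  r <- compute_sofa(sepsis_input(gcs = 12))
  expect_identical(unname(r$organ_subscores["cns"]), 2L)
  expect_setequal(r$missing_organs,
                  c("respiration", "coagulation", "liver", "cardiovascular",
                    "renal"))
  expect_identical(r$total, 2L)
})

test_that("SOFA totals are additive and subscores bounded on random inputs", {
  set.seed(31)
  for (i in 1:300) {
    si <- sepsis_input(
      gcs = sample(3:15, 1), sbp = sample(60:180, 1), dbp = sample(30:110, 1),
      resp_rate = sample(8:40, 1), body_temperature = round(runif(1, 35, 41), 1),
      pao2 = sample(40:120, 1), fio2 = round(runif(1, 0.21, 1), 2),
      platelets = sample(5:400, 1), creatinine = round(runif(1, 0.3, 8), 2),
      total_bilirubin = round(runif(1, 0.1, 20), 2),
      lactate = round(runif(1, 0.5, 10), 2),
      vasopressor_ordered = runif(1) < 0.3)
    r <- compute_sofa(si)
    expect_identical(r$total, as.integer(sum(r$organ_subscores)))
    expect_true(all(r$organ_subscores >= 0 & r$organ_subscores <= 4))
    q <- compute_qsofa(si)
    expect_true(q$score >= 0 && q$score <= 3)
  }
})

test_that("worsening any single physiologic input never lowers the scores", {
  base <- list(gcs = 15, sbp = 120, dbp = 80, resp_rate = 16,
               body_temperature = 37, pao2 = 95, fio2 = 0.21,
               platelets = 250, creatinine = 0.8, total_bilirubin = 0.5,
               lactate = 1.0)
  worse <- list(gcs = 6, sbp = 70, dbp = 40, resp_rate = 30,
                body_temperature = 39.5, pao2 = 55, fio2 = 0.9,
                platelets = 30, creatinine = 4.5, total_bilirubin = 8,
                lactate = 6)
  b <- do.call(sepsis_input, base)
  sofa_b <- compute_sofa(b)$total
  qsofa_b <- compute_qsofa(b)$score
  for (field in names(worse)) {
    args <- base
    args[[field]] <- worse[[field]]
    x <- do.call(sepsis_input, args)
    expect_gte(compute_sofa(x)$total, sofa_b)
    expect_gte(compute_qsofa(x)$score, qsofa_b)
  }
})

test_that("fio2 of zero is rejected, implausible values refused at construction", {
  expect_error(sepsis_input(fio2 = 0), class = "cdskit_validation_error")
  expect_error(sepsis_input(body_temperature = 50),
               class = "cdskit_validation_error")
  expect_error(sepsis_input(gcs = 16), class = "cdskit_validation_error")
})

test_that("the Sepsis-3 composition gates sepsis and septic shock correctly", {
  # screened in, SOFA >= 2 -> sepsis with recommendations
  septic <- sepsis_input(body_temperature = 38.6, blood_culture_ordered = TRUE,
                         gcs = 12, sbp = 95, dbp = 55, resp_rate = 24,
                         creatinine = 2.4, platelets = 80,
                         total_bilirubin = 2.5, pao2 = 70, fio2 = 0.4,
                         lactate = 3.1)
  a <- assess_sepsis(septic)
  expect_true(a$suspected_infection)
  expect_true(a$sepsis)
  expect_gt(length(a$recommendations), 0)
  expect_false(a$septic_shock)  # no vasopressor order

  # screened out despite organ dysfunction -> no sepsis
  not_screened <- sepsis_input(body_temperature = 37.0, gcs = 6, sbp = 70,
                               dbp = 40, creatinine = 5, platelets = 15,
                               total_bilirubin = 13, pao2 = 50, fio2 = 0.8)
  a2 <- assess_sepsis(not_screened)
  expect_gte(a2$sofa$total, 8)
  expect_false(a2$sepsis)
  expect_length(a2$recommendations, 0)

  # shock conjunction: sepsis + vasopressor + lactate > 2
  shocked <- assess_sepsis(sepsis_input(
    body_temperature = 38.6, antibiotics_ordered = TRUE,
    vasopressor_ordered = TRUE, lactate = 3.1, gcs = 12, sbp = 85, dbp = 50,
    creatinine = 2.1))
  expect_true(shocked$septic_shock)

  # invariants: sepsis => suspected_infection, shock => sepsis
  expect_true(!shocked$sepsis || shocked$suspected_infection)
  expect_true(!shocked$septic_shock || shocked$sepsis)
})

test_that("treatment items carry completed marks matched to existing orders", {
  septic <- sepsis_input(body_temperature = 38.6, antibiotics_ordered = TRUE,
                         blood_culture_ordered = FALSE, gcs = 12, sbp = 90,
                         dbp = 50, creatinine = 2.4)
  a <- assess_sepsis(septic)
  items <- a$recommendations
  by_id <- stats::setNames(items, vapply(items, `[[`, "", "item_id"))
  expect_true(by_id$broad_spectrum_antibiotics$completed)
  expect_false(by_id$blood_cultures$completed)
  expect_false(by_id$measure_lactate$completed)  # no lactate on file

  # culture ordered but nothing else, no lactate on file -> only the
  # cultures item is marked completed
  none <- assess_sepsis(sepsis_input(body_temperature = 38.6,
                                     blood_culture_ordered = TRUE, gcs = 10,
                                     sbp = 85, dbp = 45))
  expect_true(none$sepsis)
  done <- vapply(none$recommendations, `[[`, logical(1), "completed")
  ids <- vapply(none$recommendations, `[[`, "", "item_id")
  expect_identical(ids[done], "blood_cultures")

  # contract: recommendations require a sepsis-positive assessment
  healthy <- assess_sepsis(sepsis_input(body_temperature = 36.8))
  expect_error(recommend_treatment(healthy, septic),
               class = "cdskit_contract_error")
})

test_that("item ids stay unique across random septic inputs", {
  set.seed(13)
  for (i in 1:100) {
    si <- sepsis_input(
      body_temperature = round(runif(1, 37.6, 41), 1),
      blood_culture_ordered = TRUE,
      antibiotics_ordered = runif(1) < 0.5,
      vasopressor_ordered = runif(1) < 0.3,
      lactate = if (runif(1) < 0.5) round(runif(1, 0.5, 8), 1) else NA,
      gcs = sample(3:15, 1), sbp = sample(60:120, 1), dbp = sample(30:80, 1),
      creatinine = round(runif(1, 1.5, 6), 1))
    a <- assess_sepsis(si)
    if (a$sepsis) {
      ids <- vapply(a$recommendations, `[[`, "", "item_id")
      expect_false(anyDuplicated(ids) > 0)
    }
  }
})

test_that("the qSOFA descriptor declares exactly three clinical components", {
  expect_identical(nrow(qsofa_components()), 3L)
  expect_setequal(qsofa_components()$variable, c("sbp", "resp_rate", "gcs"))
})
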