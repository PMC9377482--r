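test_that("the registry registers, lists and refuses duplicates", {
  reg <- engine_registry()
  eng <- sepsis3_engine()
  register_engine(reg, eng$descriptor, eng$fn)
  listed <- list_engines(reg)
  expect_identical(listed$name, "sepsis3")
  expect_error(register_engine(reg, eng$descriptor, eng$fn),
               class = "cdskit_contract_error")
})

test_that("the shipped manifest registers both engines at startup", {
  reg <- default_registry()
  listed <- list_engines(reg)
  expect_identical(nrow(listed), 2L)
  expect_setequal(listed$name, c("sepsis3", "edtriage"))
  expect_setequal(listed$kind, c("knowledge_based", "nonknowledge_based"))
})

test_that("handle_request equals calling the engine on extracted features", {
  reg <- default_registry()
  b <- febrile_bundle(temp = 38.6)
  req <- cds_request("sepsis3", b, ref_time)
  resp <- handle_request(req, reg)
  expect_null(resp$error)

  eng <- sepsis3_engine()
  direct <- eng$fn(extract_features(b, eng$descriptor, ref_time))
  expect_identical(resp$result$qsofa$score, direct$qsofa$score)
  expect_identical(resp$result$sofa$total, direct$sofa$total)
  expect_identical(resp$result$sepsis, direct$sepsis)

  # the preprocessing log always travels with the response
  expect_false(is.null(resp$preprocessing_log))
  expect_true("gcs" %in% resp$missing_features)
})

test_that("unknown engines and engine failures come back as typed responses", {
  reg <- default_registry()
  resp <- handle_request(cds_request("nonexistent", febrile_bundle(),
                                     ref_time), reg)
  expect_identical(resp$error$kind, "engine_not_found")

  boom <- engine_registry()
  desc <- engine_descriptor("boom", "1.0", "knowledge_based",
                            data.frame(feature_name = "body_temperature",
                                       canonical_unit = "Cel",
                                       required = TRUE,
                                       kind = "observation"))
  register_engine(boom, desc, function(record) stop("engine exploded"))
  resp2 <- handle_request(cds_request("boom", febrile_bundle(), ref_time),
                          boom)
  expect_identical(resp2$error$kind, "engine_failure")
  expect_match(resp2$error$message, "exploded")
})

test_that("peer summaries are gathered when asked for and degrade per peer", {
  reg <- default_registry()
  req <- cds_request("sepsis3", febrile_bundle(temp = 38.6), ref_time,
                     include_peer_summaries = TRUE,
                     peers = list(local_peer(fixture_store(), "peer1"),
                                  unreachable_peer()),
                     cohort = sepsis_cohort_spec(), k = 5)
  resp <- handle_request(req, reg)
  expect_length(resp$peer_summaries, 2)
  expect_s3_class(resp$peer_summaries[[1]], "summary_report")
  expect_s3_class(resp$peer_summaries[[2]], "peer_unavailable")
  # option isolation: without the flag the rest of the response is identical
  resp_off <- handle_request(cds_request("sepsis3", febrile_bundle(38.6),
                                         ref_time), reg)
  expect_length(resp_off$peer_summaries, 0)
  expect_identical(resp_off$result, resp$result)
})

test_that("the ui payload is ordered, pure, and adds no clinical content", {
  reg <- default_registry()
  septic_bundle <- fhir_bundle(list(
    fhir_patient("p1", "1960-01-01", "male"),
    fhir_encounter("e1", "p1", "emergency", ref_time),
    fhir_observation("o-t", "p1", "LOINC", "8310-5", value = 38.8,
                     unit = "Cel", effective_time = "2024-03-01T11:00:00Z"),
    fhir_observation("o-g", "p1", "LOINC", "9269-2", value = 10, unit = "1",
                     effective_time = "2024-03-01T11:00:00Z"),
    fhir_observation("o-s", "p1", "LOINC", "8480-6", value = 85,
                     unit = "mm[Hg]", effective_time = "2024-03-01T11:00:00Z"),
    fhir_observation("o-d", "p1", "LOINC", "8462-4", value = 45,
                     unit = "mm[Hg]", effective_time = "2024-03-01T11:00:00Z"),
    fhir_service_request("sr1", "p1", "SNOMED", "30088009",
                         "2024-03-01T11:00:00Z")))
  with_peer <- handle_request(cds_request(
    "sepsis3", septic_bundle, ref_time, include_peer_summaries = TRUE,
    peers = list(local_peer(fixture_store())),
    cohort = sepsis_cohort_spec(), k = 5), reg)
  expect_true(with_peer$result$sepsis)
  expect_identical(names(with_peer$ui_payload),
                   c("headline", "recommendations", "peer_statistics",
                     "data_quality"))

  without_peer <- handle_request(cds_request("sepsis3", septic_bundle,
                                             ref_time), reg)
  expect_identical(names(without_peer$ui_payload),
                   c("headline", "recommendations", "data_quality"))

  # purity: recomposition from the same parts is identical
  again <- compose_ui_payload(without_peer$result, list(),
                              without_peer$features)
  expect_identical(again, without_peer$ui_payload)

  # provenance: headline numbers equal the engine result, nothing invented
  hl <- with_peer$ui_payload$headline$values
  expect_identical(hl$sofa, with_peer$result$sofa$total)
  expect_identical(hl$qsofa, with_peer$result$qsofa$score)
})

test_that("the triage engine runs through the same pipeline", {
  reg <- default_registry()
  b <- fhir_bundle(list(
    fhir_patient("p1", "1950-01-01", "male"),
    fhir_encounter("e1", "p1", "emergency", ref_time,
                   arrival_mode = "ambulance"),
    fhir_observation("o-s", "p1", "LOINC", "8480-6", value = 95,
                     unit = "mm[Hg]", effective_time = "2024-03-01T11:00:00Z"),
    fhir_observation("o-hr", "p1", "LOINC", "8867-4", value = 120,
                     unit = "/min", effective_time = "2024-03-01T11:00:00Z"),
    fhir_observation("o-sp", "p1", "LOINC", "59408-5", value = 89,
                     unit = "%", effective_time = "2024-03-01T11:00:00Z")))
  resp <- handle_request(cds_request("edtriage", b, ref_time), reg)
  expect_null(resp$error)
  expect_s3_class(resp$result, "triage_prediction")
  expect_true(all(resp$result$probabilities >= 0 &
                    resp$result$probabilities <= 1))
  expect_identical(resp$ui_payload$headline$kind, "triage_prediction")
})

test_that("end-to-end handling is deterministic for a fixed request", {
  reg <- default_registry()
  g <- generate_patient_bundle(cohort_profile(n = 5, seed = 33), 2)
  r1 <- handle_request(cds_request("sepsis3", g$bundle,
                                   g$truth$reference_time), reg)
  r2 <- handle_request(cds_request("sepsis3", g$bundle,
                                   g$truth$reference_time), reg)
  expect_identical(r1$result, r2$result)
  expect_identical(r1$ui_payload, r2$ui_payload)
})
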