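# small hand-built fixtures used across test files

ref_time <- "2024-03-01T12:00:00Z"

febrile_bundle <- function(temp = 38.2, culture = TRUE) {
  entries <- list(
    fhir_patient("p1", "1969-05-01", "female"),
    fhir_encounter("e1", "p1", "emergency", ref_time),
    fhir_observation("o-temp", "p1", "LOINC", "8310-5", value = temp,
                     unit = "Cel", effective_time = "2024-03-01T10:00:00Z"))
  if (culture) {
    entries <- c(entries, list(fhir_service_request(
      "sr-bc", "p1", "SNOMED", "30088009", "2024-03-01T11:00:00Z")))
  }
  fhir_bundle(entries, bundle_id = "b-febrile")
}

# a hand-countable local store: 40 cohort members, 12 on drug 1777806,
# 3 on drug 1771162
fixture_store <- function() {
  pid <- sprintf("p%02d", 1:50)
  person <- data.frame(person_id = pid, birth_date = "1970-01-01",
                       sex_concept = 8507L, stringsAsFactors = FALSE)
  visit <- data.frame(visit_id = paste0("v", pid), person_id = pid,
                      class = "emergency", start = ref_time, end = ref_time,
                      stringsAsFactors = FALSE)
  condition <- data.frame(person_id = pid[1:40],
                          condition_concept_id = 132797L, time = ref_time,
                          stringsAsFactors = FALSE)
  drug <- data.frame(
    person_id = c(pid[1:12], pid[13:15]),
    drug_concept_id = c(rep(1777806L, 12), rep(1771162L, 3)),
    time = ref_time, stringsAsFactors = FALSE)
  local_store(person = person, visit = visit, condition = condition,
              drug_exposure = drug)
}

sepsis_cohort_spec <- function() {
  cohort_spec("sepsis", condition_concepts = 132797L)
}

input_from_row <- function(r) {
  sepsis_input(
    gcs = r$gcs, sbp = r$sbp, dbp = r$dbp, resp_rate = r$resp_rate,
    body_temperature = r$body_temperature, pao2 = r$pao2, fio2 = r$fio2,
    platelets = r$platelets, creatinine = r$creatinine,
    total_bilirubin = r$total_bilirubin, lactate = r$lactate,
    blood_culture_ordered = r$blood_culture_ordered,
    antibiotics_ordered = r$antibiotics_ordered,
    vasopressor_ordered = r$vasopressor_ordered)
}

random_summary_report <- function(seed, institution = "site", k = 5) {
  set.seed(seed)
  n_cells <- sample(1:6, 1)
  counts <- sample(0:20, n_cells, replace = TRUE)
  n_total <- max(sum(counts), 1)
  cells <- data.frame(
    label = paste0("drug_", sample(1000:1020, n_cells)),
    count = as.numeric(counts), rate = counts / n_total,
    suppressed = FALSE, partially_suppressed = FALSE,
    contributing_sites = 1L, stringsAsFactors = FALSE)
  suppress_small_cells(
    cdskit:::new_summary_report(institution, "sepsis", n_total, cells, k), k)
}
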