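# Synthetic fixtures: seed-deterministic ED/inpatient cohorts with known
# ground truth, so every other module is testable offline. Ground truth
# (screening flag, qSOFA, SOFA) is computed at generation time by a
# straight-line oracle written independently of the engine code — their
# agreement on large cohorts is an informative gate, not a tautology.
#
# Vital/lab sampling uses truncated normal distributions with plausible
# normal vs. deranged ranges shipped in vital_distributions.csv; clinical
# realism beyond that is a non-goal, since all downstream checks are
# oracle-relative rather than epidemiologic.

#' Configure a synthetic cohort
#'
#' @param n number of patients (>= 1).
#' @param sepsis_prevalence probability a patient is generated septic
#'   (deranged physiology + high order rates).
#' @param order_probabilities list with `septic` and `nonseptic` named
#'   vectors of probabilities for `blood_culture`, `antibiotics`,
#'   `vasopressor` orders.
#' @param lab_missingness,vital_missingness per-feature probability that a
#'   lab / vital observation is simply not generated.
#' @param antibiotic_mixture named probability vector over OMOP drug
#'   concept ids, used when materializing drug exposures.
#' @param outcome_probs in-hospital death / hospitalization probabilities
#'   by septic status (feeds the local store).
#' @param triage_coefficients per-outcome named logistic coefficients on
#'   the encoded triage features (see [triage_feature_names()]); these are
#'   the recovery-test ground truth.
#' @param seed integer master seed; everything derives from it.
#' @return an object of class `cohort_profile`.
#' @export
cohort_profile <- function(n,
                           sepsis_prevalence = 0.3,
                           order_probabilities = list(
                             septic = c(blood_culture = 0.9,
                                        antibiotics = 0.85,
                                        vasopressor = 0.4),
                             nonseptic = c(blood_culture = 0.10,
                                           antibiotics = 0.15,
                                           vasopressor = 0.02)),
                           lab_missingness = 0.08,
                           vital_missingness = 0.02,
                           antibiotic_mixture = c(`1777806` = 0.5,
                                                  `1771162` = 0.3,
                                                  `1709170` = 0.2),
                           outcome_probs = list(
                             septic = c(death = 0.25, hospitalization = 0.9),
                             nonseptic = c(death = 0.02,
                                           hospitalization = 0.3)),
                           triage_coefficients = default_triage_coefficients(),
                           seed = 1L) {
  stopifnot(n >= 1, sepsis_prevalence >= 0, sepsis_prevalence <= 1,
            abs(sum(antibiotic_mixture) - 1) < 1e-8)
  structure(list(n = as.integer(n), sepsis_prevalence = sepsis_prevalence,
                 order_probabilities = order_probabilities,
                 lab_missingness = lab_missingness,
                 vital_missingness = vital_missingness,
                 antibiotic_mixture = antibiotic_mixture,
                 outcome_probs = outcome_probs,
                 triage_coefficients = triage_coefficients,
                 seed = as.integer(seed)),
            class = "cohort_profile")
}

#' Default generating coefficients for the triage outcome model
#'
#' Named coefficients on the encoded feature scale; unnamed coordinates are
#' zero. These are the truth the parameter-recovery tests compare against.
#' @return list of named numeric vectors, one per outcome.
#' @export
default_triage_coefficients <- function() {
  list(
    mortality = c("(Intercept)" = -2.2, age_s = 0.9, sbp_s = -0.8,
                  spo2_s = -0.6, heart_rate_s = 0.4),
    critical_care = c("(Intercept)" = -1.6, age_s = 0.5, sbp_s = -0.7,
                      heart_rate_s = 0.6, spo2_s = -0.7, resp_rate_s = 0.5),
    hospitalization = c("(Intercept)" = -0.7, age_s = 0.8,
                        body_temperature_s = 0.4, resp_rate_s = 0.3))
}

seed_for <- function(profile, index, stream = 0L) {
  (profile$seed * 10007L + index * 13L + stream) %% 2147483629L
}

load_vital_distributions <- function() {
  if (is.null(the$vitals)) {
    the$vitals <- read_table_file(ext_file("vital_distributions.csv"))
  }
  the$vitals
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

draw_vital <- function(feature, deranged) {
  tab <- load_vital_distributions()
  row <- tab[tab$feature == feature &
               tab$status == if (deranged) "deranged" else "normal", ]
  rtrunc_norm(1, row$mean, row$sd, row$lo, row$hi)
}

# ---- independent generation-time oracle ----------------------------------
# Straight-line re-statement of the screening rule, qSOFA and the Sepsis-3
# SOFA strata. Deliberately does not touch the engine code or its data
# files.

oracle_screen <- function(temp, bc, abx) {
  if (is.na(temp)) return(FALSE)
  temp > 37.5 && (bc || abx)
}

oracle_qsofa <- function(sbp, rr, gcs) {
  s <- 0L
  if (!is.na(sbp) && sbp <= 100) s <- s + 1L
  if (!is.na(rr) && rr >= 22) s <- s + 1L
  if (!is.na(gcs) && gcs < 15) s <- s + 1L
  s
}

oracle_sofa <- function(pao2, fio2, platelets, bilirubin, sbp, dbp, vaso,
                        gcs, creatinine) {
  total <- 0L
  if (!is.na(pao2) && !is.na(fio2) && fio2 > 0) {
    r <- pao2 / fio2
    total <- total +
      if (r < 100) 4L else if (r < 200) 3L else if (r < 300) 2L else
        if (r < 400) 1L else 0L
  }
  if (!is.na(platelets)) {
    total <- total +
      if (platelets < 20) 4L else if (platelets < 50) 3L else
        if (platelets < 100) 2L else if (platelets < 150) 1L else 0L
  }
  if (!is.na(bilirubin)) {
    total <- total +
      if (bilirubin >= 12) 4L else if (bilirubin >= 6) 3L else
        if (bilirubin >= 2) 2L else if (bilirubin >= 1.2) 1L else 0L
  }
  if (vaso) {
    total <- total + 3L
  } else if (!is.na(sbp) && !is.na(dbp)) {
    if ((sbp + 2 * dbp) / 3 < 70) total <- total + 1L
  }
  if (!is.na(gcs)) {
    total <- total +
      if (gcs < 6) 4L else if (gcs < 10) 3L else if (gcs < 13) 2L else
        if (gcs < 15) 1L else 0L
  }
  if (!is.na(creatinine)) {
    total <- total +
      if (creatinine >= 5) 4L else if (creatinine >= 3.5) 3L else
        if (creatinine >= 2) 2L else if (creatinine >= 1.2) 1L else 0L
  }
  total
}

# draw one patient's raw values, order flags and oracle truth
draw_sepsis_patient <- function(profile, index) {
  set.seed(seed_for(profile, index))
  septic <- stats::runif(1) < profile$sepsis_prevalence
  derange <- function(p_if_septic, p_if_not = 0.05) {
    stats::runif(1) < (if (septic) p_if_septic else p_if_not)
  }
  miss_lab <- function() stats::runif(1) < profile$lab_missingness
  miss_vital <- function() stats::runif(1) < profile$vital_missingness

  temp <- if (miss_vital()) NA else round(draw_vital("body_temperature",
                                                     derange(0.9)), 1)
  sbp <- if (miss_vital()) NA else round(draw_vital("sbp", derange(0.8)))
  dbp <- if (miss_vital()) NA else round(draw_vital("dbp", derange(0.8)))
  rr <- if (miss_vital()) NA else round(draw_vital("resp_rate", derange(0.8)))
  gcs <- if (miss_vital()) NA else if (septic && stats::runif(1) < 0.5) {
    sample(3:14, 1)
  } else {
    sample(c(rep(15, 9), 13, 14), 1)
  }
  pao2 <- if (miss_lab()) NA else round(draw_vital("pao2", derange(0.8)))
  fio2 <- if (miss_lab()) NA else round(draw_vital("fio2", derange(0.8)), 2)
  platelets <- if (miss_lab()) NA else round(draw_vital("platelets",
                                                        derange(0.7)))
  creatinine <- if (miss_lab()) NA else round(draw_vital("creatinine",
                                                         derange(0.7)), 2)
  bilirubin <- if (miss_lab()) NA else round(draw_vital("total_bilirubin",
                                                        derange(0.6)), 2)
  lactate <- if (miss_lab()) NA else round(draw_vital("lactate",
                                                      derange(0.8)), 2)
  op <- profile$order_probabilities[[if (septic) "septic" else "nonseptic"]]
  bc <- stats::runif(1) < op[["blood_culture"]]
  abx <- stats::runif(1) < op[["antibiotics"]]
  vaso <- stats::runif(1) < op[["vasopressor"]]

  list(
    index = index, septic = septic,
    values = list(gcs = gcs, sbp = sbp, dbp = dbp, resp_rate = rr,
                  body_temperature = temp, pao2 = pao2, fio2 = fio2,
                  platelets = platelets, creatinine = creatinine,
                  total_bilirubin = bilirubin, lactate = lactate),
    orders = list(blood_culture = bc, antibiotics = abx, vasopressor = vaso),
    truth = list(
      septic = septic,
      expected_screen_flag = oracle_screen(temp, bc, abx),
      expected_qsofa = oracle_qsofa(sbp, rr, gcs),
      expected_sofa = oracle_sofa(pao2, fio2, platelets, bilirubin, sbp,
                                  dbp, vaso, gcs, creatinine)))
}

#' Draw raw sepsis-engine inputs with ground truth (no FHIR wrapping)
#'
#' The same per-patient draw that [generate_patient_bundle()] wraps in FHIR,
#' returned as flat tables. Useful for large oracle-agreement runs.
#'
#' @param profile a [cohort_profile()].
#' @return list of data frames `inputs` (one row per patient, the
#'   14 engine inputs) and `truth` (`septic`, `expected_screen_flag`,
#'   `expected_qsofa`, `expected_sofa`).
#' @export
generate_sepsis_inputs <- function(profile) {
  stopifnot(inherits(profile, "cohort_profile"))
  draws <- lapply(seq_len(profile$n), draw_sepsis_patient, profile = profile)
  inputs <- do.call(rbind, lapply(draws, function(d) {
    data.frame(c(d$values,
                 list(blood_culture_ordered = d$orders$blood_culture,
                      antibiotics_ordered = d$orders$antibiotics,
                      vasopressor_ordered = d$orders$vasopressor)),
               stringsAsFactors = FALSE)
  }))
  truth <- do.call(rbind, lapply(draws, function(d) {
    data.frame(d$truth, stringsAsFactors = FALSE)
  }))
  list(inputs = inputs, truth = truth)
}

REFERENCE_TIME <- "2024-03-01T12:00:00Z"

#' Generate one synthetic patient bundle with ground truth
#'
#' The bundle holds a Patient, an emergency Encounter, one final Observation
#' per generated vital/lab (timestamped within the 24 h lookback; FiO2 is
#' emitted in percent to exercise unit normalization) and
#' MedicationRequest/ServiceRequest entries for the sampled orders (ATC J01*
#' antibiotic, C01CA* vasopressor, SNOMED blood culture). Ground truth is
#' computed by the built-in oracle at generation time.
#'
#' @param profile a [cohort_profile()].
#' @param index patient index (1-based); `(profile, index, seed)` fully
#'   determines the output.
#' @return list with `bundle` (a [fhir_bundle()]) and `truth` (one-row data
#'   frame including `patient_id` and `reference_time`).
#' @export
generate_patient_bundle <- function(profile, index) {
  stopifnot(inherits(profile, "cohort_profile"))
  d <- draw_sepsis_patient(profile, index)
  set.seed(seed_for(profile, index, stream = 1L))
  ref <- parse_iso8601(REFERENCE_TIME)
  pid <- sprintf("p%04d", index)
  age <- sample(18:90, 1)
  birth <- format(as.Date(ref) - round(age * 365.25) - sample(0:180, 1),
                  "%Y-%m-%d")
  entries <- list(
    fhir_patient(pid, birth, sample(c("male", "female"), 1)),
    fhir_encounter(paste0("e", pid), pid, "emergency",
                   ref, arrival_mode = sample(
                     c("ambulance", "walk_in", "transfer"), 1,
                     prob = c(0.35, 0.6, 0.05))))
  loinc <- c(gcs = "9269-2", sbp = "8480-6", dbp = "8462-4",
             resp_rate = "9279-1", body_temperature = "8310-5",
             pao2 = "2703-7", fio2 = "3150-0", platelets = "777-3",
             creatinine = "2160-0", total_bilirubin = "1975-2",
             lactate = "2524-7")
  unit <- c(gcs = "1", sbp = "mm[Hg]", dbp = "mm[Hg]", resp_rate = "/min",
            body_temperature = "Cel", pao2 = "mm[Hg]", fio2 = "%",
            platelets = "10*3/uL", creatinine = "mg/dL",
            total_bilirubin = "mg/dL", lactate = "mmol/L")
  k <- length(entries)
  for (nm in names(d$values)) {
    v <- d$values[[nm]]
    if (is.na(v)) next
    if (nm == "fio2") v <- round(v * 100, 1)  # wire unit is percent
    k <- k + 1
    entries[[k]] <- fhir_observation(
      id = sprintf("%s-obs-%s", pid, nm), subject_ref = pid,
      code_system = "LOINC", code = loinc[[nm]], value = v,
      unit = unit[[nm]],
      effective_time = ref - round(stats::runif(1, 0.5, 6) * 3600),
      status = "final")
  }
  if (d$orders$blood_culture) {
    k <- k + 1
    entries[[k]] <- fhir_service_request(
      paste0(pid, "-sr-bc"), pid, "SNOMED", "30088009",
      ref - round(stats::runif(1, 0.2, 4) * 3600))
  }
  if (d$orders$antibiotics) {
    k <- k + 1
    entries[[k]] <- fhir_medication_request(
      paste0(pid, "-mr-abx"), pid, "ATC",
      sample(c("J01CA04", "J01DD04", "J01DH02"), 1),
      ref - round(stats::runif(1, 0.2, 4) * 3600))
  }
  if (d$orders$vasopressor) {
    k <- k + 1
    entries[[k]] <- fhir_medication_request(
      paste0(pid, "-mr-vaso"), pid, "ATC", "C01CA03",
      ref - round(stats::runif(1, 0.2, 4) * 3600))
  }
  truth <- data.frame(patient_id = pid, reference_time = REFERENCE_TIME,
                      d$truth, age = age, stringsAsFactors = FALSE)
  list(bundle = fhir_bundle(entries, bundle_id = paste0("bundle-", pid)),
       truth = truth)
}

#' Generate a full synthetic cohort
#'
#' @param profile a [cohort_profile()].
#' @return list with `bundles` (list of [fhir_bundle()]) and `truth` (data
#'   frame, one row per patient).
#' @export
generate_cohort <- function(profile) {
  out <- lapply(seq_len(profile$n), generate_patient_bundle,
                profile = profile)
  list(bundles = lapply(out, `[[`, "bundle"),
       truth = do.call(rbind, lapply(out, `[[`, "truth")))
}

SEPSIS_CONDITION_CONCEPT <- 132797L

#' Materialize an OMOP-CDM-like local store for the cohort
#'
#' Persons and ED visits for every patient; a sepsis condition row
#' (concept 132797) for septic patients; drug exposures for patients with
#' an antibiotics order, with the drug concept drawn from the profile's
#' antibiotic mixture; inpatient visits and death rows sampled from the
#' profile's outcome probabilities. Referential integrity holds by
#' construction and is re-validated by [local_store()].
#'
#' @param profile a [cohort_profile()].
#' @return a [local_store()].
#' @export
generate_local_store <- function(profile) {
  stopifnot(inherits(profile, "cohort_profile"))
  draws <- lapply(seq_len(profile$n), draw_sepsis_patient, profile = profile)
  set.seed(seed_for(profile, 0L, stream = 2L))
  ref <- parse_iso8601(REFERENCE_TIME)
  n <- profile$n
  pid <- sprintf("p%04d", seq_len(n))
  septic <- vapply(draws, `[[`, logical(1), "septic")
  abx <- vapply(draws, function(d) d$orders$antibiotics, logical(1))

  person <- data.frame(person_id = pid,
                       birth_date = format(as.Date(ref) -
                                             sample(18:90, n, TRUE) * 365,
                                           "%Y-%m-%d"),
                       sex_concept = sample(c(8507L, 8532L), n, TRUE),
                       stringsAsFactors = FALSE)
  visit <- data.frame(visit_id = paste0("v", pid), person_id = pid,
                      class = "emergency",
                      start = format_iso8601(ref - 3600 * 6),
                      end = format_iso8601(ref),
                      stringsAsFactors = FALSE)
  op <- profile$outcome_probs
  p_hosp <- ifelse(septic, op$septic[["hospitalization"]],
                   op$nonseptic[["hospitalization"]])
  p_death <- ifelse(septic, op$septic[["death"]], op$nonseptic[["death"]])
  hosp <- stats::runif(n) < p_hosp
  died <- stats::runif(n) < p_death
  if (any(hosp)) {
    visit <- rbind(visit, data.frame(
      visit_id = paste0("vh", pid[hosp]), person_id = pid[hosp],
      class = "inpatient", start = format_iso8601(ref),
      end = format_iso8601(ref + 3600 * 24 * 5), stringsAsFactors = FALSE))
  }
  condition <- if (any(septic)) {
    data.frame(person_id = pid[septic],
               condition_concept_id = SEPSIS_CONDITION_CONCEPT,
               time = format_iso8601(ref), stringsAsFactors = FALSE)
  } else NULL
  drug <- if (any(abx)) {
    data.frame(person_id = pid[abx],
               drug_concept_id = as.integer(sample(
                 names(profile$antibiotic_mixture), sum(abx), TRUE,
                 prob = profile$antibiotic_mixture)),
               time = format_iso8601(ref), stringsAsFactors = FALSE)
  } else NULL
  death <- if (any(died)) {
    data.frame(person_id = pid[died],
               time = format_iso8601(ref + 3600 * 24 * 3),
               stringsAsFactors = FALSE)
  } else NULL
  local_store(person = person, visit = visit, condition = condition,
              drug_exposure = drug, death = death)
}

#' Generate a triage training table with known outcome model
#'
#' One row per ED visit: the [triage_input()] fields plus 0/1 outcome
#' columns sampled from independent logistic models on the encoded
#' features, using the profile's `triage_coefficients`. The generating
#' coefficients (expanded to the full encoded coordinate system, zeros
#' elsewhere) and the true per-row outcome probabilities are attached as
#' attributes `"coefficients"` and `"true_probabilities"` for recovery and
#' calibration tests.
#'
#' @param profile a [cohort_profile()].
#' @return data frame of `profile$n` rows.
#' @export
generate_triage_dataset <- function(profile) {
  stopifnot(inherits(profile, "cohort_profile"))
  set.seed(seed_for(profile, 0L, stream = 3L))
  n <- profile$n
  cc <- load_chief_complaints()$code
  tab <- load_vital_distributions()
  # derangement is sampled independently per vital so the design matrix is
  # not collinear through a single severity factor; recovery experiments
  # then have well-conditioned information at moderate n
  draw <- function(feature, digits = 0) {
    deranged <- stats::runif(n) < 0.25
    d <- tab[tab$feature == feature & tab$status == "deranged", ][1, ]
    nr <- tab[tab$feature == feature & tab$status == "normal", ][1, ]
    round(ifelse(deranged,
                 rtrunc_norm(n, d$mean, d$sd, d$lo, d$hi),
                 rtrunc_norm(n, nr$mean, nr$sd, nr$lo, nr$hi)), digits)
  }
  ds <- data.frame(
    age = round(rtrunc_norm(n, 52, 20, 18, 95)),
    sex = sample(c("male", "female"), n, TRUE),
    chief_complaint = sample(cc, n, TRUE),
    onset_to_visit = round(stats::rexp(n, 1 / 12), 1),
    arrival_mode = sample(c("walk_in", "ambulance", "transfer"), n, TRUE,
                          prob = c(0.60, 0.35, 0.05)),
    trauma = stats::runif(n) < 0.25,
    sbp = draw("sbp"), dbp = draw("dbp"), heart_rate = draw("heart_rate"),
    resp_rate = draw("resp_rate"),
    body_temperature = draw("body_temperature", digits = 1),
    spo2 = draw("spo2"),
    mental_status = sample(AVPU_LEVELS, n, TRUE,
                           prob = c(0.85, 0.08, 0.04, 0.03)),
    stringsAsFactors = FALSE)
  X <- encode_triage_frame(ds)
  nms <- colnames(X)
  full_coef <- list()
  true_p <- list()
  for (oc in names(profile$triage_coefficients)) {
    beta <- stats::setNames(numeric(length(nms)), nms)
    given <- profile$triage_coefficients[[oc]]
    if (!all(names(given) %in% nms)) {
      cdskit_abort(sprintf("unknown coefficient name(s) for '%s'", oc),
                   "cdskit_contract_error")
    }
    beta[names(given)] <- given
    p <- stats::plogis(as.numeric(X %*% beta))
    ds[[oc]] <- as.integer(stats::runif(n) < p)
    full_coef[[oc]] <- beta
    true_p[[oc]] <- p
  }
  attr(ds, "coefficients") <- full_coef
  attr(ds, "true_probabilities") <- true_p
  ds
}
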