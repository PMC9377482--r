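# cdskit

A desk-scale clinical decision support (CDS) platform for R. `cdskit` is
aimed at clinical-informatics teams who need a self-contained, testable model
of the full CDS pipeline — from an HL7 FHIR R4 payload to a rendered
decision-support document — without a hospital integration, a vocabulary
server, or any patient data.

The package covers five cooperating layers:

* **FHIR I/O** — parse, validate and serialize collection bundles holding a
  typed subset of R4 resources (Patient, Encounter, Observation,
  MedicationRequest, ServiceRequest). Unknown resource types are carried
  opaquely, never dropped.
* **Vocabulary preprocessing** — a bundled LOINC/ATC mini-vocabulary maps
  codes to canonical features, normalizes units (e.g. °F → °C, % → fraction)
  and selects the latest final observation inside a configurable lookback
  window, producing the exact feature record a reasoning engine declares it
  needs.
* **Reasoning engines**, hosted in a pluggable registry:
  * a **knowledge-based Sepsis-3 advisor**: suspected-infection screening
    (temperature strictly above 37.5 °C together with a blood-culture or
    antibiotics order), qSOFA (SBP ≤ 100 mmHg, RR ≥ 22 /min, GCS < 15;
    positive at ≥ 2), the six-organ SOFA score (0–24), septic-shock
    determination (vasopressor order and lactate > 2 mmol/L), and an
    hour-1-bundle-style treatment list with already-completed practices
    marked;
  * a **retrainable ED triage predictor**: three independent logistic heads
    for hospital mortality, critical care and hospitalization over a frozen
    encoding of the triage-stage inputs, with quintile risk bands (1–5)
    stored in a plain-JSON model artifact.
* **Federated summaries** — population-level reports (antibiotic usage,
  outcomes) built from an OMOP-CDM-like local store with small-cell
  suppression at threshold *k*, merged across institutions with
  re-suppression; a schema gate rejects any peer payload containing
  person-level fields.
* **Synthetic fixtures** — a seed-deterministic cohort generator with an
  independent generation-time score oracle, so every layer is testable
  offline.

The core clinical logic follows the Sepsis-3 consensus: sepsis is suspected
infection plus organ dysfunction, operationalized as a total SOFA score of at
least 2 over an assumed baseline of 0,

```
qSOFA = [SBP ≤ 100] + [RR ≥ 22] + [GCS < 15],          qSOFA⁺  ⇔  qSOFA ≥ 2
SOFA  = Σ organ subscores,  organ ∈ {respiration, coagulation, liver,
                                     cardiovascular, CNS, renal},  each 0–4
MAP   = (SBP + 2·DBP) / 3
```

## Worked example

Build a febrile, hypotensive ED patient as a FHIR bundle and run the sepsis
engine through the full service pipeline:

```r
library(cdskit)

b <- fhir_bundle(list(
  fhir_patient("p1", "1958-04-02", "male"),
  fhir_encounter("e1", "p1", "emergency", "2024-03-01T12:00:00Z"),
  fhir_observation("o-temp", "p1", "LOINC", "8310-5", value = 38.8,
                   unit = "Cel", effective_time = "2024-03-01T11:20:00Z"),
  fhir_observation("o-gcs", "p1", "LOINC", "9269-2", value = 12, unit = "1",
                   effective_time = "2024-03-01T11:25:00Z"),
  fhir_observation("o-sbp", "p1", "LOINC", "8480-6", value = 88,
                   unit = "mm[Hg]", effective_time = "2024-03-01T11:25:00Z"),
  fhir_observation("o-dbp", "p1", "LOINC", "8462-4", value = 46,
                   unit = "mm[Hg]", effective_time = "2024-03-01T11:25:00Z"),
  fhir_observation("o-rr", "p1", "LOINC", "9279-1", value = 26,
                   unit = "/min", effective_time = "2024-03-01T11:25:00Z"),
  fhir_observation("o-lact", "p1", "LOINC", "2524-7", value = 3.4,
                   unit = "mmol/L", effective_time = "2024-03-01T11:40:00Z"),
  fhir_observation("o-crea", "p1", "LOINC", "2160-0", value = 2.1,
                   unit = "mg/dL", effective_time = "2024-03-01T11:40:00Z"),
  fhir_service_request("sr-bc", "p1", "SNOMED", "30088009",
                       "2024-03-01T11:45:00Z"),
  fhir_medication_request("mr-abx", "p1", "ATC", "J01DD04",
                          "2024-03-01T11:50:00Z")))

handle_request(cds_request("sepsis3", b, "2024-03-01T12:00:00Z"))
#> <cds_response>
#> <sepsis_assessment>
#>   suspected infection: TRUE
#>   qSOFA 3 (positive)  SOFA 5 [missing: respiration, coagulation, liver]
#>   sepsis: TRUE   septic shock: FALSE
#>   recommendations:
#>    [x] Measure serum lactate; remeasure if initial lactate > 2 mmol/L
#>    [x] Obtain blood cultures before administering antibiotics
#>    [x] Administer broad-spectrum antibiotics
#>    [ ] Begin 30 mL/kg crystalloid for hypotension or lactate >= 4 mmol/L
#>    [ ] Apply vasopressors if MAP < 65 mmHg after fluid resuscitation
#>   missing features: pao2, fio2, platelets, total_bilirubin
#>   peer summaries: 0  ui sections: 3
```

Reading the output: the 38.8 °C temperature plus the blood-culture order
screens the patient in; qSOFA is 3/3 (SBP 88 ≤ 100, RR 26 ≥ 22, GCS 12 < 15);
SOFA is 5 from the cardiovascular (MAP = 60 mmHg), CNS (GCS 12) and renal
(creatinine 2.1 mg/dL) systems, with the lab-starved organs scored 0 and
listed as missing rather than imputed. Screen + SOFA ≥ 2 makes the Sepsis-3
call; the three practices already ordered are check-marked so the display can
emphasize the two that are not.

A command-line front end over the same functions ships in
`inst/cli/cds.R` (`validate`, `run`, `engines`, `triage-train`,
`triage-predict`, `summary`, `fixtures`).

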