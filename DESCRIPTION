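Package: cdskit
Title: Desk-Scale Clinical Decision Support Platform with FHIR Ingestion,
    Sepsis-3 Scoring, ED Triage Prediction, and Federated Summaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained clinical decision support (CDS) platform at desk
    scale. Parses and validates a typed subset of HL7 FHIR R4 collection
    bundles (Patient, Encounter, Observation, MedicationRequest,
    ServiceRequest); converts bundles into canonical, unit-normalized feature
    records via a bundled LOINC/ATC mini-vocabulary; hosts a pluggable
    reasoning-engine registry with two shipped engines - a knowledge-based
    Sepsis-3 treatment advisor (suspected-infection screening, qSOFA, SOFA
    organ subscores, septic-shock determination, hour-1-style treatment
    recommendations with completed-practice marks) and a retrainable logistic
    emergency-department triage predictor (hospital mortality, critical care,
    hospitalization, with quintile risk bands); builds population-level
    summary reports from OMOP-CDM-like local stores with small-cell
    suppression and merges reports across institutions without exchanging
    person-level data. Ships a seed-deterministic synthetic-cohort generator
    with independent generation-time score oracles so every component is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
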