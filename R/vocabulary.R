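# Vocabulary-driven preprocessing: concept mapping, unit normalization and
# latest-value feature extraction. The bundled mini-vocabulary covers the
# measured inputs of the shipped engines (LOINC), an ATC prefix list defining
# antibiotics (J01*) and vasopressors/inotropes (C01CA*), and a blood-culture
# procedure code. Full OMOP vocabulary ingestion is a non-goal.

the <- new.env(parent = emptyenv())

#' Load the bundled concept vocabulary
#'
#' @param path delimited file with header
#'   `source_system,source_code,feature_name,omop_concept_id,canonical_unit`.
#'   Defaults to the vocabulary shipped with the package.
#' @return data frame of concept mappings (invisibly cached as the default).
#' @export
load_vocabulary <- function(path = ext_file("vocabulary.csv")) {
  v <- read_table_file(path)
  key <- paste(v$source_system, v$source_code, sep = "|")
  if (anyDuplicated(key)) {
    cdskit_abort("vocabulary contains duplicate (source_system, source_code) pairs",
                 "cdskit_validation_error")
  }
  if (any(v$omop_concept_id <= 0)) {
    cdskit_abort("omop_concept_id must be positive", "cdskit_validation_error")
  }
  the$vocabulary <- v
  invisible(v)
}

default_vocabulary <- function() {
  if (is.null(the$vocabulary)) load_vocabulary()
  the$vocabulary
}

#' Map a source code to its canonical concept
#'
#' @param system coding system (e.g. `"LOINC"`).
#' @param code source code (e.g. `"8310-5"`).
#' @param vocabulary mapping table; defaults to the bundled vocabulary.
#' @return a list with `source_system`, `source_code`, `feature_name`,
#'   `omop_concept_id`, `canonical_unit`, or `NULL` when the code is not
#'   mapped (a typed miss, not an error — misses are recorded in the
#'   preprocessing log by [extract_features()]).
#' @export
map_code <- function(system, code, vocabulary = default_vocabulary()) {
  hit <- vocabulary[vocabulary$source_system == system &
                      vocabulary$source_code == code, , drop = FALSE]
  if (!nrow(hit)) return(NULL)
  as.list(hit[1, ])
}

unit_formulas <- list(
  identity = function(x) x,
  fahrenheit_to_celsius = function(x) (x - 32) * 5 / 9,
  kelvin_to_celsius = function(x) x - 273.15,
  percent_to_fraction = function(x) x / 100,
  per_litre_to_per_decilitre_mg = function(x) x * 100 / 1000,
  umol_per_l_creatinine_to_mg_per_dl = function(x) x / 88.42
)

load_conversions <- function(path = ext_file("unit_conversions.csv")) {
  if (is.null(the$conversions)) the$conversions <- read_table_file(path)
  the$conversions
}

#' Convert a value to an engine's canonical unit
#'
#' Identity when the units already agree; otherwise the (from, to) pair must
#' be present in the bundled conversion registry.
#'
#' @param value numeric.
#' @param unit unit the value is expressed in.
#' @param canonical_unit target unit.
#' @return numeric value in the canonical unit.
#' @export
normalize_unit <- function(value, unit, canonical_unit) {
  if (identical(unit, canonical_unit)) return(value)
  reg <- load_conversions()
  hit <- reg[reg$from_unit == unit & reg$to_unit == canonical_unit, , drop = FALSE]
  if (!nrow(hit)) {
    cdskit_abort(sprintf("no registered conversion from '%s' to '%s'",
                         unit, canonical_unit), "cdskit_unit_error")
  }
  unit_formulas[[hit$formula_id[1]]](value)
}

#' Describe an engine's input contract
#'
#' @param engine_name,version identity of the engine.
#' @param kind `"knowledge_based"` or `"nonknowledge_based"`.
#' @param required_features data frame with columns `feature_name`,
#'   `canonical_unit`, `required` (logical) and `kind`
#'   (`"observation"`, `"order"` or `"demographic"`).
#' @param lookback_hours how far back from the reference time observations
#'   and orders are eligible (default 24 h).
#' @return an object of class `engine_descriptor`.
#' @export
engine_descriptor <- function(engine_name, version, kind, required_features,
                              lookback_hours = 24) {
  stopifnot(kind %in% c("knowledge_based", "nonknowledge_based"),
            lookback_hours > 0,
            !anyDuplicated(required_features$feature_name))
  structure(list(engine_name = engine_name, version = version, kind = kind,
                 required_features = required_features,
                 lookback_hours = lookback_hours),
            class = "engine_descriptor")
}

#' @export
print.engine_descriptor <- function(x, ...) {
  cat(sprintf("<engine_descriptor> %s v%s (%s), %d features, lookback %g h\n",
              x$engine_name, x$version, x$kind,
              nrow(x$required_features), x$lookback_hours))
  invisible(x)
}

avpu_to_gcs <- c(A = 15, V = 12, P = 8, U = 3)

load_order_classes <- function() {
  if (is.null(the$order_classes)) {
    the$order_classes <- read_table_file(ext_file("order_classes.csv"))
  }
  the$order_classes
}

log_row <- function(resource_id, system, code, feature, event) {
  data.frame(resource_id = resource_id, system = system, code = code,
             feature = feature, event = event, stringsAsFactors = FALSE)
}

#' Extract an engine's canonical feature record from a bundle
#'
#' Embodies the preprocessing stage between the FHIR payload and a reasoning
#' engine. For each observation-type feature the latest final Observation
#' within `[reference_time - lookback, reference_time]` wins (ties in
#' observed time broken by bundle entry order); values are converted to the
#' descriptor's canonical unit. Order-type features (blood culture,
#' antibiotics, vasopressors) become booleans, true iff a matching
#' active/completed request exists in-window. Demographic features (age, sex,
#' arrival mode) are read from Patient/Encounter entries. Preliminary
#' observations and unmapped codes never contribute; both are noted in the
#' preprocessing log. Required features that cannot be filled land in
#' `missing` — missingness is data, not an error.
#'
#' @param bundle a [fhir_bundle()].
#' @param descriptor an [engine_descriptor()].
#' @param reference_time POSIXct or ISO-8601 string; the clinical "now".
#' @return an object of class `feature_record`: `patient_id`,
#'   `reference_time`, `features` (named list of `value`, `unit`,
#'   `observed_time`, `provenance`), `missing` (character vector) and `log`
#'   (data frame of mapping events).
#' @export
extract_features <- function(bundle, descriptor, reference_time) {
  stopifnot(inherits(bundle, "fhir_bundle"),
            inherits(descriptor, "engine_descriptor"))
  ref <- if (inherits(reference_time, "POSIXct")) reference_time else
    parse_iso8601(reference_time)
  if (is.na(ref)) cdskit_abort("unparseable reference_time", "cdskit_parse_error")
  window_start <- ref - descriptor$lookback_hours * 3600

  wanted <- descriptor$required_features
  feats <- list()
  logs <- list()
  add_log <- function(x) logs[[length(logs) + 1L]] <<- x

  patient <- NULL; encounter <- NULL
  for (e in bundle$entries) {
    if (inherits(e, "fhir_patient") && is.null(patient)) patient <- e
    if (inherits(e, "fhir_encounter") && is.null(encounter)) encounter <- e
  }
  patient_id <- patient$id %||%
    (if (length(bundle$entries)) bundle$entries[[1]]$subject_ref else NULL) %||%
    NA_character_

  # observation features: scan entries in order, keep latest-in-window final
  obs_rows <- wanted[wanted$kind == "observation", , drop = FALSE]
  best <- list()  # feature -> list(value, unit, time, provenance)
  for (e in bundle$entries) {
    if (!inherits(e, "fhir_observation")) next
    m <- map_code(e$code$system, e$code$code)
    if (is.null(m)) {
      add_log(log_row(e$id, e$code$system, e$code$code, NA_character_,
                      "unmapped_code"))
      next
    }
    if (!m$feature_name %in% obs_rows$feature_name) next
    if (!identical(e$status, "final")) {
      add_log(log_row(e$id, e$code$system, e$code$code, m$feature_name,
                      "ignored_preliminary"))
      next
    }
    t_obs <- parse_iso8601(e$effective_time)
    if (is.na(t_obs) || t_obs < window_start || t_obs > ref) {
      add_log(log_row(e$id, e$code$system, e$code$code, m$feature_name,
                      "outside_lookback"))
      next
    }
    canonical <- obs_rows$canonical_unit[obs_rows$feature_name == m$feature_name]
    if (!is.null(e$value_quantity)) {
      val <- normalize_unit(e$value_quantity$value, e$value_quantity$unit,
                            canonical)
    } else {
      val <- e$value_coded$code  # coded observations stay coded
    }
    prev <- best[[m$feature_name]]
    # strictly-later wins; equal times keep the earlier entry (bundle order)
    if (is.null(prev) || t_obs > prev$observed_time) {
      best[[m$feature_name]] <- list(value = val, unit = canonical,
                                     observed_time = t_obs, provenance = e$id)
    }
  }
  feats <- best

  # AVPU fallback for GCS: coded mental status maps A/V/P/U -> 15/12/8/3
  if ("gcs" %in% obs_rows$feature_name && is.null(feats[["gcs"]]) &&
      !is.null(feats[["mental_status_avpu"]])) {
    av <- feats[["mental_status_avpu"]]
    g <- avpu_to_gcs[[toupper(as.character(av$value))]]
    if (!is.null(g)) {
      feats[["gcs"]] <- list(value = g, unit = "1",
                             observed_time = av$observed_time,
                             provenance = av$provenance)
      add_log(log_row(av$provenance, "AVPU", as.character(av$value), "gcs",
                      "avpu_mapped_to_gcs"))
    }
  }

  # order features: any matching active/completed request in-window
  classes <- load_order_classes()
  for (fn in wanted$feature_name[wanted$kind == "order"]) {
    rule <- classes[classes$feature_name == fn, , drop = FALSE]
    hit <- NULL
    for (e in bundle$entries) {
      code <- if (inherits(e, "fhir_medication_request")) e$medication_code
      else if (inherits(e, "fhir_service_request")) e$procedure_code
      else next
      kind_ok <- e$resource_type %in% rule$resource_kind
      if (!kind_ok || !e$status %in% c("active", "completed")) next
      match_ok <- any(rule$system == code$system &
                        startsWith(code$code, rule$code_prefix))
      if (!match_ok) next
      t_ord <- parse_iso8601(e$authored_time)
      if (is.na(t_ord) || t_ord < window_start || t_ord > ref) next
      hit <- e
      break
    }
    feats[[fn]] <- list(value = !is.null(hit), unit = "bool",
                        observed_time = if (!is.null(hit))
                          parse_iso8601(hit$authored_time) else ref,
                        provenance = hit$id %||% NA_character_)
  }

  # demographics from Patient / Encounter
  for (fn in wanted$feature_name[wanted$kind == "demographic"]) {
    val <- switch(fn,
      age = if (!is.null(patient) && nzchar(patient$birth_date %||% "")) {
        floor(as.numeric(difftime(ref, parse_iso8601(patient$birth_date),
                                  units = "days")) / 365.25)
      },
      sex = patient$sex %||% NULL,
      arrival_mode = encounter$arrival_mode %||% NULL,
      encounter_class = encounter$class_code %||% NULL,
      NULL)
    if (!is.null(val)) {
      feats[[fn]] <- list(value = val, unit = wanted$canonical_unit[
        wanted$feature_name == fn], observed_time = ref,
        provenance = patient$id %||% NA_character_)
    }
  }

  present <- intersect(wanted$feature_name, names(feats))
  missing <- setdiff(wanted$feature_name[wanted$required], present)
  feats <- feats[intersect(names(feats), wanted$feature_name)]

  structure(list(
    patient_id = patient_id,
    reference_time = ref,
    features = feats,
    missing = missing,
    log = if (length(logs)) do.call(rbind, logs) else
      log_row(character(0), character(0), character(0), character(0),
              character(0))
  ), class = "feature_record")
}

#' @export
print.feature_record <- function(x, ...) {
  cat(sprintf("<feature_record> patient %s @ %s: %d features, %d missing\n",
              x$patient_id, format_iso8601(x$reference_time),
              length(x$features), length(x$missing)))
  invisible(x)
}

#' Pull plain feature values out of a feature record
#' @param record a `feature_record`.
#' @param name feature name.
#' @param default returned when the feature is absent.
#' @return the feature's value (numeric, coded string, or logical).
#' @export
feature_value <- function(record, name, default = NA) {
  f <- record$features[[name]]
  if (is.null(f)) default else f$value
}
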