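# FHIR R4 subset: collection Bundles holding Patient, Encounter, Observation,
# MedicationRequest and ServiceRequest resources. Unsupported resource types
# are carried opaquely (flagged, never dropped) so real-world bundles degrade
# gracefully. JSON handling is jsonlite throughout; XML FHIR is out of scope.

SUPPORTED_RESOURCE_TYPES <- c(
  "Patient", "Encounter", "Observation", "MedicationRequest", "ServiceRequest"
)

new_coded_value <- function(system, code, display = NULL) {
  list(system = as.character(system), code = as.character(code),
       display = display)
}

#' Construct an Observation resource
#'
#' Exactly one of `value_quantity` (a numeric value with a unit string) or
#' `value_coded` (a system/code pair, e.g. an AVPU mental-status code) must be
#' given.
#'
#' @param id resource id, unique within its bundle.
#' @param subject_ref patient id the observation is about.
#' @param code_system,code coding of what was measured (e.g. `"LOINC"`,
#'   `"8310-5"` for body temperature).
#' @param value numeric value, for quantity observations.
#' @param unit unit string accompanying `value`.
#' @param value_system,value_code coded value, for coded observations.
#' @param effective_time ISO-8601 string or POSIXct; when the value was
#'   observed.
#' @param status `"final"` or `"preliminary"`; only final values feed
#'   decisions downstream.
#' @return an object of class `fhir_observation`.
#' @export
fhir_observation <- function(id, subject_ref, code_system, code,
                             value = NULL, unit = NULL,
                             value_system = NULL, value_code = NULL,
                             effective_time, status = "final") {
  structure(list(
    resource_type = "Observation",
    id = as.character(id),
    subject_ref = as.character(subject_ref),
    code = new_coded_value(code_system, code),
    value_quantity = if (!is.null(value)) list(value = as.numeric(value),
                                               unit = as.character(unit)),
    value_coded = if (!is.null(value_code)) new_coded_value(value_system,
                                                            value_code),
    effective_time = if (inherits(effective_time, "POSIXct"))
      format_iso8601(effective_time) else as.character(effective_time),
    status = status
  ), class = c("fhir_observation", "fhir_resource"))
}

#' Construct a MedicationRequest resource
#'
#' @param id resource id.
#' @param subject_ref patient id.
#' @param code_system,code medication coding (ATC or RxNorm).
#' @param authored_time ISO-8601 string or POSIXct.
#' @param status `"active"` or `"completed"`.
#' @return an object of class `fhir_medication_request`.
#' @export
fhir_medication_request <- function(id, subject_ref, code_system, code,
                                    authored_time, status = "active") {
  structure(list(
    resource_type = "MedicationRequest",
    id = as.character(id),
    subject_ref = as.character(subject_ref),
    medication_code = new_coded_value(code_system, code),
    intent = "order",
    authored_time = if (inherits(authored_time, "POSIXct"))
      format_iso8601(authored_time) else as.character(authored_time),
    status = status
  ), class = c("fhir_medication_request", "fhir_resource"))
}

#' Construct a ServiceRequest resource
#'
#' @inheritParams fhir_medication_request
#' @param code_system,code procedure coding (e.g. a blood-culture order).
#' @return an object of class `fhir_service_request`.
#' @export
fhir_service_request <- function(id, subject_ref, code_system, code,
                                 authored_time, status = "active") {
  structure(list(
    resource_type = "ServiceRequest",
    id = as.character(id),
    subject_ref = as.character(subject_ref),
    procedure_code = new_coded_value(code_system, code),
    authored_time = if (inherits(authored_time, "POSIXct"))
      format_iso8601(authored_time) else as.character(authored_time),
    status = status
  ), class = c("fhir_service_request", "fhir_resource"))
}

#' Construct a Patient resource
#' @param id patient id.
#' @param birth_date `YYYY-MM-DD`.
#' @param sex administrative sex, `"male"`, `"female"` or `"other"`.
#' @return an object of class `fhir_patient`.
#' @export
fhir_patient <- function(id, birth_date, sex) {
  structure(list(
    resource_type = "Patient",
    id = as.character(id),
    birth_date = as.character(birth_date),
    sex = as.character(sex)
  ), class = c("fhir_patient", "fhir_resource"))
}

#' Construct an Encounter resource
#' @param id encounter id.
#' @param subject_ref patient id.
#' @param class_code `"emergency"`, `"inpatient"` or `"outpatient"`.
#' @param start_time ISO-8601 string or POSIXct.
#' @param arrival_mode optional arrival-mode code
#'   (`"ambulance"`, `"walk_in"`, `"transfer"`).
#' @return an object of class `fhir_encounter`.
#' @export
fhir_encounter <- function(id, subject_ref, class_code, start_time,
                           arrival_mode = NULL) {
  structure(list(
    resource_type = "Encounter",
    id = as.character(id),
    subject_ref = as.character(subject_ref),
    class_code = as.character(class_code),
    start_time = if (inherits(start_time, "POSIXct"))
      format_iso8601(start_time) else as.character(start_time),
    arrival_mode = arrival_mode
  ), class = c("fhir_encounter", "fhir_resource"))
}

#' Construct a collection Bundle
#'
#' @param entries list of `fhir_resource` objects (typed or opaque).
#' @param bundle_id opaque bundle identifier.
#' @return an object of class `fhir_bundle`.
#' @export
fhir_bundle <- function(entries = list(), bundle_id = "bundle-1") {
  structure(list(
    bundle_id = as.character(bundle_id),
    bundle_type = "collection",
    entries = entries
  ), class = "fhir_bundle")
}

#' @export
print.fhir_bundle <- function(x, ...) {
  types <- vapply(x$entries, function(e) e$resource_type, character(1))
  cat("<fhir_bundle> id:", x$bundle_id, " type:", x$bundle_type,
      " entries:", length(x$entries), "\n")
  if (length(types)) print(table(types))
  invisible(x)
}

# --- wire format -----------------------------------------------------------

encounter_class_to_wire <- c(emergency = "EMER", inpatient = "IMP",
                             outpatient = "AMB")
encounter_class_from_wire <- stats::setNames(names(encounter_class_to_wire),
                                             encounter_class_to_wire)

coding_to_wire <- function(cv) {
  list(coding = list(list(system = cv$system, code = cv$code)))
}

coding_from_wire <- function(x) {
  cd <- x$coding[[1]]
  new_coded_value(cd$system %||% "", cd$code %||% "")
}

subject_from_wire <- function(x) sub("^Patient/", "", x$reference %||% "")

resource_to_wire <- function(r) {
  switch(r$resource_type,
    Patient = list(resourceType = "Patient", id = r$id,
                   birthDate = r$birth_date, gender = r$sex),
    Encounter = {
      out <- list(resourceType = "Encounter", id = r$id,
                  subject = list(reference = paste0("Patient/", r$subject_ref)),
                  class = list(code = unname(
                    encounter_class_to_wire[[r$class_code]])),
                  period = list(start = r$start_time))
      if (!is.null(r$arrival_mode)) {
        out$hospitalization <- list(admitSource = list(
          coding = list(list(system = "arrival-mode", code = r$arrival_mode))))
      }
      out
    },
    Observation = {
      out <- list(resourceType = "Observation", id = r$id, status = r$status,
                  code = coding_to_wire(r$code),
                  subject = list(reference = paste0("Patient/", r$subject_ref)),
                  effectiveDateTime = r$effective_time)
      if (!is.null(r$value_quantity)) {
        out$valueQuantity <- list(value = r$value_quantity$value,
                                  unit = r$value_quantity$unit)
      }
      if (!is.null(r$value_coded)) {
        out$valueCodeableConcept <- coding_to_wire(r$value_coded)
      }
      out
    },
    MedicationRequest = list(
      resourceType = "MedicationRequest", id = r$id, status = r$status,
      intent = r$intent,
      medicationCodeableConcept = coding_to_wire(r$medication_code),
      subject = list(reference = paste0("Patient/", r$subject_ref)),
      authoredOn = r$authored_time),
    ServiceRequest = list(
      resourceType = "ServiceRequest", id = r$id, status = r$status,
      intent = "order",
      code = coding_to_wire(r$procedure_code),
      subject = list(reference = paste0("Patient/", r$subject_ref)),
      authoredOn = r$authored_time),
    # opaque entry: emit the retained raw payload untouched
    r$raw
  )
}

resource_from_wire <- function(x) {
  rt <- x$resourceType %||% ""
  if (!rt %in% SUPPORTED_RESOURCE_TYPES) {
    return(structure(list(resource_type = rt, id = x$id %||% NA_character_,
                          raw = x, opaque = TRUE),
                     class = c("fhir_opaque", "fhir_resource")))
  }
  switch(rt,
    Patient = fhir_patient(x$id %||% "", x$birthDate %||% "",
                           x$gender %||% "other"),
    Encounter = {
      cls <- encounter_class_from_wire[[x$class$code %||% "AMB"]] %||%
        "outpatient"
      am <- tryCatch(x$hospitalization$admitSource$coding[[1]]$code,
                     error = function(e) NULL)
      fhir_encounter(x$id %||% "", subject_from_wire(x$subject), cls,
                     x$period$start %||% "", arrival_mode = am)
    },
    Observation = {
      vq <- x$valueQuantity
      vc <- x$valueCodeableConcept
      if (!is.null(vq) && !is.null(vc)) {
        cdskit_abort(sprintf(
          "Observation '%s': both valueQuantity and valueCodeableConcept present",
          x$id %||% "?"), "cdskit_validation_error")
      }
      cd <- coding_from_wire(x$code)
      vcd <- if (!is.null(vc)) coding_from_wire(vc)
      fhir_observation(
        id = x$id %||% "", subject_ref = subject_from_wire(x$subject),
        code_system = cd$system, code = cd$code,
        value = vq$value, unit = vq$unit,
        value_system = vcd$system, value_code = vcd$code,
        effective_time = x$effectiveDateTime %||% "",
        status = x$status %||% "final")
    },
    MedicationRequest = {
      cd <- coding_from_wire(x$medicationCodeableConcept)
      fhir_medication_request(x$id %||% "", subject_from_wire(x$subject),
                              cd$system, cd$code, x$authoredOn %||% "",
                              x$status %||% "active")
    },
    ServiceRequest = {
      cd <- coding_from_wire(x$code)
      fhir_service_request(x$id %||% "", subject_from_wire(x$subject),
                           cd$system, cd$code, x$authoredOn %||% "",
                           x$status %||% "active")
    })
}

#' Parse a FHIR R4 JSON collection bundle
#'
#' Supported resource types are converted into typed entries; any other
#' resource type is retained as an opaque, flagged entry rather than dropped.
#' With `strict = TRUE` (the default) a bundle failing [validate_bundle()] is
#' rejected with an error naming the offending resource and field.
#'
#' @param text a JSON string, or the path of a file containing one.
#' @param strict reject bundles with validation issues?
#' @return a [fhir_bundle()].
#' @export
parse_bundle <- function(text, strict = TRUE) {
  if (length(text) == 1L && !grepl("[{]", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  doc <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e) cdskit_abort(
      paste0("malformed JSON: ", conditionMessage(e)), "cdskit_parse_error")
  )
  if (!identical(doc$resourceType, "Bundle")) {
    cdskit_abort("document is not a FHIR Bundle", "cdskit_parse_error")
  }
  if (!identical(doc$type, "collection")) {
    cdskit_abort(sprintf("unsupported bundle type '%s' (only 'collection')",
                         doc$type %||% ""), "cdskit_parse_error")
  }
  entries <- lapply(doc$entry %||% list(),
                    function(e) resource_from_wire(e$resource))
  b <- fhir_bundle(entries, bundle_id = doc$id %||% "bundle")
  if (strict) {
    issues <- validate_bundle(b)
    if (nrow(issues)) {
      cdskit_abort(sprintf(
        "bundle '%s' failed validation: resource '%s', field '%s': %s",
        b$bundle_id, issues$resource_id[1], issues$field[1], issues$rule[1]),
        "cdskit_validation_error")
    }
  }
  b
}

#' Serialize a bundle back to FHIR R4 JSON
#'
#' Inverse of [parse_bundle()]: `parse_bundle(serialize_bundle(b))` is
#' field-identical to `b`, with entry order preserved.
#'
#' @param bundle a [fhir_bundle()].
#' @param path optional file to write to.
#' @return the JSON string, invisibly when `path` is given.
#' @export
serialize_bundle <- function(bundle, path = NULL) {
  stopifnot(inherits(bundle, "fhir_bundle"))
  doc <- list(
    resourceType = "Bundle", id = bundle$bundle_id, type = bundle$bundle_type,
    entry = lapply(bundle$entries, function(r) list(resource = resource_to_wire(r)))
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

issue_row <- function(resource_id, field, rule) {
  data.frame(resource_id = resource_id, field = field, rule = rule,
             stringsAsFactors = FALSE)
}

#' Validate a bundle against the typed-subset invariants
#'
#' Issues are data, not exceptions: an empty data frame means every invariant
#' holds. Checked rules: unique entry ids; exactly one value kind per
#' Observation; parseable timestamps; non-empty medication / procedure codes;
#' patient birth date not after encounter start.
#'
#' @param bundle a [fhir_bundle()].
#' @return data frame with columns `resource_id`, `field`, `rule`.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "fhir_bundle"))
  issues <- list()
  add <- function(x) issues[[length(issues) + 1L]] <<- x

  ids <- vapply(bundle$entries, function(e) e$id %||% NA_character_,
                character(1))
  dup <- duplicated(ids) & !is.na(ids)
  for (i in which(dup)) {
    add(issue_row(ids[i], "id", "entry ids must be unique within bundle"))
  }

  birth_by_patient <- list()
  for (e in bundle$entries) {
    if (inherits(e, "fhir_patient")) birth_by_patient[[e$id]] <- e$birth_date
  }

  for (e in bundle$entries) {
    if (inherits(e, "fhir_observation")) {
      has_q <- !is.null(e$value_quantity)
      has_c <- !is.null(e$value_coded)
      if (has_q == has_c) {
        add(issue_row(e$id, "value",
                      "exactly one of value_quantity / value_coded required"))
      }
      if (is.na(parse_iso8601(e$effective_time))) {
        add(issue_row(e$id, "effective_time", "unparseable timestamp"))
      }
      if (!e$status %in% c("final", "preliminary")) {
        add(issue_row(e$id, "status", "status must be final or preliminary"))
      }
    } else if (inherits(e, "fhir_medication_request")) {
      if (!nzchar(e$medication_code$code %||% "")) {
        add(issue_row(e$id, "medication_code", "medication code must be non-empty"))
      }
      if (is.na(parse_iso8601(e$authored_time))) {
        add(issue_row(e$id, "authored_time", "unparseable timestamp"))
      }
    } else if (inherits(e, "fhir_service_request")) {
      if (!nzchar(e$procedure_code$code %||% "")) {
        add(issue_row(e$id, "procedure_code", "procedure code must be non-empty"))
      }
      if (is.na(parse_iso8601(e$authored_time))) {
        add(issue_row(e$id, "authored_time", "unparseable timestamp"))
      }
    } else if (inherits(e, "fhir_encounter")) {
      if (is.na(parse_iso8601(e$start_time))) {
        add(issue_row(e$id, "start_time", "unparseable timestamp"))
      } else {
        bd <- birth_by_patient[[e$subject_ref]]
        if (!is.null(bd) && !is.na(parse_iso8601(bd)) &&
            parse_iso8601(bd) > parse_iso8601(e$start_time)) {
          add(issue_row(e$id, "start_time",
                        "patient birth_date is after encounter start_time"))
        }
      }
      if (!e$class_code %in% c("emergency", "inpatient", "outpatient")) {
        add(issue_row(e$id, "class_code", "unknown encounter class"))
      }
    }
  }
  if (!length(issues)) {
    return(issue_row(character(0), character(0), character(0)))
  }
  do.call(rbind, issues)
}
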