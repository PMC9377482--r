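# Request/response orchestration: a pluggable in-process engine registry and
# the preprocessing -> engine -> integration pipeline. Engines are invoked
# on demand only (no interruptive alerting); failures are typed response
# documents, never raw conditions, so an EHR-side integration can always
# render something. The service layer adds no clinical content of its own:
# every number in the UI payload traces to an engine result or a summary
# report.

#' Create an empty engine registry
#' @return an environment-backed registry object.
#' @export
engine_registry <- function() {
  structure(list(env = new.env(parent = emptyenv())),
            class = "engine_registry")
}

registry_key <- function(name, version) paste(name, version, sep = "@")

#' Register a reasoning engine
#'
#' @param registry an [engine_registry()].
#' @param descriptor the engine's [engine_descriptor()].
#' @param fn engine callable: `feature_record` in, result object out.
#' @return the registry, invisibly.
#' @export
register_engine <- function(registry, descriptor, fn) {
  stopifnot(inherits(registry, "engine_registry"),
            inherits(descriptor, "engine_descriptor"), is.function(fn))
  key <- registry_key(descriptor$engine_name, descriptor$version)
  if (!is.null(registry$env[[key]])) {
    cdskit_abort(sprintf("engine '%s' already registered", key),
                 "cdskit_contract_error")
  }
  registry$env[[key]] <- list(descriptor = descriptor, fn = fn)
  invisible(registry)
}

#' List registered engines
#' @param registry an [engine_registry()].
#' @return data frame of `name`, `version`, `kind`, `n_features`.
#' @export
list_engines <- function(registry) {
  keys <- sort(ls(registry$env))
  rows <- lapply(keys, function(k) {
    d <- registry$env[[k]]$descriptor
    data.frame(name = d$engine_name, version = d$version, kind = d$kind,
               n_features = nrow(d$required_features),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(name = character(0), version = character(0),
                      kind = character(0), n_features = integer(0)))
  }
  do.call(rbind, rows)
}

resolve_engine <- function(registry, name, version = NULL) {
  keys <- ls(registry$env)
  hit <- if (is.null(version)) {
    cand <- sort(keys[startsWith(keys, paste0(name, "@"))], decreasing = TRUE)
    if (length(cand)) cand[1] else NA_character_
  } else {
    k <- registry_key(name, version)
    if (k %in% keys) k else NA_character_
  }
  if (is.na(hit)) return(NULL)
  registry$env[[hit]]
}

#' Load the engine manifest and register the shipped engines
#'
#' Engines are in-process plugins discovered from a delimited manifest
#' (`name,version,constructor`); each constructor is an exported function
#' returning `list(descriptor, fn)`.
#'
#' @param path manifest file; defaults to the bundled one (sepsis3 and
#'   edtriage).
#' @return a populated [engine_registry()].
#' @export
default_registry <- function(path = ext_file("engine_manifest.csv")) {
  man <- read_table_file(path)
  reg <- engine_registry()
  for (i in seq_len(nrow(man))) {
    ctor <- get(man$constructor[i], envir = asNamespace("cdskit"))
    eng <- ctor()
    register_engine(reg, eng$descriptor, eng$fn)
  }
  reg
}

#' Construct a CDS request
#'
#' @param engine_name registered engine to run.
#' @param bundle the patient's [fhir_bundle()].
#' @param reference_time clinical "now" (POSIXct or ISO-8601).
#' @param include_peer_summaries request population summaries from peers?
#' @param peers list of peer endpoint callables (see [local_peer()]).
#' @param cohort optional [cohort_spec()] for the peer summaries.
#' @param k suppression threshold forwarded to peers.
#' @return an object of class `cds_request`.
#' @export
cds_request <- function(engine_name, bundle, reference_time,
                        include_peer_summaries = FALSE, peers = list(),
                        cohort = NULL, k = 10) {
  stopifnot(inherits(bundle, "fhir_bundle"))
  structure(list(engine_name = engine_name, bundle = bundle,
                 reference_time = reference_time,
                 options = list(include_peer_summaries = include_peer_summaries,
                                peers = peers, cohort = cohort, k = k)),
            class = "cds_request")
}

error_response <- function(kind, message) {
  structure(list(error = list(kind = kind, message = message),
                 result = NULL, preprocessing_log = NULL,
                 peer_summaries = list(), ui_payload = NULL),
            class = "cds_response")
}

#' Handle a CDS request end to end
#'
#' The deterministic pipeline of the platform: extract the engine's feature
#' record from the bundle, run the engine, optionally gather peer
#' summaries (an unreachable peer degrades to an unavailability marker,
#' never a failure), and compose the UI payload. Unknown engines and engine
#' failures come back as typed error responses. Required features that
#' could not be extracted travel in the preprocessing log and the feature
#' record's `missing` set — never silently defaulted.
#'
#' @param request a [cds_request()].
#' @param registry engine registry (default: the shipped engines).
#' @return an object of class `cds_response`: `result`, `features`,
#'   `preprocessing_log`, `missing_features`, `peer_summaries`,
#'   `ui_payload`, and `error` (NULL on success).
#' @export
handle_request <- function(request, registry = default_registry()) {
  stopifnot(inherits(request, "cds_request"))
  eng <- resolve_engine(registry, request$engine_name)
  if (is.null(eng)) {
    return(error_response("engine_not_found",
                          sprintf("no engine named '%s' is registered",
                                  request$engine_name)))
  }
  record <- extract_features(request$bundle, eng$descriptor,
                             request$reference_time)
  result <- tryCatch(eng$fn(record), error = function(e) e)
  if (inherits(result, "error")) {
    return(error_response("engine_failure", conditionMessage(result)))
  }
  summaries <- list()
  if (isTRUE(request$options$include_peer_summaries) &&
      !is.null(request$options$cohort)) {
    summaries <- lapply(request$options$peers, request_summary,
                        spec = request$options$cohort,
                        k = request$options$k)
  }
  structure(list(
    error = NULL,
    result = result,
    features = record,
    preprocessing_log = record$log,
    missing_features = record$missing,
    peer_summaries = summaries,
    ui_payload = compose_ui_payload(result, summaries, record)
  ), class = "cds_response")
}

headline_for <- function(result) {
  if (inherits(result, "sepsis_assessment")) {
    list(kind = "sepsis_assessment",
         values = list(suspected_infection = result$suspected_infection,
                       qsofa = result$qsofa$score,
                       qsofa_positive = result$qsofa$positive,
                       sofa = result$sofa$total,
                       sepsis = result$sepsis,
                       septic_shock = result$septic_shock))
  } else if (inherits(result, "triage_prediction")) {
    list(kind = "triage_prediction",
         values = c(as.list(result$probabilities),
                    list(risk_band = result$risk_band)))
  } else {
    list(kind = "generic", values = unclass(result))
  }
}

#' Compose the structured display document
#'
#' Pure assembly of what the pipeline already computed, in a fixed section
#' order: (1) headline scores, (2) recommendation list with completed marks
#' when the result carries one, (3) peer statistics tables when any peer
#' summary is present, (4) data-quality notes from the preprocessing log.
#' Sections without content are omitted, so a sepsis assessment with one
#' peer summary yields four sections and one without summaries yields
#' three.
#'
#' @param result engine result (`sepsis_assessment`, `triage_prediction`,
#'   or a generic score map).
#' @param summaries list of `summary_report` / `peer_unavailable` objects.
#' @param record the `feature_record` the engine consumed (optional).
#' @return an object of class `ui_payload`: a named list of ordered
#'   sections.
#' @export
compose_ui_payload <- function(result, summaries = list(), record = NULL) {
  sections <- list()
  sections$headline <- headline_for(result)
  if (inherits(result, "sepsis_assessment") &&
      length(result$recommendations)) {
    sections$recommendations <- result$recommendations
  }
  if (length(summaries)) {
    sections$peer_statistics <- lapply(summaries, function(s) {
      if (inherits(s, "peer_unavailable")) {
        list(available = FALSE, reason = s$reason)
      } else {
        list(available = TRUE, institution = s$institution_id,
             n_total = s$n_total, cells = s$cells)
      }
    })
  }
  sections$data_quality <- list(
    missing_features = if (!is.null(record)) record$missing else character(0),
    log = if (!is.null(record)) record$log else NULL)
  structure(sections, class = "ui_payload")
}

#' @export
print.cds_response <- function(x, ...) {
  if (!is.null(x$error)) {
    cat(sprintf("<cds_response> ERROR [%s]: %s\n", x$error$kind,
                x$error$message))
    return(invisible(x))
  }
  cat("<cds_response>\n")
  print(x$result)
  if (length(x$missing_features)) {
    cat("  missing features:", paste(x$missing_features, collapse = ", "),
        "\n")
  }
  cat(sprintf("  peer summaries: %d  ui sections: %d\n",
              length(x$peer_summaries), length(x$ui_payload)))
  invisible(x)
}
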