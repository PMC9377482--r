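# Federated integration: population-level summary reports built from an
# OMOP-CDM-like local store, small-cell suppression, and merging of reports
# across institutions. Only SummaryReport objects ever cross an institution
# boundary — never person-level rows. Differential privacy and the full
# OHDSI cohort-definition language are non-goals; the residual differencing
# risk of re-suppressed merges is documented, not eliminated.

#' An OMOP-CDM-like local store
#'
#' A minimal relational subset: person, visit, measurement, drug_exposure,
#' condition and death tables. Foreign keys are validated at construction.
#'
#' @param person data frame `person_id`, `birth_date`, `sex_concept`.
#' @param visit data frame `visit_id`, `person_id`, `class`, `start`, `end`.
#' @param measurement data frame `person_id`, `concept_id`, `value`, `unit`,
#'   `time`.
#' @param drug_exposure data frame `person_id`, `drug_concept_id`, `time`.
#' @param condition data frame `person_id`, `condition_concept_id`, `time`.
#' @param death data frame `person_id`, `time`.
#' @return an object of class `local_store`.
#' @export
local_store <- function(person, visit, measurement = NULL,
                        drug_exposure = NULL, condition = NULL,
                        death = NULL) {
  empty <- function(...) {
    cols <- c(...)
    stats::setNames(as.data.frame(rep(list(character(0)), length(cols))),
                    cols)
  }
  measurement <- measurement %||% empty("person_id", "concept_id", "value",
                                        "unit", "time")
  drug_exposure <- drug_exposure %||% empty("person_id", "drug_concept_id",
                                            "time")
  condition <- condition %||% empty("person_id", "condition_concept_id",
                                    "time")
  death <- death %||% empty("person_id", "time")
  pid <- person$person_id
  for (nm in c("visit", "measurement", "drug_exposure", "condition",
               "death")) {
    tab <- get(nm)
    if (nrow(tab) && !all(tab$person_id %in% pid)) {
      cdskit_abort(sprintf("table '%s' has person_id values not in person",
                           nm), "cdskit_validation_error")
    }
  }
  concept_cols <- list(drug_exposure = "drug_concept_id",
                       condition = "condition_concept_id",
                       measurement = "concept_id")
  for (nm in names(concept_cols)) {
    tab <- get(nm)
    ids <- tab[[concept_cols[[nm]]]]
    if (length(ids) && any(as.numeric(ids) <= 0, na.rm = TRUE)) {
      cdskit_abort(sprintf("non-positive concept id in '%s'", nm),
                   "cdskit_validation_error")
    }
  }
  structure(list(person = person, visit = visit, measurement = measurement,
                 drug_exposure = drug_exposure, condition = condition,
                 death = death), class = "local_store")
}

#' Read a local store from a directory of delimited files
#' @param dir directory containing `person.csv`, `visit.csv` and optionally
#'   `measurement.csv`, `drug_exposure.csv`, `condition.csv`, `death.csv`.
#' @return a [local_store()].
#' @export
read_local_store <- function(dir) {
  rd <- function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(p)) read_table_file(p) else NULL
  }
  local_store(person = rd("person"), visit = rd("visit"),
              measurement = rd("measurement"),
              drug_exposure = rd("drug_exposure"),
              condition = rd("condition"), death = rd("death"))
}

#' Write a local store to a directory of delimited files
#' @param store a [local_store()].
#' @param dir output directory (created if needed).
#' @export
write_local_store <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(store)) {
    utils::write.csv(store[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Define a cohort
#'
#' @param name cohort name; merged reports must agree on it.
#' @param condition_concepts integer concept ids; membership requires at
#'   least one matching condition row.
#' @param visit_class optional visit class filter (`"emergency"`,
#'   `"inpatient"`, ...); a member must have at least one such visit.
#' @param stratifier column stratifying the drug cells
#'   (default `"drug_concept_id"`).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(name, condition_concepts, visit_class = NULL,
                        stratifier = "drug_concept_id") {
  if (!length(condition_concepts)) {
    cdskit_abort("cohort_spec needs at least one inclusion rule",
                 "cdskit_contract_error")
  }
  structure(list(name = name, condition_concepts = condition_concepts,
                 visit_class = visit_class, stratifier = stratifier),
            class = "cohort_spec")
}

new_summary_report <- function(institution_id, cohort, n_total, cells, k) {
  structure(list(institution_id = institution_id, cohort = cohort,
                 n_total = n_total, cells = cells, k_threshold = k,
                 generated_time = format_iso8601(Sys.time())),
            class = "summary_report")
}

empty_cells <- function() {
  data.frame(label = character(0), count = numeric(0), rate = numeric(0),
             suppressed = logical(0), partially_suppressed = logical(0),
             contributing_sites = integer(0), stringsAsFactors = FALSE)
}

#' Build a population-level summary report from a local store
#'
#' Resolves the cohort (condition concept set, optional visit class), then
#' emits one cell per stratifier level — e.g. per antibiotic drug concept —
#' plus outcome cells for in-hospital death and hospitalization, each with
#' count and rate (count / n_total). Small-cell suppression at threshold `k`
#' is applied before the report leaves the function. An empty cohort gives
#' `n_total = 0` with no cells; a zero count is reported as 0, not
#' suppressed (revealing absence is an accepted threat-model choice).
#'
#' @param store a [local_store()].
#' @param spec a [cohort_spec()].
#' @param k suppression threshold (default 10).
#' @param institution_id label carried in the report.
#' @return an object of class `summary_report`.
#' @export
build_summary <- function(store, spec, k = 10, institution_id = "local") {
  stopifnot(inherits(store, "local_store"), inherits(spec, "cohort_spec"),
            k >= 1)
  members <- unique(store$condition$person_id[
    store$condition$condition_concept_id %in% spec$condition_concepts])
  if (!is.null(spec$visit_class)) {
    with_visit <- unique(store$visit$person_id[
      store$visit$class %in% spec$visit_class])
    members <- intersect(members, with_visit)
  }
  n_total <- length(members)
  if (n_total == 0) {
    return(new_summary_report(institution_id, spec$name, 0L, empty_cells(), k))
  }
  drugs <- store$drug_exposure[store$drug_exposure$person_id %in% members, ,
                               drop = FALSE]
  cells <- empty_cells()
  if (nrow(drugs)) {
    # count persons, not exposures, per drug concept
    per_drug <- tapply(drugs$person_id, drugs[[spec$stratifier]],
                       function(p) length(unique(p)))
    cells <- data.frame(label = paste0("drug_", names(per_drug)),
                        count = as.numeric(per_drug),
                        rate = as.numeric(per_drug) / n_total,
                        suppressed = FALSE, partially_suppressed = FALSE,
                        contributing_sites = 1L, stringsAsFactors = FALSE)
  }
  died <- length(intersect(store$death$person_id, members))
  hospitalized <- length(unique(store$visit$person_id[
    store$visit$person_id %in% members & store$visit$class == "inpatient"]))
  outcome <- data.frame(
    label = c("outcome_in_hospital_death", "outcome_hospitalization"),
    count = c(died, hospitalized),
    rate = c(died, hospitalized) / n_total,
    suppressed = FALSE, partially_suppressed = FALSE,
    contributing_sites = 1L, stringsAsFactors = FALSE)
  cells <- rbind(cells, outcome)
  suppress_small_cells(
    new_summary_report(institution_id, spec$name, n_total, cells, k), k)
}

#' Apply small-cell suppression to a report
#'
#' Every cell with `0 < count < k` is marked suppressed and its count and
#' rate withheld (`NA`). Idempotent; `k = 1` is the identity. Zero counts
#' are kept visible by design.
#'
#' @param report a `summary_report`.
#' @param k threshold (defaults to the report's own).
#' @return the suppressed `summary_report`.
#' @export
suppress_small_cells <- function(report, k = report$k_threshold) {
  stopifnot(inherits(report, "summary_report"))
  cells <- report$cells
  if (nrow(cells)) {
    small <- !is.na(cells$count) & cells$count > 0 & cells$count < k
    cells$suppressed <- cells$suppressed | small
    cells$count[cells$suppressed] <- NA_real_
    cells$rate[cells$suppressed] <- NA_real_
  }
  report$cells <- cells
  report$k_threshold <- k
  report
}

#' Merge summary reports from peer institutions
#'
#' All reports must share the cohort name and threshold `k`. Per-label
#' counts are summed over the sites where the label is unsuppressed; a label
#' suppressed at any site is marked partially suppressed and carries the
#' number of sites that did contribute. `n_total` is summed, rates are
#' recomputed against it, and the merged cells are re-suppressed at the same
#' `k` so the merged report honors the same disclosure floor.
#'
#' @param reports list of `summary_report` objects.
#' @return the merged `summary_report`.
#' @export
merge_summaries <- function(reports) {
  stopifnot(length(reports) >= 1,
            all(vapply(reports, inherits, logical(1), "summary_report")))
  cohorts <- unique(vapply(reports, `[[`, character(1), "cohort"))
  if (length(cohorts) != 1) {
    cdskit_abort(sprintf("cannot merge reports for different cohorts: %s",
                         paste(cohorts, collapse = ", ")),
                 "cdskit_contract_error")
  }
  ks <- unique(vapply(reports, function(r) as.numeric(r$k_threshold),
                      numeric(1)))
  if (length(ks) != 1) {
    cdskit_abort("cannot merge reports with different k thresholds",
                 "cdskit_contract_error")
  }
  n_total <- as.integer(sum(vapply(reports,
                                   function(r) as.numeric(r$n_total),
                                   numeric(1))))
  labels <- unique(unlist(lapply(reports, function(r) r$cells$label)))
  rows <- lapply(labels, function(lb) {
    contrib <- 0; suppressed_anywhere <- FALSE; total <- 0
    for (r in reports) {
      i <- match(lb, r$cells$label)
      if (is.na(i)) next
      if (r$cells$suppressed[i]) {
        suppressed_anywhere <- TRUE
      } else {
        total <- total + r$cells$count[i]
        contrib <- contrib + (r$cells$contributing_sites[i] %||% 1L)
      }
    }
    # a label suppressed at every site stays fully suppressed in the merge
    all_suppressed <- suppressed_anywhere && contrib == 0
    data.frame(label = lb,
               count = if (all_suppressed) NA_real_ else total,
               rate = if (all_suppressed || n_total == 0) NA_real_ else
                 total / n_total,
               suppressed = all_suppressed,
               partially_suppressed = suppressed_anywhere,
               contributing_sites = as.integer(contrib),
               stringsAsFactors = FALSE)
  })
  cells <- if (length(rows)) do.call(rbind, rows) else empty_cells()
  merged <- new_summary_report(
    paste(vapply(reports, `[[`, character(1), "institution_id"),
          collapse = "+"),
    cohorts, n_total, cells, ks)
  suppress_small_cells(merged, ks)
}

#' @export
print.summary_report <- function(x, ...) {
  cat(sprintf("<summary_report> '%s' @ %s: n = %s (k = %s)\n", x$cohort,
              x$institution_id, x$n_total, x$k_threshold))
  if (nrow(x$cells)) {
    print(x$cells[, c("label", "count", "rate", "suppressed",
                      "partially_suppressed")], row.names = FALSE)
  }
  invisible(x)
}

PERSON_LEVEL_FIELDS <- c("person_id", "patient_id", "birth_date",
                         "subject_ref", "visit_id")

#' Validate a summary payload received from a peer
#'
#' Schema gate on anything crossing the institution boundary: the payload
#' must look like a serialized summary report and must not contain any
#' person-level field (person_id, birth_date, ...) at any nesting depth.
#'
#' @param payload a list (parsed JSON).
#' @return the payload, invisibly, or an error of class
#'   `cdskit_privacy_error`.
#' @export
validate_summary_payload <- function(payload) {
  all_names <- function(x) {
    if (!is.list(x)) return(character(0))
    c(names(x), unlist(lapply(x, all_names), use.names = FALSE))
  }
  bad <- intersect(tolower(all_names(payload)), PERSON_LEVEL_FIELDS)
  if (length(bad)) {
    cdskit_abort(sprintf("peer payload contains person-level field(s): %s",
                         paste(bad, collapse = ", ")),
                 "cdskit_privacy_error")
  }
  needed <- c("cohort", "n_total", "cells", "k_threshold")
  if (!all(needed %in% names(payload))) {
    cdskit_abort("peer payload is not a summary report",
                 "cdskit_privacy_error")
  }
  invisible(payload)
}

summary_to_payload <- function(report) {
  cells <- report$cells
  payload_cells <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- list(label = cells$label[i], suppressed = cells$suppressed[i],
                 partially_suppressed = cells$partially_suppressed[i],
                 contributing_sites = cells$contributing_sites[i])
    if (!cells$suppressed[i]) {
      # suppressed counts and rates are absent from the wire form entirely
      cell$count <- cells$count[i]
      cell$rate <- cells$rate[i]
    }
    cell
  })
  list(schema_version = "1.0", institution_id = report$institution_id,
       cohort = report$cohort, n_total = report$n_total,
       cells = payload_cells, k_threshold = report$k_threshold,
       generated_time = report$generated_time)
}

payload_to_summary <- function(payload) {
  cells <- if (length(payload$cells)) {
    do.call(rbind, lapply(payload$cells, function(cl) {
      data.frame(label = cl$label,
                 count = cl$count %||% NA_real_,
                 rate = cl$rate %||% NA_real_,
                 suppressed = isTRUE(cl$suppressed),
                 partially_suppressed = isTRUE(cl$partially_suppressed),
                 contributing_sites = as.integer(cl$contributing_sites %||% 1L),
                 stringsAsFactors = FALSE)
    }))
  } else empty_cells()
  r <- new_summary_report(payload$institution_id %||% "peer",
                          payload$cohort, payload$n_total, cells,
                          payload$k_threshold)
  r$generated_time <- payload$generated_time %||% r$generated_time
  r
}

#' Serialize a summary report to its wire JSON
#' @param report a `summary_report`.
#' @return JSON string (the one wire format shared by the local CDS API and
#'   peer exchange). Suppressed cells have no `count`/`rate` keys at all.
#' @export
summary_report_json <- function(report) {
  jsonlite::toJSON(summary_to_payload(report), auto_unbox = TRUE,
                   digits = NA, null = "null")
}

#' Construct a loopback peer endpoint over a local store
#'
#' Peers are callables taking `(spec, k)` and returning a wire payload —
#' the same request/response schema as the local service, so tests can run
#' the full exchange without a network.
#'
#' @param store a [local_store()].
#' @param institution_id label for the peer.
#' @return a function usable as `peer` in [request_summary()].
#' @export
local_peer <- function(store, institution_id = "peer") {
  force(store); force(institution_id)
  function(spec, k) {
    summary_to_payload(build_summary(store, spec, k = k,
                                     institution_id = institution_id))
  }
}

#' A peer endpoint that is always unreachable (for degradation tests)
#' @return a peer function that signals unavailability.
#' @export
unreachable_peer <- function() {
  function(spec, k) cdskit_abort("peer unreachable", "cdskit_peer_error")
}

#' Request a summary report from a peer institution
#'
#' The request carries only the cohort spec and threshold; the response is
#' schema-validated and rejected if it contains any person-level field. An
#' unreachable peer yields a typed unavailability marker rather than an
#' error, so the CDS response can degrade to local-only content.
#'
#' @param peer a peer endpoint callable (see [local_peer()]).
#' @param spec a [cohort_spec()].
#' @param k suppression threshold.
#' @return a `summary_report`, or an object of class `peer_unavailable`.
#' @export
request_summary <- function(peer, spec, k = 10) {
  payload <- tryCatch(peer(spec, k), error = function(e) e)
  if (inherits(payload, "error")) {
    return(structure(list(reason = conditionMessage(payload)),
                     class = "peer_unavailable"))
  }
  validate_summary_payload(payload)
  payload_to_summary(payload)
}
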