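# Knowledge-based sepsis treatment advisor: suspected-infection screen,
# qSOFA, SOFA with organ subscores, Sepsis-3 status, septic-shock check and
# an hour-1-bundle-style recommendation list with completed-practice marks.
#
# The screening rule is body temperature strictly above 37.5 degC together
# with an existing blood-culture or antibiotics order. qSOFA cutoffs
# (SBP <= 100, RR >= 22, GCS < 15) and the SOFA stratum table follow the
# Sepsis-3 consensus and ship as versioned data files under extdata.

SEPSIS_INPUT_FIELDS <- c(
  "gcs", "sbp", "dbp", "resp_rate", "body_temperature", "pao2", "fio2",
  "platelets", "creatinine", "total_bilirubin", "lactate",
  "blood_culture_ordered", "antibiotics_ordered", "vasopressor_ordered")

plausibility_bounds <- list(
  gcs = c(3, 15), sbp = c(30, 300), dbp = c(10, 200), resp_rate = c(0, 80),
  body_temperature = c(25, 45), pao2 = c(10, 700), fio2 = c(0.21, 1.0),
  platelets = c(0, 2000), creatinine = c(0, 30), total_bilirubin = c(0, 60),
  lactate = c(0, 30))

#' Construct the sepsis engine's 14-component input
#'
#' All fields are optional (`NA` = not measured / not ordered); present
#' physiologic values must fall within plausibility bounds. Units are fixed:
#' pressures mmHg, temperature degC, platelets 10^3/uL, creatinine and
#' bilirubin mg/dL, lactate mmol/L, FiO2 a fraction in [0.21, 1].
#'
#' @param gcs Glasgow Coma Scale total, integer 3-15.
#' @param sbp,dbp systolic / diastolic blood pressure, mmHg.
#' @param resp_rate respiratory rate, breaths/min.
#' @param body_temperature degC.
#' @param pao2 arterial oxygen partial pressure, mmHg.
#' @param fio2 fraction of inspired oxygen, 0.21-1.0.
#' @param platelets platelet count, 10^3/uL.
#' @param creatinine serum creatinine, mg/dL.
#' @param total_bilirubin mg/dL.
#' @param lactate serum lactate, mmol/L.
#' @param blood_culture_ordered,antibiotics_ordered,vasopressor_ordered
#'   order flags (logical; `NA` treated as no order).
#' @return an object of class `sepsis_input`.
#' @export
sepsis_input <- function(gcs = NA, sbp = NA, dbp = NA, resp_rate = NA,
                         body_temperature = NA, pao2 = NA, fio2 = NA,
                         platelets = NA, creatinine = NA,
                         total_bilirubin = NA, lactate = NA,
                         blood_culture_ordered = NA,
                         antibiotics_ordered = NA,
                         vasopressor_ordered = NA) {
  x <- list(gcs = gcs, sbp = sbp, dbp = dbp, resp_rate = resp_rate,
            body_temperature = body_temperature, pao2 = pao2, fio2 = fio2,
            platelets = platelets, creatinine = creatinine,
            total_bilirubin = total_bilirubin, lactate = lactate,
            blood_culture_ordered = isTRUE(blood_culture_ordered),
            antibiotics_ordered = isTRUE(antibiotics_ordered),
            vasopressor_ordered = isTRUE(vasopressor_ordered))
  for (nm in names(plausibility_bounds)) {
    v <- x[[nm]]
    if (!is.na(v)) {
      b <- plausibility_bounds[[nm]]
      if (v < b[1] || v > b[2]) {
        cdskit_abort(sprintf("%s = %g outside plausibility bounds [%g, %g]",
                             nm, v, b[1], b[2]), "cdskit_validation_error")
      }
    }
  }
  if (!is.na(x$gcs) && x$gcs != round(x$gcs)) {
    cdskit_abort("gcs must be an integer", "cdskit_validation_error")
  }
  structure(x, class = "sepsis_input")
}

#' Screen for suspected sepsis
#'
#' Flag iff body temperature is strictly above 37.5 degC and a blood-culture
#' test or antibiotics have been ordered. A missing temperature screens out,
#' with a `"note"` attribute recording the missingness.
#'
#' @param input a [sepsis_input()].
#' @return logical flag.
#' @export
screen_suspected_sepsis <- function(input) {
  stopifnot(inherits(input, "sepsis_input"))
  if (is.na(input$body_temperature)) {
    return(structure(FALSE, note = "body_temperature missing; cannot screen"))
  }
  isTRUE(input$body_temperature > 37.5) &&
    (input$blood_culture_ordered || input$antibiotics_ordered)
}

load_qsofa_cutoffs <- function() {
  if (is.null(the$qsofa)) the$qsofa <- read_table_file(ext_file("qsofa_cutoffs.csv"))
  the$qsofa
}

#' Compute the quick SOFA (qSOFA) score
#'
#' Three components, one point each: SBP <= 100 mmHg, respiratory rate
#' >= 22/min, altered mentation (GCS < 15). A missing component contributes
#' no point and is listed in `missing`. Positive at score >= 2.
#'
#' @param input a [sepsis_input()].
#' @return an object of class `qsofa_result` with `score`, `components`
#'   (named logical vector), `positive` and `missing`.
#' @export
compute_qsofa <- function(input) {
  stopifnot(inherits(input, "sepsis_input"))
  cut <- load_qsofa_cutoffs()
  comp <- logical(nrow(cut))
  names(comp) <- cut$component
  missing <- character(0)
  for (i in seq_len(nrow(cut))) {
    v <- input[[cut$variable[i]]]
    if (is.na(v)) {
      comp[i] <- FALSE
      missing <- c(missing, cut$component[i])
      next
    }
    comp[i] <- switch(cut$operator[i],
                      le = v <= cut$threshold[i],
                      ge = v >= cut$threshold[i],
                      lt = v < cut$threshold[i],
                      gt = v > cut$threshold[i])
  }
  score <- sum(comp)
  structure(list(score = score, components = comp,
                 positive = score >= 2, missing = missing),
            class = "qsofa_result")
}

#' The qSOFA component schema
#'
#' @return data frame with one row per clinical component of the qSOFA
#'   screen (`component`, `variable`, `operator`, `threshold`).
#' @export
qsofa_components <- function() load_qsofa_cutoffs()

load_sofa_table <- function() {
  if (is.null(the$sofa)) {
    tab <- read_table_file(ext_file("sofa_table.csv"))
    tab$stratum_max[tab$stratum_max == "Inf"] <- Inf
    tab$stratum_max <- as.numeric(tab$stratum_max)
    the$sofa <- tab
  }
  the$sofa
}

sofa_lookup <- function(tab, organ, value) {
  rows <- tab[tab$organ == organ, , drop = FALSE]
  hit <- rows$stratum_min <= value & value < rows$stratum_max
  if (!any(hit)) 0L else rows$subscore[which(hit)[1]]
}

#' Compute the SOFA score from the available inputs
#'
#' Six organ subscores (0-4) from the bundled stratum table: respiration
#' (PaO2/FiO2 ratio), coagulation (platelets), liver (bilirubin),
#' cardiovascular (mean arterial pressure, derived as `(SBP + 2 DBP)/3`, with
#' an existing vasopressor order scoring 3 since agent and dose are not in
#' the input schema), CNS (GCS), renal (creatinine). Organs whose inputs are
#' absent score 0 and are listed in `missing_organs` — conservative bedside
#' convention, no imputation.
#'
#' @param input a [sepsis_input()].
#' @return an object of class `sofa_result` with `total`, `organ_subscores`
#'   (named integer vector) and `missing_organs`.
#' @export
compute_sofa <- function(input) {
  stopifnot(inherits(input, "sepsis_input"))
  tab <- load_sofa_table()
  sub <- c(respiration = 0L, coagulation = 0L, liver = 0L,
           cardiovascular = 0L, cns = 0L, renal = 0L)
  missing_organs <- character(0)

  if (!is.na(input$pao2) && !is.na(input$fio2)) {
    if (input$fio2 == 0) {
      cdskit_abort("fio2 = 0: PaO2/FiO2 ratio undefined", "cdskit_validation_error")
    }
    sub["respiration"] <- sofa_lookup(tab, "respiration",
                                      input$pao2 / input$fio2)
  } else missing_organs <- c(missing_organs, "respiration")

  if (!is.na(input$platelets)) {
    sub["coagulation"] <- sofa_lookup(tab, "coagulation", input$platelets)
  } else missing_organs <- c(missing_organs, "coagulation")

  if (!is.na(input$total_bilirubin)) {
    sub["liver"] <- sofa_lookup(tab, "liver", input$total_bilirubin)
  } else missing_organs <- c(missing_organs, "liver")

  if (input$vasopressor_ordered) {
    sub["cardiovascular"] <- 3L
  } else if (!is.na(input$sbp) && !is.na(input$dbp)) {
    map <- (input$sbp + 2 * input$dbp) / 3
    sub["cardiovascular"] <- sofa_lookup(tab, "cardiovascular", map)
  } else missing_organs <- c(missing_organs, "cardiovascular")

  if (!is.na(input$gcs)) {
    sub["cns"] <- sofa_lookup(tab, "cns", input$gcs)
  } else missing_organs <- c(missing_organs, "cns")

  if (!is.na(input$creatinine)) {
    sub["renal"] <- sofa_lookup(tab, "renal", input$creatinine)
  } else missing_organs <- c(missing_organs, "renal")

  structure(list(total = sum(sub), organ_subscores = sub,
                 missing_organs = missing_organs),
            class = "sofa_result")
}

#' Full sepsis assessment per Sepsis-3
#'
#' Composes the screen, qSOFA and SOFA: `sepsis` is true when the patient
#' screens in for suspected infection and total SOFA >= 2 (baseline SOFA
#' assumed 0 when no prior data exist); `septic_shock` additionally requires
#' a vasopressor order and lactate > 2 mmol/L. Both scores are always
#' computed and reported. When sepsis is true, treatment recommendations are
#' attached via [recommend_treatment()].
#'
#' @param input a [sepsis_input()].
#' @return an object of class `sepsis_assessment`.
#' @export
assess_sepsis <- function(input) {
  stopifnot(inherits(input, "sepsis_input"))
  screened <- screen_suspected_sepsis(input)
  qsofa <- compute_qsofa(input)
  sofa <- compute_sofa(input)
  sepsis <- isTRUE(as.logical(screened)) && sofa$total >= 2
  shock <- sepsis && input$vasopressor_ordered &&
    !is.na(input$lactate) && input$lactate > 2
  out <- structure(list(
    suspected_infection = isTRUE(as.logical(screened)),
    qsofa = qsofa, sofa = sofa, sepsis = sepsis, septic_shock = shock,
    recommendations = list()
  ), class = "sepsis_assessment")
  if (sepsis) out$recommendations <- recommend_treatment(out, input)
  out
}

load_treatment_items <- function() {
  if (is.null(the$treatment)) {
    the$treatment <- read_table_file(ext_file("treatment_items.csv"))
  }
  the$treatment
}

#' Treatment recommendations with completed-practice marks
#'
#' Returns the bundled hour-1-style item list; practices already completed
#' (an existing matching order, or a lactate measurement on file) are marked
#' so the display can emphasize what has not yet been done. The list is
#' config-replaceable via the `treatment_items.csv` data file.
#'
#' @param assessment a `sepsis_assessment` with `sepsis = TRUE`.
#' @param input the [sepsis_input()] the assessment was computed from.
#' @return list of treatment items (`item_id`, `label`, `completed`,
#'   `rationale`).
#' @export
recommend_treatment <- function(assessment, input) {
  stopifnot(inherits(assessment, "sepsis_assessment"),
            inherits(input, "sepsis_input"))
  if (!isTRUE(assessment$sepsis)) {
    cdskit_abort("recommend_treatment called on a non-sepsis assessment",
                 "cdskit_contract_error")
  }
  items <- load_treatment_items()
  lapply(seq_len(nrow(items)), function(i) {
    done <- switch(items$completed_when[i],
                   lactate_present = !is.na(input$lactate),
                   blood_culture_ordered = input$blood_culture_ordered,
                   antibiotics_ordered = input$antibiotics_ordered,
                   vasopressor_ordered = input$vasopressor_ordered,
                   never = FALSE,
                   FALSE)
    list(item_id = items$item_id[i], label = items$label[i],
         completed = isTRUE(done),
         rationale = sprintf("Sepsis-3 positive (SOFA %d)",
                             assessment$sofa$total))
  })
}

#' @export
print.sepsis_assessment <- function(x, ...) {
  cat("<sepsis_assessment>\n")
  cat(sprintf("  suspected infection: %s\n", x$suspected_infection))
  cat(sprintf("  qSOFA %d (%s)  SOFA %d%s\n", x$qsofa$score,
              if (x$qsofa$positive) "positive" else "negative", x$sofa$total,
              if (length(x$sofa$missing_organs))
                paste0(" [missing: ",
                       paste(x$sofa$missing_organs, collapse = ", "), "]")
              else ""))
  cat(sprintf("  sepsis: %s   septic shock: %s\n", x$sepsis, x$septic_shock))
  if (length(x$recommendations)) {
    cat("  recommendations:\n")
    for (it in x$recommendations) {
      cat(sprintf("   [%s] %s\n", if (it$completed) "x" else " ", it$label))
    }
  }
  invisible(x)
}

# descriptor + callable for the engine registry ----------------------------

sepsis3_required_features <- function() {
  obs <- c(gcs = "1", sbp = "mm[Hg]", dbp = "mm[Hg]", resp_rate = "/min",
           body_temperature = "Cel", pao2 = "mm[Hg]", fio2 = "1",
           platelets = "10*3/uL", creatinine = "mg/dL",
           total_bilirubin = "mg/dL", lactate = "mmol/L",
           mental_status_avpu = "coded")
  ord <- c(blood_culture_ordered = "bool", antibiotics_ordered = "bool",
           vasopressor_ordered = "bool")
  rbind(
    data.frame(feature_name = names(obs), canonical_unit = unname(obs),
               required = names(obs) != "mental_status_avpu",
               kind = "observation", stringsAsFactors = FALSE),
    data.frame(feature_name = names(ord), canonical_unit = unname(ord),
               required = TRUE, kind = "order", stringsAsFactors = FALSE))
}

feature_record_to_sepsis_input <- function(record) {
  g <- function(nm) {
    v <- feature_value(record, nm, NA)
    if (is.null(v)) NA else v
  }
  sepsis_input(
    gcs = g("gcs"), sbp = g("sbp"), dbp = g("dbp"), resp_rate = g("resp_rate"),
    body_temperature = g("body_temperature"), pao2 = g("pao2"),
    fio2 = g("fio2"), platelets = g("platelets"), creatinine = g("creatinine"),
    total_bilirubin = g("total_bilirubin"), lactate = g("lactate"),
    blood_culture_ordered = isTRUE(g("blood_culture_ordered")),
    antibiotics_ordered = isTRUE(g("antibiotics_ordered")),
    vasopressor_ordered = isTRUE(g("vasopressor_ordered")))
}

#' The shipped knowledge-based sepsis engine
#'
#' Packages the Sepsis-3 advisor as a registry plugin: an
#' [engine_descriptor()] declaring the 14-component input schema plus the
#' engine callable (`feature_record` in, `sepsis_assessment` out).
#'
#' @return list with `descriptor` and `fn`.
#' @export
sepsis3_engine <- function() {
  list(
    descriptor = engine_descriptor(
      engine_name = "sepsis3", version = "1.0", kind = "knowledge_based",
      required_features = sepsis3_required_features(), lookback_hours = 24),
    fn = function(record) assess_sepsis(feature_record_to_sepsis_input(record))
  )
}
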