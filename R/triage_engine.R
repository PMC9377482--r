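# Nonknowledge-based ED triage engine. Three independent binary logistic
# heads (hospital mortality, critical care, hospitalization) over a frozen
# deterministic encoding of the triage-stage inputs, with quintile risk
# bands stored in the model. The engine contract is model-agnostic; the
# shipped default is logistic regression fit by glm, an honest desk-scale
# stand-in for the original deep model, explicitly not a reproduction of it.

TRIAGE_OUTCOMES <- c("mortality", "critical_care", "hospitalization")
ARRIVAL_MODES <- c("walk_in", "ambulance", "transfer")
AVPU_LEVELS <- c("A", "V", "P", "U")

load_chief_complaints <- function() {
  if (is.null(the$cc)) the$cc <- read_table_file(ext_file("chief_complaints.csv"))
  the$cc
}

#' Construct a triage-stage input
#'
#' The fields available at ED triage, before examination: demographics,
#' chief complaint, symptom timing, arrival mode, trauma flag, initial
#' vital signs and AVPU mental status. Any vital may be `NA`.
#'
#' @param age years (>= 0).
#' @param sex `"male"` or `"female"`.
#' @param chief_complaint code from the frozen 20-item list (see
#'   `chief_complaints.csv`); unknown codes are bucketed as `"other"` with a
#'   warning.
#' @param onset_to_visit hours from symptom onset to ED visit (>= 0).
#' @param arrival_mode `"ambulance"`, `"walk_in"` or `"transfer"`.
#' @param trauma logical.
#' @param sbp,dbp,heart_rate,resp_rate,body_temperature,spo2 initial vitals
#'   (mmHg, /min, degC, %).
#' @param mental_status AVPU level `"A"`, `"V"`, `"P"` or `"U"`.
#' @return an object of class `triage_input`.
#' @export
triage_input <- function(age, sex, chief_complaint, onset_to_visit = NA,
                         arrival_mode = "walk_in", trauma = FALSE,
                         sbp = NA, dbp = NA, heart_rate = NA, resp_rate = NA,
                         body_temperature = NA, spo2 = NA,
                         mental_status = "A") {
  stopifnot(age >= 0, is.na(onset_to_visit) || onset_to_visit >= 0,
            arrival_mode %in% ARRIVAL_MODES, mental_status %in% AVPU_LEVELS)
  cc <- load_chief_complaints()$code
  if (!chief_complaint %in% c(cc, "other")) {
    warning(sprintf("unknown chief complaint '%s'; using 'other'",
                    chief_complaint))
    chief_complaint <- "other"
  }
  structure(list(age = age, sex = sex, chief_complaint = chief_complaint,
                 onset_to_visit = onset_to_visit, arrival_mode = arrival_mode,
                 trauma = isTRUE(trauma), sbp = sbp, dbp = dbp,
                 heart_rate = heart_rate, resp_rate = resp_rate,
                 body_temperature = body_temperature, spo2 = spo2,
                 mental_status = mental_status),
            class = "triage_input")
}

# frozen encoding spec v1: numeric vitals are centred/scaled with fixed
# constants (not data-derived, so train and serve agree by construction);
# missing numerics contribute a 0 fill plus a missingness indicator;
# categoricals are one-hot against frozen lists with the first level as
# baseline.
triage_encoding_spec <- function() {
  list(
    version = "1",
    numeric = data.frame(
      field = c("age", "onset_to_visit", "sbp", "dbp", "heart_rate",
                "resp_rate", "body_temperature", "spo2"),
      center = c(50, 12, 120, 75, 85, 18, 37, 97),
      scale = c(20, 12, 20, 12, 20, 5, 0.7, 3),
      stringsAsFactors = FALSE),
    arrival_modes = ARRIVAL_MODES,
    avpu = AVPU_LEVELS,
    chief_complaints = c(load_chief_complaints()$code, "other")
  )
}

#' Names of the encoded feature vector, in order
#' @param spec an encoding spec, default the frozen v1 spec.
#' @return character vector of coordinate names.
#' @export
triage_feature_names <- function(spec = triage_encoding_spec()) {
  c("(Intercept)",
    paste0(spec$numeric$field, "_s"),
    paste0(spec$numeric$field, "_miss"),
    "sex_male", "trauma",
    paste0("arrival_", spec$arrival_modes[-1]),
    paste0("mental_", spec$avpu[-1]),
    paste0("cc_", spec$chief_complaints[-1]))
}

#' Encode a triage input as a fixed-length numeric vector
#'
#' Deterministic: identical inputs give identical vectors. Numeric fields
#' are scaled as `(x - center)/scale` with frozen constants and zero-filled
#' when missing (with a paired missingness indicator); categoricals are
#' one-hot against the frozen category lists (baselines: walk-in, AVPU A,
#' the first chief-complaint code).
#'
#' @param input a [triage_input()].
#' @param spec encoding spec (default frozen v1).
#' @return named numeric vector, first coordinate an intercept term of 1.
#' @export
encode_triage <- function(input, spec = triage_encoding_spec()) {
  stopifnot(inherits(input, "triage_input"))
  nms <- triage_feature_names(spec)
  v <- stats::setNames(numeric(length(nms)), nms)
  v["(Intercept)"] <- 1
  for (i in seq_len(nrow(spec$numeric))) {
    f <- spec$numeric$field[i]
    x <- input[[f]]
    if (is.na(x)) {
      v[paste0(f, "_miss")] <- 1
    } else {
      v[paste0(f, "_s")] <- (x - spec$numeric$center[i]) / spec$numeric$scale[i]
    }
  }
  v["sex_male"] <- as.numeric(identical(input$sex, "male"))
  v["trauma"] <- as.numeric(input$trauma)
  if (input$arrival_mode != spec$arrival_modes[1]) {
    v[paste0("arrival_", input$arrival_mode)] <- 1
  }
  if (input$mental_status != spec$avpu[1]) {
    v[paste0("mental_", input$mental_status)] <- 1
  }
  if (input$chief_complaint != spec$chief_complaints[1]) {
    v[paste0("cc_", input$chief_complaint)] <- 1
  }
  v
}

df_row_to_triage_input <- function(row) {
  num <- function(x) if (is.null(x) || is.na(x)) NA else as.numeric(x)
  triage_input(
    age = as.numeric(row$age), sex = as.character(row$sex),
    chief_complaint = as.character(row$chief_complaint),
    onset_to_visit = num(row$onset_to_visit),
    arrival_mode = as.character(row$arrival_mode),
    trauma = as.logical(row$trauma),
    sbp = num(row$sbp), dbp = num(row$dbp), heart_rate = num(row$heart_rate),
    resp_rate = num(row$resp_rate),
    body_temperature = num(row$body_temperature), spo2 = num(row$spo2),
    mental_status = as.character(row$mental_status))
}

encode_triage_frame <- function(data, spec = triage_encoding_spec()) {
  rows <- lapply(seq_len(nrow(data)),
                 function(i) encode_triage(df_row_to_triage_input(data[i, ]),
                                           spec))
  do.call(rbind, rows)
}

#' Fit the triage prediction model
#'
#' Follows the standard patient-level-prediction loop: encode the cohort,
#' split into training and test sets (seeded, so fits are reproducible
#' bit-for-bit), and fit one independent binomial logistic head per outcome
#' in `mortality`, `critical_care`, `hospitalization` (the outcomes are not
#' mutually exclusive). Risk-band edges are the quintiles of the
#' training-set predicted probabilities, stored in the model so banding is
#' frozen at train time. Test-set AUROC per head is recorded when the pROC
#' package is available.
#'
#' @param data one row per ED visit: the [triage_input()] fields as columns
#'   plus 0/1 outcome columns `mortality`, `critical_care`,
#'   `hospitalization`.
#' @param config list: `seed` (integer, default 1), `test_fraction`
#'   (default 0.25).
#' @return an object of class `triage_model`.
#' @export
fit_triage_model <- function(data, config = list()) {
  seed <- config$seed %||% 1L
  test_fraction <- config$test_fraction %||% 0.25
  for (oc in TRIAGE_OUTCOMES) {
    if (!oc %in% names(data)) {
      cdskit_abort(sprintf("outcome column '%s' absent", oc),
                   "cdskit_contract_error")
    }
    if (length(unique(data[[oc]])) < 2) {
      cdskit_abort(sprintf("outcome '%s' has a single class; cannot fit", oc),
                   "cdskit_contract_error")
    }
  }
  spec <- triage_encoding_spec()
  X <- encode_triage_frame(data, spec)
  set.seed(seed)
  n <- nrow(X)
  test_idx <- sort(sample.int(n, size = max(1L, round(n * test_fraction))))
  train_idx <- setdiff(seq_len(n), test_idx)

  heads <- list(); bands <- list(); metrics <- list()
  for (oc in TRIAGE_OUTCOMES) {
    y <- data[[oc]]
    # drop constant columns in the training design (rare categories absent
    # from the split); their coefficients are reported as 0
    Xtr <- X[train_idx, , drop = FALSE]
    keep <- c(TRUE, apply(Xtr[, -1, drop = FALSE], 2,
                          function(col) stats::var(col) > 0))
    fit <- suppressWarnings(stats::glm.fit(
      Xtr[, keep, drop = FALSE], y[train_idx],
      family = stats::binomial()))
    if (!fit$converged || anyNA(fit$coefficients)) {
      cdskit_abort(sprintf(
        "logistic fit for outcome '%s' did not converge (n = %d)", oc,
        length(train_idx)), "cdskit_fit_error")
    }
    coefs <- stats::setNames(numeric(ncol(X)), colnames(X))
    coefs[names(fit$coefficients)] <- fit$coefficients
    heads[[oc]] <- coefs
    p_train <- stats::plogis(as.numeric(Xtr %*% coefs))
    bands[[oc]] <- unname(stats::quantile(p_train, probs = c(.2, .4, .6, .8)))
    p_test <- stats::plogis(as.numeric(X[test_idx, , drop = FALSE] %*% coefs))
    auc <- if (requireNamespace("pROC", quietly = TRUE) &&
               length(unique(y[test_idx])) == 2) {
      as.numeric(pROC::auc(pROC::roc(y[test_idx], p_test, quiet = TRUE,
                                     direction = "<", levels = c(0, 1))))
    } else NA_real_
    metrics[[oc]] <- list(test_auroc = auc,
                          train_prevalence = mean(y[train_idx]))
  }
  structure(list(
    model_kind = "logistic",
    heads = heads,
    band_edges = bands,
    encoding_version = spec$version,
    metrics = metrics,
    training = list(n = n, n_train = length(train_idx),
                    n_test = length(test_idx), seed = seed,
                    test_fraction = test_fraction),
    model_version = "1.0"
  ), class = "triage_model")
}

#' @export
print.triage_model <- function(x, ...) {
  cat(sprintf("<triage_model> %s v%s, encoding v%s, trained on n=%d (seed %d)\n",
              x$model_kind, x$model_version, x$encoding_version,
              x$training$n, x$training$seed))
  for (oc in names(x$metrics)) {
    cat(sprintf("  %-16s prevalence %.3f  test AUROC %s\n", oc,
                x$metrics[[oc]]$train_prevalence,
                ifelse(is.na(x$metrics[[oc]]$test_auroc), "NA",
                       sprintf("%.3f", x$metrics[[oc]]$test_auroc))))
  }
  invisible(x)
}

#' Assign a predefined risk band
#'
#' Band = 1 + number of stored edges strictly below the probability, giving
#' an integer 1-5 for the default quintile edges.
#'
#' @param probability value in `[0, 1]`.
#' @param band_edges strictly increasing numeric vector of 4 edges.
#' @return integer band.
#' @export
assign_risk_band <- function(probability, band_edges) {
  if (any(is.na(probability)) || any(probability < 0 | probability > 1)) {
    cdskit_abort("probability outside [0, 1]", "cdskit_contract_error")
  }
  stopifnot(!is.unsorted(band_edges, strictly = TRUE))
  vapply(probability,
         function(p) 1L + sum(band_edges < p), integer(1))
}

#' Predict triage outcomes for one visit
#'
#' @param model a [fit_triage_model()] result (or one read back with
#'   [read_triage_model()]).
#' @param input a [triage_input()].
#' @return an object of class `triage_prediction`: `probabilities` (named,
#'   one per outcome), `risk_band` (1-5, from the mortality head's stored
#'   band edges), `model_version`.
#' @export
predict_triage <- function(model, input) {
  stopifnot(inherits(model, "triage_model"))
  spec <- triage_encoding_spec()
  if (!identical(model$encoding_version, spec$version)) {
    cdskit_abort(sprintf("model encoding v%s does not match encoder v%s",
                         model$encoding_version, spec$version),
                 "cdskit_contract_error")
  }
  v <- encode_triage(input, spec)
  probs <- vapply(model$heads,
                  function(b) stats::plogis(sum(b * v)), numeric(1))
  structure(list(
    probabilities = probs,
    risk_band = assign_risk_band(probs[["mortality"]],
                                 model$band_edges$mortality),
    model_version = model$model_version
  ), class = "triage_prediction")
}

#' @export
#' @rdname predict_triage
#' @param object,... standard predict-method arguments; `...` must contain
#'   `input`.
predict.triage_model <- function(object, input, ...) {
  predict_triage(object, input)
}

#' @export
print.triage_prediction <- function(x, ...) {
  cat("<triage_prediction>\n")
  for (oc in names(x$probabilities)) {
    cat(sprintf("  %-16s %.3f\n", oc, x$probabilities[[oc]]))
  }
  cat(sprintf("  risk band: %d (model v%s)\n", x$risk_band, x$model_version))
  invisible(x)
}

#' Write / read a triage model as versioned JSON
#'
#' The artifact is plain JSON (parameters, encoding version, band edges,
#' training metadata) — no opaque binaries, so models diff and audit like
#' any other text file.
#'
#' @param model a `triage_model`.
#' @param path file path.
#' @return `read_triage_model` returns the `triage_model`.
#' @export
write_triage_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_triage_model
#' @export
read_triage_model <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  x$heads <- lapply(x$heads, unlist)
  x$band_edges <- lapply(x$band_edges, as.numeric)
  structure(x, class = "triage_model")
}

# registry plugin ----------------------------------------------------------

edtriage_required_features <- function() {
  obs <- c(sbp = "mm[Hg]", dbp = "mm[Hg]", heart_rate = "/min",
           resp_rate = "/min", body_temperature = "Cel", spo2 = "%",
           mental_status_avpu = "coded", chief_complaint = "coded",
           onset_to_visit = "h")
  rbind(
    data.frame(feature_name = names(obs), canonical_unit = unname(obs),
               required = FALSE, kind = "observation",
               stringsAsFactors = FALSE),
    data.frame(feature_name = c("age", "sex", "arrival_mode"),
               canonical_unit = c("a", "coded", "coded"),
               required = c(TRUE, TRUE, FALSE), kind = "demographic",
               stringsAsFactors = FALSE))
}

feature_record_to_triage_input <- function(record) {
  g <- function(nm, default = NA) feature_value(record, nm, default)
  triage_input(
    age = as.numeric(g("age", 0)),
    sex = as.character(g("sex", "female")),
    chief_complaint = as.character(g("chief_complaint", "other")),
    onset_to_visit = suppressWarnings(as.numeric(g("onset_to_visit"))),
    arrival_mode = as.character(g("arrival_mode", "walk_in")),
    trauma = isTRUE(as.logical(g("trauma_flag", FALSE))),
    sbp = suppressWarnings(as.numeric(g("sbp"))),
    dbp = suppressWarnings(as.numeric(g("dbp"))),
    heart_rate = suppressWarnings(as.numeric(g("heart_rate"))),
    resp_rate = suppressWarnings(as.numeric(g("resp_rate"))),
    body_temperature = suppressWarnings(as.numeric(g("body_temperature"))),
    spo2 = suppressWarnings(as.numeric(g("spo2"))),
    mental_status = as.character(g("mental_status_avpu", "A")))
}

#' The shipped ED triage engine
#'
#' Wraps a [triage_model] as a registry plugin. With `model = NULL` a
#' default model is trained once on a seeded synthetic cohort (n = 1000,
#' seed 20) and cached for the session.
#'
#' @param model optional pre-trained [fit_triage_model()] result.
#' @return list with `descriptor` and `fn`.
#' @export
edtriage_engine <- function(model = NULL) {
  if (is.null(model)) {
    if (is.null(the$default_triage_model)) {
      prof <- cohort_profile(n = 1000, seed = 20)
      ds <- generate_triage_dataset(prof)
      the$default_triage_model <- fit_triage_model(ds, list(seed = 20))
    }
    model <- the$default_triage_model
  }
  list(
    descriptor = engine_descriptor(
      engine_name = "edtriage", version = "1.0",
      kind = "nonknowledge_based",
      required_features = edtriage_required_features(), lookback_hours = 24),
    fn = function(record) predict_triage(model,
                                         feature_record_to_triage_input(record))
  )
}
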