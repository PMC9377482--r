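---
title: "Methods: a desk-scale clinical decision support platform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale clinical decision support platform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`cdskit` models the complete path a clinical decision support request takes
— FHIR payload, vocabulary-driven preprocessing, a reasoning engine, an
optional federated summary exchange, and a composed display document — as
ordinary R functions over plain-text artifacts. This vignette records the
scientific and numerical choices behind each layer, what the synthetic data
do and do not establish, and the known limitations.

## The clinical rule set

**Suspected-infection screen.** A patient screens in when body temperature
is strictly above 37.5 °C *and* a blood-culture test or antibiotics have
been ordered within the lookback window. The inequality is strict: 37.5 °C
exactly does not flag. The order clause is interpreted as an existing
active/completed order — "has been recommended" in bedside terms — because
only orders are observable in the exchanged resources. A missing temperature
screens out and is annotated, never guessed.

**qSOFA.** Three components, one point each: systolic blood pressure
≤ 100 mmHg, respiratory rate ≥ 22 /min, altered mentation (GCS < 15);
positive at a score of 2 or more. The cutoffs are the Sepsis-3 consensus
values and ship as a versioned data file (`qsofa_cutoffs.csv`) rather than
constants in code, since deployments occasionally localize them. Mentation
may arrive either as a numeric GCS observation or as an AVPU code; the
mapping A→15, V→12, P→8, U→3 is a documented convention of this package,
applied only when no numeric GCS is available.

**SOFA.** Six organ subscores of 0–4 from the standard stratum table
(`sofa_table.csv`, half-open intervals `[min, max)` on the measured
variable): respiration by PaO₂/FiO₂, coagulation by platelets, liver by
bilirubin, cardiovascular by mean arterial pressure, CNS by GCS, renal by
creatinine. Numerical conventions:

* MAP is derived as `(SBP + 2·DBP)/3` — the inputs carry SBP/DBP, not MAP.
* A vasopressor order scores the cardiovascular system 3. The input schema
  is a boolean order flag without agent or dose, which cannot distinguish
  the dose-stratified grades 2–4; grade 3 is the central choice and is
  applied whenever the flag is set, regardless of MAP.
* The respiration grades 3–4 classically also require ventilatory support;
  ventilation status is not in the input schema, so grading is by ratio
  alone. This can overscore unventilated patients with low ratios.
* Missing organ inputs score 0 and are listed in `missing_organs` — the
  conservative bedside convention; nothing is imputed.
* `FiO2 = 0` is a hard error (undefined ratio), while a missing FiO₂ simply
  leaves respiration unscored.

**Sepsis-3 composition.** Sepsis = screened-in ∧ SOFA ≥ 2, with baseline
SOFA assumed 0 when no prior data exist (a documented limitation: patients
with chronic organ dysfunction are over-called). Septic shock additionally
requires a vasopressor order and lactate > 2 mmol/L. Both qSOFA and SOFA are
always computed and reported — qSOFA is a bedside screen, not a gate, so the
assessment never hides one score behind the other.

**Treatment recommendations.** The shipped list is the five
hour-1-bundle-style items (lactate measurement, cultures before antibiotics,
broad-spectrum antibiotics, 30 mL/kg crystalloid for hypotension or
lactate ≥ 4, vasopressors for MAP < 65 after fluids), stored in a
config-replaceable data file. Items are marked completed when the inputs
show the matching order (or a lactate value on file); the crystalloid item
has no observable counterpart in the input schema and is always presented as
open.

## Preprocessing

The preprocessing layer turns a bundle into exactly the feature record an
engine's descriptor declares: for each observation feature, the latest
`final`-status observation inside `[reference_time − lookback,
reference_time]` wins, with ties on timestamp broken deterministically by
bundle entry order (first occurrence kept). Preliminary observations,
out-of-window values and unmapped codes never contribute; each leaves an
event in the preprocessing log that travels with the CDS response. The
default lookback is 24 h per descriptor — a standard CDS practice choice,
configurable per engine. Unit conversion goes through a small registry
(`unit_conversions.csv`) with formulas implemented in code; normalization to
a unit is idempotent by construction. Order-type features (antibiotics =
ATC `J01*`, vasopressors/inotropes = ATC `C01CA*`, blood culture = SNOMED
30088009) become booleans: true iff a matching active/completed request
exists in-window. The bundled vocabulary is deliberately minimal — the
eleven measured sepsis inputs, the triage vitals, and the order classes —
full OMOP vocabulary ingestion is out of scope.

## The triage model

The triage engine is model-agnostic behind its registry contract; the
shipped default is three *independent* binomial logistic heads (mortality,
critical care, hospitalization — the outcomes co-occur, so a multiclass head
would be wrong) over a frozen encoding:

* numeric fields scaled as `(x − center)/scale` with fixed, data-independent
  constants (age centred at 50 y / scaled by 20 y; SBP 120/20 mmHg, and so
  on), so training and serving agree by construction;
* missing numerics contribute a zero fill plus a paired missingness
  indicator;
* categoricals one-hot against frozen lists (20 chief-complaint codes plus
  an `other` bucket, AVPU, arrival mode), baselines being the first level.

Fitting uses `glm.fit` with a seeded train/test split (default 75/25);
training-design columns that are constant in a split are dropped from the
fit and reported as zero coefficients. A single-class outcome is a loud,
typed error. Risk bands are the quintile edges of the training-set predicted
probabilities, stored in the model artifact, so "predefined risk score"
determinism holds: band = 1 + number of edges strictly below the
probability. The artifact is versioned JSON — parameters, encoding version,
band edges, training metadata — and the encoding version is checked at
predict time. The quintile banding scheme is this package's stand-in for a
site-defined scale; nothing here attempts to reproduce any published triage
model's weights or discrimination.

## Federated summaries

Only `summary_report` objects cross an institution boundary. A report is
built by resolving a cohort (condition concept set, optional visit class)
against the OMOP-like store, then counting persons per drug concept and per
outcome (in-hospital death, hospitalization — a fixture convention).
Small-cell suppression withholds any cell with `0 < count < k`; the default
`k = 10`, with `k` configurable per exchange. Zero counts stay visible —
revealing absence is an accepted threat-model choice, documented here rather
than hidden. Suppressed cells lose their `count`/`rate` keys entirely in the
wire JSON, not just their values. Merging sums counts over contributing
(unsuppressed) sites, marks labels suppressed anywhere as partially
suppressed with the contributing-site count, and re-suppresses the merged
cells at the same `k`. Re-suppression prevents only the direct form of
reconstruction; differencing attacks across report versions remain possible
and are out of scope, as is differential privacy. Incoming peer payloads
pass a schema gate that rejects any person-level field (`person_id`,
`birth_date`, …) at any nesting depth; peers are callables sharing the local
request/response schema, so a loopback peer exercises the full exchange
without a network.

## The service layer

Engines are in-process plugins discovered from a delimited manifest and
registered by (name, version); invocation is on-demand only — no
interruptive alerting. `handle_request` is deterministic given (bundle,
engine version, reference time, peers): preprocessing, engine, optional peer
summaries, then a purely assembled display document in fixed section order
(headline, recommendations, peer statistics, data quality). Failures are
typed response documents (`engine_not_found`, `engine_failure`), and an
unreachable peer degrades to an unavailability marker while the local result
stands. The service layer adds no clinical content: every number in the
display document traces to an engine result or a summary report. The
platform's HTTP surface is represented by these request/response documents
and a thin CLI (`inst/cli/cds.R`); the functions are the API.

## Synthetic data and what tests show

The generator emulates single-visit ED encounters: a septic flag drawn at
the configured prevalence (default 0.3) switches vitals and labs between
truncated-normal "normal" and "deranged" ranges
(`vital_distributions.csv`), order flags follow per-status probabilities
(e.g. blood cultures 0.9 septic vs 0.1 non-septic), and labs go missing at a
configurable rate (default 0.08; vitals 0.02). Every quantity is rounded to
its clinically recorded precision before the ground-truth oracle sees it, so
the oracle and the pipeline compare on identical numbers even though FiO₂
travels on the wire in percent. The triage table is sampled with
*independent* per-vital derangement, so the design matrix is not collinear
through a single severity factor and coefficient-recovery experiments have
well-conditioned information at moderate n; outcome labels come from
logistic models whose coefficients are recorded alongside the data.

Ground truth (screen flag, qSOFA, SOFA) is computed at generation time by a
straight-line oracle implemented separately from the engines — different
code, different representation of the strata — so large-cohort agreement is
an informative check of both implementations, not a tautology. Everything is
seed-deterministic: patient `i` under profile seed `s` is fully reproducible
in isolation.

What passing tests show: the rule set, scoring tables, extraction windows,
suppression algebra and fitting machinery are internally correct and
mutually consistent at realistic value ranges. What they do not show:
performance on real EHR data — real bundles carry duplicated and conflicting
observations, free-text complaints, unit idiosyncrasies beyond the bundled
registry, and multi-visit longitudinal structure, none of which the
generator emulates. The synthetic prevalences and distributions are
plausible, not epidemiologic estimates.

## Problem sizes and numerical checks

The test suite runs the oracle-agreement gate at 10,000 patients, the
serialization round-trip at 1,000 bundles, suppression soundness over 200
random report pairs, parameter recovery at n = 5,000 visits, and the
end-to-end pipeline count at 200 patients — sizes chosen so each property is
exercised well past its small-sample regime while the whole suite stays
quick on a laptop. Recovery is checked on the generating effect
coefficients: at n = 5,000 with ~50 encoded columns the intercept's sampling
standard error (~0.2, driven by the one-hot blocks) exceeds any tolerance
that would be informative for the slopes, so the intercept is assessed
implicitly through the calibration of predicted probabilities and the
AUROC-versus-generative-optimum comparison instead. Test-set AUROC is
compared against the generative model's own AUROC on the same split — the
Bayes-optimal reference for sampled labels — rather than against an absolute
figure, which would depend on the arbitrary signal strength chosen for the
generator.

## Known limitations

* Baseline SOFA is assumed 0; chronic organ dysfunction inflates the acute
  score.
* The vasopressor boolean collapses the cardiovascular strata 2–4 to 3, and
  respiration 3–4 ignore ventilation status.
* The AVPU→GCS mapping and the 20-code chief-complaint list are package
  conventions, not consortium standards.
* Suppression does not protect against cross-report differencing; `k` and
  the zero-count policy are configurable but the algebra is not
  differentially private.
* The triage default model is a logistic stand-in; its discrimination on
  synthetic data says nothing about any published model's performance on
  real patients.
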