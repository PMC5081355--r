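# Generator configuration calibrated to the development-sample descriptives:
# average annual counts of each diagnostic test, MM diagnoses and
# chemotherapy days per patient by stratum, and per-window symptom/treatment
# probabilities by diagnosis stratum.

GEN_EVENT_TYPES <- c("protein_electrophoresis", "quantitative_immunoglobulin",
                     "serum_free_light_chain", "serum_albumin",
                     "beta2_microglobulin", "bone_marrow", "skeletal_survey",
                     "ldh", "mm_dx", "chemo_days")

#' Default generator configuration (table-calibrated)
#'
#' Annual event rates per patient-stratum and window-level symptom/treatment
#' probabilities equal the published development-sample descriptives, e.g.
#' controls average 3 MM-diagnosis dates and 1.20 protein-electrophoresis
#' claims per year, incident treated cases 39 MM-diagnosis dates and 240
#' chemotherapy days per year. Stratum sizes default to the development
#' sample (684/54/18/182/80). Enrollment duration is uniform on 1-4 years;
#' case events concentrate around the EMR diagnosis date via a two-rate burst
#' model (uniform pre-anchor baseline, post-anchor weight multiplied by
#' `burst$multiplier` decaying with half-life `burst$half_life_days`) - the
#' burst shape is an artifact construct, only the annual means are
#' calibrated.
#'
#' @return a `generator_config` list: `n` (patients per stratum), `rates`
#'   (stratum x event-type annual means), `window_probs` (feature x
#'   diagnosis-stratum probabilities), `enrollment_days` (range),
#'   `start_window` (enrollment start range), `burst`, `chemo_cycle_days`.
#' @export
default_config_from_tables <- function() {
  rates <- rbind(
    control             = c(1.20, 0.68, 0.34, 0.05, 0.28, 0.93, 0.27, 0.63,  3,   0),
    incident_untreated  = c(2.25, 1.36, 1.12, 0.05, 0.84, 0.88, 0.60, 0.77,  8,   0),
    prevalent_untreated = c(3.80, 1.31, 1.00, 0.04, 0.65, 1.03, 0.47, 0.62, 18,   0),
    incident_treated    = c(4.80, 2.69, 2.23, 0.14, 1.27, 1.67, 1.00, 2.50, 39, 240),
    prevalent_treated   = c(5.37, 3.09, 3.17, 0.09, 1.93, 0.95, 0.67, 2.85, 34, 202))
  colnames(rates) <- GEN_EVENT_TYPES

  window_probs <- rbind(
    corticosteroid        = c(0.261, 0.283, 0.797),
    anemia_treatment      = c(0.138, 0.180, 0.319),
    bisphosphonate        = c(0.136, 0.542, 0.614),
    monoclonal_gammopathy = c(0.193, 0.041, 0.126),
    other_malignancy      = c(0.186, 0.124, 0.192),
    anemia_dx             = c(0.291, 0.248, 0.382),
    osteoporosis_dx       = c(0.034, 0.009, 0.017),
    skeletal_related_event = c(0.093, 0.076, 0.136),
    bone_pain_lesions     = c(0.072, 0.050, 0.100),
    fatigue               = c(0.097, 0.054, 0.126),
    shortness_of_breath   = c(0.076, 0.096, 0.099),
    chest_pain            = c(0.138, 0.143, 0.163),
    peripheral_neuropathy = c(0.048, 0.030, 0.029),
    renal_failure         = c(0.152, 0.111, 0.239),
    hypercalcemia         = c(0.010, 0.027, 0.053),
    pneumonia             = c(0.077, 0.046, 0.077),
    herpes_zoster         = c(0.013, 0.021, 0.026),
    uti_kidney_infection  = c(0.091, 0.066, 0.048))
  colnames(window_probs) <- c("control", "case_untreated", "case_treated")

  structure(list(
    n = c(control = 684L, incident_untreated = 54L, prevalent_untreated = 18L,
          incident_treated = 182L, prevalent_treated = 80L),
    rates = rates,
    window_probs = window_probs,
    enrollment_days = c(365L, 1461L),
    start_window = as.Date(c("2001-01-01", "2011-01-01")),
    burst = list(multiplier = 8, half_life_days = 180),
    chemo_cycle_days = 5L,
    age_mean = 65, age_sd = 10
  ), class = "generator_config")
}

#' Validate a generator configuration
#'
#' @param config a `generator_config`.
#' @return the config, invisibly.
#' @export
validate_generator_config <- function(config) {
  if (!all(STRATA %in% names(config$n)) || any(config$n < 0)) {
    stop("invalid config: n must be named per stratum and >= 0", call. = FALSE)
  }
  if (!all(STRATA %in% rownames(config$rates)) ||
      !all(GEN_EVENT_TYPES %in% colnames(config$rates)) ||
      any(config$rates < 0)) {
    stop("invalid config: rates must cover all strata and event types and be >= 0",
         call. = FALSE)
  }
  if (any(config$window_probs < 0 | config$window_probs > 1)) {
    stop("invalid config: window_probs must lie in [0, 1]", call. = FALSE)
  }
  if (config$enrollment_days[1L] < 365L ||
      config$enrollment_days[1L] > config$enrollment_days[2L]) {
    stop("invalid config: enrollment_days must be an increasing range >= 365",
         call. = FALSE)
  }
  invisible(config)
}
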