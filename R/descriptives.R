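# Stratum descriptives used during algorithm development: average annual
# event counts per patient (tabulated by true MM status and chemotherapy
# treatment) and per-diagnosis window summaries.

STRATA <- c("control", "incident_untreated", "prevalent_untreated",
            "incident_treated", "prevalent_treated")

# Patient-level stratum. "Treated" means at least one chemotherapy claim on
# or after the anchor date within the observation period; combined with the
# incident flag this yields the four case strata. (Defining "treated" as any
# chemotherapy in the observation period would make the prevalent-untreated
# stratum structurally empty, since prevalent status is itself established by
# pre-anchor chemotherapy.)
patient_strata <- function(labels, bundle, config) {
  mc <- bundle$medical_claims
  dc <- bundle$drug_claims
  chemo_cs <- config$codesets$chemotherapy
  chemo_med <- medical_claims_in_codeset(mc, chemo_cs, config)
  chemo_drug <- drug_claims_in_codeset(dc, chemo_cs, config)
  chemo <- rbind(data.frame(patient_id = mc$patient_id[chemo_med],
                            date = mc$service_date[chemo_med]),
                 data.frame(patient_id = dc$patient_id[chemo_drug],
                            date = dc$fill_date[chemo_drug]))
  out <- character(nrow(labels))
  for (i in seq_len(nrow(labels))) {
    if (labels$label[i] == "control") { out[i] <- "control"; next }
    ch <- chemo[chemo$patient_id == labels$patient_id[i], , drop = FALSE]
    treated <- any(ch$date >= labels$anchor_date[i] &
                     ch$date >= labels$observation_start[i] &
                     ch$date <= labels$observation_end[i])
    out[i] <- paste0(if (isTRUE(labels$incident[i])) "incident" else "prevalent",
                     if (treated) "_treated" else "_untreated")
  }
  out
}

#' Average annual event counts per patient, by stratum
#'
#' For every labeled patient, counts events inside the observation period and
#' divides by observation years (days / 365.25), then averages within
#' stratum. Diagnostic tests are counted per claim; MM diagnoses and
#' chemotherapy days as distinct service dates. Cases split into
#' incident/prevalent (from the gold label) crossed with treated/untreated
#' (chemotherapy on or after the anchor date).
#'
#' @param labels gold-label data frame (with `incident`, `observation_start`,
#'   `observation_end`).
#' @param bundle a [claims_bundle()].
#' @param config a [codeset_config()].
#' @return data frame: one row per non-empty stratum with `n_patients` and an
#'   annualized-mean column per event type (`mm_dx`, each diagnostic test,
#'   `chemo_days`).
#' @export
annualized_rates <- function(labels, bundle, config) {
  obs_days <- as.integer(labels$observation_end) -
    as.integer(labels$observation_start) + 1L
  if (any(obs_days <= 0L)) {
    stop("zero-length observation period", call. = FALSE)
  }
  strata <- patient_strata(labels, bundle, config)
  ev <- precompute_events(bundle, config)
  event_types <- c(config$diagnostic_tests, "mm_dx", "chemo_days")

  rates <- matrix(0, nrow(labels), length(event_types),
                  dimnames = list(NULL, event_types))
  for (i in seq_len(nrow(labels))) {
    e <- ev[[labels$patient_id[i]]]
    lo <- as.integer(labels$observation_start[i])
    hi <- as.integer(labels$observation_end[i])
    yrs <- obs_days[i] / DAYS_PER_YEAR
    if (is.null(e)) next
    for (nm in config$diagnostic_tests) {
      d <- e$per_test[[nm]]
      rates[i, nm] <- sum(d >= lo & d <= hi) / yrs
    }
    mm <- e$mm_dx_dates
    rates[i, "mm_dx"] <- sum(mm >= lo & mm <= hi) / yrs
    ch <- unique(e$chemo_dates)
    rates[i, "chemo_days"] <- sum(ch >= lo & ch <= hi) / yrs
  }

  present <- STRATA[STRATA %in% strata]
  rows <- lapply(present, function(s) {
    idx <- strata == s
    means <- colMeans(rates[idx, , drop = FALSE])
    cbind(data.frame(stratum = s, n_patients = sum(idx),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(means)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign a diagnosis-level stratum to every panel row
#'
#' Strata are `control`, `case_untreated`, `case_treated`. Following the
#' gold-standard accounting convention, index diagnoses of *incident* cases
#' dated before the EMR diagnosis date are assigned to the control stratum
#' (at those times the patient is known not to have established MM yet).
#' Diagnoses of unlabeled patients get `NA`.
#'
#' @param panel output of [build_panel()] (or [extract_features()]).
#' @param labels gold-label data frame.
#' @param bundle,config used to determine treated status.
#' @return character vector, one stratum per panel row.
#' @export
assign_diagnosis_strata <- function(panel, labels, bundle, config) {
  strata <- patient_strata(labels, bundle, config)
  lab_map <- setNames(labels$label, labels$patient_id)
  inc_map <- setNames(labels$incident, labels$patient_id)
  anchor_map <- setNames(as.integer(labels$anchor_date), labels$patient_id)
  treated_map <- setNames(grepl("_treated$", strata), labels$patient_id)

  out <- rep(NA_character_, nrow(panel))
  pid <- panel$patient_id
  known <- pid %in% labels$patient_id
  is_control <- known & lab_map[pid] == "control"
  out[is_control] <- "control"
  is_case <- known & lab_map[pid] == "case"
  pre_emr <- is_case & !is.na(inc_map[pid]) & inc_map[pid] &
    as.integer(as.Date(panel$index_date)) < anchor_map[pid]
  out[pre_emr] <- "control"
  rest <- is_case & !pre_emr
  out[rest] <- ifelse(treated_map[pid[rest]], "case_treated", "case_untreated")
  out
}

#' Per-diagnosis window summaries by stratum
#'
#' For each feature column of [extract_features()] output, reports the
#' percentage of index diagnoses with at least one event and, for count
#' features, the mean and standard deviation (n-1 denominator). The `case`
#' stratum is the union of `case_untreated` and `case_treated`.
#'
#' @param features output of [extract_features()].
#' @param strata vector from [assign_diagnosis_strata()].
#' @return long data frame: `stratum`, `n_diagnoses`, `feature`, `pct_any`,
#'   `mean`, `sd`.
#' @export
window_summaries <- function(features, strata) {
  feature_cols <- setdiff(names(features),
                          c("patient_id", "index_date", "claim_id"))
  groups <- list(control = strata == "control",
                 case = strata %in% c("case_untreated", "case_treated"),
                 case_untreated = strata == "case_untreated",
                 case_treated = strata == "case_treated")
  rows <- list()
  for (g in names(groups)) {
    idx <- which(groups[[g]])
    if (length(idx) == 0L) next
    for (col in feature_cols) {
      v <- features[[col]][idx]
      if (is.logical(v)) {
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = g, n_diagnoses = length(idx), feature = col,
          pct_any = 100 * mean(v), mean = NA_real_, sd = NA_real_,
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = g, n_diagnoses = length(idx), feature = col,
          pct_any = 100 * mean(v > 0), mean = mean(v),
          sd = if (length(idx) > 1L) sd(v) else 0,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
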