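# Gold-standard cohort construction. Cases are anchored on an oncology-EMR
# MM diagnosis with a clinic visit; controls are primary-care-EMR-linked
# patients who carry MM diagnosis codes on claims during an observation
# period in which the EMR shows they do not have MM.

#' Age at a date, from birth year
#'
#' De-identified claims carry birth year only, so age is computed at year
#' precision: `year(date) - birth_year`.
#'
#' @param date a Date vector.
#' @param birth_year integer vector.
#' @return integer vector of ages.
#' @export
age_at <- function(date, birth_year) {
  as.integer(format(as.Date(date), "%Y")) - as.integer(birth_year)
}

#' Does a free-text note mention multiple myeloma?
#'
#' Case-insensitive substring scan against a term list. The default list
#' deliberately includes the bare "myeloma" so that phrasing such as
#' "smoldering myeloma" is caught; it is configurable because broad terms
#' also catch negated mentions.
#'
#' @param note_text character vector of note texts.
#' @param term_list non-empty character vector of search terms.
#' @return logical vector.
#' @export
note_mentions_mm <- function(note_text,
                             term_list = c("multiple myeloma", "myeloma")) {
  if (length(term_list) == 0L) {
    stop("term_list must be non-empty", call. = FALSE)
  }
  txt <- tolower(as.character(note_text))
  hit <- rep(FALSE, length(txt))
  for (term in tolower(term_list)) {
    hit <- hit | grepl(term, txt, fixed = TRUE)
  }
  hit & !is.na(txt)
}

#' Default cohort-selection parameters
#'
#' @return a list: `pre_days` (90) and `post_days` (30) of continuous
#'   enrollment around the case anchor, `overlap_days` (365) minimum
#'   EMR/claims overlap for controls, `min_age` (18), `mm_terms` for the
#'   note scan, and `chemo_mm_association` (`"same_claim"` or `"same_day"`).
#' @export
cohort_params <- function() {
  list(pre_days = 90L, post_days = 30L, overlap_days = 365L, min_age = 18L,
       mm_terms = c("multiple myeloma", "myeloma"),
       chemo_mm_association = "same_claim")
}

# Service dates of chemotherapy claims "associated with" an MM diagnosis.
# Default reading: chemotherapy code and MM diagnosis code on the SAME claim
# record; "same_day" instead pairs any chemo claim (medical or pharmacy) with
# any MM-coded claim on the same service date.
chemo_mm_assoc_dates <- function(bundle, config, patient_ids = NULL,
                                 mode = c("same_claim", "same_day")) {
  mode <- match.arg(mode)
  mc <- bundle$medical_claims
  dc <- bundle$drug_claims
  if (!is.null(patient_ids)) {
    mc <- mc[mc$patient_id %in% patient_ids, , drop = FALSE]
    dc <- dc[dc$patient_id %in% patient_ids, , drop = FALSE]
  }
  chemo_cs <- config$codesets$chemotherapy
  mm_cs <- config$codesets$mm_diagnosis
  mm_hit <- medical_claims_in_codeset(mc, mm_cs, config)
  chemo_med <- medical_claims_in_codeset(mc, chemo_cs, config)
  if (mode == "same_claim") {
    idx <- chemo_med & mm_hit
    return(data.frame(patient_id = mc$patient_id[idx],
                      date = mc$service_date[idx]))
  }
  chemo_dates <- rbind(
    data.frame(patient_id = mc$patient_id[chemo_med],
               date = mc$service_date[chemo_med]),
    data.frame(patient_id = dc$patient_id[drug_claims_in_codeset(dc, chemo_cs, config)],
               date = dc$fill_date[drug_claims_in_codeset(dc, chemo_cs, config)]))
  mm_dates <- data.frame(patient_id = mc$patient_id[mm_hit],
                         date = mc$service_date[mm_hit])
  key <- paste(chemo_dates$patient_id, chemo_dates$date)
  keep <- key %in% paste(mm_dates$patient_id, mm_dates$date)
  chemo_dates[keep, , drop = FALSE]
}

#' Classify a case as incident or prevalent
#'
#' A case is incident when no chemotherapy claim associated with an MM
#' diagnosis occurs strictly before the EMR anchor date. "Associated with"
#' defaults to chemotherapy and MM diagnosis codes on the same claim record.
#'
#' @param patient_id patient identifier.
#' @param anchor_date the EMR MM diagnosis date.
#' @param bundle a [claims_bundle()].
#' @param config a [codeset_config()].
#' @param association `"same_claim"` (default) or `"same_day"`.
#' @return `TRUE` (incident) or `FALSE` (prevalent).
#' @export
classify_incident <- function(patient_id, anchor_date, bundle, config,
                              association = "same_claim") {
  assoc <- chemo_mm_assoc_dates(bundle, config, patient_ids = patient_id,
                                mode = association)
  !any(assoc$date < as.Date(anchor_date))
}

#' Select gold-standard cases from the oncology EMR
#'
#' A patient is a case when the oncology EMR records an MM diagnosis with a
#' clinic visit date, age at the EMR diagnosis date is at least `min_age`,
#' and merged claims enrollment continuously covers `pre_days` before through
#' `post_days` after the diagnosis. When several EMR records qualify, the
#' earliest eligible diagnosis date anchors the case. The observation period
#' is the merged enrollment span containing the anchor window.
#'
#' @param bundle a [claims_bundle()].
#' @param config a [codeset_config()].
#' @param params see [cohort_params()].
#' @return a data frame of gold labels: `patient_id`, `label` (`"case"`),
#'   `anchor_date`, `incident`, `observation_start`, `observation_end`.
#' @export
select_cases <- function(bundle, config, params = cohort_params()) {
  eo <- bundle$emr_oncology
  out <- empty_labels()
  if (nrow(eo) == 0L) return(out)
  persons <- bundle$persons
  spans <- merged_spans_by_patient(bundle$enrollment)
  by_map <- setNames(persons$birth_year, persons$patient_id)

  eo <- eo[!is.na(eo$visit_date), , drop = FALSE]
  if (nrow(eo) == 0L) return(out)
  eo <- eo[order(eo$patient_id, eo$emr_dx_date), , drop = FALSE]

  rows <- list()
  for (pid in unique(eo$patient_id)) {
    recs <- eo[eo$patient_id == pid, , drop = FALSE]
    sp <- spans[[pid]]
    if (is.null(sp)) next
    for (i in seq_len(nrow(recs))) {
      dx <- recs$emr_dx_date[i]
      if (age_at(dx, by_map[[pid]]) < params$min_age) next
      cover <- sp$start_date <= dx - params$pre_days &
        sp$end_date >= dx + params$post_days
      if (!any(cover)) next
      span <- sp[which(cover)[1L], ]
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, label = "case", anchor_date = dx,
        incident = classify_incident(pid, dx, bundle, config,
                                     params$chemo_mm_association %||% "same_claim"),
        observation_start = span$start_date,
        observation_end = span$end_date,
        stringsAsFactors = FALSE)
      break
    }
  }
  if (length(rows) == 0L) return(out)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select gold-standard controls from primary-care-EMR-linked claims
#'
#' Controls are patients known not to have MM despite carrying MM diagnosis
#' codes. Eligibility: age >= `min_age` at observation start, an observation
#' period of at least `overlap_days` where claims enrollment overlaps
#' primary-care EMR coverage (taken as the span from first to last note), and
#' at least one MM-coded claim inside it. Exclusions, all evaluated within
#' the observation period: (1) a chemotherapy claim associated with an MM
#' diagnosis, (2) any stem-cell-transplant claim, (3) any note matching the
#' MM text scan ([note_mentions_mm()]). When several disjoint overlap windows
#' qualify, the earliest is used (it maximizes follow-up).
#'
#' @inheritParams select_cases
#' @return a data frame of gold labels with `label = "control"`, `incident`
#'   `NA`, and `anchor_date` equal to the observation start.
#' @export
select_controls <- function(bundle, config, params = cohort_params()) {
  notes <- bundle$emr_notes
  out <- empty_labels()
  if (nrow(notes) == 0L) return(out)
  persons <- bundle$persons
  spans <- merged_spans_by_patient(bundle$enrollment)
  by_map <- setNames(persons$birth_year, persons$patient_id)
  mm_cs <- config$codesets$mm_diagnosis
  sct_cs <- config$codesets$stem_cell_transplant
  mc <- bundle$medical_claims
  mm_hit <- medical_claims_in_codeset(mc, mm_cs, config)
  sct_hit <- if (is.null(sct_cs)) rep(FALSE, nrow(mc)) else {
    medical_claims_in_codeset(mc, sct_cs, config)
  }
  assoc <- chemo_mm_assoc_dates(bundle, config,
                                mode = params$chemo_mm_association %||% "same_claim")

  rows <- list()
  for (pid in unique(notes$patient_id)) {
    sp <- spans[[pid]]
    if (is.null(sp)) next
    nd <- notes$note_date[notes$patient_id == pid]
    emr_lo <- min(nd); emr_hi <- max(nd)
    # candidate observation windows: enrollment spans clipped to EMR coverage
    w_lo <- pmax(sp$start_date, emr_lo)
    w_hi <- pmin(sp$end_date, emr_hi)
    ok <- !is.na(w_lo) & w_lo <= w_hi &
      (as.integer(w_hi) - as.integer(w_lo) + 1L) >= params$overlap_days
    if (!any(ok)) next
    found <- NULL
    for (k in order(w_lo)[ok[order(w_lo)]]) {
      lo <- w_lo[k]; hi <- w_hi[k]
      if (age_at(lo, by_map[[pid]]) < params$min_age) next
      pm <- mc$patient_id == pid & mc$service_date >= lo & mc$service_date <= hi
      if (!any(pm & mm_hit)) next
      found <- c(lo, hi)
      break
    }
    if (is.null(found)) next
    lo <- found[1L]; hi <- found[2L]
    # exclusions within the observation period
    a <- assoc[assoc$patient_id == pid, , drop = FALSE]
    if (any(a$date >= lo & a$date <= hi)) next
    pm <- mc$patient_id == pid & mc$service_date >= lo & mc$service_date <= hi
    if (any(pm & sct_hit)) next
    nidx <- notes$patient_id == pid & notes$note_date >= lo & notes$note_date <= hi
    if (any(note_mentions_mm(notes$note_text[nidx], params$mm_terms))) next
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = pid, label = "control", anchor_date = lo, incident = NA,
      observation_start = lo, observation_end = hi, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(out)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_labels <- function() {
  data.frame(patient_id = character(0), label = character(0),
             anchor_date = as.Date(character(0)), incident = logical(0),
             observation_start = as.Date(character(0)),
             observation_end = as.Date(character(0)),
             stringsAsFactors = FALSE)
}

#' Build the merged gold-standard file
#'
#' Runs [select_cases()] and [select_controls()] and merges them; a patient
#' selected by both (possible only in pathological inputs) is kept as a case.
#'
#' @inheritParams select_cases
#' @return a gold-label data frame (cases then controls).
#' @export
build_gold_standard <- function(bundle, config, params = cohort_params()) {
  cases <- select_cases(bundle, config, params)
  controls <- select_controls(bundle, config, params)
  controls <- controls[!controls$patient_id %in% cases$patient_id, , drop = FALSE]
  out <- rbind(cases, controls)
  rownames(out) <- NULL
  out
}

#' Split labeled patients into development and validation halves
#'
#' A seeded uniform permutation of the (sorted) patient ids assigns the first
#' `ceiling(n/2)` to the development sample and the rest to validation. The
#' assignment is deterministic given the seed and invariant to the input row
#' order.
#'
#' @param labels gold-label data frame.
#' @param seed integer seed.
#' @return data frame with `patient_id` and `sample`
#'   (`"development"`/`"validation"`).
#' @export
split_sample <- function(labels, seed) {
  ids <- sort(unique(as.character(labels$patient_id)))
  n <- length(ids)
  if (n == 0L) stop("split_sample: no labeled patients", call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  n_dev <- ceiling(n / 2)
  sample <- rep("validation", n)
  sample[perm <= n_dev] <- "development"
  data.frame(patient_id = ids, sample = sample, stringsAsFactors = FALSE)
}
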