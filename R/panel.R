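# Per-diagnosis evaluation panel. Every MM-coded claim with 90 days of
# continuous enrollment before and 30 days after its service date is an
# eligible index event; features are extracted in windows of at most 180
# days on each side of the index.
#
# Window conventions (all endpoints inclusive):
#   prior MM-dx window  [index-180, index-1]
#   post  MM-dx window  [index+1, index+180]
#   ">30 days following"  [index+31, index+180]
#   diagnostic-test lookback includes the index day: [index-90, index] and
#     [index-180, index] (tests are commonly billed on the diagnosis day)
#   chemotherapy "prior to or on" [index-180, index]; "following"
#     [index, index+180]
#   symptom/treatment lookback [index-180, index-1]

#' Default panel parameters
#'
#' @return list with `pre_days` (90), `post_days` (30), `feature_days` (180),
#'   `test_lookback_days` (90) and `count_mode` (`"distinct_date"` or
#'   `"per_claim"` for MM-diagnosis counting).
#' @export
panel_params <- function() {
  list(pre_days = 90L, post_days = 30L, feature_days = 180L,
       test_lookback_days = 90L, count_mode = "distinct_date")
}

#' Is a date continuously enrolled around?
#'
#' `TRUE` iff a single merged span covers the inclusive window
#' `[date - days_before, date + days_after]` entirely.
#'
#' @param spans merged enrollment spans (see [merge_enrollment()]).
#' @param date a Date (vectorized).
#' @param days_before,days_after non-negative integer day counts.
#' @return logical vector.
#' @export
continuous_enrollment <- function(spans, date, days_before, days_after) {
  if (days_before < 0L || days_after < 0L) {
    stop("days_before/days_after must be >= 0", call. = FALSE)
  }
  date <- as.Date(date)
  vapply(as.integer(date), function(d) {
    any(as.integer(spans$start_date) <= d - days_before &
          as.integer(spans$end_date) >= d + days_after)
  }, logical(1))
}

#' Build the index-diagnosis panel
#'
#' One row per MM-coded medical claim (rows of a multi-row claim are
#' deduplicated by `claim_id`) that satisfies the continuous-enrollment rule.
#' Rows are ordered by `patient_id`, `index_date`, then `claim_id`.
#'
#' @param bundle a [claims_bundle()].
#' @param config a [codeset_config()].
#' @param params see [panel_params()].
#' @return data frame with `patient_id`, `index_date`, `claim_id`.
#' @export
build_panel <- function(bundle, config, params = panel_params()) {
  mc <- bundle$medical_claims
  empty <- data.frame(patient_id = character(0),
                      index_date = as.Date(character(0)),
                      claim_id = character(0), stringsAsFactors = FALSE)
  if (nrow(mc) == 0L) return(empty)
  hit <- medical_claims_in_codeset(mc, config$codesets$mm_diagnosis, config)
  cand <- mc[hit, c("patient_id", "service_date", "claim_id"), drop = FALSE]
  cand <- unique(cand)
  if (nrow(cand) == 0L) return(empty)
  spans <- merged_spans_by_patient(bundle$enrollment)
  keep <- logical(nrow(cand))
  for (pid in unique(cand$patient_id)) {
    idx <- which(cand$patient_id == pid)
    sp <- spans[[pid]]
    if (is.null(sp)) next
    keep[idx] <- continuous_enrollment(sp, cand$service_date[idx],
                                       params$pre_days, params$post_days)
  }
  out <- cand[keep, , drop = FALSE]
  names(out)[names(out) == "service_date"] <- "index_date"
  out <- out[order(out$patient_id, out$index_date, out$claim_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Precompute per-patient event-date vectors (integer days) used by both
# feature extraction and the rule engine. Dates are per-claim for test and
# chemotherapy events and distinct-and-sorted for MM diagnosis dates.
precompute_events <- function(bundle, config) {
  mc <- bundle$medical_claims
  dc <- bundle$drug_claims
  mm_hit <- medical_claims_in_codeset(mc, config$codesets$mm_diagnosis, config)
  test_hit <- rep(FALSE, nrow(mc))
  per_test <- list()
  for (nm in config$diagnostic_tests) {
    h <- medical_claims_in_codeset(mc, config$codesets[[nm]], config)
    per_test[[nm]] <- h
    test_hit <- test_hit | h
  }
  bm_hit <- per_test[["bone_marrow"]] %||% rep(FALSE, nrow(mc))
  chemo_cs <- config$codesets$chemotherapy
  chemo_med <- medical_claims_in_codeset(mc, chemo_cs, config)
  chemo_drug <- drug_claims_in_codeset(dc, chemo_cs, config)

  other <- c(config$treatments, config$symptoms)
  per_other_med <- lapply(other, function(nm) {
    medical_claims_in_codeset(mc, config$codesets[[nm]], config)
  })
  names(per_other_med) <- other
  per_other_drug <- lapply(other, function(nm) {
    drug_claims_in_codeset(dc, config$codesets[[nm]], config)
  })
  names(per_other_drug) <- other

  svc <- as.integer(mc$service_date)
  fill <- as.integer(dc$fill_date)
  pids <- unique(c(mc$patient_id, dc$patient_id))
  mc_split <- split(seq_len(nrow(mc)), mc$patient_id)
  dc_split <- split(seq_len(nrow(dc)), dc$patient_id)
  spans <- merged_spans_by_patient(bundle$enrollment)

  events <- lapply(setNames(pids, pids), function(pid) {
    i <- mc_split[[pid]] %||% integer(0)
    j <- dc_split[[pid]] %||% integer(0)
    ev <- list(
      mm_dx_dates = sort(unique(svc[i][mm_hit[i]])),
      test_dates = sort(svc[i][test_hit[i]]),
      bm_dates = sort(svc[i][bm_hit[i]]),
      chemo_dates = sort(c(svc[i][chemo_med[i]], fill[j][chemo_drug[j]]))
    )
    ev$per_test <- lapply(per_test, function(h) sort(svc[i][h[i]]))
    ev$per_other <- lapply(setNames(other, other), function(nm) {
      sort(c(svc[i][per_other_med[[nm]][i]], fill[j][per_other_drug[[nm]][j]]))
    })
    ev$spans <- spans[[pid]] %||%
      data.frame(start_date = as.Date(character(0)),
                 end_date = as.Date(character(0)))
    ev
  })
  events
}

# Count events per index via findInterval on a sorted date vector; windows
# are [index + lo, index + hi] in days, intersected with enrollment when
# clip = TRUE.
count_in_window <- function(sorted_dates, index_days, lo, hi) {
  if (length(sorted_dates) == 0L) return(integer(length(index_days)))
  findInterval(index_days + hi, sorted_dates) -
    findInterval(index_days + lo - 1L, sorted_dates)
}

clip_to_spans <- function(dates, spans) {
  if (length(dates) == 0L || nrow(spans) == 0L) return(integer(0))
  keep <- rep(FALSE, length(dates))
  for (k in seq_len(nrow(spans))) {
    keep <- keep | (dates >= as.integer(spans$start_date[k]) &
                      dates <= as.integer(spans$end_date[k]))
  }
  dates[keep]
}

#' Extract windowed features for panel rows
#'
#' Computes, for every index diagnosis, the per-window counts and booleans
#' used in algorithm development: distinct MM-diagnosis service dates before
#' and after the index, per-test claim counts in 90- and 180-day lookbacks
#' (including the index day), chemotherapy presence before/on and following
#' the index, symptom and treatment booleans in the 180-day lookback, and
#' enrollment-covered day counts in each 180-day window. Event dates are
#' clipped to enrollment.
#'
#' @param panel output of [build_panel()].
#' @param bundle a [claims_bundle()].
#' @param config a [codeset_config()].
#' @param params see [panel_params()].
#' @param events optional precomputed event index (internal reuse).
#' @return the panel data frame with feature columns appended:
#'   `n_mm_dx_prior`, `n_mm_dx_post`, `has_mm_dx_post_30`,
#'   `n_<test>_90`, `n_<test>_180`, `chemo_prior_or_on`, `chemo_post`,
#'   `has_<treatment-or-symptom>`, `observed_days_prior`,
#'   `observed_days_post`.
#' @export
extract_features <- function(panel, bundle, config, params = panel_params(),
                             events = NULL) {
  if (is.null(events)) events <- precompute_events(bundle, config)
  fd <- params$feature_days
  tl <- params$test_lookback_days
  n <- nrow(panel)
  idx_days <- as.integer(as.Date(panel$index_date))

  cols <- list(
    n_mm_dx_prior = integer(n), n_mm_dx_post = integer(n),
    has_mm_dx_post_30 = logical(n))
  for (nm in config$diagnostic_tests) {
    cols[[paste0("n_", nm, "_", tl)]] <- integer(n)
    cols[[paste0("n_", nm, "_", fd)]] <- integer(n)
  }
  cols$chemo_prior_or_on <- logical(n)
  cols$chemo_post <- logical(n)
  other <- c(config$treatments, config$symptoms)
  for (nm in other) cols[[paste0("has_", nm)]] <- logical(n)
  cols$observed_days_prior <- integer(n)
  cols$observed_days_post <- integer(n)

  for (pid in unique(panel$patient_id)) {
    rows <- which(panel$patient_id == pid)
    ev <- events[[pid]]
    if (is.null(ev)) next
    d <- idx_days[rows]
    sp <- ev$spans
    mm <- clip_to_spans(ev$mm_dx_dates, sp)
    cols$n_mm_dx_prior[rows] <- count_in_window(mm, d, -fd, -1L)
    cols$n_mm_dx_post[rows] <- count_in_window(mm, d, 1L, fd)
    cols$has_mm_dx_post_30[rows] <- count_in_window(mm, d, 31L, fd) > 0L
    for (nm in config$diagnostic_tests) {
      td <- clip_to_spans(ev$per_test[[nm]], sp)
      cols[[paste0("n_", nm, "_", tl)]][rows] <- count_in_window(td, d, -tl, 0L)
      cols[[paste0("n_", nm, "_", fd)]][rows] <- count_in_window(td, d, -fd, 0L)
    }
    ch <- clip_to_spans(ev$chemo_dates, sp)
    cols$chemo_prior_or_on[rows] <- count_in_window(ch, d, -fd, 0L) > 0L
    cols$chemo_post[rows] <- count_in_window(ch, d, 0L, fd) > 0L
    for (nm in other) {
      od <- clip_to_spans(ev$per_other[[nm]], sp)
      cols[[paste0("has_", nm)]][rows] <- count_in_window(od, d, -fd, -1L) > 0L
    }
    for (r in rows) {
      dd <- idx_days[r]
      cols$observed_days_prior[r] <- covered_days(sp, as.Date(dd - fd, origin = "1970-01-01"),
                                                  as.Date(dd - 1L, origin = "1970-01-01"))
      cols$observed_days_post[r] <- covered_days(sp, as.Date(dd + 1L, origin = "1970-01-01"),
                                                 as.Date(dd + fd, origin = "1970-01-01"))
    }
  }
  cbind(panel, as.data.frame(cols, stringsAsFactors = FALSE))
}
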