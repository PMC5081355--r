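# Independent brute-force oracle for the rule engine. Deliberately shares no
# windowing, matching, or panel code with the engine: codes are matched with
# regular expressions, enrollment coverage is checked against an explicit
# day set, and every window is re-counted with direct scans. Intended for
# testing; quadratic-ish and unapologetic about it.

bf_pattern_regex <- function(pattern_string, mode) {
  raw <- toupper(gsub(".", "", pattern_string, fixed = TRUE))
  n_wild <- nchar(raw) - nchar(sub("X+$", "", raw))
  prefix <- substr(raw, 1L, nchar(raw) - n_wild)
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", prefix)
  if (n_wild == 0L) {
    paste0("^", esc, "$")
  } else if (mode == "per_char") {
    paste0("^", esc, paste(rep(".", n_wild), collapse = ""), "$")
  } else {
    paste0("^", esc)
  }
}

bf_code_matches <- function(codes, cs, systems, mode, code_systems) {
  hit <- rep(FALSE, length(codes))
  for (p in cs$patterns) {
    if (!p$system %in% systems) next
    ok <- if (length(code_systems)) code_systems == p$system else TRUE
    hit <- hit | (ok & grepl(bf_pattern_regex(p$pattern, mode), codes))
  }
  hit
}

bf_med_matches <- function(mc, cs, config) {
  mode <- config$wildcard_mode %||% "zero_or_more"
  dx_cols <- if (identical(config$dx_match %||% "any_slot", "primary_only")) "dx1" else DX_SLOTS
  hit <- rep(FALSE, nrow(mc))
  for (col in dx_cols) {
    hit <- hit | bf_code_matches(mc[[col]], cs, "ICD9DX", mode, character(0))
  }
  hit | bf_code_matches(mc$proc_code, cs, PROC_SYSTEMS, mode, mc$proc_system)
}

#' Brute-force re-derivation of a patient's flag (test oracle)
#'
#' Recomputes the [flag_patient()] result for one patient by exhaustive
#' direct scanning of the raw bundle tables, using none of the engine's
#' windowing or matching code. Supports the same predicate kinds and clause
#' trees as the engine.
#'
#' @param spec an [algorithm_spec()].
#' @param bundle a [claims_bundle()].
#' @param patient_id the patient to evaluate.
#' @param config a [codeset_config()].
#' @param pre_days,post_days panel eligibility margins (90/30 defaults).
#' @return list with `flagged` and `flag_date`.
#' @export
brute_force_flag <- function(spec, bundle, patient_id, config,
                             pre_days = 90L, post_days = 30L) {
  mode <- config$wildcard_mode %||% "zero_or_more"
  mc <- bundle$medical_claims[bundle$medical_claims$patient_id == patient_id, , drop = FALSE]
  dc <- bundle$drug_claims[bundle$drug_claims$patient_id == patient_id, , drop = FALSE]
  en <- bundle$enrollment[bundle$enrollment$patient_id == patient_id, , drop = FALSE]

  covered <- if (nrow(en)) {
    unique(unlist(Map(function(s, e) seq(as.integer(s), as.integer(e)),
                      en$start_date, en$end_date)))
  } else integer(0)

  mm_rows <- bf_med_matches(mc, config$codesets$mm_diagnosis, config)
  test_days <- integer(0)
  for (nm in config$diagnostic_tests) {
    rows <- bf_med_matches(mc, config$codesets[[nm]], config)
    test_days <- c(test_days, as.integer(mc$service_date[rows]))
  }
  bm_days <- as.integer(mc$service_date[bf_med_matches(mc, config$codesets$bone_marrow, config)])
  chemo_days <- c(
    as.integer(mc$service_date[bf_med_matches(mc, config$codesets$chemotherapy, config)]),
    as.integer(dc$fill_date[bf_code_matches(dc$ndc, config$codesets$chemotherapy,
                                            "NDC", mode, character(0))]))
  mm_days <- unique(as.integer(mc$service_date[mm_rows]))

  eval_pred_bf <- function(p, i) {
    days <- switch(p$kind,
      mm_dx_count = mm_days,
      diagnostic_test_count = test_days,
      bone_marrow_count = bm_days,
      chemo_present = chemo_days)
    in_win <- days[days >= i + p$window[1L] & days <= i + p$window[2L]]
    if (!is.null(p$sequence_anchor)) {
      alo <- i + p$anchor_window[1L]; ahi <- i + p$anchor_window[2L]
      tw <- test_days[test_days >= alo & test_days <= ahi]
      anchor <- if (length(tw) >= 2L) min(tw) else {
        bw <- bm_days[bm_days >= alo & bm_days <= ahi]
        if (length(bw) >= 1L) min(bw) else NA_integer_
      }
      if (is.na(anchor)) return(FALSE)
      in_win <- in_win[in_win < anchor]
    }
    length(in_win) >= p$threshold
  }
  eval_tree_bf <- function(node, i) {
    if (inherits(node, "predicate")) return(eval_pred_bf(node, i))
    vals <- vapply(node$children, eval_tree_bf, logical(1), i = i)
    if (node$op == "all") all(vals) else any(vals)
  }

  cand <- unique(mc[mm_rows, c("service_date", "claim_id")])
  cand <- cand[order(cand$service_date, cand$claim_id), , drop = FALSE]
  for (r in seq_len(nrow(cand))) {
    i <- as.integer(cand$service_date[r])
    window <- seq(i - pre_days, i + post_days)
    if (!all(window %in% covered)) next
    if (eval_tree_bf(spec$clause, i)) {
      return(list(flagged = TRUE, flag_date = cand$service_date[r]))
    }
  }
  list(flagged = FALSE, flag_date = as.Date(NA))
}
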