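# Patient-level diagnostic-accuracy metrics. Because cases and controls come
# from two different EMR systems, PPV cannot be computed directly; it is
# derived from sensitivity, specificity and the fraction of a reference
# population flagged (f):
#
#   PPV = (sensitivity * (f + specificity - 1)) / (f * (sensitivity + specificity - 1))
#
# equivalently Bayes' rule with the implied prevalence
#   p = (f + specificity - 1) / (sensitivity + specificity - 1).

#' Patient-level confusion counts
#'
#' @param flags data frame from [flag_population()] (`patient_id`,
#'   `flagged`).
#' @param labels gold-label data frame (`patient_id`, `label`). Every labeled
#'   patient must have a flag result.
#' @return list with `tp`, `fn`, `tn`, `fp`.
#' @export
confusion_counts <- function(flags, labels) {
  fl <- setNames(flags$flagged, flags$patient_id)
  missing <- setdiff(labels$patient_id, flags$patient_id)
  if (length(missing)) {
    stop("input error: labeled patient '", missing[1L],
         "' has no flag result", call. = FALSE)
  }
  is_case <- labels$label == "case"
  flagged <- as.logical(fl[labels$patient_id])
  list(tp = sum(is_case & flagged), fn = sum(is_case & !flagged),
       tn = sum(!is_case & !flagged), fp = sum(!is_case & flagged))
}

#' Sensitivity and specificity from confusion counts
#'
#' @param counts list with `tp`, `fn`, `tn`, `fp`.
#' @return list with `sensitivity` and `specificity`.
#' @export
sensitivity_specificity <- function(counts) {
  if (counts$tp + counts$fn == 0L) {
    stop("undefined-metric error: no cases (tp + fn == 0)", call. = FALSE)
  }
  if (counts$tn + counts$fp == 0L) {
    stop("undefined-metric error: no controls (tn + fp == 0)", call. = FALSE)
  }
  list(sensitivity = counts$tp / (counts$tp + counts$fn),
       specificity = counts$tn / (counts$tn + counts$fp))
}

#' Fraction of a reference population flagged
#'
#' The reference population for the derived-PPV calculation defaults, in the
#' pipeline, to patients with at least one MM-coded claim (see
#' [mm_reference_population()]); the percentage flagged among them is the `f`
#' of the derived-PPV formula.
#'
#' @param flags data frame from [flag_population()].
#' @param reference_population character vector of patient ids.
#' @return proportion in `[0, 1]`.
#' @export
flagged_fraction <- function(flags, reference_population) {
  reference_population <- unique(as.character(reference_population))
  if (length(reference_population) == 0L) {
    stop("empty reference population", call. = FALSE)
  }
  fl <- flags[flags$patient_id %in% reference_population, , drop = FALSE]
  sum(fl$flagged) / length(reference_population)
}

#' Patients with at least one MM-coded claim
#'
#' @param bundle a [claims_bundle()].
#' @param config a [codeset_config()].
#' @return character vector of patient ids.
#' @export
mm_reference_population <- function(bundle, config) {
  mc <- bundle$medical_claims
  hit <- medical_claims_in_codeset(mc, config$codesets$mm_diagnosis, config)
  sort(unique(mc$patient_id[hit]))
}

check_ppv_inputs <- function(sensitivity, specificity, flagged_fraction) {
  if (sensitivity + specificity <= 1) {
    stop("inconsistent-inputs error: sensitivity + specificity <= 1",
         call. = FALSE)
  }
  if (flagged_fraction <= 0) {
    stop("inconsistent-inputs error: flagged_fraction <= 0", call. = FALSE)
  }
  if (flagged_fraction < 1 - specificity) {
    stop("inconsistent-inputs error: flagged_fraction < 1 - specificity ",
         "(negative implied prevalence)", call. = FALSE)
  }
  if (flagged_fraction > sensitivity) {
    stop("inconsistent-inputs error: flagged_fraction > sensitivity ",
         "(implied prevalence > 1)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Derived positive predictive value
#'
#' Computes PPV from sensitivity, specificity, and the flagged fraction `f`
#' via `PPV = (se * (f + sp - 1)) / (f * (se + sp - 1))`. This equals Bayes'
#' rule evaluated at the prevalence implied by `f` (see
#' [implied_prevalence()]) and lies in `[0, 1]` whenever the stated
#' preconditions hold.
#'
#' @param sensitivity,specificity proportions with
#'   `sensitivity + specificity > 1`.
#' @param flagged_fraction proportion in
#'   `[1 - specificity, sensitivity]`, strictly positive.
#' @return PPV in `[0, 1]`.
#' @examples
#' derived_ppv(0.8, 0.9, 0.45)  # 0.888...
#' @export
derived_ppv <- function(sensitivity, specificity, flagged_fraction) {
  check_ppv_inputs(sensitivity, specificity, flagged_fraction)
  (sensitivity * (flagged_fraction + specificity - 1)) /
    (flagged_fraction * (sensitivity + specificity - 1))
}

#' Prevalence implied by a flagged fraction
#'
#' Inverts `f = se * p + (1 - sp) * (1 - p)`:
#' `p = (f + sp - 1) / (se + sp - 1)`.
#'
#' @inheritParams derived_ppv
#' @return prevalence in `[0, 1]`.
#' @export
implied_prevalence <- function(sensitivity, specificity, flagged_fraction) {
  check_ppv_inputs(sensitivity, specificity, flagged_fraction)
  (flagged_fraction + specificity - 1) / (sensitivity + specificity - 1)
}

#' Full performance summary for one algorithm run
#'
#' @param flags data frame from [flag_population()].
#' @param labels gold-label data frame.
#' @param reference_population patient ids used for [flagged_fraction()];
#'   when `NULL` the derived PPV and implied prevalence are `NA`.
#' @return one-row data frame: `algorithm_id`, confusion counts,
#'   `sensitivity`, `specificity`, `flagged_fraction`, `derived_ppv`,
#'   `implied_prevalence` (the last two `NA` when the formula's
#'   preconditions fail).
#' @export
performance_metrics <- function(flags, labels, reference_population = NULL) {
  counts <- confusion_counts(flags, labels)
  ss <- sensitivity_specificity(counts)
  f <- if (is.null(reference_population)) NA_real_ else {
    flagged_fraction(flags, reference_population)
  }
  ppv <- prev <- NA_real_
  if (!is.na(f)) {
    ok <- tryCatch({ check_ppv_inputs(ss$sensitivity, ss$specificity, f); TRUE },
                   error = function(e) { warning(conditionMessage(e), call. = FALSE); FALSE })
    if (ok) {
      ppv <- derived_ppv(ss$sensitivity, ss$specificity, f)
      prev <- implied_prevalence(ss$sensitivity, ss$specificity, f)
    }
  }
  data.frame(algorithm_id = flags$algorithm_id[1L] %||% NA_character_,
             tp = counts$tp, fn = counts$fn, tn = counts$tn, fp = counts$fp,
             sensitivity = ss$sensitivity, specificity = ss$specificity,
             flagged_fraction = f, derived_ppv = ppv,
             implied_prevalence = prev, stringsAsFactors = FALSE)
}
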