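# Boolean clause-tree rule engine. A case-finding algorithm is an AND/OR
# tree over windowed predicates evaluated at an index diagnosis; a patient is
# flagged at the earliest panel-eligible index that satisfies the tree.

PREDICATE_KINDS <- c("mm_dx_count", "diagnostic_test_count",
                     "bone_marrow_count", "chemo_present")

#' Create a windowed predicate
#'
#' Predicate kinds:
#' * `mm_dx_count` — distinct MM-diagnosis service dates in the window
#'   (the index date itself counts when the window contains offset 0);
#' * `diagnostic_test_count` — claims from the union of the diagnostic-test
#'   code sets (per claim, not per distinct date);
#' * `bone_marrow_count` — bone-marrow aspirate/biopsy claims;
#' * `chemo_present` — chemotherapy claims (medical or pharmacy).
#'
#' `sequence_anchor = "before_earliest_qualifying_test"` restricts
#' `mm_dx_count` to dates strictly before the anchor date: the earliest test
#' date when at least two diagnostic-test claims fall in `anchor_window`,
#' otherwise the earliest bone-marrow date there; if neither route qualifies
#' the predicate is false.
#'
#' @param kind one of `r paste(PREDICATE_KINDS, collapse = ", ")`.
#' @param window integer length-2 vector of day offsets relative to the index
#'   (inclusive), e.g. `c(-90, 0)`.
#' @param threshold positive integer minimum count.
#' @param sequence_anchor optional, `"before_earliest_qualifying_test"`.
#' @param anchor_window window in which the anchoring tests are sought
#'   (default `c(-90, 0)`).
#' @return a `predicate` object.
#' @export
predicate <- function(kind, window, threshold = 1L, sequence_anchor = NULL,
                      anchor_window = c(-90L, 0L)) {
  kind <- match.arg(kind, PREDICATE_KINDS)
  window <- as.integer(window)
  if (length(window) != 2L || window[1L] > window[2L]) {
    stop("specification error: window must be (start, end) with start <= end",
         call. = FALSE)
  }
  threshold <- as.integer(threshold)
  if (is.na(threshold) || threshold < 1L) {
    stop("specification error: threshold must be >= 1", call. = FALSE)
  }
  if (!is.null(sequence_anchor) &&
      !identical(sequence_anchor, "before_earliest_qualifying_test")) {
    stop("specification error: unknown sequence_anchor", call. = FALSE)
  }
  structure(list(kind = kind, window = window, threshold = threshold,
                 sequence_anchor = sequence_anchor,
                 anchor_window = as.integer(anchor_window)),
            class = "predicate")
}

#' Clause-tree constructors
#'
#' `clause_all()` is a conjunction, `clause_any()` a disjunction; children
#' may be predicates or nested clauses. Empty clauses are rejected.
#'
#' @param ... predicates or clauses.
#' @return a `clause` object.
#' @export
clause_all <- function(...) make_clause("all", list(...))

#' @rdname clause_all
#' @export
clause_any <- function(...) make_clause("any", list(...))

make_clause <- function(op, children) {
  if (length(children) == 0L) {
    stop("specification error: empty ", op, " clause", call. = FALSE)
  }
  ok <- vapply(children, function(x) inherits(x, c("predicate", "clause")),
               logical(1))
  if (!all(ok)) {
    stop("specification error: clause children must be predicates or clauses",
         call. = FALSE)
  }
  structure(list(op = op, children = children), class = "clause")
}

#' Create an algorithm specification
#'
#' @param algorithm_id label used in outputs.
#' @param clause a [clause_all()]/[clause_any()] tree or a single
#'   [predicate()].
#' @return an `algorithm_spec` object.
#' @export
algorithm_spec <- function(algorithm_id, clause) {
  if (!inherits(clause, c("predicate", "clause"))) {
    stop("specification error: clause must be a predicate or clause tree",
         call. = FALSE)
  }
  structure(list(algorithm_id = as.character(algorithm_id), clause = clause),
            class = "algorithm_spec")
}

#' The baseline two-diagnosis algorithm
#'
#' Flags a patient at an index when at least two distinct MM-diagnosis
#' service dates (the index plus one additional) fall within 180 days on
#' either side of the index. Same-day duplicate claims never qualify because
#' counting is by distinct service date.
#'
#' @return an [algorithm_spec()].
#' @export
baseline_spec <- function() {
  algorithm_spec("baseline",
                 predicate("mm_dx_count", c(-180L, 180L), threshold = 2L))
}

#' The validated high-specificity algorithm ("Algorithm 2")
#'
#' Clauses, all relative to the index diagnosis:
#' * A — at least 1 additional MM diagnosis more than 30 days after the
#'   index (`[index+31, index+180]`);
#' * B — at least 2 diagnostic-test claims, or 1 bone-marrow test, during the
#'   90 days up to and including the index;
#' * C — at least 2 additional MM-diagnosis dates strictly before the
#'   earliest test date satisfying B (within `[index-180, index-1]`);
#' * D — chemotherapy during the 180 days following the index (inclusive of
#'   the index day).
#'
#' The published clause text is ambiguous about how the trailing
#' "or chemotherapy" binds; the default reading `(A & B & C) | D` treats
#' chemotherapy as a standalone disjunct (it was described as an "OR" used to
#' improve sensitivity, not a requirement). The alternatives
#' `"c_or_d"` = `A & B & (C | D)` and `"bc_or_d"` = `A & ((B & C) | D)` are
#' available for sensitivity analysis.
#'
#' @param precedence `"abc_or_d"` (default), `"c_or_d"`, or `"bc_or_d"`.
#' @return an [algorithm_spec()].
#' @export
algorithm2_spec <- function(precedence = c("abc_or_d", "c_or_d", "bc_or_d")) {
  precedence <- match.arg(precedence)
  A <- predicate("mm_dx_count", c(31L, 180L), threshold = 1L)
  B <- clause_any(
    predicate("diagnostic_test_count", c(-90L, 0L), threshold = 2L),
    predicate("bone_marrow_count", c(-90L, 0L), threshold = 1L))
  C <- predicate("mm_dx_count", c(-180L, -1L), threshold = 2L,
                 sequence_anchor = "before_earliest_qualifying_test",
                 anchor_window = c(-90L, 0L))
  D <- predicate("chemo_present", c(0L, 180L), threshold = 1L)
  clause <- switch(precedence,
    abc_or_d = clause_any(clause_all(A, B, C), D),
    c_or_d   = clause_all(A, B, clause_any(C, D)),
    bc_or_d  = clause_all(A, clause_any(clause_all(B, C), D)))
  algorithm_spec(paste0("algorithm2",
                        if (precedence != "abc_or_d") paste0("_", precedence)),
                 clause)
}

# Anchor date for sequence-anchored predicates: earliest diagnostic-test date
# in the anchor window when >= 2 test claims are present there, else the
# earliest bone-marrow date, else NA (predicate fails).
anchor_date_at_index <- function(pred, index_day, ev) {
  lo <- index_day + pred$anchor_window[1L]
  hi <- index_day + pred$anchor_window[2L]
  tests <- ev$test_dates[ev$test_dates >= lo & ev$test_dates <= hi]
  if (length(tests) >= 2L) return(min(tests))
  bm <- ev$bm_dates[ev$bm_dates >= lo & ev$bm_dates <= hi]
  if (length(bm) >= 1L) return(min(bm))
  NA_integer_
}

eval_predicate <- function(pred, index_day, ev) {
  lo <- index_day + pred$window[1L]
  hi <- index_day + pred$window[2L]
  dates <- switch(pred$kind,
    mm_dx_count = ev$mm_dx_dates,
    diagnostic_test_count = ev$test_dates,
    bone_marrow_count = ev$bm_dates,
    chemo_present = ev$chemo_dates)
  dates <- dates[dates >= lo & dates <= hi]
  if (!is.null(pred$sequence_anchor)) {
    anchor <- anchor_date_at_index(pred, index_day, ev)
    if (is.na(anchor)) return(FALSE)
    dates <- dates[dates < anchor]
  }
  length(dates) >= pred$threshold
}

eval_clause <- function(clause, index_day, ev) {
  if (inherits(clause, "predicate")) return(eval_predicate(clause, index_day, ev))
  if (!inherits(clause, "clause")) {
    stop("specification error: malformed clause tree", call. = FALSE)
  }
  vals <- vapply(clause$children, eval_clause, logical(1),
                 index_day = index_day, ev = ev)
  if (clause$op == "all") all(vals) else any(vals)
}

#' Evaluate an algorithm at one index diagnosis
#'
#' @param spec an [algorithm_spec()].
#' @param index_date the index diagnosis date (panel-eligible).
#' @param events per-patient event list from `precompute_events()`, or a
#'   bundle+patient pair via `...` convenience is not provided; use
#'   [flag_population()] for whole-population runs.
#' @return `TRUE`/`FALSE`.
#' @export
evaluate_at_index <- function(spec, index_date, events) {
  eval_clause(spec$clause, as.integer(as.Date(index_date)), events)
}

#' Flag one patient at the earliest qualifying index
#'
#' Scans the patient's panel rows in date order (claim-id tiebreak) and flags
#' at the first index satisfying the clause tree.
#'
#' @param spec an [algorithm_spec()].
#' @param panel this patient's rows of [build_panel()] output.
#' @param events this patient's event list.
#' @return list with `flagged`, `flag_date` (NA when unflagged), and
#'   `qualifying_claim_id`.
#' @export
flag_patient <- function(spec, panel, events) {
  if (nrow(panel) > 0L) {
    o <- order(panel$index_date, panel$claim_id)
    for (i in o) {
      if (evaluate_at_index(spec, panel$index_date[i], events)) {
        return(list(flagged = TRUE, flag_date = panel$index_date[i],
                    qualifying_claim_id = panel$claim_id[i]))
      }
    }
  }
  list(flagged = FALSE, flag_date = as.Date(NA), qualifying_claim_id = NA_character_)
}

#' Flag every patient in a bundle
#'
#' Builds the index panel (unless supplied), precomputes event indexes, and
#' applies [flag_patient()] to every person. Patients without eligible
#' indexes are reported unflagged.
#'
#' @param spec an [algorithm_spec()].
#' @param bundle a [claims_bundle()].
#' @param config a [codeset_config()].
#' @param panel optional precomputed [build_panel()] output.
#' @param events optional precomputed `precompute_events()` output.
#' @param params see [panel_params()].
#' @return data frame: `patient_id`, `algorithm_id`, `flagged`, `flag_date`.
#' @export
flag_population <- function(spec, bundle, config, panel = NULL, events = NULL,
                            params = panel_params()) {
  if (is.null(panel)) panel <- build_panel(bundle, config, params)
  if (is.null(events)) events <- precompute_events(bundle, config)
  ids <- bundle$persons$patient_id
  flagged <- rep(FALSE, length(ids))
  flag_date <- as.Date(rep(NA_character_, length(ids)))
  panel_split <- split(panel, panel$patient_id)
  for (k in seq_along(ids)) {
    pp <- panel_split[[ids[k]]]
    if (is.null(pp)) next
    res <- flag_patient(spec, pp, events[[ids[k]]])
    flagged[k] <- res$flagged
    flag_date[k] <- res$flag_date
  }
  data.frame(patient_id = ids, algorithm_id = spec$algorithm_id,
             flagged = flagged, flag_date = flag_date,
             stringsAsFactors = FALSE)
}

clause_to_list <- function(x) {
  if (inherits(x, "predicate")) {
    out <- list(kind = x$kind, window = as.integer(x$window),
                threshold = x$threshold)
    if (!is.null(x$sequence_anchor)) {
      out$sequence_anchor <- x$sequence_anchor
      out$anchor_window <- as.integer(x$anchor_window)
    }
    return(out)
  }
  setNames(list(lapply(x$children, clause_to_list)), x$op)
}

clause_from_list <- function(x) {
  if (!is.null(x$kind)) {
    return(predicate(x$kind, x$window, x$threshold %||% 1L,
                     sequence_anchor = x$sequence_anchor %||% NULL,
                     anchor_window = x$anchor_window %||% c(-90L, 0L)))
  }
  op <- intersect(names(x), c("all", "any"))
  if (length(op) != 1L) {
    stop("specification error: clause node must be 'all' or 'any'",
         call. = FALSE)
  }
  make_clause(op, lapply(x[[op]], clause_from_list))
}

#' Read / write algorithm specifications
#'
#' YAML serialization: `algorithm_id` plus a `clause` tree of nested
#' `all:`/`any:` lists whose leaves are predicate objects.
#'
#' @param path file path.
#' @return [read_algorithm_spec()] returns an [algorithm_spec()];
#'   [write_algorithm_spec()] returns `path`, invisibly.
#' @export
read_algorithm_spec <- function(path) {
  x <- yaml::read_yaml(path)
  algorithm_spec(x$algorithm_id, clause_from_list(x$clause))
}

#' @rdname read_algorithm_spec
#' @param spec an [algorithm_spec()].
#' @export
write_algorithm_spec <- function(spec, path) {
  yaml::write_yaml(list(algorithm_id = spec$algorithm_id,
                        clause = clause_to_list(spec$clause)), path)
  invisible(path)
}

#' Resolve a built-in algorithm by name
#'
#' @param name `"baseline"`, `"algorithm2"`, `"algorithm2_c_or_d"`,
#'   `"algorithm2_bc_or_d"`, or a path to a YAML spec file.
#' @return an [algorithm_spec()].
#' @export
resolve_algorithm <- function(name) {
  switch(name,
    baseline = baseline_spec(),
    algorithm2 = algorithm2_spec(),
    algorithm2_c_or_d = algorithm2_spec("c_or_d"),
    algorithm2_bc_or_d = algorithm2_spec("bc_or_d"),
    {
      if (file.exists(name)) return(read_algorithm_spec(name))
      stop("unknown algorithm '", name, "'", call. = FALSE)
    })
}
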