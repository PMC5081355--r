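# Longitudinal claims data model and the delimited-table interchange format
# shared by every other module. A bundle holds six tables keyed by
# patient_id; all dates are whole calendar days (R Date), diagnosis codes are
# stored in dotless upper-case canonical form, and rows are kept in a
# deterministic canonical order so that write -> read round-trips exactly.

BUNDLE_TABLES <- c("persons", "enrollment", "medical_claims", "drug_claims",
                   "emr_oncology", "emr_notes")

BUNDLE_COLUMNS <- list(
  persons        = c("patient_id", "birth_year", "sex"),
  enrollment     = c("patient_id", "start_date", "end_date"),
  medical_claims = c("claim_id", "patient_id", "service_date",
                     "dx1", "dx2", "dx3", "dx4", "proc_code", "proc_system"),
  drug_claims    = c("claim_id", "patient_id", "fill_date", "ndc", "days_supply"),
  emr_oncology   = c("patient_id", "emr_dx_date", "visit_date", "diagnosis_label"),
  emr_notes      = c("patient_id", "note_date", "note_text")
)

DX_SLOTS <- c("dx1", "dx2", "dx3", "dx4")
PROC_SYSTEMS <- c("CPT4", "HCPCS", "ICD9PROC")

#' Canonicalize clinical codes
#'
#' Claims extracts ubiquitously drop the dot from ICD-9-CM codes; the
#' canonical form used throughout the package is dotless and upper-case.
#' Canonicalization is idempotent.
#'
#' @param x character vector of codes (NA and empty strings pass through).
#' @return character vector of canonical codes.
#' @examples
#' canonicalize_code("203.00")  # "20300"
#' @export
canonicalize_code <- function(x) {
  x <- as.character(x)
  out <- toupper(gsub(".", "", x, fixed = TRUE))
  out[is.na(x)] <- NA_character_
  out
}

empty_bundle_table <- function(table) {
  cols <- BUNDLE_COLUMNS[[table]]
  out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                       stringsAsFactors = FALSE)
  date_cols <- intersect(cols, c("start_date", "end_date", "service_date",
                                 "fill_date", "emr_dx_date", "visit_date",
                                 "note_date"))
  for (col in date_cols) out[[col]] <- as.Date(character(0))
  if ("birth_year" %in% cols) out$birth_year <- integer(0)
  if ("days_supply" %in% cols) out$days_supply <- integer(0)
  out
}

canonical_table_order <- function(table, df) {
  key <- switch(table,
    persons        = list(df$patient_id),
    enrollment     = list(df$patient_id, df$start_date, df$end_date),
    medical_claims = list(df$patient_id, df$service_date, df$claim_id, df$dx1),
    drug_claims    = list(df$patient_id, df$fill_date, df$claim_id),
    emr_oncology   = list(df$patient_id, df$emr_dx_date, df$visit_date),
    emr_notes      = list(df$patient_id, df$note_date, df$note_text))
  do.call(order, key)
}

#' Construct a validated claims bundle
#'
#' A `claims_bundle` is the in-memory container for one linked extract:
#' persons, enrollment spans, medical claims (ICD-9-CM diagnoses in up to
#' four slots plus an optional CPT-4/HCPCS/ICD-9 procedure), pharmacy claims
#' (NDC), oncology-EMR diagnosis records, and primary-care free-text notes.
#' Diagnosis, procedure and NDC codes are canonicalized on construction and
#' rows are sorted into canonical order. Claims with more than four diagnosis
#' codes are represented as multiple rows sharing a `claim_id`.
#'
#' @param persons data frame with `patient_id`, `birth_year`, `sex`.
#' @param enrollment data frame with `patient_id`, `start_date`, `end_date`
#'   (both inclusive).
#' @param medical_claims data frame with `claim_id`, `patient_id`,
#'   `service_date`, `dx1`..`dx4`, `proc_code`, `proc_system`.
#' @param drug_claims data frame with `claim_id`, `patient_id`, `fill_date`,
#'   `ndc`, `days_supply`.
#' @param emr_oncology data frame with `patient_id`, `emr_dx_date`,
#'   `visit_date`, `diagnosis_label`.
#' @param emr_notes data frame with `patient_id`, `note_date`, `note_text`.
#' @return an object of class `claims_bundle` (a named list of the six
#'   tables).
#' @export
claims_bundle <- function(persons = NULL, enrollment = NULL,
                          medical_claims = NULL, drug_claims = NULL,
                          emr_oncology = NULL, emr_notes = NULL) {
  tables <- list(persons = persons, enrollment = enrollment,
                 medical_claims = medical_claims, drug_claims = drug_claims,
                 emr_oncology = emr_oncology, emr_notes = emr_notes)
  for (nm in BUNDLE_TABLES) {
    df <- tables[[nm]]
    if (is.null(df)) df <- empty_bundle_table(nm)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    missing <- setdiff(BUNDLE_COLUMNS[[nm]], names(df))
    if (length(missing)) {
      stop(sprintf("schema error: table '%s' is missing column '%s'",
                   nm, missing[1L]), call. = FALSE)
    }
    df <- df[, BUNDLE_COLUMNS[[nm]], drop = FALSE]
    tables[[nm]] <- df
  }

  tables$persons$patient_id <- as.character(tables$persons$patient_id)
  tables$persons$birth_year <- as.integer(tables$persons$birth_year)
  tables$persons$sex <- as.character(tables$persons$sex)

  for (nm in setdiff(BUNDLE_TABLES, "persons")) {
    tables[[nm]]$patient_id <- as.character(tables[[nm]]$patient_id)
  }
  for (nm in c("medical_claims", "drug_claims")) {
    tables[[nm]]$claim_id <- as.character(tables[[nm]]$claim_id)
  }

  mc <- tables$medical_claims
  mc$service_date <- as.Date(mc$service_date)
  for (slot in DX_SLOTS) {
    v <- canonicalize_code(mc[[slot]])
    v[is.na(v)] <- ""
    mc[[slot]] <- v
  }
  pc <- canonicalize_code(mc$proc_code); pc[is.na(pc)] <- ""
  mc$proc_code <- pc
  ps <- toupper(as.character(mc$proc_system)); ps[is.na(ps)] <- ""
  mc$proc_system <- ps
  tables$medical_claims <- mc

  dc <- tables$drug_claims
  dc$fill_date <- as.Date(dc$fill_date)
  dc$ndc <- canonicalize_code(dc$ndc)
  dc$days_supply <- as.integer(dc$days_supply)
  tables$drug_claims <- dc

  en <- tables$enrollment
  en$start_date <- as.Date(en$start_date)
  en$end_date <- as.Date(en$end_date)
  tables$enrollment <- en

  eo <- tables$emr_oncology
  eo$emr_dx_date <- as.Date(eo$emr_dx_date)
  eo$visit_date <- as.Date(eo$visit_date)
  eo$diagnosis_label <- as.character(eo$diagnosis_label)
  tables$emr_oncology <- eo

  nt <- tables$emr_notes
  nt$note_date <- as.Date(nt$note_date)
  nt$note_text <- as.character(nt$note_text)
  tables$emr_notes <- nt

  for (nm in BUNDLE_TABLES) {
    df <- tables[[nm]]
    df <- df[canonical_table_order(nm, df), , drop = FALSE]
    rownames(df) <- NULL
    tables[[nm]] <- df
  }

  bundle <- structure(tables, class = "claims_bundle")
  validate_bundle(bundle)
  bundle
}

#' Validate a claims bundle
#'
#' Checks the structural invariants: referential integrity of `patient_id`
#' against `persons`, enrollment `start_date <= end_date`, `days_supply >= 1`,
#' plausible `birth_year`, and that a medical claim row carries either at
#' least one diagnosis code or a procedure code.
#'
#' @param bundle a `claims_bundle`.
#' @return the bundle, invisibly; errors describe the first violation.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "claims_bundle"))
  ids <- bundle$persons$patient_id
  if (anyDuplicated(ids)) {
    stop("persons: duplicated patient_id '",
         ids[duplicated(ids)][1L], "'", call. = FALSE)
  }
  for (nm in setdiff(BUNDLE_TABLES, "persons")) {
    orphan <- setdiff(bundle[[nm]]$patient_id, ids)
    if (length(orphan)) {
      stop(sprintf(
        "referential-integrity error: table '%s' references patient_id '%s' absent from persons",
        nm, orphan[1L]), call. = FALSE)
    }
  }
  by <- bundle$persons$birth_year
  this_year <- as.integer(format(Sys.Date(), "%Y"))
  if (length(by) && any(!is.na(by) & (by < 1880L | by > this_year))) {
    stop("persons: implausible birth_year (must be 1880..current year)",
         call. = FALSE)
  }
  en <- bundle$enrollment
  if (nrow(en) && any(en$start_date > en$end_date)) {
    stop("enrollment: start_date > end_date", call. = FALSE)
  }
  mc <- bundle$medical_claims
  if (nrow(mc)) {
    has_dx <- Reduce(`|`, lapply(DX_SLOTS, function(s) nzchar(mc[[s]])))
    if (any(!has_dx & !nzchar(mc$proc_code))) {
      stop("medical_claims: row with neither diagnosis nor procedure code",
           call. = FALSE)
    }
    bad_sys <- nzchar(mc$proc_code) & !(mc$proc_system %in% PROC_SYSTEMS)
    if (any(bad_sys)) {
      stop("medical_claims: proc_system must be one of ",
           paste(PROC_SYSTEMS, collapse = ", "), call. = FALSE)
    }
  }
  dcl <- bundle$drug_claims
  if (nrow(dcl) && any(is.na(dcl$days_supply) | dcl$days_supply < 1L)) {
    stop("drug_claims: days_supply must be >= 1", call. = FALSE)
  }
  invisible(bundle)
}

read_bundle_table <- function(directory_path, table) {
  path <- file.path(directory_path, paste0(table, ".csv"))
  if (!file.exists(path)) {
    stop(sprintf("schema error: expected table file '%s.csv' in '%s'",
                 table, directory_path), call. = FALSE)
  }
  df <- read.csv(path, colClasses = "character", na.strings = character(0),
                 check.names = FALSE)
  missing <- setdiff(BUNDLE_COLUMNS[[table]], names(df))
  if (length(missing)) {
    stop(sprintf("schema error: table '%s' is missing column '%s'",
                 table, missing[1L]), call. = FALSE)
  }
  date_cols <- intersect(BUNDLE_COLUMNS[[table]],
                         c("start_date", "end_date", "service_date",
                           "fill_date", "emr_dx_date", "note_date"))
  for (col in date_cols) df[[col]] <- parse_iso_dates(df[[col]], table, col)
  if (table == "emr_oncology") {
    df$visit_date <- parse_iso_dates(df$visit_date, table, "visit_date",
                                     allow_na = TRUE)
  }
  df
}

#' Read a claims bundle from a directory of delimited tables
#'
#' Reads the six-table interchange layout (`persons.csv`, `enrollment.csv`,
#' `medical_claims.csv`, `drug_claims.csv`, `emr_oncology.csv`,
#' `emr_notes.csv`; comma-delimited UTF-8, header row, ISO-8601 dates),
#' canonicalizes codes, sorts rows canonically and validates the result.
#'
#' @param directory_path directory containing the table files.
#' @return a validated [claims_bundle()].
#' @export
read_bundle <- function(directory_path) {
  tables <- lapply(setNames(BUNDLE_TABLES, BUNDLE_TABLES),
                   function(t) read_bundle_table(directory_path, t))
  do.call(claims_bundle, tables)
}

#' Write a claims bundle to a directory of delimited tables
#'
#' Emits exactly the layout [read_bundle()] consumes; `read_bundle(
#' write_bundle(b))` reproduces `b` field for field.
#'
#' @param bundle a validated `claims_bundle`.
#' @param directory_path output directory (created if absent).
#' @return `directory_path`, invisibly.
#' @export
write_bundle <- function(bundle, directory_path) {
  validate_bundle(bundle)
  if (!dir.exists(directory_path)) {
    ok <- dir.create(directory_path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory '", directory_path, "'", call. = FALSE)
  }
  for (nm in BUNDLE_TABLES) {
    df <- bundle[[nm]]
    out <- df
    for (col in names(out)) {
      if (inherits(out[[col]], "Date")) out[[col]] <- format(out[[col]], "%Y-%m-%d")
    }
    write.csv(out, file.path(directory_path, paste0(nm, ".csv")),
              row.names = FALSE, na = "")
  }
  invisible(directory_path)
}

#' Merge enrollment spans for one patient
#'
#' Returns the minimal set of non-overlapping spans. Two spans merge when
#' they overlap or abut within `gap_days` (default 0: the second span must
#' start exactly one day after the first ends). Both endpoints are inclusive.
#'
#' @param spans data frame with `start_date`, `end_date` (and optionally
#'   `patient_id`, which must be constant).
#' @param gap_days non-negative integer gap tolerance in days.
#' @return data frame of merged spans sorted by `start_date`.
#' @examples
#' merge_enrollment(data.frame(start_date = as.Date(c("2012-01-01", "2012-06-01")),
#'                             end_date   = as.Date(c("2012-05-31", "2012-12-31"))))
#' @export
merge_enrollment <- function(spans, gap_days = 0L) {
  if (gap_days < 0L) stop("gap_days must be >= 0", call. = FALSE)
  spans <- as.data.frame(spans, stringsAsFactors = FALSE)
  if ("patient_id" %in% names(spans) &&
      length(unique(spans$patient_id)) > 1L) {
    stop("merge_enrollment expects spans for a single patient", call. = FALSE)
  }
  s <- as.Date(spans$start_date); e <- as.Date(spans$end_date)
  if (any(s > e)) stop("enrollment span with start_date > end_date", call. = FALSE)
  if (length(s) <= 1L) {
    out <- data.frame(start_date = s, end_date = e)
    return(out[order(out$start_date), , drop = FALSE])
  }
  o <- order(s, e)
  s <- as.integer(s[o]); e <- as.integer(e[o])
  ms <- s[1L]; me <- e[1L]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(s)[-1L]) {
    if (s[i] <= me + 1L + gap_days) {
      me <- max(me, e[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- s[i]; me <- e[i]
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  data.frame(start_date = as.Date(out_s, origin = "1970-01-01"),
             end_date = as.Date(out_e, origin = "1970-01-01"))
}

# Merged spans for every patient: named list patient_id -> merged span df.
merged_spans_by_patient <- function(enrollment, gap_days = 0L) {
  if (nrow(enrollment) == 0L) return(list())
  lapply(split(enrollment[, c("start_date", "end_date")],
               enrollment$patient_id),
         merge_enrollment, gap_days = gap_days)
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n")
  for (nm in BUNDLE_TABLES) {
    cat(sprintf("  %-15s %6d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}
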