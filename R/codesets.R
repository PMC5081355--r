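# Configurable clinical code sets. A code pattern is a fixed prefix plus an
# optional trailing run of 'x' wildcards ("203.0x"); matching is on canonical
# (dotless, upper-case) codes. A code set is a named list of patterns which
# may mix coding systems (e.g. chemotherapy spans CPT-4 administration codes,
# HCPCS J-codes and NDCs).

CODE_SYSTEMS <- c("ICD9DX", "CPT4", "HCPCS", "NDC", "ICD9PROC")

#' Create a code pattern
#'
#' Patterns are written the way ICD-9-CM families are quoted in the clinical
#' literature: a prefix with an optional dot and a trailing run of `x`
#' wildcards, e.g. `"203.0x"` for the multiple myeloma family. Wildcards may
#' only appear as a trailing run.
#'
#' @param system coding system, one of `ICD9DX`, `CPT4`, `HCPCS`, `NDC`,
#'   `ICD9PROC`.
#' @param pattern pattern string; dot optional; trailing `x`/`X` characters
#'   are wildcards.
#' @return a `code_pattern` object.
#' @export
code_pattern <- function(system, pattern) {
  system <- toupper(as.character(system))
  if (!system %in% CODE_SYSTEMS) {
    stop("configuration error: unknown code system '", system, "'",
         call. = FALSE)
  }
  raw <- gsub(".", "", as.character(pattern), fixed = TRUE)
  if (!nzchar(raw)) {
    stop("configuration error: empty code pattern", call. = FALSE)
  }
  chars <- strsplit(raw, "")[[1L]]
  is_wild <- chars %in% c("x", "X")
  n_wild <- 0L
  while (n_wild < length(chars) && is_wild[length(chars) - n_wild]) {
    n_wild <- n_wild + 1L
  }
  if (any(is_wild[seq_len(length(chars) - n_wild)])) {
    stop("configuration error: wildcard 'x' must be a trailing run in pattern '",
         pattern, "'", call. = FALSE)
  }
  prefix <- toupper(substr(raw, 1L, length(chars) - n_wild))
  if (!nzchar(prefix)) {
    stop("configuration error: pattern '", pattern,
         "' has no fixed prefix", call. = FALSE)
  }
  structure(list(system = system, pattern = as.character(pattern),
                 prefix = prefix, n_wild = n_wild),
            class = "code_pattern")
}

#' Match canonical codes against a code pattern
#'
#' Two wildcard dialects are supported. The default, `"zero_or_more"`, treats
#' the trailing wildcard run as matching zero or more additional characters,
#' so `"203.0x"` matches both the 4-digit `"2030"` and the 5-digit
#' `"20300"`–`"20309"` (ICD-9-CM families appear at mixed specificity in real
#' extracts). `"per_char"` requires exactly one character per wildcard. A
#' wildcard-free pattern matches only by exact string equality in either
#' dialect.
#'
#' @param pattern a [code_pattern()] (or a pattern string, interpreted with
#'   `system = "ICD9DX"`).
#' @param code character vector of canonical (dotless, upper-case) codes.
#' @param mode wildcard dialect, `"zero_or_more"` (default) or `"per_char"`.
#' @return logical vector, one element per code.
#' @examples
#' pattern_matches("203.0x", c("20300", "20310", "2030"))
#' @export
pattern_matches <- function(pattern, code, mode = c("zero_or_more", "per_char")) {
  mode <- match.arg(mode)
  if (!inherits(pattern, "code_pattern")) pattern <- code_pattern("ICD9DX", pattern)
  code <- as.character(code)
  out <- !is.na(code) & nzchar(code)
  if (pattern$n_wild == 0L) {
    return(out & code == pattern$prefix)
  }
  hit <- out & startsWith(code, pattern$prefix)
  if (mode == "per_char") {
    hit <- hit & nchar(code) == nchar(pattern$prefix) + pattern$n_wild
  }
  hit
}

#' Create a named code set
#'
#' @param name label, e.g. `"mm_diagnosis"` or `"bone_marrow"`.
#' @param patterns list of [code_pattern()] objects (or character vector of
#'   pattern strings, requiring `system`).
#' @param system default coding system applied to plain-string patterns.
#' @return a `codeset` object.
#' @export
codeset <- function(name, patterns, system = NULL) {
  patterns <- lapply(patterns, function(p) {
    if (inherits(p, "code_pattern")) return(p)
    if (is.list(p) && !is.null(p$pattern)) {
      return(code_pattern(p$system %||% system, p$pattern))
    }
    p <- as.character(p)
    # "SYSTEM:pattern" strings allow mixed-system sets in flat configs
    if (grepl(":", p, fixed = TRUE)) {
      parts <- strsplit(p, ":", fixed = TRUE)[[1L]]
      return(code_pattern(parts[1L], parts[2L]))
    }
    if (is.null(system)) {
      stop("configuration error: pattern '", p, "' in codeset '", name,
           "' has no coding system", call. = FALSE)
    }
    code_pattern(system, p)
  })
  structure(list(name = as.character(name), patterns = patterns),
            class = "codeset")
}

#' Assemble a code-set configuration
#'
#' A configuration is a named collection of code sets plus the group
#' structure the rule engine and descriptives rely on: which sets are the
#' diagnostic tests, which are treatments, and which are symptoms. The
#' `mm_diagnosis` set is mandatory.
#'
#' @param codesets named list of [codeset()] objects.
#' @param diagnostic_tests character vector of code-set names forming the
#'   diagnostic-test group (the union used by test-count predicates).
#' @param treatments,symptoms character vectors of code-set names.
#' @param wildcard_mode wildcard dialect passed to [pattern_matches()].
#' @param dx_match `"any_slot"` (default) to match diagnosis patterns on any
#'   of the four diagnosis slots, or `"primary_only"` to restrict to `dx1`.
#' @return a `codeset_config` object.
#' @export
codeset_config <- function(codesets, diagnostic_tests = character(0),
                           treatments = character(0), symptoms = character(0),
                           wildcard_mode = "zero_or_more",
                           dx_match = c("any_slot", "primary_only")) {
  dx_match <- match.arg(dx_match)
  names(codesets) <- vapply(codesets, function(cs) cs$name, character(1))
  if (anyDuplicated(names(codesets))) {
    stop("configuration error: duplicated codeset names", call. = FALSE)
  }
  if (!"mm_diagnosis" %in% names(codesets)) {
    stop("configuration error: configuration must define 'mm_diagnosis'",
         call. = FALSE)
  }
  for (grp in list(diagnostic_tests, treatments, symptoms)) {
    unknown <- setdiff(grp, names(codesets))
    if (length(unknown)) {
      stop("configuration error: group references unknown codeset '",
           unknown[1L], "'", call. = FALSE)
    }
  }
  structure(list(codesets = codesets,
                 diagnostic_tests = diagnostic_tests,
                 treatments = treatments,
                 symptoms = symptoms,
                 wildcard_mode = wildcard_mode,
                 dx_match = dx_match),
            class = "codeset_config")
}

#' Does a claim match a code set?
#'
#' A medical claim matches when any diagnosis slot matches an `ICD9DX`
#' pattern (primary *or* secondary position by default) or its procedure code
#' matches a procedure-system pattern of the same system. A drug claim
#' matches on its NDC.
#'
#' @param claim one-row data frame (a `medical_claims` or `drug_claims` row).
#' @param cs a [codeset()].
#' @param config optional [codeset_config()] supplying `wildcard_mode` and
#'   `dx_match`.
#' @return `TRUE` or `FALSE`.
#' @export
claim_in_codeset <- function(claim, cs, config = NULL) {
  claim <- as.data.frame(claim, stringsAsFactors = FALSE)
  if ("ndc" %in% names(claim)) {
    return(as.logical(drug_claims_in_codeset(claim, cs, config)))
  }
  as.logical(medical_claims_in_codeset(claim, cs, config))
}

# Vectorized membership of medical-claim rows in a codeset.
medical_claims_in_codeset <- function(mc, cs, config = NULL) {
  mode <- config$wildcard_mode %||% "zero_or_more"
  dx_cols <- if (identical(config$dx_match %||% "any_slot", "primary_only")) {
    "dx1"
  } else DX_SLOTS
  hit <- rep(FALSE, nrow(mc))
  for (p in cs$patterns) {
    if (p$system == "ICD9DX") {
      for (col in dx_cols) hit <- hit | pattern_matches(p, mc[[col]], mode)
    } else if (p$system %in% PROC_SYSTEMS) {
      hit <- hit | (mc$proc_system == p$system &
                      pattern_matches(p, mc$proc_code, mode))
    }
  }
  hit
}

# Vectorized membership of drug-claim rows in a codeset (NDC patterns only).
drug_claims_in_codeset <- function(dc, cs, config = NULL) {
  mode <- config$wildcard_mode %||% "zero_or_more"
  hit <- rep(FALSE, nrow(dc))
  for (p in cs$patterns) {
    if (p$system == "NDC") hit <- hit | pattern_matches(p, dc$ndc, mode)
  }
  hit
}

codesets_to_list <- function(config) {
  sets <- lapply(config$codesets, function(cs) {
    list(patterns = vapply(cs$patterns,
                           function(p) paste0(p$system, ":", p$pattern),
                           character(1)))
  })
  list(codesets = sets,
       groups = list(diagnostic_tests = config$diagnostic_tests,
                     treatments = config$treatments,
                     symptoms = config$symptoms),
       options = list(wildcard_mode = config$wildcard_mode,
                      dx_match = config$dx_match))
}

config_from_list <- function(x) {
  sets <- lapply(names(x$codesets), function(nm) {
    spec <- x$codesets[[nm]]
    codeset(nm, as.list(spec$patterns), system = spec$system %||% NULL)
  })
  names(sets) <- names(x$codesets)
  codeset_config(sets,
                 diagnostic_tests = as.character(x$groups$diagnostic_tests %||% character(0)),
                 treatments = as.character(x$groups$treatments %||% character(0)),
                 symptoms = as.character(x$groups$symptoms %||% character(0)),
                 wildcard_mode = x$options$wildcard_mode %||% "zero_or_more",
                 dx_match = x$options$dx_match %||% "any_slot")
}

#' Load / save a code-set configuration
#'
#' The on-disk format is YAML: a `codesets` map of name to
#' `{system, patterns}` (patterns may also be written as `SYSTEM:pattern`
#' strings for mixed-system sets), a `groups` map naming the diagnostic-test,
#' treatment and symptom sets, and an `options` map.
#'
#' @param path file path.
#' @return [load_codesets()] returns a [codeset_config()];
#'   [write_codesets()] returns `path`, invisibly.
#' @export
load_codesets <- function(path) {
  if (!file.exists(path)) {
    stop("configuration error: codesets file '", path, "' not found",
         call. = FALSE)
  }
  config_from_list(yaml::read_yaml(path))
}

#' @rdname load_codesets
#' @param config a [codeset_config()].
#' @export
write_codesets <- function(config, path) {
  yaml::write_yaml(codesets_to_list(config), path)
  invisible(path)
}

#' Default code-set configuration
#'
#' The multiple myeloma diagnosis family is the published ICD-9-CM 203.0x.
#' Every other set (chemotherapy, stem cell transplant, the eight diagnostic
#' tests, treatments, symptoms) ships as a clearly labeled PLACEHOLDER list
#' of plausible codes: the study-grade lists are proprietary and users are
#' expected to supply their own via [load_codesets()]. The synthetic-data
#' generator emits codes drawn from these placeholders, so the shipped
#' pipeline is self-consistent.
#'
#' @return a [codeset_config()].
#' @export
default_codesets <- function() {
  cs <- function(name, system, patterns) codeset(name, as.list(patterns), system)
  sets <- list(
    # Published: ICD-9-CM multiple myeloma family.
    cs("mm_diagnosis", "ICD9DX", "203.0x"),
    # PLACEHOLDER lists below; replace with study-grade code lists.
    codeset("chemotherapy", list("CPT4:964xx", "CPT4:965xx", "HCPCS:J9xxx")),
    cs("stem_cell_transplant", "CPT4", c("38240", "38241")),
    cs("protein_electrophoresis", "CPT4", c("84165", "84166", "86334", "86335")),
    cs("quantitative_immunoglobulin", "CPT4", c("82784", "82787")),
    cs("serum_free_light_chain", "CPT4", "83883"),
    cs("serum_albumin", "CPT4", "82040"),
    cs("beta2_microglobulin", "CPT4", "82232"),
    cs("bone_marrow", "CPT4", c("38220", "38221", "85097")),
    cs("skeletal_survey", "CPT4", c("77074", "77075")),
    cs("ldh", "CPT4", "83615"),
    cs("corticosteroid", "NDC", "00054xxxxxx"),
    codeset("bisphosphonate", list("NDC:00069xxxxxx", "HCPCS:J3487")),
    codeset("anemia_treatment", list("HCPCS:J0885", "HCPCS:J0881", "CPT4:36430")),
    cs("monoclonal_gammopathy", "ICD9DX", "273.1"),
    cs("other_malignancy", "ICD9DX", c("174.9", "185", "202.8x")),
    cs("anemia_dx", "ICD9DX", c("285.x", "280.0")),
    cs("osteoporosis_dx", "ICD9DX", "733.0x"),
    cs("skeletal_related_event", "ICD9DX", c("733.1x", "198.5")),
    cs("bone_pain_lesions", "ICD9DX", c("733.90", "719.4x")),
    cs("fatigue", "ICD9DX", "780.79"),
    cs("shortness_of_breath", "ICD9DX", "786.05"),
    cs("chest_pain", "ICD9DX", "786.5x"),
    cs("peripheral_neuropathy", "ICD9DX", "356.x"),
    cs("renal_failure", "ICD9DX", c("584.x", "585.x", "586")),
    cs("hypercalcemia", "ICD9DX", "275.42"),
    cs("pneumonia", "ICD9DX", c("486", "481")),
    cs("herpes_zoster", "ICD9DX", "053.x"),
    cs("uti_kidney_infection", "ICD9DX", c("599.0", "590.x"))
  )
  codeset_config(
    sets,
    diagnostic_tests = c("protein_electrophoresis", "quantitative_immunoglobulin",
                         "serum_free_light_chain", "serum_albumin",
                         "beta2_microglobulin", "bone_marrow",
                         "skeletal_survey", "ldh"),
    treatments = c("corticosteroid", "bisphosphonate", "anemia_treatment"),
    symptoms = c("monoclonal_gammopathy", "other_malignancy", "anemia_dx",
                 "osteoporosis_dx", "skeletal_related_event",
                 "bone_pain_lesions", "fatigue", "shortness_of_breath",
                 "chest_pain", "peripheral_neuropathy", "renal_failure",
                 "hypercalcemia", "pneumonia", "herpes_zoster",
                 "uti_kidney_infection")
  )
}

# A concrete code instantiating a pattern (wildcards filled with '0'),
# used by the synthetic-data generator.
concrete_code <- function(pattern) {
  paste0(pattern$prefix, strrep("0", pattern$n_wild))
}
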