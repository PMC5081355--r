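# Fixtures are built in code. A medium synthetic population is cached per
# test session because several files exercise it.

.fixture_env <- new.env(parent = emptyenv())

shared_codesets <- function() {
  if (is.null(.fixture_env$cs)) .fixture_env$cs <- default_codesets()
  .fixture_env$cs
}

medium_population <- function() {
  if (is.null(.fixture_env$pop)) {
    gc <- default_config_from_tables()
    gc$n <- c(control = 120L, incident_untreated = 20L,
              prevalent_untreated = 10L, incident_treated = 30L,
              prevalent_treated = 15L)
    .fixture_env$pop <- generate_population(gc, seed = 42L,
                                            codesets = shared_codesets())
  }
  .fixture_env$pop
}

# One-patient bundle with events at fixed day offsets from an index date.
# mm/test/chemo/sct are vectors of day offsets.
timeline_bundle <- function(mm = integer(0), test = integer(0),
                            chemo = integer(0), sct = integer(0),
                            index_date = as.Date("2010-07-01"),
                            enroll_from = as.Date("2009-01-01"),
                            enroll_to = as.Date("2011-12-31")) {
  ib <- as.integer(index_date)
  rows <- list(); n <- 0L
  add <- function(off, dx1 = "", proc = "", sys = "") {
    for (o in off) {
      n <<- n + 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        claim_id = sprintf("T%04d", n), patient_id = "PT1",
        service_date = as.Date(ib + o, origin = "1970-01-01"),
        dx1 = dx1, dx2 = "", dx3 = "", dx4 = "",
        proc_code = proc, proc_system = sys, stringsAsFactors = FALSE)
    }
  }
  add(mm, dx1 = "20300")
  add(test, proc = "84165", sys = "CPT4")
  add(chemo, dx1 = "V5811", proc = "96400", sys = "CPT4")
  add(sct, proc = "38241", sys = "CPT4")
  claims_bundle(
    persons = data.frame(patient_id = "PT1", birth_year = 1950L, sex = "F"),
    enrollment = data.frame(patient_id = "PT1", start_date = enroll_from,
                            end_date = enroll_to),
    medical_claims = if (length(rows)) do.call(rbind, rows) else NULL)
}

# Hand-built cohort-selection fixture covering case and control criteria.
cohort_fixture <- function() {
  pid <- c("CASE_OK", "CASE_YOUNG", "CASE_SHORT_ENROLL", "CASE_PREVALENT",
           "CTRL_OK", "CTRL_SCT", "CTRL_NOTE", "CTRL_CHEMO")
  persons <- data.frame(
    patient_id = pid,
    birth_year = c(1950L, 1995L, 1950L, 1950L, 1945L, 1945L, 1945L, 1945L),
    sex = "F", stringsAsFactors = FALSE)
  enrollment <- data.frame(
    patient_id = pid,
    start_date = as.Date(c("2012-01-01", "2012-01-01", "2012-05-01",
                           "2012-01-01", "2010-01-01", "2010-01-01",
                           "2010-01-01", "2010-01-01")),
    end_date = as.Date(c(rep("2012-12-31", 4), rep("2011-12-31", 4))),
    stringsAsFactors = FALSE)
  emr_oncology <- data.frame(
    patient_id = pid[1:4],
    emr_dx_date = as.Date("2012-06-01"),
    visit_date = as.Date("2012-06-01"),
    diagnosis_label = "Multiple myeloma", stringsAsFactors = FALSE)
  emr_notes <- data.frame(
    patient_id = rep(pid[5:8], each = 2),
    note_date = rep(as.Date(c("2010-01-01", "2011-12-31")), 4),
    note_text = c(rep("routine visit", 4), "routine visit",
                  "pt with Multiple Myeloma, stable", "routine visit",
                  "routine visit"),
    stringsAsFactors = FALSE)
  mk_claim <- function(id, p, date, dx1 = "", proc = "", sys = "") {
    data.frame(claim_id = id, patient_id = p, service_date = as.Date(date),
               dx1 = dx1, dx2 = "", dx3 = "", dx4 = "",
               proc_code = proc, proc_system = sys, stringsAsFactors = FALSE)
  }
  medical_claims <- rbind(
    # prevalent case: chemo + MM dx on the same claim, 31 days pre-anchor
    mk_claim("M1", "CASE_PREVALENT", "2012-05-01", dx1 = "20300",
             proc = "96400", sys = "CPT4"),
    # every control needs >= 1 MM-coded claim in the window
    mk_claim("M2", "CTRL_OK", "2010-06-01", dx1 = "20301"),
    mk_claim("M3", "CTRL_SCT", "2010-06-01", dx1 = "20300"),
    mk_claim("M4", "CTRL_SCT", "2010-07-01", proc = "38241", sys = "CPT4"),
    mk_claim("M5", "CTRL_NOTE", "2010-06-01", dx1 = "20300"),
    mk_claim("M6", "CTRL_CHEMO", "2010-06-01", dx1 = "20300"),
    mk_claim("M7", "CTRL_CHEMO", "2010-08-01", dx1 = "20300",
             proc = "96400", sys = "CPT4"))
  claims_bundle(persons = persons, enrollment = enrollment,
                medical_claims = medical_claims,
                emr_oncology = emr_oncology, emr_notes = emr_notes)
}
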