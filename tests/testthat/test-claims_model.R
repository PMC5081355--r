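test_that("code canonicalization strips dots, upper-cases, and is idempotent", {
  expect_identical(canonicalize_code("203.00"), "20300")
  expect_identical(canonicalize_code("v58.11"), "V5811")
  # independent string oracle
  codes <- c("203.00", "v58.11", "E934.7", "84165", "00054-123-45")
  oracle <- toupper(gsub("\\.", "", codes))
  expect_identical(canonicalize_code(codes), oracle)
  expect_identical(canonicalize_code(canonicalize_code(codes)),
                   canonicalize_code(codes))
})

test_that("bundle construction validates schema and referential integrity", {
  b <- claims_bundle(persons = data.frame(patient_id = "P1",
                                          birth_year = 1950L, sex = "F"))
  expect_s3_class(b, "claims_bundle")
  expect_identical(nrow(b$medical_claims), 0L)

  expect_error(claims_bundle(persons = data.frame(patient_id = "P1")),
               "missing column 'birth_year'")
  expect_error(
    claims_bundle(
      persons = data.frame(patient_id = "P1", birth_year = 1950L, sex = "F"),
      enrollment = data.frame(patient_id = "P2",
                              start_date = as.Date("2010-01-01"),
                              end_date = as.Date("2010-12-31"))),
    "referential-integrity")
  expect_error(
    claims_bundle(
      persons = data.frame(patient_id = "P1", birth_year = 1950L, sex = "F"),
      enrollment = data.frame(patient_id = "P1",
                              start_date = as.Date("2010-12-31"),
                              end_date = as.Date("2010-01-01"))),
    "start_date > end_date")
})

test_that("diagnosis codes are canonicalized on construction", {
  b <- claims_bundle(
    persons = data.frame(patient_id = "P1", birth_year = 1950L, sex = "F"),
    medical_claims = data.frame(claim_id = "C1", patient_id = "P1",
                                service_date = as.Date("2010-06-01"),
                                dx1 = "203.00", dx2 = "", dx3 = "", dx4 = "",
                                proc_code = "", proc_system = ""))
  expect_identical(b$medical_claims$dx1, "20300")
})

test_that("write/read round-trips a generated 100-patient bundle exactly", {
  gc <- default_config_from_tables()
  gc$n <- c(control = 70L, incident_untreated = 10L, prevalent_untreated = 5L,
            incident_treated = 10L, prevalent_treated = 5L)
  gen <- generate_population(gc, seed = 5L, codesets = shared_codesets())
  dir <- withr::local_tempdir()
  write_bundle(gen$bundle, dir)
  back <- read_bundle(dir)
  for (tab in names(unclass(gen$bundle))) {
    expect_equal(back[[tab]], gen$bundle[[tab]], ignore_attr = FALSE)
  }
})

test_that("empty bundle writes six header-only files", {
  b <- claims_bundle(persons = data.frame(patient_id = character(0),
                                          birth_year = integer(0),
                                          sex = character(0)))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  files <- list.files(dir)
  expect_setequal(files, paste0(c("persons", "enrollment", "medical_claims",
                                  "drug_claims", "emr_oncology", "emr_notes"),
                                ".csv"))
  for (f in files) {
    expect_length(readLines(file.path(dir, f)), 1L)
  }
})

test_that("read_bundle reports row-level date errors and missing columns", {
  b <- claims_bundle(persons = data.frame(patient_id = "P1",
                                          birth_year = 1950L, sex = "F"))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  writeLines(c("patient_id,start_date,end_date", "P1,2010-01-01,not-a-date"),
             file.path(dir, "enrollment.csv"))
  expect_error(read_bundle(dir), "unparseable date 'not-a-date' at row 1")
  writeLines("patient_id,start_date", file.path(dir, "enrollment.csv"))
  expect_error(read_bundle(dir), "missing column 'end_date'")
})

test_that("merge_enrollment merges abutting spans and keeps gapped ones", {
  # day-arithmetic oracle: Jun 1 is exactly one day after May 31
  spans <- data.frame(start_date = as.Date(c("2012-01-01", "2012-06-01")),
                      end_date = as.Date(c("2012-05-31", "2012-12-31")))
  merged <- merge_enrollment(spans)
  expect_identical(nrow(merged), 1L)
  expect_identical(merged$start_date, as.Date("2012-01-01"))
  expect_identical(merged$end_date, as.Date("2012-12-31"))

  gapped <- data.frame(start_date = as.Date(c("2012-01-01", "2012-06-01")),
                       end_date = as.Date(c("2012-03-31", "2012-12-31")))
  expect_identical(nrow(merge_enrollment(gapped)), 2L)
  # 61-day gap closes with a large enough tolerance
  expect_identical(nrow(merge_enrollment(gapped, gap_days = 61L)), 1L)

  single <- data.frame(start_date = as.Date("2012-01-01"),
                       end_date = as.Date("2012-12-31"))
  expect_equal(merge_enrollment(single), single)
  expect_error(merge_enrollment(data.frame(start_date = as.Date("2012-02-01"),
                                           end_date = as.Date("2012-01-01"))),
               "start_date > end_date")
})

test_that("merge_enrollment is invariant to span order and truly minimal", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(1:6, 1)
    s <- as.Date("2010-01-01") + sample(0:400, n)
    e <- s + sample(0:90, n, replace = TRUE)
    spans <- data.frame(start_date = s, end_date = e)
    m1 <- merge_enrollment(spans)
    m2 <- merge_enrollment(spans[sample(n), , drop = FALSE])
    expect_equal(m1, m2)
    # oracle: merged day set equals raw day set, spans pairwise separated
    days_raw <- sort(unique(unlist(Map(seq, as.integer(s), as.integer(e)))))
    days_m <- sort(unlist(Map(seq, as.integer(m1$start_date),
                              as.integer(m1$end_date))))
    expect_identical(days_m, days_raw)
    if (nrow(m1) > 1L) {
      expect_true(all(as.integer(m1$start_date[-1L]) >
                        as.integer(m1$end_date[-nrow(m1)]) + 1L))
    }
  }
})
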