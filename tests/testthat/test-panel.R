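test_that("continuous_enrollment requires one span to cover the window", {
  span <- data.frame(start_date = as.Date("2012-01-01"),
                     end_date = as.Date("2012-12-31"))
  expect_true(continuous_enrollment(span, as.Date("2012-06-01"), 90, 30))
  late <- data.frame(start_date = as.Date("2012-05-01"),
                     end_date = as.Date("2012-12-31"))
  # only 31 days precede June 1
  expect_false(continuous_enrollment(late, as.Date("2012-06-01"), 90, 30))
  abutting <- merge_enrollment(
    data.frame(start_date = as.Date(c("2012-01-01", "2012-06-01")),
               end_date = as.Date(c("2012-05-31", "2012-12-31"))))
  expect_true(continuous_enrollment(abutting, as.Date("2012-06-01"), 90, 30))
  expect_error(continuous_enrollment(span, as.Date("2012-06-01"), -1, 30),
               ">= 0")
})

test_that("panel keeps MM-coded claims meeting the 90/30 rule, in order", {
  start <- as.Date("2010-01-01")
  b <- claims_bundle(
    persons = data.frame(patient_id = "P1", birth_year = 1950L, sex = "F"),
    enrollment = data.frame(patient_id = "P1", start_date = start,
                            end_date = start + 500),
    medical_claims = data.frame(
      claim_id = c("C1", "C2", "C3", "C4", "C5"),
      patient_id = "P1",
      service_date = start + c(100, 105, 400, 10, 490),
      dx1 = c("20300", "20300", "20301", "20300", "20300"),
      dx2 = "", dx3 = "", dx4 = "", proc_code = "", proc_system = ""))
  panel <- build_panel(b, shared_codesets())
  # day 10 fails the 90-day lookback, day 490 fails the 30-day follow-up
  expect_identical(panel$claim_id, c("C1", "C2", "C3"))
  expect_identical(panel$index_date, start + c(100, 105, 400))
  # patient with no MM claims: empty panel
  b2 <- timeline_bundle(test = c(-10, 0))
  expect_identical(nrow(build_panel(b2, shared_codesets())), 0L)
})

test_that("feature extraction matches hand enumeration", {
  cfg <- shared_codesets()
  b <- timeline_bundle(mm = c(-60, -50, 0, 45), test = c(-40, -20))
  panel <- build_panel(b, cfg)
  f <- extract_features(panel, b, cfg)
  r <- f[f$index_date == as.Date("2010-07-01"), ]
  expect_identical(r$n_mm_dx_prior, 2L)
  expect_identical(r$n_mm_dx_post, 1L)
  expect_true(r$has_mm_dx_post_30)
  expect_identical(r$n_protein_electrophoresis_90, 2L)
  expect_identical(r$n_protein_electrophoresis_180, 2L)
  expect_false(r$chemo_prior_or_on)
  expect_identical(r$observed_days_prior, 180L)
  expect_identical(r$observed_days_post, 180L)
})

test_that("chemo on the index day counts to both windows", {
  cfg <- shared_codesets()
  b <- timeline_bundle(mm = 0, chemo = 0)
  f <- extract_features(build_panel(b, cfg), b, cfg)
  expect_true(f$chemo_prior_or_on)
  expect_true(f$chemo_post)
})

test_that("an index with no other events has zero counts and FALSE flags", {
  cfg <- shared_codesets()
  b <- timeline_bundle(mm = 0)
  f <- extract_features(build_panel(b, cfg), b, cfg)
  count_cols <- grep("^n_", names(f), value = TRUE)
  expect_true(all(unlist(f[count_cols]) == 0L))
  bool_cols <- grep("^(has_|chemo_)", names(f), value = TRUE)
  expect_true(all(!unlist(f[bool_cols])))
})

test_that("events outside every window never change features (locality)", {
  cfg <- shared_codesets()
  b1 <- timeline_bundle(mm = c(-60, 0, 45), test = -40)
  b2 <- timeline_bundle(mm = c(-200, -60, 0, 45, 200), test = c(-200, -40, 181))
  p1 <- build_panel(b1, cfg)
  f1 <- extract_features(p1, b1, cfg)
  f2 <- extract_features(build_panel(b2, cfg), b2, cfg)
  r1 <- f1[f1$index_date == as.Date("2010-07-01"), -match("claim_id", names(f1))]
  r2 <- f2[f2$index_date == as.Date("2010-07-01"), -match("claim_id", names(f2))]
  rownames(r1) <- rownames(r2) <- NULL
  expect_equal(r1, r2)
})

test_that("windows are clipped to enrollment and observed days reflect it", {
  cfg <- shared_codesets()
  # enrollment starts 100 days before the index: prior window is truncated
  b <- timeline_bundle(mm = 0, enroll_from = as.Date("2010-07-01") - 100,
                       enroll_to = as.Date("2010-07-01") + 200)
  f <- extract_features(build_panel(b, cfg), b, cfg)
  expect_identical(f$observed_days_prior, 100L)
  expect_identical(f$observed_days_post, 180L)
  expect_true(all(f$observed_days_prior >= 90L))
})

test_that("prior MM-dx counts equal a brute-force scan on a synthetic population", {
  cfg <- shared_codesets()
  pop <- medium_population()
  panel <- build_panel(pop$bundle, cfg)
  f <- extract_features(panel, pop$bundle, cfg)
  mc <- pop$bundle$medical_claims
  mm_rows <- grepl("^2030", mc$dx1) | grepl("^2030", mc$dx2) |
    grepl("^2030", mc$dx3) | grepl("^2030", mc$dx4)
  mm_by_pid <- split(as.integer(mc$service_date[mm_rows]), mc$patient_id[mm_rows])
  # check a seeded random subset of indexes against the direct scan
  set.seed(1)
  rows <- sample(nrow(f), 1000)
  for (r in rows) {
    d <- as.integer(f$index_date[r])
    dates <- unique(mm_by_pid[[f$patient_id[r]]])
    expect_identical(f$n_mm_dx_prior[r],
                     sum(dates >= d - 180L & dates <= d - 1L))
  }
  # panel eligibility implies continuous enrollment (cross-check)
  spans <- mmclaims:::merged_spans_by_patient(pop$bundle$enrollment)
  for (pid in unique(panel$patient_id[seq_len(500)])) {
    idx <- panel$index_date[panel$patient_id == pid]
    expect_true(all(continuous_enrollment(spans[[pid]], idx, 90, 30)))
  }
})
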