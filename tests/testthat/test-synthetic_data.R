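test_that("default generator config carries the published calibration values", {
  gc <- default_config_from_tables()
  expect_equal(gc$rates["control", "mm_dx"], 3)
  expect_equal(gc$rates["control", "protein_electrophoresis"], 1.20)
  expect_equal(gc$rates["incident_untreated", "mm_dx"], 8)
  expect_equal(gc$rates["incident_treated", "mm_dx"], 39)
  expect_equal(gc$rates["incident_treated", "chemo_days"], 240)
  expect_equal(gc$rates["prevalent_treated", "chemo_days"], 202)
  expect_equal(gc$window_probs["corticosteroid", "control"], 0.261)
  expect_equal(gc$window_probs["corticosteroid", "case_treated"], 0.797)
  expect_equal(unname(gc$n[c("control", "incident_untreated",
                             "prevalent_untreated", "incident_treated",
                             "prevalent_treated")]),
               c(684L, 54L, 18L, 182L, 80L))
  expect_silent(validate_generator_config(gc))
  bad <- gc; bad$rates["control", "mm_dx"] <- -1
  expect_error(validate_generator_config(bad), "invalid config")
})

test_that("generation is deterministic and empty configs yield empty bundles", {
  gc <- default_config_from_tables()
  gc$n[] <- 0L
  gen0 <- generate_population(gc, seed = 1L, codesets = shared_codesets())
  expect_identical(nrow(gen0$bundle$persons), 0L)
  expect_identical(nrow(gen0$labels), 0L)

  gc$n <- c(control = 15L, incident_untreated = 3L, prevalent_untreated = 2L,
            incident_treated = 4L, prevalent_treated = 2L)
  g1 <- generate_population(gc, seed = 9L, codesets = shared_codesets())
  g2 <- generate_population(gc, seed = 9L, codesets = shared_codesets())
  expect_identical(g1, g2)
  g3 <- generate_population(gc, seed = 10L, codesets = shared_codesets())
  expect_false(identical(g1$bundle$medical_claims, g3$bundle$medical_claims))
})

test_that("controls carry no chemotherapy or transplant claims and clean notes", {
  cfg <- shared_codesets()
  pop <- medium_population()
  ctrl <- pop$labels$patient_id[pop$labels$label == "control"]
  mc <- pop$bundle$medical_claims[pop$bundle$medical_claims$patient_id %in% ctrl, ]
  chemo <- mmclaims:::medical_claims_in_codeset(mc, cfg$codesets$chemotherapy, cfg)
  sct <- mmclaims:::medical_claims_in_codeset(mc, cfg$codesets$stem_cell_transplant, cfg)
  expect_identical(sum(chemo), 0L)
  expect_identical(sum(sct), 0L)
  dc <- pop$bundle$drug_claims[pop$bundle$drug_claims$patient_id %in% ctrl, ]
  expect_identical(sum(mmclaims:::drug_claims_in_codeset(dc, cfg$codesets$chemotherapy, cfg)), 0L)
  notes <- pop$bundle$emr_notes
  expect_false(any(note_mentions_mm(notes$note_text)))
})

test_that("generated cohort is recovered exactly by the selectors", {
  cfg <- shared_codesets()
  pop <- medium_population()
  labels <- build_gold_standard(pop$bundle, cfg)
  truth <- pop$labels
  m <- merge(labels, truth, by = "patient_id", suffixes = c("", ".truth"))
  expect_identical(nrow(m), nrow(truth))
  expect_identical(m$label, m$label.truth)
  expect_identical(m$anchor_date, m$anchor_date.truth)
  expect_identical(m$incident, m$incident.truth)
  expect_identical(m$observation_start, m$observation_start.truth)
  expect_identical(m$observation_end, m$observation_end.truth)
})

test_that("empirical annual rates converge to configured rates (n = 2000)", {
  gc <- default_config_from_tables()
  gc$n <- c(control = 2000L, incident_untreated = 0L, prevalent_untreated = 0L,
            incident_treated = 0L, prevalent_treated = 0L)
  gen <- generate_population(gc, seed = 123L, codesets = shared_codesets())
  t1 <- annualized_rates(gen$labels, gen$bundle, shared_codesets())
  expect_equal(t1$mm_dx, 3, tolerance = 0.05)
  expect_equal(t1$protein_electrophoresis, 1.20, tolerance = 0.05)
  expect_equal(t1$bone_marrow, 0.93, tolerance = 0.05)
  expect_equal(t1$ldh, 0.63, tolerance = 0.05)
})

test_that("archetype timelines carry their annotated expected flags", {
  cfg <- shared_codesets()
  ar <- generate_archetypes(cfg)
  expect_s3_class(ar$bundle, "claims_bundle")
  specs <- list(baseline = baseline_spec(),
                algorithm2 = algorithm2_spec(),
                algorithm2_c_or_d = algorithm2_spec("c_or_d"),
                algorithm2_bc_or_d = algorithm2_spec("bc_or_d"))
  for (nm in names(specs)) {
    fl <- flag_population(specs[[nm]], ar$bundle, cfg)
    exp <- ar$expected[ar$expected$algorithm_id == specs[[nm]]$algorithm_id, ]
    m <- merge(fl, exp, by = "patient_id", suffixes = c(".got", ".want"))
    expect_identical(m$flagged.got, m$flagged.want)
    flagged <- m$flagged.want
    expect_identical(m$flag_date.got[flagged], m$flag_date.want[flagged])
  }
  # the precedence contrast: the chemo-only timeline flips between variants
  d_only <- ar$expected[ar$expected$patient_id == "d_only", ]
  expect_true(d_only$flagged[d_only$algorithm_id == "algorithm2"])
  expect_false(d_only$flagged[d_only$algorithm_id == "algorithm2_c_or_d"])
})
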