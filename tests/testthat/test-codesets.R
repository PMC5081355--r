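test_that("the MM family pattern matches published examples", {
  expect_true(pattern_matches("203.0x", "20300"))
  expect_false(pattern_matches("203.0x", "20310"))
  # zero-or-more dialect: a 4-digit family stem also matches
  expect_true(pattern_matches("203.0x", "2030"))
})

test_that("wildcard dialects agree with an independent regex oracle", {
  # exhaustive enumeration of all 3-5 digit numeric codes
  codes <- c(sprintf("%03d", 0:999), sprintf("%04d", 0:9999),
             sprintf("%05d", 0:99999))
  p <- code_pattern("ICD9DX", "203.0x")
  expect_identical(pattern_matches(p, codes), grepl("^2030", codes))
  expect_identical(pattern_matches(p, codes, mode = "per_char"),
                   grepl("^2030.$", codes))
  p2 <- code_pattern("ICD9DX", "203.0xx")
  expect_identical(pattern_matches(p2, codes, mode = "per_char"),
                   grepl("^2030..$", codes))
})

test_that("wildcard-free patterns match by exact equality only", {
  codes <- c("84165", "841650", "8416", "84165X", "84164")
  expect_identical(pattern_matches(code_pattern("CPT4", "84165"), codes),
                   codes == "84165")
  expect_identical(pattern_matches(code_pattern("CPT4", "84165"), codes,
                                   mode = "per_char"),
                   codes == "84165")
})

test_that("malformed patterns are rejected", {
  expect_error(code_pattern("ICD9DX", "20x30"), "trailing run")
  expect_error(code_pattern("ICD9DX", "xxx"), "no fixed prefix")
  expect_error(code_pattern("ICD9DX", ""), "empty code pattern")
  expect_error(code_pattern("ICD10", "C90"), "unknown code system")
})

test_that("claims match a codeset on any diagnosis slot and on procedures", {
  cfg <- shared_codesets()
  mm <- cfg$codesets$mm_diagnosis
  claim <- data.frame(claim_id = "C1", patient_id = "P1",
                      service_date = as.Date("2010-01-01"),
                      dx1 = "4019", dx2 = "20301", dx3 = "", dx4 = "",
                      proc_code = "", proc_system = "",
                      stringsAsFactors = FALSE)
  expect_true(claim_in_codeset(claim, mm, cfg))
  # primary-only matching is a config option
  cfg_primary <- codeset_config(cfg$codesets, dx_match = "primary_only")
  expect_false(claim_in_codeset(claim, mm, cfg_primary))

  sct <- cfg$codesets$stem_cell_transplant
  proc_claim <- data.frame(claim_id = "C2", patient_id = "P1",
                           service_date = as.Date("2010-01-01"),
                           dx1 = "", dx2 = "", dx3 = "", dx4 = "",
                           proc_code = "38241", proc_system = "CPT4",
                           stringsAsFactors = FALSE)
  expect_true(claim_in_codeset(proc_claim, sct, cfg))
  # system mismatch must not match
  proc_claim$proc_system <- "HCPCS"
  expect_false(claim_in_codeset(proc_claim, sct, cfg))
  # empty codeset never matches
  empty <- structure(list(name = "empty", patterns = list()), class = "codeset")
  expect_false(claim_in_codeset(claim, empty, cfg))
})

test_that("adding patterns never shrinks the matched set (monotonicity)", {
  set.seed(7)
  codes <- sprintf("%05d", sample(0:99999, 400))
  mc <- data.frame(claim_id = paste0("C", seq_along(codes)), patient_id = "P1",
                   service_date = as.Date("2010-01-01"),
                   dx1 = codes, dx2 = "", dx3 = "", dx4 = "",
                   proc_code = "", proc_system = "", stringsAsFactors = FALSE)
  for (rep in 1:20) {
    p1 <- sprintf("%03dx", sample(0:999, 1))
    p2 <- sprintf("%02dx", sample(0:99, 1))
    small <- codeset("s", list(p1), system = "ICD9DX")
    big <- codeset("b", list(p1, p2), system = "ICD9DX")
    h_small <- mmclaims:::medical_claims_in_codeset(mc, small, NULL)
    h_big <- mmclaims:::medical_claims_in_codeset(mc, big, NULL)
    expect_true(all(h_big[h_small]))
  }
})

test_that("codeset configuration round-trips through YAML", {
  cfg <- shared_codesets()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_codesets(cfg, path)
  back <- load_codesets(path)
  expect_identical(names(back$codesets), names(cfg$codesets))
  expect_identical(back$diagnostic_tests, cfg$diagnostic_tests)
  expect_identical(back$symptoms, cfg$symptoms)
  for (nm in names(cfg$codesets)) {
    expect_identical(
      vapply(back$codesets[[nm]]$patterns, function(p) paste0(p$system, ":", p$prefix, strrep("x", p$n_wild)), ""),
      vapply(cfg$codesets[[nm]]$patterns, function(p) paste0(p$system, ":", p$prefix, strrep("x", p$n_wild)), ""))
  }
  expect_error(load_codesets(file.path(tempdir(), "nope.yaml")), "not found")
})

test_that("a configuration must define mm_diagnosis", {
  expect_error(codeset_config(list(codeset("bone_marrow", list("38220"),
                                           system = "CPT4"))),
               "mm_diagnosis")
})

test_that("the shipped default codesets file loads and matches the defaults", {
  path <- system.file("extdata", "codesets_default.yaml", package = "mmclaims")
  expect_true(nzchar(path))
  shipped <- load_codesets(path)
  expect_identical(names(shipped$codesets), names(default_codesets()$codesets))
  expect_true(pattern_matches(shipped$codesets$mm_diagnosis$patterns[[1]], "20301"))
})
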