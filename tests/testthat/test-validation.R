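mk_flags <- function(ids, flagged) {
  fd <- as.Date(rep(NA_character_, length(flagged)))
  fd[flagged] <- as.Date("2010-01-01")
  data.frame(patient_id = ids, algorithm_id = rep("test", length(ids)),
             flagged = flagged, flag_date = fd, stringsAsFactors = FALSE)
}
mk_labels <- function(ids, labels) {
  data.frame(patient_id = ids, label = labels, stringsAsFactors = FALSE)
}

test_that("confusion counts tabulate patient-level agreement", {
  ids <- sprintf("P%d", 1:5)
  counts <- confusion_counts(mk_flags(ids, c(TRUE, TRUE, TRUE, FALSE, FALSE)),
                             mk_labels(ids, c(rep("case", 3), rep("control", 2))))
  expect_identical(counts, list(tp = 3L, fn = 0L, tn = 2L, fp = 0L))
  counts2 <- confusion_counts(mk_flags(ids[1:4], c(TRUE, FALSE, TRUE, FALSE)),
                              mk_labels(ids[1:4], c("case", "case", "control", "control")))
  expect_identical(counts2, list(tp = 1L, fn = 1L, tn = 1L, fp = 1L))
  empty <- confusion_counts(mk_flags(character(0), logical(0)),
                            mk_labels(character(0), character(0)))
  expect_identical(empty, list(tp = 0L, fn = 0L, tn = 0L, fp = 0L))
  expect_error(confusion_counts(mk_flags("P1", TRUE), mk_labels("P2", "case")),
               "input error")
})

test_that("sensitivity and specificity are the usual ratios", {
  expect_equal(sensitivity_specificity(list(tp = 3, fn = 0, tn = 2, fp = 0)),
               list(sensitivity = 1, specificity = 1))
  # mirrors the published operating point (83% / 94%)
  expect_equal(sensitivity_specificity(list(tp = 83, fn = 17, tn = 94, fp = 6)),
               list(sensitivity = 0.83, specificity = 0.94))
  expect_equal(sensitivity_specificity(list(tp = 0, fn = 5, tn = 5, fp = 0)),
               list(sensitivity = 0, specificity = 1))
  expect_error(sensitivity_specificity(list(tp = 0, fn = 0, tn = 1, fp = 0)),
               "undefined-metric")
})

test_that("flagged fraction is computed over the reference population", {
  ids <- sprintf("P%d", 1:100)
  flags <- mk_flags(ids, c(rep(TRUE, 44), rep(FALSE, 56)))
  expect_equal(flagged_fraction(flags, ids), 0.44)
  expect_equal(flagged_fraction(mk_flags(ids, rep(FALSE, 100)), ids), 0)
  expect_equal(flagged_fraction(mk_flags(ids, rep(TRUE, 100)), ids), 1)
  expect_error(flagged_fraction(flags, character(0)), "empty reference")
})

test_that("derived PPV matches the printed formula and the Bayes oracle", {
  expect_equal(derived_ppv(1, 1, 0.1), 1)
  # Bayes oracle: p = 0.5 => f = 0.8*0.5 + 0.1*0.5 = 0.45, PPV = 0.40/0.45
  expect_equal(derived_ppv(0.8, 0.9, 0.45), 0.4 / 0.45, tolerance = 1e-12)
  expect_equal(implied_prevalence(0.8, 0.9, 0.45), 0.5, tolerance = 1e-12)
  expect_equal(implied_prevalence(1, 1, 0.37), 0.37)
  expect_equal(implied_prevalence(0.8, 0.9, 0.10), 0)
  expect_error(derived_ppv(0.8, 0.9, 0.05), "flagged_fraction < 1 - specificity")
  expect_error(derived_ppv(0.8, 0.9, 0.85), "flagged_fraction > sensitivity")
  expect_error(derived_ppv(0.4, 0.5, 0.45), "sensitivity \\+ specificity <= 1")
  expect_error(derived_ppv(0.8, 0.9, 0), "flagged_fraction <= 0")
})

test_that("derived PPV is monotone nondecreasing in the flagged fraction", {
  # PPV = k * (1 - (1 - sp)/f) with k = se/(se + sp - 1) > 0, so at fixed
  # sensitivity/specificity a larger flagged fraction implies a larger
  # implied prevalence and hence a larger PPV
  se <- 0.83; sp <- 0.94
  f <- seq(1 - sp + 1e-6, se, length.out = 200)
  ppv <- vapply(f, function(x) derived_ppv(se, sp, x), numeric(1))
  expect_true(all(diff(ppv) >= -1e-12))
  expect_true(all(ppv >= 0 & ppv <= 1))
})

test_that("implied prevalence inverts the expected flagged fraction", {
  set.seed(3)
  for (rep in 1:200) {
    se <- runif(1, 0.55, 1); sp <- runif(1, 0.55, 1); p <- runif(1)
    f <- se * p + (1 - sp) * (1 - p)
    if (f <= 0) next
    expect_equal(implied_prevalence(se, sp, f), p, tolerance = 1e-12)
  }
})

test_that("performance_metrics assembles the full row and degrades gracefully", {
  ids <- sprintf("P%d", 1:10)
  flags <- mk_flags(ids, c(rep(TRUE, 5), rep(FALSE, 5)))
  labels <- mk_labels(ids, c(rep("case", 5), rep("control", 5)))
  m <- performance_metrics(flags, labels, reference_population = ids)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$flagged_fraction, 0.5)
  expect_equal(m$derived_ppv, 1)
  expect_equal(m$implied_prevalence, 0.5)
  # inconsistent inputs yield NA metrics with a warning, not an error
  # cases unflagged while half the controls are flagged: se + sp <= 1
  bad_flags <- mk_flags(ids, c(FALSE, FALSE, rep(TRUE, 4), rep(FALSE, 4)))
  bad_labels <- mk_labels(ids, c(rep("case", 2), rep("control", 8)))
  expect_warning(m2 <- performance_metrics(bad_flags, bad_labels,
                                           reference_population = ids))
  expect_true(is.na(m2$derived_ppv))
})
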