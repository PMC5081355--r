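# Seeded synthetic claims/EMR generator. Per patient: one enrollment span of
# sampled duration; event counts drawn Poisson with mean rate x person-years
# so annualized means are calibrated by construction; MM-diagnosis and
# chemotherapy days realized as DISTINCT service dates (sampled without
# replacement) because downstream counting is by distinct date; case events
# concentrated around the EMR diagnosis date via a two-rate burst weight;
# chemotherapy days grouped into cycle blocks of consecutive days.
#
# Construction invariants: controls carry zero chemotherapy and zero
# stem-cell-transplant claims and their notes never mention myeloma; every
# case passes select_cases(); prevalent cases carry one pre-anchor
# chemotherapy claim bearing an MM diagnosis code (the association that makes
# them prevalent), incident cases none.

# Post-anchor burst weights over integer days.
burst_weights <- function(days, anchor, burst) {
  w <- rep(1, length(days))
  post <- days >= anchor
  w[post] <- 1 + burst$multiplier *
    2^(-(days[post] - anchor) / burst$half_life_days)
  w
}

# Exactly n distinct days from [lo, hi] grouped into consecutive cycle
# blocks with a random phase and random block order.
sample_cycle_days <- function(n, lo, hi, cycle_days) {
  avail <- hi - lo + 1L
  n <- min(n, avail)
  if (n <= 0L) return(integer(0))
  phase <- sample.int(cycle_days, 1L) - 1L
  days <- lo:hi
  block <- (days - lo + phase) %/% cycle_days
  blocks <- split(days, block)
  picked <- unlist(blocks[sample.int(length(blocks))], use.names = FALSE)
  sort(picked[seq_len(n)])
}

# Weighted sample of n distinct days.
sample_distinct_days <- function(n, days, weights = NULL) {
  n <- min(n, length(days))
  if (n <= 0L) return(integer(0))
  sort(sample(days, n, replace = FALSE, prob = weights))
}

#' Generate a calibrated synthetic population
#'
#' Returns a [claims_bundle()] plus the ground-truth gold labels for the
#' generated patients. Deterministic given `seed`: the same config and seed
#' reproduce the bundle exactly.
#'
#' @param config a `generator_config` (see [default_config_from_tables()]).
#' @param seed integer seed.
#' @param codesets the [codeset_config()] whose (placeholder) codes the
#'   generated claims instantiate.
#' @return list with `bundle` and `labels`.
#' @export
generate_population <- function(config = default_config_from_tables(),
                                seed = 1L, codesets = default_codesets()) {
  validate_generator_config(config)
  with_seed(seed, generate_population_impl(config, codesets))
}

generate_population_impl <- function(config, codesets) {
  code_of <- function(nm) concrete_code(codesets$codesets[[nm]]$patterns[[1L]])
  sys_of <- function(nm) codesets$codesets[[nm]]$patterns[[1L]]$system
  mm_code <- code_of("mm_diagnosis")
  chemo_proc <- "96400"  # instantiates the CPT4 964xx placeholder family

  persons <- list(); enroll <- list(); med <- list(); drug <- list()
  onc <- list(); notes <- list(); labels <- list()
  claim_counter <- 0L
  next_claims <- function(k) {
    ids <- sprintf("C%08d", claim_counter + seq_len(k))
    claim_counter <<- claim_counter + k
    ids
  }
  med_chunk <- function(pid, days, dx1 = "", proc_code = "", proc_system = "") {
    k <- length(days)
    if (k == 0L) return(NULL)
    data.table::data.table(
      claim_id = next_claims(k), patient_id = pid,
      service_date = as.Date(days, origin = "1970-01-01"),
      dx1 = dx1, dx2 = "", dx3 = "", dx4 = "",
      proc_code = proc_code, proc_system = proc_system)
  }
  drug_chunk <- function(pid, days, ndc) {
    k <- length(days)
    if (k == 0L) return(NULL)
    data.table::data.table(
      claim_id = next_claims(k), patient_id = pid,
      fill_date = as.Date(days, origin = "1970-01-01"),
      ndc = ndc, days_supply = 30L)
  }

  pid_counter <- 0L
  start_lo <- as.integer(config$start_window[1L])
  start_hi <- as.integer(config$start_window[2L])

  for (stratum in STRATA) {
    n_pat <- config$n[[stratum]]
    if (n_pat == 0L) next
    is_case <- stratum != "control"
    incident <- startsWith(stratum, "incident")
    treated <- endsWith(stratum, "_treated") && is_case
    wp_col <- if (!is_case) "control" else if (treated) "case_treated" else "case_untreated"
    rates <- config$rates[stratum, ]

    for (i in seq_len(n_pat)) {
      pid_counter <- pid_counter + 1L
      pid <- sprintf("P%06d", pid_counter)
      dur <- sample(config$enrollment_days[1L]:config$enrollment_days[2L], 1L)
      start <- sample(start_lo:start_hi, 1L)
      end <- start + dur - 1L
      yrs <- dur / DAYS_PER_YEAR
      all_days <- start:end

      anchor <- NA_integer_
      if (is_case) {
        # incident cases anchored early so the post-diagnosis period can hold
        # the configured chemotherapy days; prevalent cases need pre-anchor
        # history, so they anchor later
        anchor <- if (incident) start + sample(90:100, 1L) else {
          start + sample(180L:max(180L, dur - 31L), 1L)
        }
        age <- round(rnorm(1, config$age_mean, config$age_sd))
      } else {
        age <- round(rnorm(1, config$age_mean, config$age_sd))
      }
      age <- min(max(age, 19), 95)
      ref_date <- if (is_case) anchor else start
      birth_year <- as.integer(format(as.Date(ref_date, origin = "1970-01-01"), "%Y")) - age

      persons[[pid]] <- data.table::data.table(
        patient_id = pid, birth_year = birth_year,
        sex = sample(c("M", "F"), 1L))
      enroll[[pid]] <- data.table::data.table(
        patient_id = pid,
        start_date = as.Date(start, origin = "1970-01-01"),
        end_date = as.Date(end, origin = "1970-01-01"))

      w <- if (is_case) burst_weights(all_days, anchor, config$burst) else NULL

      # MM diagnosis claims: distinct service dates, rate-calibrated
      n_mm <- rpois(1L, rates[["mm_dx"]] * yrs)
      if (!is_case) n_mm <- max(1L, n_mm)  # controls need >= 1 MM-coded claim
      mm_days <- sample_distinct_days(n_mm, all_days, w)
      med[[length(med) + 1L]] <- med_chunk(pid, mm_days, dx1 = mm_code)

      # diagnostic-test claims: per-claim counting, dates may repeat
      for (nm in codesets$diagnostic_tests) {
        n_t <- rpois(1L, rates[[nm]] * yrs)
        if (n_t > 0L) {
          t_days <- sample(all_days, n_t, replace = TRUE, prob = w)
          med[[length(med) + 1L]] <- med_chunk(pid, sort(t_days),
                                               proc_code = code_of(nm),
                                               proc_system = sys_of(nm))
        }
      }

      # chemotherapy days (treated strata): distinct dates in cycle blocks
      if (treated) {
        n_ch <- rpois(1L, rates[["chemo_days"]] * yrs)
        ch_lo <- if (incident) anchor else start
        ch_days <- sample_cycle_days(n_ch, ch_lo, end, config$chemo_cycle_days)
        if (incident && length(ch_days) == 0L) ch_days <- anchor
        med[[length(med) + 1L]] <- med_chunk(pid, ch_days, dx1 = "V5811",
                                             proc_code = chemo_proc,
                                             proc_system = "CPT4")
        if (!incident && !any(ch_days >= anchor)) {
          # prevalent-treated must show treatment on/after the anchor
          med[[length(med) + 1L]] <- med_chunk(pid, anchor, dx1 = "V5811",
                                               proc_code = chemo_proc,
                                               proc_system = "CPT4")
        }
      }
      if (is_case && !incident) {
        # the chemotherapy-with-MM-diagnosis claim that makes the case prevalent
        assoc_day <- anchor - sample(30:90, 1L)
        med[[length(med) + 1L]] <- med_chunk(pid, assoc_day, dx1 = mm_code,
                                             proc_code = chemo_proc,
                                             proc_system = "CPT4")
      }

      # window-level symptom/treatment draws
      feat_lo <- if (is_case) max(start, anchor - 180L) else start
      feat_hi <- if (is_case) anchor - 1L else end
      for (nm in rownames(config$window_probs)) {
        if (runif(1) >= config$window_probs[nm, wp_col]) next
        day <- sample(feat_lo:feat_hi, 1L)
        p1 <- codesets$codesets[[nm]]$patterns[[1L]]
        if (p1$system == "NDC") {
          drug[[length(drug) + 1L]] <- drug_chunk(pid, day, concrete_code(p1))
        } else if (p1$system == "ICD9DX") {
          med[[length(med) + 1L]] <- med_chunk(pid, day, dx1 = concrete_code(p1))
        } else {
          med[[length(med) + 1L]] <- med_chunk(pid, day, proc_code = concrete_code(p1),
                                               proc_system = p1$system)
        }
      }

      if (is_case) {
        onc[[pid]] <- data.table::data.table(
          patient_id = pid,
          emr_dx_date = as.Date(anchor, origin = "1970-01-01"),
          visit_date = as.Date(anchor, origin = "1970-01-01"),
          diagnosis_label = "Multiple myeloma")
      } else {
        notes[[pid]] <- data.table::data.table(
          patient_id = pid,
          note_date = as.Date(c(start, end), origin = "1970-01-01"),
          note_text = c("routine visit; chronic conditions stable",
                        "follow-up visit; no new problems"))
      }

      labels[[pid]] <- data.table::data.table(
        patient_id = pid,
        label = if (is_case) "case" else "control",
        anchor_date = as.Date(if (is_case) anchor else start, origin = "1970-01-01"),
        incident = if (is_case) incident else NA,
        observation_start = as.Date(start, origin = "1970-01-01"),
        observation_end = as.Date(end, origin = "1970-01-01"))
    }
  }

  bind <- function(x, empty_table) {
    if (length(x) == 0L) return(empty_bundle_table(empty_table))
    as.data.frame(data.table::rbindlist(x))
  }
  bundle <- claims_bundle(
    persons = bind(persons, "persons"),
    enrollment = bind(enroll, "enrollment"),
    medical_claims = bind(med, "medical_claims"),
    drug_claims = bind(drug, "drug_claims"),
    emr_oncology = bind(onc, "emr_oncology"),
    emr_notes = bind(notes, "emr_notes"))
  labels_df <- if (length(labels)) as.data.frame(data.table::rbindlist(labels)) else empty_labels()
  list(bundle = bundle, labels = labels_df)
}

#' Deterministic archetype timelines with annotated expected flags
#'
#' A fixed micro-population of literal clause instantiations used for exact
#' engine tests: a timeline satisfying A&B&C; one satisfying only the
#' chemotherapy disjunct D; one failing only the two-test requirement B; one
#' failing the strictly-before-the-tests boundary of C; a baseline-only pair
#' of diagnoses 10 days apart; and a patient whose MM claims all fall on a
#' single day (duplicate billing). `expected` annotates each patient's flag
#' under the baseline algorithm and all three Algorithm-2 precedence
#' variants.
#'
#' @param codesets a [codeset_config()] supplying concrete codes.
#' @return list with `bundle` and `expected` (`patient_id`, `algorithm_id`,
#'   `flagged`, `flag_date`).
#' @export
generate_archetypes <- function(codesets = default_codesets()) {
  ib <- as.integer(as.Date("2010-07-01"))
  mm_code <- concrete_code(codesets$codesets$mm_diagnosis$patterns[[1L]])
  test_code <- concrete_code(codesets$codesets$protein_electrophoresis$patterns[[1L]])
  chemo_proc <- "96400"

  rows <- list(); claim_n <- 0L
  add_med <- function(pid, offsets, dx1 = "", proc_code = "", proc_system = "") {
    for (off in offsets) {
      claim_n <<- claim_n + 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        claim_id = sprintf("A%05d", claim_n), patient_id = pid,
        service_date = as.Date(ib + off, origin = "1970-01-01"),
        dx1 = dx1, dx2 = "", dx3 = "", dx4 = "",
        proc_code = proc_code, proc_system = proc_system,
        stringsAsFactors = FALSE)
    }
  }
  mm <- function(pid, offsets) add_med(pid, offsets, dx1 = mm_code)
  test <- function(pid, offsets) add_med(pid, offsets, proc_code = test_code,
                                         proc_system = "CPT4")
  chemo <- function(pid, offsets) add_med(pid, offsets, dx1 = "V5811",
                                          proc_code = chemo_proc,
                                          proc_system = "CPT4")

  mm("abc", c(-60, -50, 0, 45));      test("abc", c(-40, -20))
  mm("d_only", 0);                    chemo("d_only", 10)
  mm("fail_b", c(-60, -50, 0, 45));   test("fail_b", -40)
  mm("c_true", c(-45, -41, 0, 45));   test("c_true", c(-40, -20))
  mm("c_false", c(-41, -40, 0, 45));  test("c_false", c(-40, -20))
  mm("baseline_pair", c(0, 10))
  mm("dup_day", c(0, 0, 0))

  pids <- c("abc", "d_only", "fail_b", "c_true", "c_false",
            "baseline_pair", "dup_day")
  bundle <- claims_bundle(
    persons = data.frame(patient_id = pids, birth_year = 1950L, sex = "F",
                         stringsAsFactors = FALSE),
    enrollment = data.frame(patient_id = pids,
                            start_date = as.Date("2009-06-01"),
                            end_date = as.Date("2011-06-30"),
                            stringsAsFactors = FALSE),
    medical_claims = do.call(rbind, rows))

  day <- function(off) as.Date(ib + off, origin = "1970-01-01")
  exp_row <- function(pid, alg, flagged, off = NA) {
    data.frame(patient_id = pid, algorithm_id = alg, flagged = flagged,
               flag_date = if (is.na(off)) as.Date(NA) else day(off),
               stringsAsFactors = FALSE)
  }
  a2 <- c("algorithm2", "algorithm2_c_or_d", "algorithm2_bc_or_d")
  expected <- rbind(
    exp_row("abc", "baseline", TRUE, -60),
    do.call(rbind, lapply(a2, function(a) exp_row("abc", a, TRUE, 0))),
    exp_row("d_only", "baseline", FALSE),
    exp_row("d_only", "algorithm2", TRUE, 0),
    exp_row("d_only", "algorithm2_c_or_d", FALSE),
    exp_row("d_only", "algorithm2_bc_or_d", FALSE),
    exp_row("fail_b", "baseline", TRUE, -60),
    do.call(rbind, lapply(a2, function(a) exp_row("fail_b", a, FALSE))),
    exp_row("c_true", "baseline", TRUE, -45),
    do.call(rbind, lapply(a2, function(a) exp_row("c_true", a, TRUE, 0))),
    exp_row("c_false", "baseline", TRUE, -41),
    do.call(rbind, lapply(a2, function(a) exp_row("c_false", a, FALSE))),
    exp_row("baseline_pair", "baseline", TRUE, 0),
    do.call(rbind, lapply(a2, function(a) exp_row("baseline_pair", a, FALSE))),
    exp_row("dup_day", "baseline", FALSE),
    do.call(rbind, lapply(a2, function(a) exp_row("dup_day", a, FALSE))))
  rownames(expected) <- NULL
  list(bundle = bundle, expected = expected)
}
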