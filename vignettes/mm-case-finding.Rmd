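---
title: "Claims-based case-finding for multiple myeloma: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Claims-based case-finding for multiple myeloma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmclaims)
```

## The problem

Multiple myeloma (MM) is diagnosed through a drawn-out work-up — serum and
urine protein electrophoresis, immunoglobulin quantification, free light
chain assays, beta-2-microglobulin, bone-marrow biopsy, skeletal surveys —
and sits on a spectrum with MGUS and smoldering MM. ICD-9-CM 203.0x codes are
therefore written on claims long before (and often without) a confirmed
diagnosis: rule-out testing, precursor monitoring, and miscoding all leave MM
codes on patients who never develop the disease. A cohort defined by "one
claim with 203.0x" is badly contaminated; a cohort defined by "MM code plus
MM chemotherapy" loses every untreated and early-stage patient.

`mmclaims` implements the middle path: deterministic boolean rules over the
*timing and combination* of coded events around each MM-coded claim,
developed against an EMR-linked gold standard and validated with
patient-level sensitivity, specificity, and a derived PPV.

## Gold standard

Cases are patients with an MM diagnosis *and a clinic visit* in an oncology
EMR, aged ≥18 at the EMR diagnosis date, continuously enrolled in claims for
at least 90 days before through 30 days after it. A case is *incident* when
no chemotherapy claim associated with an MM diagnosis precedes the EMR date
(strictly), *prevalent* otherwise. "Associated with" defaults to both codes
on the same claim record; a same-day variant is available
(`cohort_params()$chemo_mm_association`), because claims extracts differ in
whether line items share records.

Controls are patients known *not* to have MM who nevertheless carry MM codes:
≥12 months (implemented as 365 days) of overlap between claims enrollment and
primary-care EMR coverage containing ≥1 MM-coded claim, excluding anyone
with chemo-associated-with-MM, any stem-cell-transplant claim, or any note
matching a case-insensitive substring scan (default terms `"multiple
myeloma"`, `"myeloma"` — deliberately broad; it also catches "smoldering
myeloma", and a user narrowing it should know it will then miss such
phrasing). EMR coverage is approximated by the span from first to last note;
when several disjoint overlap windows qualify, the earliest is used (it
maximizes follow-up). Control age is assessed at observation start, since no
single diagnosis date exists.

The merged file is split into development and validation halves by a seeded
uniform permutation of the sorted patient ids, `ceiling(n/2)` to development.
The split mechanics (RNG, odd-n rule) are artifact conventions; only
"random half split" is inherited.

## Panel and windows

Every MM-coded claim with 90/30 continuous enrollment is an eligible index.
All windows are inclusive of both endpoints and expressed in whole days
(claims carry service dates only):

| quantity | window |
|---|---|
| prior MM diagnoses | `[t−180, t−1]` |
| following MM diagnoses | `[t+1, t+180]` |
| "more than 30 days following" | `[t+31, t+180]` |
| diagnostic-test lookback | `[t−90, t]` and `[t−180, t]` |
| chemotherapy "prior to or on" / "following" | `[t−180, t]` / `[t, t+180]` |
| symptoms and treatments | `[t−180, t−1]` |

The test lookback includes the index day because diagnostic tests are
commonly billed on the diagnosis date; the chemotherapy-following window
includes it for the same reason. MM diagnoses are counted as *distinct
service dates* (duplicate same-day billing rows must not qualify a patient);
per-claim counting is a config option. Diagnostic tests are counted per
claim. Feature windows are clipped to enrollment and each row carries
observed-day counts so users can normalize truncated windows.

## The rule engine

Algorithms are AND/OR clause trees over four predicate kinds (`mm_dx_count`,
`diagnostic_test_count`, `bone_marrow_count`, `chemo_present`), each with a
window and threshold. A patient is flagged at the earliest eligible index
satisfying the tree; ties on a day are broken by claim id.

Two genuinely open readings had to be fixed:

* **Clause precedence.** The prose description of the validated algorithm
  ends with "... and ≥2 additional MM diagnoses prior to the tests, or
  chemotherapy during the 180 days following". We read this as
  `(A ∧ B ∧ C) ∨ D`: chemotherapy was described as an "OR" added to improve
  sensitivity and explicitly *not* a requirement, which only the standalone
  disjunct delivers. The groupings `A ∧ B ∧ (C ∨ D)` and
  `A ∧ ((B ∧ C) ∨ D)` ship as named variants
  (`algorithm2_spec("c_or_d")`, `algorithm2_spec("bc_or_d")`), and the
  archetype fixtures include a chemotherapy-only timeline that flips between
  them.
* **"Prior to the tests."** The anchor is the earliest test date among the
  claims satisfying B: the minimum test date when ≥2 test claims fall in the
  lookback, else the earliest bone-marrow date. Earliest-date anchoring is
  the strictest deterministic reading (fewer diagnoses can precede it);
  the C predicate demands dates *strictly* before the anchor.

Every engine result can be re-derived by `brute_force_flag()`, an
intentionally naive oracle that re-matches codes with regular expressions,
checks enrollment against an explicit day set, and re-counts every window by
direct scan — no shared windowing code. The acceptance suite requires exact
agreement on 500 seeded synthetic patients per built-in algorithm.

## Validation metrics

Sensitivity and specificity are patient-level ratios against the gold
standard. PPV cannot be computed directly (cases and controls come from
different EMR populations), so it is derived from the flagged fraction `f`
of a reference population:

$$\mathrm{PPV} = \frac{se\,(f + sp - 1)}{f\,(se + sp - 1)},\qquad
p = \frac{f + sp - 1}{se + sp - 1}$$

The formula is Bayes' rule evaluated at the implied prevalence `p`; the
package enforces the domain `se + sp > 1`, `0 < f`, `1 − sp ≤ f ≤ se` and
errors name the violated inequality. Note PPV is *increasing* in `f` at
fixed `se`/`sp` (larger flagged fraction ⇒ larger implied prevalence).
The reference population defaults to patients with ≥1 MM-coded claim rather
than all enrollees: back-solving published operating points under the
formula yields `f ≈ 0.44`, implausible as a whole-population fraction but
natural among MM-coded patients. This reading is inferred, not stated, and
is config-exposed (`--reference-population mm-dx|all`).

## The synthetic world

`generate_population()` emulates the *stratum structure and event
intensities* of the development-sample descriptives, nothing more. Per
patient: one enrollment span, uniform 1–4 years (realistic for commercial
claims); event counts drawn Poisson with mean rate × person-years at the
published stratum rates (controls 3 MM-diagnosis dates/yr, incident
untreated 8, prevalent untreated 18, incident treated 39 with 240
chemotherapy days/yr, prevalent treated 34 with 202); MM-diagnosis and
chemotherapy days realized as distinct dates (sampled without replacement,
chemotherapy in 5-day cycle blocks) so distinct-date counting recovers the
configured means; symptom/treatment presence as window-level Bernoulli draws
at the published percentages. Case events concentrate around the EMR
diagnosis date via a two-rate burst weight (uniform baseline before, weight
`1 + m·2^{−Δ/h}` after, defaults `m = 8`, `h = 180` days). The burst shape
is an artifact construct — the source reports only annual means — chosen as
the simplest intensity that reproduces them while putting diagnostic
activity where the algorithms look.

Deliberate generator conventions, and their small costs:

* Chemotherapy claims carry the V58.11 encounter code, not an MM code, so
  240 chemo days/yr do not inflate the 39 MM-dx dates/yr. Prevalent cases
  get exactly one pre-anchor chemotherapy claim bearing an MM code — the
  association that defines prevalence — adding ~1 MM-dx date per patient
  (a 1–2% upward bias on the prevalent strata means; the calibration
  targets are the control and incident strata, which are unaffected).
* Incident cases anchor 90–100 days after enrollment start so the
  post-anchor period can physically hold 240 chemotherapy days/yr; at the
  1-year minimum enrollment the Poisson upper tail is truncated by available
  days (expected bias below 0.1%).
* Controls are forced to ≥1 MM-coded claim (they are defined by having one);
  with control rates the truncation bias is ~10⁻³ of a claim.
* "Treated" in the descriptives means ≥1 chemotherapy claim *on or after*
  the anchor within observation. Defining it as any-chemo-in-observation
  would make the prevalent-untreated stratum structurally empty, since
  prevalence is itself established by pre-anchor chemotherapy.

What the generator does **not** emulate: coding noise and rule-out dynamics
(controls' MM codes are not clustered into realistic work-up episodes),
multiple enrollment spans, secondary-position diagnoses, real code lists
(every non-203.0x code set is a placeholder the generated claims
instantiate), inter-event correlation beyond the burst, and EMR/claims
linkage error. A green test therefore establishes that the machinery is
correct and calibrated — not that the shipped operating points transfer to
real claims. On the default synthetic population the baseline rule's
specificity collapses (every control carries MM codes by construction) and
the validated algorithm's specificity is far higher, reproducing the
published *ordering*; absolute published values (sensitivity 83%,
specificity 94%, PPV 93%) are out of reach at desk scale and are not
asserted anywhere.

## Numerical and degenerate-input choices

* Dates are whole days; years are days/365.25; age is year(date) − birth
  year (de-identified claims carry birth year only).
* Enrollment spans are inclusive on both ends; spans merge only when they
  overlap or abut exactly (gap tolerance 0 days, configurable) — the
  strictest faithful reading of "continuously enrolled".
* Wildcards: a trailing `x` run matches zero or more characters, so
  `203.0x` matches the 4-digit stem `2030` as well as `20300`–`20309`
  (claims extracts code families at mixed specificity); an
  exactly-one-character mode is available. Wildcard-free patterns match by
  exact equality. Diagnosis patterns match any of the four slots by
  default (`primary_only` available).
* Empty clause trees, interior wildcards, zero denominators, inconsistent
  PPV inputs, orphan patient ids, and unparseable dates all fail fast with
  errors naming the offending object.
* Standard deviations use the n−1 denominator.

## Known limitations

Only the baseline and the highest-performing validated algorithm ship as
built-ins; the other explored variants were never published in reproducible
form, though the clause-tree engine can express them. Placeholder code sets
must be replaced with study-grade lists before any use on real data. The
text scan is substring matching, not NLP, and will count negated mentions
("no evidence of myeloma") as mentions. Incident/prevalent labeling inherits
the EMR's visibility limits: care delivered outside the linked systems is
invisible, which is precisely the measurement error the original design
accepted.
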