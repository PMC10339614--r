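---
title: "Harmonising multi-study JIA registry data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonising multi-study JIA registry data: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortforge)
```

## The setting

Four UK observational studies recruit overlapping populations of children
with juvenile idiopathic arthritis (JIA): CAPS (an inception cohort entered
at diagnosis), CHARMS (entered at the start of methotrexate or TNF-inhibitor
treatment), and the two biologics registers BSPAR-Et and BCRD (entered at
the start of etanercept or of other biologics/methotrexate respectively).
Pooling them multiplies the available sample for treatment-response
research, but three obstacles stand in the way: the same child may appear
in several studies (or twice within one study after a repeat treatment
course); each study stores the same clinical content under different column
names, codings and granularity; and no study collects every variable.
`cohortforge` implements the pipeline that resolves all three, and a
synthetic data generator that stands in for the governed source extracts.

## Deterministic linkage by salted digest

Every UK patient carries an NHS (or Scottish CHI) number whose tenth digit
is a modulus-11 check digit over the first nine (weights 10 down to 2;
check = 11 − (Σ wᵢdᵢ mod 11), with 11 mapped to 0 and a remainder of 1
meaning no valid number exists with that prefix). Because 11 is prime, *no*
single-digit substitution can preserve validity — a property the test suite
verifies by exhaustive enumeration. A mistyped digit therefore produces an
*invalid* number rather than a false link: deterministic linkage on this
identifier can miss pairs but, under the single-substitution error model,
cannot merge two different children.

Records are linked by a salted one-way digest: SHA-256 over the
canonicalised identifier bytes (spaces and hyphens stripped — numbers are
conventionally printed in 3-3-4 groups) followed by the salt bytes,
rendered as 64 uppercase hex characters. The salt makes digests
project-specific: the same identifiers hashed with a different salt share
nothing. We deliberately do not claim bit-compatibility with any external
pseudonymisation tool; the package ships its own frozen test vectors, and
the tests cross-check the digest against a second, independent SHA-256
implementation. Cluster identifiers are sequential opaque tokens assigned
in input order — not derived from the digest — and the digest-to-cluster
map is kept as a separate object, so shareable outputs cannot be attacked
with a dictionary of hashed identifiers.

Records with a missing or invalid identifier are never linked: each becomes
its own singleton cluster, flagged unlinkable. This accepts the risk of
missed duplicates in exchange for zero false merges, and the reconciliation
report (`reconcile_known_duplicates()`) surfaces exactly those suspects by
cross-checking digest clusters against externally asserted duplicate lists:
asserted pairs the digests confirm, pairs they missed (identifier-error
suspects), and digest-discovered links absent from the asserted list.

## The common data model

The CDM covers demographics, JIA classification (the eight ILAR
subtypes), serology (ANA, RF, HLA-B27), uveitis history, the eight core
outcome variables (active and limited joint counts 0–71, CHAQ 0–3, ESR,
CRP, physician and parent/patient globals 0–10, pain VAS 0–10) and
treatment episodes (drug, start/stop dates, route, dose, stop reason).
Three principles govern the mapping:

* **Most inclusive shared definition.** Where studies code at different
  granularity the CDM keeps the coarsest coding all studies can reach —
  ethnicity, for instance, collapses to Caucasian/Non-Caucasian because
  one study only ever recorded that dichotomy. The shipped YAML mapping
  tables are editable; the source codings in them are illustrative, since
  no public codebook exists for the real extracts.
* **Structural vs random missingness.** A variable a study never collected
  (pain VAS and stop reason in CHARMS; diagnosis date in CAPS and CHARMS;
  symptom-onset date and treatment route in the two biologics registers)
  is materialised as missing in every mapped record and flagged
  structural. The availability matrix is config, queryable via
  `availability()`, and an invariant — 100% missing for every unavailable
  (study, variable) — is asserted in the tests and audited by the analysis
  workflow.
* **No invention, no silent coercion.** A source value absent from a value
  map is an error naming the code and study; a missing source value is
  missing in the CDM; units are fixed (ESR mm/h, CRP mg/L) with no
  conversion attempted in this version.

## Time points, duplicates, inclusion

Month arithmetic is fixed in days for reproducibility: 3 months = 91 days,
6 months = 183, 12 months = 365, windows inclusive at both ends. Baseline
(T1) takes the latest visit in [−91, 0] days relative to drug start;
follow-up (T2) takes the in-window ([+91, +365]) visit minimising the
distance to day 183. Equidistant T2 ties go to the earlier visit — earlier
data are less contaminated by subsequent treatment changes; the choice is
ours and is config-visible. The narrower 4–8-month T2 variant is available
by overriding the window, and a property test asserts that widening the T2
window can never shrink a cohort.

Duplicate treatment records are resolved at the *person* level, never by
merging fields across records: mixing values measured on different dates in
different studies would fabricate visits that never happened. One record
per (person, drug class) is retained by study precedence. Only the top of
the hierarchy is externally motivated (CHARMS was designed for
treatment-response evaluation and has the lowest core-variable
missingness); the full default order CHARMS > BSPAR-Et > BCRD > CAPS is a
documented, configurable choice. Records tied within one study are
separated by fewer missing core outcome variables at baseline, then the
earlier start date, then record ID — a deterministic secondary rule.

Each record's **index episode** for a drug class is the earliest episode of
that class starting on or after 91 days before the record's study entry;
records whose class episodes all predate entry (pure treatment history)
fall back to the earliest such episode. This anchors cohort entry at the
course the registration is actually about, while letting the linked,
pooled history veto it: the treatment-naive criterion fails if *any* linked
record shows a same-class course starting earlier. Cross-study memory is
precisely what linkage buys. The four inclusion criteria (ILAR-classified
JIA; treatment-naive; course continued ≥ 91 days; ≥ 1 core outcome variable
non-missing at T1) are all evaluated — failures accumulate rather than
short-circuit — and the conservation ledger is exact: candidate records =
retained + duplicate-removed + excluded, checked identically in tests.
Anchoring the COV check at baseline is an interpretation (the criteria
predate time-point analysis); T1 is the natural anchor because every
eligible person must have one.

## Outcome measures

JADAS = PGA + PGE + min(AJC, cap) + clamp((ESR − 20)/10, 0, 10), with
cap 10, 27 or 71 by variant; all three caps sit behind one parameter
because the intended joint-count variant is not fixed by the resource. The
ESR-based score is the only variant in this version. ACR Pedi response at
level L requires ≥ 3 of the 6 core variables (PGA, PGE, CHAQ, AJC, LJC,
ESR — pain VAS is not one of the six) improved by ≥ L% with > 30% worsening
in ≤ 1. Percent change from a zero baseline is undefined, so a documented
rule applies: a zero baseline cannot improve, and counts as worsened iff
the follow-up value is positive. Both scores are computed for complete
cases only, with missing components named rather than imputed; imputation
is out of scope here.

## What the generator emulates — and what it does not

The generator is a first-class, tested module, not a fixture. It emulates
the *structure* of the four-study resource:

* **Overlap.** In exact-count mode the study-membership histogram is an
  input: singletons, within-study repeaters, and two/three/four-study
  individuals in configured numbers, plus extra within-study repeat
  records spread uniformly over the multi-record individuals (the true
  within-person distribution of the extras is not published; uniform
  assignment is our modelling choice). The calibrated configuration
  (`paper_calibrated_config()`) plants 5435 individuals and 7013 records
  with the published 197/961/142/4 multiplicities, which the linkage stage
  must then recover exactly. A stochastic mode with per-study enrolment
  probabilities exists for property tests.
* **Identifiers.** Valid modulus-11 numbers from the reserved,
  never-allocated 999 test range — realistic validation behaviour with no
  privacy risk. Identifier corruption substitutes one digit per affected
  record (always invalidating, per the check-digit property) and is logged
  in the planted truth; the calibrated configuration leaves corruption off
  because the published counts are post-correction, after reconciliation
  against known-duplicate lists.
* **Design heterogeneity.** CAPS records enter at diagnosis, the other
  studies at treatment start; visit schedules follow each study's design
  (6/12 months then annual for the registers and CAPS; 3 and 6 months for
  CHARMS); entry assessments fall on or up to 30 days before the entry
  date, follow-ups jitter ±30 days around their nominal offset. Each
  registration record carries the person's full episode history, so the
  same course surfaces once per record — exactly the duplication the
  person-level hierarchy is there to remove.
* **Distributions.** Demographics are calibrated to the published MTX
  cohort: 67.6% female, 87.3% Caucasian, ILAR subtype frequencies, age at
  onset Normal(6.6, 4.3) truncated at zero by redrawing (which raises the
  realised mean to ≈ 7.2 — the tests compare against the truncated-normal
  expectation, not the untruncated mean). Random missingness rates per
  variable default to the 10–60% band reported for such registries.

It does **not** model biology: follow-up disease-activity values decay
smoothly from baseline by construction, there are no treatment effects,
flares, or correlated missingness. Passing tests therefore demonstrate the
*mechanics* — linkage recovery, structural missingness, conservation,
window selection — on data with realistic shape, and say nothing about
clinical effect sizes. The published final cohort sizes (2899 MTX / 2401
TNFi / 1018 in both) depend on the governed data and are intentionally not
reproduction targets; the pipeline's cohort sizes land in the same order of
magnitude under default parameters, which is all that can be claimed.

## Numerical and degenerate-input choices

* Dates are ISO-8601 calendar dates; all offsets are integer days; rows
  with unparseable dates are quarantined in an error sidecar, never
  silently dropped.
* An empty record set summarises to an all-zero duplication report with
  the undefined percentage reported as 0; empty cohorts report `NA`
  percentages flagged `empty_cohort`.
* Percentages are reported to one decimal place; the duplicate-record
  percentage is by definition within [0, 100].
* Same-day visit ties in window selection resolve to the first row in
  input order, making bulk and per-record selection identical (tested
  against each other).
* All randomness flows from the single seed in the run configuration;
  reruns are byte-identical, asserted on file hashes in the manifest.

## Problem sizes used by the tests

The suite exercises the calibrated full-scale linkage (7013 records) once;
cohort-pipeline properties run on fixtures of 60–300 persons; the
oracle-equivalence sweep uses 100 fixtures of ≤ 500 records; the
sampling-bound checks (injected 30% missingness recovered within ±2 points,
planted 67.6% female within ±3) use one 2000-person fixture. These sizes
keep the full suite within a few minutes while leaving every statistical
assertion several standard errors of headroom.

## Known limitations

* Linkage is purely deterministic: children with a missing or mistyped
  identifier in one study remain split across clusters (surfaced, but not
  repaired — probabilistic linkage on names/dates of birth is out of
  scope).
* The shipped dialect codings are plausible reconstructions, not the real
  studies' codebooks; anyone harmonising real extracts must edit the YAML
  mapping first.
* No unit conversion, free-text cleaning, or imputation; JADAS-CRP and
  clinical-JADAS variants are not implemented.
* The secondary same-study tie-break (fewest missing COVs at T1) uses the
  baseline extract only; records could in principle be compared across all
  time points.
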