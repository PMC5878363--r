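---
title: "Methods: deterministic registry linkage and the linked care cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deterministic registry linkage and the linked care cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hivcarelink)
```

## The problem

Clinic-based HIV cohorts and health-department surveillance registries
see the same people through different windows. The clinic chart is rich
but blind to care delivered elsewhere (the *silent transfer*); the
surveillance registry is population-wide but thin, with incomplete
reporting of some laboratory streams. Neither database alone supports an
accurate care continuum — the nested proportions diagnosed → retained in
care (RIC) → on antiretroviral therapy (ART) → virally suppressed (VS).
`hivcarelink` implements the full triangulation pipeline: deterministic
multi-key record linkage between a clinical cohort and HIV/STD
surveillance registries, reconciliation of the matched records, and
continuum estimation on the pre- versus post-linkage data — together with
a synthetic dual-registry generator so that every stage can be validated
against a known truth with no patient data involved.

## Deterministic multi-key linkage

Person identity is carried by five fields: first name, last name, date of
birth, sex at birth, and (optionally) SSN. Identity fields are stored
verbatim; all cleaning happens at key-construction time and is
deterministic and idempotent (`normalize_component()`): names are
uppercased, diacritic-folded and stripped to letters, SSNs to exactly
nine digits, dates to `YYYYMMDD`, sex to `M`/`F`.

`build_keys()` derives eleven composite match keys per person (the HIV
variant; the STD variant drops the SSN-exact key, leaving ten — the STD
registry match does not rely on SSN). The catalogue spans the standard
deterministic-linkage key families: full exact composites (K2, K9),
phonetic composites built on American Soundex (K3, K8) that absorb most
misspellings, partial-name composites (K5 first initial, K10 first three
letters), SSN-bearing keys (K1, K7, K11), and two order-invariant keys.
The order-invariant forms deserve a note: because each key is matched
*separately* — key *k* of one registry joined only to key *k* of the
other — a key defined as "names swapped" would only ever match records
where *both* registries swapped, which detects nothing. K6 therefore uses
the alphabetically sorted name pair and K4 canonicalises the date of
birth as year + sorted(month, day), so a one-sided first/last swap or a
day/month transposition still produces exact agreement on that key.
A key whose required component is missing gets an empty key string and
can never match, which keeps missing SSNs from joining records.

Each key yields one candidate-pair dataset (`match_single_key()`);
`merge_and_dedup()` unions the eleven datasets by the (study ID,
surveillance ID) pair, accumulating the agreeing keys. A pair is accepted
when it agrees on at least `min_keys` (default 2) distinct keys, or on
the SSN-exact key alone — a near-unique identifier deserves singleton
acceptance; partial keys do not. True matches on clean records agree on
all eleven keys at once, so the 2-key threshold costs essentially no
recall on clean data and suppresses chance single-key collisions.
One-to-many conflicts resolve in favour of the strongest pair (SSN-exact
agreement outranks any key count, then the key count decides); exact ties
are flagged for manual review and withheld from the automated merge.
Both the catalogue and the acceptance rule are configurable; probabilistic
(Fellegi–Sunter) weighting is deliberately out of scope.

## Reconciliation of matched records

`merge_linked()` builds one analysis record per cohort person:

* **Diagnosis dates** — the earlier date wins regardless of source, for
  both HIV and AIDS diagnoses.
* **Vital status** — deceased if either source says deceased (surveillance
  death ascertainment is stronger than clinic follow-up).
* **Transmission risk** — a single category per person via a fixed
  priority order (default `msm_idu > idu > msm > heterosexual >
  perinatal > other_unknown`, configurable). The rule never synthesizes a
  combined category no source recorded: {msm, idu} reconciles to `idu`,
  not to `msm_idu`.
* **OI at AIDS** — OR across sources when either knows; missing only when
  neither does.
* **Race/ethnicity and residence** — the cohort value wins; surveillance
  disagreement on residence is tagged `both-conflict` in a provenance
  column rather than silently dropped.
* **Sex at birth** is a matching variable; a conflict sets a review flag
  and never silently overrides.
* **Laboratories** — the union of both sources passes through fuzzy
  deduplication (`dedup_labs()`): two results of the same type, one from
  each source, collapse when their dates lie within 7 days and their
  values agree — viral loads
  within 0.1 log10 or both below 200 copies/mL (below-detection results
  count as < 200), CD4 exactly equal by default. The survivor keeps the
  earlier date and, across sources, the cohort value. The pass is greedy
  in chronological order with a deterministic tie-break, so results do
  not depend on input order. These tolerances are conservative choices
  (a plausible reporting jitter of a few days; a log-scale band well
  under assay variability for VL) and are fully configurable through
  `fuzzy_lab_rule()`.

Participants co-enrolled at more than one cohort site are collapsed to a
single analytic record at their earliest enrollment before linkage
(`dedup_coenrollment()`), detected by exact SSN or full name+DOB+sex
agreement within the cohort extract.

## Continuum definitions

All outcome definitions live in `compute_continuum()` over a configurable
`analysis_window()` (default 2014-06-15 to 2015-06-15):

* **Eligibility** — actively enrolled with at least one year of follow-up
  by the window end, not withdrawn or transferred before the window
  start, alive. Exclusion reasons are tallied.
* **RIC** — two HIV-related encounters (visit or lab, dates deduplicated,
  any site) at least 90 days apart inside the window. "At least" is
  inclusive: exactly 90 days qualifies, 89 does not; window endpoints are
  inclusive; day arithmetic is exact calendar days.
* **On ART** — any prescription interval overlapping the window
  (inclusive; an open end date is an ongoing prescription). ART comes
  from the cohort source only, as surveillance does not collect it.
* **VS** — defined only among persons retained *and* on ART with at least
  one VL on file by the window end; true when the last-dated VL is
  strictly below 200 copies/mL. Same-date ties keep the cohort-origin
  value, then the lower value. Below-detection results are suppressed.
* **Ever-VS** — any VL < 200 between enrollment and the reference date.
* **LTFU** — no dated evidence of care for 18 calendar months or more as
  of the reference date (inclusive at exactly 18, same day-of-month
  anchor); a person with no dated events at all is LTFU and flagged
  degenerate.
* **Care sites** — from lab provenance: `one` if all labs (or none) are
  from the enrollment site, `three_plus` if ≥ 2 labs come from ≥ 2
  distinct other facilities, `two` otherwise.

Pre- versus post-linkage comparisons are computed over the identical
person universe (the matched, eligible set determined on the post-linkage
data), so the contrast isolates what the added surveillance data changes:
paired agreement per outcome (Cohen's kappa with the degenerate
all-one-cell table defined as 1), an independent chi-square on the
outcome margins (Pearson, no continuity correction), and Wilcoxon
rank-sum for continuous contrasts (exact enumeration when n1 + n2 ≤ 12
and tie-free, otherwise the tie-corrected normal approximation).
Kappa values are labelled strong (≥ .60), moderate (.40–.59) and poor to
fair (< .40) — reporting labels only. P values print in the
epidemiological style (`<.001`, `.016`, `>.99`); significance is flagged
at p < .05.

## The synthetic dual-registry generator

`generate_population()` draws a ground-truth cohort; `emit_registries()`
derives the three extracts from it. The generator's defaults encode the
study conditions the pipeline is meant to operate under:

* **Marginals** — sex 25.99% female; race 73.7/15.7/10.6% black, white,
  other; residence 74.1/18.8/5.7/1.4% DC/MD/VA/other; a care-site mixture
  of 76.83/15.49/7.68% for 1/2/≥3 sites; per-stratum suppression rates
  89.51/78.5/72.3% (multi-site patients fare worse; the 2-site value is
  interpolated between its neighbours).
* **Registry overlap** — 98.5% of residents appear in HIV surveillance,
  79% of non-residents (whose labs are reported to other jurisdictions),
  reproducing an overall match rate near 93% with non-residents dominating
  the unmatched.
* **Identity errors** (per surveillance/STD transcription; the cohort
  carries the enrolled identity as the reference copy, the standard
  simulation layout for linkage studies): typo 2% per name (always edit
  distance 1), day/month DOB transposition 2% (only when the day can be a
  month), SSN missing 15%, nickname substitution 3% from a packaged map,
  surname change 1.5% — per-field rates in the range reported for
  administrative registries.
* **Differential capture** — calibrated from the binomial capture model
  so the emitted registries show the real-world asymmetry: surveillance
  captures CD4 results at 98% regardless of value but suppressed VLs at
  only 30% (unsuppressed 85%), the cohort captures all labs at the
  enrollment site but only 30% of external labs. The resulting
  surveillance-to-cohort VL ratio is ≈ 0.37–0.39 with CD4 counts within a
  few percent of each other.
* **Care behaviour** — multi-site persons receive most labs away from
  their enrollment site (35–65% external) and keep fewer home-clinic
  visits; regular engagement in care rises with the site count (66%,
  75%, 93% for 1/2/≥3 sites — transient multi-site patients re-enter
  care more often), the rest are sporadic. A
  2-site person always has ≥ 1 lab at exactly one other facility and a
  ≥ 3-site person ≥ 2 labs at ≥ 2 other facilities, so the true site
  category equals the drawn stratum. 2% of persons are co-enrolled at a
  second cohort site; ~3% die; ~12% withdraw or transfer; diagnosis dates
  recorded by the clinic lag the true (surveillance) date in 30% of
  persons by 0.5–4 years.

Randomness is organised as one master seed with a documented per-person
substream derivation, so regenerating with more persons leaves earlier
persons bit-identical, and every run is reproducible byte for byte.

What the generator does **not** model: disease progression or
transmission dynamics, geographic structure, correlated comorbidities
(they are independent given the site-count stratum), realistic name
frequency distributions, or within-person trends in viral load
(suppression is a per-person state). Passing tests therefore demonstrate
that the pipeline's logic is correct under a faithful rendering of the
registries' structural asymmetries — not that any particular real-world
dataset would yield the same numbers.

## Numerical and design choices

* Problem sizes: the test suite exercises the full pipeline at 60–2,000
  persons, parameter recovery at 10,000, and the bundled analysis scripts
  run at 6,054; these sizes give sub-percent Monte-Carlo noise on the
  recovered proportions while keeping runs comfortable on one CPU.
* Acceptance of a linkage pair with fewer than two agreeing keys is
  refused even when that loses a true pair: under the default error
  rates ~0.5–1% of pairs (surname change or early-position typo plus a
  missing SSN) are genuinely unbridgeable by any deterministic key here,
  a floor that motivates probabilistic linkage but is out of scope.
* Zero-denominator percentage cells are an explicit `NA` marker;
  evaluation of an empty linkage reports precision 1 with a
  zero-denominator flag rather than 0/0.
* Whether "HIV-related encounter" includes ART prescription dates is an
  open definitional point; only visits and labs count here, keeping the
  encounter proxy independent of the ART outcome.
* Surveillance-only persons never enter any denominator: the analysis
  universe is always the enrolled cohort.
* Chi-square is computed without continuity correction (switchable in
  principle by calling `stats::chisq.test` directly); the pre/post
  outcome comparison uses an independent chi-square on the margins with
  the paired kappa reported alongside, since a McNemar-style pairing is
  not what the reporting convention of this literature shows.

## Known limitations

Deterministic linkage has no tunable trade-off curve: a pair either
agrees on enough keys or it does not, and heavily corrupted identities
without SSN are lost. Lab deduplication is greedy, so a chain of results
spaced just inside the window can collapse onto the earliest member.
The co-enrollment collapse relies on exact identity agreement within the
cohort and will miss a co-enrolled pair whose records disagree on every
exact key. Calendar-month LTFU arithmetic anchors on the day of month of
the reference date, which is one of several defensible conventions.
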