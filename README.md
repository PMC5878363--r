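# hivcarelink

Deterministic multi-key record linkage between a clinical HIV cohort and
health-department surveillance registries, with reconciliation of the
matched records and HIV care-continuum analysis on the pre- versus
post-linkage data.

## The problem

Clinic cohorts and surveillance registries each see only part of a
patient's care. A clinic chart misses labs drawn at other facilities
(*silent transfers*), so a clinic-only care continuum underestimates
retention in care (RIC); a surveillance registry receives CD4 results
reliably but suppressed viral loads (VL) incompletely, so it
overestimates viremia. Triangulating the two gives a more accurate
continuum — at the price of a linkage problem, since the databases share
no common identifier.

`hivcarelink` implements the whole workflow for people working with such
paired registries:

* **Linkage** — eleven deterministic identity keys (exact, phonetic
  Soundex, partial, SSN-based, and order-invariant composites of name,
  date of birth, sex and SSN) are matched separately and the per-key
  candidate sets merged; a pair is accepted on ≥ 2 agreeing keys or an
  exact SSN match. A ten-key variant (no SSN key) links the STD registry.
* **Reconciliation** — earliest diagnosis date regardless of source,
  deceased-if-either vital status, hierarchical transmission risk, fuzzy
  laboratory deduplication (±7 days; VL within 0.1 log10 or both < 200
  copies/mL; CD4 exact), per-field provenance tags, review flags for
  conflicts on matching variables.
* **Continuum** — eligibility filtering, RIC (two encounters ≥ 90 days
  apart in a 12-month window), on-ART, viral suppression (last VL < 200
  among retained-and-on-ART with a VL on file), ever-suppression, loss to
  follow-up (18 months), and receipt-of-care classification at 1, 2 or
  ≥ 3 sites from lab provenance.
* **Comparison statistics** — nested cascades with explicit numerators
  and denominators, paired Cohen's kappa, chi-square and Wilcoxon
  rank-sum tests, deterministic CSV report tables.
* **Synthetic dual registries** — a generator that draws a ground-truth
  population and emits cohort/surveillance/STD extracts with configurable
  identity corruption and differential lab capture plus the true match
  set, so the whole pipeline is testable end to end without patient data.

## Worked example

```r
library(hivcarelink)

cfg <- sim_config(n_persons = 2000, seed = 7)
res <- run_pipeline(cfg)

res$link
#> <link_result> 1863 accepted pair(s), 0 flagged for review, 138 unmatched cohort ID(s)
res$evaluation[c("precision", "recall")]
#> $precision
#> [1] 1
#> $recall
#> [1] 0.9941302
```

Precision and recall are measured against the generator's truth set: with
the default corruption model (2% typos per name, 15% missing SSNs, 3%
nicknames, 1.5% surname changes, 2% day/month birth-date transpositions)
the 11-key match recovers over 99% of true pairs without a single false
pair. The continuum contrast on the same run:

```r
res$comparison$cascade_pre[2:4, ]
#>   stratum stage  numerator denominator   pct
#> 1 overall ric          945        1620 58.33
#> 2 overall on_art       908         945 96.08
#> 3 overall vs           754         869 86.77
res$comparison$cascade_post[2:4, ]
#> 1 overall ric          984        1620 60.74
#> 2 overall on_art       946         984 96.14
#> 3 overall vs           786         910 86.37
```

Retention rises after linkage (surveillance labs reveal encounters the
clinic never saw) while measured suppression falls (the newly retained
are disproportionately multi-site patients with poorer outcomes) — the
signature pattern of registry triangulation. `res$status_post` holds the
per-person flags; `build_cascade(res$status_post, stratify_by_sites =
TRUE)` breaks the cascade down by the 1 / 2 / ≥ 3 care-site categories.

The `analysis/` directory stages the same workflow as numbered scripts
(`01_simulate.R` … `05_report.R`) writing their tables under `results/`;
the methods vignette (`vignettes/linked-care-cascade-methods.Rmd`)
documents every definition, tolerance and generator assumption.

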