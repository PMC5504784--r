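# perilink

Consistency checking and cleaning for probabilistically linked perinatal
administrative data.

## The problem

Perinatal cohorts are built by probabilistic linkage of birth
notifications, hospital and emergency department (ED) episodes, death
registrations, congenital-condition notifications and pharmaceutical
claims, across jurisdictions with incompatible person-identifier spaces.
Probabilistic linkage produces *false positive links* (another person's
records attached to a woman or baby) and *missed links* (one person split
across identifiers). Linkage units see identifiers but no content;
researchers see content but no identifiers — and content is where the
errors show, as biological and chronological impossibilities.

perilink implements a 22-step quality-assurance protocol over such a
cohort:

* **Steps 1–3** — uniqueness: identical and partial duplicates, death
  registration completeness, babyPPNs shared across birth records.
* **Steps 4–8** — within-person perinatal consistency: birthweight vs
  gestation screening, birth order vs plurality, pregnancy intervals, and
  the parity sequence. The two driving quantities are the conception date,
  `baby_dob − 7·g + 14` days for gestation `g` in completed weeks, and the
  inter-pregnancy interval `conception(next) − prior_delivery − 7` days —
  a negative interval is biologically impossible for one woman and
  indicates a false link. Parity must increase strictly across deliveries;
  recoverable gaps are imputed, single-digit slips (e.g. 0-1-2-13) are
  repaired, and interleaved sequences (e.g. 0-1-2-0-1) exclude the family.
* **Steps 9–16** — cross-source coherence: the baby's date of birth
  reconciled against hospital/ED records within the maternal delivery
  admission window, congenital notifications, mother's year of birth and
  recorded sex, births after hysterectomy, services after death, and
  admission/discharge ordering.
* **Steps 17–22** — cross-jurisdiction identifier resolution: claims links
  accepted at the recommended match-weight thresholds (≥29 in jurisdiction
  A, ≥28 in B), PATID↔mumPPN graph anomalies resolved into clusters or
  pruned, cluster and cross-state candidates validated by pooling records
  and re-running the person-level checks, and identifiers collapsed into
  `finalPPNmum` by the hierarchy CrossID → ClusterID → mumPPN.

Nothing is ever deleted or overwritten: every decision is an appended
entry in a flag ledger (person-level `exclusion`, record-level
`duplicate`/`deletion`, link-level `disregard_link`, field corrections,
and a review queue for cases the automated adjudication rules decline to
decide). Analyses consume filtered *views* derived from the ledger.

A seeded synthetic-cohort generator with labelled error injection is
included: clean draws pass every check by construction, and each of 22
injectable error classes records the flag and step expected to catch it,
so detection and false-positive behaviour are testable end to end.

## Worked example

```r
library(perilink)

coh <- generate_clean_cohort(cohort_config(n_mothers_per_jurisdiction = 150,
                                           seed = 42))
inj <- inject_errors(coh, error_plan(negative_interval_false_link = 3,
                                     parity_typo = 2,
                                     supply_after_death = 2, seed = 9))
res <- run_pipeline(inj)
res
#> perilink pipeline result
#>   flags: 13 (11 exclusion, 0 duplicate, 0 deletion, 2 link)
#>   corrections: 2, review queue: 0
#>   mothers: 307 mumPPNs -> 300 finalPPNmums (3 excluded)

summarize_pipeline(res)
#>    step_id           kind     n
#> 1:   S18.2 disregard_link     2
#> 2:    S6.4      exclusion    11
#> 3:  S8.2.4     correction     2
```

Reading the output: the three mothers given an overlapping pregnancy are
flagged for exclusion at step 6.4, and the 11 exclusion entries are those
three plus their children (family propagation: a false link implicates
the whole family). The two claims links whose supply postdates the
woman's death are disregarded at step 18.2. The two parity typos are
repaired, not flagged:

```r
ledger_corrections(res$ledger)[step_id == "S8.2.4"]
#>    record_id  field old_value new_value
#> 1:  P-000208 parity        13         3
#> 2:  P-000523 parity        11         1
```

307 mumPPNs collapse to 300 `finalPPNmum`s because the cohort's
cross-state women (two person numbers, one woman) are recognised at step
20 and merged at step 21. The ground truth for every injected error is in
`inj$truth`; the original tables are never modified.

A thin command-line front end is installed with the package
(`inst/scripts/perilink-cli.R`) with subcommands `synth`, `run` and
`report` over the same API.

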