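---
title: "Consistency checking and cleaning of linked perinatal data with perilink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consistency checking and cleaning of linked perinatal data with perilink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perilink)
library(data.table)
```

## The problem

Perinatal research cohorts are typically assembled by probabilistic record
linkage: birth notifications, hospital separations, emergency department
(ED) attendances, death registrations, congenital-condition notifications
and pharmaceutical claims are brought together under project-specific
person numbers without any shared unique identifier. Probabilistic linkage
is imperfect in two directions. A *false positive link* attaches another
person's records to a woman or baby; a *missed link* splits one person's
records across several identifiers. Neither can be detected by the linkage
units themselves, which see personal identifiers but no health content.
Researchers, who see content but no identifiers, can detect both — through
biological and chronological impossibilities in the linked content.

perilink implements a 22-step protocol for exactly this situation: a
mother–pregnancy–baby cohort spanning two jurisdictions (called A and B
here), each with its own person-number space (`mumPPN`, `babyPPN`), plus a
national pharmaceutical-claims identifier (`PATID`) connected to the state
spaces only through probabilistic mapping tables with match weights.

The steps fall into four groups:

* **Steps 1–3, uniqueness.** Identical duplicates in every source; partial
  duplicates of the same death adjudicated on discharge evidence;
  completeness of the death registration stream; and babyPPNs appearing on
  more than one birth record (different mothers sharing a babyPPN is a
  linkage error; the same mother twice is a double entry or an error,
  adjudicated over auxiliary fields).
* **Steps 4–8, perinatal consistency.** Birthweight–gestation outlier
  screening (documented, never altered); birth order versus plurality;
  pregnancy intervals; and the parity sequence. Parity — the count of
  previous pregnancies of at least 20 weeks — must increase strictly across
  one woman's deliveries, so an interleaved sequence such as 0-1-2-0-1 is
  strong evidence that two women's records were merged.
* **Steps 9–16, cross-source coherence.** The baby's date of birth checked
  (and, under strict safeguards, corrected) against hospital/ED records and
  the maternal delivery admission window; congenital notifications against
  birth records; the mother's year of birth, recorded sex, hysterectomy
  history, and the ordering of admissions, discharges and deaths.
* **Steps 17–22, cross-jurisdiction identifier resolution.** Claims links
  are accepted at the recommended weight thresholds; PATIDs matching
  several mumPPNs are resolved into clusters (missed state links) or
  pruned; links are dropped when supply postdates death; clusters and
  cross-state candidates are validated by pooling records and re-running
  the person-level checks; and identifiers collapse into `finalPPNmum`
  by the hierarchy accepted CrossID, then accepted ClusterID, then the
  mumPPN itself.

## Core quantities

Two derived dates drive the within-person checks. With gestational age $g$
in completed weeks and delivery date $t$,

$$\text{conception}(t, g) = t - 7g + 14 \text{ days},$$

the two-week offset arising because gestational age is counted from the
last menstrual period. The interval between consecutive pregnancies with
prior delivery $t_0$ is

$$I = \text{conception}(t_1, g_1) - t_0 - 7 \text{ days},$$

the 7-day allowance covering truncation of gestation to completed weeks.
$I < 0$ (conception strictly before the prior delivery) is biologically
impossible for one woman and flags the whole family. All date arithmetic is
exact day counts on calendar dates; there are no timezones and no
fractional days.

The parity assessment compares, per mother, the number of recorded
deliveries (`count`) with the span of recorded parity values
(`expected` = highest − lowest + 1) and the sequence class (strictly
increasing = logical). The exclusion rule for illogical sequences is
deliberately conservative: expected = 1 with count ≥ 4, or expected ≥ 2
with count − expected ≥ 2. Loosening the first clause to count ≥ 3 would
enlarge the excluded set considerably, which is why the stricter printed
form is the default and is not configurable.

## The flag ledger: never delete, never overwrite

Source tables are immutable. Every decision is an appended entry in a
ledger: person-level `exclusion` flags, record-level `duplicate` and
`deletion` flags, link-level `disregard_link` flags, field corrections
(old value, new value, step), and a review queue for cases an automated
rule declines to decide. Steps run in protocol order and each sees a
*view* with all earlier decisions applied, matching the
apply-before-next-step semantics of the protocol. Exclusion propagates
within families after every person-level step: a linkage error detected
for a child implicates the mother's link, and hence all of her children's
records — excluding only the problematic record would bias analyses that
use the prior pregnancy or inter-pregnancy exposure.

Because the ledger is append-only and idempotent (an identical entry is
recorded once), replaying the pipeline over its own output is a fixed
point: no new flags, an identity resolution map, and content-identical
re-derived corrections. Unresolved review-queue cases deliberately
persist — they carry no flag, so they surface again until a human decides.

## Automated stand-ins for manual review

The original protocol used on-screen scrutiny at three points. perilink
replaces these with conservative, auditable rules; anything the rules
cannot decide goes to the exported review queue rather than being decided
silently.

* **Suspected double entries (step 3.4).** The records are compared over
  the auxiliary review fields (baby DOB, plurality, birth order,
  birthweight, gestational age, Apgar score, discharge status, mother's
  age, postcode, country of birth, hospital). *Agreement* means every
  field with at least two non-missing values is constant and at least
  three fields are comparable; then one record is kept (lowest record id,
  for determinism) and the rest flagged duplicate. Disagreement excludes
  the mother.
* **Multi-match PATIDs (step 17).** The linkage unit's external advice is
  replaced by a pre-screen with the step-19 consistency battery: a
  consistent group of mumPPNs becomes a cluster; otherwise the
  highest-weight link is kept (ties broken by number of perinatal records,
  then lexicographically) and the rest disregarded, with a review-queue
  entry.
* **Partial death duplicates (step 1.2).** A hospital discharge with
  deceased status on one of the candidate dates selects that date;
  otherwise the case is queued.

## The consistency battery for identifier groups

Steps 19 and 20 validate candidate identifier groups by pooling the
members' records and re-running the person-level checks. Two rules are
deliberately stricter in this pooled context than their single-woman
counterparts. Any disagreement in perinatal mother year of birth across
members fails the group (the step-11 rule, two out-of-range records or
more than three distinct values, is tuned for noisy encounter data and
would let a two-member group with different YOBs pass). Likewise any
illogical pooled parity sequence fails the group, without the step-8.3.1
thresholds: for records claimed to belong to *one* woman, a single parity
inversion is already decisive evidence against the merge. These choices
also make accepted groups stable under re-integration: a merged cluster
necessarily passes the ordinary step-8 assessment afterwards.

For a rejected cross-state group, only the links of the PATIDs that
actually span both jurisdictions are disregarded, on one side: the side
carrying an exclusion flag if there is one, otherwise the side with the
lower match weight. A same-state PATID attached to the same network keeps
its link.

## The synthetic cohort generator

No real linked data can ship with the package, so validation rests on a
seeded generator whose clean output satisfies every rule by construction,
plus labelled error injection. The generator emulates:

* two jurisdictions with independent person-number spaces and one national
  PATID per woman;
* 1–6 pregnancies per mother (probabilities 0.30/0.35/0.20/0.10/0.04/0.01),
  singleton/twin/triplet probabilities 0.97/0.028/0.002, gestation centred
  on 39 completed weeks (earlier for plural pregnancies, range clipped to
  25–43), gestation-dependent birthweight clipped to 400–5000 g, and
  strictly positive inter-pregnancy intervals of 90–1000 days;
* per delivery: one perinatal record per baby (plurality *k* gives *k*
  records sharing maternal fields with birth orders 1..*k*), a maternal
  delivery admission spanning the birth date, and a newborn admission;
  additional hospital/ED contacts at Poisson rates; deaths (newborn deaths
  in hospital, with deceased discharge status; mother deaths registered
  after every recorded event); claims with the woman's month and year of
  birth; and congenital notifications for jurisdiction-A babies;
* mapping tables with one accepted link per woman per state of use (weight
  drawn at or above the threshold, 29 in A and 28 in B) plus sub-threshold
  decoy links in [17, threshold) at a 5% rate, exercising the extraction
  filter;
* cross-state women (default 1%) generated as two mumPPNs sharing one
  underlying woman, with parity continuing across the move — the true
  positives that step 20 must find.

These defaults are stated once here as the package's study conditions and
are not tuned against test outcomes. Two simplifications are worth
noting. Clean cohorts carry death registrations only; a separate
causes-of-death stream appears only under injection, because any second
death record for one person — whatever its stream — is treated as a
partial duplicate by step 1.2. And clean cohorts contain no within-state
split women; identifier splits are an injected error class with recorded
ground truth.

What passing tests on this generator shows is that every detection rule
fires exactly where it should and nowhere else, on data whose errors are
known. What it cannot show is performance on real administrative data,
where error classes co-occur, missingness is structured, and prevalences
are unknown — the injection rates here are arbitrary by design and carry
no epidemiological meaning.

Error injection uses an RNG stream independent of the generator, so the
clean cohort is reproducible under varying plans. Each of the 22 error
classes touches only families no other injection touches and appends a
ground-truth row naming the flag and step expected to catch it. For
deterministic classes (e.g. negative interval, birth after hysterectomy,
supply after death) recovery is exact; review-adjudicated classes
(partial duplicates without evidence, ambiguous DOB reconciliation) are
guaranteed to land either in a flag or in the review queue.

## Numerical and boundary decisions

* 20 weeks = 140 days, read literally: a DOB gap *under* 140 days is
  "less than 20 weeks" (age corrected at step 9.4), a gap *over* 140 days
  is "more than 20 weeks" (exclusion at step 14.3), and exactly 140 days
  is neither — such records are flagged for deletion, the conservative
  record-level action.
* The pregnancy-interval exclusion is strictly `< 0`; an interval of 0 is
  not flagged. The death allowance is strictly more than 3 days; supply
  after death is a strict inequality, so a claim on the death date is kept.
* Year-of-birth validity windows (babies 1920–2014, mothers 1900–2014) and
  the weight thresholds are configuration with the recommended defaults;
  the plausible mother-YOB range of step 11 is always re-derived from the
  perinatal data at hand.
* Step 8 typo repair considers a single record changed in one decimal
  digit, or a value of 10 or more among single-digit neighbours, and only
  accepts a repair that makes the sequence strictly increasing with
  expected = count; ambiguity (more than one candidate repair) leaves the
  sequence as a documented grey inconsistency. The search triggers when
  expected − count ≥ 4 or expected ≥ 10, so a sequence like 0-1-2-6-4
  (expected − count = 2) stays grey rather than being "repaired".
* With unresolved duplicate death dates (review cases), the earliest date
  is used for the service-after-death comparison.
* Step 9.4 corrects the encounter's recorded age but leaves its patient
  DOB in place: step 14 needs the original discrepancy between patient DOB
  and the updated DOB to grade its severity.
* All tie-breaks (kept record in a duplicate group, kept link on equal
  weights) are deterministic: lowest record id, then most perinatal
  records, then lexicographic order.

## Problem sizes used in the test suite

The bundled validation runs on cohorts of 1,000 mothers per jurisdiction:
twenty clean seeded cohorts for the zero-false-positive property, one
cohort with 25 injected instances of each deterministic error class for
the recovery property, 10,000 sampled date/gestation pairs against an
independent day-count oracle, and 200 random bipartite identifier graphs
of up to 50 nodes against a transitive-closure oracle. These sizes give
stable properties (250 independently placed error families among 2,000)
while keeping the default check fast.

## Known limitations

* The hysterectomy procedure-code list is configuration; the bundled file
  is a synthetic format example, not a clinically curated list.
* Identification of delivery admissions uses an explicit `is_delivery`
  marker; deriving delivery admissions from diagnosis/procedure codes is
  out of scope and must happen upstream.
* The automated stand-ins for clerical review are conservative proxies;
  on real data their review queues should be worked by a human, and the
  step-17 pre-screen is this package's rule, not the original linkage
  unit's criteria, which were never published.
* Only two jurisdictions are supported; the mapping schema rejects others.

## A short session

```{r example}
coh <- generate_clean_cohort(cohort_config(n_mothers_per_jurisdiction = 150,
                                           seed = 42))
inj <- inject_errors(coh, error_plan(negative_interval_false_link = 3,
                                     parity_typo = 2,
                                     supply_after_death = 2, seed = 9))
res <- run_pipeline(inj)
res
summarize_pipeline(res)
head(inj$truth[, .(error_class, expected_flag, expected_step)])
```
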