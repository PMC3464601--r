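---
title: "Linked versus unlinked discharge data: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linked versus unlinked discharge data: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the data
model the generator emulates, the selection and ascertainment rules,
every tunable parameter with its default and rationale, the numerical
conventions, and the places where a genuinely open design question was
decided one way rather than another.

## The problem

Hospital discharge data are generated per *episode of care*, not per
person. Without a system-wide unique patient identifier, a single
fall-related hip fracture in an older person can be counted several
times: the sending and receiving episodes of an inter-hospital
transfer, early readmissions for staged surgery or complications,
care-type changes, and revision procedures all produce fresh records.
Counting episodes therefore overestimates incidence, and because the
extra records are coded less completely than the index admission, any
patient profile built from them — comorbidity prevalence above all — is
distorted too.

The package quantifies this bias by running both pathways over one
dataset in which the truth is known by construction:

1. a **linked pathway**: internal deterministic linkage collapses
   episodes to persons, and a reference-standard selector identifies
   incident fractures person by person;
2. an **unlinked pathway**: five selection heuristics (base case and
   variants S1–S4) that operate on episodes alone.

Every downstream comparison — confusion matrices, overestimation,
prevalence differences, rates — is then an exact computation, because
the generator labels each episode with its true person and true
incident event.

## The synthetic cohort

`simulation_config()` holds every parameter; `simulate_cohort(config,
seed)` is deterministic given both. The defaults define the study
conditions:

* **Window**: 1 July 2005 – 30 June 2008 (fiscal years 2005/06–2007/08).
* **Persons**: 20,000 by default; 72% female; ages drawn from a
  lognormal truncated to [65, 105] and fitted numerically (three-point
  least squares on the quartiles) to median 81, IQR 72–86. A
  two-parameter family cannot hit an asymmetric quartile triple
  exactly; the truncation at 65 compresses the lower tail enough that
  the fit lands within a year of each target.
* **Residence**: 25% of persons live in nursing homes. Their fractures
  appear in the data with admission source `nursing_home` and are
  outside the community-dwelling incidence scope — every selector
  requires admission from private residence, so these episodes
  populate the true-negative pool. Ground-truth incident labels are
  likewise restricted to community dwellers, keeping the oracle and
  the selectors on the same estimand.
* **Fracture risk**: the probability of a first fall-related hip
  fracture over the window is 0.12 at age 80 and doubles every 6 years
  of age (capped at 0.9), producing the strong age gradient admission
  rates are known to show. The cohort is deliberately case-enriched
  relative to a general population — it stands in for an extract of
  fall-injury admissions, not for the population at large; the
  population table (below) carries the denominators that make rates
  meaningful.
* **Second fractures**: 2.3% of fractured, surviving persons sustain a
  second fracture. The admission-to-admission gap is lognormal with
  median 335 days (log-sd 0.69, matching an IQR of roughly 216–551
  days), truncated below at 120 days, and the second admission is
  additionally forced to start at least 121 days after the first
  chain's last discharge, so the clearance rule's assumptions hold by
  construction. So that the realised second-fracture fraction is
  exactly binomial at the configured rate, persons destined for a
  second event have their first event placed early enough in the window
  to fit it (and that first chain carries no readmission episodes);
  this mild conditioning affects 2.3% of events and is the price of a
  clean parameter-recovery property. The second event's external-cause
  triple differs from the first in all three components with
  probability `second_triple_differs` (default 1 — the assumption the
  reference standard relies on; lower it to study the rule's failure
  mode).
* **Event chains**: each event yields an acute emergency index episode
  (principal diagnosis S72.0–S72.2, fall mechanism W00–W19, a place and
  activity code, fixation/arthroplasty procedure codes). With
  configured probabilities it gains a transfer pair (sender discharged
  with status `transfer`, receiver admitted from source `transfer` at
  another hospital the same or next day), a readmission within 30 days
  of discharge, and/or one at 31–120 days. Readmission episodes are
  non-emergency with probability 0.5, non-acute with probability 0.2,
  and revision-procedure-only with probability 0.15. In-hospital death
  (probability 0.055) occurs during the index acute admission and ends
  the chain — clinically, that is where hip-fracture deaths happen, and
  it is what makes the death-exclusion contrasts between scenarios
  visible.
* **Nuisance-rate defaults.** The frequencies of transfers and
  readmissions in real extracts are not published directly, but the
  published accuracy structure of the unlinked heuristics constrains
  them tightly: a ~10% base-case overestimate that barely drops when
  the readmission window is extended from 30 to 120 days implies that
  detectable 120-day readmissions are rare (`readmission_120d_prob` =
  0.02) while same-event readmissions overall are common
  (`readmission_30d_prob` = 0.40); the large further drop under the
  stricter S3 criteria implies most duplicate episodes are
  non-emergency, non-acute or revision-only; and the sensitivity gap
  between excluding and including deaths matches an in-hospital death
  share near 5–6%. These defaults were derived once from that
  arithmetic and then frozen.
* **Non-fracture fall injuries**: Poisson(0.5) episodes per person over
  the window with principal diagnoses in S00–T75/T79 outside
  S72.0–S72.2. They give specificity a denominator and the lookback a
  pool of prior records, mirroring the fact that a fall-injury extract
  contains far more than hip fractures.
* **Hospitals**: 60 public and 40 private; each person has a usual
  hospital (public with probability 0.80); readmissions return to the
  previous hospital with probability 0.809, so about 64.7% of
  readmissions are to the same public hospital — exactly the fraction
  of repeat admissions an unlinked analysis can recognise, since
  private hospitals expose no usable site identifier and different
  hospitals share no patient identifier.
* **Boundary censoring**: `prestart_event_fraction` places that share
  of first events before the window start, so their index episode is
  missing from the dataset while later chain episodes remain —
  emulating left-censoring of the lookback window. The default is 0
  because a nonzero share necessarily breaks exact oracle agreement
  (an orphaned readmission can qualify as an incident); switch it on
  to study that failure mode deliberately.

### Linkage keys and their corruption

Each episode records sex, date of birth, postcode, a ten-digit
Medicare-number surrogate and country of birth as captured at
admission. `corrupt_linkage_keys()` perturbs them independently per
episode: date-of-birth errors (wrong day — possibly an impossible
calendar date, which key standardisation later flags and treats as
missing — or a one-year shift) with probability 0.13, postcode changes
0.12, missing Medicare 0.22, a mis-keyed Medicare digit 0.04. In
addition 1.6% of persons share a family Medicare number with another
cohort member, which is what gives the Medicare-only pass a realistic
false-positive mechanism. These five values were calibrated jointly —
once, over seven seeds at n = 20,000 — so that the default passes
yield a transfer-pair false-negative rate near 0.15 and a matched-pair
false-positive rate inside [0.01, 0.02], the error regime reported for
production internal linkage of this kind; they were then frozen.

### Population table

`population_table()` emits one row per fiscal year × sex × five-year
age band (65–69 … 85+): a population estimate whose age–sex proportions
equal the cohort's sampling proportions, the number of nursing-home
residents (the configured fraction), and the community denominator
(their difference). The total, 268,000 persons 65+, is the one free
scaling constant; it is set so that the directly standardised admission
rate lands at the published order of magnitude for this outcome
(~500 per 100,000 per year). The same table's first year, sexes
combined, is the default standard population for direct
standardisation.

## Internal linkage

`standardise_keys()` trims and case-folds strings, unifies null
markers, validates postcode (four digits) and Medicare (ten digits)
formats, and parses dates of birth — an impossible date flags the
episode and becomes a missing key rather than an error. Missing keys
never match anything; there is no wildcard matching.

`link_records()` applies ordered passes; within a pass, episodes
agreeing exactly on every pass key are merged by union-find, and merges
are transitive across passes, so the result is an equivalence partition
independent of row order (person identifiers are assigned canonically
from the smallest episode id per cluster). The default passes are
(1) sex + date of birth + Medicare, (2) sex + date of birth + postcode
+ country, (3) Medicare alone. This three-pass set is a documented
configuration default standing in for a production system's longer
step list, which is not public; the pass structure is configurable for
exactly that reason.

`linkage_quality()` scores a result against truth. The false-negative
rate is the fraction of same-person transfer sender/receiver pairs left
in different clusters — transfers are the one record type where the
data themselves prove two episodes belong to one person, which is why
production linkage audits use them. The false-positive rate is the
fraction of within-cluster episode pairs whose true persons differ,
over all within-cluster pairs. Zero denominators report `NA`, never 0.

## Case selection

`extract_fall_injury_episodes()` applies the three entry conditions
(fall mechanism W00–W19; principal diagnosis S00–T75 or T79, a range
chosen to exclude injuries from medical care; age 65+). Code tests are
structural string comparisons on the dotted ICD-10-AM forms; malformed
codes exclude the episode with a message.

The six selectors share the inclusion core — hip-fracture principal
diagnosis (S72.0–S72.2) and admission from private
residence/accommodation — and differ in exclusions:

| | base | S1 | S2 | S3 | S4 | reference |
|---|---|---|---|---|---|---|
| in-hospital death excluded | x | | x | x | | |
| readmission ≤ 30 d excluded | x | x | x | x | x | (clearance) |
| readmission ≤ 120 d excluded | | | x | x | x | (clearance) |
| revision-only excluded | | | | x | x | x |
| non-acute excluded | | | | x | x | x |
| non-emergency excluded | | | | x | x | x |
| person linkage | | | | | | x |
| external-cause rule | | | | | | x |

Conventions that needed deciding:

* **Windows and gaps.** "Within 30/120 days of discharge" is read
  inclusively: gap = next admission date − previous discharge date, in
  whole days, excluded when 0 ≤ gap ≤ window. The clearance period
  requires gap ≥ 120. The generator schedules second events at ≥ 121
  days so the boundary day, where the exclusion window and the
  clearance bound would touch, does not arise in synthetic data; both
  bounds are arguments and can be moved.
* **Unlinked readmission detection** uses the only person identity an
  unlinked dataset carries: the (hospital, hospital-generated patient
  id) pair, and only when both episodes are in public hospitals. The
  prior episode searched for must itself be a hip-fracture episode: a
  readmission is only recognisable as a readmission *for the same
  condition*. (Matching against any prior fall record would let an
  unrelated wrist-fracture admission three months earlier suppress a
  genuine hip-fracture index — a sensitivity loss the published
  accuracy structure of these heuristics does not show.)
* **Unlinked pseudo-person**: (hospital, patient id) in public
  hospitals, the episode itself elsewhere.
* **Reference-standard clearance anchor.** Within a person, qualifying
  episodes (emergency, acute, non-revision-only, private residence,
  hip-fracture diagnosis; discharge status disregarded) are processed
  in admission order. The first founds an incident. Every other
  hip-fracture episode of the person extends the current incident's
  chain, advancing the anchor to its discharge date (a rolling
  anchor): whether a later admission is "120 days clear" is judged
  against the end of the care episode, not its beginning. A later
  qualifying episode founds a new incident only if it clears the
  anchor by ≥ 120 days *and* its external-cause triple differs from
  the current incident's in all three components. The triple rule can
  be switched off (`use_external_cause_rule = FALSE`) to reproduce the
  clearance-only sensitivity analysis.
* **"Revision-only"** means a non-empty procedure list every code of
  which is in the configured revision set; an episode carrying a
  revision code plus a fixation code is retained.
* **Same-day ties** are ordered by (admission date, discharge date,
  episode id) for a deterministic "first".

## Comorbidity

The engine is code-list-agnostic: `inst/extdata/comorbidity_codes.csv`
maps each condition to ICD-10 prefixes with a Charlson flag and Deyo
weight, covering the seventeen Deyo–Charlson conditions and five risk
factors (osteoporosis, Parkinson's disease, visual impairment,
deafness, delirium). The shipped prefixes are a published-style ICD-10
mapping assembled for this package — a faithful stand-in, clearly
replaceable, not a reproduction of any jurisdiction's validated list.
The loader rejects prefix overlaps between conditions except inside
the declared severity hierarchies (diabetes with/without complications,
mild versus moderate/severe liver disease, cancer versus metastasis),
where the index counts only the severer member; prevalence tables keep
both, as comorbidity tables conventionally do.

A condition is present if at least one mapped code with condition-onset
flag *present on admission* appears on the index record or — linked
pathway with lookback — on any earlier record of the person in the
dataset. Codes flagged *arose during episode* never count: that is the
onset flag doing the work of separating comorbidity from in-hospital
adverse events. The index record is the first multiday episode of the
incident's chain (administrative same-day records carry little
diagnosis coding), falling back to the index episode itself. The
unlinked pathway has no person identity, so it searches only the
identified episode; that asymmetry, plus per-episode under-coding
(`per_episode_coding_prob`, default 0.70, with 5% of coded conditions
flagged as hospital-acquired), is what drives unlinked prevalence
estimates below linked ones. Lookback is limited to records in the
extracted (fall-related) dataset — reproducing the real limitation
that one only sees a patient's earlier admissions if they were also
fall-related.

## Evaluation

* **Unit of analysis.** Labels are per extracted *episode*: the
  confusion matrix cross-classifies every extracted fall-injury episode
  by reference label × scenario label. Whether published accuracy
  figures of this kind are computed over episodes or over fracture
  events is typically not stated; episodes are used here because both
  pathways label them directly, and the choice is surfaced rather than
  hidden.
* **Specificity denominator.** True negatives are all extracted
  episodes labelled non-incident by both the reference and the
  scenario. This is the single largest analytic judgement call in the
  package: nothing smaller (e.g. hip-fracture episodes only) gives
  specificity a stable meaning across scenarios.
* **Confidence intervals** are Wilson score intervals at 95% by
  default (the interval never leaves [0, 100] and always contains the
  point estimate); Clopper–Pearson exact and Wald intervals are
  available, since the CI method behind published tables of this kind
  is usually unnamed.
* **Proportion tests**: two-sample chi-square without continuity
  correction, switching to Fisher's exact test when any expected cell
  is below 5; two-tailed.
* **Rates**: cases per 100,000 community denominator per fiscal year ×
  sex × age band; direct standardisation collapses sexes within age
  band and weights by a fixed standard population, normalised to sum
  to one. Reported percentages are conventionally rounded to one
  decimal, half-up; all computation is at full precision.
* Two reference standards are evaluated side by side — one built on
  the truth partition, one on the linkage output — so users can
  separate selection-rule bias from linkage error. A production
  analysis conflates them of necessity; a synthetic one need not.

## Numerical and testing conventions

Determinism is absolute: a single seed governs every stochastic stage,
and identical configuration plus seed reproduces byte-identical CSVs.
The test suite works at three scales: hand-built fixtures of two to
five episodes for every boundary rule; cohorts of 800–8,000 persons
for property checks (partition validity, monotonicity of passes and of
exclusion flags, idempotence of selection, lookback monotonicity); and
one shared 20,000-person run for calibration and parameter-recovery
checks — second-fracture fraction, in-hospital death rate,
same-public-hospital reuse, linkage error bands, and comorbidity
prevalence recovery under full coding — each tested against exact
binomial 99% intervals (prevalence recovery familywise: at least 90%
of the 22 conditions inside their interval, since 22 simultaneous 99%
tests would fail by chance alone in about one run in five). These
sizes are the package's chosen study scale; the recovery checks match
the scale at which the emulated quantities were reported.

## What passing tests do and do not show

The generator emulates the *structure* the analysis assumes: episode
chains per event, the specific error regime of deterministic linkage,
under-coded comorbidity with onset flags, detectability limits of
unlinked readmission checks. It does not emulate casemix funding
fields, seasonal admission patterns, secular trends in incidence
(years are exchangeable by construction), coding-practice drift,
correlated comorbidity (conditions are drawn independently), or
laterality (the coding system of the emulated era lacked it). Passing
the suite therefore shows that the pipeline's logic is correct and
that its estimators recover known parameters under the stated model —
it does not certify any particular real-world dataset, whose nuisance
rates must be expected to differ. The configuration surface exists so
that users can move every one of these assumptions and watch the
accuracy structure respond.
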