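---
title: "Alert-driven recruitment: model, accounting and bias monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alert-driven recruitment: model, accounting and bias monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctalert)
```

## The recruitment model

`ctalert` models recruitment through a clinical trial alert (CTA) embedded in
general-practice software. The unit of observation is an *EPR opening*: every
time a patient's electronic record is displayed, the tool checks the
demographic inclusion rule — women with completed age ≥ 60, men ≥ 70, both
evaluated at the date of that opening — and, for eligible patients, fires an
on-screen reminder while transmitting a pseudonymised identification record
to the study centre. Because age is evaluated per opening rather than at
study start, patients who cross a threshold mid-study enter the net sample at
their next visit, and the net sample is by construction the set of eligible
patients who generated at least one *recorded* opening.

Each identified record then evolves through a small state machine:

* `OPEN` — identified, no decision yet. Clicking the reminder off does not
  change the state; the alert re-fires at the next opening. Unfinished
  surveys also count as open (state `SURVEY_IN_PROGRESS`), since they can be
  resumed at a later visit.
* `EXCLUDED` — staff documented an exclusion criterion (psychiatric
  disorder, language barrier, patient not physically present, other).
  Absorbing.
* `REFUSED` — contacted and declined. Absorbing.
* `ENROLLED` — contacted, consented, survey completed. Absorbing.
* `DECEASED` — the opened EPR belongs to a deceased patient. Absorbing.

Only `OPEN` and `SURVEY_IN_PROGRESS` admit further recruitment events; on the
four absorbing states a plain EPR opening is tolerated (the alert no longer
fires) and anything else is a protocol error. `replay_log()` folds an event
log through this machine and additionally enforces that recruitment events
follow a same-day identification event, that refusals and consents follow a
contact, and that exclusions carry a reason. Replay is deterministic, so the
registry is a pure function of the log.

### Funnel accounting conventions

`funnel_counts()` classifies each record once, by final state, into
`identified = open + excluded + contacted` and
`contacted = refused + enrolled`. Two conventions make these identities exact
on the bundled reference data:

* Surveys in progress are reported inside *open* with a separate sub-count.
  In the reference study this preserves the 43-of-1,569 unfinished-survey
  accounting: the package reports the recomputed completion rate of 97.3%
  (1,526/1,569), not a re-rounded one.
* Deceased records are a separate absorbing state but are reported inside
  the *exclusion* arm with a separate sub-count. The reference funnel
  (10,906 + 3,248 + 1,913 = 16,067) leaves no separate slot for its 22
  deceased EPRs, and treating a noted death as one more reason recruitment
  ended at the review step is the most conservative reading; the sub-count
  keeps the information visible.

Percentages in the per-practice table are rounded half-up to one decimal and
prose-style percentages half-up to integers, which is the convention of the
reference tables (base R's `round()` would round half to even). The
small/large practice threshold (600 identified EPRs), the per-practice target
(200) and the poor-recruiter cutoff (5%) are arguments with the reference
study's values as defaults.

### The bundled reference tables

`cta_reference_practices()`, `cta_reference_funnel()` and
`cta_reference_strata()` carry the published per-practice, funnel and
stage-demography tables of a 12-month osteoporosis-survey recruitment study
in 25 German practices. The demography source prints stage and sex totals as
counts but the age-band interior only as percentages, so
`cta_reference_strata()` reconstructs integer counts by constrained rounding:
counts were chosen so that every within-column share reproduces the printed
value at one decimal, columns sum to the printed totals, and each stratum's
net count equals the sum of its outcome counts (funnel conservation). One
inconsistency in the source cannot be reconstructed: the men's open-stage
age shares as printed (41.5/58.5) contradict the men's net-sample shares
(56.4/43.6) under conservation — the row sums would give 44.3/55.7. Interchanging
the two cells restores consistency to within rounding, so the reconstruction
adopts the interchanged orientation (58.5/41.5); every other printed share
reproduces exactly at one decimal. `cta_reference_log()` expands these
marginals into a replayable event log; the joint allocation of strata to
practices and the timestamps are deterministic conventions, not data.

## Pseudonymisation

Study IDs are HMAC-SHA256 digests of the practice-internal patient ID under a
per-practice secret, truncated to 128 bits. This gives determinism (the same
patient always maps to the same study ID, so repeat openings accumulate on
one record), injectivity for any realistic panel (collision probability
< 10⁻²⁰ at 10⁵ patients), and one-wayness: without the practice-held key the
internal ID cannot be recovered, matching the contract that re-identification
is possible only inside the practice.

## The practice simulator

The simulator exists so that every downstream stage — replay, funnel
accounting, bias testing, suppression — can be exercised against known ground
truth. It deliberately emulates the *mechanics* of alert-driven recruitment,
not general-practice reality:

* **Panels** (`generate_panel()`): patients i.i.d. from a stratum
  distribution, birth dates uniform within band (80+ capped at 95), a small
  deceased fraction (default 0.15%, the order of the reference study's 22 of
  16,067) whose EPRs may still be opened.
  The default demography is the reference net sample: 72% women split
  29.2/32.4/38.4 across the bands, 28% men split 56.4/43.6.
* **Visits** (`simulate_visits()`): a homogeneous Poisson process per
  patient — the source material gives no visit model beyond identification
  firing on EPR opening — with a default rate of 0.5 openings per patient
  per month, a value we fixed once as plausible for this age group in German
  general practice (the reference study prints no visit frequencies; results
  that depend on it are always stated per recorded visit or per contact).
  Times are uniform over practice hours (08:00–18:00) of uniform study days,
  in whole seconds so that the JSON-Lines serialisation is lossless. Each
  opening is flagged `physically_present` with probability
  `1 − not_present_prob` (default 0.2, feeding the house-bound exclusion
  reason); openings inside configured downtime windows are flagged
  unrecorded — visible to the oracle, invisible to the registry.
* **Staff** (`staff_behaviour()`, `simulate_staff()`): at every recorded
  opening of an alerting record, staff respond with probability `p_respond`
  (times an optional per-stratum multiplier — the bias injector — capped at
  1), otherwise click off. Responses split into exclusion versus contact,
  contacts into refusal versus consent-and-survey; a started survey is
  interrupted with `p_interrupt_given_start` and resumes at the patient's
  next recorded visit. All transitions are legal by construction.

The default behaviour probabilities are calibrated analytically to the
reference funnel: with per-visit response probability $r$ and $N \sim
\mathrm{Pois}(\lambda)$ recorded visits, a patient is ever reviewed with
probability $1 - e^{-\lambda r}$; at the default $\lambda = 6$ (0.5/month ×
12 months), $r = -\ln(1-0.32)/6 \approx 0.064$ gives the reference 32%
reviewed share. The branch probabilities are the reference stage ratios:
exclusions 3,248/5,161 of responses, refusals 387/1,913 of contacts,
interruptions 43/1,569 of starts. Final in-progress counts run slightly below
the interruption probability because resumed surveys complete; the
approximation is immaterial at these rates.

Randomness is reproducible: panels and visit streams use sub-seeds derived by
hashing (master seed, practice label, role) into [0, 2³¹), the staff pass
pre-draws all its uniforms under one sub-seed, and the same master seed gives
a byte-identical log file.

## Bias monitoring

`stage_demography()` tabulates records by stage and stratum;
`representation_ratio()` is a stratum's enrolled share over its net share
(scale-invariant; 1 = proportional). `chi_square_bias_test()` runs the
Pearson test on the 2×k stratum table. Its default mode compares enrolees
against net-sample *non*-enrolees: the descriptive "net sample vs enrolees"
comparison uses overlapping groups (every enrolee is in the net sample),
which breaks the independence the test assumes, so the overlapping variant is
kept only as an explicit option (`enrolled_vs_net`) for reproducing the
descriptive framing. Degenerate tables (a zero expected cell) are refused
rather than patched, and no continuity correction is applied — with
thousands of records per margin it would only blur the statistic. The source
reports no test statistics, so there is nothing numeric to match; the
package's statistic is instead verified against an independently coded
Pearson formula in the test suite.

`registry_consistency()` audits capture completeness: the fraction of
oracle-identified records (full panel query, i.e. all identification events
including unrecorded ones) that the registry holds. Under the simulator a
patient is missed exactly when all of their $N \sim \mathrm{Pois}(\lambda)$
visits fall into downtime covering a fraction $f$ of the study, so the
expected overlap has the closed form
$1 - e^{-\lambda}(e^{\lambda f}-1)/(1-e^{-\lambda})$, which the tests use as
the oracle. Real-world overlap additionally reflects software failures and
query imprecision and is not reproducible from first principles.

### Adaptive suppression

`suppression_policy()` implements the counter-measure that the real-time
registry makes possible: once at least `min_enrolled` patients are enrolled
(default 50 — below that, shares are too noisy to act on), a stratum is
suppressed whenever its enrolled share exceeds its net share by more than
`tolerance` percentage points (default 5, roughly twice the binomial
standard error of a share at the activation threshold), and released as soon
as the excess falls back within tolerance. Suppressed strata receive no
reminder (`should_alert()` is false), so their enrolment pauses while
under-represented strata catch up. In `simulate_study()` the policy pools
registry counts across practices, as a study centre would. The paired
simulations in the test suite (biased staff multipliers, 50 seeds) show the
median total-variation distance between enrolled and net demography drops
with the policy on; suppression cannot *create* enrolments in strata the
staff never contact, so it narrows but does not eliminate bias.

## Numerical and design choices

* Half-up rounding everywhere a table or prose percentage is produced;
  unrounded shares everywhere a decision or ratio is computed.
* Demography vectors must sum to 1 within 1e-9; downtime windows must lie
  within the study window; probabilities are validated into [0, 1].
* Completed age uses calendar years with a month/day comparison; a Feb-29
  birthday completes on Mar 1 in non-leap years.
* Event-log files are JSON Lines with a closed schema; the writer is
  byte-deterministic and the reader reports the first offending line.
* Test problem sizes are chosen so the full suite runs in about two minutes:
  parameter recovery uses one practice of 11,000 patients (≥ 10,000
  contacts), registry consistency 50 seeds × 300 patients, the suppression
  comparison 50 paired runs × 2,500 patients (≥ 500 enrolees per arm).

## Limitations

The simulator's staff model is memoryless and stationary: no fatigue, no
learning, no weekday structure, no within-day scheduling, and visit rates are
homogeneous across patients. It emulates none of the undocumented selection
channels flagged for real recruitment (education, communicativeness, visit
timing), so a passing suppression test shows the policy corrects *demographic*
imbalance under the modelled behaviour — not that it would remove bias of
unknown origin in the field. The reference event log is a marginal
reconstruction: any analysis that depends on the joint distribution of
practice × stratum × stage beyond the published marginals is a convention of
the reconstruction, not evidence.
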