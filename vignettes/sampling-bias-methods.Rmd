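---
title: "Methods: quantifying sampling-design bias in EHR-based risk modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying sampling-design bias in EHR-based risk modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Electronic health records are powerful but observational in a specific,
treacherous way: data exist because someone ordered them.  Two mechanisms
distort naive EHR analyses.  *Ascertainment bias*: sicker patients
accumulate complete data because of clinical need, so selecting "everyone
with complete data" (a convenience sample) selects for latent risk.
*Prevalent-disease misclassification*: a condition present before a
patient's record begins is often coded only once the patient actually
interacts with the system, so if follow-up starts the moment data become
available, old disease is counted as new, inflating early incidence.

`ehrbias` implements a controlled experiment around these mechanisms: a
synthetic EHR generator in which both are explicit, tunable processes;
two competing sample constructions (a longitudinal primary-care cohort
versus a complete-data convenience sample); rule-based recovery of vital
signs from note text; two established cardiovascular risk scores; and
the survival metrics needed to show where the bias lands (it lands in
calibration, not discrimination).

## The generative model

### Population and latent risk

Each of `n_patients` receives demographics (truncated-normal age at
entry, mean 48, SD 17, range 18-89; 60% female; a race mix dominated by
White patients), anthropometrics, blood pressure, lipids, and binary
comorbidities whose prevalence rises with age.  These *true* covariates
are evaluated under the deployed risk score (CHARGE-AF by default) to
give each patient a latent linear predictor `LP`.  The score is made the
*literally true* model: event times are exponential with hazard

    h_i = -log(S0)/horizon * exp(LP_i - meanLP)

using the score's published baseline survival `S0` and centering
constant `meanLP`.  Under this choice a perfectly measured sample is
perfectly calibrated, so any miscalibration observed downstream is
attributable to the sampling and observation mechanisms — which is the
point of the experiment.  (The exported `assign_outcomes()` primitive
defaults to centering at the population mean LP, the more conventional
parameterization for free-standing simulations; the generator's default
config overrides the centering to the published constant as described.)

A configurable fraction (default 10%) has outcome onset *before* the
record begins (uniform within the prior five years): prevalent disease.
Death is an independent exponential (0.005/year); administrative
censoring is at day 7305 (20 years from the epoch).  Dates are integer
days from a simulation epoch; ages use exact-day arithmetic (365.25
days/year) to avoid calendar ambiguity.

### Encounters

55% of patients are "engaged" in longitudinal primary care: office
visits at registry codes and primary-care locations every 330-760 days,
plus sporadic specialty encounters.  The rest have only sparse,
clinically driven encounters.  An incident outcome generates an
inpatient encounter shortly after onset (mean 14 days) — data acquired
*because of* disease, the engine of ascertainment bias.

### The observation process

Tabular vitals and labs are generated complete at every encounter and
then thinned:

    P(recorded) = plogis(qlogis(1 - missingness_base) +
                         strength * (z + 2 * clinical_encounter))

with `z` the standardized latent LP.  The monotone logistic link is a
modeling choice — the phenomenon is documented in the field, its
functional form is not — and is the minimal mechanism producing
risk-dependent completeness; `strength = 0` recovers completely-at-random
missingness.  Default base missingness (45/40/35/35% for height, weight,
systolic, diastolic; 60% for lipids) reflects the >40% baseline
missingness typical of tabular vitals.

Diagnoses are coded with delay.  Comorbidities are recorded at the first
encounter after an exponential delay (mean `coding_delay_days`, default
180); patients with sparse streams may never be coded — the origin of
"lower measured comorbidity" in the convenience sample.  Incident
outcomes are coded at their event-driven encounter.  Prevalent outcomes
are anchored to the first primary-care visit (engaged patients) or the
first encounter at which all score components were measured
(non-engaged) — so a convenience sample whose clock starts at component
completeness sees these codes arrive just *after* baseline and counts
them as incident.  Setting `coding_delay_days = 0` collapses every
recorded date to the true onset, switching the mechanism off.

### Notes

Each encounter generates a note with probability 0.6; each measured
vital is mentioned with probability 0.6.  Embedded values are the
encounter's own measurements, so same-day tabular/NLP pairs agree up to
unit rounding; 15% of blood pressures are independent repeat
measurements, the documented source of same-day disagreement.  Note text
is drawn from a style registry shared with the extractor: bare numbers
in canonical units, explicit unit tokens (inches, m, lbs, ...), compound
shapes (feet+inches, lbs+oz, including 5'11'' quote notation), the
`NUM/NUM` blood-pressure shape, deliberately unextractable failure
dialects ("wgt 183", "hgt 163", "VS-142/92"), and the "optimal weight
... for BMI of 25" distractor.  Ground truth for every embedding is kept
in the hidden-truth tables, enabling exact round-trip testing.

Hidden truth (latent LP, true onsets, complete measurement tables, note
ground truth) lives in `ds$truth`, separate from the observable tables;
all pipeline stages consume `observable_tables(ds)` only.

## Sample construction

**Longitudinal cohort**: an encounter is a primary-care visit iff its
code *and* location are in the registry.  Entry requires a pair of such
visits 1-3 years apart; the interval is read as the closed `[365, 1095]`
days (the boundary convention is not dictated by the field; closed is
the inclusive reading), and follow-up starts at the second visit of the
earliest qualifying pair (ties among simultaneous pairs cannot change
the start date; the scan is deterministic).  Age at start must lie in
`[18, 90)` with exact-day arithmetic, demographics must be complete, and
zero-length follow-up (last encounter on the start date) drops the
member.

**Convenience sample**: follow-up starts at the earliest date at which
every measured score component has a tabular value within the preceding
3 years (height exempt: any prior value).  Candidate start dates are
evaluated only at measurement dates, since joint availability can only
change there — a finite, exact search.  Exclusions: no follow-up of any
kind, outcome already recorded at start, age, demographics.

Follow-up for both ends at the earliest of recorded outcome, death, last
encounter of any kind, the 90th birthday, or administrative censoring;
analysis additionally truncates at the score horizon.

## Vital-sign extraction

The labeler scans for context words (height/ht, weight/wt, pressure/bp,
optionally colon-suffixed, case-insensitive) and matches the longest
applicable shape anchored at the first number starting within 40
characters — templated note text keeps false positives low at that
window, which is a package choice, not an external constant.  Blood
pressure admits only `NUM/NUM`.  Quote notation is normalized to
`ft`/`in` tokens before matching; accepted extractions never overlap
(earliest span wins).

Post-processing: unit harmonization to cm/kg/mmHg (unitless numbers are
taken as already canonical — the EHR-flowsheet convention the bare
dialect emulates), compound shapes summed, `NUM/NUM` split into
systolic/diastolic, physiological constraints (91-305 cm, 20-450 kg,
50-300 / 20-200 mmHg), and a weight-distractor filter discarding
matches followed within 30 characters by
`for\s+(a\s+)?bmi\s+(of\s+)?2[0-9](\.[0-9])?`.

Baseline selection takes the value most closely preceding the start of
follow-up within 3 years (height exempt); same-date ties break
tabular-first, then latest note order (repeat same-day values keep the
last).  NLP values never overwrite tabular ones — they only fill gaps —
and the convenience sample never uses them, mirroring the asymmetry of
the design under study.

## Risk scores

Coefficients, centering constants, and baseline survivals for CHARGE-AF
(5-year atrial fibrillation) and the four sex/race-stratified Pooled
Cohort Equations (10-year MI/stroke) ship as CSV data files read at
call time; transforms (per-5-year age, log terms, treated/untreated
pressure interactions) are code, coefficients are data.  The PCE
deployment default maps Black patients to the Black equations and all
others to the White equations; a `white_only` mode restricts the White
equations to White patients and marks others ineligible.  CHARGE-AF's
race coefficient applies to White patients only.  Its published age
range appears in two variants in circulation (46-90 and 45-94); the
constructor defaults to `[46, 90]` and exposes the alternative as an
argument.  Predicted risk is `1 - S0^exp(LP - meanLP)`.

**Recalibration-in-the-large** replaces each stratum's `S0` with the
sample's own baseline survival at the horizon — the Breslow cumulative
hazard from a Cox model with the centered LP as offset — and `meanLP`
with the sample mean.  The plainer alternative (substituting the
Kaplan-Meier survival) is *not* used: the KM estimate is the marginal
survival, and by Jensen's inequality the marginal differs from the
baseline-at-mean whenever the LP has spread, so KM substitution would
*introduce* miscalibration into a perfectly calibrated sample.  The
offset-Breslow estimate recovers the generating `S0` on data simulated
from the score itself, which is the behavior a recalibration step must
have to be interpretable in this experiment.

## Evaluation statistics

- **KM cumulative risk** with Greenwood-variance intervals on the
  complementary log-log scale (boundary-respecting).
- **Incidence rates** per 1000 person-years with the Wald normal
  approximation.
- **HR per 1-SD**: Cox partial likelihood (Efron ties) on the
  standardized LP.
- **IPCW concordance** (Uno): comparable pairs are (event at `t_i`,
  `t_i < horizon`, `t_j > t_i`), weighted `G(t_i-)^-2` with `G` the KM
  estimate of the censoring distribution; prediction ties count 1/2.
  Implemented directly (chunked `O(n * events)` vectorization) and
  verified against a brute-force all-pairs oracle, to which it is
  exactly equal when censoring is absent.  CI by patient bootstrap.
- **GND test**: deciles of predicted risk; per-group KM observed risk
  and Greenwood variance at the horizon; groups with <5 events merge
  into the lower (else upper) neighbor with degrees of freedom reduced
  accordingly — the small-group convention of the test's literature,
  which the deployment reports but does not standardize.
- **ICI**: mean |p - o(p)| where o(p) is a proportional-hazards
  regression on a natural cubic spline of cloglog(p) (knots at the
  0.05/0.35/0.65/0.95 quantiles, configurable), evaluated at the
  horizon via the Breslow baseline.  Near-constant predictions make the
  spline degenerate; the index then falls back to comparison against
  the overall KM risk, with a warning.  Percentile bootstrap CI under a
  fixed seed.
- **Calibration slope**: coefficient of cloglog(p) in a Cox model.
  Using cloglog(p) rather than the raw LP makes the slope invariant to
  recalibration-in-the-large (the transform shifts additively) and
  well-defined after any monotone risk transform.
- **Sample comparison**: bootstrap (patients resampled within each
  sample independently, fixed seed) of the ICI and slope differences;
  two-sided p from the percentile position of zero at the field's 0.05
  threshold.

Predictions are clamped to `[1e-10, 1 - 1e-10]` before cloglog.  All
bootstrap draws are deterministic given the seed; 200 iterations are
used in the packaged experiments (p-value resolution 0.005, an order of
magnitude below the decision threshold).

## What the experiment shows — and what it cannot

With both mechanisms active, the convenience sample reproduces the
qualitative signature reported for real multi-institutional EHRs:
higher incidence than the primary-care cohort despite *lower* measured
comorbidity, an abrupt event inflection in the first 90 days of
follow-up, similar discrimination, and materially worse absolute
calibration (larger ICI, flatter slope), only partially repaired by
recalibration.  Zeroing `ascertainment_strength` and
`coding_delay_days` removes all three signatures, identifying the
mechanisms as the cause.

The generator is a caricature, deliberately.  Real notes are longer,
noisier, and full of dialects the style registry does not contain, so
100% round-trip recovery says the extractor is faithful to its
specified dialects, not that it would recover 100% in the wild.  Real
missingness mechanisms mix MNAR components beyond a single logistic
link on one latent score; real comorbidity onset is not fixed at record
entry; competing risks are reduced to independent death censoring; and
cholesterol enters only as a score input.  Conclusions about the
*direction* and *mechanism* of sampling bias transfer; magnitudes do
not.

## Problem sizes and determinism

The packaged analyses and tests run the full experiment at 20,000
patients (the default `sim_config`), parameter-recovery checks at
20,000 records, and oracle-equivalence checks at n <= 200 where exact
agreement is asserted.  Every random stage flows from a single integer
seed; identical configuration and seed reproduce byte-identical
datasets, reports, and bootstrap intervals.
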