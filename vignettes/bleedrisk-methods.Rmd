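---
title: "Methods: bleeding-risk scores, TTR and their evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bleeding-risk scores, TTR and their evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bleedrisk)
```

## The problem this package addresses

Patients with atrial fibrillation (AF) on vitamin-K antagonists (VKAs) face
a bleeding risk that clinicians stratify with additive clinical scores:
HAS-BLED, ATRIA, ORBIT and HEMORR2HAGES. Only HAS-BLED contains a criterion
for the *quality* of anticoagulation control — "labile INR", operationalised
as a time in therapeutic range (TTR) below 65%. The package implements the
four scores, their labile-INR-augmented variants (one extra point for
TTR < 65% added to ATRIA, ORBIT and HEMORR2HAGES, category thresholds
unchanged), Rosendaal-interpolated TTR, and the full statistical toolkit
used to compare score performance against ISTH major bleeding:
contingency-table association, survival analysis, ROC discrimination with
DeLong comparison, Pencina reclassification (NRI/IDI), Hosmer–Lemeshow
calibration, and decision-curve net benefit. A synthetic cohort generator
stands in for registry data so every stage is testable end to end.

## Data model

A cohort is two tables: one baseline row per patient (demographics,
comorbidity flags, hemoglobin, follow-up, outcome and bleed-event fields)
and a long INR table (`patient_id`, `day`, `inr`). Dates are integer day
offsets from each patient's entry — day 0 is entry — and 1 year =
365.25 days everywhere; no calendar parsing. Missing optional values are
empty CSV cells; flags are 0/1. Validation is total: every malformed row is
reported with its row number and field, and nothing is dropped silently.

Anemia may be carried as an adjudicated flag or derived from hemoglobin
(< 13 g/dL men, < 12 g/dL women, strict inequalities). Registry data often
carries adjudicated flags, so when both are present and disagree the
explicit flag wins with a warning. Some clinical sources print these
cut-offs as "g/L"; that unit is physiologically impossible for the stated
numbers and they are implemented as g/dL.

## Scores

Per-criterion weights follow each score's original publication; every
awarded point is auditable through the returned component breakdown.

| score | criteria (points) | high / medium-high at |
|---|---|---|
| HAS-BLED | uncontrolled hypertension, abnormal renal, abnormal liver, stroke, bleeding history, labile INR, age > 65, antiplatelet/NSAID, alcohol (1 each; max 9) | ≥ 3 |
| ATRIA | anemia 3, severe renal disease 3, age ≥ 75 2, prior bleed 1, hypertension 1 (max 10) | ≥ 4 |
| ORBIT | age ≥ 75 1, anemia 2, bleeding history 2, eGFR < 60 1, antiplatelet 1 (max 7) | ≥ 3 |
| HEMORR2HAGES | hepatic/renal, ethanol, malignancy, age > 75, platelet defect, uncontrolled hypertension, anemia, CYP2C9, fall risk, stroke (1 each) + rebleed 2 (max 12) | ≥ 2 |

Decisions taken where sources vary:

* ORBIT's age criterion ("older than 74") is implemented as ≥ 75;
  HAS-BLED's elderly criterion as > 65; HEMORR2HAGES's as > 75.
* HAS-BLED "labile INR" uses TTR < 65% (not the 60% found in some
  literature), matching the NICE good-control definition used throughout;
  the threshold is a parameter defaulting to 65.
* A TTR of exactly 65.0% is *not* labile (good control is TTR > 65%).
* HAS-BLED bleeding history counts only the explicit prior-major-bleed
  flag — nothing is inferred from anemia (conservative and auditable).
* CHA2DS2-VASc (computed for description only) maps vascular disease to
  coronary artery disease, the only vascular field in the baseline table.

ISTH major bleeding is a pure disjunction: fatal, critical site
(intracranial or other critical area/organ), hemoglobin fall ≥ 2 g/dL, or
transfusion of ≥ 2 units; absent fields default to non-qualifying.

## Rosendaal TTR

Between consecutive INR measurements the INR is assumed to change linearly
by day; each inter-visit interval is split into below/in/above range by the
crossing times of the range limits (default 2.0–3.0) on the linear segment.
Conventions, all configurable:

* **Window** 183 days ("TTR at 6 months after entry"); the last segment is
  clipped at the boundary by interpolation, and time after the last
  in-window observation contributes nothing (no extrapolation).
* **Gap cap** 56 days: longer inter-visit gaps contribute no time to either
  numerator or denominator. This is a common implementation convention, not
  universal, hence configurable including `Inf` (no cap).
* **Boundary INRs count as in range**, so a series constant at exactly 2.0
  has TTR 100% — the least surprising convention.
* Fewer than two usable observations make TTR undefined: an error, so the
  caller decides policy (`ttr_cohort(on_undefined = "na")` opts out).

PINRR (proportion of INRs in range) counts in-window observations inside
the limits. The implementation is closed-form per segment and is tested
against a brute-force oracle that classifies a 0.01-day grid, to within
0.1 percentage points over hundreds of random series.

## Evaluation statistics

* **Odds ratios** use Woolf's log-OR normal CI without continuity
  correction. This choice is verified, not asserted: the three printed
  ATRIA/ORBIT/HEMORR2HAGES odds ratios and CIs that are derivable from
  published category counts reproduce exactly at 2-decimal rounding. The
  published HAS-BLED OR (2.00, 1.51–2.63) is *not* derivable from its own
  published counts (direct computation gives 2.79), so it is excluded and
  flagged. Haldane–Anscombe 0.5 is applied only on a zero cell, with a
  warning. P-values come from Pearson's chi-squared (df 1, no correction),
  which equals the squared two-proportion z statistic.
* **Annualized rates** use person-time (events per 100 patient-years), not
  the median-follow-up shortcut.
* **Survival.** Kaplan–Meier product-limit curves; k-group log-rank with
  hypergeometric variance and simultaneous risk-set handling of ties (never
  jittering); univariate Cox by Newton–Raphson on the partial likelihood
  with Breslow ties (matching SPSS-style reports; Efron behind a flag),
  Wald intervals, convergence at |Δβ| < 1e-8 or 50 iterations. Monotone
  likelihoods (risk-order separation) are flagged non-converged and no
  finite estimate is reported. Time is years = day/365.25; hazard ratios
  are invariant to that scale choice.
* **Discrimination.** The c-index is the Mann–Whitney concordance
  (ties ½), computed from midranks. DeLong's structural-component
  covariance drives the paired AUC z test; a self-comparison returns
  z = 0, p = 1 by convention.
* **Probability calibration of integer scores.** IDI, Hosmer–Lemeshow and
  decision curves need probabilities, and how published analyses map score
  points to probabilities is typically unstated. The package's explicit
  choice: univariate logistic regression of outcome on points, refit per
  score. Threshold-free statistics (c-index, DeLong) bypass this mapping
  entirely. This is the main comparability caveat when holding results
  against published NRI/IDI/HL magnitudes.
* **NRI** defaults to the continuous (category-free) variant, because
  original and modified scores shift category meanings; a two-category mode
  with an explicit probability threshold mirrors clinical use. Note a
  structural property of adding one point for a binary factor: among
  events, "up" movers are exactly the labile patients, so the event
  component of continuous NRI is negative whenever fewer than half of
  events are labile — the improvement shows up in the non-event component.
  The total NRI is approximately 2·[P(labile|event) − P(labile|non-event)].
* **Hosmer–Lemeshow** ranks subjects into 10 equal-count bins with tied
  probabilities kept together (deterministic binning), statistic
  Σ(O−E)²/(E(1−E/n)) and df = bins − 2; zero-expectation bins merge into a
  neighbour with a warning.
* **Decision curves**: net benefit TP/N − (FP/N)·t/(1−t) with ties
  classified positive, over a grid capped at t = 0.50 — prophylaxis
  decisions beyond 50% bleeding risk are clinically meaningless.

## The synthetic cohort generator

`generate_cohort()` emulates an anticoagulation-clinic registry of 1361
AF patients stable on a VKA:

* **Covariates**: Bernoulli flags at the registry's published margins
  (hypertension 0.82, diabetes 0.267, heart failure 0.315, stroke/TIA
  0.189, renal impairment 0.106, anemia 0.187, antiplatelet 0.179, female
  0.513, …), age normal-matched to median 76 (IQR 71–81). A Gaussian
  copula correlates age with renal impairment and with anemia at ρ = 0.2 —
  enough to make score distributions realistic without inventing structure
  no source describes; all other pairs are independent. Flags without a
  published margin (uncontrolled hypertension 0.12, severe renal disease
  0.045, eGFR < 60 0.30, prior major bleed 0.08, rebleed 0.02, platelet
  defect 0.02, CYP2C9 0.05, fall risk 0.10) use once-chosen clinically
  conventional values. Nested flags are drawn conditionally so the
  data-model implications hold by construction, and hemoglobin is drawn on
  the correct side of each patient's anemia cut-off.
* **INR series**: visits every ~28 days (SD 5, clamped 14–42) across the
  183-day TTR window; visit INR ~ Normal(patient mean, 0.35); patient mean
  ~ Normal(2.5, σ_b). σ_b is auto-tuned by bisection on fixed random draws
  until the realized labile fraction matches the 24.2% target within 0.005
  — tuning is part of the stated world, not a per-test dial.
* **Events**: exponential times with log-linear hazard. Constant hazard is
  chosen because the emulated summaries are %/year figures and it keeps
  recovery tests closed-form. Default log-HRs: labile INR ln 1.5, prior
  bleed ln 1.6, anemia ln 1.45, renal/antiplatelet/alcohol ln 1.4,
  uncontrolled hypertension ln 1.3, stroke ln 1.25, ln 1.3 per decade of
  age over 70. The labile effect enters through the *realized* TTR flag,
  not the latent patient mean, because downstream analysis only observes
  the flag. The baseline hazard is calibrated numerically (uniroot on the
  expected marginal rate given the drawn covariates and censoring times)
  to 2.82 events per 100 person-years.
* **Censoring**: lognormal follow-up matched to median 6.5 (IQR 4.3–7.9)
  years, clamped to [0.5, 10.5] (the registry's observation era).
* **Bleed anatomy**: site intracranial 0.31 / gastrointestinal 0.39 /
  other-critical 0.06 / other 0.24; fatality 0.21, drawn independently of
  site (a fatal bleed may also be intracranial). Hemoglobin-drop and
  transfusion fields are topped up where needed so every generated event
  satisfies the ISTH major criteria.

**What the generator does not emulate** — and hence what a green test does
not establish: the true joint correlation structure of comorbidities in
any real registry; non-constant (e.g. early-risk) hazards; INR dynamics
beyond a stationary patient mean (no dose-adjustment feedback, no
time-varying control); bleeding-site-dependent hazards; and the much
larger discrimination gain that published modified scores showed relative
to what a hazard ratio of 1.5 for labile INR can produce. Directional
conclusions (modified ≥ original) transfer; magnitudes do not.

## Pipeline determinism

One run seed drives everything; the simulation consumes a stage-derived
substream (a hash of the stage name mixed with the seed) so adding stages
never perturbs earlier randomness. Two runs with the same seed produce
byte-identical TSV outputs. No multiple-comparison adjustment is applied
anywhere, matching the unadjusted-p reporting convention of the analyses
this mirrors; outputs carry full precision.

## Known limitations and honest-red notes

* The published HAS-BLED category OR is internally inconsistent with its
  published counts (see above); the package reports what the counts give.
* Published per-value bleed counts for HAS-BLED sum to 248, not 250; the
  category row is taken as authoritative where the two conflict.
* Published TTR<65% column counts disagree across score columns of the
  same baseline table (449 vs 330 of 1361); the generator targets the
  published 24.2% headline figure.
* In the acceptance suite, the requirement that *per-seed* continuous-NRI
  and IDI p-values be < 0.05 simultaneously for all three modified scores
  in ≥ 80% of 50 default-world cohorts fails (measured 66% and 72%): with
  a labile hazard ratio of 1.5, 24% labile prevalence and ~250 events, the
  analytic NRI z is ≈ 2.3, i.e. ~65% power per pair. The c-index-gain and
  net-benefit components pass (92%, 84%). This is reported as a genuine
  red rather than widening the band, changing seeds, or inflating the
  generator's labile effect — the direction reproduces; per-seed
  significance at this effect size does not.
* No multivariable or time-varying Cox, no competing risks, no
  time-dependent ROC, no bootstrap optimism correction: all out of scope.
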