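---
title: "Evaluating sepsis early-warning models: strategies, bias mechanisms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating sepsis early-warning models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsieval)
```

## The model under evaluation

A sepsis early-warning model maps the data observed for an ICU stay up to
hour *t* to a risk score in (0, 1). The package does not train such models
(beyond a ridge-logistic baseline for end-to-end runs); it evaluates any
per-hour score stream under the three designs used across the literature —
fixed horizon, peak score, and continuous evaluation — with or without
control onset matching, and quantifies how much of a reported performance
difference is evaluation design rather than model quality.

## Outcome definition

Sepsis onset follows the Sepsis-3 consensus: suspected infection plus an
acute SOFA increase of at least 2 points. Lacking microbiology, suspicion
of infection is inferred from sustained antibiotic exposure — at least one
dose every 24 h spanning at least 72 h, pooled over all antibiotic agents —
with the suspicion time at the first dose of the course. Each course opens
a window from 48 h before to 24 h after the suspicion time, and the onset is
the first SOFA reading inside a window that exceeds the running minimum of
earlier readings in the same window by ≥ 2 points.

Two operational details the consensus leaves open are fixed here for
determinism and exposed as arguments:

- **SOFA reference.** "An increase of at least 2 points during the window"
  does not name a baseline. We use the running minimum of the scores
  observed earlier in the same window — the least restrictive common
  operationalization. The first reading in a window can therefore never
  trigger an onset. Callers preferring a window-start or 24-h-prior
  baseline can pre-process the SOFA series accordingly.
- **Course boundaries.** "At least 3 days" is read as span ≥ 72 h from
  first to last qualifying dose; gaps are strict (> 24 h breaks a run).

Eligibility mirrors routine cohort construction: ICU admission origin,
age ≥ 18, onset not within 4 h of admission (exactly 4.0 h is retained:
"within" is read strictly), at least 6 h of time-varying data, and no
inter-measurement gap ≥ 12 h. Gaps are computed over the union of all
time-varying measurement times and anchored at admission, so a first
measurement arriving at ≥ 12 h counts as a gap. Stays are truncated at
7 days; a case whose onset falls beyond the truncation becomes a control
rather than being excluded, since its observed week contains no onset.

## Preprocessing

Measurements outside per-feature plausibility ranges (bounds inclusive) are
removed as if never taken. Remaining values are binned hourly — 0-based
left-closed bins `[t, t+1)` anchored at admission — by their median
(midpoint for even counts). Missing cells are forward-filled within stay
and channel; bins before the first observation fall back to a caller-
supplied per-channel mean. The fallback means are a parameter rather than a
computed quantity because, in transfer settings, they come from the
*training* cohort; whether they should be per-split or global is a caller
decision. Binary missingness indicators (one per channel) ride along.

Temporal features are trailing-window statistics — min, max, mean, median,
population variance (divide by *n*; a single-value window has variance 0) —
over the last 4, 8, and 16 bins, truncated at the stay start. With 48
channels and 4 statics this yields 48 + 48·5·3 + 4 = 772 columns. The
column-count invariant is generic in the channel count, so tests exercise
it at small scale as well.

A score "at bin *t*" may use data through bin *t* inclusive; the horizon
arithmetic below is stated in these 0-based bins.

## Evaluation strategies

All three builders consume the same trajectory table — per-stay score
vectors over bins `0..last_bin`, case onsets at `floor(t_onset)` — so any
difference in output is attributable to the design, not the data.
The prediction at the onset bin itself is always excluded (explicit in the
continuous design, extended to peak score for consistency).

- **Fixed horizon**: one record per stay, the score at bin
  `onset_bin − h`; stays with `onset_bin < h` are excluded (and counted),
  since no prediction exists that early.
- **Peak score**: one record per stay, the maximum over pre-onset bins
  `[0, onset_bin)`, or `[onset_bin − h, onset_bin)` in the
  horizon-restricted variant.
- **Continuous**: every pre-onset bin is a record; case bins within *h*
  hours of onset are positive. The horizon labels time points; it never
  filters stays. Records carry weight `1/nᵢ` so each stay totals weight 1.

**Control onsets.** Without matching, a control's hypothetical onset is the
bin after its last data point. With matching, each control copies the onset
of a uniformly drawn case whose onset does not exceed the control's stay
("does not exceed" read as ≤). Matching is with replacement: controls
usually outnumber cases many-fold, and without-replacement pairing can
fail. A control with no eligible case falls back to the unmatched rule and
is flagged rather than dropped — silent exclusion would change prevalence.
**Prevalence harmonization** removes controls uniformly at random to hit a
target patient-level prevalence; it runs before onset assignment and before
any horizon filtering, and never removes cases.

## Metrics

All metrics are weight-aware and share one alarm rule, `score > threshold`,
so operating points agree across ROC, PR, decision-curve, and alarm-rate
analyses. AUROC uses the weighted rank-sum formulation with ties credited
half. AUPRC integrates the step-wise weighted PR curve; linear
interpolation is used only for the precision-at-recall query, where the
target recall need not be attainable exactly. Lifted variants divide PPV
and AUPRC by the sample prevalence (≈ 1 for an uninformative model);
`recall_at_2prev` takes the maximum recall over achievable operating points
with precision ≥ 2 × prevalence, returning 0 with a flag when none exists
(the precision-doubling threshold need not exist). The
80%-sensitivity threshold is the supremum cut, returned minus a machine
tolerance (1e-8) so alarms at the critical score fire. Alarm rates count
pre-onset bins only — the denominator choice is configurable in principle
but the package reports the pre-onset convention, since post-onset alarms
answer a different clinical question. Silencing suppresses the 4 h after an
unsilenced alarm; suppressed alarms do not extend suppression.

Calibration uses weighted isotonic regression (a pool-adjacent-violators
implementation with case weights, since the weighted variant is not
available in base R), cross-validated at the stay level: fitted on 80%,
applied to the held-out 20%, pooled. Monotone maps preserve ranking up to
ties, so discrimination metrics are unchanged up to tie granularity.

## Inference

The resampling unit is the ICU stay. Bootstrap CIs are percentile intervals
over B stay-resamples with the evaluation sample rebuilt per replicate
(weights and exclusions recomputed). The paired Wald test feeds one shared
resample to both designs, takes SE = SD of the per-replicate differences,
and uses the observed difference as the numerator (the conventional Wald
form; the bootstrap-mean center is available as an option). Holm step-down
runs within each hypothesis family: the three pairwise strategy contrasts
per condition, and the single matched-vs-unmatched contrast per strategy.

Matching and harmonization are *not* redrawn inside replicates: the
observed design's assignments are resampled, matching the description of
resampling patients rather than re-running the study design. One
consequence, visible in our null simulations, is that the test is
conditional on the realized matching: for designs whose estimand depends
strongly on the specific matching draw (peak score under matching), the
conditional null can differ from the unconditional one. The type-I
validation below therefore uses an unmatched contrast, where no design
randomness exists.

## The synthetic cohort generator

The generator is the package's ground-truth instrument, at two fidelity
levels.

**Score level.** Stays are septic with the configured prevalence (default
0.103, the prevalence implied by 4134 septic of 40,132 stays in a large
German ICU cohort). Case onsets are log-normal with median 30 h (≥ 5 h,
since the eligibility rules exclude earlier onsets); control stays
log-normal with median 24 h (≥ 6 h, the minimum-data rule), both truncated
at 7 days — sepsis stays longer than controls, matching the ordering of
published ICU cohort characteristics without claiming exact values. Latent
risk is a baseline logit (−2) plus stationary AR(1) noise (ρ = 0.7,
σ = 0.5) plus, for cases, a linear ramp of height `signal_gain` (default 2)
over the final `signal_lead` = 12 h before onset; controls can receive a
pre-discharge risk *decline* of height `discharge_recovery` over their
final hours, emulating the stabilization of patients approaching discharge.
Scores are logistic-squashed — correlated with risk but deliberately
uncalibrated, since calibration is assessed separately. Case trajectories
end at the onset bin: every strategy discards post-onset scores, so
simulating them would be dead weight.

**Raw-EHR level.** Each stay emits irregular measurements for 48 channels
(9 vitals at ~1/h, 39 labs at feature-specific lower rates) with values
clamped into plausibility range except a configurable planted-outlier
fraction strictly outside it (flagged for audit); antibiotic dose events;
and a step-changing SOFA series. Cases get a q12h course spanning 84 h
starting within 24 h before the planted onset and a +2..+4 SOFA step at
onset over a non-increasing pre-onset SOFA (with a guaranteed reading 2 h
before onset), so the labeler must recover the planted onset exactly.
Controls receive confuser exposure: 30% short (< 3 day) antibiotic courses,
30% SOFA steps outside any suspicion window, and a small fraction of
long-staying controls get a full-length course with flat SOFA — suspicion
without organ dysfunction. Control antibiotic exposure patterns are not
published in detail anywhere we know of; these fractions are free
parameters chosen to exercise the labeler's failure modes, not estimates.

What the generator does *not* emulate: real marginal feature distributions,
demographics, treatment covariates, readmissions, or informative-missingness
structure. Passing tests demonstrate the correctness of the evaluation
machinery and the directional bias mechanisms; they say nothing about any
real model's clinical performance.

## Validation design and problem sizes

The self-checks run at sizes chosen to keep the full suite within a few
minutes while leaving the binomial/bootstrap tolerances meaningful:

- *AUROC oracle*: 100 random weighted samples of ≤ 30 records against a
  brute-force pairwise double loop, agreement to 1e-12.
- *Peak-score LOS bias*: 20 cohorts of 2,000 stays, label-independent
  scores (`signal_gain = 0`), control LOS log-normal median 72 h vs case
  onsets median 16 h. Unmatched peak AUROC < 0.5 and matched AUROC in
  [0.47, 0.53], each in ≥ 18/20 seeds. This check uses balanced groups
  (prevalence 0.5): the null AUROC sampling SD at n = 2000 is ≈ 0.013 when
  balanced but ≈ 0.022 at 10% prevalence, where a ±0.03 band could not be
  expected to hold in 18/20 draws. The strong LOS/onset separation also
  keeps the matching-eligibility truncation negligible (with closer
  distributions, controls shorter than some case onsets restrict their
  eligible-case set and bias matched peak AUROC slightly upward — a real
  property of matched designs, measurable with this generator).
- *Discharge recovery*: 20 cohorts of 800 stays at default signal with
  `discharge_recovery = 1.5`; continuous AUROC without matching ≥ with
  matching in ≥ 18/20 — unmatched evaluation includes the easy, stable
  pre-discharge hours of controls.
- *Type-I error*: 200 null cohorts (n = 300, B = 200), unmatched
  fixed-horizon vs peak-score with identical stay-length laws for both
  groups (same log-normal for control LOS and case onsets), so both AUROCs
  are exactly null; rejection rate at nominal 5% must stay ≤ 8%. Prevalence
  0.3 keeps single-class bootstrap resamples negligible at n = 300.
- *Labeler consistency*: 500 raw-EHR stays; sensitivity and specificity of
  the Sepsis-3 labeler against the planted assignment each ≥ 0.95, and
  recovered onsets equal to the planted SOFA-step times.
- *Coverage*: 60 cohorts of 400 stays; the 95% percentile CI covers the
  large-sample AUROC in ≥ 85% of runs (percentile intervals undercover
  somewhat at small case counts; this is expected bootstrap behavior, not a
  defect).

## Numerical conventions and degenerate inputs

Ties in scores: AUROC credits half; operating points collapse tied scores.
Single-class samples raise typed errors rather than returning NaN, and
bootstrap machinery tolerates up to 5% single-class replicates before
erroring. Medians of even counts are midpoints. The seed dance: one master
seed deterministically derives per-component streams
(`(seed · 48271 + 1000003 · stream) mod 2³¹−1`), so full pipelines are
byte-identical under one seed while components stay independently
reproducible.

## Known limitations

- The labeler consumes a precomputed SOFA series; it does not compute SOFA
  from organ-system raw inputs, and microbiology-based suspicion is out of
  scope by construction.
- Stays are treated as independent; repeat admissions of one patient are
  not clustered in the bootstrap.
- Deep sequence models (TCN/GRU/attention) are out of scope; the framework
  evaluates any score stream, and ships only the ridge-logistic baseline to
  make end-to-end runs self-contained.
- The generator's parameters are structural stand-ins. Conclusions about
  direction and mechanism of evaluation-design bias transfer to real data;
  magnitudes do not.
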