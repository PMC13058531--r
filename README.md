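# sepsieval

Evaluation strategies for sepsis onset prediction models in intensive care.

## The problem

Early-warning models for sepsis in the ICU emit an hourly risk score
f(X<sub>1:t</sub>) for every patient. How that stream of scores is turned
into a performance number is a design choice with large consequences. Three
conventions dominate the literature:

- **Fixed horizon** — one score per stay, taken exactly *h* hours before the
  (actual or hypothetical) onset: y<sub>pred</sub> = f(X<sub>1:t<sub>onset</sub>−h</sub>).
- **Peak score** — one score per stay, the maximum over all pre-onset bins:
  y<sub>pred</sub> = max<sub>t &lt; t<sub>onset</sub></sub> f(X<sub>1:t</sub>).
- **Continuous** — every pre-onset hourly score is a record; bins within *h*
  hours of onset are positive, everything else negative, with per-stay
  inverse-frequency weights so each stay contributes total weight 1.

Because controls have no onset, each strategy needs a hypothetical control
onset: either the last available data point (no matching) or an onset copied
from a randomly paired case whose onset does not exceed the control's stay
(**onset matching**). The same model on the same data can yield markedly
different AUROCs across these designs — notably, peak-score evaluation is
biased downward whenever controls stay longer than cases, because longer
score series produce larger maxima purely by chance.

`sepsieval` implements the full comparison pipeline as tidyverse-style R:

- **Sepsis-3 labeling** from EHR event streams: suspicion of infection from
  sustained antibiotic courses (≥1 dose/24 h for ≥3 days), an SI window of
  −48 h/+24 h, onset at the first SOFA rise ≥2 points within a window, plus
  the cohort eligibility filters (adult, ICU origin, onset ≥4 h, ≥6 h data,
  no 12 h gaps, 7-day truncation).
- **Preprocessing**: plausibility filtering, hourly median aggregation,
  forward-fill + mean-fallback imputation with missingness indicators, and
  trailing-window temporal features (min/max/mean/median/variance over
  4/8/16 h; 48 channels + 4 statics → 772 columns), with a cross-validated
  ridge-logistic baseline scorer.
- **Evaluation samples** for the three strategies, with onset matching,
  prevalence harmonization and horizon filtering.
- **Weighted metrics**: AUROC, AUPRC, PPV/NPV/recall, prevalence-lifted
  variants, Brier score, cross-validated isotonic calibration, decision
  curves (net benefit), and alarm rates per patient-hour with a silencing
  window.
- **Inference**: stay-level bootstrap CIs, the paired bootstrap Wald test
  (shared resample for both designs, SE = SD of per-replicate differences),
  and Holm step-down correction per hypothesis family.
- **Synthetic cohorts** at two fidelity levels — score trajectories and raw
  EHR-like event streams — with planted structure so every component can be
  validated against known ground truth.

## Worked example

```r
library(sepsieval)

# a 2,000-stay cohort: 10% prevalence, pre-onset risk ramp, AR(1) noise
coh <- generate_score_cohort(cohort_config(n_stays = 2000, seed = 42))

grid <- experiment_grid(strategies = c("fixed_horizon", "peak_score", "continuous"),
                        matching = c(FALSE, TRUE), horizons = 6,
                        B = 200, seed = 42)
exp <- run_experiment(coh, grid)
report_summary(exp)
#> # A tibble: 6 × 5
#>   strategy      matching horizon metric formatted
#>   <chr>         <lgl>      <dbl> <chr>  <chr>
#> 1 continuous    FALSE          6 auroc  0.96 (0.95–0.97)
#> 2 continuous    TRUE           6 auroc  0.96 (0.95–0.97)
#> 3 fixed_horizon FALSE          6 auroc  0.91 (0.88–0.92)
#> 4 fixed_horizon TRUE           6 auroc  0.90 (0.88–0.92)
#> 5 peak_score    FALSE          6 auroc  0.99 (0.99–1.00)
#> 6 peak_score    TRUE           6 auroc  0.99 (0.99–1.00)
```

Each row is one evaluation design applied to the *same* cohort and scores;
the spread across rows is pure evaluation-design effect. The peak row picks
the best score within the final 6 pre-onset hours, the continuous row
assesses every pre-onset hour, and the fixed-horizon row asks a strictly
harder question (the score exactly 6 h out). The
contrasts table (`exp$contrasts`) holds paired bootstrap Wald tests with
Holm-adjusted p-values per family, and `autoplot(exp)` draws the
horizon-performance curves.

The bias mechanics are reproducible in isolation: with label-independent
scores and long-staying controls, unmatched peak-score AUROC drops far below
0.5 (~0.20 under the default check conditions) while onset matching restores
it to ~0.50.

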