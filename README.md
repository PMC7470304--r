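# tvmatch

Time-varying risk-set matching and survival analysis for hospitalized-cohort
treatment studies.

## The problem

Observational estimates of an in-hospital treatment effect are doubly
treacherous: treatment choice is confounded by disease severity, and
exposure begins days into the admission, so naive comparisons award the
treated group the "immortal" days they had to survive to become treated.
`tvmatch` implements the full analysis pipeline of a study design built for
this setting — azithromycin in patients hospitalized with COVID-19
pneumonia — and a synthetic longitudinal cohort generator rich enough to
test every stage of it:

1. **Risk-set matching with time-varying covariates.** Each treated patient,
   taken on the day of their first dose, is matched by brute force to a
   never-treated control at a hospital day on which the control's clinical
   state is similar. Hard constraints: same sex and obesity status, age
   within ±15 years, identical radiographic involvement (affected quadrants,
   0–4, with the study's imputation rule between equal radiographs ≤ 6 days
   apart), SAFI within [−1.1, +2.0] and C-reactive protein within [−6, +4]
   mg/dL of the treated patient, and the same co-treatments with starts
   aligned within 3 days. Feasible candidates are ranked by a logistic
   propensity score on SAFI, blood pressure, heart rate and CRP, and paired
   1:1 without replacement.
2. **Matched-subcohort outcomes.** Change in SAFI
   (saturation % / FiO2 %, ceiling 100/21 = 4.76), saturation and FiO2 at
   48/72/96 h (Student's t), and Kaplan–Meier / log-rank time to discharge
   (deceased excluded, censored 30 days after admission).
3. **Unmatched-subcohort adjusted analyses.** Within patients on
   hydroxychloroquine + lopinavir/ritonavir (corticosteroid users and
   asymmetrically distributed co-treatments excluded), a Cox
   proportional-hazards model of time to discharge adjusted for sex, age,
   obesity, heart failure, chronic renal failure, SAHS, and emergency-room
   saturation, CRP and radiograph quadrants; plus a Fisher mortality
   comparison with a small-event caveat.
4. **Synthetic cohorts.** A latent-severity longitudinal simulator whose
   defaults reproduce the source cohort's printed profile (n = 418, age
   65.4 ± 16.6, 57% male, the published comorbidity prevalences, ~19%
   30-day mortality, median stay 8 days, 57% treated, severity-confounded
   assignment) with a configurable true treatment effect — null by default —
   so calibration, confounding reduction and parameter recovery are all
   testable.

## Worked example

```r
library(tvmatch)

x <- simulate_cohort(default_config(seed = 1))
x
#> <cohort> 418 patients, 4111 patient-days, 7361 treatment events
#>   deaths: 79, discharges: 332, in hospital at censoring: 7

pairs <- match_cohort(x)           # enumerate -> propensity -> 1:1 greedy
nrow(pairs); attr(pairs, "n_treated")
#> 37 of 230 treated patients matched (logistic propensity model)

safi_change(pairs, x, 48)
#> Change from follow-up day 1 at 48 hours (matched subcohorts)
#>   saturation treated  -0.62 (n37)  control   2.41 (n29)  diff   3.04 (-0.53; 6.60)  p=0.094
#>   fio2       treated -13.41 (n37)  control  -4.21 (n29)  diff   9.20 (-0.47; 18.87)  p=0.062
#>   safi       treated   0.52 (n37)  control   0.31 (n29)  diff  -0.21 (-0.47; 0.05)  p=0.105

discharge_analysis_matched(pairs, x)
#> Time to discharge (deceased excluded)
#>   control  n=35 events=35 mean stay 7.1 d, median 6.0 d
#>   treated  n=33 events=33 mean stay 8.1 d, median 7.0 d
#>   log-rank chisq 0.384, p = 0.535 (6 deceased excluded)

sub <- select_unmatched_subcohorts(x)
discharge_cox_unmatched(x, sub)
#> Adjusted Cox (discharge): exposure HR 0.66 (95% CI 0.36-1.20; p = 0.169), n=72, 71 events
```

The simulated truth here is a *null* treatment effect with
severity-confounded assignment: the matched log-rank is correctly
non-significant, and the adjusted Cox CI covers 1. The `n29` in the 48-h
table reflects control-side exclusions (palliative sedation, no observation
at the horizon day), mirroring how the real analysis loses patients at
later horizons.

Everything is also scriptable end to end:

```sh
Rscript inst/cli/tvmatch run --config config.json --seed 1 --out report/
```

writes `pairs.csv`, `balance.csv`, `safi_changes.csv`, `km.csv` (+ plot),
`cox_summary.csv` and a `manifest.json` carrying the seed and a config hash
(identical config ⇒ identical bundle).

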