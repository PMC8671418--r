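# circanuc

Circadian analysis of urinary modified-nucleoside excretion and wrist
actigraphy in cancer patients.

## The problem

The circadian timing system shapes cell proliferation and drug metabolism,
and its disruption predicts poor outcome in metastatic colorectal cancer.
Two non-invasive windows onto it are (i) the rest-activity rhythm recorded
by a wrist accelerometer, and (ii) the timed urinary excretion of modified
nucleosides (pseudouridine, 1-methylguanosine, ...), breakdown products of
RNA turnover normalized to creatinine. `circanuc` implements the full
statistical pipeline for such a study:

- **Rest-activity quantification.** A 3-state Gaussian hidden Markov model
  on `log1p` 1-min activity counts segments each recording into
  inactive/rest (IA), moderately active (MA) and highly active (HA) states.
  Derived indices: the IA self-transition probability p1-1, the median HA
  activity, the rest duration *a* (integral of the 24-h IA probability
  profile), the center of rest *c*, and a Rhythm Index
  `RI = 100 (W − a²/24)/(a − a²/24)` (with *W* the IA mass inside the
  *a*-hour window centered at *c*) that is 100% for perfectly regular
  bedtimes and 0% for a rest profile spread uniformly over the day. Also:
  the dichotomy index I<O (% of in-bed epochs below the median out-of-bed
  activity), the 24-h autocorrelation r24, the dominant period from a
  resampled smoothed periodogram, and a 24-h activity cosinor.
- **Cosinor rhythmometry.** For timed urine samples, the two-component
  cosinor model on the log concentration,
  `log y(t) = M + A12 cos(2πt/12 + θ12) + A24 cos(2πt/24 + θ24) + e(t)`,
  fitted exactly by linearized least squares; mesor and overall
  amplitude/acrophase are reported on the concentration scale from the
  exponentiated fitted curve. A component is rhythmic when its
  zero-amplitude test (exact F test on the cos/sin pair, df = 2 and n − 5)
  gives p ≤ 0.1; patients with < 7 valid samples are excluded.
- **Association analysis.** Spearman correlation grids with figure-style
  significance tiers; a residual-resampling bootstrap (B = 1000) that
  re-estimates each patient's rhythm parameters per trial and only confirms
  a correlation when the 90% quantile of bootstrap p-values is ≤ 0.1;
  stepwise-AIC covariate selection; Welch t contrasts.
- **Chemotherapy response.** Log-linear trend classification of daily
  overnight excretions (slope p ≤ 0.05), ±50% multiplicative CEA change
  categories, the Freeman–Halton exact test of the trend × CEA table, and
  the survival contrast between trend classes.
- **Synthetic cohorts.** Deterministic generators for all data streams with
  known latent truth (states, rhythm parameters, trends), so every stage is
  validated end to end without clinical data.

## Worked example

```r
library(circanuc)

# one regular sleeper, 5 days of 1-min counts with known latent states
g <- generate_actigraphy(actigraphy_params(), seed = 42)
m <- fit_hmm(g$series, n_restarts = 10, seed = 1)
m
#> <hmm_model> 3-state Gaussian HMM on log1p counts
#>   emission means: 0.409 2.981 4.993
#>   p1-1 (IA self-transition): 0.9948  loglik: -8055.1 (converged)
mean(m$states == g$states)          # Viterbi accuracy vs latent truth
#> [1] 0.978

hmm_indices(fingerprint(g$series, m), m, g$series)
#>       p11 median_ha rest_duration_a center_of_rest_c rhythm_index
#> 1  0.9948       146            7.75             3.12         91.7
dichotomy_index(g$series)           # I<O, %
#> [1] 99.3
```

The indices read as: this simulated patient rests 7.75 h per day centered
at 03:07, stays in the rest state with probability 0.995 per minute, and
has a highly regular rest window (RI 91.7%, I<O 99.3%) — a robust
rest-activity rhythm.

```r
# two-component cosinor on a simulated 10-sample urine series
p <- urine_sim_params(mesor_log = log(7), amp24_log = 0.5, noise_sd_log = 0.1)
d <- generate_urine_series(p, seed = 1)
fit_multicomponent_cosinor(d$time_h, d$concentration)
#> <cosinor_fit> n = 10 samples, periods 12+24 h
#>   mesor 6.82, overall amplitude 4.58 (0.67 of mesor), acrophase 12:16
#>   amplitude p-values: A12 = 0.0212, A24 = 8.51e-05
#>   rhythmic (alpha = 0.1): yes
```

The whole study design runs in one call:

```r
report <- run_pipeline(pipeline_config(n_patients = 29, seed = 1))
report$cohort_summary       # per-nucleoside cohort rhythm summary
report$chemo$association    # trend x CEA contingency table + exact p
```

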