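---
title: "Methods: circadian quantification of rest-activity and urinary nucleoside excretion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian quantification of rest-activity and urinary nucleoside excretion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`circanuc` quantifies the circadian timing system of cancer patients from
two non-invasive data streams — minute-level wrist actigraphy and timed
urinary modified-nucleoside concentrations — and relates both to
chemotherapy response markers. This vignette is the package's account of
the underlying models, the tunable parameters, the numerical choices, and
what the synthetic-data validation does and does not demonstrate.

## Rest-activity segmentation by a hidden Markov model

Activity counts from a wrist accelerometer at 1-min epochs are
non-negative, heavily right-skewed integers with a hard floor at zero
during rest. We model `log1p(counts)` as a homogeneous 3-state Gaussian
HMM; the states are relabelled after fitting so that emission means
increase, giving the inactive/rest (IA), moderately active (MA) and highly
active (HA) states. The model *thresholds the series probabilistically*:
every epoch receives a posterior probability of each state rather than a
hard cutoff.

Fitting is by Baum–Welch EM with scaled forward–backward recursions
(implemented in C++), stopping at a relative log-likelihood change below
`1e-8` or 500 iterations, whichever comes first; non-convergence is
flagged on the returned object. EM is restarted (default 50 times) from
quantile-based initial means with random quantile perturbations, keeping
the best log-likelihood. Two numerical guards matter in practice:

- **Emission SD floor (0.2 on the log1p scale).** Counts are integers, so
  the rest state concentrates on a few discrete values (0, 1, 2). An
  unconstrained Gaussian EM will happily collapse one state onto the
  zero-count spike with vanishing variance, absorbing infinite density.
  The floor is well below any plausible within-state spread and removes
  that degenerate optimum without affecting well-separated fits.
- **Degenerate inputs.** Series with fewer than three distinct activity
  levels (e.g. an all-zero recording) cannot identify three states and are
  rejected with an error, as are recordings shorter than 24 h.

A *time-varying* (harmonically modulated) transition matrix is a natural
extension; the package deliberately fits the homogeneous model because
every downstream summary it reports — in particular the scalar p1-1 —
is a time-homogeneous quantity, and the homogeneous model keeps the EM
exactly reproducible at a fixed seed.

### Derived indices

The *fingerprint* averages the posterior state probabilities over days
within clock-time bins (10 min by default), giving the individual's
typical 24-h rest-activity profile. From it we derive

- rest duration `a` = integral of the IA profile over 24 h (hours);
- center of rest `c` = circular mean clock time weighted by IA
  probability;
- Rhythm Index `RI = 100 (W − a²/24) / (a − a²/24)`, clipped to
  [0, 100] %, where `W` is the IA integral over the `a`-hour window
  centered at `c`. The formula is constructed to satisfy the two defining
  limits: a square-wave rest profile (identical bedtimes every day,
  IA self-transition near 1) has `W = a`, hence RI = 100 %; a uniform IA
  profile (`P_IA ≡ a/24`, no circadian regulation of rest) has
  `W = a²/24`, hence RI = 0 %. RI is undefined (`NA`) at `a = 0` or
  `a = 24`; an exactly uniform profile has no circular center, and any
  window placement then gives RI = 0. Because the formula is pinned only
  at these limits, RI values should be compared within analyses done by
  this package, not against other rhythm-index implementations.
- p1-1 = fitted IA→IA transition probability, and the median count over
  Viterbi-decoded HA epochs.

The dichotomy index I<O is the percentage of in-bed epochs with counts
*strictly below* the median out-of-bed count. In-bed status comes from the
sleep diary, not from the HMM — the two instruments are deliberately kept
independent. Days are pooled: one out-of-bed median per recording. Pooling
(rather than averaging per-day indices) uses all epochs symmetrically and
is stable when single nights are short; it is a genuine convention choice
and is stated here because both variants appear in the actigraphy
literature.

r24 is the Pearson autocorrelation of the count series at a 1440-epoch
lag over all overlapping pairs; any series whose period divides 24 h gives
r24 = 1, and a constant series returns `NA`.

The dominant period is the peak of a lightly smoothed, zero-padded
periodogram within a 16–32 h search band, with quadratic interpolation of
the peak bin; its uncertainty comes from resampling whole day-blocks with
replacement (default 100 resamples) and taking 2.5 %/97.5 % quantiles of
the re-estimated peaks. Day-blocks preserve the within-day autocorrelation
that epoch-level resampling would destroy.

## Two-component cosinor of urinary excretion

Timed concentrations (µg/g creatinine) are modelled on the natural-log
scale as

```
log y(t) = M + A12 cos(2πt/12 + θ12) + A24 cos(2πt/24 + θ24) + e(t)
```

with fixed 12-h and 24-h periods. The log transform stabilizes the
multiplicative assay and biological noise; natural log is used (the base
only shifts log-scale parameter values, never flags or reported-scale
quantities). With fixed periods the model is linear in
`(M, A cosθ, −A sinθ)`, so the fit is exact least squares on cos/sin
regressors converted back to amplitude/phase — no nonlinear optimization,
no starting values, no convergence failures. Day-2 samples at the same
clock time enter at `t + 24` and act as replicates under the 24-h-periodic
model.

Reporting convention: mesor = `exp(M)`; the overall amplitude is half the
max–min range of the exponentiated fitted curve on a 1-min grid, and the
overall acrophase is the clock time of that curve's maximum (earliest
minute on ties). This makes the reported mesor and amplitude mutually
consistent on the concentration scale. Relative amplitude is the ratio
amplitude/mesor, reported as a fraction.

**Rhythm detection.** A component is rhythmic when its zero-amplitude test
gives p ≤ 0.1, and a series is rhythmic when either component is. The
liberal 0.1 threshold reflects the sparse design: five parameters
estimated from as few as 7–10 samples. The test itself is the exact
Wald/F test of the component's (cos, sin) coefficient pair against zero,
`F(2, n − 5)` — in a Gaussian linear model this test is exactly
calibrated at every n. The seemingly simpler t-test on the folded
amplitude `Â/se(Â)` is *not*: `Â ≥ 0` by construction, and at n = 10 the
delta-method t-test rejects a true null in roughly 20 % of fits at the
0.1 level. We report `t = Â/se(Â)` for reference but base the flags on
the F form; the package's null-calibration suite verifies a rejection
rate close to nominal (about 11 % at α = 0.1 over 2000 simulated null
fits). Patients with fewer than 7 valid samples for a nucleoside are
excluded from that nucleoside's analysis; samples at a single clock time
leave the harmonics unidentifiable and are rejected as a singular design.

Cohort summaries aggregate per-patient fits per nucleoside: means,
ranges, medians and quartiles for mesor, amplitude and relative
amplitude, the between-patient CV of the mesor, and *circular* statistics
for the acrophase (the circular median of acrophases 23:00 and 01:00 is
midnight, not noon; quartiles are taken on deviations centered at the
circular median).

## Correlation analysis and the bootstrap uncertainty check

Associations between rhythm parameters and rest-activity indices use
Spearman rank correlations with pairwise deletion (at least 4 complete
pairs), two-sided p-values (exact permutation null below n = 10, the
t-approximation otherwise), and significance tiers at 0.1/0.05/0.01/0.001.

Cosinor-derived parameters are estimates, not measurements, so a
correlation involving them is re-examined under their estimation
uncertainty: for each of B = 1000 trials, each patient's *own* residuals
are resampled with replacement, the log series rebuilt, the cosinor refit
(one matrix solve for all trials, reusing the fixed design), the derived
parameter recomputed, and the Spearman p-value recalculated across
patients. The correlation is confirmed only when the 90 % quantile of the
B p-values is ≤ 0.1 — i.e. it must survive in at least 90 % of the
resampled worlds. Resampling stays within patients because the residual
scale is patient-specific; pooling residuals across patients would leak
one patient's noise level into another's refit. The bootstrap refits use
a 10-min curve grid for the derived amplitude/acrophase (the rank
correlation is insensitive to the grid below this resolution, and the
refit matrix stays small).

Covariate effects on any response parameter are screened by bidirectional
stepwise selection minimizing AIC from the full main-effects linear
model (via `MASS::stepAIC`), with the intercept-only model as lower
scope. Two-group contrasts default to the Welch t-test — equality of
variances between, say, patients with and without comorbidities is not
something we wish to assume.

## Chemotherapy-response classification

Daily overnight excretions around a course (at least 5 points) are
regressed as log concentration on day; the course is classified as an
increasing/decreasing trend when the slope's p ≤ 0.05, else "no change".
The log scale makes the class invariant to the measurement unit. CEA
changes compare the last value at or before the course start to the
latest value 30–60 days after; the default convention is multiplicative
and symmetric — ratio > 3/2 is an increase, < 2/3 a decrease — because
"changed by more than 50 %" is ambiguous between multiplicative and
additive readings and only the multiplicative one treats increases and
decreases symmetrically. The additive convention (±50 % relative change)
is available behind a flag.

A patient is a "trend" patient when any monitored nucleoside (default:
1-methylguanosine, 4-acetylcytidine, adenosine, cytidine — configurable)
shows a trend. The trend × CEA-category table is tested by the
Freeman–Halton generalization of Fisher's exact test: all tables sharing
the observed margins are enumerated recursively, and the p-value sums the
multivariate hypergeometric probabilities of tables no more probable than
the observed one, with a relative tolerance of `1e-12` for probability
ties (computed in log space to avoid underflow). Rows or columns with
zero margins are dropped first; a table reduced below 2×2 is degenerate
and returns p = 1. The implementation is validated against R's
independent network-algorithm implementation on hundreds of random
tables. Survival between trend classes is compared by the Welch t-test.

## What the synthetic cohorts emulate — and what they do not

The generators are first-class, tested code and define the study
conditions for every validation:

- **Actigraphy**: a nightly bed window (default 23:00–07:00, i.e. 8 h)
  jittered night-to-night (SD 15 min by default), latent IA inside it,
  brief MA interruptions at a Poisson rate per night (default 1, with
  geometric dwell), and a persistent MA/HA Markov chain in the daytime;
  counts are truncated, integer-rounded lognormal-type emissions on the
  log1p scale. Default emission means (0.4, 3.0, 5.0 log1p units)
  correspond to median counts of roughly 0, 20 and 150 per minute.
- **Urine**: exactly the two-component log-cosine model plus Gaussian
  log-noise, sampled at the study schedule of 10 collections over two
  days (07:00, 11:00, 15:00, 19:00, 23:00). Between-patient mesors are
  lognormal around field-typical medians with SD 0.30 on the log scale
  (CV ≈ 31 %, inside the 25–42 % range typical of such cohorts); the
  within-patient noise SD (0.15–0.25 by phenotype) is a modelling choice,
  as day-to-day variance components are not separately identifiable from
  two days of data.
- **Treatment courses**: log-linear daily excretions over 3 pre + 14
  post-course days, and a two-point CEA series (baseline one week before,
  follow-up at day 45) drawn inside the requested change category —
  the analysis uses only the ±50 % categorization, so two points suffice.
- **Cohorts**: scenario presets `robust-rhythm`, `disrupted` and `mixed`
  set the phenotype blend (40/35/25 % robust/intermediate/disrupted in
  `mixed`), with covariates drawn from plausible categorical margins.

Passing tests on these cohorts demonstrates that the estimators recover
known structure under the stated noise model and remain calibrated under
its null — they do not demonstrate robustness to device artefacts,
missing epochs (a gap is an error, not an imputation target), non-wear,
assay drift, or non-sinusoidal excretion waveforms. Those failure modes
require real recordings.

Problem sizes used by the validation suite and the reproduction script
(5-day recordings; 20-seed decoding checks; 500-replicate acrophase
recovery; 2000-fit null calibrations; 10–15-replicate bootstrap
discrimination runs at B = 1000) were chosen so that each property's
sampling noise is small relative to the tolerance it is tested against.

## Known limitations

- The Rhythm Index formula is anchored only at its published limit
  behaviours; absolute RI values are implementation-specific.
- p1-1 from the homogeneous HMM averages over the day; a time-varying
  transition model would separate nocturnal from diurnal persistence.
- The Freeman–Halton enumeration is exponential in table size; it is
  intended for the small contingency tables of clinical response
  categories (any margin pattern with a few dozen subjects is instant).
- No multiplicity correction is applied across the correlation grid or
  across nucleosides; the bootstrap quantile rule is the only safeguard,
  as in the study design the package implements.
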