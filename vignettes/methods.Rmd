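---
title: "Methods: distress classification from auditory evoked potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distress classification from auditory evoked potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aepscatter)
```

`aepscatter` classifies tinnitus-related distress from auditory evoked
potentials (AEPs) and clinical covariates. This vignette documents the
models, the assumptions behind them, the tunable parameters, and the
design decisions that were genuinely open, so the analysis can be audited
without reading the source.

## The problem and the data model

Two AEP subtypes are analysed per ear. The auditory brainstem response
(ABR) is recorded at 30 kHz over a 15 ms window (450 samples) after a
click at 22/s and 80 dB nHL, band-limited to 33–1500 Hz; its waves of
interest are the vertex-positive peaks I, III and V within ~10 ms. The
auditory middle latency response (AMLR) is recorded at 3 kHz over 150 ms
after a 2 kHz tone burst at 6.1/s and 70 dB nHL (10–1500 Hz); its
components are the troughs Na, Nb and peaks Pa, Pb at ~12–60 ms. All
voltages are microvolts; a latency is milliseconds from stimulus onset,
with sample `k` (0-based) at `k / fs * 1000` ms.

Patients carry a Tinnitus Handicap Inventory score (THI, 0–100; scores below 18
fail cohort inclusion). Distress groups split at THI ≥ 48 ("high", severe to
catastrophic) versus THI < 48 ("low", mild to moderate): the cut separates
the clinically bothersome range while keeping the groups numerically
comparable.

## Synthetic cohorts: what they emulate, and what they do not

No public AEP dataset accompanies this workflow, so every stage is
exercised on synthetic cohorts (`cohort_config()`, `generate_cohort()`).
A waveform is a sum of Gaussian bumps — one per wave template, with a
signed nominal amplitude (negative for troughs) — plus additive noise:

* Default templates (literature-typical nominal values, not empirical
  estimates): ABR I/III/V at 1.6/3.9/5.6 ms, 0.30/0.30/0.45 µV, width
  0.25 ms; small un-annotated II and IV bumps; AMLR Na/Pa/Nb/Pb at
  18/30/42/55 ms, −0.8/+1.0/−0.7/+0.6 µV, width 4 ms.
* Per-ear biological variability: each recorded ear draws one latency and
  one amplitude offset per wave (defaults: ABR 0.1 ms and 0.05 µV; AMLR
  1.0 ms and 0.1 µV; amplitude offsets push peaks up and troughs down so
  signs are preserved). This variability is what makes extracted metrics
  approximately normally distributed and ears exchangeable — exactly the
  distributional structure the downstream t-test workflow assumes. Without
  it, high-SNR latencies collapse onto two or three sample values and the
  parametric tests are miscalibrated. Offsets are drawn independently per
  ear, not shared within a patient: the ear-level two-sample t-tests treat
  ears as independent observations, and the generator emulates the
  structure that analysis assumes. Real ears of one patient are of course
  correlated; modelling that correlation would require a clustered
  analysis that is out of scope here (the classifier stage does respect
  it, by grouping ears into folds).
* Acquisition noise: white Gaussian, default 0.05 µV (a realistic residual
  for averaged evoked potentials with amplitudes under 1 µV); a 1/f option
  exists because residual EEG noise is not white, but the analyses do not
  depend on the noise colour.
* Group effects (high minus low distress), configurable per wave. Defaults
  follow the directions described in the tinnitus electrophysiology
  literature: ABR latencies
  slightly shorter and amplitudes slightly larger in the high-distress
  group (−0.04…−0.08 ms, +0.02…+0.05 µV); AMLR latencies longer and
  absolute amplitudes larger (+1.0…+1.5 ms, 0.10–0.15 µV toward the
  extremum). Magnitudes are generator choices on the order of the
  within-group variability, not values estimated from data.
* THI scores are drawn uniformly inside [18, 47] (low) or [48, 100]
  (high) so the group label and the THI ≥ 48 rule coincide by
  construction; the default high-distress fraction is 0.46, a conventional
  choice, not a claim about prevalence.
* The clinical table has 33 features: 15 named covariates (Age, Height,
  Alcohol, Hearing loss 6000, Hearing loss, Matching type, Family history,
  Education, Vertigo, Frequency, Day pattern, Number sounds, Quality,
  Rhythmic, GUF) plus 18 documented fillers, mixed numeric and
  integer-coded categorical (levels coded 0, 1, 2, …; e.g. two-level
  variables are no = 0 / yes = 1 and ordinal fillers are coded in
  increasing order). Variables named in `clinical_effects` get a
  group-dependent mean shift; `missing_rate` of feature cells are blanked
  at random. The four ear-specific audiological variables are derived from
  a per-ear measures table through the laterality rule (below).

What the generator does **not** emulate: within-patient ear correlation
(see above), non-Gaussian wave shapes, latency–amplitude dependence,
age- or hearing-dependent wave morphology, item-level questionnaire
structure, and informative missingness. Tests passing on these cohorts
show the pipeline recovers what it injects under its own assumptions —
they do not certify performance on clinical recordings.

## Peak annotation

`annotate_records()` finds, per wave, the extremum of the correct polarity
inside a latency window: ABR I 1.0–2.5 ms, III 3.0–4.8 ms, V 4.8–7.5 ms
(maxima); AMLR Na 12–25, Pa 25–40, Nb 35–52, Pb 45–80 ms (Na/Nb minima,
Pa/Pb maxima). The windows are declared assumptions following the
components' physiological ranges; they are configurable. Rules:

* A candidate must be a strict local extremum (greater than its left
  neighbour, at least its right neighbour — so a flat plateau resolves to
  its earliest sample); window-boundary samples are excluded. A flat or
  monotone window yields `found = FALSE` and an explicit `NA` metric,
  never a zero.
* Canonical ordering (I < III < V, Na < Pa < Nb < Pb) is enforced
  greedily: each window is truncated to start after the previously found
  wave.
* Optional zero-phase Gaussian smoothing (`smooth = TRUE`, default sd
  0.1 ms) is off by default: on clean averages it only blurs amplitudes,
  but it helps under heavy noise.

A caveat the tests respect: where waves overlap (e.g. Pa flanked by Na and
Nb), the extremum of the *mixture* is systematically displaced from the
generating bump's centre — by about −0.2 ms for the default AMLR
templates. This is physics, not an annotator defect; generator-fidelity
tests therefore use single-wave templates where the readout is unbiased.

## Group statistics

For each (subtype, wave, metric) the two distress groups are compared
(`compare_metric()`): Levene's test for homogeneity of variance (classical
mean-centred form by default; median-centring available), then a
two-tailed Student t-test if the Levene p ≥ 0.05, otherwise Welch's
unequal-variances t-test. Effect size is Cohen's d with the pooled
standard deviation on the Student branch and the mean-of-variances
analogue on the Welch branch; the 95% CI comes from the chosen test's
degrees of freedom. AMLR amplitudes are compared on absolute values
(trough depth is the clinically meaningful magnitude); ABR amplitudes are
signed. Normality is judged graphically (`plot_metric_qq()`), not by
analytic tests, which over-reject at these sample sizes; the workflow
proceeds parametrically.

Metrics with p < 0.05 become time-domain classifier features
(`select_time_features()`), *without* multiple-testing correction — the
gate is marginal by design, mirroring common practice in this literature;
a Holm option is provided for sensitivity analysis.

Subgroup stratification crosses gender (2) × hearing class (3) × THI
group (2) into exactly 12 strata. Hearing class is the pure-tone average
over 250 Hz–8 kHz thresholds, binned ≤ 20 dB HL (normal), (20, 60] (mild
loss), > 60 (severe loss). The conventional bins ([0–20], [21–60], [>61])
leave non-integer averages between bins undefined; the contiguous
half-open bins above are the implemented resolution. Hearing class is
assigned per ear (for bilateral asymmetric losses per-ear is the finer
and safer choice).

## The wavelet scattering transform

The transform cascades wavelet convolutions, the modulus non-linearity,
and low-pass averaging:

* order 0: `S0 = |x * φ|`
* order 1: `S1(t, λ1) = |x * ψ_λ1| * φ`
* order 2: `S2(t, λ1, λ2) = ||x * ψ_λ1| * ψ_λ2| * φ`

with analytic Morlet wavelets ψ (Gaussian frequency response with the
standard zero-mean correction) and a Gaussian scaling filter φ whose time
support is the invariance scale T. Two filter banks are used (order 2 is
the standard depth: almost all energy sits in orders 0–1, which the
acceptance checks confirm on synthetic batches), with quality factors
Q = (8, 1) wavelets per octave.

The vendor-toolbox conventions behind the reference output shapes are
not public, so this package fixes its own, calibrated once so that the
two reference configurations reproduce those shapes exactly — ABR (30 kHz,
450 samples, T = 6 ms): 40 paths × 15 windows; AMLR (3 kHz, 420 samples,
T = 81 ms): 65 paths × 7 windows. With normalized frequencies (cycles per
sample) and `T_s = T · fs`:

* scaling filter bandwidth `σ_φ = 1.5 / T_s`;
* wavelet bandwidth `σ_ψ(λ) = λ (2^{1/Q} − 1)` (adjacent constant-Q
  filters overlap near half power);
* per bank, geometric centre frequencies `0.4 · 2^{−k/Q}` (the top filter
  sits at 80% of Nyquist to limit aliasing of the analytic response)
  while `σ_ψ > σ_φ`, continued by a linearly spaced tail of
  constant-bandwidth (`σ_φ`) filters every `2σ_φ` down to `λ > 2σ_φ`, so
  wavelet resolution never falls below the averaging filter's;
* an order-2 path (λ1, λ2) is admitted iff λ2 lies strictly below the
  order-1 envelope bandwidth `σ_ψ(λ1)` (standard admissibility);
* critical downsampling: hop `= 2^{round(log2 T_s) − 2}` samples, i.e. a
  quarter of the invariance scale rounded to a power of two; outputs are
  read at samples 0, hop, 2·hop, …, giving `ceil(N / hop)` half-overlapping
  windows.

Numerical choices:

* Convolutions run at full resolution via FFT on a symmetric-reflection
  padded grid (next power of two ≥ 2N); only the final φ-outputs are
  subsampled. At 450-sample signals this is exact and fast; production
  scattering toolboxes downsample intermediates instead, a convention
  this package does not need.
* The banks are normalised to a capped tight frame: wavelet responses are
  rescaled so the Littlewood–Paley sum `|φ̂|² + Σ|ψ̂|²` equals 1 wherever
  the bank has appreciable response, never exceeds 1 anywhere (the
  non-expansiveness bound), with amplification capped at 2× so spectral
  regions the frequency grid genuinely leaves uncovered stay uncovered.
  The covered band — where the frame bound ≥ 0.5 is asserted — is the
  scaling filter's half-power band plus the span of wavelet centres;
  between 2σ_φ and the lowest wavelet the calibrated grid leaves a small
  gap by construction.
* Order 0 takes the modulus `|x * φ|`: a signed voltage series convolved
  with φ can be negative, while the raw tensor must stay non-negative for
  the log transform; the modulus reconciles the two and keeps the
  transform non-expansive.
* `log_coeffs()` computes `ln(max(value, floor))` with floor 1e-12
  (µV-scale units, configurable) — the natural log compresses the heavy
  right tail of scattering magnitudes. The log is applied before
  averaging over windows (`log_first = TRUE`); whether the original
  toolbox logged before or after averaging is ambiguous, so the other
  order is one flag away. `scale_average()` then takes the arithmetic
  mean across windows per path, producing 40 (ABR) or 65 (AMLR) features
  per signal, 105 concatenated.
* The AMLR analysis uses a 420-sample series although 450 are recorded;
  the reference configuration analyses 420, so the pipeline truncates
  explicitly (`truncate_records()`, logged, never silent) and records the
  analysed length in the run log.

## Clinical features and LASSO

`impute_clinical()` replaces missing numeric cells with the observed
column mean and missing categorical cells with the mode (ties resolve to
the lexicographically smallest level, with a message). Ear-specific
audiological variables aggregate to patients by laterality: bilateral
tinnitus averages the ears, unilateral takes the affected ear,
head-derived tinnitus averages the ear(s) with a tinnitus match
(`aggregate_ear_variables()`; a unilateral patient with the affected ear
missing is a data error, not an imputation case).

`lasso_select()` runs L1-penalised logistic regression on the
one-hot-encoded table. "Repeated selection" here means: per repeat,
10-fold CV with re-randomised folds picks a penalty, and a column counts
as selected if its coefficient is nonzero at that penalty; a column (and
its parent categorical feature) is finally selected when chosen in ≥ 50%
of repeats (default 100 repeats; a single-run mode exists). Two penalty
rules are provided: the deviance-minimising `lambda.min` (default) and
the 1-SE rule. The default follows the convention of reporting the
CV-optimal penalty; note that `lambda.min` deliberately trades false
positives for sensitivity and routinely admits noise columns, so when a
sparse, stable subset is the goal — as in the recovery checks of the test
suite — the 1-SE rule is the appropriate mode. Predictors are
standardised inside the fit (glmnet's internal standardisation); whether
the original analysis standardised is unstated, but penalised regression
across mixed-unit covariates is only well-defined on a common scale.

## Classification

Seven classifiers (LDA; linear, radial and polynomial SVM; Gaussian naive
Bayes; single-hidden-layer neural network; random forest) run under
stratified 10-fold cross-validation (`cross_validate()`):

* Instances are ears for AEP-feature and integrated models, patients for
  clinical-only models. In ear-level models the two ears of a patient are
  forced into the same fold: clinical covariates (and in real data the
  waveforms too) are duplicated across a patient's ears, and letting them
  straddle a split would leak.
* Standardisation is fit on the training fold only. Hyperparameters come
  from small fixed grids (SVM cost {0.25, 0.5, 1, 2, 4}; RBF bandwidth =
  median-heuristic γ × {0.5, 1, 2} with cost {0.25, 1, 4}; polynomial
  degree {2, 3} with coef0 = 1, since the homogeneous even-degree kernel
  is sign-symmetric and cannot represent a threshold; RF 500 trees with
  √p ± 1 split candidates; NN size {3, 5, 7}, decay {0.01, 0.1}), chosen
  by inner 5-fold CV on AUC within each training fold.
* Per fold, AUC is the trapezoidal area under the ROC of held-out scores
  (ties stepped diagonally — exactly the Mann–Whitney U statistic over
  `n⁺·n⁻`, an identity the tests assert to 1e-10); sensitivity and
  specificity are taken at the 0.5 posterior threshold, with the
  Youden-optimal threshold reported alongside. The headline numbers are
  means over folds; the pooled-prediction AUC is also reported.
* Everything is deterministic given the seed: fold assignment, inner
  grids, and model RNG all derive from it.

`integrate_features()` broadcasts the selected clinical features to both
ears and concatenates them with the scattering features (e.g. 65 AMLR
coefficients + 15 selected clinical variables = 80 columns);
`benchmark()` tabulates every feature set × model combination and flags
the best AUC per set.

## Problem sizes used by the test suite

The statistical contracts are verified at sizes chosen to keep Monte
Carlo error far from the asserted bands: type-I calibration of the
p < 0.05 gate on 500 null cohorts of 24 patients (every metric within
5% ± 2%); effect-size recovery on an amplitude-shift grid of
{0, 0.25, 0.5, 1} × the 0.05 µV noise scale, 20 seeds × 60 patients,
with the zero-effect AUC required in [0.43, 0.57]; annotator recovery on
1000 noise-free randomized records (± 1 sample); LASSO recovery at
n = 500 with five informative columns of standardized effect 0.8 (5/5
recovered, ≤ 3 false positives, in ≥ 90% of 20 seeds); and the
permutation leakage guard on a 400-patient null cohort, where all seven
classifiers must stay within 0.5 ± 0.07 — at substantially smaller
cohorts the known pessimistic bias of cross-validation under the null
(training- and test-fold class means of a fixed sample anti-correlate)
approaches the band edge, which is a property of CV, not of leakage.

## Known limitations

* The scattering conventions match the reference output shapes and the
  standard construction, but the original toolbox's internals are
  unpublished; coefficient *values* are this package's own convention
  even where shapes agree.
* The ear-level t-tests inherit the independence assumption discussed
  above; a mixed-model extension would be the principled treatment of
  within-patient correlation.
* The marginal p < 0.05 gate controls no family-wise error; the Holm flag
  exists precisely because eleven simultaneous gates at 5% are liberal.
* Synthetic validation bounds what can be claimed: the pipeline is shown
  to be calibrated, leak-free and able to recover injected structure, not
  to reproduce clinical classification performance.
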