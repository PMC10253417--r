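# aepscatter

Classifying tinnitus-related distress from auditory evoked potentials
(AEPs) and clinical covariates.

Tinnitus severity is usually graded with self-report questionnaires such as
the Tinnitus Handicap Inventory (THI, 0–100). An objective complement is to
look for electrophysiological correlates in the auditory pathway: the
auditory brainstem response (ABR, waves I–V within ~10 ms of a click) and
the auditory middle latency response (AMLR, troughs Na/Nb and peaks Pa/Pb
at ~12–60 ms). `aepscatter` implements, end to end and fully tested, a
workflow for separating low-distress (THI < 48) from high-distress
(THI ≥ 48) ears and patients:

1. **Waveform I/O** — a documented XML dialect and long CSV for per-ear
   voltage series in µV with acquisition metadata (`read_aep_records()`,
   `write_aep_records()`, `docs/formats.md`).
2. **Synthetic cohorts** — a generator that emulates the statistical
   structure the analysis assumes (Gaussian-bump waves plus noise, a
   33-variable clinical table, controllable group effects), so every stage
   is testable without patient data (`cohort_config()`,
   `generate_cohort()`).
3. **Peak annotation** — windowed-extremum detection of waves I/III/V and
   Na/Pa/Nb/Pb; latency in ms from stimulus onset, amplitude in µV
   (`annotate_records()`, `metrics_table()`).
4. **Group statistics** — Levene's test gating Student vs Welch t-tests,
   Cohen's d, 95% CIs, THI-48 grouping, gender × hearing stratification
   into 12 subgroups, and the p < 0.05 feature gate (`compare_groups()`,
   `stratify()`, `select_time_features()`).
5. **Wavelet scattering** — a from-scratch second-order wavelet time
   scattering transform. With analytic Morlet wavelets ψ and a Gaussian
   scaling filter φ of support T:

       S0 x(t)        = |x * φ|
       S1 x(t, λ1)    = |x * ψ_λ1| * φ
       S2 x(t, λ1,λ2) = ||x * ψ_λ1| * ψ_λ2| * φ

   with quality factors Q = (8, 1), log coefficients, and averaging over
   time windows into per-signal feature vectors (`scattering_network()`,
   `scatter()`, `scale_average()`).
6. **Clinical features** — mean/mode imputation, ear-to-patient
   aggregation by tinnitus laterality, and repeated cross-validated LASSO
   selection (`impute_clinical()`, `aggregate_ear_variables()`,
   `lasso_select()`).
7. **Classification** — seven classifiers (LDA, linear/radial/polynomial
   SVM, naive Bayes, neural network, random forest) under stratified,
   patient-grouped 10-fold cross-validation, reporting mean AUC,
   sensitivity and specificity (`cross_validate()`, `benchmark()`).

`run_pipeline()` orchestrates all stages from one (YAML-loadable)
configuration with a hash manifest for reproducibility.

## Worked example

```r
library(aepscatter)

cfg <- cohort_config(n_patients = 60, seed = 1)
cohort <- generate_cohort(cfg)

# time-domain metrics and group statistics
metrics <- metrics_table(annotate_records(cohort$records))
cmp <- compare_groups(metrics, cohort$patients)
select_time_features(cmp)

# scattering features for the ABR records
net <- scattering_network(30000, 450, 0.006, c(8, 1))
print(net)
```

The network prints:

```
<scattering_network>
 fs: 30000 Hz, length: 450, invariance scale: 0.006 s
 Q = (8, 1), paths: 40 (1/21/18 by order), windows: 15 (hop 32)
```

i.e. every 450-sample ABR signal becomes a 40-path × 15-window tensor
(one order-0 path, 21 order-1 paths, 18 admissible order-2 paths), and
scale averaging reduces it to 40 features. The AMLR network
(`scattering_network(3000, 420, 0.081, c(8, 1))`) gives 65 paths × 7
windows; concatenated, 105 scattering features per ear. Continuing:

```r
net_amlr <- scattering_network(3000, 420, 0.081, c(8, 1))
amlr <- truncate_records(dplyr::filter(cohort$records, subtype == "AMLR"), 420)
feats <- scatter_features(amlr, net_amlr)
labels <- factor(ifelse(cohort$patients$thi_score >= 48, "high", "low"),
                 c("low", "high"))[match(feats$patient_id,
                                         cohort$patients$patient_id)]
rep <- cross_validate(feats[, -(1:4)], labels, model_spec("random_forest"),
                      folds = 10, seed = 1, groups = feats$patient_id)
glance(rep)
#> # A tibble: 1 × 7
#>   kind          n_features folds   auc sensitivity specificity pooled_auc
#>   <chr>              <int> <dbl> <dbl>       <dbl>       <dbl>      <dbl>
#> 1 random_forest         65    10 0.655       0.575       0.683      0.656
```

An AUC of 0.66 means the 65 AMLR scattering features rank a random
high-distress ear above a random low-distress ear about two times out of
three under the default injected effects (AMLR latencies ~1.5 ms longer
and absolute amplitudes ~0.1 µV larger in the high-distress group,
against per-ear wave jitter of 1 ms / 0.1 µV and 0.05 µV noise). Growing
the configured effects or shrinking the jitter moves the AUC up;
removing the effects moves it to 0.5 (see the parameter-recovery tests).
The small default ABR effects, by contrast, leave the ABR scattering
model near chance.

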