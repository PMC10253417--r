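# shared fixtures, built once per test run

# a small cohort with default group effects, used by several modules
fixture_cohort <- local({
  ch <- NULL
  function() {
    if (is.null(ch)) {
      ch <<- suppressMessages(
        generate_cohort(cohort_config(n_patients = 40, seed = 20260925)))
    }
    ch
  }
})

# random but valid record collections for round-trip property tests
random_records <- function(n, seed) {
  if (n == 0) return(aepscatter:::empty_aep_records())
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      subtype <- sample(c("ABR", "AMLR"), 1)
      len <- sample(c(30L, 450L, 451L), 1)
      aep_record(
        record_id = sprintf("r%03d", i),
        patient_id = sprintf("p%02d", (i + 1) %/% 2),
        ear = sample(c("left", "right"), 1),
        subtype = subtype,
        samples = rnorm(len, sd = 0.5),
        fs_hz = if (runif(1) < 0.5) NULL else sample(c(3000, 30000), 1))
    })
    suppressMessages(dplyr::bind_rows(rows))
  })
}

# a null cohort configuration: no group effects anywhere
null_cohort_config <- function(seed, n_patients = 24, ...) {
  cohort_config(
    n_patients = n_patients, seed = seed,
    latency_shift_ms = list(ABR = c(), AMLR = c()),
    amplitude_shift_uv = list(ABR = c(), AMLR = c()),
    clinical_effects = c(), ...)
}

# ear-level wide table of all time-domain metrics for a cohort
metric_feature_table <- function(cohort) {
  mt <- metrics_table(annotate_records(cohort$records))
  wide <- mt |>
    dplyr::mutate(f = paste(subtype, wave, metric)) |>
    dplyr::select(patient_id, ear, f, value) |>
    tidyr::pivot_wider(names_from = "f", values_from = "value")
  wide[stats::complete.cases(wide), ]
}

patient_labels <- function(cohort, ids) {
  lab <- stats::setNames(as.character(cohort$patients$distress),
                         cohort$patients$patient_id)
  factor(lab[ids], c("low", "high"))
}
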