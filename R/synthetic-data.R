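#' Default wave templates for synthetic AEP waveforms
#'
#' Each generated waveform is a sum of Gaussian bumps, one per template,
#' plus additive noise. Nominal latencies, signed amplitudes (negative for
#' troughs) and widths are literature-typical values for adult click ABR
#' and tone-burst AMLR recordings; they are generator defaults, not
#' empirical estimates. ABR waves II and IV are generated as small bumps
#' but flagged `annotate = FALSE`: the annotation stage scores only
#' I/III/V (ABR) and Na/Pa/Nb/Pb (AMLR).
#'
#' @param subtype `"ABR"` or `"AMLR"`.
#' @return Tibble with columns `label`, `latency_ms`, `amplitude_uv`,
#'   `width_ms`, `annotate`.
#' @export
wave_templates <- function(subtype = c("ABR", "AMLR")) {
  subtype <- match.arg(subtype)
  if (subtype == "ABR") {
    tibble(
      label = c("I", "II", "III", "IV", "V"),
      latency_ms = c(1.6, 2.8, 3.9, 4.9, 5.6),
      amplitude_uv = c(0.30, 0.15, 0.30, 0.18, 0.45),
      width_ms = rep(0.25, 5),
      annotate = c(TRUE, FALSE, TRUE, FALSE, TRUE)
    )
  } else {
    tibble(
      label = c("Na", "Pa", "Nb", "Pb"),
      latency_ms = c(18, 30, 42, 55),
      amplitude_uv = c(-0.8, 1.0, -0.7, 0.6),
      width_ms = rep(4, 4),
      annotate = rep(TRUE, 4)
    )
  }
}

validate_templates <- function(templates, subtype) {
  if (any(templates$width_ms <= 0)) abort("template width_ms must be > 0")
  if (is.unsorted(templates$latency_ms, strictly = TRUE)) {
    abort("template latencies must be strictly increasing")
  }
  if (subtype == "ABR" && any(templates$amplitude_uv < 0)) {
    abort("ABR template amplitudes must be >= 0")
  }
  invisible(templates)
}

default_latency_shifts <- function() {
  # high-distress minus low-distress group means (ms): ABR latencies shorter
  # in the high group, AMLR latencies longer (see the methods vignette)
  list(
    ABR = c(I = -0.04, III = -0.08, V = -0.08),
    AMLR = c(Na = 1.0, Pa = 1.5, Nb = 1.5, Pb = 1.5)
  )
}

default_amplitude_shifts <- function() {
  # high-distress group: larger ABR amplitudes, larger AMLR absolute
  # amplitudes (troughs shift negative)
  list(
    ABR = c(I = 0.05, III = 0.02, V = 0.04),
    AMLR = c(Na = -0.12, Pa = 0.15, Nb = -0.10, Pb = 0.10)
  )
}

#' Configuration for a synthetic cohort
#'
#' Bundles and validates every knob of the synthetic-data generator: cohort
#' size, the high-distress fraction, per-wave group effects (high minus low
#' group), waveform noise, clinical-covariate effects, and the missingness
#' rate of the clinical table. Defaults emulate the structure of the reference
#' cohort this package's analyses assume: 248 patients, both ears recorded
#' per subtype, distress groups split at THI = 48 with roughly 46% of
#' patients in the high group, ABR effects that shorten latencies and raise
#' amplitudes in the high-distress group, and AMLR effects that lengthen
#' latencies and raise absolute amplitudes.
#'
#' @param n_patients Number of patients.
#' @param high_distress_fraction Probability a patient is high-distress.
#' @param latency_shift_ms,amplitude_shift_uv Named lists (`ABR`, `AMLR`) of
#'   named per-wave shifts applied to the high-distress group templates.
#' @param noise_sd_uv Standard deviation of additive white Gaussian noise in
#'   microvolts.
#' @param latency_jitter_sd_ms,amplitude_jitter_sd_uv Named numeric vectors
#'   (per subtype) of biological wave variability: each recorded ear draws
#'   one latency offset and one amplitude offset per wave, independently
#'   across ears. This variability is what makes extracted metrics
#'   approximately normal and ears exchangeable, the distributional
#'   structure the downstream ear-level t-test workflow assumes; set to
#'   zero for exactly templated cohorts.
#' @param noise_type `"white"` (default) or `"one_over_f"` for 1/f-shaped
#'   noise of the same standard deviation.
#' @param clinical_effects Named numeric vector of group mean shifts for
#'   numeric clinical variables (high minus low group).
#' @param missing_rate Fraction of clinical feature cells blanked at random.
#' @param seed Integer RNG seed; all generators are deterministic given it.
#' @param subtypes Character vector of subtypes to simulate.
#' @param templates Named list of template tibbles; default [wave_templates()].
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 248,
                          high_distress_fraction = 0.46,
                          latency_shift_ms = default_latency_shifts(),
                          amplitude_shift_uv = default_amplitude_shifts(),
                          noise_sd_uv = 0.05,
                          latency_jitter_sd_ms = c(ABR = 0.1, AMLR = 1.0),
                          amplitude_jitter_sd_uv = c(ABR = 0.05,
                                                     AMLR = 0.1),
                          noise_type = c("white", "one_over_f"),
                          clinical_effects = c(GUF = 8, Age = 4,
                                               `Hearing loss` = 6),
                          missing_rate = 0.05,
                          seed = 1L,
                          subtypes = c("ABR", "AMLR"),
                          templates = list(ABR = wave_templates("ABR"),
                                           AMLR = wave_templates("AMLR"))) {
  noise_type <- match.arg(noise_type)
  if (high_distress_fraction < 0 || high_distress_fraction > 1) {
    abort("high_distress_fraction must be in [0, 1]")
  }
  if (noise_sd_uv < 0) abort("noise_sd_uv must be >= 0")
  if (any(latency_jitter_sd_ms < 0) || any(amplitude_jitter_sd_uv < 0)) {
    abort("jitter standard deviations must be >= 0")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("missing_rate must be in [0, 1)")
  }
  if (n_patients < 1) abort("n_patients must be >= 1")
  subtypes <- match.arg(subtypes, several.ok = TRUE)
  for (s in subtypes) validate_templates(templates[[s]], s)
  bad <- setdiff(names(clinical_effects), clinical_numeric_variables())
  if (length(bad)) {
    abort(paste0("clinical_effects names unknown or non-numeric: ",
                 paste(bad, collapse = ", ")))
  }
  structure(list(
    n_patients = as.integer(n_patients),
    high_distress_fraction = high_distress_fraction,
    latency_shift_ms = latency_shift_ms,
    amplitude_shift_uv = amplitude_shift_uv,
    noise_sd_uv = noise_sd_uv,
    latency_jitter_sd_ms = latency_jitter_sd_ms,
    amplitude_jitter_sd_uv = amplitude_jitter_sd_uv,
    noise_type = noise_type,
    clinical_effects = clinical_effects, missing_rate = missing_rate,
    seed = as.integer(seed), subtypes = subtypes, templates = templates
  ), class = "cohort_config")
}

#' Generate one synthetic AEP waveform
#'
#' The waveform is the sum of Gaussian bumps
#' `amplitude_uv * exp(-(t - latency_ms)^2 / (2 * width_ms^2))` over the
#' template rows, plus i.i.d. zero-mean Gaussian noise (or 1/f-shaped noise)
#' of standard deviation `noise_sd_uv`. Uses the current RNG state; seed
#' management belongs to the caller (see [generate_cohort()]).
#'
#' @param templates Template tibble (see [wave_templates()]).
#' @param subtype,fs_hz Record metadata.
#' @param n_samples Series length.
#' @param noise_sd_uv Noise standard deviation in microvolts.
#' @param noise_type `"white"` or `"one_over_f"`.
#' @param record_id,patient_id,ear Identifiers for the returned record.
#' @return A one-row record tibble (see [aep_record()]).
#' @export
generate_waveform <- function(templates, subtype, fs_hz = NULL,
                              n_samples = 450L, noise_sd_uv = 0,
                              noise_type = "white",
                              record_id = "r1", patient_id = "p1",
                              ear = "left") {
  subtype <- match.arg(subtype, c("ABR", "AMLR"))
  validate_templates(templates, subtype)
  fs_hz <- fs_hz %||% aep_defaults(subtype)$fs_hz
  window_ms <- n_samples / fs_hz * 1000
  if (any(templates$latency_ms >= window_ms)) {
    abort(paste0("template latency beyond the ", round(window_ms, 2),
                 " ms analysis window"))
  }
  t_ms <- (seq_len(n_samples) - 1) / fs_hz * 1000
  x <- rep(0, n_samples)
  for (i in seq_len(nrow(templates))) {
    x <- x + templates$amplitude_uv[i] *
      exp(-(t_ms - templates$latency_ms[i])^2 / (2 * templates$width_ms[i]^2))
  }
  if (noise_sd_uv > 0) {
    x <- x + noise_sd_uv * draw_noise(n_samples, noise_type)
  }
  aep_record(record_id, patient_id, ear, subtype, x, fs_hz = fs_hz)
}

draw_noise <- function(n, type) {
  if (type == "white") return(rnorm(n))
  # 1/f: shape white noise in the frequency domain, renormalise to unit sd
  w <- rnorm(n)
  wf <- fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)
  shaped <- Re(fft(wf / sqrt(f), inverse = TRUE)) / n
  shaped / sd(shaped)
}

shift_lookup <- function(shifts, labels) {
  if (is.null(shifts) || !length(shifts)) return(rep(0, length(labels)))
  out <- unname(shifts[labels])
  out[is.na(out)] <- 0
  out
}

shifted_templates <- function(templates, subtype, config, high) {
  if (!high) return(templates)
  templates %>%
    mutate(
      latency_ms = .data$latency_ms +
        shift_lookup(config$latency_shift_ms[[subtype]], .data$label),
      amplitude_uv = .data$amplitude_uv +
        shift_lookup(config$amplitude_shift_uv[[subtype]], .data$label)
    )
}

#' Generate a full synthetic cohort
#'
#' Draws patient-level attributes (distress group, THI score, gender,
#' tinnitus laterality), two waveform records per patient per subtype (left
#' and right ear) with the configured group effects applied to the
#' high-distress templates, per-ear audiological measures, and the
#' 33-variable clinical table. The THI score is drawn inside `[18, 47]`
#' (low) or `[48, 100]` (high) so the group label and the THI >= 48 rule
#' coincide for every patient. Byte-identical output given the same
#' configuration (including its seed).
#'
#' @param config A [cohort_config()].
#' @param include_clinical Also generate ear measures and the clinical
#'   table (default `TRUE`). Waveforms and patient attributes are drawn
#'   first, so they are identical either way under the same seed.
#' @return A list with tibbles `patients` (patient_id, gender, laterality,
#'   thi_score, distress), `records`, `ear_measures` and `clinical`
#'   (the patient-by-33-variable table); the latter two are `NULL` when
#'   `include_clinical = FALSE`.
#' @export
generate_cohort <- function(config, include_clinical = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, {
    n <- config$n_patients
    pid <- sprintf("p%03d", seq_len(n))
    high <- rbinom(n, 1, config$high_distress_fraction) == 1
    thi <- ifelse(high, sample(48:100, n, replace = TRUE),
                  sample(18:47, n, replace = TRUE))
    patients <- tibble(
      patient_id = pid,
      gender = sample(c("female", "male"), n, replace = TRUE),
      laterality = sample(c("left", "right", "bilateral", "head"), n,
                          replace = TRUE, prob = c(0.2, 0.2, 0.5, 0.1)),
      thi_score = as.integer(thi),
      distress = factor(ifelse(high, "high", "low"), c("low", "high"))
    )
    # per ear: group-shifted templates plus per-record wave offsets, then
    # acquisition noise; offsets are drawn independently per ear so ears
    # are exchangeable, the structure the ear-level statistics assume
    records <- purrr::map(config$subtypes, function(s) {
      d <- aep_defaults(s)
      t_ms <- (seq_len(d$n_samples) - 1) / d$fs_hz * 1000
      group_tpl <- purrr::map(c(FALSE, TRUE), function(hi) {
        tpl <- shifted_templates(config$templates[[s]], s, config, hi)
        validate_templates(tpl, s)
        if (any(tpl$latency_ms >= max(t_ms))) {
          abort("template latency beyond the analysis window")
        }
        tpl
      })
      lat_sd <- shift_lookup(config$latency_jitter_sd_ms, s)
      amp_sd <- shift_lookup(config$amplitude_jitter_sd_uv, s)
      subject_signal <- function(i) {
        tpl <- group_tpl[[if (high[i]) 2 else 1]]
        nw <- nrow(tpl)
        lat <- tpl$latency_ms + rnorm(nw, 0, lat_sd)
        # keep amplitude signs: offsets push peaks up and troughs down
        amp <- tpl$amplitude_uv +
          sign(tpl$amplitude_uv) * rnorm(nw, 0, amp_sd)
        Reduce(`+`, purrr::map(seq_len(nw), function(j) {
          amp[j] * exp(-(t_ms - lat[j])^2 / (2 * tpl$width_ms[j]^2))
        }))
      }
      idx <- rep(seq_len(n), each = 2)
      ears <- rep(c("left", "right"), n)
      samples <- purrr::map(seq_along(idx), function(k) {
        x <- subject_signal(idx[k])
        if (config$noise_sd_uv > 0) {
          x <- x + config$noise_sd_uv * draw_noise(d$n_samples,
                                                  config$noise_type)
        }
        x
      })
      tibble(
        record_id = paste(pid[idx], tolower(s), substr(ears, 1, 1),
                          sep = "_"),
        patient_id = pid[idx], ear = ears, subtype = s, fs_hz = d$fs_hz,
        samples = samples, stimulus_type = d$stimulus_type,
        rate_hz = d$rate_hz, intensity_db_nhl = d$intensity_db_nhl,
        highpass_hz = d$highpass_hz, lowpass_hz = d$lowpass_hz)
    }) %>% bind_rows()
    if (include_clinical) {
      ear_measures <- generate_ear_measures(patients, config)
      clinical <- generate_clinical_table(config, patients, ear_measures)
    } else {
      ear_measures <- NULL
      clinical <- NULL
    }
    list(patients = patients, records = records,
         ear_measures = ear_measures, clinical = clinical)
  })
}

generate_ear_measures <- function(patients, config) {
  n <- nrow(patients)
  hl_shift <- shift_lookup(config$clinical_effects, "Hearing loss")
  high <- patients$distress == "high"
  base_hl <- pmax(0, rnorm(n, 25, 12) + hl_shift * high)
  rows <- purrr::map(seq_len(n), function(i) {
    matched <- switch(patients$laterality[i],
      left = c(TRUE, FALSE), right = c(FALSE, TRUE),
      bilateral = c(TRUE, TRUE),
      head = if (runif(1) < 0.5) c(TRUE, TRUE) else {
        m <- sample(c(TRUE, FALSE)); m
      })
    tibble(
      patient_id = patients$patient_id[i],
      ear = c("left", "right"),
      hearing_loss_db = round(pmax(0, base_hl[i] + rnorm(2, 0, 5)), 1),
      max_tinnitus_freq_hz = round(pmax(125, rnorm(2, 6000, 1500))),
      matching_loudness_db = round(pmax(0, rnorm(2, 55, 12)), 1),
      min_masking_level_db = round(pmax(0, rnorm(2, 60, 12)), 1),
      matched = matched
    )
  })
  bind_rows(rows)
}

clinical_numeric_variables <- function() {
  c("Age", "Height", "Hearing loss 6000", "Hearing loss", "GUF", "Frequency",
    "Number sounds", "Weight", "BMI", "Tinnitus duration", "Loudness",
    "Sleep quality", "Stress", "Coffee", "Noise exposure", "Awareness")
}

clinical_categorical_variables <- function() {
  c("Alcohol", "Matching type", "Family history", "Education", "Vertigo",
    "Day pattern", "Quality", "Rhythmic", "Smoking", "Sport", "Onset type",
    "Masking", "Somatic modulation", "Headache", "Hyperacusis",
    "Medication", "Handedness")
}

#' Names and types of the 33 clinical variables
#'
#' The schema combines the 15 named covariates of the reference protocol
#' (age, anthropometrics, audiometry, tinnitus descriptors, GUF) with 18
#' documented filler covariates, mixed numeric and integer-coded
#' categorical. Categorical level maps are documented in the methods
#' vignette; levels are coded `0, 1, 2, ...`.
#'
#' @return Tibble with columns `variable`, `type`.
#' @export
clinical_schema <- function() {
  tibble(
    variable = c(clinical_numeric_variables(),
                 clinical_categorical_variables()),
    type = c(rep("numeric", length(clinical_numeric_variables())),
             rep("categorical", length(clinical_categorical_variables())))
  ) %>% arrange(.data$variable)
}

#' Generate the 33-variable clinical table
#'
#' One row per patient; 33 feature columns plus `patient_id`, `thi_score`
#' and `laterality` carried for labelling and ear aggregation. Variables
#' named in `config$clinical_effects` have their high-distress group mean
#' shifted by the configured amount; `missing_rate` of feature cells are
#' blanked at random (`NA`). The four audiological variables subject to the
#' ear-to-patient rule ("Hearing loss", "Frequency" i.e. maximum tinnitus
#' frequency, matching loudness and minimal masking level contributions)
#' are derived from `ear_measures` via [aggregate_ear_variables()].
#'
#' @param config A [cohort_config()].
#' @param patients Patient tibble from [generate_cohort()].
#' @param ear_measures Per-ear audiological tibble; generated if `NULL`.
#'   Uses the current RNG state (seed management belongs to the caller).
#' @return The clinical tibble.
#' @export
generate_clinical_table <- function(config, patients, ear_measures = NULL) {
  n <- nrow(patients)
  if (is.null(ear_measures)) ear_measures <- generate_ear_measures(patients, config)
  high <- patients$distress == "high"
  eff <- function(v) shift_lookup(config$clinical_effects, v)
  agg <- aggregate_ear_variables(ear_measures, patients)
  num <- tibble(
    Age = round(pmin(80, pmax(18, rnorm(n, 52, 12) + eff("Age") * high))),
    Height = round(rnorm(n, 172, 9) + eff("Height") * high),
    Weight = round(rnorm(n, 78, 12) + eff("Weight") * high),
    `Hearing loss 6000` = round(pmax(0, rnorm(n, 30, 15) +
                                       eff("Hearing loss 6000") * high), 1),
    `Hearing loss` = agg$hearing_loss,
    GUF = as.integer(round(pmin(45, pmax(0, rnorm(n, 15, 7) +
                                           eff("GUF") * high)))),
    Frequency = agg$max_tinnitus_freq,
    `Number sounds` = pmin(5, pmax(1, round(rnorm(n, 2, 1) +
                                              eff("Number sounds") * high))),
    `Tinnitus duration` = round(pmax(0.5, rnorm(n, 8, 5) +
                                       eff("Tinnitus duration") * high), 1),
    Loudness = round(pmin(100, pmax(0, agg$matching_loudness +
                                      eff("Loudness") * high)), 1),
    `Sleep quality` = pmin(10, pmax(0, round(rnorm(n, 5, 2) +
                                               eff("Sleep quality") * high))),
    Stress = pmin(10, pmax(0, round(rnorm(n, 5, 2) + eff("Stress") * high))),
    Coffee = pmax(0, round(rnorm(n, 2, 1.5) + eff("Coffee") * high)),
    `Noise exposure` = pmin(10, pmax(0, round(rnorm(n, 4, 2) +
                                                eff("Noise exposure") * high))),
    Awareness = pmin(100, pmax(0, round(rnorm(n, 55, 20) +
                                          eff("Awareness") * high))),
    BMI = NA_real_
  )
  num$BMI <- round(num$Weight / (num$Height / 100)^2, 1)
  cats <- clinical_categorical_variables()
  nlevels <- c(Alcohol = 3, `Matching type` = 3, `Family history` = 2,
               Education = 4, Vertigo = 2, `Day pattern` = 3, Quality = 4,
               Rhythmic = 2, Smoking = 3, Sport = 3, `Onset type` = 2,
               Masking = 3, `Somatic modulation` = 2, Headache = 2,
               Hyperacusis = 2, Medication = 2, Handedness = 2)
  cat_tbl <- purrr::map(cats, function(v) {
    sample.int(nlevels[[v]], n, replace = TRUE) - 1L
  }) %>% setNames(cats) %>% as_tibble()
  clinical <- dplyr::bind_cols(
    tibble(patient_id = patients$patient_id,
           thi_score = patients$thi_score,
           laterality = patients$laterality),
    num[, intersect(clinical_numeric_variables(), names(num))],
    cat_tbl
  )
  feat <- clinical_schema()$variable
  if (config$missing_rate > 0) {
    for (v in feat) {
      blank <- runif(n) < config$missing_rate
      clinical[[v]][blank] <- NA
    }
  }
  clinical
}
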