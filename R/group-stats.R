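#' Classify hearing level from audiometric thresholds
#'
#' Averages the supplied pure-tone thresholds (octave frequencies between
#' 250 Hz and 8 kHz) and bins the average into `normal` (<= 20 dB HL),
#' `mild_loss` ((20, 60] dB HL) or `severe_loss` (> 60 dB HL). The bins are
#' contiguous half-open intervals, so non-integer averages are always
#' classified.
#'
#' @param thresholds Numeric vector of thresholds for one ear (dB HL), or a
#'   numeric matrix / data frame with one row per ear.
#' @return A factor with levels `normal`, `mild_loss`, `severe_loss` (one
#'   element per ear).
#' @examples
#' hearing_class(c(10, 15, 20))
#' hearing_class(45)
#' @export
hearing_class <- function(thresholds) {
  pta <- if (is.matrix(thresholds) || is.data.frame(thresholds)) {
    if (!ncol(thresholds)) abort("no thresholds supplied")
    rowMeans(as.matrix(thresholds), na.rm = TRUE)
  } else {
    if (!length(thresholds)) abort("no thresholds supplied")
    mean(thresholds, na.rm = TRUE)
  }
  if (anyNA(pta)) abort("no observed thresholds for at least one ear")
  cut(pta, breaks = c(-Inf, 20, 60, Inf),
      labels = c("normal", "mild_loss", "severe_loss"))
}

#' Compare one waveform metric between distress groups
#'
#' Implements the per-metric statistical recipe: Levene's test for
#' homogeneity of variance on the two samples; a two-tailed Student t-test
#' when `levene_p >= var_alpha`, otherwise Welch's unequal-variances
#' t-test; Cohen's d with the pooled standard deviation (Student branch) or
#' its Welch analogue (mean of the two variances); the 95% confidence
#' interval for the mean difference from the chosen test's degrees of
#' freedom. The orientation of `t` and `d` is `low` minus `high`.
#'
#' @param values_low,values_high Numeric samples (missing values dropped);
#'   each needs at least two observations.
#' @param levene_center Centering for Levene's test: `"mean"` (classical
#'   test, default) or `"median"` (Brown-Forsythe variant).
#' @param var_alpha Significance level of the variance gate (default 0.05).
#' @param metric_id Optional label copied into the output.
#' @return A one-row tibble: `metric_id`, `n_low`, `n_high`, `mean_low`,
#'   `sd_low`, `mean_high`, `sd_high`, `levene_p`, `test_used`, `t_stat`,
#'   `df`, `p_value`, `ci_lo`, `ci_hi`, `cohens_d`.
#' @export
compare_metric <- function(values_low, values_high,
                           levene_center = c("mean", "median"),
                           var_alpha = 0.05, metric_id = NA_character_) {
  levene_center <- match.arg(levene_center)
  x <- values_low[!is.na(values_low)]
  y <- values_high[!is.na(values_high)]
  if (length(x) < 2 || length(y) < 2) {
    abort(paste0("insufficient data for metric ", metric_id,
                 ": need n >= 2 per group (got ", length(x), "/",
                 length(y), ")"))
  }
  lev <- car::leveneTest(
    c(x, y), factor(rep(c("low", "high"), c(length(x), length(y)))),
    center = if (levene_center == "mean") base::mean else stats::median)
  levene_p <- lev[["Pr(>F)"]][1]
  welch <- levene_p < var_alpha
  tt <- t.test(x, y, var.equal = !welch, conf.level = 0.95)
  d <- if (welch) {
    (mean(x) - mean(y)) / sqrt((var(x) + var(y)) / 2)
  } else {
    sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                 (length(x) + length(y) - 2))
    (mean(x) - mean(y)) / sp
  }
  tibble(
    metric_id = metric_id, n_low = length(x), n_high = length(y),
    mean_low = mean(x), sd_low = sd(x),
    mean_high = mean(y), sd_high = sd(y),
    levene_p = levene_p,
    test_used = if (welch) "welch" else "student",
    t_stat = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
    cohens_d = d
  )
}

canonical_wave_order <- function() {
  tibble(subtype = rep(c("ABR", "AMLR"), c(3, 4)),
         wave = c("I", "III", "V", "Na", "Pa", "Nb", "Pb")) %>%
    mutate(wave_rank = row_number())
}

#' Group comparisons for every waveform metric
#'
#' Joins a long metric table (see [metrics_table()]) to patient distress
#' labels and runs [compare_metric()] per (subtype, wave, metric). AMLR
#' amplitudes are compared on absolute values (the convention for trough
#' components); ABR amplitudes and all latencies are compared on signed
#' values. Rows with unfound waves are dropped per metric.
#'
#' @param metrics Long metric table from [metrics_table()].
#' @param patients Tibble with `patient_id` and a `distress` factor
#'   (`low`/`high`), e.g. from [generate_cohort()].
#' @inheritParams compare_metric
#' @return Tibble of [compare_metric()] rows plus `subtype`, `wave`,
#'   `metric`, in canonical wave order.
#' @export
compare_groups <- function(metrics, patients,
                           levene_center = c("mean", "median"),
                           var_alpha = 0.05) {
  levene_center <- match.arg(levene_center)
  dat <- metrics %>%
    left_join(patients %>% select("patient_id", "distress"),
              by = "patient_id") %>%
    filter(.data$found, !is.na(.data$value)) %>%
    mutate(value = ifelse(.data$subtype == "AMLR" &
                            .data$metric == "amplitude",
                          abs(.data$value), .data$value))
  combos <- dat %>% distinct(.data$subtype, .data$wave, .data$metric)
  out <- purrr::pmap(combos, function(subtype, wave, metric) {
    sub <- dat[dat$subtype == subtype & dat$wave == wave &
                 dat$metric == metric, ]
    compare_metric(sub$value[sub$distress == "low"],
                   sub$value[sub$distress == "high"],
                   levene_center = levene_center, var_alpha = var_alpha,
                   metric_id = paste(subtype, wave, metric, sep = ":")) %>%
      mutate(subtype = subtype, wave = wave, metric = metric, .before = 1)
  }) %>% bind_rows()
  out %>%
    left_join(canonical_wave_order(), by = c("subtype", "wave")) %>%
    arrange(.data$wave_rank, .data$metric) %>%
    select(-"wave_rank")
}

#' Stratify ears by gender, hearing class and THI group
#'
#' Crosses 2 genders x 3 hearing classes x 2 THI groups into the twelve
#' strata of the subgroup analysis. The result is a partition: every ear
#' appears in exactly one stratum, and empty strata are retained.
#'
#' @param ears Tibble with one row per ear and columns `gender`
#'   (`female`/`male`), `hearing_class` (`normal`/`mild_loss`/
#'   `severe_loss`), `thi_group` (`low`/`high`) and an identifier column
#'   (`ear_id`, or `patient_id` + `ear`).
#' @return Tibble of 12 rows: the three stratum attributes, `n`, and a
#'   list-column `members` of identifier vectors.
#' @export
stratify <- function(ears) {
  needed <- c("gender", "hearing_class", "thi_group")
  missing_cols <- setdiff(needed, names(ears))
  if (length(missing_cols)) {
    abort(paste0("ears is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(ears[needed])) abort("stratification attributes contain NA")
  ok <- list(gender = c("female", "male"),
             hearing_class = c("normal", "mild_loss", "severe_loss"),
             thi_group = c("low", "high"))
  for (v in needed) {
    bad <- setdiff(unique(as.character(ears[[v]])), ok[[v]])
    if (length(bad)) {
      abort(paste0("invalid ", v, " value(s): ", paste(bad, collapse = ", ")))
    }
  }
  id <- if ("ear_id" %in% names(ears)) {
    ears$ear_id
  } else if (all(c("patient_id", "ear") %in% names(ears))) {
    paste(ears$patient_id, ears$ear, sep = ":")
  } else {
    abort("ears needs an 'ear_id' column or 'patient_id' + 'ear'")
  }
  grid <- tidyr::expand_grid(
    gender = factor(ok$gender, ok$gender),
    hearing_class = factor(ok$hearing_class, ok$hearing_class),
    thi_group = factor(ok$thi_group, ok$thi_group))
  key <- paste(ears$gender, ears$hearing_class, ears$thi_group, sep = "|")
  grid %>%
    mutate(members = purrr::pmap(grid, function(gender, hearing_class,
                                                thi_group) {
      id[key == paste(gender, hearing_class, thi_group, sep = "|")]
    })) %>%
    mutate(n = lengths(.data$members))
}

#' Select significant time-domain features
#'
#' Keeps the metrics whose group comparison falls below `alpha`, in
#' canonical wave order. No multiple-testing correction is applied by
#' default (the workflow gates each metric marginally at p < 0.05); a Holm
#' correction is available for sensitivity analysis.
#'
#' @param comparisons Output of [compare_groups()] on the THI-only
#'   grouping.
#' @param alpha Significance gate (default 0.05).
#' @param method `"none"` (default) or `"holm"`.
#' @return Tibble of selected rows: `subtype`, `wave`, `metric`,
#'   `feature`, `p_value`.
#' @export
select_time_features <- function(comparisons, alpha = 0.05,
                                 method = c("none", "holm")) {
  method <- match.arg(method)
  p <- if (method == "holm") {
    stats::p.adjust(comparisons$p_value, "holm")
  } else {
    comparisons$p_value
  }
  comparisons %>%
    mutate(p_gate = p) %>%
    filter(.data$p_gate < alpha) %>%
    left_join(canonical_wave_order(), by = c("subtype", "wave")) %>%
    arrange(.data$wave_rank, .data$metric) %>%
    mutate(feature = paste(.data$subtype, .data$wave, .data$metric,
                           sep = ":")) %>%
    select("subtype", "wave", "metric", "feature", "p_value")
}

#' Quantile-quantile plots per waveform metric and group
#'
#' Normality is judged graphically in this workflow (analytic tests are
#' oversensitive at these sample sizes); this exports the per-metric,
#' per-group QQ plots against the normal distribution.
#'
#' @inheritParams compare_groups
#' @return A ggplot object, facetted by metric with groups coloured.
#' @export
plot_metric_qq <- function(metrics, patients) {
  dat <- metrics %>%
    left_join(patients %>% select("patient_id", "distress"),
              by = "patient_id") %>%
    filter(.data$found, !is.na(.data$value)) %>%
    mutate(label = paste(.data$subtype, .data$wave, .data$metric))
  ggplot2::ggplot(dat, ggplot2::aes(sample = .data$value,
                                    colour = .data$distress)) +
    ggplot2::stat_qq(size = 0.5) + ggplot2::stat_qq_line() +
    ggplot2::facet_wrap(~label, scales = "free_y") +
    ggplot2::labs(x = "theoretical quantiles", y = "sample quantiles") +
    ggplot2::theme_minimal()
}

#' Boxplots of waveform metrics by distress group
#'
#' @inheritParams compare_groups
#' @return A ggplot object.
#' @export
plot_metric_box <- function(metrics, patients) {
  dat <- metrics %>%
    left_join(patients %>% select("patient_id", "distress"),
              by = "patient_id") %>%
    filter(.data$found, !is.na(.data$value)) %>%
    mutate(label = paste(.data$subtype, .data$wave, .data$metric))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$distress, y = .data$value,
                                    fill = .data$distress)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~label, scales = "free_y") +
    ggplot2::labs(x = "THI distress group", y = "metric value") +
    ggplot2::theme_minimal()
}
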