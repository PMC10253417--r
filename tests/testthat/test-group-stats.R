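# closed-form oracle for the pooled-variance t-test and Cohen's d
oracle_student <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df),
       d = (mean(x) - mean(y)) / sqrt(sp2))
}

oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  se2 <- var(x) / nx + var(y) / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((var(x) / nx)^2 / (nx - 1) + (var(y) / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df),
       d = (mean(x) - mean(y)) / sqrt((var(x) + var(y)) / 2))
}

test_that("compare_metric matches the textbook closed forms", {
  low <- c(1, 2, 3, 4, 5); high <- c(2, 3, 4, 5, 6)
  cmp <- compare_metric(low, high)
  expect_equal(cmp$test_used, "student")
  expect_equal(cmp$t_stat, -1, tolerance = 1e-12)
  expect_equal(cmp$df, 8)
  expect_equal(cmp$p_value, 0.34659351, tolerance = 1e-6)
  expect_equal(cmp$cohens_d, -0.6324555, tolerance = 1e-6)
  # randomized cases against both oracle branches
  withr::with_seed(55, {
    for (i in 1:30) {
      x <- rnorm(sample(5:40, 1), sd = sample(c(1, 5), 1))
      y <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1),
                 sd = sample(c(1, 5), 1))
      cmp <- compare_metric(x, y)
      o <- if (cmp$test_used == "welch") oracle_welch(x, y) else
        oracle_student(x, y)
      expect_equal(cmp$t_stat, o$t, tolerance = 1e-10)
      expect_equal(cmp$df, o$df, tolerance = 1e-10)
      expect_equal(cmp$p_value, o$p, tolerance = 1e-10)
      expect_equal(cmp$cohens_d, o$d, tolerance = 1e-10)
      # CI from the chosen test's df
      se <- abs(mean(x) - mean(y)) / abs(o$t)
      hw <- qt(0.975, o$df) * se
      expect_equal(cmp$ci_hi - cmp$ci_lo, 2 * hw, tolerance = 1e-8)
    }
  })
})

test_that("identical samples give t = 0, p = 1, d = 0", {
  cmp <- compare_metric(c(1, 2, 3), c(1, 2, 3))
  expect_equal(cmp$t_stat, 0)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$cohens_d, 0)
})

test_that("the Levene gate selects Welch under gross variance inequality", {
  withr::with_seed(66, {
    used <- replicate(200, {
      compare_metric(rnorm(50, sd = 1), rnorm(50, sd = 10))$test_used
    })
    expect_gte(mean(used == "welch"), 0.95)
  })
  expect_error(compare_metric(1, c(1, 2)), "insufficient")
})

test_that("hearing classes follow the half-open pure-tone-average bins", {
  expect_equal(as.character(hearing_class(15)), "normal")
  expect_equal(as.character(hearing_class(45)), "mild_loss")
  expect_equal(as.character(hearing_class(20)), "normal")  # boundary
  expect_equal(as.character(hearing_class(60)), "mild_loss")
  expect_equal(as.character(hearing_class(60.5)), "severe_loss")
  expect_equal(as.character(hearing_class(c(10, 20, 30))), "normal")
  m <- rbind(c(10, 10), c(40, 50), c(70, 80))
  expect_equal(as.character(hearing_class(m)),
               c("normal", "mild_loss", "severe_loss"))
  expect_error(hearing_class(numeric(0)), "no observed|no thresholds")
})

test_that("stratification forms the twelve-way partition", {
  withr::with_seed(12, {
    ears <- tibble::tibble(
      ear_id = sprintf("e%03d", 1:120),
      gender = sample(c("female", "male"), 120, TRUE),
      hearing_class = sample(c("normal", "mild_loss", "severe_loss"),
                             120, TRUE),
      thi_group = sample(c("low", "high"), 120, TRUE))
    s <- stratify(ears)
    expect_equal(nrow(s), 12)
    expect_equal(sum(s$n), 120)
    all_members <- unlist(s$members)
    expect_setequal(all_members, ears$ear_id)
    expect_equal(anyDuplicated(all_members), 0)
  })
})

test_that("a single-ear cohort fills one stratum and leaves 11 empty", {
  ears <- tibble::tibble(ear_id = "e1", gender = "female",
                         hearing_class = "normal", thi_group = "high")
  s <- stratify(ears)
  expect_equal(sum(s$n == 0), 11)
  expect_equal(sum(s$n), 1)
})

test_that("a balanced cohort of 240 ears gives strata of 20", {
  grid <- tidyr::expand_grid(
    gender = c("female", "male"),
    hearing_class = c("normal", "mild_loss", "severe_loss"),
    thi_group = c("low", "high"), rep = 1:20)
  grid$ear_id <- sprintf("e%03d", seq_len(nrow(grid)))
  s <- stratify(grid)
  expect_true(all(s$n == 20))
  expect_error(stratify(grid[, c("ear_id", "gender")]), "missing")
})

test_that("the p < 0.05 gate reproduces the expected selection pattern", {
  sig <- tibble::tribble(
    ~subtype, ~wave, ~metric,
    "ABR", "III", "latency",
    "ABR", "V", "latency",
    "ABR", "I", "amplitude",
    "ABR", "V", "amplitude",
    "AMLR", "Pa", "latency",
    "AMLR", "Nb", "latency",
    "AMLR", "Pb", "latency",
    "AMLR", "Na", "amplitude",
    "AMLR", "Pa", "amplitude",
    "AMLR", "Nb", "amplitude",
    "AMLR", "Pb", "amplitude")
  all_metrics <- tidyr::expand_grid(
    subtype = c("ABR", "AMLR"),
    wave = c("I", "III", "V", "Na", "Pa", "Nb", "Pb"),
    metric = c("latency", "amplitude")) |>
    dplyr::filter((subtype == "ABR" & wave %in% c("I", "III", "V")) |
                    (subtype == "AMLR" & wave %in% c("Na", "Pa", "Nb",
                                                     "Pb")))
  comparisons <- dplyr::mutate(
    all_metrics,
    sig = paste(subtype, wave, metric) %in%
      paste(sig$subtype, sig$wave, sig$metric),
    p_value = ifelse(sig, 0.01, 0.5))
  sel <- select_time_features(comparisons)
  expect_equal(nrow(sel), 11)
  expect_setequal(sel$feature, paste(sig$subtype, sig$wave, sig$metric,
                                     sep = ":"))
  # canonical order: waves I, III, V, Na, Pa, Nb, Pb
  expect_equal(unique(sel$wave), c("I", "III", "V", "Na", "Pa", "Nb", "Pb"))
  # no selection when nothing is significant
  none <- dplyr::mutate(all_metrics, p_value = 0.5)
  expect_equal(nrow(select_time_features(none)), 0)
})

test_that("an injected single-wave effect is the one selected", {
  withr::with_seed(77, {
    hits <- replicate(20, {
      seed <- sample.int(1e6, 1)
      cfg <- cohort_config(
        n_patients = 150, seed = seed, noise_sd_uv = 0.03,
        latency_shift_ms = list(ABR = c(V = 0.15), AMLR = c()),
        amplitude_shift_uv = list(ABR = c(), AMLR = c()),
        clinical_effects = c())
      ch <- suppressMessages(generate_cohort(cfg, include_clinical = FALSE))
      mt <- metrics_table(annotate_records(ch$records))
      sel <- select_time_features(compare_groups(mt, ch$patients),
                                  alpha = 0.001)
      nrow(sel) >= 1 && "ABR:V:latency" %in% sel$feature
    })
    expect_gte(mean(hits), 0.9)
  })
})

test_that("AMLR amplitudes are compared on absolute values", {
  ch <- fixture_cohort()
  mt <- metrics_table(annotate_records(ch$records))
  cmp <- compare_groups(mt, ch$patients)
  na_row <- cmp[cmp$subtype == "AMLR" & cmp$wave == "Na" &
                  cmp$metric == "amplitude", ]
  # Na is a trough (negative voltage); means compared on |value| are positive
  expect_gt(na_row$mean_low, 0)
  expect_gt(na_row$mean_high, 0)
  abr_i <- cmp[cmp$subtype == "ABR" & cmp$wave == "I" &
                 cmp$metric == "amplitude", ]
  expect_gt(abr_i$mean_low, 0)  # signed, positive peak
})

test_that("the Holm option is stricter than the marginal gate", {
  comparisons <- tibble::tibble(
    subtype = "ABR", wave = c("I", "III", "V"), metric = "latency",
    p_value = c(0.02, 0.03, 0.04))
  marginal <- select_time_features(comparisons)
  holm <- select_time_features(comparisons, method = "holm")
  expect_equal(nrow(marginal), 3)
  expect_lt(nrow(holm), 3)
})

test_that("metric plots build without error", {
  ch <- fixture_cohort()
  abr <- dplyr::filter(ch$records, subtype == "ABR")[1:20, ]
  mt <- metrics_table(annotate_records(abr))
  p1 <- plot_metric_qq(mt, ch$patients)
  p2 <- plot_metric_box(mt, ch$patients)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
  f <- withr::local_tempfile(fileext = ".png")
  suppressMessages(ggplot2::ggsave(f, p1, width = 8, height = 6, dpi = 60))
  expect_true(file.exists(f))
})
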