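#' Assemble a pipeline run configuration
#'
#' Collects every stage's settings in one validated list: the synthetic
#' cohort (or, in future, loaded data), the two scattering networks, the
#' statistics gate, LASSO selection, and the classification benchmark.
#' Accepts the same structure from a YAML or JSON file via
#' [read_run_config()].
#'
#' @param cohort A [cohort_config()] or a named list of its arguments.
#' @param scattering Named list per subtype with `invariance_scale_s`,
#'   `q_factors` and optionally `truncate_to` (samples).
#' @param stats_alpha Significance gate for time-domain features.
#' @param lasso Named list of [lasso_select()] arguments
#'   (`folds`, `repeats`, `threshold`, `rule`).
#' @param models Character vector of classifier kinds.
#' @param folds Outer CV folds for the benchmark.
#' @param seed Global seed (mandatory); stage seeds derive from it.
#' @param outdir Output directory for stage artifacts.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort = list(),
                       scattering = list(
                         ABR = list(invariance_scale_s = 0.006,
                                    q_factors = c(8, 1)),
                         AMLR = list(invariance_scale_s = 0.081,
                                     q_factors = c(8, 1),
                                     truncate_to = 420)),
                       stats_alpha = 0.05,
                       lasso = list(folds = 10, repeats = 20,
                                    threshold = 0.5, rule = "min"),
                       models = model_kinds(),
                       folds = 10,
                       seed = NULL,
                       outdir = tempfile("aep_run_")) {
  if (is.null(seed)) abort("run_config requires an explicit seed")
  if (!inherits(cohort, "cohort_config")) {
    cohort$seed <- cohort$seed %||% seed
    cohort <- do.call(cohort_config, cohort)
  }
  for (s in names(scattering)) {
    if (is.null(scattering[[s]]$invariance_scale_s)) {
      abort(paste0("scattering settings for ", s,
                   " lack invariance_scale_s"))
    }
    scattering[[s]]$q_factors <- scattering[[s]]$q_factors %||% c(8, 1)
  }
  models <- match.arg(models, model_kinds(), several.ok = TRUE)
  structure(list(cohort = cohort, scattering = scattering,
                 stats_alpha = stats_alpha, lasso = lasso, models = models,
                 folds = folds, seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose top-level
#'   keys are [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(cfg$scattering)) {
    cfg$scattering <- purrr::map(cfg$scattering, function(s) {
      s$q_factors <- as.numeric(unlist(s$q_factors %||% c(8, 1)))
      s
    })
  }
  if (!is.null(cfg$cohort)) {
    for (nm in c("latency_shift_ms", "amplitude_shift_uv")) {
      if (!is.null(cfg$cohort[[nm]])) {
        cfg$cohort[[nm]] <- purrr::map(cfg$cohort[[nm]], unlist)
      }
    }
    if (!is.null(cfg$cohort$clinical_effects)) {
      cfg$cohort$clinical_effects <- unlist(cfg$cohort$clinical_effects)
    }
  }
  do.call(run_config, cfg)
}

log_stage <- function(con, stage, ...) {
  entry <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                stage = stage, ...)
  writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE), con)
}

#' Run the full pipeline
#'
#' Executes simulate -> annotate -> stats -> scatter -> clinical-prep ->
#' lasso -> benchmark, writing every intermediate artifact under
#' `config$outdir` together with a line-delimited JSON run log and a
#' manifest listing settings, seeds and output MD5 hashes. Re-running the
#' same configuration reproduces identical hashes.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (list with `stages`, `hashes`,
#'   `settings`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  logcon <- file(out("run_log.jsonl"), open = "wt")
  on.exit(close(logcon))
  stages <- character()

  # 1 simulate
  cohort <- generate_cohort(config$cohort)
  write_aep_records(cohort$records, out("records.xml"))
  write_clinical_table(cohort$clinical, out("clinical.csv"))
  utils::write.csv(cohort$patients, out("patients.csv"), row.names = FALSE)
  log_stage(logcon, "simulate", n_patients = nrow(cohort$patients),
            n_records = nrow(cohort$records), seed = config$cohort$seed)
  stages <- c(stages, "simulate")

  # 2 annotate
  ann <- annotate_records(cohort$records)
  metrics <- metrics_table(ann)
  utils::write.csv(metrics, out("metrics.csv"), row.names = FALSE)
  log_stage(logcon, "annotate", n_annotations = nrow(ann),
            found_rate = mean(ann$found))
  stages <- c(stages, "annotate")

  # 3 stats
  comparisons <- compare_groups(metrics, cohort$patients)
  time_features <- select_time_features(comparisons, config$stats_alpha)
  utils::write.csv(comparisons, out("comparisons.csv"), row.names = FALSE)
  utils::write.csv(time_features, out("time_features.csv"),
                   row.names = FALSE)
  log_stage(logcon, "stats", n_comparisons = nrow(comparisons),
            n_selected = nrow(time_features), alpha = config$stats_alpha)
  stages <- c(stages, "stats")

  # 4 scatter
  scat <- purrr::imap(config$scattering, function(s, subtype) {
    recs <- cohort$records %>% filter(.data$subtype == !!subtype)
    if (!is.null(s$truncate_to)) {
      recs <- truncate_records(recs, s$truncate_to)
    }
    n <- length(recs$samples[[1]])
    net <- scattering_network(recs$fs_hz[1], n, s$invariance_scale_s,
                              s$q_factors)
    feats <- scatter_features(recs, net)
    utils::write.csv(feats, out(paste0("wst_", tolower(subtype), ".csv")),
                     row.names = FALSE)
    log_stage(logcon, "scatter", subtype = subtype, signal_length = n,
              hop = net$hop, n_paths = nrow(net$paths),
              n_windows = net$n_windows)
    list(net = net, feats = feats)
  })
  stages <- c(stages, "scatter")

  # 5 clinical preparation
  clinical <- impute_clinical(cohort$clinical)
  utils::write.csv(clinical, out("clinical_imputed.csv"), row.names = FALSE)
  log_stage(logcon, "clinical",
            imputed_cells = sum(is.na(cohort$clinical[
              intersect(clinical_schema()$variable,
                        names(cohort$clinical))])))
  stages <- c(stages, "clinical")

  # 6 lasso
  labels_patient <- binarize_thi(clinical$thi_score)
  sel <- lasso_select(clinical, labels_patient,
                      folds = config$lasso$folds %||% 10,
                      repeats = config$lasso$repeats %||% 20,
                      threshold = config$lasso$threshold %||% 0.5,
                      rule = config$lasso$rule %||% "min",
                      seed = config$seed)
  utils::write.csv(tidy(sel), out("lasso_report.csv"), row.names = FALSE)
  log_stage(logcon, "select", n_selected = length(sel$selected))
  stages <- c(stages, "select")

  # 7 benchmark
  feature_sets <- build_feature_sets(cohort, metrics, time_features, scat,
                                     clinical, sel)
  bench <- benchmark(feature_sets, kinds = config$models,
                     folds = config$folds, seed = config$seed)
  utils::write.csv(bench %>% select(-dplyr::any_of("reports")),
                   out("benchmark.csv"), row.names = FALSE)
  log_stage(logcon, "classify", n_rows = nrow(bench),
            best = bench$kind[which.max(bench$auc)])
  stages <- c(stages, "classify")

  close(logcon); on.exit()
  # the log carries wall-clock timestamps, so it is not part of the
  # reproducibility contract
  files <- sort(setdiff(list.files(config$outdir),
                        c("manifest.json", "run_log.jsonl")))
  hashes <- tools::md5sum(file.path(config$outdir, files))
  names(hashes) <- files
  manifest <- list(
    package_version = as.character(utils::packageVersion("aepscatter")),
    seed = config$seed, stages = stages,
    settings = list(stats_alpha = config$stats_alpha,
                    models = config$models, folds = config$folds,
                    lasso = config$lasso),
    hashes = as.list(hashes))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

build_feature_sets <- function(cohort, metrics, time_features, scat,
                               clinical, sel) {
  sets <- list()
  labels_by_patient <- setNames(as.character(cohort$patients$distress),
                                cohort$patients$patient_id)
  # time-domain features: one row per ear, the selected metrics of both
  # subtypes as columns; ears missing any selected wave are dropped
  if (nrow(time_features)) {
    td <- metrics %>%
      mutate(feature = paste(.data$subtype, .data$wave, .data$metric,
                             sep = ":")) %>%
      filter(.data$feature %in% time_features$feature) %>%
      select("patient_id", "ear", "feature", "value") %>%
      tidyr::pivot_wider(names_from = "feature", values_from = "value")
    td <- td[complete.cases(td), ]
    if (nrow(td)) {
      sets[["time_domain"]] <- list(
        features = td %>% select(-"ear", -"patient_id"),
        labels = factor(labels_by_patient[td$patient_id], c("low", "high")),
        groups = td$patient_id)
    }
  }
  wst <- purrr::map(scat, function(s) {
    f <- s$feats
    list(features = feature_matrix(f),
         labels = factor(labels_by_patient[f$patient_id], c("low", "high")),
         groups = f$patient_id)
  })
  for (nm in names(wst)) sets[[paste0("wst_", tolower(nm))]] <- wst[[nm]]
  if (all(c("ABR", "AMLR") %in% names(scat))) {
    a <- scat$ABR$feats; m <- scat$AMLR$feats
    key_a <- paste(a$patient_id, a$ear); key_m <- paste(m$patient_id, m$ear)
    m2 <- m[match(key_a, key_m), ]
    both <- dplyr::bind_cols(
      feature_matrix(a) %>% dplyr::rename_with(~ paste0("ABR_", .x)),
      feature_matrix(m2) %>% dplyr::rename_with(~ paste0("AMLR_", .x)))
    sets[["wst_both"]] <- list(
      features = both,
      labels = factor(labels_by_patient[a$patient_id], c("low", "high")),
      groups = a$patient_id)
  }
  sets[["clinical_all"]] <- list(
    features = encode_clinical(clinical,
                               intersect(clinical_schema()$variable,
                                         names(clinical)))$x,
    labels = binarize_thi(clinical$thi_score),
    groups = clinical$patient_id)
  if (length(sel$selected)) {
    sets[["clinical_selected"]] <- list(
      features = encode_clinical(clinical, sel$selected)$x,
      labels = binarize_thi(clinical$thi_score),
      groups = clinical$patient_id)
  }
  if ("AMLR" %in% names(scat) && length(sel$selected)) {
    integ <- integrate_features(scat$AMLR$feats, clinical, sel$selected)
    enc <- encode_clinical(integ, sel$selected)
    sets[["integrated"]] <- list(
      features = dplyr::bind_cols(
        feature_matrix(scat$AMLR$feats),
        as_tibble(enc$x)),
      labels = factor(labels_by_patient[integ$patient_id],
                      c("low", "high")),
      groups = integ$patient_id)
  }
  sets
}
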