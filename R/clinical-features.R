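#' Impute missing clinical values
#'
#' Numeric columns: missing values are replaced with the column mean over
#' observed values. Categorical (character/factor/integer-coded) columns:
#' missing values are replaced with the most frequent level; ties resolve
#' to the lexicographically smallest level and are reported. Observed cells
#' are never changed.
#'
#' @param table Clinical tibble.
#' @param feature_cols Columns to impute; defaults to the 33-variable
#'   schema columns present in `table` (see [clinical_schema()]).
#' @return The imputed tibble (no missing cells in `feature_cols`).
#' @export
impute_clinical <- function(table, feature_cols = NULL) {
  schema <- clinical_schema()
  feature_cols <- feature_cols %||% intersect(schema$variable, names(table))
  for (v in feature_cols) {
    x <- table[[v]]
    if (!anyNA(x)) next
    if (all(is.na(x))) {
      abort(paste0("column '", v, "' is entirely missing: cannot impute"))
    }
    type <- schema$type[match(v, schema$variable)]
    categorical <- isTRUE(type == "categorical") || is.character(x) ||
      is.factor(x)
    if (!categorical && is.numeric(x)) {
      x[is.na(x)] <- mean(x, na.rm = TRUE)
    } else {
      tab <- sort(table(as.character(x)), decreasing = TRUE)
      modes <- names(tab)[tab == max(tab)]
      fill <- sort(modes)[1]
      if (length(modes) > 1) {
        inform(paste0("column '", v, "': modal tie, using smallest level '",
                      fill, "'"))
      }
      if (is.factor(x)) {
        x[is.na(x)] <- fill
      } else if (is.numeric(x)) {
        x[is.na(x)] <- as.numeric(fill)
      } else {
        x[is.na(x)] <- fill
      }
    }
    table[[v]] <- x
  }
  table
}

#' Aggregate per-ear audiological variables to patient level
#'
#' Applies the laterality rule to the four ear-specific variables (hearing
#' loss, maximum tinnitus frequency, tinnitus matching loudness, minimal
#' masking level): bilateral tinnitus averages the two ears; unilateral
#' tinnitus takes the affected ear; head-derived tinnitus averages the
#' ear(s) where tinnitus matching was detected.
#'
#' @param ear_measures Tibble with columns `patient_id`, `ear`,
#'   `hearing_loss_db`, `max_tinnitus_freq_hz`, `matching_loudness_db`,
#'   `min_masking_level_db`, `matched` (logical).
#' @param patients Tibble with `patient_id` and `laterality`
#'   (`left`/`right`/`bilateral`/`head`).
#' @return Tibble with one row per patient: `patient_id`, `hearing_loss`,
#'   `max_tinnitus_freq`, `matching_loudness`, `min_masking_level`.
#' @export
aggregate_ear_variables <- function(ear_measures, patients) {
  vars <- c("hearing_loss_db", "max_tinnitus_freq_hz",
            "matching_loudness_db", "min_masking_level_db")
  out_names <- c("hearing_loss", "max_tinnitus_freq", "matching_loudness",
                 "min_masking_level")
  rows <- purrr::map(seq_len(nrow(patients)), function(i) {
    pid <- patients$patient_id[i]
    lat <- patients$laterality[i]
    em <- ear_measures[ear_measures$patient_id == pid, ]
    if (!nrow(em)) abort(paste0("no ear measures for patient ", pid))
    pick <- switch(lat,
      bilateral = em,
      left = em[em$ear == "left", ],
      right = em[em$ear == "right", ],
      head = em[em$matched, ],
      abort(paste0("patient ", pid, ": unknown laterality '", lat, "'")))
    if (!nrow(pick)) {
      abort(paste0("patient ", pid, " (", lat,
                   "): no ear value available for the laterality rule"))
    }
    vals <- colMeans(pick[vars])
    if (anyNA(vals)) {
      abort(paste0("patient ", pid, " (", lat,
                   "): missing value on the ear required by the rule"))
    }
    tibble(patient_id = pid, !!!setNames(as.list(unname(vals)), out_names))
  })
  bind_rows(rows)
}

#' Binarize a THI score into distress groups
#'
#' `high` if and only if the score is at least 48. Scores below the study
#' inclusion floor of 18 trigger a warning (such records are excluded from
#' cohorts at validation).
#'
#' @param thi_score Integer vector of THI scores (0--100).
#' @return Factor with levels `low`, `high`.
#' @examples
#' binarize_thi(c(18, 47, 48, 100))
#' @export
binarize_thi <- function(thi_score) {
  if (any(thi_score < 0 | thi_score > 100, na.rm = TRUE)) {
    abort("THI scores must lie in [0, 100]")
  }
  low_incl <- !is.na(thi_score) & thi_score < 18
  if (any(low_incl)) {
    warn(paste0(sum(low_incl), " score(s) below the inclusion floor of 18"))
  }
  factor(ifelse(thi_score >= 48, "high", "low"), levels = c("low", "high"))
}

encode_clinical <- function(table, feature_cols) {
  schema <- clinical_schema()
  pieces <- purrr::map(feature_cols, function(v) {
    x <- table[[v]]
    type <- schema$type[match(v, schema$variable)]
    if (isTRUE(type == "categorical") || is.character(x) || is.factor(x)) {
      f <- factor(x)
      if (nlevels(f) < 2) {
        m <- matrix(0, nrow(table), 0)
        return(list(m = m, parent = character()))
      }
      m <- model.matrix(~ f - 1)
      colnames(m) <- paste0(v, "=", levels(f))
      list(m = m, parent = rep(v, ncol(m)))
    } else {
      m <- matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, v))
      list(m = m, parent = v)
    }
  })
  list(x = do.call(cbind, purrr::map(pieces, "m")),
       parent = unlist(purrr::map(pieces, "parent")))
}

#' LASSO selection of clinical features
#'
#' Repeated cross-validated L1-penalised logistic regression on the
#' one-hot-encoded, post-imputation clinical table. Per repeat, 10-fold CV
#' picks the penalty minimising the binomial deviance (`lambda.min`; the
#' 1-SE rule is available) and the nonzero coefficients at that penalty
#' are recorded. A column is selected when its coefficient is nonzero in
#' at least `threshold` of the repeats; a parent categorical feature
#' counts as selected when any of its levels is. Predictors are
#' standardised inside the fitting procedure. Deterministic given `seed`.
#'
#' @param table Imputed clinical tibble (no missing feature cells).
#' @param labels Factor of distress groups (`low`/`high`), one per row.
#' @param feature_cols Feature columns; defaults to the schema columns.
#' @param folds Number of CV folds (default 10).
#' @param repeats Number of repeated CV runs with re-randomised folds
#'   (default 100). `repeats = 1` gives the single-run `lambda.min` mode.
#' @param threshold Minimum selection frequency (default 0.5).
#' @param rule `"min"` (deviance-minimising penalty, default) or `"1se"`.
#' @param seed Integer seed.
#' @return Object of class `lasso_selection`: list with `selected`
#'   (ordered character vector of parent features), `report` (per-column
#'   tibble: `column`, `feature`, `frequency`, `mean_coef`), and the call
#'   settings. `tidy()` returns the report.
#' @export
lasso_select <- function(table, labels, feature_cols = NULL, folds = 10,
                         repeats = 100, threshold = 0.5,
                         rule = c("min", "1se"), seed = 1L) {
  rule <- match.arg(rule)
  schema <- clinical_schema()
  feature_cols <- feature_cols %||% intersect(schema$variable, names(table))
  labels <- factor(labels)
  if (nlevels(labels) != 2) {
    abort("labels must have exactly two classes")
  }
  if (anyNA(table[feature_cols])) {
    abort("table has missing cells: run impute_clinical() first")
  }
  enc <- encode_clinical(table, feature_cols)
  x <- enc$x
  y <- labels
  s <- if (rule == "min") "lambda.min" else "lambda.1se"
  withr::with_seed(seed, {
    hits <- matrix(0, ncol(x), repeats, dimnames = list(colnames(x), NULL))
    coefs <- matrix(0, ncol(x), repeats, dimnames = list(colnames(x), NULL))
    for (r in seq_len(repeats)) {
      cvfit <- glmnet::cv.glmnet(x, y, family = "binomial",
                                 nfolds = folds, standardize = TRUE,
                                 type.measure = "deviance")
      b <- as.numeric(stats::coef(cvfit, s = s))[-1]  # drop intercept
      hits[, r] <- b != 0
      coefs[, r] <- b
    }
  })
  report <- tibble(
    column = colnames(x), feature = enc$parent,
    frequency = rowMeans(hits),
    mean_coef = rowMeans(coefs)
  )
  parent_freq <- report %>%
    group_by(.data$feature) %>%
    summarise(frequency = max(.data$frequency), .groups = "drop")
  selected <- feature_cols[feature_cols %in%
                             parent_freq$feature[parent_freq$frequency >=
                                                   threshold]]
  structure(list(selected = selected, report = report,
                 folds = folds, repeats = repeats, threshold = threshold,
                 rule = rule, seed = seed),
            class = "lasso_selection")
}

#' @export
print.lasso_selection <- function(x, ...) {
  cat("<lasso_selection> ", length(x$selected), " feature(s) selected (",
      x$repeats, " repeats, ", x$folds, "-fold CV, threshold ",
      x$threshold, "):\n  ", paste(x$selected, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Tidy a LASSO selection report
#'
#' @param x A `lasso_selection`.
#' @param ... Unused.
#' @return The per-column selection report tibble.
#' @export
tidy.lasso_selection <- function(x, ...) {
  x$report %>% arrange(dplyr::desc(.data$frequency))
}

#' Write the clinical table with a JSON schema sidecar
#'
#' @param table Clinical tibble.
#' @param path CSV output path; the sidecar is written to
#'   `paste0(path, ".schema.json")`.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  schema <- clinical_schema() %>%
    filter(.data$variable %in% names(table))
  jsonlite::write_json(schema, paste0(path, ".schema.json"))
  invisible(path)
}
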