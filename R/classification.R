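#' Supported classifier kinds
#' @return Character vector of the seven model kinds.
#' @export
model_kinds <- function() {
  c("lda", "svm_linear", "svm_radial", "svm_poly", "naive_bayes",
    "neural_net", "random_forest")
}

default_grid <- function(kind, p) {
  switch(kind,
    lda = tibble(.dummy = 1),
    svm_linear = tibble(cost = c(0.25, 0.5, 1, 2, 4)),
    svm_radial = tidyr::expand_grid(cost = c(0.25, 1, 4),
                                    gamma_scale = c(0.5, 1, 2)),
    svm_poly = tidyr::expand_grid(cost = c(0.25, 1, 4), degree = c(2, 3)),
    naive_bayes = tibble(.dummy = 1),
    neural_net = tidyr::expand_grid(size = c(3, 5, 7),
                                    decay = c(0.01, 0.1)),
    random_forest = tibble(mtry = pmax(1, round(sqrt(p)) + (-1:1))) %>%
      distinct(),
    abort(paste0("unknown model kind '", kind, "'"))
  )
}

#' Specify a classifier
#'
#' Bundles a model kind with its hyperparameter grid. When the grid has
#' more than one row, [cross_validate()] picks the row maximising inner
#' cross-validated AUC on each training fold. Default grids are small and
#' standard: SVM cost \{0.25, 0.5, 1, 2, 4\} (linear; a 3 x 3
#' cost-by-bandwidth grid around the median heuristic for the RBF kernel;
#' cost by degree \{2, 3\} for the polynomial kernel), random forest with
#' 500 trees and sqrt(p) +/- 1 split candidates, a single-hidden-layer
#' neural network with size \{3, 5, 7\} and weight decay \{0.01, 0.1\},
#' and Gaussian naive Bayes / LDA without tuning.
#'
#' @param kind One of [model_kinds()].
#' @param grid Optional tibble overriding the default hyperparameter grid.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(kind = model_kinds(), grid = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, grid = grid), class = "model_spec")
}

# stratified fold assignment; optional grouping keeps all rows of one
# group (e.g. the two ears of a patient) in the same fold
make_folds <- function(labels, k, groups = NULL) {
  n <- length(labels)
  if (is.null(groups)) groups <- seq_len(n)
  gtab <- tibble(group = groups, label = labels) %>%
    group_by(.data$group) %>%
    summarise(label = .data$label[1], .groups = "drop")
  fold_of_group <- do.call(c, unname(purrr::map(
    split(gtab$group, gtab$label), function(g) {
      g <- sample(g)
      setNames(rep_len(sample(seq_len(k)), length(g)), g)
    })))
  folds <- unname(fold_of_group[as.character(groups)])
  as.integer(folds)
}

scale_train_test <- function(xtr, xte) {
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2, sd)
  keep <- sdv > 0 & is.finite(sdv)
  if (!any(keep)) abort("all features are constant in a training fold")
  xtr <- xtr[, keep, drop = FALSE]; xte <- xte[, keep, drop = FALSE]
  list(tr = sweep(sweep(xtr, 2, mu[keep]), 2, sdv[keep], "/"),
       te = sweep(sweep(xte, 2, mu[keep]), 2, sdv[keep], "/"))
}

median_heuristic_gamma <- function(x) {
  n <- min(nrow(x), 100L)
  idx <- seq_len(n)
  d <- stats::dist(x[idx, , drop = FALSE])
  m <- median(d[d > 0])
  if (!is.finite(m) || m == 0) 1 / ncol(x) else 1 / (2 * m^2)
}

# fit one model and return posterior scores for the positive (high) class
fit_score <- function(kind, params, xtr, ytr, xte) {
  sc <- scale_train_test(xtr, xte)
  xtr <- sc$tr; xte <- sc$te
  pos <- levels(ytr)[2]
  if (kind == "lda") {
    # low tol: scattering features are strongly collinear by construction
    fit <- MASS::lda(xtr, grouping = ytr, tol = 1e-10)
    return(predict(fit, xte)$posterior[, pos])
  }
  if (kind %in% c("svm_linear", "svm_radial", "svm_poly")) {
    kernel <- c(svm_linear = "linear", svm_radial = "radial",
                svm_poly = "polynomial")[[kind]]
    args <- list(x = xtr, y = ytr, kernel = kernel, cost = params$cost,
                 probability = TRUE, scale = FALSE)
    if (kind == "svm_radial") {
      args$gamma <- median_heuristic_gamma(xtr) * params$gamma_scale
    }
    if (kind == "svm_poly") {
      # inhomogeneous kernel: coef0 = 0 makes even degrees sign-symmetric
      args$degree <- params$degree
      args$coef0 <- 1
    }
    fit <- do.call(e1071::svm, args)
    pr <- attr(predict(fit, xte, probability = TRUE), "probabilities")
    return(pr[, pos])
  }
  if (kind == "naive_bayes") {
    fit <- e1071::naiveBayes(xtr, ytr)
    return(predict(fit, xte, type = "raw")[, pos])
  }
  if (kind == "neural_net") {
    fit <- nnet::nnet(xtr, class.ind(ytr), size = params$size,
                      decay = params$decay, softmax = TRUE, maxit = 200,
                      trace = FALSE)
    return(predict(fit, xte)[, pos])
  }
  if (kind == "random_forest") {
    fit <- randomForest::randomForest(xtr, ytr, ntree = 500,
                                      mtry = min(params$mtry, ncol(xtr)))
    return(predict(fit, xte, type = "prob")[, pos])
  }
  abort(paste0("unknown model kind '", kind, "'"))
}

class.ind <- function(y) {
  m <- model.matrix(~ y - 1)
  colnames(m) <- levels(y)
  m
}

#' Trapezoidal ROC curve and AUC
#'
#' Ranks held-out scores, sweeps every threshold, and integrates the ROC
#' by the trapezoidal rule. Equivalent to the Mann-Whitney U statistic
#' divided by `n_pos * n_neg` (ties counted half).
#'
#' @param scores Numeric scores, larger meaning more likely positive.
#' @param labels Factor with the positive class as the second level.
#' @return List with `auc` and `roc` (tibble `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- factor(labels)
  pos <- labels == levels(labels)[2]
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) abort("both classes needed to compute a ROC")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # group tied scores so the curve steps diagonally through ties
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(auc = auc, roc = tibble(fpr = fpr, tpr = tpr))
}

inner_cv_auc <- function(kind, params, x, y, k = 5L) {
  folds <- make_folds(y, k)
  aucs <- purrr::map_dbl(seq_len(k), function(f) {
    te <- folds == f
    if (length(unique(y[!te])) < 2 || length(unique(y[te])) < 2) {
      return(NA_real_)
    }
    s <- fit_score(kind, params, x[!te, , drop = FALSE], y[!te],
                   x[te, , drop = FALSE])
    roc_auc(s, y[te])$auc
  })
  mean(aucs, na.rm = TRUE)
}

#' Cross-validated evaluation of one classifier
#'
#' Stratified k-fold cross-validation with an ear-aware grouping option:
#' when `groups` is supplied (e.g. patient ids for ear-level instances),
#' all instances of a group land in the same fold, so the two ears of one
#' patient never straddle a train/test split. Within each training fold,
#' features are standardised on training data only and, if the
#' hyperparameter grid has several rows, a small inner CV picks the row
#' with the best inner AUC. Per-fold AUC comes from the trapezoidal ROC of
#' the held-out scores; sensitivity and specificity use the 0.5 posterior
#' threshold (the Youden-optimal threshold is reported alongside).
#' Reported summary metrics are means over folds.
#'
#' @param features Tibble or matrix of numeric features (finite).
#' @param labels Factor (`low`/`high`); `high` is the positive class.
#' @param spec A [model_spec()].
#' @param folds Number of folds (default 10).
#' @param seed Integer seed controlling fold assignment and model RNG.
#' @param groups Optional grouping vector (same length as labels).
#' @return Object of class `cv_report`; see [tidy.cv_report()] and
#'   [glance.cv_report()].
#' @export
cross_validate <- function(features, labels, spec, folds = 10, seed = 1L,
                           groups = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) abort("features must be finite")
  labels <- factor(labels)
  if (nlevels(labels) != 2) abort("labels must have exactly two classes")
  grid <- spec$grid %||% default_grid(spec$kind, ncol(x))
  withr::with_seed(seed, {
    fold_id <- make_folds(labels, folds, groups)
    if (any(tapply(labels, fold_id, function(l) length(unique(l))) < 2)) {
      abort("a fold lost one class entirely: reduce folds or rebalance")
    }
    fold_rows <- purrr::map(seq_len(folds), function(f) {
      te <- fold_id == f
      xtr <- x[!te, , drop = FALSE]; ytr <- labels[!te]
      xte <- x[te, , drop = FALSE]; yte <- labels[te]
      best <- if (nrow(grid) > 1) {
        scores_by_row <- purrr::map_dbl(seq_len(nrow(grid)), function(g) {
          inner_cv_auc(spec$kind, grid[g, ], xtr, ytr)
        })
        grid[which.max(scores_by_row), ]
      } else {
        grid[1, ]
      }
      s <- fit_score(spec$kind, best, xtr, ytr, xte)
      r <- roc_auc(s, yte)
      pred_pos <- s >= 0.5
      pos <- yte == levels(yte)[2]
      tp <- sum(pred_pos & pos); fn <- sum(!pred_pos & pos)
      tn <- sum(!pred_pos & !pos); fp <- sum(pred_pos & !pos)
      youden <- r$roc$tpr - r$roc$fpr
      tibble(fold = f, auc = r$auc,
             sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
             tp = tp, fp = fp, tn = tn, fn = fn,
             youden_threshold = {
               # score threshold attaining the max Youden index
               ord <- order(s, decreasing = TRUE)
               k <- which.max(youden) - 1L
               if (k == 0) Inf else sort(s, decreasing = TRUE)[k]
             },
             params = list(best), scores = list(s),
             truth = list(yte))
    })
  })
  fm <- bind_rows(fold_rows)
  pooled <- roc_auc(unlist(fm$scores), factor(unlist(purrr::map(fm$truth,
                                                                as.character)),
                                              levels(labels)))
  structure(list(
    kind = spec$kind, n_features = ncol(x), folds = folds, seed = seed,
    fold_metrics = fm %>% select(-"scores", -"truth"),
    fold_assignment = tibble(instance = seq_along(labels),
                             fold = fold_id, label = labels),
    roc_points = pooled$roc, pooled_auc = pooled$auc,
    mean_auc = mean(fm$auc), mean_sensitivity = mean(fm$sensitivity),
    mean_specificity = mean(fm$specificity)
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$kind, " (", x$n_features, " features, ", x$folds,
      "-fold)\n  mean AUC ", round(x$mean_auc, 4), ", sensitivity ",
      round(x$mean_sensitivity, 4), ", specificity ",
      round(x$mean_specificity, 4), "\n", sep = "")
  invisible(x)
}

#' Per-fold metrics of a cross-validation report
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return Tibble of per-fold AUC, sensitivity, specificity and confusion
#'   counts.
#' @export
tidy.cv_report <- function(x, ...) {
  x$fold_metrics %>% select(-"params")
}

#' One-row summary of a cross-validation report
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return One-row tibble: kind, n_features, mean AUC/sensitivity/
#'   specificity and the pooled-prediction AUC.
#' @export
glance.cv_report <- function(x, ...) {
  tibble(kind = x$kind, n_features = x$n_features, folds = x$folds,
         auc = x$mean_auc, sensitivity = x$mean_sensitivity,
         specificity = x$mean_specificity, pooled_auc = x$pooled_auc)
}

#' ROC curve of a cross-validation report
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot object (pooled held-out scores).
#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(object$roc_points,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false-positive rate", y = "true-positive rate",
                  title = paste0(object$kind, " (AUC ",
                                 round(object$mean_auc, 4), ")")) +
    ggplot2::theme_minimal()
}

#' Combine scattering features with selected clinical features
#'
#' Ear-level integration: each ear keeps its own scattering coefficients
#' and inherits its patient's selected clinical features (broadcast to
#' both ears). Non-selected clinical columns are dropped, as are
#' audiological variables unrelated to tinnitus-matching ears when
#' `drop_unmatched_audio` names them.
#'
#' @param scattering_features Output of [scatter_features()] (rows are
#'   ears).
#' @param clinical Clinical tibble with `patient_id`.
#' @param selected Character vector of selected clinical columns.
#' @param drop_unmatched_audio Optional character vector of audiological
#'   columns to exclude from the integrated matrix.
#' @return Tibble: ids, then scattering columns, then clinical columns.
#' @export
integrate_features <- function(scattering_features, clinical, selected,
                               drop_unmatched_audio = NULL) {
  selected <- setdiff(selected, drop_unmatched_audio)
  orphan <- setdiff(scattering_features$patient_id, clinical$patient_id)
  if (length(orphan)) {
    abort(paste0("ears without a clinical row: ",
                 paste(head(orphan, 5), collapse = ", ")))
  }
  missing_cols <- setdiff(selected, names(clinical))
  if (length(missing_cols)) {
    abort(paste0("selected features not in the clinical table: ",
                 paste(missing_cols, collapse = ", ")))
  }
  scattering_features %>%
    left_join(clinical %>% select("patient_id", dplyr::all_of(selected)),
              by = "patient_id")
}

feature_matrix <- function(df) {
  df %>% select(-dplyr::any_of(c("record_id", "patient_id", "ear",
                                 "subtype")))
}

#' Benchmark several classifiers over several feature sets
#'
#' Runs [cross_validate()] for every (feature set, model) combination and
#' tabulates the mean AUC, sensitivity and specificity, flagging the best
#' model per feature set by AUC.
#'
#' @param feature_sets Named list; each element a list with elements
#'   `features` (tibble/matrix), `labels` (factor) and optionally `groups`.
#' @param kinds Character vector of model kinds (default all seven).
#' @param folds,seed Passed to [cross_validate()].
#' @param grids Optional named list of grid overrides per kind.
#' @return Tibble: `feature_set`, `kind`, `n_features`, `auc`,
#'   `sensitivity`, `specificity`, `best`; the per-set best model's
#'   `cv_report` objects are attached as the `reports` attribute.
#' @export
benchmark <- function(feature_sets, kinds = model_kinds(), folds = 10,
                      seed = 1L, grids = NULL) {
  stopifnot(length(names(feature_sets)) == length(feature_sets))
  rows <- list(); reports <- list()
  for (set_name in names(feature_sets)) {
    fs <- feature_sets[[set_name]]
    for (kind in kinds) {
      rep <- cross_validate(fs$features, fs$labels,
                            model_spec(kind, grid = grids[[kind]]),
                            folds = folds, seed = seed,
                            groups = fs$groups)
      rows[[length(rows) + 1]] <- glance(rep) %>%
        mutate(feature_set = set_name, .before = 1)
      reports[[paste(set_name, kind, sep = "/")]] <- rep
    }
  }
  out <- bind_rows(rows) %>%
    group_by(.data$feature_set) %>%
    mutate(best = row_number() == which.max(.data$auc)) %>%
    ungroup()
  attr(out, "reports") <- reports
  out
}
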