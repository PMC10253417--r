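test_that("trapezoidal AUC equals the Mann-Whitney statistic", {
  withr::with_seed(8, {
    for (i in 1:25) {
      n <- sample(20:80, 1)
      y <- factor(sample(c("low", "high"), n, TRUE), c("low", "high"))
      if (length(unique(y)) < 2) next
      s <- rnorm(n)
      if (i %% 3 == 0) s <- round(s)  # force ties
      r <- roc_auc(s, y)
      # U statistic with ties counted half
      pos <- s[y == "high"]; neg <- s[y == "low"]
      u <- sum(vapply(pos, function(p) {
        sum(p > neg) + 0.5 * sum(p == neg)
      }, numeric(1)))
      expect_equal(r$auc, u / (length(pos) * length(neg)),
                   tolerance = 1e-10)
      expect_equal(r$roc$fpr[1], 0)
      expect_equal(r$roc$tpr[nrow(r$roc)], 1)
    }
  })
})

sep_data <- function(n = 400, gap = 6, seed = 2) {
  withr::with_seed(seed, {
    y <- factor(rep(c("low", "high"), each = n / 2), c("low", "high"))
    x <- tibble::tibble(
      f1 = rnorm(n, ifelse(y == "high", gap, 0)),
      f2 = rnorm(n))
    list(x = x, y = y)
  })
}

test_that("a linearly separable problem reaches near-perfect AUC", {
  d <- sep_data()
  r <- cross_validate(d$x, d$y, model_spec("svm_linear"), folds = 10,
                      seed = 1)
  expect_gte(r$mean_auc, 0.99)
  expect_gte(r$mean_sensitivity, 0.95)
  expect_gte(r$mean_specificity, 0.95)
})

test_that("cross-validation is reproducible given the seed", {
  d <- sep_data(n = 120, gap = 1)
  a <- cross_validate(d$x, d$y, model_spec("random_forest"), folds = 5,
                      seed = 7)
  b <- cross_validate(d$x, d$y, model_spec("random_forest"), folds = 5,
                      seed = 7)
  expect_identical(glance(a), glance(b))
  expect_identical(a$fold_metrics$auc, b$fold_metrics$auc)
  c <- cross_validate(d$x, d$y, model_spec("random_forest"), folds = 5,
                      seed = 8)
  expect_false(identical(a$fold_metrics$auc, c$fold_metrics$auc))
})

test_that("sensitivity and specificity recompute from confusion counts", {
  d <- sep_data(n = 200, gap = 2)
  r <- cross_validate(d$x, d$y, model_spec("lda"), folds = 10, seed = 3)
  fm <- tidy(r)
  expect_equal(fm$sensitivity, fm$tp / (fm$tp + fm$fn))
  expect_equal(fm$specificity, fm$tn / (fm$tn + fm$fp))
  expect_equal(r$mean_sensitivity, mean(fm$sensitivity))
  expect_equal(r$mean_auc, mean(fm$auc))
  g <- glance(r)
  expect_equal(g$auc, r$mean_auc)
  expect_s3_class(autoplot(r), "ggplot")
})

test_that("folds partition instances and keep patient ears together", {
  d <- sep_data(n = 200, gap = 1)
  groups <- rep(sprintf("p%03d", 1:100), each = 2)
  r <- cross_validate(d$x, d$y, model_spec("lda"), folds = 10, seed = 5,
                      groups = groups)
  fa <- r$fold_assignment
  expect_equal(sort(unique(fa$fold)), 1:10)
  expect_equal(nrow(fa), 200)
  by_group <- tapply(fa$fold, groups, function(f) length(unique(f)))
  expect_true(all(by_group == 1))
})

test_that("every model kind trains, scores and stays in [0, 1]", {
  d <- sep_data(n = 100, gap = 2, seed = 9)
  for (kind in model_kinds()) {
    grid <- if (kind == "neural_net") tibble::tibble(size = 3, decay = 0.1)
      else if (kind == "svm_radial") tibble::tibble(cost = 1,
                                                    gamma_scale = 1)
      else if (kind == "svm_poly") tibble::tibble(cost = 1, degree = 2)
      else if (kind == "svm_linear") tibble::tibble(cost = 1)
      else NULL
    r <- cross_validate(d$x, d$y, model_spec(kind, grid = grid), folds = 5,
                        seed = 2)
    expect_true(all(r$fold_metrics$auc >= 0 & r$fold_metrics$auc <= 1))
    expect_true(r$mean_sensitivity >= 0 && r$mean_sensitivity <= 1)
    expect_gte(r$mean_auc, 0.8)  # an easy, clearly separated problem
  }
})

test_that("degenerate inputs are rejected with clear errors", {
  d <- sep_data(n = 40, gap = 1)
  x_bad <- d$x
  x_bad$f1[1] <- NA
  expect_error(cross_validate(x_bad, d$y, model_spec("lda")), "finite")
  expect_error(cross_validate(d$x, factor(rep("high", 40)),
                              model_spec("lda")), "two classes")
})

test_that("feature integration broadcasts clinical rows to both ears", {
  scat <- tibble::tibble(
    record_id = c("p1_l", "p1_r", "p2_l", "p2_r"),
    patient_id = c("p1", "p1", "p2", "p2"),
    ear = c("left", "right", "left", "right"),
    subtype = "AMLR",
    !!!stats::setNames(as.list(as.data.frame(matrix(rnorm(4 * 65), 4))),
                       paste0("s", 1:65)))
  clin <- tibble::tibble(patient_id = c("p1", "p2"),
                         !!!stats::setNames(as.list(as.data.frame(
                           matrix(rnorm(2 * 15), 2))), paste0("c", 1:15)))
  comb <- integrate_features(scat, clin, paste0("c", 1:15))
  expect_equal(ncol(comb) - 4, 80)  # 65 scattering + 15 clinical
  # the two ears of one patient share the clinical sub-row
  p1 <- comb[comb$patient_id == "p1", paste0("c", 1:15)]
  expect_equal(p1[1, ], p1[2, ], ignore_attr = TRUE)
  expect_false(isTRUE(all.equal(
    comb[1, paste0("s", 1:65)], comb[2, paste0("s", 1:65)],
    check.attributes = FALSE)))
  # empty selection returns the scattering matrix unchanged
  same <- integrate_features(scat, clin, character())
  expect_equal(ncol(same), ncol(scat))
  # orphan ears are a join error
  expect_error(integrate_features(scat, clin[1, ], paste0("c", 1:15)),
               "clinical row")
  expect_error(integrate_features(scat, clin, "nope"), "not in")
})

test_that("benchmark tabulates every feature set by model combination", {
  d1 <- sep_data(n = 80, gap = 2, seed = 4)
  d2 <- sep_data(n = 80, gap = 0.3, seed = 5)
  sets <- list(strong = list(features = d1$x, labels = d1$y),
               weak = list(features = d2$x, labels = d2$y))
  out <- benchmark(sets, kinds = c("lda", "naive_bayes"), folds = 5,
                   seed = 6)
  expect_equal(nrow(out), 4)
  expect_equal(sum(out$best), 2)  # one best model per feature set
  expect_setequal(unique(out$feature_set), c("strong", "weak"))
  expect_equal(out$n_features, rep(2L, 4))
  reports <- attr(out, "reports")
  expect_length(reports, 4)
  one <- glance(reports[["strong/lda"]])
  expect_equal(out$auc[out$feature_set == "strong" & out$kind == "lda"],
               one$auc)
})

test_that("permuted labels drive a classifier to chance level", {
  # label-free features: any persistent deviation from 0.5 means leakage
  d <- sep_data(n = 400, gap = 0, seed = 11)
  withr::with_seed(12, y_perm <- sample(d$y))
  r <- cross_validate(d$x, y_perm, model_spec("lda"), folds = 10, seed = 13)
  expect_lt(abs(r$mean_auc - 0.5), 0.12)
})
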