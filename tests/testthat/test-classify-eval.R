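test_that("the forest memorizes separable data and is seed-deterministic", {
  tab <- small_pair_table(seed = 2, signal = 6)
  fit <- train_forest(tab, forest_config(n_trees = 100), seed = 5)
  prob <- predict(fit, tab)
  expect_equal(as.integer(prob > 0.5), tab$label)
  expect_identical(prob, predict(train_forest(tab, forest_config(n_trees = 100),
                                              seed = 5), tab))

  one_class <- tab[tab$label == 0, ]
  expect_error(train_forest(one_class, forest_config(n_trees = 10)),
               "single-class")
  expect_error(predict(fit, tab[, 1:10]), "missing feature columns")
})

test_that("permuted labels leave out-of-bag accuracy near the majority rate", {
  tab <- small_pair_table(seed = 3, signal = 6, n_targets = 12, n_drugs = 24,
                          n_positives = 72)
  maj_rate <- max(table(tab$label)) / nrow(tab)
  oob <- vapply(1:10, function(sd) {
    null_tab <- tab
    null_tab$label <- withr::with_seed(sd, sample(tab$label))
    fit <- train_forest(null_tab, forest_config(n_trees = 200), seed = sd)
    conf <- fit$forest$confusion[, 1:2]
    sum(diag(conf)) / sum(conf)
  }, numeric(1))
  expect_lt(abs(mean(oob) - maj_rate), 0.05)
})

test_that("confusion metrics follow their defining ratios", {
  # TP=90, FN=10, TN=900, FP=0
  labels <- c(rep(1, 100), rep(0, 900))
  prob <- c(rep(0.9, 90), rep(0.1, 10), rep(0.1, 900))
  m <- compute_metrics(labels, prob)
  expect_equal(m$tp, 90); expect_equal(m$fn, 10)
  expect_equal(m$tn, 900); expect_equal(m$fp, 0)
  expect_equal(m$se, 0.9)
  expect_equal(m$sp, 1.0)
  expect_equal(m$acc, 0.99)
  expect_equal(m$f, 180 / 190)

  perfect <- compute_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_true(all(unlist(perfect[, c("acc", "se", "sp", "f", "precision",
                                     "recall")]) == 1))

  all_pos <- compute_metrics(c(1, 1, 0, 0), rep(1, 4))
  expect_equal(all_pos$se, 1)
  expect_equal(all_pos$sp, 0)
  expect_equal(all_pos$acc, 0.5)

  # zero denominators surface as NaN, never as 0
  none_pred <- compute_metrics(c(1, 0), c(0.1, 0.1))
  expect_true(is.nan(none_pred$precision))
})

test_that("metric identities hold on random confusion settings", {
  set.seed(14)
  for (rep in 1:25) {
    n <- sample(20:200, 1)
    labels <- sample(0:1, n, replace = TRUE, prob = c(0.7, 0.3))
    if (length(unique(labels)) < 2) next
    prob <- round(runif(n), 2)
    m <- compute_metrics(labels, prob)
    expect_equal(m$acc * (m$tp + m$tn + m$fp + m$fn), m$tp + m$tn)
    if (is.finite(m$precision) && is.finite(m$recall) &&
        (m$precision + m$recall) > 0) {
      expect_equal(m$f, 2 * m$precision * m$recall / (m$precision + m$recall))
    }
    expect_equal(m$recall, m$se)
  }
})

test_that("ROC/PR extremes behave and AUC equals the Mann-Whitney oracle", {
  lab <- c(1, 1, 1, 0, 0, 0)
  expect_equal(curves(lab, c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1))$auc, 1)
  expect_equal(curves(lab, c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1))$aupr, 1)
  expect_equal(curves(lab, c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9))$auc, 0)
  expect_error(curves(c(1, 1), c(0.2, 0.3)), "single-class")

  set.seed(21)
  for (rep in 1:30) {
    n <- sample(10:200, 1)
    labels <- sample(0:1, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), sample(1:3, 1))  # coarse rounding forces ties
    cv <- curves(labels, scores)
    expect_equal(cv$auc, auc_mwu(labels, scores), tolerance = 1e-12)
    expect_gte(cv$aupr, 0); expect_lte(cv$aupr, 1)
    expect_equal(cv$roc$fpr[1], 0); expect_equal(cv$roc$tpr[1], 0)
    expect_equal(cv$roc$fpr[nrow(cv$roc)], 1)
    expect_equal(cv$roc$tpr[nrow(cv$roc)], 1)
  }
})

test_that("AUC agrees with pROC on tied score vectors", {
  withr::with_seed(8, {
    labels <- sample(0:1, 150, replace = TRUE)
    scores <- round(runif(150), 1)
  })
  expect_equal(curves(labels, scores)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("AUPR under random scores approaches prevalence", {
  withr::with_seed(90, {
    n <- 10000
    labels <- c(rep(1, 1500), rep(0, n - 1500))
    scores <- runif(n)
  })
  expect_lt(abs(curves(labels, scores)$aupr - 0.15), 0.05)
})

test_that("cross-validation folds partition the pairs into near-equal parts", {
  folds <- dtiforest:::make_folds(103, 5, seed = 3)
  expect_length(folds, 103)
  expect_setequal(sort(unname(table(folds))), c(20, 20, 21, 21, 21))
  expect_setequal(unique(folds), 1:5)
})

test_that("cross_validate recovers a strong planted signal in train_only mode", {
  st <- simulate_dti(8, 20, 30, c(45, 60), signal_strength = 6, seed = 11)
  tab <- pair_features(st, lambda_order = 1, s = 10)
  cv <- cross_validate(tab, n_folds = 5, seed = 11,
                       forest = forest_config(n_trees = 150))
  expect_equal(nrow(cv$folds), 5L)
  expect_equal(cv$folds$fold, 1:5)
  expect_gt(cv$summary$mean[cv$summary$metric == "auc"], 0.95)
  # identical rerun under the same master seed
  cv2 <- cross_validate(tab, n_folds = 5, seed = 11,
                        forest = forest_config(n_trees = 150))
  expect_identical(cv$folds, cv2$folds)

  g <- glance(cv)
  expect_equal(g$balance_scope, "train_only")
  expect_equal(g$auc, unname(cv$summary$mean[cv$summary$metric == "auc"]))
  expect_identical(tidy(cv), cv$folds)
})

test_that("autoplot methods return ggplot objects", {
  withr::with_seed(2, {
    labels <- sample(0:1, 60, replace = TRUE)
    scores <- runif(60)
  })
  expect_s3_class(autoplot(curves(labels, scores)), "ggplot")
  st <- simulate_dti(6, 12, 18, c(30, 40), signal_strength = 5, seed = 3)
  cv <- cross_validate(pair_features(st, 1, 8), n_folds = 3, seed = 2,
                       lasso_lambda = 1,
                       balance = balance_config(k_neighbors = 3, seed = 1),
                       forest = forest_config(n_trees = 60))
  expect_s3_class(autoplot(cv), "ggplot")
})
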