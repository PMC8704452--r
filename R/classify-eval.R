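#' Random forest configuration
#'
#' @param n_trees Number of bootstrap trees (default 500).
#' @param mtry Candidate features per split; default `floor(sqrt(Q))` where
#'   Q is the feature count at training time.
#' @param seed Optional integer seed.
#' @return A list of class `forest_config`.
#' @export
forest_config <- function(n_trees = 500L, mtry = NULL, seed = NULL) {
  stopifnot(n_trees >= 1L)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry, seed = seed),
            class = "forest_config")
}

#' Train a random forest DTI classifier
#'
#' Fits an ensemble of unpruned classification trees, each on a bootstrap
#' resample with `mtry` candidate features per node. Predicted interaction
#' probability is the fraction of tree votes for the positive class.
#' Deterministic given a seed.
#'
#' @param table Pair feature tibble with a 0/1 `label` column and both
#'   classes present.
#' @param cfg A [forest_config()].
#' @param seed Optional seed overriding `cfg$seed`.
#' @return An object of class `dti_forest` wrapping the fitted ensemble.
#' @export
train_forest <- function(table, cfg = forest_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "forest_config"))
  if (length(unique(table$label)) < 2L) {
    stop("single-class input: cannot train a classifier")
  }
  feats <- feature_names(table)
  X <- as.matrix(table[, feats])
  y <- factor(table$label, levels = c(0L, 1L))
  mtry <- if (is.null(cfg$mtry)) max(1L, floor(sqrt(length(feats)))) else
    min(as.integer(cfg$mtry), length(feats))
  fit_fun <- function() {
    randomForest::randomForest(x = X, y = y, ntree = cfg$n_trees, mtry = mtry)
  }
  rf <- if (!is.null(seed)) withr::with_seed(seed, fit_fun()) else fit_fun()
  structure(
    list(forest = rf, feature_names = feats, n_trees = cfg$n_trees,
         mtry = mtry),
    class = "dti_forest"
  )
}

#' @export
print.dti_forest <- function(x, ...) {
  cat("<dti_forest> ", x$n_trees, " trees, mtry = ", x$mtry, ", ",
      length(x$feature_names), " features\n", sep = "")
  invisible(x)
}

#' Predict interaction probabilities
#'
#' @param object A `dti_forest`.
#' @param newdata Pair feature tibble containing at least the training
#'   feature columns.
#' @param ... Unused.
#' @return Numeric vector of vote-fraction probabilities for the positive
#'   class, one per row of `newdata`.
#' @export
predict.dti_forest <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$feature_names, names(newdata))
  if (length(missing_cols) > 0L) {
    stop("newdata is missing feature columns: ",
         paste(utils::head(missing_cols, 5L), collapse = ", "))
  }
  X <- as.matrix(newdata[, object$feature_names])
  unname(stats::predict(object$forest, X, type = "prob")[, "1"])
}

#' Confusion-matrix metrics at a fixed threshold
#'
#' Thresholds probabilities (predicted interaction iff probability strictly
#' exceeds `threshold`) and reports the confusion counts with
#' ACC = (TP+TN)/(TP+TN+FP+FN), SE = TP/(TP+FN), SP = TN/(TN+FP),
#' F = 2TP/(2TP+FP+FN), precision = TP/(TP+FP) and recall = SE. Ratios with
#' a zero denominator are reported as `NaN`, never silently as 0.
#'
#' @param labels 0/1 vector of true labels.
#' @param probabilities Numeric vector of scores in \[0, 1\].
#' @param threshold Decision threshold (default 0.5).
#' @return A one-row tibble: `tp, fp, tn, fn, acc, se, sp, f, precision,
#'   recall`.
#' @export
compute_metrics <- function(labels, probabilities, threshold = 0.5) {
  stopifnot(length(labels) == length(probabilities), length(labels) > 0L)
  pred <- as.integer(probabilities > threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  ratio <- function(num, den) if (den == 0) NaN else num / den
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    acc = ratio(tp + tn, tp + tn + fp + fn),
    se = ratio(tp, tp + fn),
    sp = ratio(tn, tn + fp),
    f = ratio(2 * tp, 2 * tp + fp + fn),
    precision = ratio(tp, tp + fp),
    recall = ratio(tp, tp + fn)
  )
}

#' ROC and precision-recall curves
#'
#' Sweeps the decision threshold over the distinct score values (ties
#' grouped), tracing the ROC curve from (0,0) to (1,1) and the PR curve over
#' increasing recall. AUC is the trapezoidal area under the ROC curve (equal
#' to the tie-corrected normalized Mann-Whitney U statistic); AUPR is the
#' step-wise integral of precision over recall increments, without
#' interpolation between PR points (linear PR interpolation is optimistic).
#'
#' @param labels 0/1 vector with both classes present.
#' @param probabilities Scores in \[0, 1\].
#' @return An object of class `dti_curves`: tibbles `roc`
#'   (`threshold, fpr, tpr`) and `pr` (`threshold, recall, precision`), and
#'   scalars `auc`, `aupr`.
#' @export
curves <- function(labels, probabilities) {
  stopifnot(length(labels) == length(probabilities))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("curves are undefined for single-class labels")
  }
  ord <- order(probabilities, decreasing = TRUE)
  lab <- labels[ord]
  prob <- probabilities[ord]
  grp_last <- which(!duplicated(prob, fromLast = TRUE))  # last index per tie group
  tp <- cumsum(lab == 1L)[grp_last]
  fp <- cumsum(lab == 0L)[grp_last]
  roc <- tibble::tibble(
    threshold = c(Inf, prob[grp_last]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  pr <- tibble::tibble(
    threshold = prob[grp_last],
    recall = tp / n_pos,
    precision = tp / (tp + fp)
  )
  aupr <- sum(diff(c(0, pr$recall)) * pr$precision)
  structure(list(roc = roc, pr = pr, auc = auc, aupr = aupr),
            class = "dti_curves")
}

#' @export
print.dti_curves <- function(x, ...) {
  cat("<dti_curves> AUC = ", sprintf("%.4f", x$auc), ", AUPR = ",
      sprintf("%.4f", x$aupr), " (", nrow(x$roc) - 1L, " thresholds)\n",
      sep = "")
  invisible(x)
}

#' Plot ROC and/or PR curves
#'
#' @param object A `dti_curves` result.
#' @param which `"roc"`, `"pr"`, or `"both"` (default).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot dti_curves
autoplot.dti_curves <- function(object, which = c("both", "roc", "pr"), ...) {
  which <- match.arg(which)
  roc_df <- dplyr::mutate(object$roc, panel = "ROC", x = .data$fpr, y = .data$tpr)
  pr_df <- dplyr::mutate(object$pr, panel = "Precision-recall",
                         x = .data$recall, y = .data$precision)
  df <- switch(which, roc = roc_df, pr = pr_df, both = dplyr::bind_rows(roc_df, pr_df))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = NULL,
      subtitle = sprintf("AUC = %.4f, AUPR = %.4f", object$auc, object$aupr)
    ) +
    ggplot2::theme_minimal()
}

# near-equal random partition into n_folds; sizes differ by at most 1
make_folds <- function(n, n_folds, seed) {
  withr::with_seed(seed, sample(rep(seq_len(n_folds), length.out = n)))
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483629)
}

#' Five-fold cross-validated evaluation of the full pipeline
#'
#' Randomly partitions the pair rows into `n_folds` near-equal folds and,
#' for each fold, fits the selection + balancing + forest pipeline and
#' evaluates on the held-out rows.
#'
#' Two balancing scopes are supported. `"train_only"` (the default, and the
#' methodologically sound choice) fits the Lasso and applies SMOTE inside
#' each training split only, so held-out rows are untouched originals.
#' `"global"` applies Lasso and SMOTE to the full table before splitting, so
#' held-out folds contain synthetic minority rows; this reproduces the
#' historical protocol of evaluating on the balanced data and is optimistic
#' on null data. Reports name the scope used.
#'
#' @param table Pair feature tibble with `label`.
#' @param n_folds Number of folds (default 5).
#' @param seed Master seed; fold assignment and all per-fold randomness are
#'   derived from it.
#' @param lasso_lambda Fixed Lasso weight; if `NULL`, chosen per training
#'   split by [choose_lambda_reg()] over `lasso_grid`.
#' @param lasso_grid Candidate Lasso weights (default scales with the row
#'   count so selection strength is size-free).
#' @param balance A [balance_config()] or `NULL` to skip SMOTE.
#' @param balance_scope `"train_only"` or `"global"`.
#' @param forest A [forest_config()].
#' @return An object of class `dti_cv`: `folds` (per-fold metric tibble,
#'   including `auc`/`aupr`), `summary` (mean and SD per metric),
#'   `balance_scope`, and the configs used.
#' @export
cross_validate <- function(table, n_folds = 5L, seed = 1L,
                           lasso_lambda = NULL,
                           lasso_grid = 2 * nrow(table) * c(1e-4, 1e-3, 1e-2),
                           balance = balance_config(),
                           balance_scope = c("train_only", "global"),
                           forest = forest_config()) {
  balance_scope <- match.arg(balance_scope)
  stopifnot(n_folds >= 2L)

  fit_and_score <- function(train, test, fold_seed) {
    prob <- fit_pipeline(train, lasso_lambda, lasso_grid, balance, forest,
                         fold_seed, predict_on = test)
    scalars <- compute_metrics(test$label, prob)
    if (length(unique(test$label)) == 2L) {
      cv <- curves(test$label, prob)
      scalars$auc <- cv$auc
      scalars$aupr <- cv$aupr
    } else {
      warning("fold without both classes in evaluation: AUC/AUPR undefined")
      scalars$auc <- NaN
      scalars$aupr <- NaN
    }
    scalars
  }

  if (balance_scope == "global") {
    sel_lambda <- lasso_lambda %||%
      choose_lambda_reg(table, n_folds, lasso_grid, derive_seed(seed, 0L))
    sel <- lasso_select(table, sel_lambda)
    work <- select_features(sel, table)
    if (!is.null(balance)) {
      work <- smote_balance(work, balance, seed = derive_seed(seed, 999L))
    }
    folds <- make_folds(nrow(work), n_folds, seed)
    fold_tbl <- purrr::map_dfr(seq_len(n_folds), function(f) {
      train <- work[folds != f, , drop = FALSE]
      test <- work[folds == f, , drop = FALSE]
      fit <- train_forest(train, forest, seed = derive_seed(seed, f))
      prob <- predict(fit, test)
      scalars <- compute_metrics(test$label, prob)
      cv <- curves(test$label, prob)
      scalars$auc <- cv$auc
      scalars$aupr <- cv$aupr
      dplyr::mutate(scalars, fold = .env$f, .before = 1L)
    })
  } else {
    folds <- make_folds(nrow(table), n_folds, seed)
    fold_tbl <- purrr::map_dfr(seq_len(n_folds), function(f) {
      train <- table[folds != f, , drop = FALSE]
      test <- table[folds == f, , drop = FALSE]
      dplyr::mutate(fit_and_score(train, test, derive_seed(seed, f)),
                    fold = .env$f, .before = 1L)
    })
  }

  metric_cols <- setdiff(names(fold_tbl), "fold")
  summary <- tibble::tibble(
    metric = metric_cols,
    mean = vapply(fold_tbl[metric_cols], function(v) mean(v[is.finite(v)]), numeric(1)),
    sd = vapply(fold_tbl[metric_cols], function(v) stats::sd(v[is.finite(v)]), numeric(1))
  )
  structure(
    list(folds = fold_tbl, summary = summary, balance_scope = balance_scope,
         n_folds = n_folds, seed = seed),
    class = "dti_cv"
  )
}

# shared train-side pipeline: lasso -> smote -> forest, score `predict_on`
fit_pipeline <- function(train, lasso_lambda, lasso_grid, balance, forest,
                         seed, predict_on) {
  sel_lambda <- lasso_lambda %||%
    choose_lambda_reg(train, 5L, lasso_grid, derive_seed(seed, 11L))
  sel <- lasso_select(train, sel_lambda)
  train_sel <- select_features(sel, train)
  if (!is.null(balance)) {
    train_sel <- smote_balance(train_sel, balance, seed = derive_seed(seed, 13L))
  }
  fit <- train_forest(train_sel, forest, seed = derive_seed(seed, 17L))
  predict(fit, select_features(sel, predict_on))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dti_cv <- function(x, ...) {
  cat("<dti_cv> ", x$n_folds, "-fold cross-validation (balance scope: ",
      x$balance_scope, ")\n", sep = "")
  means <- x$summary$mean
  names(means) <- x$summary$metric
  show <- intersect(c("acc", "se", "sp", "f", "auc", "aupr"), names(means))
  cat(paste(sprintf("  mean %s = %.4f", show, means[show]), collapse = "\n"),
      "\n")
  invisible(x)
}

#' @export
#' @method tidy dti_cv
tidy.dti_cv <- function(x, ...) x$folds

#' @export
#' @method glance dti_cv
glance.dti_cv <- function(x, ...) {
  out <- as.list(x$summary$mean)
  names(out) <- x$summary$metric
  dplyr::mutate(tibble::as_tibble(out), n_folds = x$n_folds,
                balance_scope = x$balance_scope)
}

#' Plot per-fold cross-validation metrics
#'
#' @param object A `dti_cv` result.
#' @param metrics Metric columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot dti_cv
autoplot.dti_cv <- function(object,
                            metrics = c("acc", "se", "sp", "f", "auc", "aupr"),
                            ...) {
  df <- tidyr::pivot_longer(object$folds,
                            cols = dplyr::any_of(metrics),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7, size = 1.5) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  subtitle = paste0(object$n_folds, "-fold CV (",
                                    object$balance_scope, " balancing)")) +
    ggplot2::theme_minimal()
}
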