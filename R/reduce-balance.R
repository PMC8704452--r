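#' L1 (Lasso) feature selection on a pair feature table
#'
#' Fits the regression-form Lasso on the 0/1 interaction label: minimize
#' sum_n (y_n - sum_m x_nm beta_m)^2 + lambda_reg * sum_m |beta_m|. Features
#' are standardized internally (zero mean, unit sample variance) and the
#' label is centered; coefficients are reported on the standardized scale.
#' The support (features with nonzero coefficients) defines a mask that
#' [select_features()] applies to any table with the same feature layout.
#'
#' The solver is glmnet's coordinate descent; the penalty above is
#' glmnet's objective scaled by 2N, so `lambda_reg` maps to a glmnet lambda
#' of `lambda_reg / (2 * N)`.
#'
#' @param table Pair feature tibble (from [pair_features()]) with a `label`
#'   column; at least 2 rows and both classes present.
#' @param lambda_reg Non-negative regularization weight on the
#'   sum-of-squares scale above.
#' @return An object of class `dti_selection`: `lambda_reg`, named
#'   `coefficients` (standardized scale), `retained` (names of the support,
#'   original order), and the full `feature_names`.
#' @export
lasso_select <- function(table, lambda_reg) {
  stopifnot(lambda_reg >= 0, nrow(table) >= 2L)
  if (length(unique(table$label)) < 2L) {
    stop("constant label: both classes are required for feature selection")
  }
  feats <- feature_names(table)
  if (length(feats) < 2L) stop("at least two feature columns are required")
  X <- as.matrix(table[, feats])
  n <- nrow(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl_safe <- ifelse(scl == 0, 1, scl)
  Xs <- sweep(sweep(X, 2, ctr), 2, scl_safe, `/`)
  y <- table$label - mean(table$label)
  lam_g <- lambda_reg / (2 * n)
  # descending path ending at the requested lambda stabilizes the fit
  path <- sort(unique(c(lam_g * c(32, 16, 8, 4, 2, 1), lam_g)), decreasing = TRUE)
  if (lam_g == 0) path <- c(0.01, 0.001, 0)
  fit <- glmnet::glmnet(Xs, y, family = "gaussian", alpha = 1,
                        lambda = path, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-14, maxit = 1e6)
  beta <- as.numeric(fit$beta[, which.min(abs(fit$lambda - lam_g))])
  names(beta) <- feats
  beta[scl == 0] <- 0  # constant features carry no information
  structure(
    list(lambda_reg = lambda_reg, coefficients = beta,
         retained = feats[beta != 0], feature_names = feats),
    class = "dti_selection"
  )
}

#' @export
print.dti_selection <- function(x, ...) {
  cat("<dti_selection> lambda = ", format(x$lambda_reg), ": ",
      length(x$retained), " of ", length(x$feature_names),
      " features retained\n", sep = "")
  invisible(x)
}

#' @export
#' @method tidy dti_selection
tidy.dti_selection <- function(x, ...) {
  tibble::tibble(feature = x$feature_names,
                 estimate = unname(x$coefficients),
                 retained = x$feature_names %in% x$retained)
}

#' Apply a selection mask to a pair feature table
#'
#' Keeps the bookkeeping columns (`target`, `drug`, `label`, `provenance`)
#' plus the retained feature columns, in their original order. The transform
#' is idempotent: applying it to an already-selected table is the identity.
#'
#' @param selection A `dti_selection` from [lasso_select()].
#' @param table A pair feature table whose feature columns are either the
#'   full original layout or the already-selected layout.
#' @return The masked tibble.
#' @export
select_features <- function(selection, table) {
  stopifnot(inherits(selection, "dti_selection"))
  feats <- feature_names(table)
  keep_cols <- intersect(c("target", "drug", "label", "provenance"), names(table))
  if (identical(feats, selection$retained)) {
    return(table)  # idempotent on already-selected tables
  }
  if (!identical(feats, selection$feature_names)) {
    stop("feature dimension mismatch: table has ", length(feats),
         " feature columns, selection was fitted on ",
         length(selection$feature_names))
  }
  table[, c(keep_cols, selection$retained)]
}

#' Choose the Lasso weight by cross-validation
#'
#' Evaluates each candidate `lambda_reg` by k-fold cross-validated squared
#' error of the penalized linear fit on the 0/1 label and returns the grid
#' value with the smallest mean CV error. Ties are broken toward the larger
#' (sparser) value. Deterministic given `seed`.
#'
#' @param table Pair feature tibble with a `label` column.
#' @param n_folds Number of folds (default 5).
#' @param grid Non-empty numeric vector of candidate weights.
#' @param seed Integer seed for the fold assignment.
#' @return The selected grid value.
#' @export
choose_lambda_reg <- function(table, n_folds = 5L, grid, seed = 1L) {
  stopifnot(length(grid) >= 1L)
  if (length(grid) == 1L) return(grid)
  grid <- sort(grid)
  folds <- make_folds(nrow(table), n_folds, seed)
  feats <- feature_names(table)
  cv_err <- vapply(grid, function(lam) {
    errs <- vapply(seq_len(n_folds), function(f) {
      tr <- table[folds != f, , drop = FALSE]
      te <- table[folds == f, , drop = FALSE]
      if (length(unique(tr$label)) < 2L) return(NA_real_)
      sel <- lasso_select(tr, lam)
      Xtr <- as.matrix(tr[, feats])
      ctr <- colMeans(Xtr)
      scl <- apply(Xtr, 2, stats::sd)
      scl[scl == 0] <- 1
      Xte <- sweep(sweep(as.matrix(te[, feats]), 2, ctr), 2, scl, `/`)
      pred <- mean(tr$label) + as.numeric(Xte %*% sel$coefficients)
      mean((te$label - pred)^2)
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }, numeric(1))
  best <- max(grid[cv_err == min(cv_err)])
  best
}

#' SMOTE balancing configuration
#'
#' Parameter bundle for [smote_balance()], following the DMwR-style
#' percentage convention: `perc_over = 500` means 5 synthetic rows per
#' minority row; `perc_under = 120` means the kept majority count is 1.2
#' times the synthetic count.
#'
#' @param perc_over Oversampling percentage, a positive multiple of 100.
#' @param perc_under Undersampling percentage.
#' @param k_neighbors Number of nearest minority neighbors (k >= 1).
#' @param seed Optional integer seed.
#' @return A list of class `balance_config`.
#' @export
balance_config <- function(perc_over = 500, perc_under = 120,
                           k_neighbors = 5L, seed = NULL) {
  stopifnot(perc_over > 0, perc_over %% 100 == 0, perc_under >= 0,
            k_neighbors >= 1L)
  structure(list(perc_over = perc_over, perc_under = perc_under,
                 k_neighbors = as.integer(k_neighbors), seed = seed),
            class = "balance_config")
}

#' SMOTE oversampling with majority undersampling
#'
#' Rebalances a pair feature table. For each minority-class row z,
#' `perc_over/100` synthetic rows are generated as z_new = z + U * (zbar - z)
#' with U ~ Uniform(0,1) drawn once per synthetic row and zbar a uniformly
#' chosen member of z's k nearest minority neighbors (Euclidean distance in
#' the current feature space; distance ties broken by row index). All
#' original minority rows are kept; `perc_under/100 *` (synthetic count)
#' majority rows are sampled uniformly without replacement (capped at the
#' majority count). With the default (500, 120, 5) parameters and m minority
#' rows against at least 6m majority rows, the output is exactly balanced:
#' 6m minority (m original + 5m synthetic) vs 6m majority.
#'
#' Original rows pass through unmodified; synthetic rows carry `NA`
#' identifiers and are flagged in a `provenance` column.
#'
#' @param table Pair feature tibble with a `label` column.
#' @param cfg A [balance_config()].
#' @param seed Optional seed overriding `cfg$seed`.
#' @return The rebalanced tibble with an added `provenance` column
#'   (`"original"` / `"synthetic"`).
#' @export
smote_balance <- function(table, cfg = balance_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "balance_config"))
  counts <- table(table$label)
  if (length(counts) < 2L) stop("both classes are required for balancing")
  minority_label <- as.integer(names(counts)[which.min(counts)])
  k <- cfg$k_neighbors
  n_min <- min(counts)
  if (n_min < k + 1L) {
    stop("minority class has ", n_min, " rows; SMOTE with k = ", k,
         " needs at least k + 1 = ", k + 1L,
         " -- use a smaller k_neighbors")
  }
  run <- function() {
    feats <- feature_names(table)
    min_rows <- table[table$label == minority_label, , drop = FALSE]
    maj_rows <- table[table$label != minority_label, , drop = FALSE]
    Xm <- as.matrix(min_rows[, feats])
    m <- nrow(Xm)
    n_per <- cfg$perc_over / 100
    D <- as.matrix(stats::dist(Xm))
    syn <- vector("list", m)
    for (i in seq_len(m)) {
      ord <- order(D[i, ], seq_len(m))       # ties broken by row index
      nn <- setdiff(ord, i)[seq_len(k)]
      pick <- nn[sample.int(k, n_per, replace = TRUE)]
      U <- stats::runif(n_per)
      syn[[i]] <- Xm[rep(i, n_per), , drop = FALSE] +
        U * (Xm[pick, , drop = FALSE] - Xm[rep(i, n_per), , drop = FALSE])
    }
    syn_mat <- do.call(rbind, syn)
    syn_tbl <- tibble::as_tibble(syn_mat)
    syn_tbl$label <- minority_label
    if ("target" %in% names(table)) syn_tbl$target <- NA_character_
    if ("drug" %in% names(table)) syn_tbl$drug <- NA_character_
    syn_tbl <- syn_tbl[, names(table)]
    n_keep <- min(round(cfg$perc_under / 100 * nrow(syn_tbl)), nrow(maj_rows))
    kept_maj <- maj_rows[sample.int(nrow(maj_rows), n_keep), , drop = FALSE]
    out <- dplyr::bind_rows(
      dplyr::mutate(min_rows, provenance = "original"),
      dplyr::mutate(syn_tbl, provenance = "synthetic"),
      dplyr::mutate(kept_maj, provenance = "original")
    )
    out
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}
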