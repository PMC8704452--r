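#' Pipeline configuration bundle
#'
#' Collects the tunable parameters of the end-to-end pipeline with their
#' defaults: PsePSSM lag `lambda_order = 3`, DCCA segment `s = 36` (both
#' chosen by mean cross-validated accuracy scans), 5-fold CV, DMwR-style
#' SMOTE (500/120/5) and a 500-tree forest.
#'
#' @param lambda_order PsePSSM lag.
#' @param s DCCA segment parameter.
#' @param n_folds CV folds.
#' @param balance [balance_config()] or `NULL`.
#' @param balance_scope `"train_only"` (default) or `"global"`.
#' @param forest [forest_config()].
#' @param lasso_lambda Fixed Lasso weight, or `NULL` to cross-validate.
#' @param lasso_grid Candidate Lasso weights used when `lasso_lambda` is
#'   `NULL` (`NULL` = size-dependent default of [cross_validate()]).
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(lambda_order = 3L, s = 36L, n_folds = 5L,
                            balance = balance_config(),
                            balance_scope = "train_only",
                            forest = forest_config(),
                            lasso_lambda = NULL, lasso_grid = NULL,
                            seed = 1L) {
  structure(list(lambda_order = as.integer(lambda_order), s = as.integer(s),
                 n_folds = as.integer(n_folds), balance = balance,
                 balance_scope = balance_scope, forest = forest,
                 lasso_lambda = lasso_lambda, lasso_grid = lasso_grid,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

cv_with_config <- function(table, config, seed) {
  args <- list(table = table, n_folds = config$n_folds, seed = seed,
               lasso_lambda = config$lasso_lambda,
               balance = config$balance, balance_scope = config$balance_scope,
               forest = config$forest)
  if (!is.null(config$lasso_grid)) args$lasso_grid <- config$lasso_grid
  do.call(cross_validate, args)
}

min_profile_length <- function(studies) {
  min(vapply(studies,
             function(st) min(vapply(st$profiles, function(p) nrow(p$scores),
                                     integer(1))),
             integer(1)))
}

scan_parameter <- function(studies, values, config, build_table) {
  if (inherits(studies, "dti_study")) studies <- list(studies)
  stopifnot(length(studies) >= 1L)
  if (is.null(names(studies)) || any(names(studies) == "")) {
    names(studies) <- paste0("dataset", seq_along(studies))
  }
  rows <- purrr::map_dfr(seq_along(values), function(i) {
    val <- values[i]
    accs <- purrr::map_dbl(studies, function(st) {
      tab <- tryCatch(build_table(st, val), error = function(e) NULL)
      if (is.null(tab)) return(NA_real_)
      cv <- cv_with_config(tab, config, derive_seed(config$seed, val))
      cv$summary$mean[cv$summary$metric == "acc"]
    })
    out <- tibble::as_tibble(as.list(accs))
    names(out) <- paste0("acc_", names(studies))
    dplyr::mutate(out, value = val, feasible = !anyNA(accs),
                  mean_acc = mean(accs), .before = 1L)
  })
  feas <- rows[rows$feasible, , drop = FALSE]
  selected <- if (nrow(feas) > 0L) {
    feas$value[which.max(feas$mean_acc)]  # which.max takes the first = smallest
  } else NA
  attr(rows, "selected") <- selected
  rows
}

#' Scan the PsePSSM lag parameter
#'
#' For each candidate lag, rebuilds the per-pair feature tables of every
#' study at that lag (DCCA segment fixed at `config$s`), runs cross-validated
#' evaluation, and records per-study and mean accuracy. The selected lag
#' (attribute `"selected"`) is the feasible candidate with the highest mean
#' accuracy, ties broken toward the smallest value. Candidates reaching any
#' protein's length are marked infeasible and excluded from selection.
#' Per-candidate seeds are derived from the master seed and the candidate
#' value, so evaluation order (or parallel execution) cannot change results.
#'
#' @param studies A `dti_study` or (optionally named) list of them.
#' @param values Candidate lags (default 0..15).
#' @param config A [pipeline_config()].
#' @return Tibble with one row per candidate (`value`, `feasible`,
#'   `mean_acc`, one `acc_*` column per study) and attribute `"selected"`.
#' @export
scan_lambda <- function(studies, values = 0:15, config = pipeline_config()) {
  scan_parameter(studies, values, config,
                 function(st, v) pair_features(st, lambda_order = v, s = config$s))
}

#' Scan the DCCA segment parameter
#'
#' Same contract as [scan_lambda()], over the DCCA segment length
#' (default candidates 9..81; a candidate is infeasible when it exceeds the
#' shortest profile length minus one).
#'
#' @inheritParams scan_lambda
#' @param values Candidate segment lengths (default 9..81).
#' @return Tibble as in [scan_lambda()], attribute `"selected"`.
#' @export
scan_s <- function(studies, values = 9:81, config = pipeline_config()) {
  scan_parameter(studies, values, config,
                 function(st, v) pair_features(st, lambda_order = config$lambda_order,
                                               s = v))
}

#' Rank novel drug-target interactions
#'
#' Trains the full pipeline (Lasso selection, SMOTE balancing, random
#' forest) on every pair of the training study, then scores every
#' (query target) x (query drug) pair and returns the pairs whose predicted
#' interaction probability strictly exceeds `cutoff`, ranked by probability
#' (descending; ties by drug id then target id).
#'
#' @param train A `dti_study` used in full as training data.
#' @param query_profiles List of [pssm_profile] objects for the query
#'   targets (each of length at least `s + 1`).
#' @param query_fingerprints Tibble (`drug_id`, `hex`) for the query drugs.
#' @param config A [pipeline_config()].
#' @param cutoff Reporting threshold on the probability (default 0.5).
#' @param drug_names,target_names Optional named character vectors mapping
#'   ids to display names.
#' @return A tibble (`drug`, `drug_name`, `target`, `target_name`, `prob`)
#'   with attributes `"fraction_above"` (share of the query grid above the
#'   cutoff) and `"n_query"` (grid size).
#' @export
predict_new <- function(train, query_profiles, query_fingerprints,
                        config = pipeline_config(), cutoff = 0.5,
                        drug_names = NULL, target_names = NULL) {
  stopifnot(inherits(train, "dti_study"))
  train_tab <- pair_features(train, config$lambda_order, config$s)
  too_short <- vapply(query_profiles,
                      function(p) nrow(p$scores) < config$s + 1L, logical(1))
  if (any(too_short)) {
    stop("query proteins shorter than s + 1 = ", config$s + 1L, ": ",
         paste(vapply(query_profiles[too_short],
                      function(p) p$protein_id, character(1)),
               collapse = ", "))
  }
  query_ds <- dti_dataset(
    tibble::tibble(target = character(), drug = character()),
    protein_feature_table(query_profiles, config$lambda_order, config$s),
    fingerprint_table(query_fingerprints$drug_id, query_fingerprints$hex)
  )
  query_tab <- pair_features(query_ds)
  grid_default <- 2 * nrow(train_tab) * c(1e-4, 1e-3, 1e-2)
  prob <- fit_pipeline(train_tab, config$lasso_lambda,
                       config$lasso_grid %||% grid_default,
                       config$balance, config$forest, config$seed,
                       predict_on = query_tab)
  recs <- tibble::tibble(
    drug = query_tab$drug,
    drug_name = if (is.null(drug_names)) NA_character_ else
      unname(drug_names[query_tab$drug]),
    target = query_tab$target,
    target_name = if (is.null(target_names)) NA_character_ else
      unname(target_names[query_tab$target]),
    prob = prob
  )
  out <- dplyr::arrange(recs[recs$prob > cutoff, , drop = FALSE],
                        dplyr::desc(.data$prob), .data$drug, .data$target)
  attr(out, "fraction_above") <- nrow(out) / nrow(query_tab)
  attr(out, "n_query") <- nrow(query_tab)
  out
}
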