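make_lasso_table <- function(n = 40, d = 6, seed = 1, informative = 2) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("x", 1:d)))
    eta <- rowSums(X[, seq_len(informative), drop = FALSE])
    label <- as.integer(eta + rnorm(n, sd = 0.3) > 0)
    dplyr::bind_cols(tibble::tibble(label = label), tibble::as_tibble(X))
  })
}

test_that("unpenalized fit is dense and heavy penalties empty the support", {
  tab <- make_lasso_table(n = 50, d = 5)
  sel0 <- lasso_select(tab, 0)
  expect_length(sel0$retained, 5L)
  sel_big <- lasso_select(tab, 1e6)
  expect_length(sel_big$retained, 0L)
  expect_true(all(sel_big$coefficients == 0))
})

test_that("orthonormal designs obey the soft-thresholding closed form", {
  n <- 8
  Q <- orthonormal_design(n, 4, seed = 33)  # orthogonal, mean 0, sd 1
  y <- withr::with_seed(34, rnorm(n))
  tab <- dplyr::bind_cols(
    tibble::tibble(label = y),
    tibble::as_tibble(`colnames<-`(Q, paste0("q", 1:4)))
  )
  # after standardization X'X = (n-1) I, so the penalized coefficients are
  # soft-thresholded least-squares coefficients at lambda / (2 (n-1))
  c_diag <- nrow(Q) - 1
  b_ls <- as.numeric(crossprod(Q, y - mean(y))) / c_diag
  for (lam in c(0.5, 2, 5)) {
    sel <- lasso_select(tab, lam)
    closed <- sign(b_ls) * pmax(abs(b_ls) - lam / (2 * c_diag), 0)
    expect_equal(unname(sel$coefficients), closed, tolerance = 1e-6)
    expect_setequal(sel$retained, paste0("q", 1:4)[closed != 0])
  }
})

test_that("selection rejects degenerate inputs and mismatched transforms", {
  tab <- make_lasso_table()
  tab$label <- 1L
  expect_error(lasso_select(tab, 1), "constant label")

  tab <- make_lasso_table()
  sel <- lasso_select(tab, 2)
  other <- make_lasso_table(d = 4, seed = 2)
  expect_error(select_features(sel, other), "mismatch")
})

test_that("the selection transform is idempotent and order-preserving", {
  tab <- make_lasso_table(n = 60, d = 8)
  sel <- lasso_select(tab, 5)
  expect_gt(length(sel$retained), 0L)
  once <- select_features(sel, tab)
  expect_identical(select_features(sel, once), once)
  expect_identical(feature_names(once), sel$retained)
  expect_identical(sel$retained,
                   intersect(sel$feature_names, sel$retained))  # original order
})

test_that("cross-validated lambda choice is deterministic and sane", {
  tab <- make_lasso_table(n = 60, d = 6)
  expect_equal(choose_lambda_reg(tab, grid = 3.14), 3.14)

  grid <- c(0.1, 1, 10, 100)
  a <- choose_lambda_reg(tab, 5, grid, seed = 4)
  b <- choose_lambda_reg(tab, 5, grid, seed = 4)
  expect_identical(a, b)
  expect_true(a %in% grid)

  # pure-noise labels: penalized support never exceeds the unpenalized one
  noise <- make_lasso_table(n = 40, d = 6, informative = 0)
  noise$label <- withr::with_seed(9, sample(0:1, 40, replace = TRUE))
  lam <- choose_lambda_reg(noise, 5, grid, seed = 4)
  expect_lte(length(lasso_select(noise, lam)$retained),
             length(lasso_select(noise, 0)$retained))
})

test_that("penalized support includes planted features across seeds", {
  hits <- 0L
  n_rep <- 10L
  for (seed in seq_len(n_rep)) {
    tab <- make_lasso_table(n = 80, d = 10, seed = seed, informative = 2)
    lam <- choose_lambda_reg(tab, 5, grid = 2 * 80 * c(1e-3, 1e-2, 1e-1),
                             seed = seed)
    sel <- lasso_select(tab, lam)
    if (all(c("x1", "x2") %in% sel$retained)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("SMOTE synthesizes on segments between minority neighbours", {
  tab <- small_pair_table(seed = 3, n_targets = 5, n_drugs = 8,
                          n_positives = 8)
  cfg <- balance_config(perc_over = 300, perc_under = 100, k_neighbors = 3,
                        seed = 12)
  out <- smote_balance(tab, cfg)
  feats <- feature_names(tab)
  minority <- tab[tab$label == 1, feats]
  syn <- out[out$provenance == "synthetic", feats]
  expect_gt(nrow(syn), 0L)
  # convex combination: every coordinate within the minority per-column range
  lo <- vapply(minority, min, numeric(1))
  hi <- vapply(minority, max, numeric(1))
  for (j in seq_along(feats)) {
    expect_true(all(syn[[j]] >= lo[j] - 1e-12 & syn[[j]] <= hi[j] + 1e-12))
  }
  # each synthetic row is z + U (zbar - z) for two minority rows z, zbar:
  # recover U from one coordinate and check all others agree
  Xm <- as.matrix(minority)
  for (r in seq_len(nrow(syn))) {
    zn <- as.numeric(syn[r, ])
    ok <- FALSE
    for (i in seq_len(nrow(Xm))) for (j in seq_len(nrow(Xm))) {
      if (i == j) next
      d <- Xm[j, ] - Xm[i, ]
      nz <- which(abs(d) > 1e-9)
      if (length(nz) == 0) next
      U <- (zn[nz[1]] - Xm[i, nz[1]]) / d[nz[1]]
      if (U >= -1e-9 && U <= 1 + 1e-9 &&
          max(abs(zn - (Xm[i, ] + U * d))) < 1e-9) { ok <- TRUE; break }
    }
    expect_true(ok, label = paste("synthetic row", r, "lies on a minority segment"))
  }
})

test_that("default SMOTE parameters yield exact 6m/6m class balance", {
  tab <- small_pair_table(seed = 5, n_targets = 8, n_drugs = 12,
                          n_positives = 12)
  m <- sum(tab$label == 1)
  out <- smote_balance(tab, balance_config(seed = 7))
  expect_equal(sum(out$label == 1), 6 * m)  # m original + 5m synthetic
  expect_equal(sum(out$label == 0), 6 * m)  # 1.2 x synthetic count
  expect_equal(sum(out$provenance == "synthetic"), 5 * m)

  # original rows pass through with unchanged values (integer feature columns
  # are promoted to double when bound with synthetic rows)
  orig_min <- out[out$provenance == "original" & out$label == 1, names(tab)]
  as_dbl <- function(t) dplyr::mutate(t, dplyr::across(dplyr::where(is.numeric),
                                                       as.numeric))
  expect_equal(as_dbl(orig_min), as_dbl(tab[tab$label == 1, ]))
  orig_maj_ids <- paste(out$target[out$label == 0], out$drug[out$label == 0])
  expect_true(all(orig_maj_ids %in% paste(tab$target, tab$drug)))
  expect_false(anyDuplicated(orig_maj_ids) > 0)  # without replacement

  # reproducible under seed
  expect_identical(out, smote_balance(tab, balance_config(seed = 7)))

  expect_error(
    smote_balance(tab[c(which(tab$label == 1)[1:4], which(tab$label == 0)), ],
                  balance_config()),
    "smaller k"
  )
})
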