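# shared fixtures and independent oracles

random_profile <- function(L, protein_id = "P1", seed = NULL) {
  gen <- function() {
    pssm_profile(protein_id,
                 sample(AMINO_ACIDS, L, replace = TRUE),
                 matrix(sample(-9:11, L * 20, replace = TRUE), nrow = L))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

random_norm_profile <- function(L, protein_id = "P1", seed = NULL) {
  normalize_profile(random_profile(L, protein_id, seed))
}

random_hex <- function(n = 256, seed = NULL) {
  gen <- function() paste(sample(c(0:9, letters[1:6]), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Brute-force DCCA coefficient: materializes every window and fits each
# straight line by explicit normal equations. Independent of the package's
# projection-based implementation.
dcca_brute <- function(x, y, s) {
  L <- length(x)
  X <- cumsum(x)
  Y <- cumsum(y)
  fit_line <- function(v, k) {
    kb <- mean(k); vb <- mean(v)
    slope <- sum((k - kb) * (v - vb)) / sum((k - kb)^2)
    vb + slope * (k - kb)
  }
  fxy <- fxx <- fyy <- 0
  for (i in seq_len(L - s)) {
    k <- i:(i + s)
    rx <- X[k] - fit_line(X[k], k)
    ry <- Y[k] - fit_line(Y[k], k)
    fxy <- fxy + sum(rx * ry) / (s + 1)
    fxx <- fxx + sum(rx * rx) / (s + 1)
    fyy <- fyy + sum(ry * ry) / (s + 1)
  }
  fxy <- fxy / (L - s); fxx <- fxx / (L - s); fyy <- fyy / (L - s)
  fxy / sqrt(fxx * fyy)
}

# Naive PsePSSM: double loop over lags and columns.
psepssm_brute <- function(E, lambda) {
  L <- nrow(E)
  out <- colMeans(E)
  for (lag in seq_len(lambda)) {
    for (j in 1:20) {
      acc <- 0
      for (i in 1:(L - lag)) acc <- acc + (E[i, j] - E[i + lag, j])^2
      out <- c(out, acc / (L - lag))
    }
  }
  unname(out)
}

# AUC as the normalized Mann-Whitney U statistic by pairwise comparison.
auc_mwu <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# design with exactly orthogonal, mean-zero, unit-sd columns:
# orthonormalize AFTER centering, then rescale so X'X = (n-1) I
orthonormal_design <- function(n, p, seed) {
  withr::with_seed(seed, {
    M <- scale(matrix(rnorm(n * p), n), scale = FALSE)
    qr.Q(qr(M)) * sqrt(n - 1)
  })
}

small_study <- function(seed = 1, signal = 0, n_targets = 6, n_drugs = 10,
                        n_positives = 15, L_range = c(45, 60)) {
  simulate_dti(n_targets, n_drugs, n_positives, L_range,
               signal_strength = signal, seed = seed)
}

# small pair table with separable planted signal, cheap parameters
small_pair_table <- function(seed = 1, signal = 0, ...) {
  pair_features(small_study(seed, signal, ...), lambda_order = 1, s = 10)
}
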