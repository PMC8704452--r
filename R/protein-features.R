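#' PsePSSM descriptor of a normalized profile
#'
#' Collapses a variable-length L x 20 normalized profile into a fixed-length
#' vector: the 20 column means, followed for each lag lambda' = 1..lambda by
#' the 20 lagged mean-squared-difference correlation factors
#' theta_j = mean over i of (E'_{i,j} - E'_{i+lambda',j})^2. The result has
#' length 20 + 20*lambda; at `lambda_order = 0` it reduces to the column
#' means alone.
#'
#' @param np A normalized profile from [normalize_profile()].
#' @param lambda_order Non-negative integer lag parameter; must be smaller
#'   than the profile length L. Default 3 (the value selected by the
#'   accuracy scan over 0..15).
#' @return Named numeric vector of length `20 + 20 * lambda_order`
#'   (`psepssm_mean_A` ... then `psepssm_l<lag>_<aa>` blocks).
#' @export
psepssm <- function(np, lambda_order = 3L) {
  stopifnot(inherits(np, "pssm_profile_norm"))
  lambda_order <- as.integer(lambda_order)
  L <- nrow(np$values)
  if (lambda_order < 0L) stop("lambda_order must be non-negative")
  if (lambda_order >= L) {
    stop("lambda_order (", lambda_order, ") must be smaller than the profile ",
         "length L = ", L, " for protein ", np$protein_id)
  }
  E <- np$values
  out <- colMeans(E)
  names(out) <- paste0("psepssm_mean_", AMINO_ACIDS)
  for (lag in seq_len(lambda_order)) {
    d <- E[seq_len(L - lag), , drop = FALSE] - E[seq_len(L - lag) + lag, , drop = FALSE]
    theta <- colMeans(d^2)
    names(theta) <- paste0("psepssm_l", lag, "_", AMINO_ACIDS)
    out <- c(out, theta)
  }
  out
}

# Residual-maker for an OLS straight-line fit on 1..(s+1); symmetric idempotent,
# so window covariances reduce to crossproducts of projected windows.
detrend_projector <- function(s) {
  k <- seq_len(s + 1)
  A <- cbind(1, k)
  diag(s + 1) - A %*% solve(crossprod(A), t(A))
}

#' Detrended cross-correlation coefficient of two series
#'
#' Computes rho_DCCA(s) between two equal-length series: both are cumulated
#' into profiles, the profiles are cut into L - s overlapping windows of
#' s + 1 points (stride 1), each window is detrended by an OLS straight line
#' in the index, and the coefficient is the ratio of the window-averaged
#' residual covariance to the product of the window-averaged residual
#' standard deviations. Window moments use divisor s + 1. The result lies in
#' \[-1, 1\] (clipped against floating-point overshoot of order 1e-15).
#'
#' If either series is constant its detrended fluctuation is zero and the
#' coefficient is undefined; by convention 0 ("no cross-correlation") is
#' returned with a warning.
#'
#' @param x,y Numeric vectors of common length L.
#' @param s Integer window parameter, `2 <= s <= L - 1`.
#' @return A single number in \[-1, 1\].
#' @export
dcca_pair <- function(x, y, s) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  L <- length(x)
  s <- as.integer(s)
  if (s < 2L || s > L - 1L) {
    stop("segment parameter s = ", s, " outside the valid range [2, L-1] for L = ", L)
  }
  degen_x <- stats::var(x) == 0
  degen_y <- stats::var(y) == 0
  if (degen_x || degen_y) {
    warning("constant series: DCCA coefficient undefined, returning 0")
    return(0)
  }
  P <- detrend_projector(s)
  idx <- outer(seq_len(L - s), 0:s, `+`)
  Rx <- matrix(cumsum(x)[idx], nrow = L - s) %*% P
  Ry <- matrix(cumsum(y)[idx], nrow = L - s) %*% P
  denom <- (s + 1) * (L - s)
  fxy <- sum(Rx * Ry) / denom
  fxx <- sum(Rx * Rx) / denom
  fyy <- sum(Ry * Ry) / denom
  rho <- fxy / sqrt(fxx * fyy)
  min(1, max(-1, rho))
}

# pair order (1,2),(1,3),...,(19,20): fixed lexicographic convention
dcca_pair_index <- function() {
  j1 <- rep(seq_len(19L), times = 19L:1L)
  j2 <- unlist(lapply(seq_len(19L), function(j) seq(j + 1L, 20L)))
  cbind(j1, j2)
}

#' All-pairs DCCA coefficient vector of a normalized profile
#'
#' Treats the 20 columns of the normalized profile as 20 non-stationary
#' series and computes [dcca_pair()] for every unordered column pair, in
#' fixed lexicographic order (A,R), (A,N), ..., (Y,V): a 190-dimensional
#' descriptor. Constant columns yield 0 for every pair they participate in,
#' with a single warning.
#'
#' @param np A normalized profile from [normalize_profile()].
#' @param s Integer window parameter; requires `s <= L - 1` for this
#'   protein. Default 36 (the value selected by the accuracy scan over
#'   9..81).
#' @return Named numeric vector of length 190 (`dcca_A_R` ...), entries in
#'   \[-1, 1\].
#' @export
dcca_vector <- function(np, s = 36L) {
  stopifnot(inherits(np, "pssm_profile_norm"))
  L <- nrow(np$values)
  s <- as.integer(s)
  if (s < 2L || s > L - 1L) {
    stop("segment parameter s = ", s, " infeasible for protein ",
         np$protein_id, " with L = ", L, " (need 2 <= s <= L-1)")
  }
  E <- np$values
  P <- detrend_projector(s)
  idx <- outer(seq_len(L - s), 0:s, `+`)
  const_col <- apply(E, 2, function(col) stats::var(col) == 0)
  Z <- matrix(0, nrow = (L - s) * (s + 1), ncol = 20L)
  for (j in seq_len(20L)) {
    W <- matrix(cumsum(E[, j])[idx], nrow = L - s)
    Z[, j] <- as.vector(W %*% P)
  }
  Cov <- crossprod(Z) / ((s + 1) * (L - s))
  d <- sqrt(diag(Cov))
  d[const_col] <- 0
  rho <- Cov / outer(d, d)
  rho[!is.finite(rho)] <- 0
  rho <- pmin(pmax(rho, -1), 1)  # rho first: pmin/pmax keep dims of arg 1
  if (any(const_col)) {
    warning("constant profile column(s) ",
            paste(AMINO_ACIDS[const_col], collapse = ", "),
            ": affected DCCA coefficients set to 0")
  }
  pr <- dcca_pair_index()
  out <- rho[pr]
  names(out) <- paste0("dcca_", AMINO_ACIDS[pr[, 1]], "_", AMINO_ACIDS[pr[, 2]])
  out
}

#' Protein feature table (PsePSSM + DCCA)
#'
#' Computes the concatenated PsePSSM and DCCA descriptors for a list of raw
#' profiles, after sigmoid normalization, and returns them as one tidy table:
#' one row per protein, `20 + 20*lambda_order + 190` feature columns.
#'
#' @param profiles List of [pssm_profile] objects.
#' @param lambda_order PsePSSM lag parameter (default 3).
#' @param s DCCA segment parameter (default 36).
#' @return A tibble with column `protein_id` followed by the feature columns.
#' @export
protein_feature_table <- function(profiles, lambda_order = 3L, s = 36L) {
  stopifnot(length(profiles) >= 1L)
  rows <- purrr::map(profiles, function(p) {
    np <- normalize_profile(p)
    v <- c(psepssm(np, lambda_order), dcca_vector(np, s))
    tibble::as_tibble_row(c(list(protein_id = p$protein_id), as.list(v)))
  })
  dplyr::bind_rows(rows)
}
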