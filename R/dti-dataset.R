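#' Assemble a bipartite drug-target interaction dataset
#'
#' Combines an interaction edge list with per-protein and per-drug feature
#' tables into a `dti_dataset`. Every (target, drug) pair in the full
#' bipartite grid is a sample: pairs in the edge list are positives, all
#' remaining pairs are implicitly negatives (no negative subsampling).
#'
#' @param edges Data frame whose first two columns are target (protein) id
#'   and drug id, one known interaction per row.
#' @param protein_features Tibble with `protein_id` followed by numeric
#'   feature columns, e.g. from [protein_feature_table()].
#' @param drug_features Tibble with `drug_id` followed by numeric feature
#'   columns, e.g. from [fingerprint_table()].
#' @return An object of class `dti_dataset` with elements `targets`, `drugs`
#'   (sorted id vectors), `positives` (tibble of edges), the two feature
#'   tables, and the derived counts.
#' @export
dti_dataset <- function(edges, protein_features, drug_features) {
  edges <- tibble::as_tibble(edges)
  stopifnot(ncol(edges) >= 2L)
  names(edges)[1:2] <- c("target", "drug")
  edges <- dplyr::distinct(edges[, 1:2])
  targets <- sort(unique(protein_features$protein_id))
  drugs <- sort(unique(drug_features$drug_id))
  missing_t <- setdiff(edges$target, targets)
  missing_d <- setdiff(edges$drug, drugs)
  if (length(missing_t) + length(missing_d) > 0L) {
    stop("edges reference entities without features: ",
         paste(c(missing_t, missing_d), collapse = ", "))
  }
  n_pairs <- length(targets) * length(drugs)
  structure(
    list(targets = targets, drugs = drugs, positives = edges,
         protein_features = protein_features, drug_features = drug_features,
         n_pairs = n_pairs, n_positives = nrow(edges),
         n_negatives = n_pairs - nrow(edges)),
    class = "dti_dataset"
  )
}

#' @export
print.dti_dataset <- function(x, ...) {
  cat("<dti_dataset> ", length(x$targets), " targets x ", length(x$drugs),
      " drugs: ", x$n_positives, " positives, ", x$n_negatives,
      " negatives (sample ratio ", sprintf("%.2f", sample_ratio(x)), ")\n",
      sep = "")
  invisible(x)
}

#' Imbalance ratio of a DTI dataset
#'
#' Number of negative pairs divided by number of positive pairs; the
#' imbalance measure reported per benchmark dataset (e.g. 14.60 for the
#' nuclear-receptor collection, 99.98 for enzymes).
#'
#' @param d A [dti_dataset].
#' @return A single number (print with 2 decimals in summaries).
#' @export
sample_ratio <- function(d) {
  stopifnot(inherits(d, "dti_dataset"))
  if (d$n_positives == 0L) {
    stop("sample ratio undefined: dataset has no positive pairs")
  }
  d$n_negatives / d$n_positives
}

#' Per-pair fused feature table
#'
#' Enumerates the full bipartite grid (targets in the outer loop, drugs in
#' the inner loop, both in lexicographic order) and attaches to each pair
#' the concatenation of its protein feature vector followed by its drug
#' feature vector, plus a 0/1 interaction label. With the default
#' parameters (lambda = 3, s = 36) the feature dimension is
#' 80 + 190 + 256 = 526.
#'
#' @param x A [dti_dataset] or [simulate_dti()] study object.
#' @param ... Passed to methods; for study objects, `lambda_order` and `s`.
#' @return A tibble with columns `target`, `drug`, `label`, then the fused
#'   features; one row per grid pair.
#' @export
pair_features <- function(x, ...) UseMethod("pair_features")

#' @rdname pair_features
#' @export
pair_features.dti_dataset <- function(x, ...) {
  pf_dim <- ncol(x$protein_features) - 1L
  df_dim <- ncol(x$drug_features) - 1L
  if (pf_dim < 1L || df_dim < 1L) stop("empty feature table")
  grid <- tidyr::expand_grid(target = x$targets, drug = x$drugs)
  grid$label <- as.integer(
    paste(grid$target, grid$drug, sep = "\r") %in%
      paste(x$positives$target, x$positives$drug, sep = "\r")
  )
  out <- dplyr::left_join(grid, x$protein_features,
                          by = c(target = "protein_id"))
  out <- dplyr::left_join(out, x$drug_features, by = c(drug = "drug_id"))
  if (anyNA(out)) stop("feature dimension mismatch or missing feature rows")
  out
}

#' Feature columns of a pair table
#'
#' Helper returning the names of the numeric feature columns of a pair
#' feature table (everything except the `target`, `drug`, `label` and
#' `provenance` bookkeeping columns).
#'
#' @param table A pair feature tibble.
#' @return Character vector of feature column names.
#' @export
feature_names <- function(table) {
  setdiff(names(table), c("target", "drug", "label", "provenance"))
}

# -- synthetic study generator -----------------------------------------------

#' Simulate a synthetic DTI study
#'
#' Generates the raw inputs of a drug-target interaction study: integer
#' evolutionary profiles (entries uniform on -9..11, the empirical range of
#' PSI-BLAST log-odds scores) with lengths drawn from `L_range`, uniformly
#' random 256-nibble hex fingerprints, and a uniformly random positive edge
#' set of the requested size. Everything is reproducible under `seed`.
#'
#' When `signal_strength > 0`, feature assembly ([pair_features()]) adds a
#' mean shift of `signal_strength` within-table standard deviations to a
#' fixed small subset of feature columns on the positive rows only, planting
#' a class signal of known size; at 0 the labels are pure noise. The shift
#' is applied at the pair level because a pair-level class signal cannot be
#' expressed in per-protein profiles (each protein occurs in both classes).
#'
#' @param n_targets,n_drugs,n_positives Grid dimensions and positive count;
#'   `n_positives` must not exceed the grid size.
#' @param L_range Length-2 integer vector, inclusive range of profile
#'   lengths. The default lower bound 83 mirrors the shortest sequence in
#'   the benchmark collections (which caps the DCCA parameter at s = 82).
#' @param signal_strength Size of the planted class signal in within-table
#'   standard deviations per designated feature (0 = none).
#' @param seed Integer seed.
#' @return An object of class `dti_study`: `profiles` (list of
#'   [pssm_profile]), `fingerprints` (tibble `drug_id`, `hex`), `edges`
#'   (tibble `target`, `drug`), and the signal settings.
#' @export
simulate_dti <- function(n_targets = 10L, n_drugs = 20L, n_positives = 30L,
                         L_range = c(83L, 120L), signal_strength = 0,
                         seed = 1L) {
  stopifnot(n_targets >= 1L, n_drugs >= 1L, length(L_range) == 2L,
            L_range[1] >= 2L, L_range[1] <= L_range[2])
  if (n_positives > n_targets * n_drugs) {
    stop("n_positives (", n_positives, ") exceeds grid size ",
         n_targets * n_drugs)
  }
  withr::with_seed(seed, {
    target_ids <- sprintf("T%03d", seq_len(n_targets))
    drug_ids <- sprintf("D%03d", seq_len(n_drugs))
    profiles <- lapply(target_ids, function(id) {
      L <- sample(seq(L_range[1], L_range[2]), 1L)
      pssm_profile(id,
                   sample(AMINO_ACIDS, L, replace = TRUE),
                   matrix(sample(-9:11, L * 20L, replace = TRUE), nrow = L))
    })
    names(profiles) <- target_ids
    hex_chars <- c(0:9, letters[1:6])
    fingerprints <- tibble::tibble(
      drug_id = drug_ids,
      hex = vapply(drug_ids, function(id) {
        paste(sample(hex_chars, 256L, replace = TRUE), collapse = "")
      }, character(1))
    )
    pos_idx <- sample.int(n_targets * n_drugs, n_positives)
    edges <- tibble::tibble(
      target = target_ids[(pos_idx - 1L) %/% n_drugs + 1L],
      drug = drug_ids[(pos_idx - 1L) %% n_drugs + 1L]
    )
    structure(
      list(profiles = profiles, fingerprints = fingerprints, edges = edges,
           signal_strength = signal_strength, seed = seed),
      class = "dti_study"
    )
  })
}

#' @export
print.dti_study <- function(x, ...) {
  cat("<dti_study> ", length(x$profiles), " targets x ",
      nrow(x$fingerprints), " drugs, ", nrow(x$edges), " positive edges",
      if (x$signal_strength > 0) paste0(", planted signal ", x$signal_strength, " SD"),
      "\n", sep = "")
  invisible(x)
}

# designated columns carrying the planted class signal (fixed by convention)
signal_feature_names <- function() {
  c(paste0("psepssm_mean_", c("A", "R", "N", "D", "C")),
    sprintf("fp_%03d", 1:5))
}

#' Assemble a study into a dataset
#'
#' Computes protein (PsePSSM + DCCA) and drug (nibble) feature tables at the
#' given parameters and assembles the [dti_dataset].
#'
#' @param study A `dti_study` from [simulate_dti()] or [read_dti_study()].
#' @param lambda_order PsePSSM lag (default 3).
#' @param s DCCA segment parameter (default 36).
#' @return A [dti_dataset].
#' @export
as_dti_dataset <- function(study, lambda_order = 3L, s = 36L) {
  stopifnot(inherits(study, "dti_study"))
  dti_dataset(
    study$edges,
    protein_feature_table(study$profiles, lambda_order, s),
    fingerprint_table(study$fingerprints$drug_id, study$fingerprints$hex)
  )
}

#' @rdname pair_features
#' @param lambda_order PsePSSM lag parameter (default 3).
#' @param s DCCA segment parameter (default 36).
#' @export
pair_features.dti_study <- function(x, lambda_order = 3L, s = 36L, ...) {
  tab <- pair_features(as_dti_dataset(x, lambda_order, s))
  if (x$signal_strength > 0) {
    pos <- tab$label == 1L
    for (col in intersect(signal_feature_names(), names(tab))) {
      sd_col <- stats::sd(tab[[col]])
      if (sd_col == 0) sd_col <- 1
      tab[[col]][pos] <- tab[[col]][pos] + x$signal_strength * sd_col
    }
  }
  tab
}

#' Read a DTI study from disk
#'
#' Loads raw study inputs: a directory of PSI-BLAST ASCII PSSM files (one
#' per target, file name stem = protein id), a fingerprint TSV
#' (`drug_id`, hex) and an interaction edge TSV (`target`, `drug`).
#'
#' @param pssm_dir Directory containing `*.pssm` files.
#' @param fingerprint_path Path to the fingerprint TSV.
#' @param edges_path Path to the edge-list TSV (no header, two columns).
#' @return A `dti_study` object (with `signal_strength = 0`).
#' @export
read_dti_study <- function(pssm_dir, fingerprint_path, edges_path) {
  files <- list.files(pssm_dir, pattern = "\\.pssm$", full.names = TRUE)
  if (length(files) == 0L) stop("no .pssm files found in ", pssm_dir)
  profiles <- lapply(files, read_pssm)
  names(profiles) <- vapply(profiles, function(p) p$protein_id, character(1))
  fp_raw <- utils::read.delim(fingerprint_path, header = FALSE,
                              colClasses = "character",
                              col.names = c("drug_id", "hex"))
  if (nrow(fp_raw) > 0L && fp_raw$drug_id[1] == "drug_id") fp_raw <- fp_raw[-1L, ]
  edges <- utils::read.delim(edges_path, header = FALSE,
                             colClasses = "character",
                             col.names = c("target", "drug"))
  structure(
    list(profiles = profiles,
         fingerprints = tibble::as_tibble(fp_raw),
         edges = tibble::as_tibble(edges),
         signal_strength = 0, seed = NA_integer_),
    class = "dti_study"
  )
}
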