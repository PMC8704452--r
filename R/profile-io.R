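#' @keywords internal
"_PACKAGE"

#' Canonical amino-acid column order
#'
#' The 20 standard amino acids in PSI-BLAST header order. All profile matrices
#' in this package carry their 20 substitution-score columns in this order,
#' and readers remap file columns to it by header, never by position.
#'
#' @format Character vector of length 20.
#' @export
AMINO_ACIDS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct a PSSM profile object
#'
#' A `pssm_profile` holds the raw evolutionary profile of one protein: an
#' L x 20 matrix of integer log-odds substitution scores (one row per residue,
#' one column per canonical amino acid) together with the residue sequence.
#'
#' @param protein_id Single string identifying the protein.
#' @param residues Character vector of single-letter residue codes (length L),
#'   or a single string of length-L.
#' @param scores Integer L x 20 matrix of log-odds scores; columns must be in
#'   (or named by) the canonical order [AMINO_ACIDS].
#' @return An object of class `pssm_profile`.
#' @seealso [read_pssm()], [normalize_profile()]
#' @export
pssm_profile <- function(protein_id, residues, scores) {
  stopifnot(is.character(protein_id), length(protein_id) == 1L)
  if (length(residues) == 1L && nchar(residues) > 1L) {
    residues <- strsplit(residues, "")[[1]]
  }
  scores <- as.matrix(scores)
  if (ncol(scores) != 20L) {
    stop("a PSSM profile must have exactly 20 score columns, got ", ncol(scores))
  }
  if (nrow(scores) < 1L) stop("a PSSM profile must have at least one residue row")
  if (nrow(scores) != length(residues)) {
    stop("row count (", nrow(scores), ") does not match residue count (",
         length(residues), ") for protein ", protein_id)
  }
  if (!is.null(colnames(scores))) {
    if (!setequal(colnames(scores), AMINO_ACIDS)) {
      stop("score column names must be the 20 canonical amino acids")
    }
    scores <- scores[, AMINO_ACIDS, drop = FALSE]
  } else {
    colnames(scores) <- AMINO_ACIDS
  }
  storage.mode(scores) <- "integer"
  structure(
    list(protein_id = protein_id, residues = residues, scores = scores),
    class = "pssm_profile"
  )
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat("<pssm_profile> ", x$protein_id, ": L = ", nrow(x$scores),
      ", score range [", min(x$scores), ", ", max(x$scores), "]\n", sep = "")
  invisible(x)
}

#' @export
print.pssm_profile_norm <- function(x, ...) {
  cat("<normalized profile> ", x$protein_id, ": L = ", nrow(x$values), "\n",
      sep = "")
  invisible(x)
}

profile_length <- function(p) nrow(if (inherits(p, "pssm_profile")) p$scores else p$values)

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the text format written by `psiblast -out_ascii_pssm`. Only the
#' first 20-column block (the position-specific log-odds scores) is used; the
#' second block of weighted observed percentages is ignored. Columns are
#' remapped from the file's header order to the canonical order
#' [AMINO_ACIDS], so files with permuted headers are read correctly.
#'
#' Rows whose residue letter is outside the 20 canonical amino acids (X, B,
#' Z, ...) are kept unchanged: dropping them would alter the profile length L
#' and every downstream feature.
#'
#' @param path Path to an ASCII PSSM file.
#' @param protein_id Identifier to attach; defaults to the file name without
#'   extension.
#' @return A [pssm_profile] object.
#' @export
read_pssm <- function(path, protein_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  # header line: first line whose leading tokens are 20+ single AA letters
  header_at <- NA_integer_
  header_order <- NULL
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) >= 20L && all(toks[1:20] %in% AMINO_ACIDS) &&
        !anyDuplicated(toks[1:20])) {
      header_at <- i
      header_order <- toks[1:20]
      break
    }
  }
  if (is.na(header_at)) {
    stop("malformed header: no amino-acid column header found in ", path)
  }

  residues <- character()
  rows <- list()
  expected_pos <- 1L
  for (i in seq((header_at + 1L), length(lines))) {
    if (i > length(lines)) break
    ln <- trimws(lines[i])
    if (ln == "") {
      if (length(rows) > 0L) break else next
    }
    toks <- strsplit(ln, "\\s+")[[1]]
    # data rows start with the 1-based residue position
    if (!grepl("^[0-9]+$", toks[1])) {
      if (length(rows) > 0L) break else next
    }
    pos <- as.integer(toks[1])
    if (pos != expected_pos) {
      stop("parse error at line ", i, ": expected residue position ",
           expected_pos, ", found ", pos)
    }
    if (length(toks) < 22L) {
      stop("parse error at line ", i, ": truncated row (", length(toks) - 2L,
           " of 20 score columns present)")
    }
    res <- toks[2]
    cells <- toks[3:22]
    if (!all(grepl("^-?[0-9]+$", cells))) {
      bad <- which(!grepl("^-?[0-9]+$", cells))[1]
      stop("parse error at line ", i, ": non-integer score '", cells[bad],
           "' in column ", bad)
    }
    residues <- c(residues, res)
    rows[[length(rows) + 1L]] <- as.integer(cells)
    expected_pos <- expected_pos + 1L
  }
  if (length(rows) == 0L) {
    stop("parse error: no score rows found after header in ", path)
  }
  scores <- do.call(rbind, rows)
  colnames(scores) <- header_order
  scores <- scores[, AMINO_ACIDS, drop = FALSE]
  pssm_profile(protein_id, residues, scores)
}

#' Write a profile in PSI-BLAST ASCII PSSM dialect
#'
#' Emits the same text dialect that [read_pssm()] consumes (log-odds block
#' followed by a dummy percentage block), so synthetic profiles round-trip
#' exactly. Intended for fixture generation and for exporting simulated data.
#'
#' @param p A [pssm_profile].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(p, path) {
  stopifnot(inherits(p, "pssm_profile"))
  hdr <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("           ", paste(sprintf("%3s", c(AMINO_ACIDS, AMINO_ACIDS)), collapse = ""))
  )
  body <- vapply(seq_len(nrow(p$scores)), function(i) {
    paste0(sprintf("%5d %s ", i, p$residues[i]),
           paste(sprintf("%3d", p$scores[i, ]), collapse = ""),
           paste(rep("   0", 20L), collapse = ""),
           "  0.00 0.00")
  }, character(1))
  writeLines(c(hdr, body, ""), path)
  invisible(path)
}

#' Sigmoid-normalize a PSSM profile
#'
#' Maps every integer log-odds score E through the logistic function
#' 1 / (1 + exp(-E)), yielding entries strictly inside (0, 1). The map is
#' strictly increasing, so within-column score order is preserved.
#'
#' @param p A [pssm_profile].
#' @return An object of class `pssm_profile_norm` with fields `protein_id`
#'   and `values` (an L x 20 numeric matrix).
#' @export
normalize_profile <- function(p) {
  stopifnot(inherits(p, "pssm_profile"))
  vals <- 1 / (1 + exp(-p$scores))
  structure(
    list(protein_id = p$protein_id, values = vals),
    class = "pssm_profile_norm"
  )
}
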