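#' Parse an FP2 fingerprint hex string into a nibble vector
#'
#' A 1024-bit FP2 path fingerprint serialized as 256 hexadecimal characters
#' is decoded into 256 integers in 0..15, one per nibble, leftmost character
#' first. This is the drug descriptor used throughout the pipeline.
#'
#' @param drug_id Identifier used in error messages and as the vector's
#'   attribute.
#' @param hex String of exactly 256 hexadecimal characters (case-insensitive).
#' @return Named integer vector of length 256 (`fp_001` ... `fp_256`).
#' @export
parse_fp2_hex <- function(drug_id, hex) {
  stopifnot(is.character(hex), length(hex) == 1L)
  if (nchar(hex) != 256L) {
    stop("fingerprint for drug ", drug_id, " has ", nchar(hex),
         " characters; expected 256 hex characters (1024 bits)")
  }
  chars <- strsplit(hex, "")[[1]]
  bad <- which(!grepl("^[0-9a-fA-F]$", chars))
  if (length(bad) > 0L) {
    stop("fingerprint for drug ", drug_id, ": non-hexadecimal character '",
         chars[bad[1]], "' at position ", bad[1])
  }
  v <- strtoi(chars, base = 16L)
  names(v) <- sprintf("fp_%03d", seq_len(256L))
  v
}

#' Re-serialize a nibble vector to canonical lowercase hex
#'
#' Inverse of [parse_fp2_hex()] on canonical lowercase input.
#'
#' @param values Integer vector of length 256 with entries in 0..15.
#' @return A 256-character lowercase hex string.
#' @export
fp2_to_hex <- function(values) {
  stopifnot(length(values) == 256L, all(values %in% 0:15))
  paste(c(0:9, letters[1:6])[values + 1L], collapse = "")
}

#' Read a drug fingerprint table
#'
#' Reads a two-column TSV (`drug_id`, 256-character hex string) and decodes
#' every fingerprint. Duplicate drug identifiers are an error.
#'
#' @param path Path to the TSV file. A header row `drug_id<TAB>hex` is
#'   accepted but optional.
#' @return A tibble with `drug_id` followed by integer columns
#'   `fp_001` ... `fp_256`.
#' @export
read_fingerprint_table <- function(path) {
  if (!file.exists(path)) stop("fingerprint table not found: ", path)
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           col.names = c("drug_id", "hex"))
  if (nrow(raw) > 0L && raw$drug_id[1] == "drug_id") raw <- raw[-1L, , drop = FALSE]
  fingerprint_table(raw$drug_id, raw$hex)
}

#' Build a fingerprint tibble from ids and hex strings
#'
#' @param drug_ids Character vector of unique drug identifiers.
#' @param hex Character vector of 256-character hex strings, same length.
#' @return A tibble with `drug_id` and integer columns `fp_001` ... `fp_256`,
#'   rows in input order.
#' @export
fingerprint_table <- function(drug_ids, hex) {
  stopifnot(length(drug_ids) == length(hex))
  dup <- drug_ids[duplicated(drug_ids)]
  if (length(dup) > 0L) {
    stop("duplicate drug_id in fingerprint table: ",
         paste(unique(dup), collapse = ", "))
  }
  mats <- t(vapply(seq_along(drug_ids),
                   function(i) parse_fp2_hex(drug_ids[i], hex[i]),
                   integer(256L)))
  dplyr::bind_cols(tibble::tibble(drug_id = as.character(drug_ids)),
                   tibble::as_tibble(mats))
}

#' Write a fingerprint tibble back to TSV
#'
#' @param fp Tibble as returned by [fingerprint_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fingerprint_table <- function(fp, path) {
  hex <- vapply(seq_len(nrow(fp)),
                function(i) fp2_to_hex(as.integer(fp[i, -1])),
                character(1))
  utils::write.table(data.frame(fp$drug_id, hex), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
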