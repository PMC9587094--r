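# Shared small helpers.  Coordinate convention, project-wide: residue indices
# stored in tibbles (anchor_idx, dxlt_idx, hit start/end) are 0-based, with
# half-open [start, end) motif spans; printed reports use 1-based positions.

AA20 <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# substring by 0-based half-open span
substr0 <- function(x, start0, end0) {
  if (end0 <= start0) return("")
  substr(x, start0 + 1L, end0)
}

assert_scalar_string <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  invisible(x)
}

# sanitise a protein string for alignment: anything outside the 20-letter
# alphabet (plus X) becomes X
clean_aa <- function(x) {
  gsub("[^ACDEFGHIKLMNPQRSTVWYX]", "X", toupper(x))
}

random_aa_string <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Read protein sequences into a tibble
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] returning the
#' tibble-of-sequences shape used throughout the package.  Works for both
#' unaligned FASTA and aligned FASTA (gaps are kept as `-`).
#'
#' @param path Path to a (aligned) FASTA file.
#' @param column Name of the sequence column in the result, `"sequence"` by
#'   default; the package uses `"aligned"` for alignment rows.
#' @return A tibble with columns `sequence_id` and `column`.
#' @export
read_fasta_tbl <- function(path, column = "sequence") {
  ss <- Biostrings::readAAStringSet(path)
  out <- tibble::tibble(
    sequence_id = sub("\\s.*$", "", names(ss)),
    seq = unname(as.character(ss))
  )
  names(out)[2] <- column
  out
}

#' Write a tibble of protein sequences to FASTA
#'
#' @param df Tibble with a `sequence_id` column and one sequence column.
#' @param path Output file path.
#' @param column Sequence column to write.
#' @return `path`, invisibly.
#' @export
write_fasta_tbl <- function(df, path, column = "sequence") {
  ss <- Biostrings::AAStringSet(setNames(df[[column]], df$sequence_id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
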