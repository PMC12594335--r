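#' @keywords internal
"_PACKAGE"

# Canonical internal alphabet is RNA: everything (hairpins, duplex
# sequences, reads) is upper-cased and T -> U before any comparison, so
# exact-match alignment and folding operate on one alphabet.

RNA_BASES <- c("A", "C", "G", "U")

#' Canonicalize a nucleotide string to the RNA alphabet
#'
#' Upper-cases and converts T to U. Does not validate residues; see
#' [validate_residues()].
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of the same length, RNA alphabet.
#' @keywords internal
canonicalize_rna <- function(x) {
  chartr("t", "U", chartr("T", "U", toupper(x)))
}

#' Validate residues against the RNA alphabet
#'
#' @param x character vector (already canonicalized).
#' @param ids identifiers used in error messages.
#' @return invisibly `x`; errors with the identifier and 1-based position
#'   of the first offending character.
#' @keywords internal
validate_residues <- function(x, ids = seq_along(x)) {
  bad <- regexpr("[^ACGU]", x)
  hit <- which(bad > 0L)
  if (length(hit)) {
    i <- hit[1L]
    stop(sprintf(
      "non-nucleotide character '%s' in sequence '%s' at position %d",
      substr(x[i], bad[i], bad[i]), ids[i], bad[i]
    ), call. = FALSE)
  }
  if (any(!nzchar(x))) {
    stop(sprintf("empty sequence for '%s'", ids[which(!nzchar(x))[1L]]),
         call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement in the RNA alphabet
#' @param x character vector of RNA strings.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp_rna <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGU", "UGCA", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# All occurrences (including overlapping) of `query` in `subject`,
# 1-based start positions. Exact match, forward strand only.
find_all_starts <- function(subject, query) {
  if (nchar(query) > nchar(subject)) return(integer(0))
  m <- Biostrings::matchPattern(query, Biostrings::BString(subject))
  Biostrings::start(m)
}
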