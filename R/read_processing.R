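# Small RNA-seq library loading, adapter discovery ("autotrim") and
# 3' adapter trimming. Libraries are held as collapsed multisets of
# distinct read sequences with copy numbers; qualities are discarded.

#' Read an sRNA-seq library (FASTQ or FASTA, optionally gzipped)
#'
#' Format is auto-detected from the first character (`@` FASTQ, `>`
#' FASTA). Reads are canonicalized to the RNA alphabet and collapsed:
#' identical sequences are stored once with summed copy numbers. Reads
#' containing characters outside A/C/G/U (e.g. N calls) are dropped
#' with a message; exact-match alignment could never place them.
#'
#' @param path path to the library file.
#' @param library_id identifier for the library; defaults to the file
#'   stem (extension and `.gz` removed).
#' @return a `read_library` object: list with `library_id`, `reads`
#'   (data.frame of `seq`, `copies`), `total_reads`, `trimmed`,
#'   `adapter`.
#' @export
read_sequencing_file <- function(path, library_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  first <- rawToChar(readBin(con, "raw", 1L))
  close(con)
  if (is.null(library_id)) {
    library_id <- sub("\\.(fastq|fq|fasta|fa)$", "",
                      sub("\\.gz$", "", basename(path)))
  }
  if (length(first) == 0L || !nzchar(first)) {   # empty library
    return(new_read_library(library_id, character(0)))
  }
  fmt <- if (identical(first, "@")) "fastq" else if (identical(first, ">"))
    "fasta" else stop("cannot detect FASTA/FASTQ format of '", path,
                      "' (first character '", first, "')", call. = FALSE)
  if (fmt == "fastq") {
    lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
    lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]  # trailing blanks
    if (length(lines) %% 4L != 0L) {
      stop("truncated FASTQ record at record ", length(lines) %/% 4L + 1L,
           " in '", path, "'", call. = FALSE)
    }
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = fmt),
    error = function(e) stop("truncated or malformed ", toupper(fmt),
                             " in '", path, "': ", conditionMessage(e),
                             call. = FALSE)
  )
  seqs <- canonicalize_rna(as.character(set))
  keep <- !grepl("[^ACGU]", seqs)
  if (any(!keep)) {
    message(sum(!keep), " read(s) with non-ACGU characters dropped from '",
            basename(path), "'")
    seqs <- seqs[keep]
  }
  new_read_library(library_id, seqs)
}

#' Build a read library from sequences in memory
#'
#' Constructor for programmatic use (the file reader and the fixture
#' generator both go through it). Identical sequences are collapsed
#' with summed copies.
#'
#' @param library_id library identifier.
#' @param seqs read sequences (RNA alphabet); repeated values allowed.
#' @param copies optional copy numbers parallel to `seqs` (default:
#'   each element counts once).
#' @param trimmed,adapter trimming state metadata.
#' @return a `read_library` object.
#' @export
new_read_library <- function(library_id, seqs, copies = NULL,
                             trimmed = FALSE, adapter = NULL) {
  if (is.null(copies)) {
    if (length(seqs)) {
      tab <- table(seqs)
      reads <- data.frame(seq = names(tab),
                          copies = as.integer(tab),
                          stringsAsFactors = FALSE)
    } else {
      reads <- data.frame(seq = character(0), copies = integer(0))
    }
  } else {
    agg <- tapply(copies, seqs, sum)
    reads <- data.frame(seq = names(agg), copies = as.integer(agg),
                        stringsAsFactors = FALSE)
  }
  rownames(reads) <- NULL
  structure(list(library_id = library_id, reads = reads,
                 total_reads = sum(reads$copies),
                 trimmed = trimmed, adapter = adapter),
            class = "read_library")
}

#' @export
print.read_library <- function(x, ...) {
  cat("sRNA-seq library '", x$library_id, "': ", nrow(x$reads),
      " distinct sequences, ", x$total_reads, " reads",
      if (x$trimmed) paste0(" (trimmed, adapter ", x$adapter, ")"), "\n",
      sep = "")
  invisible(x)
}

#' Infer the 3' adapter of an untrimmed library from a trim key
#'
#' The trim key is the sequence of a miRNA expected to be highly
#' abundant (defaults: ath-miR166a for plants, hsa-let-7a for animals).
#' Among reads containing the key as an exact substring, the suffix
#' immediately following the key is collected; the most frequent first
#' `probe_len` nucleotides of those suffixes (copy-weighted; ties broken
#' lexicographically) are returned as the adapter. Reads where the key
#' reaches the 3' end carry no adapter evidence and are excluded.
#'
#' @param library a `read_library`.
#' @param trim_key RNA string, length >= 15.
#' @param probe_len adapter prefix length to report (default 12;
#'   shortened when no suffix is that long).
#' @param min_key_hits minimum copy-weighted number of key-containing
#'   reads required (default 100).
#' @return the inferred adapter prefix (RNA string).
#' @export
infer_adapter <- function(library, trim_key, probe_len = 12L,
                          min_key_hits = 100L) {
  trim_key <- canonicalize_rna(trim_key)
  stopifnot(nchar(trim_key) >= 15L)
  reads <- library$reads
  pos <- regexpr(trim_key, reads$seq, fixed = TRUE)
  has <- pos > 0L
  suffix <- substring(reads$seq[has], pos[has] + nchar(trim_key))
  copies <- reads$copies[has]
  keep <- nzchar(suffix)
  suffix <- suffix[keep]; copies <- copies[keep]
  if (sum(copies) < min_key_hits) {
    stop("trim key not found; supply adapter or pre-trimmed reads ",
         "(", sum(copies), " key-bearing reads < ", min_key_hits, ")",
         call. = FALSE)
  }
  k <- min(probe_len, max(nchar(suffix)))
  probe <- substr(suffix, 1L, k)
  votes <- tapply(copies, probe, sum)
  winners <- names(votes)[votes == max(votes)]
  sort(winners)[1L]
}

#' Trim a 3' adapter from every read of a library
#'
#' The leftmost exact occurrence of the adapter's first `min_overlap`
#' nucleotides marks the insert end; at the read's extreme 3' end,
#' shorter matches down to `min_tail` nucleotides of adapter prefix are
#' also removed. Reads without an adapter occurrence are kept
#' unmodified. After trimming, reads outside `[min_len, max_len]` are
#' dropped and identical sequences re-collapsed.
#'
#' @param library a `read_library`.
#' @param adapter RNA string, length >= 8.
#' @param min_overlap internal-match seed length (default 8).
#' @param min_tail shortest adapter prefix removed at the 3' end
#'   (default 4).
#' @param min_len,max_len retained read-length bounds (defaults 15, 34).
#' @return a trimmed `read_library` (`trimmed = TRUE`).
#' @export
trim_adapter <- function(library, adapter, min_overlap = 8L, min_tail = 4L,
                         min_len = 15L, max_len = 34L) {
  adapter <- canonicalize_rna(adapter)
  stopifnot(nchar(adapter) >= min_overlap)
  seed <- substr(adapter, 1L, min_overlap)
  seqs <- library$reads$seq
  pos <- regexpr(seed, seqs, fixed = TRUE)
  out <- ifelse(pos > 0L, substr(seqs, 1L, pos - 1L), seqs)
  # 3'-terminal partial adapter: longest prefix of `adapter` shorter
  # than min_overlap (down to min_tail) that the read ends with
  for (ov in seq(min_overlap - 1L, min_tail)) {
    tailseq <- substring(out, nchar(out) - ov + 1L)
    hit <- pos <= 0L & nchar(out) >= ov & tailseq == substr(adapter, 1L, ov)
    out[hit] <- substr(out[hit], 1L, nchar(out[hit]) - ov)
    pos[hit] <- 1L  # only the longest terminal match is removed
  }
  len <- nchar(out)
  keep <- len >= min_len & len <= max_len
  new_read_library(library$library_id, out[keep],
                   copies = library$reads$copies[keep],
                   trimmed = TRUE, adapter = adapter)
}

#' Default trim keys by mode
#' @param mode `"plant"` or `"animal"`.
#' @return the default trim-key sequence (ath-miR166a for plants,
#'   hsa-let-7a for animals).
#' @export
default_trim_key <- function(mode = c("plant", "animal")) {
  switch(match.arg(mode),
         plant  = "UCGGACCAGGCUUCAUUCCCC",
         animal = "UGAGGUAGUAGGUUGUAUAGUU")
}
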