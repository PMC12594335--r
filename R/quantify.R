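# Expression evaluation: perfect forward-strand alignment of reads to
# the hairpin, variance-window counting of the duplex stacks, and
# per-library precision. Raw copy numbers are used throughout; the
# criteria concern reproducibility within a library, not comparative
# abundance between libraries.

#' Align a read library to a hairpin by exact matching
#'
#' Every exact, full-length, forward-strand occurrence of a read on the
#' hairpin becomes a placement carrying the read's copy number; a read
#' occurring at k positions contributes k placements (all-alignments
#' semantics). The reverse complement is never searched. This is
#' equivalent to a `-v0 -a --norc --no-unal` short-read alignment.
#'
#' @param hairpin hairpin RNA string.
#' @param library a `read_library`.
#' @param locus_id,library_id identifiers carried into the result.
#' @return a `hairpin_alignment`: list with `locus_id`, `library_id`
#'   and `placements` (data.frame of `start`, `length`, `copies`,
#'   `seq`; 1-based starts).
#' @export
align_library <- function(hairpin, library, locus_id = NA_character_,
                          library_id = library$library_id) {
  stopifnot(nchar(hairpin) >= 1L)
  reads <- library$reads
  hits <- lapply(seq_len(nrow(reads)), function(i) {
    st <- find_all_starts(hairpin, reads$seq[i])
    if (!length(st)) return(NULL)
    data.frame(start = st, length = nchar(reads$seq[i]),
               copies = reads$copies[i], seq = reads$seq[i],
               stringsAsFactors = FALSE)
  })
  placements <- do.call(rbind, hits)
  if (is.null(placements)) {
    placements <- data.frame(start = integer(0), length = integer(0),
                             copies = integer(0), seq = character(0))
  }
  placements <- placements[order(placements$start, placements$length,
                                 placements$seq), , drop = FALSE]
  rownames(placements) <- NULL
  structure(list(locus_id = locus_id, library_id = library_id,
                 placements = placements),
            class = "hairpin_alignment")
}

# TRUE for placements whose start and end both lie within +/- variance
# of the interval boundaries (the one-nucleotide positional variance
# window: both conditions must hold).
in_window <- function(placements, iv, variance = 1L) {
  ends <- placements$start + placements$length - 1L
  abs(placements$start - iv$start) <= variance & abs(ends - iv$end) <= variance
}

#' Count read copies within the positional-variance window of an interval
#'
#' A placement is counted when its start lies in
#' `[iv$start - variance, iv$start + variance]` and its end in
#' `[iv$end - variance, iv$end + variance]`; both must hold.
#'
#' @param alignment a `hairpin_alignment`.
#' @param iv strand interval (1-based closed).
#' @param variance window half-width in nt (default 1).
#' @return total copies counted (integer).
#' @export
count_window <- function(alignment, iv, variance = 1L) {
  pl <- alignment$placements
  if (!nrow(pl)) return(0L)
  sum(pl$copies[in_window(pl, iv, variance)])
}

#' Per-library expression metrics for one locus
#'
#' `precision = (mature_count + star_count) / total_on_hairpin`; a
#' placement falling in both windows (impossible for disjoint arms,
#' guarded anyway) is counted once, toward the mature.
#'
#' @param alignment a `hairpin_alignment`.
#' @param mature_iv,star_iv duplex strand intervals.
#' @param variance window half-width in nt (default 1).
#' @return one-row data.frame: `locus_id`, `library_id`,
#'   `mature_count`, `star_count`, `total_on_hairpin`, `precision`
#'   (`NA` when no reads align to the hairpin).
#' @export
library_metrics <- function(alignment, mature_iv, star_iv, variance = 1L) {
  pl <- alignment$placements
  if (nrow(pl)) {
    in_m <- in_window(pl, mature_iv, variance)
    in_s <- in_window(pl, star_iv, variance) & !in_m
    mature_count <- sum(pl$copies[in_m])
    star_count <- sum(pl$copies[in_s])
    total <- sum(pl$copies)
  } else {
    mature_count <- star_count <- total <- 0L
  }
  data.frame(locus_id = alignment$locus_id,
             library_id = alignment$library_id,
             mature_count = mature_count, star_count = star_count,
             total_on_hairpin = total,
             precision = if (total > 0L)
               (mature_count + star_count) / total else NA_real_,
             stringsAsFactors = FALSE)
}

#' Expression verdict over all libraries of a locus
#'
#' A library passes when, within that single library, the combined
#' mature+star count reaches the read floor, both strands are observed
#' at least once, and precision reaches the threshold. The locus
#' passes expression if at least one library passes; only passing
#' libraries are surfaced in the main results (all libraries go to the
#' reads file). When no library passes, flags describe the deficits:
#' the read floor unmet in every library, no library with both strands
#' observed, or (floor and both strands met somewhere) precision below
#' threshold everywhere.
#'
#' @param metrics data.frame of [library_metrics()] rows, one per
#'   library.
#' @param read_floor minimum combined mature+star copies (default 10).
#' @param precision_min precision threshold (default 0.75; compared
#'   with `>=`, so exactly 75% passes).
#' @return `list(passing, flags)`: `passing` the subset of `metrics`
#'   rows that pass; `flags` a character vector of flag codes (empty
#'   when the locus passes expression).
#' @export
expression_verdict <- function(metrics, read_floor = 10L,
                               precision_min = 0.75) {
  if (!nrow(metrics)) stop("no library metrics supplied", call. = FALSE)
  duplex <- metrics$mature_count + metrics$star_count
  floor_ok <- duplex >= read_floor
  both_ok <- metrics$mature_count >= 1L & metrics$star_count >= 1L
  prec_ok <- !is.na(metrics$precision) & metrics$precision >= precision_min
  pass <- floor_ok & both_ok & prec_ok
  if (any(pass)) {
    return(list(passing = metrics[pass, , drop = FALSE], flags = character(0)))
  }
  flags <- character(0)
  if (!any(floor_ok)) flags <- c(flags, FLAG_READ_FLOOR)
  if (!any(both_ok)) flags <- c(flags, FLAG_NO_READS)
  if (any(floor_ok & both_ok)) flags <- c(flags, FLAG_PRECISION)
  list(passing = metrics[0, , drop = FALSE], flags = flags)
}
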