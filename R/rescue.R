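# Rescue of failed loci: search the aligned reads for the most
# abundant 20-24 nt sequence on the hairpin and re-evaluate it as an
# alternative mature miRNA (star re-predicted from structure).

#' Most abundant 20-24 nt aligned sequence on a hairpin
#'
#' Copies are aggregated across all libraries per distinct
#' (start, length) placement; the hairpin substring of the most
#' abundant one is returned. Ties break to the smaller start, then to
#' the longer length.
#'
#' @param hairpin hairpin RNA string.
#' @param alignments list of `hairpin_alignment` objects (all
#'   libraries of the locus).
#' @param len_min,len_max candidate length bounds (defaults 20, 24).
#' @return `list(seq, iv, copies)` or `NULL` when no placement in the
#'   length range exists.
#' @export
find_alternative <- function(hairpin, alignments, len_min = 20L,
                             len_max = 24L) {
  pl <- do.call(rbind, lapply(alignments, `[[`, "placements"))
  if (is.null(pl) || !nrow(pl)) return(NULL)
  pl <- pl[pl$length >= len_min & pl$length <= len_max, , drop = FALSE]
  if (!nrow(pl)) return(NULL)
  agg <- stats::aggregate(copies ~ start + length, data = pl, FUN = sum)
  agg <- agg[order(-agg$copies, agg$start, -agg$length), , drop = FALSE]
  top <- agg[1L, ]
  iv <- interval(top$start, top$start + top$length - 1L)
  list(seq = substr(hairpin, iv$start, iv$end), iv = iv,
       copies = top$copies)
}

# Evaluate the alternative candidate of a failed locus; returns the
# full locus_result (any verdict) or NULL when no candidate exists or
# the candidate cannot be re-located uniquely.
evaluate_alternative <- function(locus, libraries, config,
                                 alignments = NULL) {
  if (is.null(alignments)) {
    alignments <- lapply(libraries, function(lib)
      align_library(locus$hairpin$seq, lib, locus_id = locus$locus_id))
  }
  alt <- find_alternative(locus$hairpin$seq, alignments)
  if (is.null(alt)) return(NULL)
  alt_locus <- structure(list(
    locus_id = locus$locus_id,
    hairpin = locus$hairpin,
    mature = list(id = paste0(locus$mature$id, ".alt"), seq = alt$seq),
    star = NULL, star_user_supplied = FALSE
  ), class = "locus_input")
  res <- evaluate_locus(alt_locus, libraries, config)
  res$alternative_for <- locus$locus_id
  res
}

#' Re-evaluate a failed locus with an alternative mature miRNA
#'
#' Builds a new locus input whose mature is the most abundant aligned
#' 20-24 nt sequence (star re-predicted from the fold) and runs the
#' full evaluation. The primary result is never altered; the
#' alternative is returned only when it passes, for reporting in a
#' separate alternatives table. Rescued loci warrant manual scrutiny
#' before submission to a registry.
#'
#' @param failed the failed `locus_result` of the primary evaluation.
#' @param locus the original `locus_input`.
#' @param libraries list of `read_library` objects.
#' @param config a [mode_config()].
#' @return a passing alternative `locus_result`, or `NULL` when no
#'   candidate exists or the alternative also fails.
#' @export
rescue_locus <- function(failed, locus, libraries,
                         config = mode_config("plant")) {
  stopifnot(identical(failed$verdict, "fail"))
  res <- evaluate_alternative(locus, libraries, config,
                              alignments = failed$alignments)
  if (is.null(res) || res$verdict != "pass") return(NULL)
  res
}
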