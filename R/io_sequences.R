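# Sequence input: FASTA reading, identifier conventions, locus assembly.
#
# Hairpin and mature identifiers follow the common registry convention:
# the hairpin is named like "ath-MIR399a" and the duplex sequences like
# "ath-miR399a" / "ath-miR399a*" (or "-5p"/"-3p"/"-mature" suffixes).
# Matching is case-insensitive and strips one trailing decoration.

#' Read a FASTA file of sequence records
#'
#' Residues are canonicalized to the RNA alphabet (upper case, T to U)
#' and validated; the identifier is the first whitespace-delimited token
#' of the header. Plain or gzipped files are accepted.
#'
#' @param path path to a FASTA file.
#' @param origin role tag, one of `"hairpin"`, `"mature"`, `"star"`,
#'   `"read"`; stored as an attribute and used in error messages.
#' @return a data.frame with columns `id` and `seq`, rows in file order,
#'   with attribute `origin`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">ath-MIR399a", "acgt"), fa)
#' read_fasta(fa, "hairpin")$seq  # "ACGU"
#' @export
read_fasta <- function(path, origin = c("hairpin", "mature", "star", "read")) {
  origin <- match.arg(origin)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("no FASTA records in '", path, "'", call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate identifier in '", path, "': ", dup[1L], call. = FALSE)
  }
  seqs <- canonicalize_rna(as.character(set))
  validate_residues(seqs, ids)
  out <- data.frame(id = ids, seq = unname(seqs), stringsAsFactors = FALSE)
  attr(out, "origin") <- origin
  out
}

# Strip one trailing arm/star decoration from a duplex-sequence
# identifier. Returns the base id (lower-cased for comparison) and the
# decoration class: "star", "5p", "3p", "mature" or "none".
strip_decoration <- function(id) {
  low <- tolower(id)
  if (grepl("\\*$", low)) {
    return(list(base = sub("\\*$", "", low), deco = "star"))
  }
  if (grepl("[-._]?star$", low)) {
    return(list(base = sub("[-._]?star$", "", low), deco = "star"))
  }
  if (grepl("[-._]?5p$", low)) {
    return(list(base = sub("[-._]?5p$", "", low), deco = "5p"))
  }
  if (grepl("[-._]?3p$", low)) {
    return(list(base = sub("[-._]?3p$", "", low), deco = "3p"))
  }
  if (grepl("[-._]?mature$", low)) {
    return(list(base = sub("[-._]?mature$", "", low), deco = "mature"))
  }
  list(base = low, deco = "none")
}

#' Pair hairpins with mature (and star) records into locus inputs
#'
#' Each hairpin must match exactly one mature record whose identifier,
#' after stripping a trailing decoration (`-5p`, `-3p`, `.star`, `*`,
#' `-mature`; case-insensitive, so `MIR`/`miR` are equivalent), equals
#' the hairpin identifier. A second matching record decorated as star
#' (`*`/`.star`) or carrying the opposite arm suffix is attached as the
#' user-supplied miRNA*; when both `-5p` and `-3p` are present without a
#' star decoration, the record listed first in the mature file is taken
#' as mature. Mature records matching no hairpin are dropped with a
#' warning. Loci whose mature sequence sits at the very first or last
#' hairpin position are rejected: the duplex overhang is undefined at
#' the precursor boundary.
#'
#' @param hairpins,matures data.frames from [read_fasta()].
#' @return a list of `locus_input` objects, one per hairpin, each with
#'   fields `locus_id`, `hairpin`, `mature`, `star` (or `NULL`) and
#'   `star_user_supplied`.
#' @export
match_loci <- function(hairpins, matures) {
  stopifnot(nrow(hairpins) > 0L, nrow(matures) > 0L)
  info <- lapply(matures$id, strip_decoration)
  base <- vapply(info, `[[`, "", "base")
  deco <- vapply(info, `[[`, "", "deco")
  hp_base <- tolower(hairpins$id)

  orphans <- setdiff(base, hp_base)
  if (length(orphans)) {
    drop <- base %in% orphans
    warning("ignoring mature records matching no hairpin: ",
            paste(matures$id[drop], collapse = ", "), call. = FALSE)
  }

  loci <- vector("list", nrow(hairpins))
  boundary <- character(0)
  for (i in seq_len(nrow(hairpins))) {
    hit <- which(base == hp_base[i])
    if (length(hit) == 0L) {
      stop("no mature record matches hairpin '", hairpins$id[i], "'",
           call. = FALSE)
    }
    if (length(hit) > 2L) {
      stop(length(hit), " mature records map to hairpin '", hairpins$id[i],
           "'; at most a mature and a star are allowed", call. = FALSE)
    }
    if (length(hit) == 1L) {
      m_idx <- hit; s_idx <- NA_integer_
    } else {
      d <- deco[hit]
      if (sum(d == "star") == 1L) {
        s_idx <- hit[d == "star"]; m_idx <- hit[d != "star"]
      } else if (all(sort(d) == c("3p", "5p"))) {
        m_idx <- hit[1L]; s_idx <- hit[2L]  # first listed wins
      } else {
        stop("cannot tell mature from star for hairpin '", hairpins$id[i],
             "': records ", paste(matures$id[hit], collapse = ", "),
             call. = FALSE)
      }
    }
    loc <- structure(list(
      locus_id = hairpins$id[i],
      hairpin = list(id = hairpins$id[i], seq = hairpins$seq[i]),
      mature = list(id = matures$id[m_idx], seq = matures$seq[m_idx]),
      star = if (!is.na(s_idx)) list(id = matures$id[s_idx],
                                     seq = matures$seq[s_idx]),
      star_user_supplied = !is.na(s_idx)
    ), class = "locus_input")

    st <- find_all_starts(loc$hairpin$seq, loc$mature$seq)
    if (length(st) == 1L &&
        (st == 1L || st + nchar(loc$mature$seq) - 1L == nchar(loc$hairpin$seq))) {
      boundary <- c(boundary, loc$locus_id)
    }
    loci[[i]] <- loc
  }
  if (length(boundary)) {
    stop("mature miRNA starts or ends at the precursor boundary for: ",
         paste(boundary, collapse = ", "),
         "; extend the hairpin past the processing sites", call. = FALSE)
  }
  loci
}

#' Write sequence records to a FASTA file
#' @param records data.frame with `id` and `seq` columns.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_fasta <- function(records, path) {
  writeLines(paste0(">", records$id, "\n", records$seq), path)
  invisible(path)
}
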