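# Synthetic fixtures: hairpins with planted, post-fold-verified duplex
# geometry, and read libraries with planted expression. Every
# criterion, flag and the rescue path can be exercised without real
# data. Loops and flanks are drawn from {A, C} (which cannot pair with
# each other, including wobble), making the designed stem the MFE
# structure in almost every draw; folding then verifies the realized
# geometry and the generator redraws on deviation, so the spec is
# ground truth only after verification.

#' Specification of a synthetic MIRNA fixture
#'
#' @param mature_len mature strand length in nt (default 21).
#' @param loop_len terminal loop length (default 8; drawn from A/C so
#'   it cannot pair).
#' @param planted_mismatches mature positions (keep within
#'   `4..mature_len-4`) whose star partner is de-complemented; each
#'   isolated position adds one duplex mismatch.
#' @param planted_bulge `list(side, pos, size)`: an asymmetric bulge of
#'   `size` unpaired nt on `"star"` (insertion) or `"mature"` (star
#'   deletion) side, planted after mature position `pos`.
#' @param overhang_offset shift of the annotated star interval; 0 gives
#'   the canonical 2-nt 3' overhangs, +1 yields 3-nt overhangs.
#' @param flank5_len,flank3_len flank lengths (defaults 10; `flank3_len`
#'   must be at least `2 + overhang_offset`).
#' @param arm `"5p"` (mature before the loop) or `"3p"` (mirror image).
#' @param mature_copies,star_copies,background_copies per-library read
#'   copies; background reads start outside both variance windows.
#' @param variant_profile data.frame with columns `ds`, `de`, `weight`:
#'   start/end offsets of read 5'/3' ends relative to the annotated
#'   strand and their relative frequency (default: all reads exact).
#' @param n_libraries number of libraries (default 1).
#' @param seed RNG seed for the generator (default 1).
#' @param max_tries redraw budget for post-fold verification
#'   (default 40).
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(mature_len = 21L, loop_len = 8L,
                         planted_mismatches = integer(0),
                         planted_bulge = NULL, overhang_offset = 0L,
                         flank5_len = 10L, flank3_len = 10L, arm = "5p",
                         mature_copies = 100L, star_copies = 20L,
                         background_copies = 0L,
                         variant_profile = data.frame(ds = 0L, de = 0L,
                                                      weight = 1),
                         n_libraries = 1L, seed = 1L, max_tries = 40L) {
  stopifnot(arm %in% c("5p", "3p"),
            flank3_len >= 2L + max(0L, overhang_offset),
            loop_len >= 3L)
  structure(as.list(environment()), class = "fixture_spec")
}

# substitution that can neither pair nor wobble with the mature base
NONPAIR <- c(A = "C", C = "A", G = "A", U = "C")

#' Construct a hairpin with planted, verified duplex geometry
#'
#' Builds flank + mature + loop + modified-reverse-complement(mature) +
#' flank (or the 3'-arm mirror), folds it, and verifies that the
#' realized geometry on the annotated intervals matches the plant:
#' overhangs `2 + overhang_offset` on both strands, `n_mismatch` equal
#' to planted mismatches plus bulge size, `max_asym_bulge` equal to the
#' planted bulge. Deviating draws are rejected and redrawn (bounded by
#' `max_tries`).
#'
#' @param spec a [fixture_spec()].
#' @return a `fixture_truth` list: `hairpin`, `mature_seq`,
#'   `mature_iv`, `star_seq`, `star_iv`, `fold`, `geometry`, `spec`.
#' @export
make_hairpin <- function(spec) {
  set.seed(spec$seed)
  L <- spec$mature_len
  exp_bulge <- if (is.null(spec$planted_bulge)) 0L else
    as.integer(spec$planted_bulge$size)
  exp_mis <- length(spec$planted_mismatches) + exp_bulge

  for (try in seq_len(spec$max_tries)) {
    mature <- paste(sample(RNA_BASES, L, replace = TRUE,
                           prob = c(.2, .3, .3, .2)), collapse = "")
    mb <- strsplit(mature, "")[[1L]]
    sc <- rev(chartr("ACGU", "UGCA", mb))          # sc[j] pairs mature[L-j+1]
    for (p in spec$planted_mismatches) {
      sc[L - p + 1L] <- NONPAIR[[mb[p]]]
    }
    if (!is.null(spec$planted_bulge)) {
      b <- spec$planted_bulge
      j <- L - b$pos                                # insert between j and j+1
      if (b$side == "star") {
        ins <- rep(c("C", "A"), length.out = b$size)
        sc <- append(sc, ins, after = j)
      } else {
        sc <- sc[-seq(j - b$size + 1L, j)]          # mature-side bulge
      }
    }
    star_arm <- paste(sc, collapse = "")
    Ls <- nchar(star_arm)
    loop <- paste(sample(c("A", "C"), spec$loop_len, TRUE, prob = c(.6, .4)),
                  collapse = "")
    f5 <- paste(sample(c("A", "C"), spec$flank5_len, TRUE, prob = c(.6, .4)),
                collapse = "")
    f3 <- paste(sample(c("A", "C"), spec$flank3_len, TRUE, prob = c(.6, .4)),
                collapse = "")

    o <- spec$overhang_offset
    if (spec$arm == "5p") {
      hairpin <- paste0(f5, mature, loop, star_arm, f3)
      m_s <- spec$flank5_len + 1L
      t <- spec$flank5_len + L + spec$loop_len + 1L  # star-arm start
    } else {
      hairpin <- paste0(f5, star_arm, loop, mature, f3)
      m_s <- spec$flank5_len + Ls + spec$loop_len + 1L
      t <- spec$flank5_len + 1L
    }
    mature_iv <- interval(m_s, m_s + L - 1L)
    star_iv <- interval(t + 2L + o, t + Ls + 1L + o)
    star_seq <- substr(hairpin, star_iv$start, star_iv$end)

    # uniqueness of both annotated sequences on the hairpin
    if (length(find_all_starts(hairpin, mature)) != 1L) next
    if (length(find_all_starts(hairpin, star_seq)) != 1L) next

    fr <- fold(hairpin)
    geom <- evaluate_duplex(fr, mature_iv, star_iv)
    if (!geom$valid) next
    if (geom$overhang_mature_3p != 2L + o ||
        geom$overhang_star_3p != 2L + o) next
    if (geom$n_mismatch != exp_mis || geom$max_asym_bulge != exp_bulge) next

    return(structure(list(hairpin = hairpin, mature_seq = mature,
                          mature_iv = mature_iv, star_seq = star_seq,
                          star_iv = star_iv, fold = fr, geometry = geom,
                          spec = spec),
                     class = "fixture_truth"))
  }
  stop("could not realize fixture geometry within ", spec$max_tries,
       " draws (seed ", spec$seed, ")", call. = FALSE)
}

#' Build a synthetic read library around a fixture truth
#'
#' Mature and star reads are taken from the variant profile around the
#' annotated intervals (copies apportioned deterministically by
#' weight); background reads are hairpin substrings starting outside
#' both variance windows. The library is fully determined by the
#' fixture spec. Optionally every read gets a 3' adapter appended and
#' trim-key-bearing reads are spiked in, for adapter-inference tests.
#'
#' @param truth a `fixture_truth` from [make_hairpin()].
#' @param lib_index library number (names the library `lib<i>`).
#' @param adapter optional adapter sequence appended to every read.
#' @param trim_key,key_copies when `adapter` is set, `key_copies`
#'   reads of `trim_key + adapter` are added as adapter evidence.
#' @return a `read_library`.
#' @export
make_library <- function(truth, lib_index = 1L, adapter = NULL,
                         trim_key = default_trim_key("plant"),
                         key_copies = 0L) {
  spec <- truth$spec
  hp <- truth$hairpin
  seqs <- character(0); copies <- integer(0)
  planted <- function(iv, n_copies) {
    vp <- spec$variant_profile
    alloc <- floor(vp$weight / sum(vp$weight) * n_copies)
    alloc[1L] <- alloc[1L] + n_copies - sum(alloc)
    for (r in seq_len(nrow(vp))) {
      if (alloc[r] <= 0L) next
      s <- substr(hp, iv$start + vp$ds[r], iv$end + vp$de[r])
      seqs <<- c(seqs, s); copies <<- c(copies, alloc[r])
    }
  }
  planted(truth$mature_iv, spec$mature_copies)
  planted(truth$star_iv, spec$star_copies)

  if (spec$background_copies > 0L) {
    len <- spec$mature_len
    cand <- setdiff(seq_len(nchar(hp) - len + 1L),
                    c(truth$mature_iv$start + (-1:1),
                      truth$star_iv$start + (-1:1)))
    starts <- cand[round(seq(1L, length(cand),
                             length.out = min(4L, length(cand))))]
    per <- floor(spec$background_copies / length(starts))
    extra <- spec$background_copies - per * length(starts)
    for (k in seq_along(starts)) {
      nc <- per + (k <= extra)
      if (nc <= 0L) next
      seqs <- c(seqs, substr(hp, starts[k], starts[k] + len - 1L))
      copies <- c(copies, nc)
    }
  }

  if (!is.null(adapter)) {
    seqs <- paste0(seqs, adapter)
    if (key_copies > 0L) {
      seqs <- c(seqs, paste0(canonicalize_rna(trim_key), adapter))
      copies <- c(copies, key_copies)
    }
  }
  new_read_library(paste0("lib", lib_index), seqs, copies = copies)
}

#' Write a read library as an (uncollapsed) FASTQ file
#'
#' One record per copy, constant dummy qualities; byte-identical output
#' for identical libraries.
#'
#' @param library a `read_library`.
#' @param path output path (`.fastq`, optionally `.gz`).
#' @return invisibly `path`.
#' @export
write_library_fastq <- function(library, path) {
  seqs <- rep(library$reads$seq, library$reads$copies)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@r", seq_along(seqs), "\n", seqs, "\n+\n",
                    vapply(nchar(seqs), function(n)
                      strrep("I", n), character(1L))), con)
  invisible(path)
}

#' Assemble a locus input programmatically
#'
#' Constructor used by the fixture generator and tests; [match_loci()]
#' builds the same objects from FASTA input.
#'
#' @param locus_id locus identifier.
#' @param hairpin_seq,mature_seq,star_seq RNA strings (star optional).
#' @return a `locus_input`.
#' @export
locus_input <- function(locus_id, hairpin_seq, mature_seq,
                        star_seq = NULL) {
  structure(list(
    locus_id = locus_id,
    hairpin = list(id = locus_id, seq = canonicalize_rna(hairpin_seq)),
    mature = list(id = paste0(locus_id, "-mature"),
                  seq = canonicalize_rna(mature_seq)),
    star = if (!is.null(star_seq))
      list(id = paste0(locus_id, "*"), seq = canonicalize_rna(star_seq)),
    star_user_supplied = !is.null(star_seq)
  ), class = "locus_input")
}

#' Locus input of a fixture truth (annotated star attached)
#' @param truth a `fixture_truth`.
#' @param with_star attach the annotated star as user-supplied
#'   (default TRUE).
#' @param id locus identifier.
#' @return a `locus_input`.
#' @export
fixture_locus <- function(truth, with_star = TRUE, id = "syn-MIR1") {
  locus_input(id, truth$hairpin, truth$mature_seq,
              star_seq = if (with_star) truth$star_seq)
}
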