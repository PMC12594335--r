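# Secondary structure: MFE folding of the hairpin via RNAfold
# (ViennaRNA), dot-bracket parsing, indexing of the duplex strands, star
# prediction and duplex geometry metrics.
#
# All intervals are 1-based closed `list(start, end)` on the hairpin;
# this matches the coordinate convention reports use.

#' Fold RNA sequences to their MFE structure with RNAfold
#'
#' Shells out to ViennaRNA's `RNAfold` (default parameters, 37 C),
#' which must be on the PATH. Deterministic for a given engine version.
#'
#' @param seqs character vector of RNA sequences.
#' @return a list of `fold_result` objects, each with `seq`,
#'   `dotbracket`, `mfe_kcal` and `partner` (integer vector, `NA` where
#'   unpaired, involutive where paired).
#' @export
fold_many <- function(seqs) {
  stopifnot(length(seqs) >= 1L, all(nchar(seqs) >= 1L))
  fa <- paste0(">s", seq_along(seqs), "\n", seqs, collapse = "\n")
  out <- suppressWarnings(
    system2("RNAfold", c("--noPS"), input = fa, stdout = TRUE, stderr = FALSE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    stop("RNAfold failed (exit ", status, "); is ViennaRNA installed?",
         call. = FALSE)
  }
  hdr <- grep("^>", out)
  if (length(hdr) != length(seqs)) {
    stop("unexpected RNAfold output (", length(hdr), " records for ",
         length(seqs), " sequences)", call. = FALSE)
  }
  lapply(seq_along(seqs), function(i) {
    struct_line <- out[hdr[i] + 2L]
    m <- regmatches(struct_line,
                    regexec("^([().]+)\\s+\\(\\s*(-?[0-9.]+)\\)", struct_line))[[1L]]
    if (length(m) != 3L) {
      stop("cannot parse RNAfold structure line: ", struct_line, call. = FALSE)
    }
    db <- m[2L]
    structure(list(seq = seqs[i], dotbracket = db,
                   mfe_kcal = as.numeric(m[3L]),
                   partner = partner_table(db)),
              class = "fold_result")
  })
}

#' @rdname fold_many
#' @param seq a single RNA sequence.
#' @export
fold <- function(seq) fold_many(seq)[[1L]]

#' Partner table of a dot-bracket string
#'
#' @param dotbracket balanced dot-bracket string (nested pairs only).
#' @return integer vector `p` with `p[i] = j` when i pairs j (so
#'   `p[p[i]] = i`) and `NA` where unpaired.
#' @export
partner_table <- function(dotbracket) {
  ch <- strsplit(dotbracket, "", fixed = TRUE)[[1L]]
  p <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p[i] <- j; p[j] <- i
    } else if (ch[i] != ".") {
      stop("unexpected character '", ch[i], "' in dot-bracket", call. = FALSE)
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string", call. = FALSE)
  p
}

interval <- function(start, end) list(start = as.integer(start),
                                      end = as.integer(end))
iv_len <- function(iv) iv$end - iv$start + 1L
iv_overlaps <- function(a, b) a$start <= b$end && b$start <= a$end

#' Locate a duplex sequence on the hairpin
#'
#' Exact-substring search on the forward strand.
#'
#' @param hairpin hairpin RNA string.
#' @param query mature or star RNA string (shorter than the hairpin).
#' @return a `list(status, iv)`: `status` is `"unique"` (with `iv` the
#'   1-based closed interval), `"absent"`, or `"multimap"`.
#' @export
locate_on_hairpin <- function(hairpin, query) {
  stopifnot(nchar(query) < nchar(hairpin))
  st <- find_all_starts(hairpin, query)
  if (length(st) == 0L) return(list(status = "absent", iv = NULL))
  if (length(st) > 1L) return(list(status = "multimap", iv = NULL))
  list(status = "unique", iv = interval(st, st + nchar(query) - 1L))
}

#' Extrapolated pairing partner of a strand position
#'
#' For a paired position the fold's partner is returned. For an
#' unpaired position, the helix is extrapolated antiparallel and
#' linearly from the nearest paired position of the same strand
#' interval (ties broken toward the strand's 5' end): the result is
#' `partner[i_n] - (i - i_n)` and may fall outside the hairpin. This
#' gives bulged or frayed duplex termini a definite overhang length
#' (e.g. an asymmetric bulge inside an annotated overhang reads as a
#' 3-nt overhang).
#'
#' @param fold a `fold_result`.
#' @param strand_iv interval of the strand on the hairpin.
#' @param i position (1-based, within `strand_iv`).
#' @return integer extrapolated partner position.
#' @export
extrapolated_partner <- function(fold, strand_iv, i) {
  p <- fold$partner
  if (!is.na(p[i])) return(p[i])
  idx <- strand_iv$start:strand_iv$end
  paired <- idx[!is.na(p[idx])]
  if (!length(paired)) stop("strand entirely unpaired", call. = FALSE)
  d <- abs(paired - i)
  i_n <- paired[order(d, paired)][1L]
  p[i_n] - (i - i_n)
}

#' Predict the miRNA* interval from the mature position
#'
#' The star is the sequence forming a duplex with the mature such that
#' both strands carry a two-nucleotide 3' overhang: with q() the
#' extrapolated partner over the mature interval, the star spans
#' `q(mature_end - 2) .. q(mature_start) + 2` (1-based closed).
#'
#' @param fold a `fold_result` of the hairpin.
#' @param mature_iv mature interval (unique location).
#' @return `list(ok = TRUE, iv)` or `list(ok = FALSE, reason)`. Failure
#'   reasons cover: mature strand pairing back into itself (spans the
#'   terminal loop or a secondary stem), entirely unpaired mature, star
#'   outside the hairpin, reversed, or overlapping the mature.
#' @export
predict_star <- function(fold, mature_iv) {
  p <- fold$partner
  idx <- mature_iv$start:mature_iv$end
  prt <- p[idx]
  if (any(!is.na(prt) & prt >= mature_iv$start & prt <= mature_iv$end)) {
    return(list(ok = FALSE,
                reason = "mature strand pairs with itself (spans the terminal loop)"))
  }
  if (all(is.na(prt))) {
    return(list(ok = FALSE, reason = "mature strand entirely unpaired"))
  }
  star_start <- extrapolated_partner(fold, mature_iv, mature_iv$end - 2L)
  star_end <- extrapolated_partner(fold, mature_iv, mature_iv$start) + 2L
  if (star_start >= star_end) {
    return(list(ok = FALSE, reason = "predicted star reversed or empty"))
  }
  if (star_start < 1L || star_end > length(p)) {
    return(list(ok = FALSE, reason = "predicted star outside the hairpin"))
  }
  iv <- interval(star_start, star_end)
  if (iv_overlaps(iv, mature_iv)) {
    return(list(ok = FALSE, reason = "predicted star overlaps the mature"))
  }
  list(ok = TRUE, iv = iv)
}

#' Duplex geometry: overhangs, mismatches, asymmetric bulges
#'
#' Measures the miRNA/miRNA* duplex on the folded hairpin. The 3'
#' overhangs are computed with extrapolated partners, so frayed or
#' bulged termini still yield a definite integer; the canonical
#' Dicer/DCL product has both overhangs equal to 2. Mismatches and
#' bulges are measured over the duplex span (both strands between and
#' including their outermost mutually paired bases, which excludes the
#' overhangs): each internal loop with `a` unpaired mature-side and `b`
#' unpaired star-side nucleotides contributes `max(a, b)` mismatches
#' and `|a - b|` is a candidate for the maximum asymmetric bulge.
#'
#' @param fold a `fold_result` of the hairpin.
#' @param mature_iv,star_iv disjoint strand intervals on the hairpin.
#' @return a `duplex_geometry` object with fields `mature_iv`,
#'   `star_iv`, `overhang_mature_3p`, `overhang_star_3p`, `n_mismatch`,
#'   `max_asym_bulge`, `valid`, `invalid_reason`.
#' @export
evaluate_duplex <- function(fold, mature_iv, star_iv) {
  stopifnot(!iv_overlaps(mature_iv, star_iv))
  invalid <- function(reason) {
    structure(list(mature_iv = mature_iv, star_iv = star_iv,
                   overhang_mature_3p = NA_integer_,
                   overhang_star_3p = NA_integer_,
                   n_mismatch = NA_integer_, max_asym_bulge = NA_integer_,
                   valid = FALSE, invalid_reason = reason),
              class = "duplex_geometry")
  }
  p <- fold$partner
  m_idx <- mature_iv$start:mature_iv$end
  mutual <- m_idx[!is.na(p[m_idx]) &
                  p[m_idx] >= star_iv$start & p[m_idx] <= star_iv$end]
  if (!length(mutual)) {
    return(invalid("no base pairing between miRNA and miRNA* strands"))
  }
  if (is.unsorted(rev(p[mutual]))) {
    return(invalid("crossed pairing between miRNA and miRNA* strands"))
  }
  oh <- tryCatch(list(
    star = (star_iv$end) - extrapolated_partner(fold, mature_iv, mature_iv$start),
    mature = (mature_iv$end) - extrapolated_partner(fold, star_iv, star_iv$start)
  ), error = function(e) NULL)
  if (is.null(oh)) return(invalid("strand entirely unpaired"))

  n_mis <- 0L
  max_bulge <- 0L
  if (length(mutual) > 1L) {
    for (k in seq_len(length(mutual) - 1L)) {
      a <- mutual[k + 1L] - mutual[k] - 1L
      b <- p[mutual[k]] - p[mutual[k + 1L]] - 1L
      n_mis <- n_mis + max(a, b)
      max_bulge <- max(max_bulge, abs(a - b))
    }
  }
  structure(list(mature_iv = mature_iv, star_iv = star_iv,
                 overhang_mature_3p = as.integer(oh$mature),
                 overhang_star_3p = as.integer(oh$star),
                 n_mismatch = n_mis, max_asym_bulge = max_bulge,
                 valid = TRUE, invalid_reason = NULL),
            class = "duplex_geometry")
}

#' @export
print.duplex_geometry <- function(x, ...) {
  if (!x$valid) {
    cat("invalid duplex:", x$invalid_reason, "\n")
  } else {
    cat(sprintf(
      "miRNA %d-%d / miRNA* %d-%d; 3' overhangs (mature %d, star %d); %d mismatches; max asymmetric bulge %d\n",
      x$mature_iv$start, x$mature_iv$end, x$star_iv$start, x$star_iv$end,
      x$overhang_mature_3p, x$overhang_star_3p, x$n_mismatch, x$max_asym_bulge))
  }
  invisible(x)
}
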