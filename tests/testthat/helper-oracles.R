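# Independent oracles used across tests.

# Loop-walking geometry oracle: walks the duplex from the *star* side
# of the partner table (the implementation walks from the mature side)
# and recomputes mismatch and bulge counts per internal loop.
oracle_geometry <- function(partner, mature_iv, star_iv) {
  s_idx <- star_iv$start:star_iv$end
  mutual <- s_idx[!is.na(partner[s_idx]) &
                  partner[s_idx] >= mature_iv$start &
                  partner[s_idx] <= mature_iv$end]
  if (!length(mutual)) return(NULL)
  n_mis <- 0L; max_bulge <- 0L
  if (length(mutual) > 1L) {
    for (k in seq_len(length(mutual) - 1L)) {
      a_star <- mutual[k + 1L] - mutual[k] - 1L
      a_mat <- partner[mutual[k]] - partner[mutual[k + 1L]] - 1L
      n_mis <- n_mis + max(a_star, a_mat)
      max_bulge <- max(max_bulge, abs(a_star - a_mat))
    }
  }
  list(n_mismatch = n_mis, max_asym_bulge = max_bulge)
}

# Brute-force variance-window filter: per-placement loop, no
# vectorization shared with the implementation.
oracle_count_window <- function(placements, iv, variance = 1L) {
  total <- 0L
  for (k in seq_len(nrow(placements))) {
    s <- placements$start[k]
    e <- s + placements$length[k] - 1L
    if (s >= iv$start - variance && s <= iv$start + variance &&
        e >= iv$end - variance && e <= iv$end + variance) {
      total <- total + placements$copies[k]
    }
  }
  total
}

# A hairpin_alignment built directly from a placements table.
fake_alignment <- function(placements, locus_id = "L", library_id = "lib1") {
  structure(list(locus_id = locus_id, library_id = library_id,
                 placements = placements),
            class = "hairpin_alignment")
}

# A fold_result built from a hand-written dot-bracket string (no
# folding engine involved).
fake_fold <- function(seq, dotbracket) {
  structure(list(seq = seq, dotbracket = dotbracket, mfe_kcal = NA_real_,
                 partner = partner_table(dotbracket)),
            class = "fold_result")
}

# Shorthand interval constructor for tests (1-based closed).
iv <- function(start, end) list(start = as.integer(start),
                                end = as.integer(end))

# A clean passing fixture evaluated in the given mode.
eval_fixture <- function(spec, mode = "plant", with_star = TRUE,
                         libraries = NULL, config = mode_config(mode)) {
  tr <- make_hairpin(spec)
  if (is.null(libraries)) libraries <- list(make_library(tr))
  list(truth = tr,
       result = evaluate_locus(fixture_locus(tr, with_star = with_star),
                               libraries, config))
}
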