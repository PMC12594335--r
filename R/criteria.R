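# Criteria engine: the fifteen diagnostic flags, their severities, the
# plant/animal threshold sets, and per-locus evaluation.

FLAG_MISMATCH_5   <- "More than 5 mismatches in duplex"
FLAG_MISMATCH_7   <- "More than 7 mismatches in duplex"
FLAG_2324         <- "23/24 nt miRNA"
FLAG_BULGE        <- "Asymmetric bulge greater than 3"
FLAG_HP_SHORT     <- "Hairpin is less than 50 nucleotides"
FLAG_MULTIMAP     <- "miRNA multimaps to hairpin"
FLAG_READ_FLOOR   <- "Less than 10 reads in a single library"
FLAG_NO_READS     <- "No mature or star reads detected"
FLAG_PRECISION    <- "Precision less than 75%"
FLAG_OVERHANG     <- "No 2nt 3' overhang"
FLAG_STRUCT       <- "Hairpin structure invalid"
FLAG_MATURE_LEN   <- "Mature miRNA length not met"
FLAG_STAR_LEN     <- "Star length not met"
FLAG_PRECURSOR300 <- "Precursor > 300 nt"
FLAG_PRECURSOR200 <- "Precursor > 200 nt"

#' The fifteen diagnostic flag codes
#' @return character vector of all flag codes.
#' @export
flag_codes <- function() {
  c(FLAG_MISMATCH_5, FLAG_MISMATCH_7, FLAG_2324, FLAG_BULGE, FLAG_HP_SHORT,
    FLAG_MULTIMAP, FLAG_READ_FLOOR, FLAG_NO_READS, FLAG_PRECISION,
    FLAG_OVERHANG, FLAG_STRUCT, FLAG_MATURE_LEN, FLAG_STAR_LEN,
    FLAG_PRECURSOR300, FLAG_PRECURSOR200)
}

#' Threshold configuration for plant or animal mode
#'
#' Defaults encode the published criteria: duplex strands of 20-24 nt
#' (plants) or 20-26 nt (animals); more than 5 duplex mismatches fail
#' in plants while animals warn above 5 and fail above 7; asymmetric
#' bulges above 3 nt fail; hairpins under 50 nt fail; precursors above
#' 300 nt (plants) or 200 nt (animals) warn; at least 10 combined
#' duplex reads and precision >= 75% in a single library.
#'
#' @param mode `"plant"` or `"animal"`.
#' @param ... named threshold overrides (any field below).
#' @return a `mode_config` list: `mode`, `duplex_len_min`,
#'   `duplex_len_max`, `mismatch_fail`, `mismatch_warn`,
#'   `asym_bulge_max`, `hairpin_min_len`, `precursor_warn_len`,
#'   `read_floor`, `precision_min`, `variance`.
#' @export
mode_config <- function(mode = c("plant", "animal"), ...) {
  mode <- match.arg(mode)
  cfg <- list(
    mode = mode,
    duplex_len_min = 20L,
    duplex_len_max = if (mode == "plant") 24L else 26L,
    mismatch_fail = if (mode == "plant") 5L else 7L,
    mismatch_warn = if (mode == "plant") NA_integer_ else 5L,
    asym_bulge_max = 3L,
    hairpin_min_len = 50L,
    precursor_warn_len = if (mode == "plant") 300L else 200L,
    read_floor = 10L,
    precision_min = 0.75,
    variance = 1L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(dots)] <- dots
  structure(cfg, class = "mode_config")
}

#' Severity of a flag code under a mode configuration
#'
#' @param flag_code one of [flag_codes()].
#' @param config a [mode_config()].
#' @return `"fail"` or `"warning"`. The mismatch flag above 5 fails in
#'   plants but warns in animals; the precursor-length flags are
#'   warnings in their respective mode.
#' @export
severity_of <- function(flag_code, config) {
  switch(flag_code,
    "More than 5 mismatches in duplex" =
      if (config$mode == "plant") "fail" else "warning",
    "More than 7 mismatches in duplex" = "fail",
    "23/24 nt miRNA" = "warning",
    "Asymmetric bulge greater than 3" = "fail",
    "Hairpin is less than 50 nucleotides" = "fail",
    "miRNA multimaps to hairpin" = "fail",
    "Less than 10 reads in a single library" = "fail",
    "No mature or star reads detected" = "fail",
    "Precision less than 75%" = "fail",
    "No 2nt 3' overhang" = "fail",
    "Hairpin structure invalid" = "fail",
    "Mature miRNA length not met" = "fail",
    "Star length not met" = "fail",
    "Precursor > 300 nt" = "warning",
    "Precursor > 200 nt" = "warning",
    stop("unknown flag code: ", flag_code, call. = FALSE)
  )
}

add_flag <- function(flags, code, config, detail = "") {
  rbind(flags, data.frame(code = code, severity = severity_of(code, config),
                          detail = detail, stringsAsFactors = FALSE))
}

empty_flags <- function() {
  data.frame(code = character(0), severity = character(0),
             detail = character(0), stringsAsFactors = FALSE)
}

#' Evaluate one candidate MIRNA locus against all criteria
#'
#' Runs the full cascade: hairpin length checks, mature/star indexing,
#' MFE folding, star prediction (always recorded, also when the user
#' supplied a star), duplex geometry flags, strand length flags, then
#' per-library expression flags. Evaluation continues past the first
#' failure so the flag list is complete; only when the mature (or a
#' user-supplied star) cannot be located uniquely on the hairpin are
#' geometry and expression skipped as unevaluable. The verdict fails
#' iff at least one flag has severity `"fail"`; warning-only loci pass.
#'
#' @param locus a `locus_input` from [match_loci()] (or
#'   [locus_input()]).
#' @param libraries list of `read_library` objects.
#' @param config a [mode_config()].
#' @return a `locus_result`: list with `locus_id`, sequences and
#'   intervals, `geometry`, `fold`, `star_source`, `flags` (data.frame
#'   code/severity/detail), `verdict` (`"pass"`/`"fail"`),
#'   `reported_libraries` (metrics of passing libraries),
#'   `all_metrics` (metrics of all libraries), `alignments`.
#' @export
evaluate_locus <- function(locus, libraries, config = mode_config("plant")) {
  hairpin <- locus$hairpin$seq
  n <- nchar(hairpin)
  flags <- empty_flags()

  if (n < config$hairpin_min_len) {
    flags <- add_flag(flags, FLAG_HP_SHORT, config, sprintf("%d nt", n))
  }
  if (n > config$precursor_warn_len) {
    code <- if (config$mode == "plant") FLAG_PRECURSOR300 else FLAG_PRECURSOR200
    flags <- add_flag(flags, code, config, sprintf("%d nt", n))
  }

  result <- structure(list(
    locus_id = locus$locus_id,
    mature_seq = locus$mature$seq, star_seq = NA_character_,
    mature_iv = NULL, star_iv = NULL, predicted_star_iv = NULL,
    star_source = if (locus$star_user_supplied) "user" else "predicted",
    geometry = NULL, fold = NULL,
    flags = flags, verdict = "fail",
    reported_libraries = NULL, all_metrics = NULL, alignments = NULL
  ), class = "locus_result")
  finish <- function(res, flags) {
    res$flags <- flags
    res$verdict <- if (any(flags$severity == "fail")) "fail" else "pass"
    res
  }

  loc_m <- locate_on_hairpin(hairpin, locus$mature$seq)
  if (loc_m$status == "multimap") {
    flags <- add_flag(flags, FLAG_MULTIMAP, config, "mature")
    return(finish(result, flags))
  }
  if (loc_m$status == "absent") {
    flags <- add_flag(flags, FLAG_STRUCT, config,
                      "mature sequence not found on hairpin")
    return(finish(result, flags))
  }
  mature_iv <- loc_m$iv
  result$mature_iv <- mature_iv

  fr <- fold(hairpin)
  result$fold <- fr

  # predicted star is always computed for diagnostics
  pred <- predict_star(fr, mature_iv)
  if (pred$ok) result$predicted_star_iv <- pred$iv

  star_iv <- NULL
  if (locus$star_user_supplied) {
    loc_s <- locate_on_hairpin(hairpin, locus$star$seq)
    if (loc_s$status == "multimap") {
      flags <- add_flag(flags, FLAG_MULTIMAP, config, "star")
      return(finish(result, flags))
    }
    if (loc_s$status == "absent") {
      flags <- add_flag(flags, FLAG_STRUCT, config,
                        "star sequence not found on hairpin")
      return(finish(result, flags))
    }
    star_iv <- loc_s$iv
    result$star_seq <- locus$star$seq
  } else {
    if (!pred$ok) {
      flags <- add_flag(flags, FLAG_STRUCT, config, pred$reason)
      return(finish(result, flags))
    }
    star_iv <- pred$iv
    result$star_seq <- substr(hairpin, star_iv$start, star_iv$end)
  }
  result$star_iv <- star_iv

  if (iv_overlaps(mature_iv, star_iv)) {
    flags <- add_flag(flags, FLAG_STRUCT, config,
                      "mature and star intervals overlap")
    return(finish(result, flags))
  }

  geom <- evaluate_duplex(fr, mature_iv, star_iv)
  result$geometry <- geom
  if (!geom$valid) {
    flags <- add_flag(flags, FLAG_STRUCT, config, geom$invalid_reason)
  } else {
    if (geom$overhang_mature_3p != 2L || geom$overhang_star_3p != 2L) {
      flags <- add_flag(flags, FLAG_OVERHANG, config,
                        sprintf("mature %d nt, star %d nt",
                                geom$overhang_mature_3p, geom$overhang_star_3p))
    }
    if (!is.na(config$mismatch_warn) &&
        geom$n_mismatch > config$mismatch_fail) {
      flags <- add_flag(flags, FLAG_MISMATCH_7, config,
                        sprintf("%d mismatches", geom$n_mismatch))
    } else if (geom$n_mismatch >
               min(config$mismatch_fail, config$mismatch_warn,
                   na.rm = TRUE)) {
      flags <- add_flag(flags, FLAG_MISMATCH_5, config,
                        sprintf("%d mismatches", geom$n_mismatch))
    }
    if (geom$max_asym_bulge > config$asym_bulge_max) {
      flags <- add_flag(flags, FLAG_BULGE, config,
                        sprintf("%d nt", geom$max_asym_bulge))
    }
  }

  m_len <- iv_len(mature_iv)
  s_len <- iv_len(star_iv)
  if (m_len < config$duplex_len_min || m_len > config$duplex_len_max) {
    flags <- add_flag(flags, FLAG_MATURE_LEN, config, sprintf("%d nt", m_len))
  }
  if (s_len < config$duplex_len_min || s_len > config$duplex_len_max) {
    flags <- add_flag(flags, FLAG_STAR_LEN, config, sprintf("%d nt", s_len))
  }
  if (m_len %in% c(23L, 24L) || s_len %in% c(23L, 24L)) {
    flags <- add_flag(flags, FLAG_2324, config,
                      sprintf("mature %d nt, star %d nt", m_len, s_len))
  }

  if (length(libraries)) {
    alignments <- lapply(libraries, function(lib)
      align_library(hairpin, lib, locus_id = locus$locus_id))
    metrics <- do.call(rbind, lapply(alignments, library_metrics,
                                     mature_iv = mature_iv, star_iv = star_iv,
                                     variance = config$variance))
    verdict <- expression_verdict(metrics, read_floor = config$read_floor,
                                  precision_min = config$precision_min)
    for (code in verdict$flags) {
      best <- metrics[which.max(metrics$mature_count + metrics$star_count), ]
      flags <- add_flag(flags, code, config,
                        sprintf("best library %s: %d mature + %d star of %d",
                                best$library_id, best$mature_count,
                                best$star_count, best$total_on_hairpin))
    }
    result$alignments <- alignments
    result$all_metrics <- metrics
    result$reported_libraries <- verdict$passing
  }

  finish(result, flags)
}

#' @export
print.locus_result <- function(x, ...) {
  cat(x$locus_id, ": ", toupper(x$verdict), sep = "")
  if (nrow(x$flags)) {
    cat(" [", paste0(x$flags$code, " (", x$flags$severity, ")",
                     collapse = "; "), "]", sep = "")
  }
  cat("\n")
  invisible(x)
}
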