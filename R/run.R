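# Top-level orchestration: FASTA + sRNA-seq libraries in, per-locus
# verdicts, CSVs and plots out.

#' Validate MIRNA annotations against small RNA-seq libraries
#'
#' The full pipeline: read and pair the hairpin and mature/star FASTA
#' files, load the sequencing libraries (optionally discovering and
#' trimming 3' adapters from a trim key), evaluate every locus against
#' the structural and expression criteria of the selected mode, and
#' optionally rescue failed loci with the most abundant aligned
#' 20-24 nt sequence. With `out_dir`, results/reads CSVs (and
#' alternatives, when rescue finds any) are written, plus per-locus
#' plots when `plot = TRUE`.
#'
#' @param hairpin_fasta path to the hairpin precursor FASTA.
#' @param mature_fasta path to the mature (and optional star) FASTA.
#' @param reads_files character vector of FASTQ/FASTA library paths.
#' @param mode `"plant"` or `"animal"`.
#' @param config a [mode_config()]; defaults to `mode_config(mode)`.
#' @param autotrim infer and trim 3' adapters using `trim_key`.
#' @param trim_key trim-key sequence; defaults per mode
#'   ([default_trim_key()]).
#' @param min_key_hits adapter-inference evidence floor (default 100).
#' @param rescue re-evaluate failed loci with an alternative mature.
#' @param out_dir optional output directory for CSVs and plots.
#' @param plot render per-locus structure/depth plots (needs
#'   `out_dir`).
#' @param quiet suppress per-locus progress messages.
#' @return a `mirvet_run` object: list with `results` (list of
#'   `locus_result`), `metrics` (all locus x library metrics),
#'   `alternatives` (passing rescue results), `alt_metrics`, `config`,
#'   `libraries` (trimmed `read_library` objects).
#' @export
mirvet <- function(hairpin_fasta, mature_fasta, reads_files,
                   mode = c("plant", "animal"), config = NULL,
                   autotrim = FALSE, trim_key = NULL,
                   min_key_hits = 100L, rescue = FALSE,
                   out_dir = NULL, plot = FALSE, quiet = FALSE) {
  mode <- match.arg(mode)
  if (is.null(config)) config <- mode_config(mode)
  if (is.null(trim_key)) trim_key <- default_trim_key(mode)

  hairpins <- read_fasta(hairpin_fasta, "hairpin")
  matures <- read_fasta(mature_fasta, "mature")
  loci <- match_loci(hairpins, matures)

  libraries <- lapply(reads_files, read_sequencing_file)
  if (autotrim) {
    libraries <- lapply(libraries, function(lib) {
      adapter <- infer_adapter(lib, trim_key, min_key_hits = min_key_hits)
      if (!quiet) message("library ", lib$library_id, ": adapter ", adapter)
      trim_adapter(lib, adapter)
    })
  }

  results <- vector("list", length(loci))
  alternatives <- list()
  alt_metrics <- list()
  for (i in seq_along(loci)) {
    res <- evaluate_locus(loci[[i]], libraries, config)
    if (!quiet) {
      message(res$locus_id, ": ", res$verdict,
              if (nrow(res$flags))
                paste0(" [", paste(res$flags$code, collapse = "; "), "]"))
    }
    if (rescue && res$verdict == "fail") {
      alt <- evaluate_alternative(loci[[i]], libraries, config,
                                  alignments = res$alignments)
      if (!is.null(alt)) {
        alt_metrics[[length(alt_metrics) + 1L]] <- alt$all_metrics
        if (alt$verdict == "pass") {
          alternatives[[length(alternatives) + 1L]] <- alt
          if (!quiet) message(res$locus_id, ": rescued by alternative mature ",
                              alt$mature_seq)
        }
      }
    }
    results[[i]] <- res
  }

  metrics <- do.call(rbind, c(lapply(results, `[[`, "all_metrics"),
                              list(make.row.names = FALSE)))
  run <- structure(list(results = results, metrics = metrics,
                        alternatives = alternatives,
                        alt_metrics = if (length(alt_metrics))
                          do.call(rbind, alt_metrics),
                        config = config, libraries = libraries),
                   class = "mirvet_run")

  if (!is.null(out_dir)) {
    write_results(results, out_dir)
    if (!is.null(metrics)) write_reads(metrics, out_dir)
    if (length(alternatives)) {
      alt_rows <- do.call(rbind, lapply(alternatives, result_row))
      alt_rows <- cbind(original_locus = vapply(alternatives, `[[`, "",
                                                "alternative_for"),
                        alt_rows)
      utils::write.csv(alt_rows, file.path(out_dir, "alt_results.csv"),
                       row.names = FALSE)
    }
    if (!is.null(run$alt_metrics)) {
      write_reads(run$alt_metrics, out_dir, file = "alt_reads.csv")
    }
    if (plot) {
      for (res in results) render_locus(res, out_dir = out_dir)
    }
  }
  if (!quiet) {
    v <- vapply(results, `[[`, "", "verdict")
    message("run summary: ", sum(v == "pass"), " pass / ",
            sum(v == "fail"), " fail / ", length(alternatives), " rescued")
  }
  run
}

#' @export
print.mirvet_run <- function(x, ...) {
  v <- vapply(x$results, `[[`, "", "verdict")
  cat("MIRNA validation run (", x$config$mode, " mode): ",
      length(v), " loci, ", sum(v == "pass"), " pass, ",
      sum(v == "fail"), " fail",
      if (length(x$alternatives)) paste0(", ", length(x$alternatives),
                                         " rescued"),
      "\n", sep = "")
  invisible(x)
}

#' @method summary mirvet_run
#' @export
summary.mirvet_run <- function(object, ...) {
  df <- do.call(rbind, lapply(object$results, function(r)
    data.frame(locus_id = r$locus_id, verdict = r$verdict,
               flags = paste(r$flags$code, collapse = ";"),
               stringsAsFactors = FALSE)))
  class(df) <- c("summary.mirvet_run", class(df))
  df
}

#' @export
print.summary.mirvet_run <- function(x, ...) {
  print.data.frame(x, right = FALSE, row.names = FALSE)
  invisible(x)
}
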