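# Reporting: results / reads CSVs (RFC-4180 via write.csv) and
# per-locus diagnostics plots. Coordinates in reports are 1-based
# inclusive; row order follows input order; output is byte-identical
# across repeated runs on identical input.

result_row <- function(res) {
  iv_or_na <- function(iv, what) if (is.null(iv)) NA_integer_ else iv[[what]]
  g <- res$geometry
  rep_lib <- res$reported_libraries
  joined <- function(x) if (is.null(x) || !length(x)) "" else
    paste(x, collapse = ";")
  data.frame(
    locus_id = res$locus_id,
    mature_seq = res$mature_seq,
    mature_start = iv_or_na(res$mature_iv, "start"),
    mature_end = iv_or_na(res$mature_iv, "end"),
    star_seq = res$star_seq,
    star_start = iv_or_na(res$star_iv, "start"),
    star_end = iv_or_na(res$star_iv, "end"),
    star_source = res$star_source,
    mature_len = if (is.null(res$mature_iv)) NA_integer_ else
      iv_len(res$mature_iv),
    star_len = if (is.null(res$star_iv)) NA_integer_ else iv_len(res$star_iv),
    n_mismatch = if (is.null(g)) NA_integer_ else g$n_mismatch,
    max_asym_bulge = if (is.null(g)) NA_integer_ else g$max_asym_bulge,
    overhang_mature_3p = if (is.null(g)) NA_integer_ else g$overhang_mature_3p,
    overhang_star_3p = if (is.null(g)) NA_integer_ else g$overhang_star_3p,
    passing_libraries = joined(rep_lib$library_id),
    mature_counts = joined(rep_lib$mature_count),
    star_counts = joined(rep_lib$star_count),
    precisions = joined(if (is.null(rep_lib)) NULL else
      formatC(rep_lib$precision, digits = 4L, format = "f")),
    flags = joined(res$flags$code),
    verdict = res$verdict,
    stringsAsFactors = FALSE
  )
}

#' Write the per-locus results CSV
#'
#' One row per locus in input order: sequences, 1-based coordinates,
#' duplex geometry, per-passing-library counts and precision
#' (semicolon-joined, aligned across the three columns),
#' semicolon-joined flags and the verdict.
#'
#' @param results list of `locus_result` objects.
#' @param out_dir output directory (created if missing).
#' @param file file name (default `results.csv`).
#' @return invisibly the path written.
#' @export
write_results <- function(results, out_dir, file = "results.csv") {
  stopifnot(length(results) > 0L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  df <- do.call(rbind, lapply(results, result_row))
  path <- file.path(out_dir, file)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the per-library reads CSV
#'
#' One row per (locus, library) including failing libraries; the
#' precision field is empty when no reads aligned to the hairpin.
#'
#' @param metrics data.frame of [library_metrics()] rows for all loci
#'   and libraries.
#' @param out_dir output directory (created if missing).
#' @param file file name (default `reads.csv`).
#' @return invisibly the path written.
#' @export
write_reads <- function(metrics, out_dir, file = "reads.csv") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, file)
  utils::write.csv(metrics, path, row.names = FALSE, na = "")
  invisible(path)
}

safe_filename <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

#' Render per-locus diagnostics plots
#'
#' Writes (a) a structure plot: the hairpin's base-pairing arcs over
#' the sequence with the mature span in orange and the star span in
#' blue; and (b) a read-depth plot: per-position aggregate copy depth
#' across all libraries with the dot-bracket string along the axis.
#' Rendering failures are logged and the run continues; plots are
#' diagnostics, not verdict inputs.
#'
#' @param result a `locus_result` (fold available).
#' @param alignments list of `hairpin_alignment` objects (defaults to
#'   those stored on the result).
#' @param out_dir output directory.
#' @return invisibly a character vector of the files written (length 0
#'   on failure).
#' @export
render_locus <- function(result, alignments = result$alignments, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- safe_filename(result$locus_id)
  written <- character(0)
  tryCatch({
    if (is.null(result$fold)) stop("no fold available")
    f1 <- file.path(out_dir, paste0(base, "_structure.png"))
    grDevices::png(f1, width = 1200, height = 400)
    plot_structure_arcs(result)
    grDevices::dev.off()
    written <- c(written, f1)

    f2 <- file.path(out_dir, paste0(base, "_depth.png"))
    grDevices::png(f2, width = 1200, height = 400)
    plot_read_depth(result, alignments)
    grDevices::dev.off()
    written <- c(written, f2)
  }, error = function(e) {
    message("plot rendering failed for ", result$locus_id, ": ",
            conditionMessage(e))
  })
  invisible(written)
}

plot_structure_arcs <- function(result) {
  fr <- result$fold
  n <- nchar(fr$seq)
  p <- fr$partner
  col <- rep("grey40", n)
  span <- function(iv) if (!is.null(iv)) iv$start:iv$end else integer(0)
  col[span(result$mature_iv)] <- "darkorange"
  col[span(result$star_iv)] <- "steelblue"
  graphics::plot(NULL, xlim = c(1, n), ylim = c(0, n / 2 + 2),
                 xlab = "hairpin position", ylab = "", yaxt = "n",
                 main = paste0(result$locus_id, "  (MFE ", fr$mfe_kcal,
                               " kcal/mol)"))
  for (i in seq_len(n)) {
    j <- p[i]
    if (!is.na(j) && j > i) {
      x <- (i + j) / 2; r <- (j - i) / 2
      theta <- seq(0, pi, length.out = 40)
      graphics::lines(x + r * cos(theta), r * sin(theta), col = "grey70")
    }
  }
  graphics::points(seq_len(n), rep(0, n), pch = 15, col = col, cex = 0.6)
  graphics::legend("topright", legend = c("mature", "star"),
                   col = c("darkorange", "steelblue"), pch = 15, bty = "n")
}

plot_read_depth <- function(result, alignments) {
  n <- nchar(result$fold$seq)
  depth <- numeric(n)
  for (al in alignments) {
    pl <- al$placements
    for (k in seq_len(nrow(pl))) {
      idx <- pl$start[k]:(pl$start[k] + pl$length[k] - 1L)
      depth[idx] <- depth[idx] + pl$copies[k]
    }
  }
  graphics::plot(seq_len(n), depth, type = "h", col = "grey50",
                 xlab = "hairpin position (dot-bracket below)",
                 ylab = "read depth (copies, all libraries)",
                 main = result$locus_id, xaxt = "n")
  at <- pretty(seq_len(n))
  at <- at[at >= 1 & at <= n]
  graphics::axis(1, at = at,
                 labels = substring(result$fold$dotbracket, at, at))
  span <- function(iv, colr) if (!is.null(iv))
    graphics::rect(iv$start, 0, iv$end, max(depth, 1) * 0.02,
                   col = colr, border = NA)
  span(result$mature_iv, "darkorange")
  span(result$star_iv, "steelblue")
}
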