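#' Compute quality-control metrics for a simulated FASTQ
#'
#' One pass over the reads yields: read count; min/q25/median/q75/max of
#' read lengths; a histogram of per-read mean Phred quality (unit bins); a
#' histogram of read lengths; and the overall GC fraction (G+C bases over
#' all bases). Metrics are invariant under read reordering and additive in
#' read counts when files are concatenated.
#'
#' @param fastq Path to a FASTQ file (gzip allowed) or a tibble with
#'   `read_id`, `sequence`, `quality` columns.
#' @return A `qc_metrics` object with fields `n_reads`, `length_quantiles`,
#'   `quality_histogram`, `length_histogram`, `gc_fraction`. Has
#'   [glance()], [tidy()] and [autoplot()] methods.
#' @export
compute_qc <- function(fastq) {
  if (is.character(fastq) && length(fastq) == 1) {
    if (!file.exists(fastq)) abort(paste0("FASTQ not found: ", fastq))
    if (file.size(fastq) == 0) abort("empty FASTQ file")
    fastq <- read_fastq(fastq)
  }
  stopifnot(all(c("sequence", "quality") %in% names(fastq)))
  if (nrow(fastq) == 0) abort("FASTQ contains no reads")

  len <- nchar(fastq$sequence)
  dna <- Biostrings::DNAStringSet(fastq$sequence)
  gc_counts <- Biostrings::letterFrequency(dna, letters = c("G", "C"))
  mean_q <- vapply(fastq$quality,
                   function(q) mean(utf8ToInt(q)) - 33,
                   numeric(1), USE.NAMES = FALSE)

  q_breaks <- seq(0, max(60, ceiling(max(mean_q))), by = 1)
  q_hist <- graphics::hist(mean_q, breaks = q_breaks, plot = FALSE)
  l_breaks <- pretty(c(0, max(len)), n = 50)
  l_hist <- graphics::hist(len, breaks = l_breaks, plot = FALSE)

  structure(
    list(
      n_reads = nrow(fastq),
      length_quantiles = as.list(setNames(
        quantile(len, c(0, 0.25, 0.5, 0.75, 1), names = FALSE),
        c("min", "q25", "median", "q75", "max")
      )),
      quality_histogram = tibble::tibble(mid = q_hist$mids,
                                         count = q_hist$counts),
      length_histogram = tibble::tibble(mid = l_hist$mids,
                                        count = l_hist$counts),
      gc_fraction = sum(gc_counts) / sum(len)
    ),
    class = "qc_metrics"
  )
}

#' @export
print.qc_metrics <- function(x, ...) {
  cat("<qc_metrics>", x$n_reads, "reads; median length",
      x$length_quantiles$median, "nt; GC", signif(x$gc_fraction, 3), "\n")
  invisible(x)
}

#' Write QC metrics to JSON
#'
#' @param metrics A `qc_metrics` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_qc_json <- function(metrics, path) {
  stopifnot(inherits(metrics, "qc_metrics"))
  jsonlite::write_json(unclass(metrics), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read QC metrics written by [write_qc_json()]
#'
#' @param path JSON path.
#' @return A `qc_metrics` object equal (up to numeric representation) to
#'   the one written.
#' @export
read_qc_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$quality_histogram <- tibble::as_tibble(x$quality_histogram)
  x$length_histogram <- tibble::as_tibble(x$length_histogram)
  x$length_quantiles <- as.list(x$length_quantiles)
  structure(x, class = "qc_metrics")
}

#' Render an HTML quality-control report
#'
#' Standalone HTML with a metrics table and embedded (base64 PNG) read
#' length and quality histograms, plus a sibling `.json` metrics file for
#' machine consumption.
#'
#' @param metrics A `qc_metrics` object.
#' @param out_html Output HTML path; the JSON sidecar replaces the
#'   extension with `.json`.
#' @param title Report title.
#' @param diffable If `TRUE`, omit the timestamp so identical metrics give
#'   byte-identical HTML.
#' @return `out_html`, invisibly.
#' @export
render_report <- function(metrics, out_html, title = "scnanosim QC report",
                          diffable = FALSE) {
  stopifnot(inherits(metrics, "qc_metrics"))
  json_path <- sub("\\.html?$", ".json", out_html)
  if (json_path == out_html) json_path <- paste0(out_html, ".json")
  write_qc_json(metrics, json_path)

  img <- function(plot) {
    png_file <- tempfile(fileext = ".png")
    on.exit(unlink(png_file))
    suppressMessages(ggplot2::ggsave(png_file, plot, width = 6, height = 3.5,
                                     dpi = 96))
    paste0("<img src=\"data:image/png;base64,",
           jsonlite::base64_enc(readBin(png_file, "raw",
                                        file.size(png_file))),
           "\" alt=\"plot\"/>")
  }
  q <- metrics$length_quantiles
  rows <- c(
    sprintf("<tr><td>Reads</td><td>%d</td></tr>", metrics$n_reads),
    sprintf("<tr><td>Read length (min / q25 / median / q75 / max)</td><td>%s</td></tr>",
            paste(unlist(q), collapse = " / ")),
    sprintf("<tr><td>GC fraction</td><td>%.4f</td></tr>",
            metrics$gc_fraction)
  )
  html <- c(
    "<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\"/>",
    paste0("<title>", title, "</title>"),
    "<style>body{font-family:sans-serif;max-width:60em;margin:2em auto}",
    "table{border-collapse:collapse}td{border:1px solid #999;padding:4px 8px}",
    "</style></head><body>",
    paste0("<h1>", title, "</h1>"),
    if (!diffable) paste0("<p>Generated ", format(Sys.time()), "</p>"),
    "<table>", rows, "</table>",
    "<h2>Read length distribution</h2>", img(plot_length_histogram(metrics)),
    "<h2>Mean per-read quality</h2>", img(plot_quality_histogram(metrics)),
    "</body></html>"
  )
  writeLines(html, out_html)
  invisible(out_html)
}

plot_length_histogram <- function(metrics) {
  ggplot2::ggplot(metrics$length_histogram,
                  ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Read length (nt)", y = "Reads") +
    ggplot2::theme_minimal()
}

plot_quality_histogram <- function(metrics) {
  ggplot2::ggplot(metrics$quality_histogram,
                  ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "Mean per-read Phred quality", y = "Reads") +
    ggplot2::theme_minimal()
}
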