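#' Read a PAF alignment file
#'
#' Parses the 12 mandatory pairwise-alignment-format columns emitted by
#' long-read aligners such as minimap2, plus the `cg:Z` (CIGAR) and `tp:A`
#' (alignment type) tags when present. No installed R package parses PAF, so
#' the tab-separated layout is read directly.
#'
#' @param path Path to a PAF file.
#' @return A tibble with columns `query_name`, `query_length`,
#'   `query_start`, `query_end`, `strand`, `target_name`, `target_length`,
#'   `target_start`, `target_end`, `n_matches`, `block_len`, `mapq`,
#'   `cigar` (NA when absent) and `tp` (NA when absent).
#' @export
read_paf <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort("empty PAF file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 12)) {
    abort("malformed PAF: fewer than 12 columns on some lines")
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  tag <- function(prefix) {
    vapply(fields, function(f) {
      hit <- f[startsWith(f, prefix)]
      if (length(hit) == 0) NA_character_ else sub(prefix, "", hit[1])
    }, character(1))
  }
  tibble::tibble(
    query_name = col(1),
    query_length = as.integer(col(2)),
    query_start = as.integer(col(3)),
    query_end = as.integer(col(4)),
    strand = col(5),
    target_name = col(6),
    target_length = as.integer(col(7)),
    target_start = as.integer(col(8)),
    target_end = as.integer(col(9)),
    n_matches = as.integer(col(10)),
    block_len = as.integer(col(11)),
    mapq = as.integer(col(12)),
    cigar = tag("cg:Z:"),
    tp = tag("tp:A:")
  )
}

#' Write alignments to PAF
#'
#' Inverse of [read_paf()]; `cigar` and `tp` columns, when present and
#' non-missing, are written as `cg:Z` / `tp:A` tags.
#'
#' @param paf A tibble in the layout returned by [read_paf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(paf, path) {
  base <- c("query_name", "query_length", "query_start", "query_end",
            "strand", "target_name", "target_length", "target_start",
            "target_end", "n_matches", "block_len", "mapq")
  stopifnot(all(base %in% names(paf)))
  lines <- do.call(paste, c(unname(as.list(paf[base])), sep = "\t"))
  if (!is.null(paf$tp)) {
    has <- !is.na(paf$tp)
    lines[has] <- paste0(lines[has], "\ttp:A:", paf$tp[has])
  }
  if (!is.null(paf$cigar)) {
    has <- !is.na(paf$cigar)
    lines[has] <- paste0(lines[has], "\tcg:Z:", paf$cigar[has])
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Estimate an empirical cDNA truncation model from alignments
#'
#' Real cDNA reads are rarely full-length. For each primary alignment the
#' retained segment of the transcript is summarized by its relative
#' coordinates `target_start / target_length` and
#' `target_end / target_length`; these pairs are binned into an
#' `n_bins` x `n_bins` joint histogram over the unit square, normalized to a
#' probability distribution that [apply_truncation()] samples from.
#'
#' @param paf Alignments as a tibble from [read_paf()]. Secondary
#'   alignments (`tp` other than `P`) and zero-length targets are dropped.
#' @param n_bins Number of bins per axis (default 20).
#' @return A `truncation_model` object.
#' @export
estimate_truncation_model <- function(paf, n_bins = 20L) {
  stopifnot(n_bins >= 1)
  keep <- (is.na(paf$tp) | paf$tp == "P") & paf$target_length > 0
  paf <- paf[keep, , drop = FALSE]
  if (nrow(paf) == 0) abort("no usable primary alignments")
  rel_start <- pmin(pmax(paf$target_start / paf$target_length, 0), 1)
  rel_end <- pmin(pmax(paf$target_end / paf$target_length, 0), 1)
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- function(x) pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), n_bins)
  prob <- matrix(0, n_bins, n_bins)
  tab <- table(factor(bin(rel_start), levels = seq_len(n_bins)),
               factor(bin(rel_end), levels = seq_len(n_bins)))
  prob[] <- as.numeric(tab)
  prob <- prob / sum(prob)
  structure(
    list(prob = prob, breaks = breaks, n_bins = as.integer(n_bins),
         full_length = FALSE, n_alignments = nrow(paf)),
    class = "truncation_model"
  )
}

#' Full-length (no truncation) model
#'
#' The default when no alignments are supplied: every molecule keeps its
#' entire cDNA, making truncation strictly opt-in.
#'
#' @return A degenerate `truncation_model`.
#' @export
full_length_model <- function() {
  structure(
    list(prob = matrix(1, 1, 1), breaks = c(0, 1), n_bins = 1L,
         full_length = TRUE, n_alignments = 0L),
    class = "truncation_model"
  )
}

#' @export
print.truncation_model <- function(x, ...) {
  if (x$full_length) {
    cat("<truncation_model> full-length (no truncation)\n")
  } else {
    cat("<truncation_model>", x$n_bins, "x", x$n_bins, "bins from",
        x$n_alignments, "alignments\n")
  }
  invisible(x)
}

#' Truncate cDNA sequences according to a truncation model
#'
#' For each sequence a (relative start, relative end) pair is drawn from the
#' model's joint histogram, uniformly within the chosen bin, and mapped to
#' integer 0-based half-open coordinates; at least 1 nt is always retained.
#' Uses the current RNG state. The degenerate [full_length_model()] returns
#' each sequence unchanged.
#'
#' @param cdna Character vector of non-empty cDNA sequences.
#' @param model A `truncation_model`.
#' @return A tibble with columns `sequence`, `trunc_start`, `trunc_end`.
#' @export
apply_truncation <- function(cdna, model = full_length_model()) {
  stopifnot(inherits(model, "truncation_model"))
  if (any(nchar(cdna) == 0)) abort("empty cDNA sequence")
  n <- length(cdna)
  len <- nchar(cdna)
  if (model$full_length) {
    return(tibble::tibble(sequence = cdna, trunc_start = 0L,
                          trunc_end = len))
  }
  cells <- sample.int(model$n_bins^2, n, replace = TRUE,
                      prob = as.vector(model$prob))
  row <- (cells - 1L) %% model$n_bins + 1L       # start bin
  colb <- (cells - 1L) %/% model$n_bins + 1L     # end bin
  w <- 1 / model$n_bins
  rel_start <- (row - 1L) * w + runif(n) * w
  rel_end <- (colb - 1L) * w + runif(n) * w
  swap <- rel_start > rel_end
  if (any(swap)) {   # rare off-diagonal draws with inverted order
    tmp <- rel_start[swap]
    rel_start[swap] <- rel_end[swap]
    rel_end[swap] <- tmp
  }
  start <- pmin(pmax(floor(rel_start * len), 0L), len - 1L)
  end <- pmin(pmax(ceiling(rel_end * len), start + 1L), len)
  tibble::tibble(
    sequence = substr(cdna, start + 1L, end),
    trunc_start = as.integer(start),
    trunc_end = as.integer(end)
  )
}
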