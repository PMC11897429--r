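#' Sequencing-error event profile
#'
#' Mix of error-event types used by [inject_errors()] and the cap on
#' per-base quality scores. Proportions are normalized to sum to 1;
#' defaults split events equally between substitutions, insertions and
#' deletions.
#'
#' @param p_sub,p_ins,p_del Non-negative event-type weights.
#' @param max_quality Phred cap for simulated base qualities (default 40).
#' @return An `error_profile` object.
#' @export
error_profile <- function(p_sub = 1 / 3, p_ins = 1 / 3, p_del = 1 / 3,
                          max_quality = 40L) {
  p <- c(sub = p_sub, ins = p_ins, del = p_del)
  if (any(p < 0) || sum(p) <= 0) {
    abort("event proportions must be >= 0 and not all zero")
  }
  structure(
    list(p = p / sum(p), max_quality = as.integer(max_quality)),
    class = "error_profile"
  )
}

#' Inject sequencing errors at a target identity
#'
#' Approximately `round(L * (1 - target_identity))` error events are placed
#' at distinct uniform positions of each template; event types follow the
#' profile. Substitutions replace the base with a different one, insertions
#' add a random base, deletions remove the base. Per-base qualities are
#' Phred scores consistent with the read's realized error rate
#' (`Q = -10 log10(max(1 - identity, 1e-4))`), with integer jitter in
#' \[-3, +3\], clamped to \[2, max_quality\]. Uses the current RNG state.
#'
#' @param sequence Character vector of non-empty A/C/G/T/N templates.
#' @param target_identity Target identities in (0, 1\]; recycled.
#' @param profile An [error_profile()].
#' @return A tibble with columns `sequence` (the error-bearing read),
#'   `quality` (Phred+33 string, same length as the read), `n_sub`,
#'   `n_ins`, `n_del`.
#' @export
inject_errors <- function(sequence, target_identity,
                          profile = error_profile()) {
  stopifnot(inherits(profile, "error_profile"))
  if (any(nchar(sequence) == 0)) abort("empty template sequence")
  if (any(target_identity <= 0 | target_identity > 1)) {
    abort("target_identity must be in (0, 1]")
  }
  n <- length(sequence)
  target_identity <- rep_len(target_identity, n)
  out_seq <- character(n)
  out_qual <- character(n)
  n_sub <- n_ins <- n_del <- integer(n)
  types <- names(profile$p)
  for (i in seq_len(n)) {
    chars <- strsplit(sequence[i], "", fixed = TRUE)[[1]]
    L <- length(chars)
    k <- round(L * (1 - target_identity[i]))
    if (k > 0) {
      pos <- sample.int(L, k)
      type <- sample(types, k, replace = TRUE, prob = profile$p)
      pieces <- as.list(chars)
      for (j in seq_len(k)) {
        p <- pos[j]
        pieces[[p]] <- switch(
          type[j],
          sub = sample(setdiff(DNA_BASES, chars[p]), 1),
          ins = c(chars[p], sample(DNA_BASES, 1)),
          del = character(0)
        )
      }
      chars <- unlist(pieces)
      n_sub[i] <- sum(type == "sub")
      n_ins[i] <- sum(type == "ins")
      n_del[i] <- sum(type == "del")
    }
    out_seq[i] <- paste(chars, collapse = "")
    # realized gap-included identity: matched columns over alignment columns
    realized <- (L - n_sub[i] - n_del[i]) / (L + n_ins[i])
    out_qual[i] <- quality_string(length(chars), realized,
                                  profile$max_quality)
  }
  tibble::tibble(sequence = out_seq, quality = out_qual,
                 n_sub = n_sub, n_ins = n_ins, n_del = n_del)
}

quality_string <- function(len, identity, max_quality) {
  if (len == 0) return("")
  if (identity >= 1) {   # error-free read: flat maximum quality
    return(strrep(rawToChar(as.raw(max_quality + 33L)), len))
  }
  q0 <- -10 * log10(max(1 - identity, 1e-4))
  q <- pmin(pmax(round(q0 + sample(-3:3, len, replace = TRUE)), 2),
            max_quality)
  rawToChar(as.raw(q + 33L))
}

#' Simulate a Nanopore FASTQ from template reads
#'
#' One FASTQ record per template: a per-read identity is drawn from the
#' beta identity model and errors are injected at that target
#' ([inject_errors()]). Read ids are preserved so every record links back to
#' its ground-truth molecule.
#'
#' @param templates A tibble with `read_id` and `sequence` columns, or a
#'   path to a FASTA file of templates.
#' @param model An `identity_model`.
#' @param profile An [error_profile()].
#' @param seed Integer seed; fixed seed gives a byte-identical FASTQ.
#' @return A `simulated_fastq` tibble: `read_id`, `sequence`, `quality`,
#'   `identity` (the per-read target drawn from the model).
#' @export
simulate_fastq <- function(templates, model, profile = error_profile(),
                           seed = 1L) {
  stopifnot(inherits(model, "identity_model"))
  if (is.character(templates) && length(templates) == 1) {
    templates <- read_reads_fasta(templates)
  }
  stopifnot(all(c("read_id", "sequence") %in% names(templates)))
  if (nrow(templates) == 0) {
    warn("no template reads; returning an empty FASTQ")
    return(tibble::tibble(read_id = character(), sequence = character(),
                          quality = character(), identity = numeric()))
  }
  with_seed(seed, {
    ident <- rbeta(nrow(templates), model$alpha, model$beta)
    ident <- pmin(pmax(ident, 1e-6), 1)
    res <- inject_errors(templates$sequence, ident, profile)
    tibble::tibble(
      read_id = templates$read_id,
      sequence = res$sequence,
      quality = res$quality,
      identity = ident
    )
  })
}

#' Write simulated reads to FASTQ (Phred+33)
#'
#' @param fastq A tibble with `read_id`, `sequence`, `quality`.
#' @param path Output path; `.gz` writes gzip-compressed.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(fastq, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(fastq)))
  if (any(nchar(fastq$sequence) != nchar(fastq$quality))) {
    abort("quality strings must match sequence lengths")
  }
  lines <- as.vector(rbind(paste0("@", fastq$read_id), fastq$sequence,
                           "+", fastq$quality))
  con <- if (endsWith(path, ".gz")) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ path (gzip allowed).
#' @return A tibble with `read_id`, `sequence` and `quality` (Phred+33).
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
  tibble::tibble(
    read_id = sub("\\s.*$", "", names(seqs)),
    sequence = as.character(unname(seqs)),
    quality = as.character(S4Vectors::mcols(seqs)$qualities)
  )
}
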