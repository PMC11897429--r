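#' Load a reference transcriptome, optionally with annotation and genome
#'
#' Builds the index used by [generate_perfect_reads()]. With only a
#' transcript FASTA, each transcript is its own gene. With a GTF, the
#' gene-to-transcript map and per-transcript exon structure are taken from
#' the annotation (coordinates converted to 0-based half-open); adding the
#' genome FASTA enables intron-retained (unspliced) sequences.
#'
#' FASTA identifiers are truncated at the first whitespace; transcript ids
#' are matched to the GTF with version suffixes (`.1`, `.2`, ...) stripped
#' from both sides.
#'
#' @param transcript_fasta Path to the transcript FASTA (gzip allowed).
#' @param annotation_gtf Optional GTF path with exon features carrying
#'   `gene_id` and `transcript_id` attributes.
#' @param genome_fasta Optional genome FASTA path.
#' @return A `transcriptome_index` object: transcript sequences
#'   (`DNAStringSet`), a `genes` tibble (`gene_id`, `transcript_id`,
#'   `tx_length`), and optionally an `exons` tibble (`transcript_id`,
#'   `chrom`, `start`, `end`, `strand`; 0-based half-open) and the genome.
#' @export
load_transcriptome <- function(transcript_fasta, annotation_gtf = NULL,
                               genome_fasta = NULL) {
  seqs <- Biostrings::readDNAStringSet(transcript_fasta)
  if (length(seqs) == 0) abort("empty transcript FASTA")
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) abort("duplicate transcript ids in FASTA")

  exons <- NULL
  if (!is.null(annotation_gtf)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("the rtracklayer package is required to read GTF annotation")
    }
    gr <- rtracklayer::import(annotation_gtf, format = "gtf")
    gr <- gr[gr$type == "exon"]
    if (length(gr) == 0) abort("GTF contains no exon features")
    exons <- tibble::tibble(
      gene_id = gr$gene_id,
      transcript_id = gr$transcript_id,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,   # GTF 1-based closed -> 0-based half-open
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr))
    ) |>
      dplyr::arrange(.data$transcript_id, .data$start)

    strip <- function(x) sub("\\.\\d+$", "", x)
    fasta_ids <- names(seqs)
    match_idx <- match(strip(exons$transcript_id), strip(fasta_ids))
    missing_tx <- unique(exons$transcript_id[is.na(match_idx)])
    if (length(missing_tx) > 0) {
      warn(paste0(
        length(missing_tx),
        " GTF transcript(s) absent from FASTA skipped: ",
        paste(head(missing_tx, 5), collapse = ", ")
      ))
      exons <- exons[!is.na(match_idx), , drop = FALSE]
      match_idx <- match_idx[!is.na(match_idx)]
    }
    if (nrow(exons) == 0) abort("no GTF transcript matches the FASTA")
    exons$transcript_id <- fasta_ids[match_idx]
    genes <- exons |>
      dplyr::distinct(.data$gene_id, .data$transcript_id) |>
      dplyr::mutate(tx_length = Biostrings::width(seqs)[
        match(.data$transcript_id, names(seqs))
      ])
  } else {
    genes <- tibble::tibble(
      gene_id = names(seqs),
      transcript_id = names(seqs),
      tx_length = Biostrings::width(seqs)
    )
  }

  genome <- NULL
  if (!is.null(genome_fasta)) {
    genome <- Biostrings::readDNAStringSet(genome_fasta)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }

  idx <- structure(
    list(transcripts = seqs, genes = genes, exons = exons, genome = genome),
    class = "transcriptome_index"
  )
  check_exon_lengths(idx)
  idx
}

# spliced exon length must match the transcript sequence when both known
check_exon_lengths <- function(idx) {
  if (is.null(idx$exons)) return(invisible(idx))
  len <- idx$exons |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(spliced = sum(.data$end - .data$start))
  fasta_len <- Biostrings::width(idx$transcripts)[
    match(len$transcript_id, names(idx$transcripts))
  ]
  bad <- len$transcript_id[len$spliced != fasta_len]
  if (length(bad) > 0) {
    warn(paste0(
      "exon lengths disagree with FASTA for: ",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  invisible(idx)
}

#' @export
print.transcriptome_index <- function(x, ...) {
  cat("<transcriptome_index>", length(x$transcripts), "transcripts,",
      dplyr::n_distinct(x$genes$gene_id), "genes",
      if (!is.null(x$exons)) "(with exon structure)" else "", "\n")
  invisible(x)
}

#' Pick transcripts for genes with a short-length prior
#'
#' For each gene, one of its transcripts is drawn with probability
#' proportional to `exp(-L/tau)`, where `L` is the transcript length in nt:
#' shorter isoforms are favoured, matching the 3'-biased cDNA length
#' distribution of droplet libraries. Uses the current RNG state.
#'
#' @param gene_id Character vector of gene ids (one draw per element).
#' @param index A `transcriptome_index`.
#' @param tau Length scale of the prior in nt (default 2000); larger values
#'   flatten the prior towards uniform.
#' @return Character vector of transcript ids, same length as `gene_id`.
#' @export
pick_transcript <- function(gene_id, index, tau = 2000) {
  stopifnot(inherits(index, "transcriptome_index"))
  unknown <- setdiff(unique(gene_id), index$genes$gene_id)
  if (length(unknown) > 0) {
    abort(paste0("unknown gene(s): ", paste(head(unknown, 5), collapse = ", ")))
  }
  by_gene <- split(index$genes, index$genes$gene_id)
  out <- character(length(gene_id))
  for (g in unique(gene_id)) {
    tx <- by_gene[[g]]
    pos <- which(gene_id == g)
    if (nrow(tx) == 1) {
      out[pos] <- tx$transcript_id
    } else {
      w <- exp(-(tx$tx_length - min(tx$tx_length)) / tau)  # shift for stability
      out[pos] <- sample(tx$transcript_id, length(pos), replace = TRUE,
                         prob = w)
    }
  }
  out
}

#' Intron-retained (unspliced) transcript sequence
#'
#' Returns the genomic span from the first exon start to the last exon end,
#' introns included, on the transcript's strand (reverse-complemented for
#' `-` strand genes). Requires the index to carry exon structure and the
#' genome.
#'
#' @param transcript_id Character vector of transcript ids.
#' @param index A `transcriptome_index` built with GTF and genome.
#' @return Character vector of unspliced sequences.
#' @export
unspliced_sequence <- function(transcript_id, index) {
  stopifnot(inherits(index, "transcriptome_index"))
  if (is.null(index$exons) || is.null(index$genome)) {
    abort("intron retention requires a transcriptome loaded with GTF and genome")
  }
  span <- index$exons |>
    dplyr::filter(.data$transcript_id %in% .env$transcript_id) |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      chrom = dplyr::first(.data$chrom),
      start = min(.data$start),
      end = max(.data$end),
      strand = dplyr::first(.data$strand)
    )
  missing_tx <- setdiff(unique(transcript_id), span$transcript_id)
  if (length(missing_tx) > 0) {
    abort(paste0("no exon structure for: ",
                 paste(head(missing_tx, 5), collapse = ", ")))
  }
  i <- match(transcript_id, span$transcript_id)
  seqs <- as.character(Biostrings::subseq(
    index$genome[span$chrom[i]],
    start = span$start[i] + 1L, end = span$end[i]
  ))
  minus <- span$strand[i] == "-"
  if (any(minus)) seqs[minus] <- dna_revcomp(seqs[minus])
  unname(seqs)
}
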