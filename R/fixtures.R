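#' Generate a toy reference (genome, transcriptome, GTF)
#'
#' Builds a small random genome with multi-exon genes and multi-isoform
#' transcripts, entirely self-consistent: every transcript sequence in the
#' FASTA equals the concatenation of its GTF exons extracted from the
#' genome (reverse-complemented for `-` strand genes). Isoform 1 of each
#' gene uses all exons; further isoforms drop one internal exon each, so
#' isoforms of a gene differ in length. Genes alternate strands and are laid
#' out on one chromosome separated by spacers.
#'
#' @param dir Output directory (created if needed); files `genome.fa`,
#'   `transcripts.fa`, `annotation.gtf` are written there.
#' @param n_genes Number of genes (>= 1).
#' @param isoforms_per_gene Isoforms per gene (capped at
#'   `n_exons - 1` drops plus the full isoform).
#' @param n_exons Exons per gene.
#' @param exon_length_range,intron_length_range Integer ranges (nt) that
#'   exon and intron lengths are drawn from.
#' @param seed Integer seed; same seed gives identical files.
#' @return Invisibly, a list with paths `genome`, `transcripts`, `gtf`.
#' @export
make_toy_reference <- function(dir, n_genes = 5, isoforms_per_gene = 2,
                               n_exons = 3,
                               exon_length_range = c(80, 200),
                               intron_length_range = c(50, 150),
                               seed = 1L) {
  stopifnot(n_genes >= 1, isoforms_per_gene >= 1, n_exons >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    chrom <- "chr1"
    genome <- character(0)
    offset <- 0L
    gtf <- character(0)
    tx_seqs <- character(0)
    for (g in seq_len(n_genes)) {
      gene_id <- sprintf("gene%02d", g)
      strand <- if (g %% 2 == 1) "+" else "-"
      ex_len <- sample(seq(exon_length_range[1], exon_length_range[2]),
                       n_exons, replace = TRUE)
      in_len <- if (n_exons > 1) {
        sample(seq(intron_length_range[1], intron_length_range[2]),
               n_exons - 1, replace = TRUE)
      } else integer(0)
      # 0-based half-open exon coordinates within the chromosome
      starts <- integer(n_exons)
      pos <- offset
      for (e in seq_len(n_exons)) {
        starts[e] <- pos
        pos <- pos + ex_len[e] + if (e < n_exons) in_len[e] else 0L
      }
      ends <- starts + ex_len
      locus_len <- pos - offset
      genome <- c(genome, random_dna(1, locus_len + 100L))  # +100 spacer
      gene_seq_start <- offset

      n_iso <- min(isoforms_per_gene,
                   if (n_exons > 2) n_exons - 1 else 1)
      for (k in seq_len(n_iso)) {
        tx_id <- sprintf("%s.t%d", gene_id, k)
        keep <- if (k == 1) seq_len(n_exons) else
          setdiff(seq_len(n_exons), k)   # drop internal exon k (2..n-1)
        gtf <- c(gtf, sprintf(
          "%s\ttoy\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
          chrom, min(starts[keep]) + 1L, max(ends[keep]), strand,
          gene_id, tx_id
        ))
        for (e in keep) {
          gtf <- c(gtf, sprintf(
            "%s\ttoy\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
            chrom, starts[e] + 1L, ends[e], strand, gene_id, tx_id
          ))
        }
        tx_seqs[tx_id] <- NA_character_  # filled after genome is assembled
        attr(tx_seqs, "spec") <- c(
          attr(tx_seqs, "spec"),
          list(list(tx = tx_id, keep_starts = starts[keep],
                    keep_ends = ends[keep], strand = strand))
        )
      }
      offset <- offset + locus_len + 100L
    }
    genome_seq <- paste(genome, collapse = "")
    for (s in attr(tx_seqs, "spec")) {
      pieces <- substring(genome_seq, s$keep_starts + 1L, s$keep_ends)
      seq <- paste(pieces, collapse = "")
      if (s$strand == "-") seq <- dna_revcomp(seq)
      tx_seqs[s$tx] <- seq
    }
    attr(tx_seqs, "spec") <- NULL

    genome_path <- file.path(dir, "genome.fa")
    tx_path <- file.path(dir, "transcripts.fa")
    gtf_path <- file.path(dir, "annotation.gtf")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(genome_seq, chrom)), genome_path
    )
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(tx_seqs), tx_path)
    writeLines(gtf, gtf_path)
    invisible(list(genome = genome_path, transcripts = tx_path,
                   gtf = gtf_path))
  })
}

#' Generate a random whitelist of cell barcodes
#'
#' @param n Number of barcodes.
#' @param cb_length Barcode length in nt.
#' @param path Optional output path (one barcode per line).
#' @param seed Integer seed.
#' @return Character vector of distinct barcodes (invisibly if written).
#' @export
make_whitelist <- function(n, cb_length = 16L, path = NULL, seed = 1L) {
  bc <- with_seed(seed, random_distinct_dna(n, cb_length))
  if (!is.null(path)) {
    writeLines(bc, path)
    return(invisible(bc))
  }
  bc
}

#' Generate a small random count matrix for testing and demos
#'
#' Poisson counts at a common mean; a convenience around [count_params()] +
#' [simulate_counts()].
#'
#' @param feature_ids Feature identifiers.
#' @param n_cells Number of cells.
#' @param mean Mean UMI count per feature per cell.
#' @param seed Integer seed.
#' @return A count matrix tibble.
#' @export
make_toy_counts <- function(feature_ids, n_cells, mean = 2, seed = 1L) {
  simulate_counts(
    count_params(rep(mean, length(feature_ids)), feature_ids = feature_ids),
    n_cells, seed = seed
  )
}

#' Generate a synthetic PAF with known truncation and identity structure
#'
#' Constructs alignment records whose target coordinates realize a chosen
#' relative truncation and whose match counts / CIGARs realize a chosen
#' gap-included identity (via mismatch-only alignments), so estimator
#' behaviour can be checked against a known answer.
#'
#' @param n_records Number of alignments.
#' @param target_length Transcript length (nt).
#' @param truncation Either `NULL` (full-length alignments) or a
#'   length-2 numeric `c(rel_start, rel_end)` applied to every record.
#' @param identity Gap-included identity in (0, 1] for every record.
#' @param path Optional output PAF path.
#' @param seed Integer seed.
#' @return The PAF tibble (invisibly if written to `path`).
#' @export
make_synthetic_paf <- function(n_records, target_length = 1000L,
                               truncation = NULL, identity = 0.9,
                               path = NULL, seed = 1L) {
  stopifnot(n_records >= 1, identity > 0, identity <= 1)
  with_seed(seed, {
    if (is.null(truncation)) truncation <- c(0, 1)
    t_start <- as.integer(round(truncation[1] * target_length))
    t_end <- as.integer(round(truncation[2] * target_length))
    span <- t_end - t_start
    stopifnot(span > 0)
    m <- as.integer(round(identity * span))
    cigar <- if (m == span) sprintf("%d=", span) else
      sprintf("%d=%dX", m, span - m)
    paf <- tibble::tibble(
      query_name = sprintf("read_%05d", seq_len(n_records)),
      query_length = span,
      query_start = 0L,
      query_end = span,
      strand = "+",
      target_name = "tx_1",
      target_length = as.integer(target_length),
      target_start = t_start,
      target_end = t_end,
      n_matches = m,
      block_len = span,
      mapq = 60L,
      cigar = cigar,
      tp = "P"
    )
    if (!is.null(path)) {
      write_paf(paf, path)
      return(invisible(paf))
    }
    paf
  })
}
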