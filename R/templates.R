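#' Generate perfect reads from a count matrix
#'
#' Constructs one error-free library molecule for every UMI in the count
#' matrix: exactly `matrix[f, c]` molecules per (feature `f`, cell `c`),
#' each with a freshly drawn random UMI. Per molecule the pipeline is:
#' resolve the feature to a transcript (genes use the short-length prior of
#' [pick_transcript()]; features that are themselves transcript ids are used
#' directly), optionally swap in the intron-retained sequence
#' ([unspliced_sequence()]) with probability `intron_retention_prob`,
#' truncate the cDNA ([apply_truncation()]), assemble
#' adapter + CB + UMI + polyT + cDNA + TSO ([assemble_molecule()]) and
#' orient the molecule on a random strand ([orient()]).
#'
#' Cell barcodes come from `whitelist` (drawn without replacement, in
#' order); if none is given and the matrix cell names are already valid
#' barcodes of the right length they are used as-is, otherwise random
#' distinct barcodes are generated.
#'
#' @param counts Count matrix tibble (first column `feature_id`).
#' @param index A `transcriptome_index` from [load_transcriptome()].
#' @param structure A [read_structure()].
#' @param truncation A `truncation_model`; default [full_length_model()].
#' @param whitelist Optional character vector of valid cell barcodes.
#' @param intron_retention_prob Per-molecule probability of retaining
#'   introns (default 0; requires GTF + genome in `index` when > 0).
#' @param tau Length scale (nt) of the short-transcript prior.
#' @param seed Integer seed; identical inputs and seed give identical
#'   output.
#' @return A `molecule_set` tibble with one row per molecule: `read_id`,
#'   `cell_id`, `cell_barcode`, `umi`, `gene_id`, `transcript_id`,
#'   `strand`, `trunc_start`, `trunc_end`, `unspliced`, `sequence`.
#' @export
generate_perfect_reads <- function(counts, index,
                                   structure = read_structure(),
                                   truncation = full_length_model(),
                                   whitelist = NULL,
                                   intron_retention_prob = 0,
                                   tau = 2000, seed = 1L) {
  counts <- validate_count_matrix(counts)
  stopifnot(inherits(index, "transcriptome_index"),
            inherits(structure, "read_structure"),
            inherits(truncation, "truncation_model"))
  if (intron_retention_prob < 0 || intron_retention_prob > 1) {
    abort("intron_retention_prob must be in [0, 1]")
  }
  if (intron_retention_prob > 0 &&
      (is.null(index$exons) || is.null(index$genome))) {
    abort("intron retention requires a transcriptome loaded with GTF and genome")
  }
  feats <- counts$feature_id
  is_gene <- feats %in% index$genes$gene_id
  is_tx <- feats %in% names(index$transcripts)
  bad <- feats[!is_gene & !is_tx]
  if (length(bad) > 0) {
    abort(paste0("feature(s) not in transcriptome: ",
                 paste(head(bad, 10), collapse = ", ")))
  }

  cells <- names(counts)[-1]
  with_seed(seed, {
    barcodes <- resolve_barcodes(cells, whitelist, structure$cb_length)

    mol <- counts |>
      tidyr::pivot_longer(-"feature_id", names_to = "cell_id",
                          values_to = "n") |>
      dplyr::filter(.data$n > 0) |>
      tidyr::uncount(.data$n) |>
      dplyr::mutate(cell_barcode = barcodes[.data$cell_id])
    if (nrow(mol) == 0) {
      return(empty_molecule_set())
    }

    gene_like <- mol$feature_id %in% index$genes$gene_id
    tx <- character(nrow(mol))
    if (any(gene_like)) {
      tx[gene_like] <- pick_transcript(mol$feature_id[gene_like], index, tau)
    }
    tx[!gene_like] <- mol$feature_id[!gene_like]
    gene <- ifelse(gene_like, mol$feature_id,
                   index$genes$gene_id[match(mol$feature_id,
                                             index$genes$transcript_id)])

    unspliced <- runif(nrow(mol)) < intron_retention_prob
    cdna <- character(nrow(mol))
    cdna[!unspliced] <- as.character(index$transcripts[tx[!unspliced]])
    if (any(unspliced)) {
      cdna[unspliced] <- unspliced_sequence(tx[unspliced], index)
    }

    trunc <- apply_truncation(cdna, truncation)
    umi <- generate_umi(nrow(mol), structure$umi_length)
    assembled <- assemble_molecule(mol$cell_barcode, umi, trunc$sequence,
                                   structure)
    oriented <- orient(assembled)

    out <- tibble::tibble(
      read_id = sprintf("mol_%06d", seq_len(nrow(mol))),
      cell_id = mol$cell_id,
      cell_barcode = mol$cell_barcode,
      umi = umi,
      gene_id = gene,
      transcript_id = tx,
      strand = oriented$strand,
      trunc_start = trunc$trunc_start,
      trunc_end = trunc$trunc_end,
      unspliced = as.integer(unspliced),
      sequence = oriented$sequence
    )
    class(out) <- c("molecule_set", class(out))
    out
  })
}

empty_molecule_set <- function() {
  out <- tibble::tibble(
    read_id = character(), cell_id = character(),
    cell_barcode = character(), umi = character(), gene_id = character(),
    transcript_id = character(), strand = character(),
    trunc_start = integer(), trunc_end = integer(), unspliced = integer(),
    sequence = character()
  )
  class(out) <- c("molecule_set", class(out))
  out
}

# map cell column names to barcodes: whitelist without replacement, or the
# names themselves when already valid, or fresh random distinct barcodes
resolve_barcodes <- function(cells, whitelist, cb_length) {
  if (!is.null(whitelist)) {
    whitelist <- unique(whitelist)
    if (any(!is_dna(whitelist, allow_n = FALSE)) ||
        any(nchar(whitelist) != cb_length)) {
      abort(paste0("whitelist barcodes must be ", cb_length, " nt A/C/G/T"))
    }
    if (length(whitelist) < length(cells)) {
      abort("whitelist smaller than the number of cells")
    }
    bc <- whitelist[seq_along(cells)]
  } else if (all(is_dna(cells, allow_n = FALSE) & nchar(cells) == cb_length) &&
             !anyDuplicated(cells)) {
    bc <- cells
  } else {
    bc <- random_distinct_dna(length(cells), cb_length)
  }
  setNames(bc, cells)
}

#' Write sequences to FASTA
#'
#' @param reads A tibble with `read_id` and `sequence` columns (e.g. a
#'   `molecule_set` or PCR pool).
#' @param path Output FASTA path (`.gz` for compressed).
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  seqs <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  Biostrings::writeXStringSet(seqs, path,
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Read a FASTA file into a tibble
#'
#' @param path FASTA path.
#' @return A tibble with `read_id` and `sequence`.
#' @export
read_reads_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  tibble::tibble(
    read_id = sub("\\s.*$", "", names(seqs)),
    sequence = as.character(unname(seqs))
  )
}

TRUTH_COLUMNS <- c("read_id", "cell_barcode", "umi", "gene_id",
                   "transcript_id", "strand", "trunc_start", "trunc_end",
                   "unspliced")

#' Write the ground-truth table for a molecule set
#'
#' Tab-separated, one row per molecule, columns `read_id`, `cell_barcode`,
#' `umi`, `gene_id`, `transcript_id`, `strand`, `trunc_start`, `trunc_end`,
#' `unspliced`.
#'
#' @param molecules A `molecule_set` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(molecules, path) {
  stopifnot(all(TRUTH_COLUMNS %in% names(molecules)))
  readr::write_tsv(molecules[TRUTH_COLUMNS], path, progress = FALSE)
  invisible(path)
}

#' Read a ground-truth table written by [write_truth()]
#'
#' @param path TSV path.
#' @return A tibble of ground-truth records.
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    trunc_start = "i", trunc_end = "i", unspliced = "i", .default = "c"
  ), progress = FALSE)
}
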