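# shared toy reference for perfect-read generation
tpl_dir <- withr::local_tempdir(.local_envir = teardown_env())
tpl_ref <- make_toy_reference(tpl_dir, n_genes = 5, isoforms_per_gene = 2,
                              seed = 130)
tpl_idx <- load_transcriptome(tpl_ref$transcripts, tpl_ref$gtf,
                              tpl_ref$genome)

test_that("perfect reads conserve counts exactly per (feature, cell)", {
  cm <- make_toy_counts(sprintf("gene%02d", 1:5), 4, mean = 3, seed = 131)
  mol <- generate_perfect_reads(cm, tpl_idx, seed = 132)
  expect_equal(nrow(mol), sum(as.matrix(cm[, -1])))
  got <- mol |>
    dplyr::count(.data$gene_id, .data$cell_id) |>
    tidyr::pivot_wider(names_from = "cell_id", values_from = "n",
                       values_fill = 0L)
  long_cm <- tidyr::pivot_longer(cm, -"feature_id", names_to = "cell_id",
                                 values_to = "n")
  for (i in seq_len(nrow(long_cm))) {
    n_mol <- sum(mol$gene_id == long_cm$feature_id[i] &
                   mol$cell_id == long_cm$cell_id[i])
    expect_equal(n_mol, long_cm$n[i])
  }
  # all-zero matrix: empty output
  zero <- cm
  zero[, -1] <- 0L
  mol0 <- generate_perfect_reads(zero, tpl_idx, seed = 1)
  expect_equal(nrow(mol0), 0)
  # unresolvable features are reported by name
  bad <- cm
  bad$feature_id[1] <- "missing_gene"
  expect_error(generate_perfect_reads(bad, tpl_idx, seed = 1),
               "missing_gene")
})

test_that("perfect reads carry the full structural layout", {
  rs <- read_structure()
  cm <- make_toy_counts(sprintf("gene%02d", 1:5), 6, mean = 2, seed = 133)
  mol <- generate_perfect_reads(cm, tpl_idx, structure = rs, seed = 134)
  # undo orientation using the recorded strand, then check the layout
  fwd <- ifelse(mol$strand == "-", dna_revcomp(mol$sequence), mol$sequence)
  expect_true(all(startsWith(fwd, rs$adapter)))
  expect_true(all(endsWith(fwd, rs$tso)))
  off <- nchar(rs$adapter)
  expect_true(all(substr(fwd, off + 1, off + 16) == mol$cell_barcode))
  expect_true(all(substr(fwd, off + 17, off + 28) == mol$umi))
  # 20-T oligo(dT) spacer at the recorded offset
  expect_true(all(substr(fwd, off + 29, off + 48) == strrep("T", 20)))
  # sequence length identity
  expect_equal(
    nchar(mol$sequence),
    nchar(rs$adapter) + 16 + 12 + 20 + (mol$trunc_end - mol$trunc_start) +
      nchar(rs$tso)
  )
  # truncation coordinates within the cDNA
  expect_true(all(mol$trunc_start >= 0 & mol$trunc_start < mol$trunc_end))
  # spliced molecules: cDNA fragment matches the transcript subsequence
  tx_seq <- as.character(tpl_idx$transcripts[mol$transcript_id])
  frag <- substr(fwd, off + 49, nchar(fwd) - nchar(rs$tso))
  spliced <- mol$unspliced == 0
  expect_true(all(frag[spliced] == substr(tx_seq[spliced],
                                          mol$trunc_start[spliced] + 1,
                                          mol$trunc_end[spliced])))
})

test_that("barcodes come from the whitelist, matrix names or fresh draws", {
  cm <- make_toy_counts(sprintf("gene%02d", 1:5), 3, mean = 1, seed = 135)
  wl <- make_whitelist(10, seed = 136)
  mol <- generate_perfect_reads(cm, tpl_idx, whitelist = wl, seed = 137)
  expect_true(all(mol$cell_barcode %in% wl))
  expect_equal(dplyr::n_distinct(mol$cell_barcode),
               dplyr::n_distinct(mol$cell_id))
  expect_error(
    generate_perfect_reads(cm, tpl_idx, whitelist = wl[1:2], seed = 1),
    "whitelist smaller"
  )
  # matrix columns that are valid 16-mers are used directly
  cm_bc <- cm
  names(cm_bc)[-1] <- make_whitelist(3, seed = 138)
  mol_bc <- generate_perfect_reads(cm_bc, tpl_idx, seed = 139)
  expect_setequal(unique(mol_bc$cell_barcode),
                  intersect(names(cm_bc)[-1], mol_bc$cell_barcode))
  # otherwise distinct random barcodes are drawn
  expect_true(all(nchar(mol$cell_barcode) == 16))
})

test_that("intron retention swaps in unspliced cDNA at the given rate", {
  cm <- make_toy_counts(sprintf("gene%02d", 1:5), 40, mean = 4, seed = 140)
  mol <- generate_perfect_reads(cm, tpl_idx, intron_retention_prob = 0.5,
                                seed = 141)
  frac <- mean(mol$unspliced == 1)
  n <- nrow(mol)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
  # unspliced molecules draw from the genomic span (always >= spliced length)
  uns <- mol[mol$unspliced == 1, ]
  full_len <- nchar(unspliced_sequence(uns$transcript_id, tpl_idx))
  expect_true(all(uns$trunc_end <= full_len))
  # prob 0 never retains introns; without annotation it errors
  mol0 <- generate_perfect_reads(cm, tpl_idx, seed = 142)
  expect_true(all(mol0$unspliced == 0))
  idx_plain <- load_transcriptome(tpl_ref$transcripts)
  cm_tx <- make_toy_counts(names(tpl_idx$transcripts)[1:2], 3, seed = 143)
  expect_error(
    generate_perfect_reads(cm_tx, idx_plain, intron_retention_prob = 0.5,
                           seed = 1),
    "GTF and genome"
  )
})

test_that("transcript-level matrices use the transcript directly", {
  tx_ids <- names(tpl_idx$transcripts)[1:3]
  cm <- make_toy_counts(tx_ids, 4, mean = 2, seed = 144)
  mol <- generate_perfect_reads(cm, tpl_idx, seed = 145)
  expect_true(all(mol$transcript_id %in% tx_ids))
  expect_equal(
    unname(tpl_idx$genes$gene_id[match(mol$transcript_id,
                                       tpl_idx$genes$transcript_id)]),
    mol$gene_id
  )
})

test_that("generation is deterministic: same seed, byte-identical outputs", {
  cm <- make_toy_counts(sprintf("gene%02d", 1:5), 8, mean = 2, seed = 146)
  trunc <- estimate_truncation_model(
    make_synthetic_paf(50, 1000, c(0.1, 0.9), seed = 147), n_bins = 10
  )
  run <- function() {
    mol <- generate_perfect_reads(cm, tpl_idx, truncation = trunc,
                                  intron_retention_prob = 0.2, seed = 148)
    fa <- withr::local_tempfile(fileext = ".fasta")
    tsv <- withr::local_tempfile(fileext = ".tsv")
    write_reads_fasta(mol, fa)
    write_truth(mol, tsv)
    c(readLines(fa), readLines(tsv))
  }
  expect_identical(run(), run())
  # truth TSV round-trips
  mol <- generate_perfect_reads(cm, tpl_idx, seed = 149)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_truth(mol, tsv)
  back <- read_truth(tsv)
  expect_equal(as.data.frame(back),
               as.data.frame(mol[names(back)]))
})
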