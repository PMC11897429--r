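# toy reference on disk, shared across this file
ref_dir <- withr::local_tempdir(.local_envir = teardown_env())
ref <- make_toy_reference(ref_dir, n_genes = 2, isoforms_per_gene = 2,
                          seed = 21)

test_that("transcriptome loading builds the gene/transcript maps", {
  idx <- load_transcriptome(ref$transcripts)
  expect_s3_class(idx, "transcriptome_index")
  expect_equal(length(idx$transcripts), 4)   # 2 genes x 2 isoforms
  # without GTF, each transcript is its own gene
  expect_equal(idx$genes$gene_id, idx$genes$transcript_id)

  idx2 <- load_transcriptome(ref$transcripts, ref$gtf, ref$genome)
  expect_equal(sort(unique(idx2$genes$gene_id)), c("gene01", "gene02"))
  expect_equal(nrow(idx2$genes), 4)
  expect_equal(
    sum(idx2$genes$gene_id == "gene01"), 2
  )
  # sequences survive indexing unaltered
  raw <- Biostrings::readDNAStringSet(ref$transcripts)
  expect_equal(as.character(idx2$transcripts[[names(raw)[1]]]),
               as.character(raw[[1]]))
})

test_that("GTF transcripts missing from the FASTA are skipped with a warning", {
  gtf_extra <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    readLines(ref$gtf),
    "chr1\ttoy\texon\t1\t50\t.\t+\t.\tgene_id \"ghost\"; transcript_id \"ghost.t1\";"
  ), gtf_extra)
  expect_warning(
    idx <- load_transcriptome(ref$transcripts, gtf_extra, ref$genome),
    "absent from FASTA"
  )
  expect_false("ghost.t1" %in% idx$genes$transcript_id)
})

test_that("empty FASTA is rejected", {
  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_error(load_transcriptome(empty))
})

test_that("transcript choice follows the exp(-L/tau) length prior", {
  idx <- toy_index(c(s = 500, l = 5000))
  expect_error(pick_transcript("nope", idx), "unknown gene")
  # single-transcript gene: always that transcript
  idx1 <- toy_index(c(only = 300))
  expect_true(all(pick_transcript(rep("g", 50), idx1) == "only"))
  # equal lengths: 0.5 each +- 3 SE
  idx_eq <- toy_index(c(a = 1000, b = 1000))
  set.seed(17)
  d <- pick_transcript(rep("g", 10000), idx_eq)
  expect_lt(abs(mean(d == "a") - 0.5), 3 * sqrt(0.25 / 10000))
  # closed form: lengths 500/5000 nt, tau 2000
  #   P(short) = exp(-0.25) / (exp(-0.25) + exp(-2.5)) ~ 0.9047
  set.seed(18)
  d2 <- pick_transcript(rep("g", 10000), idx, tau = 2000)
  p_short <- exp(-500 / 2000) / (exp(-500 / 2000) + exp(-5000 / 2000))
  expect_lt(abs(mean(d2 == "s") - p_short), 0.01)
})

test_that("unspliced sequences retain introns and respect strand", {
  idx <- load_transcriptome(ref$transcripts, ref$gtf, ref$genome)
  # full isoform t1 spans all exons; its unspliced length is the genomic span
  exons <- idx$exons
  for (tx in unique(exons$transcript_id)) {
    e <- exons[exons$transcript_id == tx, ]
    uns <- unspliced_sequence(tx, idx)
    expect_equal(nchar(uns), max(e$end) - min(e$start))
    spliced_len <- sum(e$end - e$start)
    expect_gte(nchar(uns), spliced_len)
    # brute-force reconstruction from the genome
    genome <- as.character(idx$genome[[unique(e$chrom)]])
    span <- substr(genome, min(e$start) + 1, max(e$end))
    if (unique(e$strand) == "-") span <- dna_revcomp(span)
    expect_equal(uns, span)
  }
  # single-exon case degenerates to the spliced sequence
  one_exon_gtf <- withr::local_tempfile(fileext = ".gtf")
  g1 <- idx$exons[idx$exons$transcript_id == idx$exons$transcript_id[1], ][1, ]
  writeLines(sprintf(
    "%s\ttoy\texon\t%d\t%d\t.\t%s\t.\tgene_id \"solo\"; transcript_id \"%s\";",
    g1$chrom, g1$start + 1L, g1$end, g1$strand, "solo.t1"
  ), one_exon_gtf)
  fa <- withr::local_tempfile(fileext = ".fa")
  seq1 <- substr(as.character(idx$genome[[g1$chrom]]), g1$start + 1, g1$end)
  if (g1$strand == "-") seq1 <- dna_revcomp(seq1)
  writeLines(c(">solo.t1", seq1), fa)
  idx_solo <- load_transcriptome(fa, one_exon_gtf, ref$genome)
  expect_equal(unspliced_sequence("solo.t1", idx_solo), seq1)
  # intron retention without annotation is refused with guidance
  expect_error(unspliced_sequence("x", toy_index()), "GTF and genome")
})
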