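# Independent oracles and small fixture builders shared across tests.

# Gap-included identity of read vs template by global alignment:
# matched columns over all alignment columns (gaps count). Edit-distance
# style scoring, computed by Biostrings, independent of inject_errors().
aligned_identity_oracle <- function(read, template) {
  aln <- Biostrings::pairwiseAlignment(
    read, template, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1
    ),
    gapOpening = 0, gapExtension = 1
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sum(p == s & p != "-") / length(p)
}

# Column-by-column identity oracle for a CIGAR over ops =, X, I, D:
# expands the alignment and counts columns under each definition.
cigar_identity_oracle <- function(cigar, mode) {
  m <- stringr::str_match_all(cigar, "(\\d+)([=XID])")[[1]]
  len <- as.integer(m[, 2])
  op <- m[, 3]
  matches <- sum(len[op == "="])
  aligned_cols <- sum(len[op %in% c("=", "X")])
  gap_cols <- sum(len[op %in% c("I", "D")])
  gap_runs <- sum(op %in% c("I", "D"))
  denom <- switch(mode,
    gap_included = aligned_cols + gap_cols,
    gap_excluded = aligned_cols,
    gap_compressed = aligned_cols + gap_runs
  )
  matches / denom
}

# random CIGAR with no two consecutive identical ops (as real aligners emit)
random_cigar <- function() {
  n_ops <- sample(3:10, 1)
  ops <- character(n_ops)
  ops[1] <- sample(c("=", "X"), 1)          # start aligned
  for (i in seq_len(n_ops)[-1]) {
    ops[i] <- sample(setdiff(c("=", "X", "I", "D"), ops[i - 1]), 1)
  }
  if (!any(ops == "=")) ops[sample(n_ops, 1)] <- "="
  len <- sample(1:30, n_ops, replace = TRUE)
  paste0(paste0(len, ops), collapse = "")
}

# PAF row realizing a given CIGAR (fields consistent with the expansion)
paf_from_cigar <- function(cigar) {
  m <- stringr::str_match_all(cigar, "(\\d+)([=XID])")[[1]]
  len <- as.integer(m[, 2])
  op <- m[, 3]
  tibble::tibble(
    query_name = "q", query_length = sum(len[op %in% c("=", "X", "I")]),
    query_start = 0L, query_end = sum(len[op %in% c("=", "X", "I")]),
    strand = "+", target_name = "t",
    target_length = sum(len[op %in% c("=", "X", "D")]),
    target_start = 0L, target_end = sum(len[op %in% c("=", "X", "D")]),
    n_matches = sum(len[op == "="]),
    block_len = sum(len),
    mapq = 60L, cigar = cigar, tp = "P"
  )
}

# two-gene index with known transcript lengths, no annotation
toy_index <- function(lengths = c(s = 500, l = 5000), gene = "g") {
  seqs <- Biostrings::DNAStringSet(setNames(
    vapply(lengths, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1)),
    names(lengths)
  ))
  structure(
    list(
      transcripts = seqs,
      genes = tibble::tibble(gene_id = gene,
                             transcript_id = names(lengths),
                             tx_length = as.integer(lengths)),
      exons = NULL, genome = NULL
    ),
    class = "transcriptome_index"
  )
}

# Galton-Watson variance of the pool size after n cycles: offspring per
# molecule is 1 + Bernoulli(p), so m = 1 + p, sigma^2 = p(1-p), and
# Var(Z_n) = N sigma^2 m^(n-1) (m^n - 1)/(m - 1)
gw_pool_sd <- function(n_input, p_dup, cycles) {
  m <- 1 + p_dup
  s2 <- p_dup * (1 - p_dup)
  if (s2 == 0) return(0)
  sqrt(n_input * s2 * m^(cycles - 1) * (m^cycles - 1) / (m - 1))
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
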