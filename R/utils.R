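DNA_BASES <- c("A", "C", "G", "T")

# stage offsets for deriving per-stage seeds from one global seed
.stage_offsets <- c(
  counts = 1L, barcodes = 2L, templates = 3L, pcr = 4L,
  errors = 5L, qc = 6L, reference = 7L, paf = 8L
)

derive_seed <- function(seed, stage) {
  stopifnot(stage %in% names(.stage_offsets))
  (as.integer(seed) + .stage_offsets[[stage]] * 7919L) %% 2147483647L
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

is_dna <- function(x, allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  !is.na(x) & grepl(pat, x)
}

#' Reverse complement of DNA strings
#'
#' Character-vector convenience around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of A/C/G/T/N sequences.
#' @return Character vector of reverse complements.
#' @examples
#' dna_revcomp(c("AAAC", "ACGT"))
#' @export
dna_revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n, width) {
  if (n == 0) return(character(0))
  m <- matrix(sample(DNA_BASES, n * width, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# n distinct random barcodes; width 16 gives 4^16 combinations so rejection
# sampling terminates immediately at realistic n
random_distinct_dna <- function(n, width) {
  out <- unique(random_dna(n, width))
  while (length(out) < n) {
    out <- unique(c(out, random_dna(n - length(out), width)))
  }
  out
}
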