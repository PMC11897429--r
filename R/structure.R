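# Default construct constants for a 10x Chromium 3' v3 library read on
# Nanopore: partial Illumina read-1 primer as the 10x/Nanopore composite
# adapter, the 10x template-switch oligo, 16 nt cell barcode, 12 nt UMI.
DEFAULT_ADAPTER <- "CTACACGACGCTCTTCCGATCT"
DEFAULT_TSO <- "ATGTACTCTGCGTTGATACCACTGCTT"

#' Describe the library-molecule read structure
#'
#' A perfect read is the concatenation
#' `adapter + cell barcode + UMI + oligo(dT) + cDNA + TSO`. Defaults follow
#' the 10x Chromium 3' v3 geometry (16 nt barcode, 12 nt UMI) with a 20 nt
#' oligo(dT) spacer; adapter and TSO strings are overridable.
#'
#' @param adapter 5' adapter sequence (A/C/G/T).
#' @param tso 3' template-switch-oligo sequence (A/C/G/T).
#' @param cb_length Cell-barcode length in nt.
#' @param umi_length UMI length in nt.
#' @param polyt_length oligo(dT) length in nt (default 20).
#' @return A `read_structure` object.
#' @export
read_structure <- function(adapter = DEFAULT_ADAPTER, tso = DEFAULT_TSO,
                           cb_length = 16L, umi_length = 12L,
                           polyt_length = 20L) {
  if (!nzchar(adapter) || !is_dna(adapter, allow_n = FALSE)) {
    abort("adapter must be a non-empty A/C/G/T string")
  }
  if (!nzchar(tso) || !is_dna(tso, allow_n = FALSE)) {
    abort("tso must be a non-empty A/C/G/T string")
  }
  if (cb_length < 1 || umi_length < 1 || polyt_length < 0) {
    abort("cb_length and umi_length must be >= 1, polyt_length >= 0")
  }
  structure(
    list(
      adapter = adapter, tso = tso,
      cb_length = as.integer(cb_length),
      umi_length = as.integer(umi_length),
      polyt_length = as.integer(polyt_length)
    ),
    class = "read_structure"
  )
}

#' @export
print.read_structure <- function(x, ...) {
  cat("<read_structure> adapter(", nchar(x$adapter), ") + CB(", x$cb_length,
      ") + UMI(", x$umi_length, ") + polyT(", x$polyt_length,
      ") + cDNA + TSO(", nchar(x$tso), ")\n", sep = "")
  invisible(x)
}

#' Generate random UMI sequences
#'
#' Uniform independent A/C/G/T strings; collisions are allowed, as in a real
#' library. Uses the current RNG state, so wrap in a seeded context (or
#' `set.seed()`) for reproducibility.
#'
#' @param n Number of UMIs.
#' @param umi_length UMI length in nt (>= 1).
#' @return Character vector of `n` UMIs.
#' @export
generate_umi <- function(n, umi_length = 12L) {
  if (umi_length < 1) abort("umi_length must be >= 1")
  random_dna(n, umi_length)
}

#' Assemble library molecules from their parts
#'
#' Concatenates, in order: adapter, cell barcode, UMI, `polyt_length`
#' consecutive T, the cDNA fragment, TSO. Vectorized over molecules.
#'
#' @param cell_barcode,umi,cdna_fragment Character vectors (recycled to a
#'   common length); barcode and UMI lengths must match `structure`.
#' @param structure A [read_structure()].
#' @return Character vector of assembled sequences.
#' @export
assemble_molecule <- function(cell_barcode, umi, cdna_fragment,
                              structure = read_structure()) {
  stopifnot(inherits(structure, "read_structure"))
  if (any(nchar(cell_barcode) != structure$cb_length)) {
    abort(paste0("cell barcodes must be ", structure$cb_length, " nt"))
  }
  if (any(nchar(umi) != structure$umi_length)) {
    abort(paste0("UMIs must be ", structure$umi_length, " nt"))
  }
  paste0(
    structure$adapter, cell_barcode, umi,
    strrep("T", structure$polyt_length), cdna_fragment, structure$tso
  )
}

#' Randomly orient sequences
#'
#' Each sequence keeps its original strand (`+`) or is reverse-complemented
#' (`-`) with equal probability, mimicking the strand-agnostic Nanopore
#' library. Uses the current RNG state.
#'
#' @param sequence Character vector of A/C/G/T/N sequences.
#' @return A tibble with columns `sequence` (possibly reverse-complemented)
#'   and `strand` (`+` or `-`).
#' @export
orient <- function(sequence) {
  if (any(!is_dna(sequence))) abort("sequences must be over A/C/G/T/N")
  flip <- runif(length(sequence)) < 0.5
  out <- sequence
  if (any(flip)) out[flip] <- dna_revcomp(sequence[flip])
  tibble::tibble(sequence = out, strand = ifelse(flip, "-", "+"))
}
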