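# hard cap on the in-memory pool; past this the branching process would
# exhaust memory long before finishing
POOL_LIMIT <- 2e7

#' Mutate a copied sequence with per-base PCR errors
#'
#' Each non-N base mutates independently with probability `p_error`
#' (implemented as a binomial draw of the mutation count followed by
#' position sampling — distributionally identical but fast at realistic
#' polymerase error rates); a mutated base is replaced uniformly by one of
#' the other three bases. Uses the current RNG state.
#'
#' @param sequence A single A/C/G/T/N string.
#' @param p_error Per-base mutation probability in \[0, 1\].
#' @return A list with `sequence` (mutated copy) and `n_mutations`.
#' @export
mutate_copy <- function(sequence, p_error) {
  stopifnot(length(sequence) == 1)
  r <- mutate_copies(sequence, p_error)
  list(sequence = r$sequence, n_mutations = r$n_mutations)
}

# vectorized core: mutate many copies at once
mutate_copies <- function(seqs, p_error) {
  if (p_error < 0 || p_error > 1) abort("p_error must be in [0, 1]")
  n <- length(seqs)
  if (n == 0 || p_error == 0) {
    return(list(sequence = seqs, n_mutations = integer(n)))
  }
  len <- nchar(seqs)
  n_n <- stringr::str_count(seqs, "N")          # N positions never mutate
  k <- rbinom(n, len - n_n, p_error)
  hit <- which(k > 0)
  for (i in hit) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    eligible <- which(chars != "N")
    pos <- if (length(eligible) == k[i]) eligible else
      sample(eligible, k[i])
    for (p in pos) {
      chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  list(sequence = seqs, n_mutations = k)
}

#' Simulate PCR amplification of a molecule pool
#'
#' Branching-process model of PCR bias: the pool starts as the input
#' molecules; at each cycle every molecule currently in the pool
#' independently spawns one copy with probability `p_dup`, and each copy is
#' mutated at `p_error` per base ([mutate_copy()]). Copies are made from the
#' current — possibly already mutated — template, so errors propagate to
#' descendants, creating UMI-duplicate families that share mutations.
#' Expected final pool size is `N * (1 + p_dup)^cycles`. Optionally a
#' uniform subsample of `sample_size` molecules is drawn after the last
#' cycle ([subsample_pool()]), mimicking loading only part of the product on
#' the flow cell.
#'
#' @param molecules A tibble with `read_id` and `sequence` columns (e.g. a
#'   `molecule_set`).
#' @param cycles Number of PCR cycles (>= 0).
#' @param p_dup Per-cycle duplication probability (default 0.9).
#' @param p_error Per-base mutation probability per copy event
#'   (default 3.5e-5).
#' @param sample_size Optional final subsample size.
#' @param seed Optional integer seed.
#' @return A `pcr_pool` tibble: `read_id` (unique), `origin_read_id`
#'   (ancestral molecule), `n_mutations` (cumulative substitutions relative
#'   to the ancestor) and `sequence`. Aggregate statistics (input size,
#'   final size before subsampling, total bases copied, total mutation
#'   events) are attached and surfaced by [glance()].
#' @export
pcr_amplify <- function(molecules, cycles, p_dup = 0.9, p_error = 3.5e-5,
                        sample_size = NULL, seed = NULL) {
  stopifnot(all(c("read_id", "sequence") %in% names(molecules)))
  if (cycles < 0) abort("cycles must be >= 0")
  if (p_dup < 0 || p_dup > 1) abort("p_dup must be in [0, 1]")
  if (anyDuplicated(molecules$read_id)) abort("duplicate input read ids")
  with_seed(seed, {
    origin <- molecules$read_id
    seqs <- molecules$sequence
    nmut <- integer(length(seqs))
    bases_copied <- 0
    mutation_events <- 0
    for (cyc in seq_len(cycles)) {
      idx <- which(runif(length(seqs)) < p_dup)
      if (length(seqs) + length(idx) > POOL_LIMIT) {
        abort(paste0(
          "PCR pool would exceed ", format(POOL_LIMIT, scientific = FALSE),
          " molecules; reduce cycles, input size or p_dup"
        ))
      }
      if (length(idx) > 0) {
        copies <- mutate_copies(seqs[idx], p_error)
        bases_copied <- bases_copied + sum(nchar(seqs[idx]))
        mutation_events <- mutation_events + sum(copies$n_mutations)
        origin <- c(origin, origin[idx])
        nmut <- c(nmut, nmut[idx] + copies$n_mutations)
        seqs <- c(seqs, copies$sequence)
      }
    }
    n_final <- length(seqs)
    is_copy <- seq_along(seqs) > nrow(molecules)
    out <- tibble::tibble(
      read_id = ifelse(is_copy,
                       sprintf("amp_%07d", cumsum(is_copy)),
                       origin),
      origin_read_id = origin,
      n_mutations = nmut,
      sequence = seqs
    )
    out <- new_pcr_pool(out, stats = list(
      n_input = nrow(molecules), cycles = cycles, p_dup = p_dup,
      p_error = p_error, n_amplified = n_final,
      bases_copied = bases_copied, mutation_events = mutation_events
    ))
    if (!is.null(sample_size)) out <- subsample_pool(out, sample_size)
    out
  })
}

new_pcr_pool <- function(df, stats) {
  attr(df, "pcr_stats") <- stats
  class(df) <- c("pcr_pool", setdiff(class(df), "pcr_pool"))
  df
}

#' Uniformly subsample a molecule pool
#'
#' Sampling is without replacement and the output order is randomized,
#' mimicking sequencing only a random subset of the PCR product.
#'
#' @param pool A tibble of molecules (e.g. a `pcr_pool`).
#' @param n Subsample size; must not exceed the pool size.
#' @param seed Optional integer seed.
#' @return The subsampled pool; `pcr_stats` attributes are preserved.
#' @export
subsample_pool <- function(pool, n, seed = NULL) {
  if (n > nrow(pool)) {
    abort(paste0("cannot sample ", n, " molecules from a pool of ",
                 nrow(pool)))
  }
  stats <- attr(pool, "pcr_stats")
  out <- with_seed(seed, pool[sample.int(nrow(pool), n), , drop = FALSE])
  if (!is.null(stats)) out <- new_pcr_pool(tibble::as_tibble(out), stats)
  out
}
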