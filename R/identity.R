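IDENTITY_MODES <- c("gap_included", "gap_excluded", "gap_compressed")

#' Per-alignment sequence identity from PAF records
#'
#' Three standard definitions over an alignment of `m` residue matches:
#' * `gap_included` — `m /` total alignment columns, gap columns counted
#'   (PAF residue matches over block length);
#' * `gap_excluded` — `m / ` aligned (non-gap) columns only;
#' * `gap_compressed` — `m / (aligned columns + number of gap runs)`:
#'   each insertion or deletion run counts as one column, the definition
#'   minimap2 reports as gap-compressed identity.
#'
#' `gap_excluded` and `gap_compressed` require a CIGAR string.
#'
#' @param paf Alignments as a tibble from [read_paf()] (columns
#'   `n_matches`, `block_len`, `cigar`).
#' @param mode One of `"gap_included"`, `"gap_excluded"`,
#'   `"gap_compressed"`.
#' @return Numeric vector of identities in \[0, 1\].
#' @export
alignment_identity <- function(paf, mode = c("gap_included", "gap_excluded",
                                             "gap_compressed")) {
  mode <- match.arg(mode)
  stopifnot(all(c("n_matches", "block_len") %in% names(paf)))
  if (any(paf$block_len <= 0)) abort("zero-length alignment")
  if (mode == "gap_included") {
    return(paf$n_matches / paf$block_len)
  }
  if (is.null(paf$cigar) || anyNA(paf$cigar)) {
    abort(paste0("mode '", mode, "' requires a CIGAR string (cg:Z tag)"))
  }
  ops <- parse_cigar(paf$cigar)
  denom <- vapply(ops, function(o) {
    aligned <- sum(o$len[o$op %in% c("M", "=", "X")])
    if (mode == "gap_excluded") aligned
    else aligned + sum(o$op %in% c("I", "D", "N"))  # each gap run once
  }, numeric(1))
  if (any(denom <= 0)) abort("CIGAR with no aligned columns")
  paf$n_matches / denom
}

# list of (op, len) per CIGAR string
parse_cigar <- function(cigar) {
  m <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")
  bad <- vapply(m, nrow, integer(1)) == 0
  if (any(bad)) abort("unparseable CIGAR string")
  lapply(m, function(x) list(len = as.integer(x[, 2]), op = x[, 3]))
}

#' Fit a beta distribution to read identities
#'
#' The read-identity model: per-read alignment identities are clamped
#' `1e-6` away from the \[0, 1\] boundaries (where the beta likelihood is
#' undefined), a method-of-moments fit provides starting values, and the
#' shape parameters are refined by maximum likelihood.
#'
#' @param identities Numeric vector of identities; at least 10 values
#'   strictly inside (0, 1) after clamping, with positive variance.
#' @param mode Identity definition the values were computed under (recorded
#'   in the model).
#' @return An `identity_model` object with `alpha`, `beta`, `mode`, `n` and
#'   `loglik`. Has [tidy()] and [glance()] methods.
#' @export
fit_identity_beta <- function(identities, mode = "gap_included") {
  mode <- match.arg(mode, IDENTITY_MODES)
  x <- identities[!is.na(identities)]
  if (any(x < 0 | x > 1)) abort("identities must lie in [0, 1]")
  x <- pmin(pmax(x, 1e-6), 1 - 1e-6)
  if (length(x) < 10) abort("need at least 10 identity values")
  m <- mean(x)
  v <- var(x)
  if (v < 1e-12) {
    abort("zero variance in identities; use a fixed identity instead of a beta model")
  }
  conc <- m * (1 - m) / v - 1
  if (conc <= 0) conc <- 1            # MoM outside the beta family; fall back
  start <- log(c(m * conc, (1 - m) * conc))
  nll <- function(p) -sum(dbeta(x, exp(p[1]), exp(p[2]), log = TRUE))
  fit <- optim(start, nll, method = "BFGS")
  structure(
    list(alpha = exp(fit$par[1]), beta = exp(fit$par[2]), mode = mode,
         n = length(x), loglik = -fit$value),
    class = "identity_model"
  )
}

#' Build an identity model from known shape parameters
#'
#' @param alpha,beta Beta shape parameters (> 0).
#' @param mode Identity definition label.
#' @return An `identity_model`.
#' @export
identity_model <- function(alpha, beta, mode = "gap_included") {
  mode <- match.arg(mode, IDENTITY_MODES)
  if (alpha <= 0 || beta <= 0) abort("alpha and beta must be > 0")
  structure(
    list(alpha = alpha, beta = beta, mode = mode, n = NA_integer_,
         loglik = NA_real_),
    class = "identity_model"
  )
}

#' @export
print.identity_model <- function(x, ...) {
  cat("<identity_model> Beta(", signif(x$alpha, 4), ", ", signif(x$beta, 4),
      "), mean identity ", signif(x$alpha / (x$alpha + x$beta), 4),
      " [", x$mode, "]\n", sep = "")
  invisible(x)
}

#' Draw per-read identities from an identity model
#'
#' @param model An `identity_model`.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Numeric vector of identities in (0, 1).
#' @export
sample_read_identity <- function(model, n = 1, seed = NULL) {
  stopifnot(inherits(model, "identity_model"))
  with_seed(seed, rbeta(n, model$alpha, model$beta))
}
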