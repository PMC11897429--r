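#' Read a feature-by-cell UMI count matrix from CSV
#'
#' The dialect is fixed: features as rows, one header row of cell barcodes,
#' the first column holding feature identifiers (genes or transcripts),
#' comma-separated, UTF-8. Entries must be non-negative integers.
#'
#' @param path Path to a CSV file.
#' @return A tibble whose first column is `feature_id` and whose remaining
#'   columns are integer UMI counts, one column per cell.
#' @seealso [write_count_matrix()] for the inverse operation.
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("count matrix file not found: ", path))
  header <- strsplit(readr::read_lines(path, n_max = 1), ",")[[1]]
  if (anyDuplicated(header[-1])) {
    abort(paste0(
      "duplicate cell barcodes in header: ",
      paste(unique(header[-1][duplicated(header[-1])]), collapse = ", ")
    ))
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (ncol(df) < 1) abort("malformed count matrix CSV: no columns")
  names(df)[1] <- "feature_id"
  for (cell in names(df)[-1]) {
    x <- suppressWarnings(as.numeric(df[[cell]]))
    if (anyNA(x) && !all(is.na(df[[cell]][is.na(x)]))) {
      bad <- df$feature_id[which(is.na(x) & !is.na(df[[cell]]))[1]]
      abort(paste0("non-numeric count at feature '", bad, "', cell '",
                   cell, "'"))
    }
    df[[cell]] <- x
  }
  validate_count_matrix(df)
}

#' Validate a count matrix tibble
#'
#' Checks the invariants of a UMI count matrix: unique feature ids and cell
#' barcodes, and integer counts >= 0. Count columns are coerced to integer.
#'
#' @param counts A data frame: first column `feature_id`, remaining columns
#'   numeric counts.
#' @return The validated tibble, count columns as integers.
#' @export
validate_count_matrix <- function(counts) {
  counts <- tibble::as_tibble(counts)
  if (ncol(counts) < 1 || names(counts)[1] != "feature_id") {
    abort("count matrix must have 'feature_id' as its first column")
  }
  feats <- counts$feature_id
  if (anyDuplicated(feats)) {
    abort(paste0(
      "duplicate feature ids: ",
      paste(unique(feats[duplicated(feats)]), collapse = ", ")
    ))
  }
  cells <- names(counts)[-1]
  if (anyDuplicated(cells)) {
    abort(paste0(
      "duplicate cell barcodes: ",
      paste(unique(cells[duplicated(cells)]), collapse = ", ")
    ))
  }
  for (cell in cells) {
    x <- counts[[cell]]
    if (!is.numeric(x)) {
      abort(paste0("non-numeric counts in column '", cell, "'"))
    }
    bad <- which(is.na(x) | x < 0 | x != floor(x))
    if (length(bad) > 0) {
      abort(paste0(
        "invalid count (negative, missing or non-integer) at feature '",
        feats[bad[1]], "', cell '", cell, "'"
      ))
    }
    counts[[cell]] <- as.integer(x)
  }
  counts
}

#' Write a count matrix to CSV
#'
#' Writes the dialect accepted by [read_count_matrix()]: features as rows,
#' header row of cell barcodes, first column of feature ids.
#'
#' @param counts A count matrix tibble (see [validate_count_matrix()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  counts <- validate_count_matrix(counts)
  readr::write_csv(counts, path, progress = FALSE)
  invisible(path)
}

#' Estimate count-simulation parameters from a UMI count matrix
#'
#' Fits the Gamma–Poisson (negative binomial) count model used by
#' [simulate_counts()]. Per-cell library-size factors are the cell totals
#' divided by the median cell total; per-feature means are averages of
#' factor-normalized counts; per-feature dispersions come from the method of
#' moments (excess variance beyond the Poisson expectation, floored at 0);
#' the library-size factor distribution is summarized by the mean and sd of
#' its log.
#'
#' For counts `X` with size factor `s`, `Var(X/s) = mu/s + phi * mu^2`, so
#' `phi = (v - m * mean(1/s)) / m^2` with `m`, `v` the sample mean and
#' variance of normalized counts.
#'
#' @param counts A count matrix tibble (first column `feature_id`).
#' @return A `count_fit` object: a list with a per-feature tibble
#'   (`feature_id`, `mean`, `dispersion`) plus `libsize_log_mean`,
#'   `libsize_log_sd` and `n_cells`. Has [tidy()] and [glance()] methods.
#' @export
estimate_count_params <- function(counts) {
  counts <- validate_count_matrix(counts)
  if (ncol(counts) < 2) abort("count matrix has no cells")
  mat <- as.matrix(counts[, -1, drop = FALSE])
  rownames(mat) <- counts$feature_id
  totals <- colSums(mat)
  if (all(totals == 0)) abort("all-zero count matrix: nothing to estimate")
  if (any(totals == 0)) {
    warn(paste0(
      sum(totals == 0),
      " cell(s) with zero total counts excluded from estimation"
    ))
    mat <- mat[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  sf <- totals / median(totals)
  norm <- sweep(mat, 2, sf, "/")
  m <- rowMeans(norm)
  if (ncol(mat) > 1) {
    v <- apply(norm, 1, var)
    phi <- ifelse(m > 0, pmax(0, (v - m * mean(1 / sf)) / m^2), 0)
  } else {
    phi <- rep(0, length(m))
  }
  structure(
    list(
      features = tibble::tibble(
        feature_id = counts$feature_id,
        mean = unname(m),
        dispersion = unname(phi)
      ),
      libsize_log_mean = mean(log(sf)),
      libsize_log_sd = if (length(sf) > 1) sd(log(sf)) else 0,
      n_cells = ncol(mat)
    ),
    class = "count_fit"
  )
}

#' Build count-model parameters directly
#'
#' Constructs the same object [estimate_count_params()] returns, from
#' user-chosen values, so synthetic matrices can be simulated without a
#' reference matrix.
#'
#' @param feature_mean Non-negative per-feature mean expression (UMIs per
#'   unit library size).
#' @param feature_dispersion Non-negative per-feature Gamma–Poisson
#'   dispersion; 0 means Poisson. Recycled to the length of `feature_mean`.
#' @param libsize_log_mean,libsize_log_sd Parameters of the log-normal
#'   per-cell library-size factor distribution.
#' @param feature_ids Feature identifiers; defaults to `gene_1 ...`.
#' @return A `count_fit` object.
#' @export
count_params <- function(feature_mean, feature_dispersion = 0,
                         libsize_log_mean = 0, libsize_log_sd = 0,
                         feature_ids = NULL) {
  n <- length(feature_mean)
  feature_dispersion <- rep_len(feature_dispersion, n)
  if (any(feature_mean < 0)) abort("feature_mean must be >= 0")
  if (any(feature_dispersion < 0)) abort("feature_dispersion must be >= 0")
  if (libsize_log_sd < 0) abort("libsize_log_sd must be >= 0")
  feature_ids <- feature_ids %||% sprintf("gene_%d", seq_len(n))
  if (anyDuplicated(feature_ids)) abort("duplicate feature_ids")
  structure(
    list(
      features = tibble::tibble(
        feature_id = feature_ids,
        mean = as.numeric(feature_mean),
        dispersion = as.numeric(feature_dispersion)
      ),
      libsize_log_mean = libsize_log_mean,
      libsize_log_sd = libsize_log_sd,
      n_cells = NA_integer_
    ),
    class = "count_fit"
  )
}

#' @export
print.count_fit <- function(x, ...) {
  cat("<count_fit> Gamma-Poisson count model:", nrow(x$features),
      "features\n")
  cat("  libsize log-mean", signif(x$libsize_log_mean, 3),
      " log-sd", signif(x$libsize_log_sd, 3), "\n")
  print(x$features, n = 5)
  invisible(x)
}

#' Simulate a synthetic UMI count matrix
#'
#' Draws one log-normal library-size factor per cell, then each count from a
#' Gamma–Poisson mixture with mean `feature mean * size factor` and the
#' feature's dispersion (`Var = mu + phi * mu^2`); dispersion 0 degenerates
#' to Poisson. Identical seeds give identical matrices.
#'
#' @param params A `count_fit` object from [estimate_count_params()] or
#'   [count_params()].
#' @param n_cells Number of cells to simulate (>= 1).
#' @param seed Integer seed.
#' @param cell_ids Optional cell column names; defaults to `cell_1 ...`.
#' @return A count matrix tibble (first column `feature_id`).
#' @export
simulate_counts <- function(params, n_cells, seed = 1L, cell_ids = NULL) {
  stopifnot(inherits(params, "count_fit"))
  if (n_cells < 1) abort("n_cells must be >= 1")
  cell_ids <- cell_ids %||% sprintf("cell_%d", seq_len(n_cells))
  if (length(cell_ids) != n_cells) abort("cell_ids length must be n_cells")
  ft <- params$features
  with_seed(seed, {
    sf <- rlnorm(n_cells, params$libsize_log_mean, params$libsize_log_sd)
    mat <- matrix(0L, nrow = nrow(ft), ncol = n_cells)
    for (i in seq_len(nrow(ft))) {
      mu <- ft$mean[i] * sf
      mat[i, ] <- if (ft$dispersion[i] > 0) {
        rnbinom(n_cells, mu = mu, size = 1 / ft$dispersion[i])
      } else {
        rpois(n_cells, mu)
      }
    }
    out <- tibble::as_tibble(
      as.data.frame(mat, col.names = cell_ids),
      .name_repair = "minimal"
    )
    names(out) <- cell_ids
    dplyr::bind_cols(tibble::tibble(feature_id = ft$feature_id), out)
  })
}
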