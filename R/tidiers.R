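#' Tidy a fitted count model
#'
#' @param x A `count_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per feature: `feature_id`, `mean`,
#'   `dispersion`.
#' @method tidy count_fit
#' @export
tidy.count_fit <- function(x, ...) x$features

#' One-row summary of a fitted count model
#'
#' @param x A `count_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: feature and cell counts, library-size
#'   parameters, median feature mean and dispersion.
#' @method glance count_fit
#' @export
glance.count_fit <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$features),
    n_cells = x$n_cells,
    libsize_log_mean = x$libsize_log_mean,
    libsize_log_sd = x$libsize_log_sd,
    median_mean = median(x$features$mean),
    median_dispersion = median(x$features$dispersion)
  )
}

#' Tidy a truncation model
#'
#' @param x A `truncation_model` object.
#' @param ... Unused.
#' @return A tibble with one row per occupied histogram cell:
#'   `rel_start_lo`, `rel_start_hi`, `rel_end_lo`, `rel_end_hi`, `prob`.
#' @method tidy truncation_model
#' @export
tidy.truncation_model <- function(x, ...) {
  grid <- expand.grid(start_bin = seq_len(x$n_bins),
                      end_bin = seq_len(x$n_bins))
  out <- tibble::tibble(
    rel_start_lo = x$breaks[grid$start_bin],
    rel_start_hi = x$breaks[grid$start_bin + 1L],
    rel_end_lo = x$breaks[grid$end_bin],
    rel_end_hi = x$breaks[grid$end_bin + 1L],
    prob = x$prob[cbind(grid$start_bin, grid$end_bin)]
  )
  dplyr::filter(out, .data$prob > 0)
}

#' Plot a truncation model as a heatmap over the unit square
#'
#' @param object A `truncation_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot truncation_model
#' @export
autoplot.truncation_model <- function(object, ...) {
  df <- tidy.truncation_model(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$rel_start_lo + .data$rel_start_hi) / 2,
    y = (.data$rel_end_lo + .data$rel_end_hi) / 2,
    fill = .data$prob
  )) +
    ggplot2::geom_tile() +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Relative 5' start", y = "Relative 3' end",
                  fill = "Probability") +
    ggplot2::theme_minimal()
}

#' Tidy an identity model
#'
#' @param x An `identity_model` object.
#' @param ... Unused.
#' @return A two-row tibble of shape parameters (`term`, `estimate`).
#' @method tidy identity_model
#' @export
tidy.identity_model <- function(x, ...) {
  tibble::tibble(term = c("alpha", "beta"),
                 estimate = c(x$alpha, x$beta))
}

#' One-row summary of an identity model
#'
#' @param x An `identity_model` object.
#' @param ... Unused.
#' @return A one-row tibble: `alpha`, `beta`, implied `mean_identity`,
#'   identity `mode`, sample size `n` and `loglik` of the fit.
#' @method glance identity_model
#' @export
glance.identity_model <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha, beta = x$beta,
    mean_identity = x$alpha / (x$alpha + x$beta),
    mode = x$mode, n = x$n, loglik = x$loglik
  )
}

#' Plot the density of an identity model
#'
#' @param object An `identity_model`.
#' @param ... Unused.
#' @return A ggplot of the beta density over (0, 1).
#' @method autoplot identity_model
#' @export
autoplot.identity_model <- function(object, ...) {
  x <- seq(0.001, 0.999, length.out = 500)
  df <- tibble::tibble(identity = x,
                       density = dbeta(x, object$alpha, object$beta))
  ggplot2::ggplot(df, ggplot2::aes(.data$identity, .data$density)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "steelblue") +
    ggplot2::labs(x = "Read identity", y = "Density") +
    ggplot2::theme_minimal()
}

#' One-row summary of a PCR amplification run
#'
#' Includes the parameter estimates implied by the realized pool: the
#' per-cycle duplication probability recovered from the growth factor,
#' `(n_amplified / n_input)^(1/cycles) - 1`, and the empirical per-base
#' mutation rate, `mutation_events / bases_copied`.
#'
#' @param x A `pcr_pool` from [pcr_amplify()].
#' @param ... Unused.
#' @return A one-row tibble: `n_input`, `cycles`, `p_dup`, `p_error`,
#'   `n_amplified`, `bases_copied`, `mutation_events`, `p_dup_hat`,
#'   `p_error_hat`.
#' @method glance pcr_pool
#' @export
glance.pcr_pool <- function(x, ...) {
  s <- attr(x, "pcr_stats")
  if (is.null(s)) abort("pool has no pcr_stats attribute")
  tibble::tibble(
    n_input = s$n_input, cycles = s$cycles, p_dup = s$p_dup,
    p_error = s$p_error, n_amplified = s$n_amplified,
    bases_copied = s$bases_copied, mutation_events = s$mutation_events,
    p_dup_hat = if (s$cycles > 0)
      (s$n_amplified / s$n_input)^(1 / s$cycles) - 1 else NA_real_,
    p_error_hat = if (s$bases_copied > 0)
      s$mutation_events / s$bases_copied else NA_real_
  )
}

#' One-row summary of QC metrics
#'
#' @param x A `qc_metrics` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_reads`, the five length quantiles,
#'   `mean_quality` (histogram-weighted) and `gc_fraction`.
#' @method glance qc_metrics
#' @export
glance.qc_metrics <- function(x, ...) {
  qh <- x$quality_histogram
  tibble::tibble(
    n_reads = x$n_reads,
    min_length = x$length_quantiles$min,
    q25_length = x$length_quantiles$q25,
    median_length = x$length_quantiles$median,
    q75_length = x$length_quantiles$q75,
    max_length = x$length_quantiles$max,
    mean_quality = sum(qh$mid * qh$count) / sum(qh$count),
    gc_fraction = x$gc_fraction
  )
}

#' Tidy QC metrics into a long histogram table
#'
#' @param x A `qc_metrics` object.
#' @param ... Unused.
#' @return A tibble with columns `metric` (`length` or `mean_quality`),
#'   `mid` and `count`.
#' @method tidy qc_metrics
#' @export
tidy.qc_metrics <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$length_histogram, metric = "length"),
    dplyr::mutate(x$quality_histogram, metric = "mean_quality")
  )[, c("metric", "mid", "count")]
}

#' Plot QC metrics (length and quality histograms)
#'
#' @param object A `qc_metrics` object.
#' @param ... Unused.
#' @return A ggplot faceted by metric.
#' @method autoplot qc_metrics
#' @export
autoplot.qc_metrics <- function(object, ...) {
  df <- tidy.qc_metrics(object)
  df <- dplyr::filter(df, .data$count > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$mid, .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "Reads") +
    ggplot2::theme_minimal()
}
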