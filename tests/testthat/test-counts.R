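test_that("count matrix CSV round-trips exactly and rejects bad input", {
  cm <- tibble::tibble(
    feature_id = c("g1", "g2"),
    cellA = c(0L, 2L), cellB = c(1L, 3L)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_count_matrix(cm, path)
  back <- read_count_matrix(path)
  expect_identical(as.data.frame(back), as.data.frame(cm))
  expect_equal(sum(as.matrix(back[, -1])), 6)

  writeLines(c("feature_id,c1", "g1,-1"), path)
  expect_error(read_count_matrix(path), "negative|invalid")
  writeLines(c("feature_id,c1", "g1,xx"), path)
  expect_error(read_count_matrix(path), "non-numeric")
  writeLines(c("feature_id,c1,c1", "g1,1,2"), path)
  expect_error(read_count_matrix(path), "duplicate")
  expect_error(
    validate_count_matrix(tibble::tibble(feature_id = c("a", "a"), c1 = 1:2)),
    "duplicate feature"
  )
  expect_error(
    validate_count_matrix(tibble::tibble(feature_id = "a", c1 = 1.5)),
    "non-integer|invalid"
  )
})

test_that("an empty-cell matrix writes a header-only CSV", {
  cm <- tibble::tibble(feature_id = character())
  path <- withr::local_tempfile(fileext = ".csv")
  write_count_matrix(cm, path)
  expect_equal(readLines(path), "feature_id")
  cm1 <- tibble::tibble(feature_id = "g", c1 = 7L)
  write_count_matrix(cm1, path)
  expect_true(any(grepl("7", readLines(path))))
})

test_that("parameter estimation handles degenerate matrices", {
  cm <- tibble::tibble(feature_id = "g", c1 = 2L, c2 = 2L, c3 = 2L)
  fit <- estimate_count_params(cm)
  expect_equal(fit$features$mean, 2)
  expect_equal(fit$features$dispersion, 0)

  cm2 <- tibble::tibble(feature_id = c("g", "z"), c1 = c(4L, 0L),
                        c2 = c(4L, 0L))
  fit2 <- estimate_count_params(cm2)
  expect_equal(fit2$features$mean[2], 0)
  expect_equal(fit2$features$dispersion[2], 0)

  zeros <- tibble::tibble(feature_id = "g", c1 = 0L, c2 = 0L)
  expect_error(estimate_count_params(zeros), "all-zero")
})

test_that("estimation recovers the generating Gamma-Poisson parameters", {
  params <- count_params(feature_mean = rep(5, 20),
                         feature_dispersion = 0.5,
                         libsize_log_sd = 0.3)
  sim <- simulate_counts(params, n_cells = 2000, seed = 401)
  fit <- estimate_count_params(sim)
  # per-feature means within 5% relative error
  expect_lt(max(abs(fit$features$mean - 5) / 5), 0.05)
  # moment dispersion estimate within 20% on average over features
  expect_lt(abs(mean(fit$features$dispersion) - 0.5) / 0.5, 0.2)
})

test_that("simulated counts match Poisson and Gamma-Poisson moments", {
  p0 <- count_params(feature_mean = 0)
  expect_true(all(as.matrix(simulate_counts(p0, 50, seed = 1)[, -1]) == 0))

  # Poisson case: mean 4, no libsize noise, n = 10000 -> SE = 0.02
  p1 <- count_params(feature_mean = 4)
  x <- as.numeric(as.matrix(simulate_counts(p1, 10000, seed = 7)[, -1]))
  expect_lt(abs(mean(x) - 4), 3 * 0.02)

  # Gamma-Poisson: variance/mean ratio ~ 1 + phi * mu = 3
  p2 <- count_params(feature_mean = 4, feature_dispersion = 0.5)
  y <- as.numeric(as.matrix(simulate_counts(p2, 20000, seed = 8)[, -1]))
  expect_equal(var(y) / mean(y), 3, tolerance = 0.1)
})

test_that("count simulation is seed-reproducible and seed-sensitive", {
  p <- count_params(feature_mean = c(1, 5, 10), feature_dispersion = 0.3)
  a <- simulate_counts(p, 100, seed = 11)
  b <- simulate_counts(p, 100, seed = 11)
  d <- simulate_counts(p, 100, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a, d))
})

test_that("total counts scale linearly with the library-size factor", {
  base <- count_params(feature_mean = rep(2, 10))
  shifted <- count_params(feature_mean = rep(2, 10), libsize_log_mean = log(3))
  t1 <- sum(as.matrix(simulate_counts(base, 3000, seed = 5)[, -1]))
  t3 <- sum(as.matrix(simulate_counts(shifted, 3000, seed = 5)[, -1]))
  expect_equal(t3 / t1, 3, tolerance = 0.05)
})

test_that("count_fit tidiers expose per-feature and summary views", {
  fit <- estimate_count_params(
    tibble::tibble(feature_id = c("a", "b"), c1 = c(1L, 3L), c2 = c(2L, 4L))
  )
  td <- tidy(fit)
  expect_named(td, c("feature_id", "mean", "dispersion"))
  gl <- glance(fit)
  expect_equal(gl$n_features, 2)
  expect_equal(gl$n_cells, 2)
})
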