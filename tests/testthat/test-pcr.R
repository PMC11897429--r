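test_that("copy mutation follows the per-base substitution model", {
  set.seed(50)
  s <- random_seq(500)
  r0 <- mutate_copy(s, 0)
  expect_identical(r0$sequence, s)
  expect_equal(r0$n_mutations, 0L)

  r1 <- mutate_copy(s, 1)
  a <- strsplit(s, "")[[1]]
  b <- strsplit(r1$sequence, "")[[1]]
  expect_true(all(a != b))            # every base differs at p_error = 1
  expect_equal(nchar(r1$sequence), nchar(s))

  # N bases are never mutated
  rn <- mutate_copy("NNNNN", 1)
  expect_identical(rn$sequence, "NNNNN")
  expect_equal(rn$n_mutations, 0L)
  half <- mutate_copy(paste0(strrep("N", 50), strrep("A", 50)), 1)
  expect_equal(substr(half$sequence, 1, 50), strrep("N", 50))
  expect_false(grepl("A", substr(half$sequence, 51, 100)))
})

test_that("amplification is a branching process with the expected growth", {
  mol <- tibble::tibble(read_id = sprintf("m%03d", 1:20),
                        sequence = rep("ACGTACGTAC", 20))
  # zero cycles: pool identical to input
  p0 <- pcr_amplify(mol, cycles = 0, seed = 1)
  expect_equal(p0$sequence, mol$sequence)
  expect_equal(nrow(p0), 20)

  # deterministic doubling: p_dup = 1, 3 cycles, 1 molecule -> 8
  p1 <- pcr_amplify(mol[1, ], cycles = 3, p_dup = 1, p_error = 0, seed = 2)
  expect_equal(nrow(p1), 8)
  expect_true(all(p1$origin_read_id == "m001"))
  expect_true(all(p1$sequence == "ACGTACGTAC"))  # p_error 0: exact copies

  # pool-size expectation N (1 + p_dup)^cycles within 3 SD (Galton-Watson)
  big <- tibble::tibble(read_id = sprintf("m%05d", 1:1000),
                        sequence = rep("ACGT", 1000))
  cases <- expand.grid(p_dup = c(0.5, 0.9, 1.0), cycles = c(1, 5, 10))
  for (i in seq_len(nrow(cases))) {
    p <- cases$p_dup[i]
    cyc <- cases$cycles[i]
    pool <- pcr_amplify(big, cycles = cyc, p_dup = p, p_error = 0,
                        seed = 100 + i)
    expected <- 1000 * (1 + p)^cyc
    tol <- max(3 * gw_pool_sd(1000, p, cyc), 0.5)
    expect_lt(abs(nrow(pool) - expected), tol)
  }
})

test_that("lineages are consistent and mutations accumulate monotonically", {
  set.seed(60)
  mol <- tibble::tibble(read_id = sprintf("m%02d", 1:10),
                        sequence = replicate(10, random_seq(300)))
  pool <- pcr_amplify(mol, cycles = 6, p_dup = 0.9, p_error = 5e-3,
                      seed = 61)
  expect_true(all(pool$origin_read_id %in% mol$read_id))
  expect_false(anyDuplicated(pool$read_id) > 0)
  # realized mutations match the recorded cumulative count per molecule
  origin_seq <- setNames(mol$sequence, mol$read_id)
  diffs <- mapply(function(s, o) {
    sum(strsplit(s, "")[[1]] != strsplit(o, "")[[1]])
  }, pool$sequence, origin_seq[pool$origin_read_id])
  # back mutations can only reduce the observed count
  expect_true(all(diffs <= pool$n_mutations))
  expect_true(any(pool$n_mutations > 0))
  # substitution-only: lengths unchanged
  expect_true(all(nchar(pool$sequence) == 300))
})

test_that("subsampling is uniform and preserves origin proportions", {
  set.seed(70)
  mol <- tibble::tibble(read_id = sprintf("o%02d", 1:10),
                        sequence = rep("ACGTACGT", 10))
  pool <- pcr_amplify(mol, cycles = 7, p_dup = 0.9, p_error = 0, seed = 71)
  expect_error(subsample_pool(pool, nrow(pool) + 1), "cannot sample")
  same <- subsample_pool(pool, nrow(pool), seed = 1)
  expect_equal(sort(same$read_id), sort(pool$read_id))
  expect_equal(nrow(subsample_pool(pool, 0, seed = 1)), 0)

  # chi-square on per-origin counts of a 10% sample vs pool proportions
  n <- round(nrow(pool) * 0.1)
  sub <- subsample_pool(pool, n, seed = 72)
  pool_prop <- table(pool$origin_read_id) / nrow(pool)
  obs <- table(factor(sub$origin_read_id, levels = names(pool_prop)))
  chi <- suppressWarnings(
    stats::chisq.test(obs, p = as.numeric(pool_prop))
  )
  expect_gt(chi$p.value, 0.001)
  # per-origin proportions within 3 multinomial SE
  se <- sqrt(as.numeric(pool_prop) * (1 - as.numeric(pool_prop)) / n)
  expect_true(all(abs(as.numeric(obs) / n - as.numeric(pool_prop)) <=
                    3 * se + 1e-9))
})

test_that("amplification via sample_size subsamples after the last cycle", {
  mol <- tibble::tibble(read_id = sprintf("m%02d", 1:50),
                        sequence = rep("ACGT", 50))
  pool <- pcr_amplify(mol, cycles = 4, sample_size = 120, seed = 80)
  expect_equal(nrow(pool), 120)
  s <- attr(pool, "pcr_stats")
  expect_gt(s$n_amplified, 120)  # stats reflect the pre-subsampling pool
})

test_that("the pool-size guard trips before memory blows up", {
  mol <- tibble::tibble(read_id = sprintf("m%06d", 1:500000),
                        sequence = rep("A", 500000))
  expect_error(pcr_amplify(mol, cycles = 10, p_dup = 1, seed = 1),
               "exceed")
})
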