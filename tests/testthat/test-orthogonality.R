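test_that("cross-matrix construction enforces squareness and completeness", {
  T3 <- const_rel(3, 0.02)
  m <- rel_to_matrix(T3)
  expect_equal(dim(m), c(3, 3))
  expect_equal(unname(diag(as.matrix(m))), rep(1000, 3))

  # missing cell named in the error
  cells <- m$cells[-2, ]
  expect_error(
    cross_matrix(cells, pairs = m$pairs),
    regexp = m$cells$col[2],
    class = "inteinscreen_shape_error"
  )

  # duplicate cell -> ambiguity error
  expect_error(
    cross_matrix(rbind(m$cells, m$cells[1, ]), pairs = m$pairs),
    class = "inteinscreen_ambiguity_error"
  )

  # build from signals + pairing, k pairs -> k^2 cells
  k <- 5
  pairing <- tidyr::expand_grid(
    row = split_pair_id(sprintf("i%d", 1:k)),
    col = split_pair_id(sprintf("i%d", 1:k))
  ) |>
    mutate(sample_id = sprintf("s%d", dplyr::row_number()))
  signals <- tibble(sample_id = pairing$sample_id, mean = 100)
  built <- build_cross_matrix(signals, pairing)
  expect_equal(nrow(built$cells), k^2)
  expect_error(
    build_cross_matrix(signals[-1, ], pairing),
    class = "inteinscreen_shape_error"
  )
})

test_that("non-cognate value collection matches the design combinatorics", {
  # a k-pair panel gives 2(k-1) non-cognate values per pair: 46 for k = 24
  m24 <- rel_to_matrix(const_rel(24, 0.01))
  expect_length(noncognate_values(m24, m24$pairs[1]), 46)

  m2 <- rel_to_matrix(const_rel(2, 0))
  expect_equal(unname(noncognate_values(m2, m2$pairs[1])), c(0, 0))

  # planted cross-talk level appears among the relative values
  T3 <- const_rel(3, 0)
  T3[1, 2] <- 0.1
  vals <- noncognate_values(rel_to_matrix(T3), rownames(T3)[1])
  expect_true(any(abs(vals - 0.1) < 1e-12))

  # cognate value never enters the non-cognate set
  T3b <- const_rel(3, 0.02)
  vals_b <- noncognate_values(rel_to_matrix(T3b), rownames(T3b)[2])
  expect_true(all(vals_b < 1))
  expect_length(vals_b, 4)

  # non-positive cognate -> undefined normalization
  bad <- rel_to_matrix(const_rel(2, 0))
  bad$cells$mean[bad$cells$row == bad$pairs[1] & bad$cells$col == bad$pairs[1]] <- 0
  expect_error(
    noncognate_values(bad, bad$pairs[1]),
    class = "inteinscreen_normalization_error"
  )
})

test_that("same-intein exclusion policy drops split-variant partners", {
  pairs <- c(split_pair_id("A", c("S1", "S2")), split_pair_id("B", "S2"))
  T3 <- const_rel(3, 0.03)
  dimnames(T3) <- list(pairs, pairs)
  m <- rel_to_matrix(T3)
  expect_length(noncognate_values(m, "A:S1", policy = "all"), 4)
  # excluding A:S2 leaves only the two B:S2 combinations
  expect_length(noncognate_values(m, "A:S1", policy = "exclude_same_intein"), 2)
})

test_that("two-threshold criterion applies strict max and median rules", {
  # all-zero cross-talk -> orthogonal
  calls0 <- classify_orthogonal(rel_to_matrix(const_rel(4, 0)))
  expect_true(all(calls0$orthogonal))

  # one value at 0.25 breaks the max rule
  T4 <- const_rel(4, 0)
  T4[1, 2] <- 0.25
  calls <- classify_orthogonal(rel_to_matrix(T4))
  expect_false(calls$orthogonal[calls$pair == rownames(T4)[1]])
  expect_false(calls$orthogonal[calls$pair == rownames(T4)[2]])

  # all 46 values equal to 0.06: max passes, median 0.06 >= 0.05 fails
  calls24 <- classify_orthogonal(rel_to_matrix(const_rel(24, 0.06)))
  expect_true(all(calls24$max_rel < 0.2))
  expect_equal(calls24$median_rel, rep(0.06, 24))
  expect_false(any(calls24$orthogonal))

  # boundary values are rejected (strict "below")
  at_max <- classify_orthogonal(rel_to_matrix(const_rel(3, 0.01)),
    max_threshold = 0.2
  )
  expect_true(all(at_max$orthogonal))
  T_at <- const_rel(3, 0)
  T_at[1, 2] <- 0.2
  expect_false(all(classify_orthogonal(rel_to_matrix(T_at))$orthogonal))

  # even-length median is the mean of the two central values
  T3 <- const_rel(3, 0)
  T3[1, 2] <- 0.08
  T3[1, 3] <- 0.04
  call1 <- classify_orthogonal(rel_to_matrix(T3), pairs = rownames(T3)[1])
  expect_equal(call1$median_rel, mean(c(0, 0.04)))
})

test_that("classification is invariant to uniform rescaling", {
  withr::with_seed(42, {
    T6 <- random_rel(6, hi = 0.3)
  })
  a <- classify_orthogonal(rel_to_matrix(T6, cognate = 1000))
  b <- classify_orthogonal(rel_to_matrix(T6, cognate = 1e6))
  expect_equal(a$orthogonal, b$orthogonal)
  expect_equal(a$max_rel, b$max_rel, tolerance = 1e-12)
})

test_that("raising either threshold never shrinks the orthogonal set", {
  withr::with_seed(7, {
    for (i in 1:20) {
      m <- rel_to_matrix(random_rel(6, hi = 0.3))
      base <- classify_orthogonal(m, max_threshold = 0.2, median_threshold = 0.05)
      up_max <- classify_orthogonal(m, max_threshold = 0.35, median_threshold = 0.05)
      up_med <- classify_orthogonal(m, max_threshold = 0.2, median_threshold = 0.15)
      expect_true(all(up_max$orthogonal[base$orthogonal]))
      expect_true(all(up_med$orthogonal[base$orthogonal]))
      # max_rel can only drop under restriction (the monotone half of the rule)
      keep <- m$pairs[1:4]
      sub <- classify_orthogonal(restrict_pairs(m, keep))
      expect_true(all(sub$max_rel <= base$max_rel[match(keep, base$pair)] + 1e-12))
    }
  })
})

test_that("pruning removes violators and keeps one variant per intein", {
  # zero off-diagonal: everything retained
  clean <- prune_mutually_orthogonal(rel_to_matrix(const_rel(4, 0)))
  expect_length(clean$mutually_orthogonal_pairs, 4)
  expect_length(clean$removed, 0)

  # one pair cross-talking at 0.5 against all others is removed, rest kept
  T4 <- const_rel(4, 0)
  T4[2, -2] <- 0.5
  T4[-2, 2] <- 0.5
  res <- prune_mutually_orthogonal(rel_to_matrix(T4))
  expect_equal(res$removed, rownames(T4)[2])
  expect_setequal(res$mutually_orthogonal_pairs, rownames(T4)[-2])
  expect_true(all(tidy(res)$orthogonal))

  # variant selection: intein A split at S1 and S2 both survive; the
  # higher-cognate variant represents the intein
  pairs <- c(split_pair_id("A", c("S1", "S2")), split_pair_id("B", "S2"))
  T3 <- const_rel(3, 0)
  dimnames(T3) <- list(pairs, pairs)
  M <- T3 * 1000
  diag(M) <- c(800, 2000, 1500)
  cells <- tibble::as_tibble(M, rownames = "row") |>
    tidyr::pivot_longer(-row, names_to = "col", values_to = "mean")
  res2 <- prune_mutually_orthogonal(cross_matrix(cells, pairs = pairs))
  expect_setequal(res2$mutually_orthogonal_pairs, pairs)
  expect_setequal(res2$pairs, c("A:S2", "B:S2"))
  expect_setequal(res2$inteins, c("A", "B"))
  expect_equal(glance(res2)$n_inteins, 2)
})

test_that("exact maximum subset equals exhaustive enumeration", {
  # diagonal-only matrix: the full panel is feasible
  m0 <- rel_to_matrix(const_rel(5, 0))
  expect_setequal(max_orthogonal_subset(m0, mode = "exact"), m0$pairs)

  # a 3-clique of mutual 0.3 cross-talk in a 6x6 panel: the whole clique
  # breaks the max rule pairwise, so at most one member can survive
  T6 <- const_rel(6, 0)
  for (i in 1:3) {
    for (j in 1:3) if (i != j) T6[i, j] <- 0.3
  }
  m6 <- rel_to_matrix(T6)
  exact <- max_orthogonal_subset(m6, mode = "exact")
  expect_length(exact, 4)
  expect_setequal(exact, oracle_max_subset(m6))

  withr::with_seed(99, {
    for (rep in 1:15) {
      m <- rel_to_matrix(random_rel(6, hi = 0.4))
      exact <- max_orthogonal_subset(m, mode = "exact")
      greedy <- max_orthogonal_subset(m, mode = "greedy")
      oracle <- oracle_max_subset(m)
      expect_equal(length(exact), length(oracle))
      expect_true(oracle_feasible(as.matrix(m), exact))
      expect_gte(length(exact), length(greedy))
    }
  })

  expect_error(
    max_orthogonal_subset(rel_to_matrix(const_rel(26, 0)), mode = "exact"),
    class = "inteinscreen_size_error"
  )
})

test_that("cross matrices round-trip through the CSV grid format", {
  withr::with_seed(3, {
    m <- rel_to_matrix(random_rel(4))
  })
  path <- withr::local_tempfile(fileext = ".csv")
  write_cross_matrix(m, path)
  back <- read_cross_matrix(path)
  expect_equal(back$pairs, m$pairs)
  expect_equal(as.matrix(back), as.matrix(m), tolerance = 1e-9)
})
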