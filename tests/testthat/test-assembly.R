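test_that("one-pot plans need one distinct intein per junction", {
  p6 <- plan_one_pot(6)
  expect_equal(p6$unit_types, 6)
  expect_equal(nrow(p6$inteins), 5)
  expect_equal(p6$units$tag, c("H6", rep("none", 4), "Strep"))
  # junctions carry distinct inteins in library order
  expect_equal(p6$units$c_side[1:5], default_intein_library()$name)
  expect_equal(p6$units$n_side[2:6], p6$units$c_side[1:5])

  p2 <- plan_one_pot(2, default_intein_library()[1, ])
  expect_equal(p2$unit_types, 2)
  expect_equal(nrow(p2$inteins), 1)

  expect_error(
    plan_one_pot(6, default_intein_library()[1:4, ]),
    regexp = "5",
    class = "inteinscreen_capacity_error"
  )
  expect_error(plan_one_pot(1), class = "inteinscreen_input_error")
  expect_error(
    plan_one_pot(3, start_tag = "H6", end_tag = "H6"),
    class = "inteinscreen_config_error"
  )
})

test_that("solid-phase plans alternate two inteins and saturate at four unit types", {
  p6 <- plan_solid_phase(6)
  expect_equal(p6$unit_types, 4)
  expect_equal(p6$cycles, 5)
  expect_equal(nrow(p6$inteins), 2)
  # A, B, A, B, A along the junctions
  expect_equal(
    p6$units$c_side[1:5],
    rep(p6$inteins$name, length.out = 5)
  )

  expect_equal(plan_solid_phase(10)$cycles, 9)
  expect_equal(plan_solid_phase(10)$unit_types, 4)
  p2 <- plan_solid_phase(2)
  expect_equal(p2$unit_types, 2)
  expect_equal(p2$cycles, 1)
  expect_equal(plan_solid_phase(3)$unit_types, 3)
  # unit_types saturates at 4 for every n >= 4
  expect_true(all(purrr::map_int(4:12, ~ plan_solid_phase(.x)$unit_types) == 4L))

  expect_error(
    plan_solid_phase(4, default_intein_library()[c(1, 1), ]),
    class = "inteinscreen_orthogonality_error"
  )
})

test_that("repeat composition sums G5/E domains over units", {
  expect_equal(product_composition(plan_one_pot(6))[, 1:2], tibble(g5_total = 18, e_total = 12))
  expect_equal(product_composition(plan_solid_phase(2))$g5_total, 6)
  expect_equal(product_composition(plan_solid_phase(10))$g5_total, 30)
  expect_equal(product_composition(plan_solid_phase(10))$e_total, 20)
  # additivity: composition of an n-unit chain is n times one unit's
  comp1 <- c(3, 2)
  for (n in c(2, 6, 10)) {
    comp <- product_composition(plan_solid_phase(n))
    expect_equal(c(comp$g5_total, comp$e_total), n * comp1)
  }
})

test_that("product mass matches an external average-mass computation", {
  # Biopython molecular_weight(..., 'protein') on the same sequences
  seqs <- c("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ", "GSGSG")
  plan <- plan_one_pot(2, default_intein_library()[1, ], sequences = seqs)
  comp <- product_composition(plan, mass = TRUE)
  expect_equal(comp$mass_kDa, round((3935.5547 + 363.3238 - 18.01528) / 1000, 1))

  expect_error(
    product_composition(plan_one_pot(2, default_intein_library()[1, ]), mass = TRUE),
    class = "inteinscreen_missing_sequence_error"
  )
})

test_that("junction compatibility flags exactly the mismatching junctions", {
  lib <- dplyr::bind_rows(
    intein_spec("A", "GSYSSG"),
    intein_spec("B", "KFAEYC")
  )
  # design units whose termini realize the preferred residues exactly
  seqs <- c("MAAAGSY", "SSGKFA", "EYCAAA")
  plan <- plan_one_pot(3, lib, sequences = seqs)
  rep1 <- check_junction_compatibility(plan)
  expect_true(all(rep1$match))
  expect_equal(rep1$n_mismatch, c(0, 0))

  # one substituted -1 residue flags exactly that junction
  seqs2 <- seqs
  seqs2[1] <- "MAAAGAY"
  rep2 <- check_junction_compatibility(plan_one_pot(3, lib, sequences = seqs2))
  expect_equal(rep2$match, c(FALSE, TRUE))
  expect_equal(rep2$n_mismatch, c(1, 0))

  # randomized junctions: flagged mismatch counts equal direct Hamming counts
  withr::with_seed(5, {
    for (i in 1:100) {
      aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
      s1 <- paste(sample(aa, 8, replace = TRUE), collapse = "")
      s2 <- paste(sample(aa, 8, replace = TRUE), collapse = "")
      plan_i <- plan_one_pot(2, lib[1, ], sequences = c(s1, s2))
      rep_i <- check_junction_compatibility(plan_i)
      realized <- paste0(substr(s1, 6, 8), substr(s2, 1, 3))
      hamming <- sum(strsplit(realized, "")[[1]] != strsplit("GSYSSG", "")[[1]])
      expect_equal(rep_i$n_mismatch, hamming)
      expect_equal(rep_i$match, hamming == 0)
    }
  })
})

test_that("ladder predictions form proper distributions with closed-form yields", {
  # p = 1: only the full-length product
  full <- simulate_yield(plan_solid_phase(6), p = 1)
  expect_equal(full$abundance[full$units == 6], 1)

  # solid phase, 5 cycles at p = 0.8: full length 0.8^5
  lad <- simulate_yield(plan_solid_phase(6), p = 0.8)
  expect_equal(lad$abundance[lad$units == 6], 0.8^5)
  expect_equal(sum(lad$abundance), 1, tolerance = 1e-9)
  # truncations follow prod(p) * (1-p) at the first failed cycle
  expect_equal(lad$abundance[lad$units == 1], 0.2)
  expect_equal(lad$abundance[lad$units == 3], 0.8^2 * 0.2)

  # one pot, n = 3, p = 0.5: {none 0.25, one junction 0.5, both 0.25}
  one <- simulate_yield(plan_one_pot(3), p = 0.5)
  expect_equal(one$abundance, c(0.25, 0.5, 0.25))
  expect_equal(one$units, 1:3)

  # abundances sum to 1 for arbitrary per-junction probabilities
  withr::with_seed(2, {
    for (i in 1:20) {
      n <- sample(2:8, 1)
      p <- stats::runif(n - 1)
      plans <- list(plan_solid_phase(n))
      if (n <= 6) plans <- c(plans, list(plan_one_pot(n)))
      for (plan_i in plans) {
        expect_equal(sum(simulate_yield(plan_i, p = p)$abundance), 1, tolerance = 1e-9)
      }
    }
  })

  # per-intein probability map resolves along the junctions
  byint <- simulate_yield(plan_solid_phase(4), p = c("gp41-1" = 1, "NrdJ-1" = 0.5))
  expect_equal(byint$abundance[byint$units == 4], 0.5)

  expect_error(
    simulate_yield(plan_solid_phase(4), p = 1.2),
    class = "inteinscreen_parameter_error"
  )
})

test_that("exact ladders agree with seeded stochastic simulation", {
  plan <- plan_solid_phase(6)
  exact <- simulate_yield(plan, p = 0.8)
  stoch <- simulate_yield(plan, p = 0.8, method = "stochastic", n_draws = 1e5, seed = 3)
  merged <- dplyr::left_join(exact, stoch, by = "units", suffix = c("_e", "_s")) |>
    mutate(abundance_s = dplyr::coalesce(abundance_s, 0))
  se <- sqrt(merged$abundance_e * (1 - merged$abundance_e) / 1e5)
  expect_true(all(abs(merged$abundance_e - merged$abundance_s) <= 3 * se + 1e-12))

  plan1 <- plan_one_pot(4, default_intein_library()[1:3, ])
  exact1 <- simulate_yield(plan1, p = c(0.9, 0.5, 0.7))
  stoch1 <- simulate_yield(plan1, p = c(0.9, 0.5, 0.7), method = "stochastic", n_draws = 1e5, seed = 4)
  m1 <- dplyr::left_join(exact1, stoch1, by = "units", suffix = c("_e", "_s")) |>
    mutate(abundance_s = dplyr::coalesce(abundance_s, 0))
  se1 <- sqrt(m1$abundance_e * (1 - m1$abundance_e) / 1e5)
  expect_true(all(abs(m1$abundance_e - m1$abundance_s) <= 3 * se1 + 1e-12))
})
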