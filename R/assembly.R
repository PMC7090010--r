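#' Define a split intein for assembly planning
#'
#' @param name Intein name.
#' @param junction_pref Preferred splice-junction residues, six one-letter
#'   amino acids spanning positions -3..+3 around the junction.
#' @param orthogonal_group Label of the mutually orthogonal set the intein
#'   belongs to (inteins sharing a group are assumed orthogonal).
#' @return One-row tibble (`name`, `junction_pref`, `orthogonal_group`).
#' @export
intein_spec <- function(name, junction_pref, orthogonal_group = "default") {
  if (nchar(junction_pref) != 6 ||
    !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", junction_pref)) {
    abort(
      "junction_pref must be 6 one-letter amino-acid codes",
      class = "inteinscreen_format_error"
    )
  }
  tibble(name = name, junction_pref = junction_pref, orthogonal_group = orthogonal_group)
}

#' Example library of five mutually orthogonal assembly inteins
#'
#' gp41-1, gp41-8, NrdJ-1, IMPDH-1 and SspGyrB split at their canonical
#' sites form a fast, mutually orthogonal working set for in vitro
#' assembly. The junction preferences shipped here are illustrative
#' placeholder sequences for demonstration and testing, not measured
#' preferences; supply your own [intein_spec()] rows for real designs.
#'
#' @return Tibble of five [intein_spec()] rows.
#' @export
default_intein_library <- function() {
  bind_rows(
    intein_spec("gp41-1", "GEYSSS", "fast_s2"),
    intein_spec("gp41-8", "SPTSSS", "fast_s2"),
    intein_spec("NrdJ-1", "GAYSSS", "fast_s2"),
    intein_spec("IMPDH-1", "SGYSSS", "fast_s2"),
    intein_spec("SspGyrB", "KFAEYC", "fast_s2")
  )
}

new_assembly_plan <- function(scheme, units, inteins, cycles) {
  designs <- units |> distinct(.data$n_side, .data$c_side, .data$tag)
  structure(
    list(
      scheme = scheme,
      units = units,
      inteins = inteins,
      cycles = cycles,
      unit_types = nrow(designs)
    ),
    class = "assembly_plan"
  )
}

#' @export
print.assembly_plan <- function(x, ...) {
  cat(
    "<assembly_plan> scheme = ", x$scheme, ": ", nrow(x$units), " units, ",
    x$unit_types, " unit type(s), ", nrow(x$inteins), " intein(s)",
    if (!is.na(x$cycles)) paste0(", ", x$cycles, " cycle(s)") else "", "\n",
    sep = ""
  )
  print(x$units, n = 6)
  invisible(x)
}

#' @export
tidy.assembly_plan <- function(x, ...) x$units

#' @export
glance.assembly_plan <- function(x, ...) {
  comp <- product_composition(x)
  tibble(
    scheme = x$scheme,
    n_units = nrow(x$units),
    unit_types = x$unit_types,
    n_inteins = nrow(x$inteins),
    cycles = x$cycles,
    g5_total = comp$g5_total,
    e_total = comp$e_total
  )
}

make_units <- function(n_units, junction_inteins, start_tag, end_tag,
                       g5_count, e_count, sequences) {
  if (start_tag == end_tag) {
    abort(
      "start and end purification tags must differ",
      class = "inteinscreen_config_error"
    )
  }
  tibble(
    unit_id = paste0("U", seq_len(n_units)),
    position = seq_len(n_units),
    n_side = c(NA_character_, junction_inteins),
    c_side = c(junction_inteins, NA_character_),
    tag = c(start_tag, rep("none", max(n_units - 2, 0)), if (n_units > 1) end_tag),
    g5_count = g5_count,
    e_count = e_count,
    sequence = if (is.null(sequences)) NA_character_ else sequences
  )
}

#' Plan a one-pot modular assembly
#'
#' One-pot assembly splices all units simultaneously in a single reaction,
#' so every junction needs its own orthogonal split intein: n units require
#' n - 1 distinct inteins and n distinct unit designs (six units, five
#' inteins for the hexameric repeat protein). The first unit carries the
#' resin/purification tag for the first capture step, the last unit a
#' different tag for the second.
#'
#' @param n_units Number of units in the chain (>= 2).
#' @param library Tibble of [intein_spec()] rows; the first `n_units - 1`
#'   are assigned to junctions in order.
#' @param start_tag,end_tag Purification tags on the terminal units
#'   (defaults H6 and Strep); must differ.
#' @param g5_count,e_count Repeat composition per unit (default the
#'   SasG5^3^E^2^ block: 3 G5 and 2 E domains).
#' @param sequences Optional character vector of unit amino-acid sequences
#'   (length `n_units`).
#' @return An `assembly_plan`.
#' @export
plan_one_pot <- function(n_units, library = default_intein_library(),
                         start_tag = "H6", end_tag = "Strep",
                         g5_count = 3, e_count = 2, sequences = NULL) {
  if (n_units < 2) {
    abort("an assembly needs at least 2 units", class = "inteinscreen_input_error")
  }
  needed <- n_units - 1
  if (anyDuplicated(library$name)) {
    abort("intein library has duplicate names", class = "inteinscreen_config_error")
  }
  if (nrow(library) < needed) {
    abort(
      paste0(
        "one-pot assembly of ", n_units, " units needs ", needed,
        " distinct orthogonal inteins; library has ", nrow(library)
      ),
      class = "inteinscreen_capacity_error"
    )
  }
  used <- library[seq_len(needed), ]
  units <- make_units(
    n_units, used$name, start_tag, end_tag,
    g5_count, e_count, sequences
  )
  new_assembly_plan("one_pot", units, used, NA_integer_)
}

#' Plan a recursive solid-phase assembly
#'
#' Solid-phase assembly grows a resin-bound chain one unit per cycle,
#' alternating between two orthogonal inteins (A, B, A, B, ...), so only
#' two inteins and at most four unit designs are needed regardless of the
#' chain length: a tagged start unit, two alternating internal designs and
#' a tagged end unit. Each added unit costs one wash-and-incubate cycle:
#' n units take n - 1 cycles.
#'
#' @param n_units Number of units (>= 2).
#' @param pair Tibble of exactly two distinct [intein_spec()] rows.
#' @inheritParams plan_one_pot
#' @return An `assembly_plan` with `cycles = n_units - 1`.
#' @export
plan_solid_phase <- function(n_units, pair = default_intein_library()[c(1, 3), ],
                             start_tag = "H6", end_tag = "Strep",
                             g5_count = 3, e_count = 2, sequences = NULL) {
  if (n_units < 2) {
    abort("an assembly needs at least 2 units", class = "inteinscreen_input_error")
  }
  if (nrow(pair) != 2 || pair$name[1] == pair$name[2]) {
    abort(
      "solid-phase assembly needs two distinct orthogonal inteins",
      class = "inteinscreen_orthogonality_error"
    )
  }
  junctions <- rep(pair$name, length.out = n_units - 1)
  units <- make_units(
    n_units, junctions, start_tag, end_tag,
    g5_count, e_count, sequences
  )
  new_assembly_plan("solid_phase", units, pair, n_units - 1L)
}

# Average (isotope-abundance-weighted) residue masses, Da; one water is
# added per chain.
AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01528

protein_mass_kda <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, names(AA_RESIDUE_MASS))
  if (length(bad) > 0) {
    abort(
      paste0("unknown residue(s): ", paste(unique(bad), collapse = ", ")),
      class = "inteinscreen_format_error"
    )
  }
  (sum(AA_RESIDUE_MASS[aa]) + WATER_MASS) / 1000
}

#' Repeat composition (and mass) of the assembled product
#'
#' Sums the repeat-domain counts over all units: n uniform SasG5^3^E^2^
#' units splice into a SasG5^(3n)^E^(2n)^ chain. With unit sequences
#' supplied the average-isotopic mass of the spliced chain (units only --
#' inteins excise and are excluded) is reported in kDa to 0.1 kDa.
#'
#' @param plan An `assembly_plan`.
#' @param mass Compute the product mass from unit sequences (error when
#'   sequences are absent).
#' @return One-row tibble: `g5_total`, `e_total`, `mass_kDa` (`NA` unless
#'   `mass = TRUE`).
#' @export
product_composition <- function(plan, mass = FALSE) {
  g5 <- sum(plan$units$g5_count)
  e <- sum(plan$units$e_count)
  mkda <- NA_real_
  if (mass) {
    if (anyNA(plan$units$sequence)) {
      abort(
        "mass requires an amino-acid sequence for every unit",
        class = "inteinscreen_missing_sequence_error"
      )
    }
    mkda <- round(protein_mass_kda(paste(plan$units$sequence, collapse = "")), 1)
  }
  tibble(g5_total = g5, e_total = e, mass_kDa = mkda)
}

#' Check realized junction residues against each intein's preference
#'
#' Splicing efficiency depends strongly on the -3..+3 residues flanking
#' each junction. For every junction the realized residues (last three of
#' the upstream unit, first three of the downstream unit) are compared
#' with the junction intein's preferred six; exact match only, no scoring.
#'
#' @param plan An `assembly_plan` whose units carry sequences.
#' @return Tibble per junction: `junction`, `intein`, `realized`,
#'   `preferred`, `match`, `n_mismatch`.
#' @export
check_junction_compatibility <- function(plan) {
  units <- plan$units
  if (anyNA(units$sequence)) {
    abort(
      "junction check requires unit sequences",
      class = "inteinscreen_missing_sequence_error"
    )
  }
  n <- nrow(units)
  map(seq_len(n - 1), function(j) {
    up <- units$sequence[j]
    down <- units$sequence[j + 1]
    realized <- paste0(
      substr(up, nchar(up) - 2, nchar(up)),
      substr(down, 1, 3)
    )
    intein <- units$c_side[j]
    preferred <- plan$inteins$junction_pref[match(intein, plan$inteins$name)]
    tibble(
      junction = j,
      intein = intein,
      realized = realized,
      preferred = preferred,
      match = realized == preferred,
      n_mismatch = sum(strsplit(realized, "")[[1]] != strsplit(preferred, "")[[1]])
    )
  }) |> list_rbind()
}

resolve_junction_p <- function(plan, p) {
  nj <- nrow(plan$units) - 1
  junction_inteins <- plan$units$c_side[seq_len(nj)]
  if (!is.null(names(p))) {
    missing_p <- setdiff(unique(junction_inteins), names(p))
    if (length(missing_p) > 0) {
      abort(
        paste0("no splicing probability for intein(s): ", paste(missing_p, collapse = ", ")),
        class = "inteinscreen_parameter_error"
      )
    }
    p <- unname(p[junction_inteins])
  } else if (length(p) == 1) {
    p <- rep(p, nj)
  } else if (length(p) != nj) {
    abort(
      paste0("p must have length 1 or ", nj, " (one per junction)"),
      class = "inteinscreen_parameter_error"
    )
  }
  if (any(p < 0 | p > 1)) {
    abort("splicing probabilities must lie in [0, 1]", class = "inteinscreen_parameter_error")
  }
  p
}

ladder_mass <- function(units, m) {
  seqs <- units$sequence[seq_len(m)]
  if (anyNA(seqs)) {
    return(NA_real_)
  }
  round(protein_mass_kda(paste(seqs, collapse = "")), 1)
}

#' Predict the incomplete-splicing product ladder
#'
#' Computes the abundance distribution of full-length product and
#' truncated by-products given per-junction splicing probabilities.
#'
#' Solid phase: the resin-bound chain stalls permanently at the first
#' failed cycle, so a species carrying m < n units has abundance
#' (prod of p over cycles < m) x (1 - p_m), and the full-length product
#' has abundance prod(p) over all n - 1 cycles (p^(n-1) for a common p).
#'
#' One pot: the n - 1 junctions succeed independently; all 2^(n-1) junction
#' outcomes are enumerated exactly (n <= 20) and each outcome is
#' represented by its principal product, the largest contiguous block of
#' spliced units. Abundances in either scheme form a proper distribution
#' (sum to 1). A seeded stochastic mode estimates the same distribution by
#' simulation.
#'
#' @param plan An `assembly_plan`.
#' @param p Per-junction splicing probability: scalar, vector (one per
#'   junction) or named per-intein map.
#' @param method `"exact"` (deterministic, default) or `"stochastic"`.
#' @param n_draws Draws for the stochastic mode.
#' @param seed Seed for the stochastic mode.
#' @return Tibble per species: `units` (units incorporated), `abundance`,
#'   `mass_kDa` (`NA` without unit sequences).
#' @export
simulate_yield <- function(plan, p, method = c("exact", "stochastic"),
                           n_draws = 1e5, seed = 1) {
  method <- match.arg(method)
  p <- resolve_junction_p(plan, p)
  n <- nrow(plan$units)
  nj <- n - 1
  if (plan$scheme == "solid_phase") {
    if (method == "exact") {
      ab <- numeric(n)
      for (m in seq_len(n - 1)) {
        ab[m] <- prod(p[seq_len(m - 1)]) * (1 - p[m])
      }
      ab[n] <- prod(p)
      species <- tibble(units = seq_len(n), abundance = ab)
    } else {
      draws <- withr::with_seed(seed, {
        fails <- matrix(stats::runif(n_draws * nj) >= rep(p, each = n_draws), n_draws, nj)
        first_fail <- apply(fails, 1, function(z) {
          i <- which(z)[1]
          if (is.na(i)) n else i
        })
        first_fail
      })
      species <- tibble(units = seq_len(n)) |>
        left_join(
          tibble(units = draws) |> count(.data$units) |> mutate(abundance = .data$n / n_draws),
          by = "units"
        ) |>
        mutate(abundance = ifelse(is.na(.data$abundance), 0, .data$abundance)) |>
        select("units", "abundance")
    }
  } else {
    if (method == "exact") {
      if (n > 20) {
        abort(
          "exact one-pot enumeration supports up to 20 units",
          class = "inteinscreen_size_error"
        )
      }
      npat <- 2^nj
      idx <- 0:(npat - 1)
      prob <- rep(1, npat)
      run <- integer(npat)
      maxrun <- integer(npat)
      for (j in seq_len(nj)) {
        success <- bitwAnd(idx, bitwShiftL(1L, j - 1L)) > 0
        prob <- prob * ifelse(success, p[j], 1 - p[j])
        run <- ifelse(success, run + 1L, 0L)
        maxrun <- pmax(maxrun, run)
      }
      sizes <- maxrun + 1L
      species <- tibble(units = sizes, abundance = prob) |>
        group_by(.data$units) |>
        summarise(abundance = sum(.data$abundance), .groups = "drop")
    } else {
      sizes <- withr::with_seed(seed, {
        succ <- matrix(stats::runif(n_draws * nj) < rep(p, each = n_draws), n_draws, nj)
        apply(succ, 1, function(z) {
          r <- rle(z)
          1L + max(0L, r$lengths[r$values])
        })
      })
      species <- tibble(units = sizes) |>
        count(.data$units) |>
        mutate(abundance = .data$n / n_draws) |>
        select("units", "abundance")
    }
  }
  species |>
    filter(.data$abundance > 0 | .data$units == n) |>
    mutate(mass_kDa = map_dbl(.data$units, ~ ladder_mass(plan$units, .x))) |>
    arrange(.data$units)
}
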