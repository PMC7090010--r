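library(dplyr)
library(tibble)

# cross_matrix from a relative cross-talk matrix T (diagonal ignored),
# with a common cognate level on the diagonal
rel_to_matrix <- function(T_rel, cognate = 1000) {
  pairs <- rownames(T_rel)
  if (is.null(pairs)) {
    pairs <- split_pair_id(sprintf("int%02d", seq_len(nrow(T_rel))))
    dimnames(T_rel) <- list(pairs, pairs)
  }
  M <- T_rel * cognate
  diag(M) <- cognate
  cells <- as_tibble(M, rownames = "row") |>
    tidyr::pivot_longer(-row, names_to = "col", values_to = "mean")
  cross_matrix(cells, pairs = pairs)
}

# k x k relative matrix with constant off-diagonal cross-talk
const_rel <- function(k, level = 0) {
  pairs <- split_pair_id(sprintf("int%02d", seq_len(k)))
  T_rel <- matrix(level, k, k, dimnames = list(pairs, pairs))
  diag(T_rel) <- 1
  T_rel
}

random_rel <- function(k, hi = 0.35) {
  pairs <- split_pair_id(sprintf("int%02d", seq_len(k)))
  T_rel <- matrix(stats::runif(k * k, 0, hi), k, k, dimnames = list(pairs, pairs))
  diag(T_rel) <- 1
  T_rel
}

# independent oracle: feasibility of a pair subset by direct arithmetic on
# the raw matrix, and the maximum feasible subset by full enumeration
oracle_feasible <- function(M, pairs) {
  for (p in pairs) {
    others <- setdiff(pairs, p)
    if (length(others) == 0) next
    rel <- c(M[p, others], M[others, p]) / M[p, p]
    rel[rel < 0] <- 0
    if (!(max(rel) < 0.2 && stats::median(rel) < 0.05)) return(FALSE)
  }
  TRUE
}

oracle_max_subset <- function(m) {
  M <- as.matrix(m)
  pairs <- m$pairs
  best <- character(0)
  for (size in rev(seq_along(pairs))) {
    if (size <= length(best)) break
    sets <- combn(pairs, size, simplify = FALSE)
    for (s in sets) {
      if (oracle_feasible(M, s)) {
        best <- s
        break
      }
    }
    if (length(best) == size) break
  }
  best
}

# minimal plate with one blank well (both channels), one complete test
# well and one test well missing its OD600 partner
tiny_plate <- function() {
  readings <- tibble(
    plate_id = "P1",
    well = c("A1", "A1", "A2", "A2", "A3"),
    sample_id = c("blk", "blk", "s1", "s1", "s2"),
    channel = c("mCherry", "OD600", "mCherry", "OD600", "mCherry"),
    time_s = 0,
    value = c(100, 0.04, 5000, 0.5, 3000)
  )
  layout <- tibble(
    sample_id = c("blk", "s1", "s2"),
    role = c("blank_medium", "test", "test"),
    replicate_group = c("blank", "g1", "g2")
  )
  list(readings = readings, layout = layout)
}

# band table builder: one row per species with given intensities, repeated
# over channels x membranes
bands_from <- function(per_quant, sample_id = "s1") {
  purrr::imap(per_quant, function(channels, membrane) {
    purrr::imap(channels, function(species_int, channel) {
      tibble(
        sample_id = sample_id, lane_id = sample_id, membrane_id = membrane,
        channel = channel, species = names(species_int),
        intensity = unname(species_int)
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}
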