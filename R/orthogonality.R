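#' Identifier for a split-intein pair
#'
#' A split pair is a parent intein bisected at one of three sites: S1 near
#' the N-terminus, S2 at the canonical endonuclease insertion site (or the
#' natural split point), S3 near the C-terminus. Pairs are keyed as
#' `"intein:site"`, e.g. `"gp41-1:S2"`.
#'
#' @param intein Parent intein name(s).
#' @param split_site Split site, one of `"S1"`, `"S2"`, `"S3"` (recycled).
#' @return Character vector of pair ids.
#' @export
split_pair_id <- function(intein, split_site = "S2") {
  ok <- split_site %in% c("S1", "S2", "S3")
  if (!all(ok)) {
    abort(
      paste0("invalid split site(s): ", paste(unique(split_site[!ok]), collapse = ", ")),
      class = "inteinscreen_format_error"
    )
  }
  paste0(intein, ":", split_site)
}

parse_pair_id <- function(pair) {
  site <- sub("^.*:", "", pair)
  tibble(
    pair = pair,
    intein = sub(":[^:]*$", "", pair),
    split_site = site
  )
}

#' Construct a cross-reactivity matrix
#'
#' A cross matrix holds the normalized signal of every N-half x C-half
#' combination of a panel of split-intein pairs: rows are N-halves, columns
#' C-halves, and the diagonal holds the cognate (matched) combinations. The
#' matrix must be square and complete -- a k-pair panel has k^2 cells
#' (576 for 24 pairs, 144 for 12).
#'
#' @param cells Tibble with columns `row` (N-half pair id), `col` (C-half
#'   pair id) and `mean` (normalized signal, a.u.); an optional `replicates`
#'   list-column carries per-cell replicate values.
#' @param pairs Pair ordering; defaults to order of first appearance in
#'   `row`.
#' @return An object of class `cross_matrix`.
#' @export
cross_matrix <- function(cells, pairs = unique(cells$row)) {
  required <- c("row", "col", "mean")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0) {
    abort(
      paste0("cross-matrix cells missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "inteinscreen_format_error"
    )
  }
  cells <- as_tibble(cells)
  if (!setequal(unique(cells$row), pairs) || !setequal(unique(cells$col), pairs)) {
    abort(
      "rows and columns must contain the same split-pair set (square matrix)",
      class = "inteinscreen_shape_error"
    )
  }
  dup <- cells |> count(.data$row, .data$col) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(
      paste0(
        "duplicate cell(s): ",
        paste(head(paste0(dup$row, " x ", dup$col), 5), collapse = "; ")
      ),
      class = "inteinscreen_ambiguity_error"
    )
  }
  expected <- tidyr::expand_grid(row = pairs, col = pairs)
  absent <- anti_join(expected, cells, by = c("row", "col"))
  if (nrow(absent) > 0) {
    abort(
      paste0(
        nrow(absent), " combination(s) absent, e.g. ",
        paste(head(paste0(absent$row, " x ", absent$col), 5), collapse = "; ")
      ),
      class = "inteinscreen_shape_error"
    )
  }
  structure(
    list(cells = cells, pairs = pairs),
    class = "cross_matrix"
  )
}

#' Assemble a cross matrix from normalized signals and a sample pairing
#'
#' @param signals Normalized-signal tibble (columns `sample_id`, `mean`, and
#'   optionally `sd`, `n`), e.g. from [normalize_plate()].
#' @param pairing Tibble mapping `sample_id` to the N-half (`row`) and
#'   C-half (`col`) pair ids of the combination that sample measured.
#' @return A [cross_matrix()].
#' @export
build_cross_matrix <- function(signals, pairing) {
  required <- c("sample_id", "row", "col")
  missing_cols <- setdiff(required, names(pairing))
  if (length(missing_cols) > 0) {
    abort(
      paste0("pairing missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "inteinscreen_format_error"
    )
  }
  unmatched <- setdiff(pairing$sample_id, signals$sample_id)
  if (length(unmatched) > 0) {
    abort(
      paste0(
        length(unmatched), " pairing sample(s) without signal, e.g. ",
        paste(head(unmatched, 5), collapse = ", ")
      ),
      class = "inteinscreen_shape_error"
    )
  }
  cells <- pairing |>
    inner_join(signals, by = "sample_id") |>
    select("row", "col", "mean")
  cross_matrix(cells, pairs = unique(pairing$row))
}

#' @export
as.matrix.cross_matrix <- function(x, ...) {
  wide <- matrix(
    NA_real_, length(x$pairs), length(x$pairs),
    dimnames = list(x$pairs, x$pairs)
  )
  wide[cbind(x$cells$row, x$cells$col)] <- x$cells$mean
  wide
}

#' @export
print.cross_matrix <- function(x, ...) {
  k <- length(x$pairs)
  cat("<cross_matrix> ", k, " x ", k, " (", k^2, " combinations)\n", sep = "")
  print(utils::head(as.matrix(x), 6L))
  invisible(x)
}

#' @export
dim.cross_matrix <- function(x) rep(length(x$pairs), 2)

#' Restrict a cross matrix to a subset of pairs
#'
#' @param m A [cross_matrix()].
#' @param pairs Pair ids to keep (original order preserved).
#' @return The restricted `cross_matrix`.
#' @export
restrict_pairs <- function(m, pairs) {
  keep <- m$pairs[m$pairs %in% pairs]
  if (length(keep) == 0) {
    abort("restriction removes every pair", class = "inteinscreen_shape_error")
  }
  cross_matrix(
    m$cells |> filter(.data$row %in% keep, .data$col %in% keep),
    pairs = keep
  )
}

#' Read / write a cross matrix as a CSV grid
#'
#' The grid has a header row of C-half pair ids and a first column (named
#' `pair`) of N-half pair ids.
#'
#' @param path CSV path.
#' @return `read_cross_matrix()` returns a [cross_matrix()];
#'   `write_cross_matrix()` returns `path` invisibly.
#' @export
read_cross_matrix <- function(path) {
  grid <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  pairs <- grid[[1]]
  cells <- grid |>
    rename(row = 1) |>
    tidyr::pivot_longer(-"row", names_to = "col", values_to = "mean")
  cross_matrix(cells, pairs = pairs)
}

#' @rdname read_cross_matrix
#' @param m A [cross_matrix()].
#' @export
write_cross_matrix <- function(m, path) {
  wide <- as.matrix(m)
  out <- as_tibble(wide, rownames = "pair")
  readr::write_csv(out, path)
  invisible(path)
}

# k x k numeric matrix of means with negatives floored at 0 (negative
# normalized signal is treated as zero product downstream).
floored_matrix <- function(m) {
  M <- as.matrix(m)
  M[M < 0] <- 0
  M
}

#' Cognate-normalized non-cognate signal values for one pair
#'
#' Collects the pair's row and column cells (its N-half against every other
#' C-half, and every other N-half against its C-half), excludes the cognate
#' diagonal cell, and divides each by the pair's cognate signal. For a k x k
#' matrix under policy `"all"` this yields 2(k-1) relative values (46 for
#' k = 24). Policy `"exclude_same_intein"` additionally drops combinations
#' whose partner is the same parent intein split at another site, where
#' sequence overlap between halves makes cross-reaction expected.
#'
#' @param m A [cross_matrix()].
#' @param pair Pair id.
#' @param policy `"all"` or `"exclude_same_intein"`.
#' @return Named numeric vector of relative values (names identify the
#'   non-cognate combination as `"N-half|C-half"`).
#' @export
noncognate_values <- function(m, pair, policy = c("all", "exclude_same_intein")) {
  policy <- match.arg(policy)
  if (!pair %in% m$pairs) {
    abort(paste0("pair not in matrix: ", pair), class = "inteinscreen_shape_error")
  }
  M <- floored_matrix(m)
  cognate <- M[pair, pair]
  if (cognate <= 0) {
    abort(
      paste0("cognate signal not positive for ", pair, "; relative values undefined"),
      class = "inteinscreen_normalization_error"
    )
  }
  others <- setdiff(m$pairs, pair)
  if (policy == "exclude_same_intein") {
    parent <- parse_pair_id(pair)$intein
    others <- others[parse_pair_id(others)$intein != parent]
  }
  if (length(others) == 0) {
    return(numeric(0))
  }
  vals <- c(
    setNames(M[pair, others], paste0(pair, "|", others)),
    setNames(M[others, pair], paste0(others, "|", pair))
  )
  vals / cognate
}

#' Apply the two-threshold orthogonality criterion
#'
#' A pair's non-cognate interactions are called negligible -- the pair
#' orthogonal -- when every cognate-normalized non-cognate value is below
#' `max_threshold` (default 0.2) and their median is below
#' `median_threshold` (default 0.05); both inequalities are strict. The
#' criterion is scale-free: rescaling all matrix values uniformly leaves
#' every call unchanged.
#'
#' @inheritParams noncognate_values
#' @param pairs Pairs to classify (default: all).
#' @param max_threshold Upper bound every relative value must stay below.
#' @param median_threshold Upper bound the median must stay below.
#' @return Tibble with one row per pair: `pair`, `intein`, `split_site`,
#'   `n_noncognate`, `max_rel`, `median_rel`, `orthogonal`.
#' @export
classify_orthogonal <- function(m, pairs = m$pairs,
                                max_threshold = 0.2, median_threshold = 0.05,
                                policy = c("all", "exclude_same_intein")) {
  policy <- match.arg(policy)
  stopifnot(median_threshold > 0, median_threshold <= max_threshold, max_threshold < 1)
  calls <- map(pairs, function(p) {
    rel <- noncognate_values(m, p, policy = policy)
    tibble(
      pair = p,
      n_noncognate = length(rel),
      max_rel = if (length(rel)) max(rel) else 0,
      median_rel = if (length(rel)) median(rel) else 0,
      orthogonal = (length(rel) == 0) ||
        (max(rel) < max_threshold && median(rel) < median_threshold)
    )
  }) |> list_rbind()
  parse_pair_id(calls$pair) |>
    select("pair", "intein", "split_site") |>
    left_join(calls, by = "pair")
}

# Blame assignment for pruning: every relative value breaching the max
# threshold implicates two pairs (the one being normalized and its
# partner); the pair implicated most often is the one whose removal
# resolves the most violations. A pair breaking only the median rule
# blames itself. Deterministic tie-break: median_rel, max_rel, pair id.
prune_order <- function(m, calls, max_threshold) {
  M <- floored_matrix(m)
  cog <- diag(M)
  names(cog) <- m$pairs
  blame <- setNames(rep(0, length(m$pairs)), m$pairs)
  for (p in m$pairs) {
    others <- setdiff(m$pairs, p)
    if (length(others) == 0) next
    rel_row <- M[p, others] / cog[p]
    rel_col <- M[others, p] / cog[p]
    offenders <- c(others[rel_row >= max_threshold], others[rel_col >= max_threshold])
    blame[p] <- blame[p] + length(offenders)
    for (q in offenders) blame[q] <- blame[q] + 1
  }
  med_fail <- calls$pair[!calls$orthogonal & calls$max_rel < max_threshold]
  blame[med_fail] <- blame[med_fail] + 1
  calls |>
    mutate(blame = blame[.data$pair]) |>
    arrange(
      desc(.data$blame), desc(.data$median_rel),
      desc(.data$max_rel), .data$pair
    )
}

#' Prune a cross matrix down to a mutually orthogonal split-intein set
#'
#' Iteratively removes the worst-offending pair and re-applies the
#' two-threshold criterion within the reduced matrix, until every remaining
#' pair classifies orthogonal. The worst offender is the pair implicated in
#' the most max-rule violations (each relative value at or above the
#' threshold implicates both the pair being normalized and its partner, so
#' a single promiscuous pair that contaminates the whole panel is removed
#' before its victims); ties break by `median_rel`, `max_rel`, then
#' lexicographic pair id, making the result deterministic. The criterion is
#' re-evaluated at every step because removing pairs changes both the
#' maximum and the median of the remaining non-cognate values. Finally, when a parent intein survives
#' with several split variants, the variant with the highest cognate signal
#' is kept, giving one representative pair per intein.
#'
#' @inheritParams classify_orthogonal
#' @return An object of class `ortho_set`: a list with `pairs` (one
#'   representative pair per surviving intein), `inteins` (surviving parent
#'   inteins), `mutually_orthogonal_pairs` (all pairs surviving the pruning,
#'   before variant selection), `removed` (pairs pruned out, in removal
#'   order) and `calls` (final classification within the pruned matrix).
#' @export
prune_mutually_orthogonal <- function(m, max_threshold = 0.2,
                                      median_threshold = 0.05,
                                      policy = c("all", "exclude_same_intein")) {
  policy <- match.arg(policy)
  keep <- m$pairs
  removed <- character(0)
  repeat {
    if (length(keep) == 0) break
    sub <- restrict_pairs(m, keep)
    calls <- classify_orthogonal(
      sub,
      max_threshold = max_threshold, median_threshold = median_threshold,
      policy = policy
    )
    if (all(calls$orthogonal)) break
    # the most-blamed pair may itself classify orthogonal (a strong binder
    # can contaminate everyone else's values); it is still the right removal
    worst <- prune_order(sub, calls, max_threshold)$pair[1]
    removed <- c(removed, worst)
    keep <- setdiff(keep, worst)
  }
  cog <- diag(floored_matrix(m))[keep]
  reps <- parse_pair_id(keep) |>
    mutate(cognate = cog) |>
    group_by(.data$intein) |>
    arrange(desc(.data$cognate), .data$pair, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  structure(
    list(
      pairs = reps$pair,
      inteins = sort(unique(reps$intein)),
      mutually_orthogonal_pairs = keep,
      removed = removed,
      calls = if (length(keep)) calls else tibble(),
      max_threshold = max_threshold,
      median_threshold = median_threshold,
      policy = policy
    ),
    class = "ortho_set"
  )
}

#' @export
print.ortho_set <- function(x, ...) {
  cat(
    "<ortho_set> ", length(x$mutually_orthogonal_pairs), " mutually orthogonal pair(s), ",
    length(x$inteins), " parent intein(s); ", length(x$removed), " removed\n",
    sep = ""
  )
  cat("inteins:", paste(x$inteins, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.ortho_set <- function(x, ...) {
  x$calls |>
    mutate(representative = .data$pair %in% x$pairs)
}

#' @export
glance.ortho_set <- function(x, ...) {
  tibble(
    n_pairs = length(x$mutually_orthogonal_pairs),
    n_inteins = length(x$inteins),
    n_removed = length(x$removed),
    max_threshold = x$max_threshold,
    median_threshold = x$median_threshold,
    policy = x$policy
  )
}

# Is the subset `pairs` mutually orthogonal within itself?
subset_feasible <- function(M, cog, pairs, max_threshold, median_threshold) {
  for (p in pairs) {
    others <- setdiff(pairs, p)
    if (length(others) == 0) next
    rel <- c(M[p, others], M[others, p]) / cog[p]
    if (!(max(rel) < max_threshold && median(rel) < median_threshold)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Largest mutually orthogonal subset of a cross matrix
#'
#' Finds the largest subset S of pairs such that every member classifies
#' orthogonal when the non-cognate values are restricted to S. `"exact"`
#' mode runs a branch-and-bound whose result equals exhaustive enumeration
#' over all subsets: branches are pruned only on the size bound and on
#' violations of the max-value rule, which is monotone under adding members
#' (the median rule is not monotone and is therefore checked on complete
#' candidate subsets only). `"greedy"` mode returns the
#' [prune_mutually_orthogonal()] surviving pairs; the exact subset is never
#' smaller than the greedy one.
#'
#' @inheritParams classify_orthogonal
#' @param mode `"exact"` (k <= 25) or `"greedy"`.
#' @return Character vector of pair ids (in matrix order).
#' @export
max_orthogonal_subset <- function(m, max_threshold = 0.2, median_threshold = 0.05,
                                  mode = c("exact", "greedy"),
                                  policy = c("all", "exclude_same_intein")) {
  mode <- match.arg(mode)
  policy <- match.arg(policy)
  if (mode == "greedy") {
    res <- prune_mutually_orthogonal(
      m,
      max_threshold = max_threshold,
      median_threshold = median_threshold, policy = policy
    )
    return(res$mutually_orthogonal_pairs)
  }
  k <- length(m$pairs)
  if (k > 25) {
    abort(
      paste0("exact mode supports up to 25 pairs (got ", k, "); use mode = \"greedy\""),
      class = "inteinscreen_size_error"
    )
  }
  M <- floored_matrix(m)
  cog <- diag(M)
  if (any(cog <= 0)) {
    abort(
      paste0(
        "cognate signal not positive for: ",
        paste(m$pairs[cog <= 0], collapse = ", ")
      ),
      class = "inteinscreen_normalization_error"
    )
  }
  names(cog) <- m$pairs
  pairs <- m$pairs
  if (policy == "exclude_same_intein") {
    # Same-intein combinations never enter the criterion under this policy;
    # mask them to zero so they cannot trigger the max rule.
    parents <- parse_pair_id(pairs)$intein
    same <- outer(parents, parents, "==")
    diag(same) <- FALSE
    M[same] <- 0
  }
  # conflict[i, j]: i and j can never coexist (some mutual relative value
  # breaches the max rule; monotone, so true in every superset).
  rel_ij <- sweep(M, 1, cog[pairs], "/") # row-normalized: M[i,j]/cog[i]
  conflict <- matrix(FALSE, k, k, dimnames = list(pairs, pairs))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j && (rel_ij[i, j] >= max_threshold || rel_ij[j, i] >= max_threshold)) {
        conflict[i, j] <- TRUE
        conflict[j, i] <- TRUE
      }
    }
  }
  best <- character(0)
  recurse <- function(idx, included) {
    if (length(included) + (k - idx + 1) <= length(best)) {
      return(invisible(NULL))
    }
    if (idx > k) {
      if (length(included) > length(best) &&
        subset_feasible(M, cog, included, max_threshold, median_threshold)) {
        best <<- included
      }
      return(invisible(NULL))
    }
    p <- pairs[idx]
    # include p first (favors larger subsets early, tightening the bound)
    if (!any(conflict[p, included])) {
      recurse(idx + 1, c(included, p))
    }
    recurse(idx + 1, included)
    invisible(NULL)
  }
  recurse(1L, character(0))
  pairs[pairs %in% best]
}

#' Heat-map of a cross matrix on the cognate-normalized scale
#'
#' @param object A [cross_matrix()].
#' @param relative Show each cell divided by its row pair's cognate signal
#'   (default) rather than raw means.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cross_matrix <- function(object, relative = TRUE, ...) {
  M <- floored_matrix(object)
  if (relative) M <- sweep(M, 1, ifelse(diag(M) > 0, diag(M), NA_real_), "/")
  df <- as_tibble(M, rownames = "row") |>
    tidyr::pivot_longer(-"row", names_to = "col", values_to = "value") |>
    mutate(
      row = factor(.data$row, levels = rev(object$pairs)),
      col = factor(.data$col, levels = object$pairs)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = if (relative) "rel. signal" else "a.u.") +
    ggplot2::labs(x = "C-half", y = "N-half") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1))
}
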