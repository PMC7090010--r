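#' Score a reaction-condition grid and pick one common optimum
#'
#' Each intein's end-point signals are first rescaled to its own maximum,
#' making the score independent of per-intein signal magnitude. Each
#' condition then receives an aggregate score across inteins; the default
#' aggregate `"min"` scores a condition by its worst-performing intein, so
#' the selected condition is the best worst case -- appropriate when the
#' goal is simultaneous use of any intein combination. `"median"` and
#' `"mean"` alternatives are provided. Conditions are ranked by score
#' (descending), ties broken by median score and then lexicographically;
#' the selected condition is the top of the ranking.
#'
#' @param grid Tibble with columns `intein`, `pH`, `NaCl_mM`,
#'   `temperature_C`, `value` (end-point normalized signal, a.u.), one row
#'   per intein x condition. Inteins with no positive signal anywhere are
#'   excluded with a warning.
#' @param aggregate `"min"`, `"median"` or `"mean"`.
#' @return An object of class `condition_screen`: list with `ranking`
#'   (tibble of conditions with `score` and `median_score`), `selected`
#'   (one-row tibble) and `aggregate`.
#' @export
score_conditions <- function(grid, aggregate = c("min", "median", "mean")) {
  aggregate <- match.arg(aggregate)
  required <- c("intein", "pH", "NaCl_mM", "temperature_C", "value")
  missing_cols <- setdiff(required, names(grid))
  if (length(missing_cols) > 0) {
    abort(
      paste0("condition grid missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "inteinscreen_format_error"
    )
  }
  grid <- as_tibble(grid)
  dead <- grid |>
    group_by(.data$intein) |>
    summarise(peak = max(.data$value), .groups = "drop") |>
    filter(.data$peak <= 0)
  if (nrow(dead) > 0) {
    warn(paste0(
      "excluding intein(s) with no positive signal: ",
      paste(dead$intein, collapse = ", ")
    ))
    grid <- grid |> filter(!.data$intein %in% dead$intein)
  }
  if (nrow(grid) == 0) {
    abort("no intein with positive signal", class = "inteinscreen_input_error")
  }
  agg_fun <- switch(aggregate, min = min, median = median, mean = mean)
  scored <- grid |>
    group_by(.data$intein) |>
    mutate(rel = pmax(.data$value, 0) / max(.data$value)) |>
    ungroup() |>
    group_by(.data$pH, .data$NaCl_mM, .data$temperature_C) |>
    summarise(
      score = agg_fun(.data$rel),
      median_score = median(.data$rel),
      n_inteins = n(),
      .groups = "drop"
    ) |>
    arrange(
      desc(.data$score), desc(.data$median_score),
      .data$pH, .data$NaCl_mM, .data$temperature_C
    )
  structure(
    list(
      ranking = scored,
      selected = scored[1, ],
      aggregate = aggregate
    ),
    class = "condition_screen"
  )
}

#' @export
print.condition_screen <- function(x, ...) {
  s <- x$selected
  cat(
    "<condition_screen> ", nrow(x$ranking), " conditions, aggregate = ", x$aggregate, "\n",
    "selected: pH ", s$pH, ", ", s$NaCl_mM, " mM NaCl, ", s$temperature_C,
    " °C (score ", signif(s$score, 3), ")\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.condition_screen <- function(x, ...) x$ranking

#' @export
glance.condition_screen <- function(x, ...) {
  bind_cols(x$selected, tibble(aggregate = x$aggregate, n_conditions = nrow(x$ranking)))
}

#' @export
autoplot.condition_screen <- function(object, ...) {
  ggplot2::ggplot(
    object$ranking,
    ggplot2::aes(
      x = factor(.data$temperature_C), y = factor(.data$NaCl_mM),
      fill = .data$score
    )
  ) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~ paste0("pH ", .data$pH)) +
    ggplot2::scale_fill_viridis_c(name = paste0(object$aggregate, " score"), limits = c(0, 1)) +
    ggplot2::labs(x = "temperature (°C)", y = "NaCl (mM)") +
    ggplot2::theme_minimal()
}
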