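#' Call cis-splicing activity from normalized end-point fluorescence
#'
#' A culture expressing an intein-interrupted reporter precursor is called
#' active when its normalized fluorescence (Fluo./OD600, control-subtracted)
#' lies strictly above the activity threshold, 2000 a.u. by default.
#'
#' @param signals Normalized-signal tibble (`sample_id`, `mean`, ...).
#' @param threshold Activity threshold in a.u. (strict `>`).
#' @return The input with `context`, `threshold` and logical `active`
#'   columns appended.
#' @export
call_cis_active <- function(signals, threshold = 2000) {
  signals |>
    as_tibble() |>
    mutate(
      context = "cis_in_vivo",
      threshold = threshold,
      active = .data$mean > threshold
    )
}

#' Call in vitro trans-splicing activity (fluorescence AND spliced-product rule)
#'
#' An in vitro reaction is active when its end-point fluorescence is
#' strictly above `fluo_threshold` (4000 a.u.) and its spliced-product
#' level is strictly above `frac_threshold` (10%) of the maximum spliced
#' level achieved in the cohort by the most efficient pair. The spliced
#' levels are normalized to the cohort maximum internally.
#'
#' @param reactions Tibble with `sample_id`, `signal` (end-point
#'   fluorescence, a.u.) and `spliced` (end-point spliced-product level,
#'   any common unit across the cohort).
#' @param fluo_threshold Fluorescence threshold, a.u. (strict `>`).
#' @param frac_threshold Fraction of the cohort-maximum spliced level
#'   (strict `>`).
#' @return The input with `spliced_rel_max`, thresholds and `active`
#'   appended.
#' @export
call_invitro_active <- function(reactions, fluo_threshold = 4000,
                                frac_threshold = 0.10) {
  reactions <- as_tibble(reactions)
  ref <- max(reactions$spliced)
  if (!is.finite(ref) || ref <= 0) {
    abort(
      "cohort maximum spliced level is not positive; relative levels undefined",
      class = "inteinscreen_reference_error"
    )
  }
  reactions |>
    mutate(
      spliced_rel_max = .data$spliced / ref,
      context = "in_vitro",
      active = .data$signal > fluo_threshold & .data$spliced_rel_max > frac_threshold
    )
}

series_value_at <- function(times, values, t) {
  if (t <= min(times)) {
    return(values[which.min(times)])
  }
  approx(times, values, xout = t, rule = 2)$y
}

#' Classify splicing kinetics as fast or slow
#'
#' A reaction is fast when its signal at `t_cut` (1 h by default, linearly
#' interpolated between samples) exceeds `frac` (75%) of its plateau, taken
#' as the maximum observed over the series. The classification is invariant
#' to rescaling the whole series. All-zero series are not classifiable
#' (`fast = NA`).
#'
#' @param series Tibble with `sample_id`, `time_s`, `value` covering
#'   `t_cut`.
#' @param frac Plateau fraction that must be reached (strict `>`).
#' @param t_cut Read-out time in seconds (default 3600).
#' @return Tibble per sample: `plateau`, `frac_at_cut` (signal at `t_cut`
#'   relative to plateau), `fast`.
#' @export
classify_fast <- function(series, frac = 0.75, t_cut = 3600) {
  series <- as_tibble(series)
  series |>
    group_by(.data$sample_id) |>
    summarise(
      plateau = max(.data$value),
      .v_cut = {
        if (max(.data$time_s) < t_cut) {
          abort(
            paste0("series for ", .data$sample_id[1], " does not cover t_cut = ", t_cut, " s"),
            class = "inteinscreen_input_error"
          )
        }
        series_value_at(.data$time_s, .data$value, t_cut)
      },
      .groups = "drop"
    ) |>
    mutate(
      frac_at_cut = ifelse(.data$plateau > 0, .data$.v_cut / .data$plateau, NA_real_),
      fast = ifelse(.data$plateau > 0, .data$frac_at_cut > frac, NA)
    ) |>
    select(-".v_cut")
}

#' Fit a delayed first-order splicing progress curve
#'
#' Least-squares fit of A(1 - exp(-k (t - d)+)), the first-order product
#' accumulation with an onset delay d that absorbs the lag between splicing
#' and fluorophore maturation. The delay can be fixed (`delay = value`),
#' fitted (`delay = NULL`, the default), or removed (`delay = 0`).
#'
#' @param series Tibble with `time_s` and `value` for one reaction (at
#'   least 4 time points).
#' @param delay `NULL` to fit the delay, or a fixed delay in seconds.
#' @return An object of class `splice_fit` with [tidy()] and [glance()]
#'   methods; elements `rate` (per second), `plateau`, `delay`, `rss` and
#'   the underlying `nls` fit.
#' @export
fit_first_order <- function(series, delay = NULL) {
  series <- as_tibble(series)
  if (nrow(series) < 4) {
    abort("need at least 4 time points", class = "inteinscreen_input_error")
  }
  t <- series$time_s
  y <- series$value
  if (diff(range(y)) <= 0 || max(y) <= 0) {
    abort(
      "series has no dynamic range; rate unidentifiable",
      class = "inteinscreen_fit_error"
    )
  }
  a0 <- max(y)
  # onset guess: last time before the signal first exceeds 5% of the plateau
  ionset <- which(y > 0.05 * a0)[1]
  d0 <- if (is.na(ionset) || ionset == 1) 0 else t[ionset - 1]
  # rate guess from the half-rise time past the onset
  ihalf <- which(y >= 0.5 * a0)[1]
  k0 <- if (is.na(ihalf) || t[ihalf] <= d0) 1e-3 else log(2) / (t[ihalf] - d0)
  df <- tibble(t = t, y = y)
  fit <- tryCatch(
    {
      if (is.null(delay)) {
        minpack.lm::nlsLM(
          y ~ A * (1 - exp(-k * pmax(t - d, 0))),
          data = df,
          start = list(A = a0, k = k0, d = d0),
          lower = c(A = 0, k = 1e-12, d = 0),
          control = minpack.lm::nls.lm.control(maxiter = 500)
        )
      } else {
        minpack.lm::nlsLM(
          y ~ A * (1 - exp(-k * pmax(t - delay, 0))),
          data = df,
          start = list(A = a0, k = k0),
          lower = c(A = 0, k = 1e-12),
          control = minpack.lm::nls.lm.control(maxiter = 500)
        )
      }
    },
    error = function(e) {
      abort(
        paste0("first-order fit did not converge: ", conditionMessage(e)),
        class = "inteinscreen_fit_error"
      )
    }
  )
  est <- coef(fit)
  structure(
    list(
      rate = unname(est["k"]),
      plateau = unname(est["A"]),
      delay = if (is.null(delay)) unname(est["d"]) else delay,
      delay_fitted = is.null(delay),
      rss = sum(resid(fit)^2),
      n = nrow(series),
      fit = fit,
      data = series
    ),
    class = "splice_fit"
  )
}

#' @export
print.splice_fit <- function(x, ...) {
  cat(
    "<splice_fit> A(1 - exp(-k (t - d)+))\n",
    "  plateau A = ", signif(x$plateau, 4),
    "  rate k = ", signif(x$rate, 4), " /s (", signif(x$rate * 3600, 4), " /h)",
    "  delay d = ", signif(x$delay, 4), " s\n",
    "  rss = ", signif(x$rss, 4), " over n = ", x$n, " points\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.splice_fit <- function(x, ...) {
  tibble(
    term = c("plateau", "rate", "delay"),
    estimate = c(x$plateau, x$rate, x$delay),
    unit = c("a.u.", "per_s", "s"),
    fitted = c(TRUE, TRUE, x$delay_fitted)
  )
}

#' @export
glance.splice_fit <- function(x, ...) {
  tibble(
    rss = x$rss,
    sigma = sqrt(x$rss / max(x$n - 3, 1)),
    n = x$n,
    rate_per_h = x$rate * 3600
  )
}

#' @export
autoplot.splice_fit <- function(object, ...) {
  grid <- tibble(time_s = seq(min(object$data$time_s), max(object$data$time_s), length.out = 200))
  grid$value <- object$plateau *
    (1 - exp(-object$rate * pmax(grid$time_s - object$delay, 0)))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "signal (a.u.)") +
    ggplot2::theme_minimal()
}
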