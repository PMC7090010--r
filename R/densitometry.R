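#' Default antibody epitope map for the dual-channel reporter blot
#'
#' The reporter construct carries an N-terminal mCherry epitope and a
#' C-terminal hexahistidine tag, probed on two membranes with two
#' antibodies. Each antibody sees the spliced product plus the unreacted
#' and side-reaction species that retain its epitope: the anti-mCherry-N
#' channel sees the precursor(s) and N-side cleavage products, the anti-His
#' channel the precursor(s) and C-side cleavage products.
#'
#' @return Named list: channel -> character vector of visible species.
#' @export
default_epitope_map <- function() {
  list(
    anti_mCherry_N = c("precursor", "n_precursor", "spliced", "n_cleavage"),
    anti_His_C = c("precursor", "c_precursor", "spliced", "c_cleavage")
  )
}

BAND_SPECIES <- c(
  "precursor", "spliced", "n_cleavage", "c_cleavage",
  "n_precursor", "c_precursor", "other"
)

validate_bands <- function(bands) {
  required <- c("lane_id", "membrane_id", "channel", "species", "intensity")
  missing_cols <- setdiff(required, names(bands))
  if (length(missing_cols) > 0) {
    abort(
      paste0("band table missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "inteinscreen_format_error"
    )
  }
  bad <- setdiff(unique(bands$species), BAND_SPECIES)
  if (length(bad) > 0) {
    abort(
      paste0("unknown band species: ", paste(bad, collapse = ", ")),
      class = "inteinscreen_format_error"
    )
  }
  if (any(bands$intensity < 0)) {
    abort("negative band intensity", class = "inteinscreen_format_error")
  }
  as_tibble(bands)
}

#' Splicing efficiency from Western-blot band intensities
#'
#' For every channel x membrane quantification, efficiency is the spliced
#' band's intensity divided by the summed intensity of all species visible
#' to that channel's antibody. The estimate is the mean (and sd) over the
#' channel x membrane values -- with two antibodies and two membranes this
#' averages n = 4 band-signal quantifications. The ratio is invariant to
#' uniform exposure rescaling within a quantification. When any
#' quantification has zero total signal the efficiency is reported as
#' absent (`NA`, "not detected") rather than extrapolated from the
#' remaining quantifications.
#'
#' @param bands Band-intensity tibble with columns `lane_id`, `membrane_id`,
#'   `channel`, `species`, `intensity` (a.u., >= 0); an optional `sample_id`
#'   column groups lanes into samples (defaults to `lane_id`).
#' @param emap Epitope map (see [default_epitope_map()]).
#' @return Tibble with one row per sample: `sample_id`, `mean`, `sd`, `n`
#'   (number of channel x membrane quantifications).
#' @export
splicing_efficiency <- function(bands, emap = default_epitope_map()) {
  bands <- validate_bands(bands)
  if (!all(map_lgl(emap, function(sp) "spliced" %in% sp))) {
    abort(
      "epitope map must list the spliced species in every channel",
      class = "inteinscreen_config_error"
    )
  }
  if (is.null(bands[["sample_id"]])) bands$sample_id <- bands$lane_id
  visible <- tibble(
    channel = rep(names(emap), lengths(emap)),
    species = unlist(emap, use.names = FALSE)
  )
  bad_channel <- setdiff(unique(bands$channel), names(emap))
  if (length(bad_channel) > 0) {
    abort(
      paste0("channel(s) absent from epitope map: ", paste(bad_channel, collapse = ", ")),
      class = "inteinscreen_config_error"
    )
  }
  per_quant <- bands |>
    inner_join(visible, by = c("channel", "species")) |>
    group_by(.data$sample_id, .data$membrane_id, .data$channel) |>
    summarise(
      spliced = sum(.data$intensity[.data$species == "spliced"]),
      total = sum(.data$intensity),
      .groups = "drop"
    ) |>
    mutate(efficiency = ifelse(.data$total > 0, .data$spliced / .data$total, NA_real_))
  per_quant |>
    group_by(.data$sample_id) |>
    summarise(
      mean = if (anyNA(.data$efficiency)) NA_real_ else mean(.data$efficiency),
      sd = if (anyNA(.data$efficiency) || n() < 2) NA_real_ else sd(.data$efficiency),
      n = n(),
      .groups = "drop"
    )
}

#' Spliced-fraction time course from band tables collected over time
#'
#' Applies [splicing_efficiency()] independently at each time point; no
#' smoothing or interpolation is applied across points.
#'
#' @param bands Band tibble as in [splicing_efficiency()] plus a `time_s`
#'   column; at least two distinct time points are required.
#' @inheritParams splicing_efficiency
#' @return Tibble: `sample_id`, `time_s`, `mean`, `sd`, `n`, ordered by time.
#' @export
spliced_fraction_timecourse <- function(bands, emap = default_epitope_map()) {
  if (is.null(bands[["time_s"]])) {
    abort("band table needs a time_s column", class = "inteinscreen_format_error")
  }
  times <- sort(unique(bands$time_s))
  if (length(times) < 2) {
    abort(
      "a time course needs at least two time points",
      class = "inteinscreen_input_error"
    )
  }
  map(times, function(t) {
    splicing_efficiency(filter(bands, .data$time_s == t), emap = emap) |>
      mutate(time_s = t, .after = "sample_id")
  }) |>
    list_rbind() |>
    arrange(.data$sample_id, .data$time_s)
}
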