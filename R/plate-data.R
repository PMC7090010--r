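#' Read a long-format plate-reader export and join the sample layout
#'
#' The canonical input is a long CSV with one row per well reading:
#' columns `plate_id`, `well`, `sample_id`, `channel`, `time_s`, `value`.
#' Channels are restricted to the reporters the platform measures
#' (`mCherry`, `GFP`, `mTagBFP`) plus `OD600`. Every `sample_id` in the file
#' must appear in the layout, which declares each sample's `role`
#' (`test`, `blank_medium`, `negative_control`, `standard`) and
#' `replicate_group`; additional layout columns (intein, split site,
#' inducers, ...) are carried along as metadata.
#'
#' @param path Path to a long-format CSV export.
#' @param layout A data frame with columns `sample_id`, `role`,
#'   `replicate_group`, plus optional metadata columns, or a path to a
#'   TSV/CSV file with those columns.
#' @return A tibble of well readings joined to the layout (one row per
#'   reading; row count equals the file's row count).
#' @examples
#' path <- tempfile(fileext = ".csv")
#' readr::write_csv(tibble::tibble(
#'   plate_id = "P1", well = c("A1", "A2"), sample_id = c("blk", "s1"),
#'   channel = "mCherry", time_s = 0, value = c(100, 5000)
#' ), path)
#' layout <- tibble::tibble(
#'   sample_id = c("blk", "s1"), role = c("blank_medium", "test"),
#'   replicate_group = c("blank", "g1")
#' )
#' read_plate_table(path, layout)
#' @export
read_plate_table <- function(path, layout) {
  if (!file.exists(path)) {
    abort(paste0("plate file not found: ", path), class = "inteinscreen_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  layout <- read_layout(layout)
  signal_table(raw, layout)
}

#' Build a validated signal table from in-memory readings
#'
#' @param readings Data frame with columns `plate_id`, `well`, `sample_id`,
#'   `channel`, `time_s`, `value`.
#' @param layout Layout data frame (see [read_plate_table()]).
#' @return Tibble of readings joined to the layout.
#' @export
signal_table <- function(readings, layout) {
  required <- c("plate_id", "well", "sample_id", "channel", "time_s", "value")
  missing_cols <- setdiff(required, names(readings))
  if (length(missing_cols) > 0) {
    abort(
      paste0("plate table is missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "inteinscreen_format_error"
    )
  }
  readings <- as_tibble(readings)
  bad_channel <- setdiff(unique(readings$channel), PLATE_CHANNELS)
  if (length(bad_channel) > 0) {
    abort(
      paste0(
        "unknown channel(s): ", paste(bad_channel, collapse = ", "),
        " (expected one of ", paste(PLATE_CHANNELS, collapse = ", "), ")"
      ),
      class = "inteinscreen_format_error"
    )
  }
  if (any(!is.finite(readings$value))) {
    abort("non-finite values in plate table", class = "inteinscreen_format_error")
  }
  if (any(readings$time_s < 0)) {
    abort("negative time_s in plate table", class = "inteinscreen_format_error")
  }
  dup <- readings |>
    count(.data$plate_id, .data$well, .data$channel, .data$time_s) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(
      paste0(
        "duplicate readings for ", nrow(dup), " (plate, well, channel, time) key(s), e.g. ",
        dup$plate_id[1], "/", dup$well[1], "/", dup$channel[1], " t=", dup$time_s[1]
      ),
      class = "inteinscreen_format_error"
    )
  }
  layout <- read_layout(layout)
  orphan <- setdiff(unique(readings$sample_id), layout$sample_id)
  if (length(orphan) > 0) {
    abort(
      paste0("sample(s) missing from layout: ", paste(orphan, collapse = ", ")),
      class = "inteinscreen_layout_error"
    )
  }
  left_join(readings, layout, by = "sample_id")
}

#' Read or validate a sample layout
#'
#' @param layout A data frame, or a path to a TSV/CSV with columns
#'   `sample_id`, `role`, `replicate_group` and optional metadata columns.
#' @return A validated layout tibble.
#' @export
read_layout <- function(layout) {
  if (is.character(layout) && length(layout) == 1) {
    reader <- if (grepl("\\.tsv$", layout)) readr::read_tsv else readr::read_csv
    layout <- reader(layout, show_col_types = FALSE, progress = FALSE)
  }
  required <- c("sample_id", "role", "replicate_group")
  missing_cols <- setdiff(required, names(layout))
  if (length(missing_cols) > 0) {
    abort(
      paste0("layout is missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "inteinscreen_layout_error"
    )
  }
  bad_role <- setdiff(unique(layout$role), SAMPLE_ROLES)
  if (length(bad_role) > 0) {
    abort(
      paste0("unknown layout role(s): ", paste(bad_role, collapse = ", ")),
      class = "inteinscreen_layout_error"
    )
  }
  as_tibble(layout)
}

#' Subtract the growth-medium blank from every reading
#'
#' For each plate, channel and (optionally) time point, the mean value of
#' the `blank_medium` wells is subtracted from every other well, removing
#' the medium's autofluorescence and absorbance background. Blank wells are
#' dropped from the output. Negative corrected values are retained, not
#' clamped: clamping would bias the medians used downstream by the
#' orthogonality criterion.
#'
#' @param table A signal table from [read_plate_table()] / [signal_table()].
#' @param per_time Subtract a per-time-point blank (default) rather than one
#'   time-averaged blank per plate and channel. Kinetic runs with a single
#'   pre-read blank should set `per_time = FALSE`.
#' @return The blank-corrected signal table (blank wells removed).
#' @export
blank_correct <- function(table, per_time = TRUE) {
  keys <- c("plate_id", "channel", if (per_time) "time_s")
  blanks <- table |>
    filter(.data$role == "blank_medium") |>
    group_by(across(all_of(keys))) |>
    summarise(.blank = mean(.data$value), .groups = "drop")
  out <- table |>
    filter(.data$role != "blank_medium") |>
    left_join(blanks, by = keys)
  uncovered <- out |>
    filter(is.na(.data$.blank)) |>
    distinct(.data$plate_id, .data$channel)
  if (nrow(uncovered) > 0) {
    abort(
      paste0(
        "no blank_medium well for plate/channel: ",
        paste(paste0(uncovered$plate_id, "/", uncovered$channel), collapse = ", ")
      ),
      class = "inteinscreen_config_error"
    )
  }
  out |>
    mutate(value = .data$value - .data$.blank) |>
    select(-".blank")
}

#' Normalize fluorescence to cell density (Fluo./OD600)
#'
#' Divides each fluorescence reading by the OD600 reading of the same well at
#' the same time point, yielding the per-cell signal. Wells whose OD600 falls
#' below `od_floor` (after blank correction) are flagged `low_od` rather than
#' dropped, since ratios against a near-zero density are unreliable.
#'
#' @param table A blank-corrected signal table containing both a fluorescence
#'   channel and `OD600` for every well/time.
#' @param od_floor OD600 below which a well is flagged (default 0.01).
#' @return Tibble with one row per well/time/fluorescence-channel:
#'   the ratio in `value`, the OD in `od600`, and a `low_od` flag.
#' @export
fluo_per_od <- function(table, od_floor = 0.01) {
  od <- table |>
    filter(.data$channel == "OD600") |>
    select("plate_id", "well", "time_s", od600 = "value")
  fluor <- table |> filter(.data$channel != "OD600")
  out <- left_join(fluor, od, by = c("plate_id", "well", "time_s"))
  if (any(is.na(out$od600))) {
    miss <- out |> filter(is.na(.data$od600)) |> distinct(.data$plate_id, .data$well)
    abort(
      paste0(
        "missing OD600 partner reading for well(s): ",
        paste(paste0(miss$plate_id, "/", miss$well), collapse = ", ")
      ),
      class = "inteinscreen_pairing_error"
    )
  }
  out |>
    mutate(
      value = .data$value / .data$od600,
      low_od = .data$od600 < od_floor
    )
}

#' Subtract the negative control and aggregate replicates
#'
#' The mean Fluo./OD600 of the negative-control replicate group is subtracted
#' from every test replicate; replicates are then aggregated per
#' `replicate_group` into mean, standard deviation and replicate count.
#' Negative results are retained. The standard deviation is reported as `NA`
#' when a group has a single replicate.
#'
#' @param ratios Per-replicate ratio table from [fluo_per_od()] (columns
#'   `replicate_group`, `channel`, `value`, ...).
#' @param control_group Name of the negative-control replicate group.
#' @return Tibble of normalized signals: `sample_id` (the replicate group),
#'   `channel`, `mean`, `sd`, `n`.
#' @export
control_subtract <- function(ratios, control_group = "negative_control") {
  ctrl <- ratios |> filter(.data$replicate_group == control_group)
  if (nrow(ctrl) == 0) {
    abort(
      paste0("control replicate group not found: ", control_group),
      class = "inteinscreen_config_error"
    )
  }
  ctrl_means <- ctrl |>
    group_by(.data$channel) |>
    summarise(.ctrl = mean(.data$value), .groups = "drop")
  ratios |>
    filter(.data$replicate_group != control_group) |>
    left_join(ctrl_means, by = "channel") |>
    mutate(.ctrl = ifelse(is.na(.data$.ctrl), 0, .data$.ctrl)) |>
    mutate(value = .data$value - .data$.ctrl) |>
    group_by(sample_id = .data$replicate_group, .data$channel) |>
    summarise(
      mean = mean(.data$value),
      sd = if (n() > 1) sd(.data$value) else NA_real_,
      n = n(),
      .groups = "drop"
    )
}

#' Subtract a per-well baseline from a time series
#'
#' Two conventions are supported: `"min"` subtracts the lowest value observed
#' in each well's series (the minimum of the result is exactly 0), and `"t0"`
#' subtracts the reading at the earliest time point (the result at t = 0 is
#' exactly 0).
#'
#' @param series Tibble with columns `time_s`, `value` and a well/sample
#'   identifier named by `by` (default `"well"`); extra columns pass through.
#' @param mode `"min"` or `"t0"`.
#' @param by Column identifying independent series.
#' @return The series with `value` baseline-subtracted.
#' @export
baseline_subtract <- function(series, mode = c("min", "t0"), by = "well") {
  mode <- match.arg(mode)
  if (nrow(series) == 0) {
    abort("empty series", class = "inteinscreen_input_error")
  }
  series |>
    group_by(across(all_of(by))) |>
    mutate(value = .data$value - if (mode == "min") {
      min(.data$value)
    } else {
      .data$value[which.min(.data$time_s)]
    }) |>
    ungroup()
}

#' Run the full in vivo normalization chain
#'
#' Convenience wrapper: blank correction, Fluo./OD600, negative-control
#' subtraction and replicate aggregation in one call.
#'
#' @inheritParams blank_correct
#' @inheritParams fluo_per_od
#' @inheritParams control_subtract
#' @return Normalized-signal tibble (see [control_subtract()]).
#' @export
normalize_plate <- function(table, control_group = "negative_control",
                            od_floor = 0.01, per_time = TRUE) {
  table |>
    blank_correct(per_time = per_time) |>
    fluo_per_od(od_floor = od_floor) |>
    control_subtract(control_group = control_group)
}
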