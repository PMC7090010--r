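#' Configuration for the synthetic-data generators
#'
#' Bundles the ground-truth parameters from which all synthetic datasets
#' are drawn, mirroring the measurement structure of the screening
#' platform: three biological replicates per sample, a growth-medium blank,
#' a negative-control group, lognormal (constant-CV) multiplicative noise
#' on fluorescence and band intensities, Gaussian noise on OD600, sparse
#' exponential non-cognate cross-talk with optional planted violators, and
#' delayed first-order kinetics.
#'
#' @param seed Mandatory integer seed; identical configurations produce
#'   identical datasets.
#' @param n_inteins Number of parent inteins in the panel.
#' @param split_variants Split sites per intein (default one `"S2"` variant
#'   each); either a character vector applied to every intein or a list of
#'   per-intein character vectors.
#' @param cognate_mean Cognate-pair normalized signal, a.u./OD600.
#' @param cognate_cv Replicate coefficient of variation of fluorescence.
#' @param crosstalk_mean Mean of the exponential distribution from which
#'   non-cognate relative levels are drawn (sparse, low-level cross-talk).
#' @param planted_violators Tibble (`pair`, `level`) of pairs whose entire
#'   row and column are set to `level` x cognate, overriding the random
#'   cross-talk.
#' @param replicate_n Biological replicates per sample (default 3).
#' @param blank_mean Medium blank fluorescence, a.u.
#' @param blank_od Medium blank absorbance.
#' @param od_mean,od_cv Culture density and its CV.
#' @param control_level Negative-control background signal, a.u./OD600.
#' @param rate_per_h,delay_s,plateau,kinetic_noise_sd First-order kinetic
#'   truth: rate (1/h), maturation-delay onset (s), plateau, additive
#'   Gaussian noise sd.
#' @param times Sampling times for kinetic traces, seconds.
#' @param efficiency,efficiency_cv True splicing efficiency and the CV of
#'   the multiplicative band-intensity noise.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_inteins = 8,
                       split_variants = "S2",
                       cognate_mean = 20000,
                       cognate_cv = 0.1,
                       crosstalk_mean = 0.01,
                       planted_violators = NULL,
                       replicate_n = 3,
                       blank_mean = 100,
                       blank_od = 0.04,
                       od_mean = 0.5,
                       od_cv = 0.05,
                       control_level = 200,
                       rate_per_h = 1.4,
                       delay_s = 1200,
                       plateau = 1,
                       kinetic_noise_sd = 0,
                       times = seq(0, 4 * 3600, by = 600),
                       efficiency = 0.8,
                       efficiency_cv = 0.05) {
  if (missing(seed) || !is.numeric(seed)) {
    abort("a numeric seed is mandatory", class = "inteinscreen_config_error")
  }
  stopifnot(
    n_inteins >= 1, replicate_n >= 1, cognate_cv >= 0, crosstalk_mean >= 0,
    od_cv >= 0, efficiency >= 0, efficiency <= 1
  )
  if (cognate_mean <= blank_mean) {
    abort(
      "degenerate config: cognate_mean must exceed blank_mean",
      class = "inteinscreen_config_error"
    )
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# lognormal multiplier with unit mean and given CV
lognoise <- function(n, cv) {
  if (cv <= 0) {
    return(rep(1, n))
  }
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

sim_pairs <- function(cfg) {
  inteins <- sprintf("int%02d", seq_len(cfg$n_inteins))
  sites <- cfg$split_variants
  if (!is.list(sites)) sites <- rep(list(sites), cfg$n_inteins)
  list_rbind(map2(inteins, sites, function(i, s) {
    tibble(intein = i, split_site = s)
  })) |>
    mutate(pair = split_pair_id(.data$intein, .data$split_site))
}

# True relative cross-talk matrix: diagonal 1, off-diagonal exponential
# draws (possibly overridden by planted violators).
sim_truth_matrix <- function(cfg, pairs) {
  k <- nrow(pairs)
  T_rel <- matrix(
    stats::rexp(k * k, rate = 1 / max(cfg$crosstalk_mean, 1e-12)),
    k, k,
    dimnames = list(pairs$pair, pairs$pair)
  )
  if (cfg$crosstalk_mean == 0) T_rel[] <- 0
  diag(T_rel) <- 1
  if (!is.null(cfg$planted_violators)) {
    for (i in seq_len(nrow(cfg$planted_violators))) {
      v <- cfg$planted_violators$pair[i]
      lvl <- cfg$planted_violators$level[i]
      if (!v %in% pairs$pair) {
        abort(paste0("planted violator not in panel: ", v), class = "inteinscreen_config_error")
      }
      T_rel[v, colnames(T_rel) != v] <- lvl
      T_rel[rownames(T_rel) != v, v] <- lvl
    }
  }
  T_rel
}

truth_calls <- function(T_rel, max_threshold = 0.2, median_threshold = 0.05) {
  pairs <- rownames(T_rel)
  map(pairs, function(p) {
    rel <- c(T_rel[p, setdiff(pairs, p)], T_rel[setdiff(pairs, p), p])
    tibble(
      pair = p,
      true_max = max(rel),
      true_median = median(rel),
      true_orthogonal = max(rel) < max_threshold && median(rel) < median_threshold
    )
  }) |> list_rbind()
}

#' Generate a synthetic cross-reactivity screen with ground truth
#'
#' Emulates the full N-half x C-half co-expression screen. At
#' `level = "matrix"` the generator returns replicate-averaged normalized
#' signals ready for [build_cross_matrix()]; at `level = "plate"` it emits
#' raw well readings (fluorescence and OD600, with blanks and a
#' negative-control group) plus the layout, so the entire
#' [normalize_plate()] chain can be exercised end to end. The ground truth
#' (true relative cross-talk matrix and the orthogonality call it implies)
#' is returned alongside.
#'
#' @param cfg A [sim_config()].
#' @param level `"matrix"` or `"plate"`.
#' @return List with `pairs`, `pairing` (sample -> matrix cell map),
#'   `truth` (list: `relative` matrix, `calls` tibble), and either
#'   `signals` (matrix level) or `plate` + `layout` (plate level).
#' @export
sim_cross_matrix <- function(cfg, level = c("matrix", "plate")) {
  level <- match.arg(level)
  withr::with_seed(cfg$seed, {
    pairs <- sim_pairs(cfg)
    k <- nrow(pairs)
    T_rel <- sim_truth_matrix(cfg, pairs)
    combos <- tidyr::expand_grid(row = pairs$pair, col = pairs$pair) |>
      mutate(
        sample_id = sprintf("cmb%04d", dplyr::row_number()),
        true_signal = cfg$cognate_mean * T_rel[cbind(.data$row, .data$col)]
      )
    truth <- list(
      relative = T_rel,
      calls = truth_calls(T_rel)
    )
    if (level == "matrix") {
      reps <- combos |>
        tidyr::uncount(cfg$replicate_n, .id = "replicate") |>
        mutate(value = .data$true_signal * lognoise(n(), cfg$cognate_cv))
      signals <- reps |>
        group_by(sample_id = .data$sample_id) |>
        summarise(
          mean = mean(.data$value),
          sd = if (cfg$replicate_n > 1) sd(.data$value) else NA_real_,
          n = n(),
          .groups = "drop"
        )
      return(list(
        pairs = pairs,
        pairing = combos |> select("sample_id", "row", "col"),
        signals = signals,
        truth = truth
      ))
    }
    # plate level: replicate wells with blanks and negative controls
    wells_per_plate <- 94L # 94 samples + 1 blank + 1 negative control
    test <- combos |>
      tidyr::uncount(cfg$replicate_n, .id = "replicate") |>
      mutate(
        well_sample = sprintf("%s_r%d", .data$sample_id, .data$replicate),
        od = stats::rnorm(n(), cfg$od_mean, cfg$od_mean * cfg$od_cv),
        signal = (cfg$control_level + .data$true_signal) * lognoise(n(), cfg$cognate_cv)
      ) |>
      mutate(
        plate = (dplyr::row_number() - 1) %/% wells_per_plate + 1,
        slot = (dplyr::row_number() - 1) %% wells_per_plate + 1
      )
    n_plates <- max(test$plate)
    well_name <- function(slot) {
      paste0(LETTERS[(slot - 1) %/% 12 + 1], (slot - 1) %% 12 + 1)
    }
    ctrl <- tibble(
      plate = seq_len(n_plates),
      slot = 95L,
      well_sample = sprintf("neg_r%d", seq_len(n_plates)),
      od = stats::rnorm(n_plates, cfg$od_mean, cfg$od_mean * cfg$od_cv),
      signal = cfg$control_level * lognoise(n_plates, cfg$cognate_cv)
    )
    blank <- tibble(
      plate = seq_len(n_plates),
      slot = 96L,
      well_sample = sprintf("blank_p%d", seq_len(n_plates))
    )
    reading <- function(df, channel, value) {
      tibble(
        plate_id = sprintf("P%02d", df$plate),
        well = well_name(df$slot),
        sample_id = df$well_sample,
        channel = channel,
        time_s = 0,
        value = value
      )
    }
    plate <- bind_rows(
      reading(test, "mCherry", cfg$blank_mean + test$od * test$signal),
      reading(test, "OD600", cfg$blank_od + test$od),
      reading(ctrl, "mCherry", cfg$blank_mean + ctrl$od * ctrl$signal),
      reading(ctrl, "OD600", cfg$blank_od + ctrl$od),
      reading(blank, "mCherry", cfg$blank_mean),
      reading(blank, "OD600", cfg$blank_od)
    )
    layout <- bind_rows(
      test |>
        distinct(.data$well_sample, .data$sample_id) |>
        mutate(role = "test") |>
        select(
          replicate_group = "sample_id", sample_id = "well_sample", "role"
        ) |>
        select("sample_id", "role", "replicate_group"),
      tibble(
        sample_id = blank$well_sample, role = "blank_medium",
        replicate_group = "blank"
      ),
      tibble(
        sample_id = ctrl$well_sample, role = "negative_control",
        replicate_group = "negative_control"
      )
    )
    list(
      pairs = pairs,
      pairing = combos |> select("sample_id", "row", "col"),
      plate = plate,
      layout = layout,
      truth = truth
    )
  })
}

#' Generate first-order kinetic traces with ground truth
#'
#' Traces follow A(1 - exp(-k (t - d)+)) with additive Gaussian noise,
#' emulating spliced-reporter formation with a fluorophore-maturation
#' onset delay.
#'
#' @param cfg A [sim_config()]; `rate_per_h`, `delay_s`, `plateau` and
#'   `kinetic_noise_sd` may be vectors (one trace each).
#' @return List with `series` (tibble `sample_id`, `time_s`, `value`) and
#'   `truth` (per-sample parameters).
#' @export
sim_kinetic_traces <- function(cfg) {
  withr::with_seed(cfg$seed, {
    truth <- tibble(
      rate_per_h = cfg$rate_per_h,
      delay_s = cfg$delay_s,
      plateau = cfg$plateau,
      noise_sd = cfg$kinetic_noise_sd
    ) |>
      mutate(sample_id = sprintf("trace%02d", dplyr::row_number()), .before = 1)
    if (any(truth$plateau < 0)) {
      abort("negative plateau in config", class = "inteinscreen_config_error")
    }
    series <- truth |>
      tidyr::expand_grid(time_s = cfg$times) |>
      mutate(
        value = .data$plateau *
          (1 - exp(-(.data$rate_per_h / 3600) * pmax(.data$time_s - .data$delay_s, 0))) +
          stats::rnorm(n(), 0, .data$noise_sd)
      ) |>
      select("sample_id", "time_s", "value")
    list(series = series, truth = truth)
  })
}

#' Generate a dual-channel, dual-membrane band-intensity table
#'
#' Emits spliced and precursor band intensities for both antibody channels
#' on two membranes (n = 4 quantifications) with multiplicative lognormal
#' noise, consistent with a true splicing efficiency.
#'
#' @param cfg A [sim_config()]; `efficiency` may be a vector (one sample
#'   per element).
#' @return List with `bands` (a [splicing_efficiency()]-ready tibble) and
#'   `truth`.
#' @export
sim_band_table <- function(cfg) {
  withr::with_seed(cfg$seed, {
    truth <- tibble(
      sample_id = sprintf("smp%02d", seq_along(cfg$efficiency)),
      efficiency = cfg$efficiency
    )
    scale <- 1e4
    bands <- truth |>
      tidyr::expand_grid(
        membrane_id = c("M1", "M2"),
        channel = c("anti_mCherry_N", "anti_His_C"),
        species = c("spliced", "precursor")
      ) |>
      mutate(
        lane_id = .data$sample_id,
        intensity = scale *
          ifelse(.data$species == "spliced", .data$efficiency, 1 - .data$efficiency) *
          lognoise(n(), cfg$efficiency_cv)
      ) |>
      select("sample_id", "lane_id", "membrane_id", "channel", "species", "intensity")
    list(bands = bands, truth = truth)
  })
}

#' Generate an activity-calling cohort with planted truth
#'
#' Plants a chosen number of active samples whose signals sit well above
#' the calling thresholds and inactive samples well below, with replicate
#' noise, for recovery tests of the threshold rules. For the in vitro
#' context both the fluorescence rule and the spliced-fraction-of-maximum
#' rule are planted jointly.
#'
#' @param seed Integer seed.
#' @param n Cohort size.
#' @param n_active Number of planted active samples.
#' @param context `"cis"` (single 2000 a.u. fluorescence rule) or
#'   `"invitro"` (4000 a.u. AND >10% of cohort-maximum spliced product).
#' @param cv Replicate noise CV.
#' @return List with `signals` (ready for [call_cis_active()] /
#'   [call_invitro_active()]) and `truth`.
#' @export
sim_activity_cohort <- function(seed, n = 34, n_active = 22,
                                context = c("cis", "invitro"), cv = 0.1) {
  context <- match.arg(context)
  stopifnot(n_active <= n)
  withr::with_seed(seed, {
    truth <- tibble(
      sample_id = sprintf("cul%02d", seq_len(n)),
      true_active = seq_len(n) <= n_active
    ) |>
      slice(sample(n())) # shuffle so activity is not positional
    if (context == "cis") {
      signals <- truth |>
        mutate(
          mean = ifelse(.data$true_active, 15000, 300) * lognoise(n(), cv)
        ) |>
        select("sample_id", "mean")
    } else {
      signals <- truth |>
        mutate(
          signal = ifelse(.data$true_active, 20000, 800) * lognoise(n(), cv),
          spliced = ifelse(.data$true_active, 0.8, 0.01) * lognoise(n(), cv)
        ) |>
        select("sample_id", "signal", "spliced")
    }
    list(signals = signals, truth = truth)
  })
}

#' Generate a reaction-condition screen grid with a planted optimum
#'
#' Every intein gets a smooth unimodal response over the pH x NaCl x
#' temperature grid with intein-specific optima, except that the planted
#' common condition is lifted to a high relative level for all inteins, so
#' the best worst-case condition is known by construction.
#'
#' @param seed Integer seed.
#' @param n_inteins Number of inteins screened.
#' @param planted One-row tibble (`pH`, `NaCl_mM`, `temperature_C`)
#'   naming the condition planted as the common optimum.
#' @param cv Measurement noise CV.
#' @return List with `grid` (ready for [score_conditions()]) and `truth`.
#' @export
sim_condition_grid <- function(seed, n_inteins = 10,
                               planted = tibble(pH = 9, NaCl_mM = 100, temperature_C = 21),
                               cv = 0.05) {
  withr::with_seed(seed, {
    conditions <- tidyr::expand_grid(
      pH = c(8, 9),
      NaCl_mM = c(100, 300, 500),
      temperature_C = c(4, 21, 30, 37, 42)
    )
    grid <- tidyr::expand_grid(
      intein = sprintf("int%02d", seq_len(n_inteins)),
      conditions
    ) |>
      group_by(.data$intein) |>
      mutate(
        # intein-specific preferences away from the planted optimum
        base = stats::runif(n(), 0.05, 0.55),
        value = 1e4 * ifelse(
          .data$pH == planted$pH &
            .data$NaCl_mM == planted$NaCl_mM &
            .data$temperature_C == planted$temperature_C,
          stats::runif(n(), 0.85, 1), .data$base
        ) * lognoise(n(), cv)
      ) |>
      ungroup() |>
      select("intein", "pH", "NaCl_mM", "temperature_C", "value")
    list(grid = grid, truth = planted)
  })
}
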