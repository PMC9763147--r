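# run code with a private, restorable RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

default_treatments <- function() {
  tibble::tibble(
    treatment = c("baseline", "oligomycin", "fccp", "2dog", "oxamate"),
    ocr_mult = c(1, 0.40, 8.0, 1.50, 0.46),
    ecar_mult = c(1, 1.50, 1.0, 0.70, 0.63)
  )
}

#' Configuration for the synthetic plate generator
#'
#' Describes the hierarchical data-generating process the analysis assumes:
#' per-condition true basal rates, per-treatment multipliers applied from
#' the injection cycle with first-order onset, an A+R non-mitochondrial OCR
#' floor with compensatory ECAR, lognormal between-experiment and well/cycle
#' noise, a cell-free background process, and a sperm-count distribution.
#' Defaults emulate a standard 24-well run: 9 cycles of 6 min, injection
#' before cycle 5, A+R before cycle 8, 2 wells per treatment and condition,
#' 4 background wells per experiment, basal means of 315/231 amol O2 min^-1
#' sperm^-1 (OCR) and 18.9/25.7 npH min^-1 sperm^-1 (ECAR) for the
#' non-capacitating/capacitating conditions.
#'
#' @param n_experiments Number of independent experiments (plates).
#' @param wells_per_treatment Wells per treatment per condition per
#'   experiment.
#' @param conditions Named list of true basal means, each `c(ocr=, ecar=)`.
#' @param treatments Tibble `treatment`, `ocr_mult`, `ecar_mult`: plateau
#'   multipliers applied from the injection cycle. Cross-signal entries
#'   encode metabolic compensation (e.g. ECAR rising under oligomycin).
#' @param ar_ocr_mult Fraction of basal OCR remaining after antimycin A +
#'   rotenone (the non-mitochondrial floor).
#' @param ar_ecar_comp Compensatory ECAR multiplier after A+R for wells
#'   whose glycolysis is not inhibited.
#' @param between_experiment_sd SD of the experiment random effect on the
#'   natural-log scale.
#' @param well_cv,cycle_cv Coefficients of variation of the multiplicative
#'   well-level and cycle-level lognormal noise (cycle noise has mean 1).
#' @param background_ocr_mean,background_ocr_sd Background OCR process
#'   (pmol O2 min^-1 well^-1), added to every well and measured alone in
#'   cell-free wells.
#' @param background_ecar_mean,background_ecar_sd Background ECAR process
#'   (mpH min^-1 well^-1).
#' @param n_background_wells Cell-free wells per experiment.
#' @param sperm_count_meanlog,sperm_count_sdlog Lognormal parameters of the
#'   per-well sperm count.
#' @param n_cycles,injection_cycle,ar_cycle Cycle plan (defaults 9, 5, 8).
#' @param cycle_minutes Minutes per measurement cycle (time bookkeeping
#'   only; no computation uses time).
#' @param onset_rate Fraction of the remaining gap to the post-injection
#'   plateau closed per cycle; the default 0.776 reaches 95% of the plateau
#'   by the second post-injection cycle. The A+R block is treated as
#'   instantaneous.
#' @param seed Master seed; identical configs generate identical data.
#'
#' @return A `generator_config` object (a validated named list).
#' @export
generator_config <- function(
    n_experiments = 4L,
    wells_per_treatment = 2L,
    conditions = list(
      non_capacitating = c(ocr = 315, ecar = 18.9),
      capacitating = c(ocr = 231, ecar = 25.7)
    ),
    treatments = default_treatments(),
    ar_ocr_mult = 0.05,
    ar_ecar_comp = 1.4,
    between_experiment_sd = 0.35,
    well_cv = 0.12,
    cycle_cv = 0.06,
    background_ocr_mean = 20, background_ocr_sd = 2,
    background_ecar_mean = 3, background_ecar_sd = 0.4,
    n_background_wells = 4L,
    sperm_count_meanlog = log(2e6), sperm_count_sdlog = 0.25,
    n_cycles = 9L, injection_cycle = 5L, ar_cycle = 8L,
    cycle_minutes = 6,
    onset_rate = 0.776,
    seed = 20221219L) {
  cfg <- list(
    n_experiments = as.integer(n_experiments),
    wells_per_treatment = as.integer(wells_per_treatment),
    conditions = conditions,
    treatments = tibble::as_tibble(treatments),
    ar_ocr_mult = ar_ocr_mult, ar_ecar_comp = ar_ecar_comp,
    between_experiment_sd = between_experiment_sd,
    well_cv = well_cv, cycle_cv = cycle_cv,
    background_ocr_mean = background_ocr_mean,
    background_ocr_sd = background_ocr_sd,
    background_ecar_mean = background_ecar_mean,
    background_ecar_sd = background_ecar_sd,
    n_background_wells = as.integer(n_background_wells),
    sperm_count_meanlog = sperm_count_meanlog,
    sperm_count_sdlog = sperm_count_sdlog,
    n_cycles = as.integer(n_cycles),
    injection_cycle = as.integer(injection_cycle),
    ar_cycle = as.integer(ar_cycle),
    cycle_minutes = cycle_minutes,
    onset_rate = onset_rate,
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_experiments < 1) config_error("n_experiments must be >= 1.")
  if (cfg$wells_per_treatment < 1) {
    config_error("wells_per_treatment must be >= 1.")
  }
  if (length(cfg$conditions) < 1 ||
      is.null(names(cfg$conditions)) || any(names(cfg$conditions) == "")) {
    config_error("conditions must be a named list of c(ocr=, ecar=) means.")
  }
  for (nm in names(cfg$conditions)) {
    m <- cfg$conditions[[nm]]
    if (!all(c("ocr", "ecar") %in% names(m)) || any(m[c("ocr", "ecar")] <= 0)) {
      config_error(paste0("Condition '", nm,
                          "' needs positive ocr and ecar means."))
    }
  }
  check_columns(cfg$treatments, c("treatment", "ocr_mult", "ecar_mult"),
                "treatments")
  if (any(cfg$treatments$ocr_mult <= 0) || any(cfg$treatments$ecar_mult <= 0)) {
    config_error("Treatment multipliers must be positive.")
  }
  if (any(c(cfg$well_cv, cfg$cycle_cv) < 0) || cfg$between_experiment_sd < 0) {
    config_error("Noise parameters must be non-negative.")
  }
  if (cfg$ar_ocr_mult <= 0 || cfg$ar_ocr_mult >= 1) {
    config_error("ar_ocr_mult must be in (0, 1).")
  }
  if (!(cfg$injection_cycle > 1 && cfg$ar_cycle > cfg$injection_cycle &&
        cfg$n_cycles >= cfg$ar_cycle)) {
    config_error("Need 1 < injection_cycle < ar_cycle <= n_cycles.")
  }
  if (cfg$onset_rate <= 0 || cfg$onset_rate > 1) {
    config_error("onset_rate must be in (0, 1].")
  }
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat("  ", x$n_experiments, " experiments, ",
      x$wells_per_treatment, " wells/treatment/condition, ",
      x$n_background_wells, " background wells\n", sep = "")
  cat("  cycles:", x$n_cycles, "| injection at", x$injection_cycle,
      "| A+R at", x$ar_cycle, "\n")
  for (nm in names(x$conditions)) {
    cat("  ", nm, ": OCR ", x$conditions[[nm]][["ocr"]], ", ECAR ",
        x$conditions[[nm]][["ecar"]], "\n", sep = "")
  }
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# plateau multiplier reached by cycle c (first-order onset)
onset_fraction <- function(cfg, cycle) {
  k <- cycle - cfg$injection_cycle + 1L
  ifelse(k <= 0, 0, 1 - (1 - cfg$onset_rate)^k)
}

# expected per-sperm multiplier path for one treatment and signal
multiplier_path <- function(cfg, treatment, signal) {
  tr <- cfg$treatments[cfg$treatments$treatment == treatment, ]
  m <- if (signal == "ocr") tr$ocr_mult else tr$ecar_mult
  cyc <- seq_len(cfg$n_cycles)
  path <- 1 + (m - 1) * onset_fraction(cfg, cyc)
  ar <- cyc >= cfg$ar_cycle
  if (signal == "ocr") {
    path[ar] <- cfg$ar_ocr_mult
  } else {
    glyco_inhibited <- treatment %in% c("2dog", "oxamate")
    path[ar] <- if (glyco_inhibited) m else max(m, cfg$ar_ecar_comp)
  }
  path
}

#' Expected modulator responses implied by a generator configuration
#'
#' Plug-through of the percent-of-baseline response formula on the
#' noiseless expectations of [generate_plate()]: OCR responses are corrected
#' by the A+R floor on both sides of the ratio, ECAR responses are not.
#' Useful as an analytic oracle and for choosing presets.
#'
#' @param config A [generator_config()].
#' @param convention `"table2"` (treatment-window mean) or `"table3"`
#'   (max under oligomycin / min under 2DOG for ECAR).
#'
#' @return A tibble: `treatment`, `signal`, `percent_of_baseline`,
#'   `delta_percent`.
#' @export
expected_responses <- function(config, convention = c("table2", "table3")) {
  convention <- match.arg(convention)
  cfg <- config
  tr_cycles <- seq(cfg$injection_cycle, cfg$ar_cycle - 1L)
  purrr::map_dfr(cfg$treatments$treatment, function(trt) {
    purrr::map_dfr(c("ocr", "ecar"), function(sig) {
      path <- multiplier_path(cfg, trt, sig)[tr_cycles]
      f <- cfg$ar_ocr_mult
      if (sig == "ocr") {
        pct <- 100 * (mean(path) - f) / (1 - f)
      } else {
        agg <- if (convention == "table3" && trt == "oligomycin") max(path)
        else if (convention == "table3" && trt == "2dog") min(path)
        else mean(path)
        pct <- 100 * agg
      }
      tibble::tibble(treatment = trt, signal = toupper(sig),
                     percent_of_baseline = pct, delta_percent = pct - 100)
    })
  })
}

#' Generate a synthetic plate run with recorded ground truth
#'
#' Simulates raw (pre-normalization) well-level OCR/ECAR kinetic traces for
#' every experiment, condition and treatment of the configuration, so the
#' full pipeline (background correction, per-sperm normalization, panel,
#' responses, mixed models) can be exercised end to end. For each well,
#' `expected(cycle) = condition mean x exp(experiment effect) x
#' exp(well effect) x treatment multiplier path`; observed per-sperm rates
#' multiply that by mean-one lognormal cycle noise; raw well rates are
#' per-sperm rates scaled by the sperm count (1 pmol = 10^6 amol) plus a
#' Gaussian background process that cell-free wells measure alone.
#'
#' @param config A [generator_config()].
#' @param seed Optional seed overriding `config$seed`.
#'
#' @return A list with elements `run` (a [plate_run()]) and `truth` (a list:
#'   `config`, `experiment_effects`, `wells`, `expected` with per-cycle
#'   noiseless per-sperm rates).
#' @export
generate_plate <- function(config, seed = NULL) {
  cfg <- config
  stopifnot(inherits(cfg, "generator_config"))
  seed <- seed %||% cfg$seed
  with_seed(seed, {
    cyc <- seq_len(cfg$n_cycles)
    time_min <- (cyc - 1) * cfg$cycle_minutes
    sd_cycle <- cv_to_sdlog(cfg$cycle_cv)
    sd_well <- cv_to_sdlog(cfg$well_cv)

    exp_ids <- sprintf("E%d", seq_len(cfg$n_experiments))
    exp_eff <- rnorm(cfg$n_experiments, 0, cfg$between_experiment_sd)
    names(exp_eff) <- exp_ids

    wells <- tidyr::expand_grid(
      experiment_id = exp_ids,
      condition = names(cfg$conditions),
      treatment = cfg$treatments$treatment,
      replicate = seq_len(cfg$wells_per_treatment)
    ) |>
      dplyr::mutate(
        well_id = sprintf("%s_%s_%s_w%d", .data$experiment_id,
                          ifelse(.data$condition == "non_capacitating",
                                 "NC", "CAP"),
                          .data$treatment, .data$replicate),
        well_effect = rnorm(dplyr::n(), 0, sd_well),
        sperm_count = round(rlnorm(dplyr::n(), cfg$sperm_count_meanlog,
                                   cfg$sperm_count_sdlog))
      )

    expected <- purrr::pmap_dfr(
      wells[, c("well_id", "experiment_id", "condition", "treatment",
                "well_effect")],
      function(well_id, experiment_id, condition, treatment, well_effect) {
        level <- exp(exp_eff[[experiment_id]] + well_effect)
        tibble::tibble(
          well_id = well_id,
          cycle = cyc,
          ocr_expected = cfg$conditions[[condition]][["ocr"]] * level *
            multiplier_path(cfg, treatment, "ocr"),
          ecar_expected = cfg$conditions[[condition]][["ecar"]] * level *
            multiplier_path(cfg, treatment, "ecar")
        )
      }
    )

    n_rows <- nrow(expected)
    mean1 <- -sd_cycle^2 / 2  # lognormal noise with mean exactly 1
    obs <- expected |>
      dplyr::left_join(wells[, c("well_id", "sperm_count")],
                       by = "well_id") |>
      dplyr::mutate(
        ocr_sperm = .data$ocr_expected * rlnorm(n_rows, mean1, sd_cycle),
        ecar_sperm = .data$ecar_expected * rlnorm(n_rows, mean1, sd_cycle),
        ocr_raw = .data$ocr_sperm * .data$sperm_count / 1e6 +
          rnorm(n_rows, cfg$background_ocr_mean, cfg$background_ocr_sd),
        ecar_raw = .data$ecar_sperm * .data$sperm_count / 1e6 +
          rnorm(n_rows, cfg$background_ecar_mean, cfg$background_ecar_sd),
        time_min = (.data$cycle - 1) * cfg$cycle_minutes
      )

    bg <- tidyr::expand_grid(
      experiment_id = exp_ids,
      bgi = seq_len(cfg$n_background_wells),
      cycle = cyc
    ) |>
      dplyr::mutate(
        well_id = sprintf("%s_bg%d", .data$experiment_id, .data$bgi),
        time_min = (.data$cycle - 1) * cfg$cycle_minutes,
        ocr_raw = rnorm(dplyr::n(), cfg$background_ocr_mean,
                        cfg$background_ocr_sd),
        ecar_raw = rnorm(dplyr::n(), cfg$background_ecar_mean,
                         cfg$background_ecar_sd)
      )

    traces <- dplyr::bind_rows(
      obs[, c("well_id", "cycle", "time_min", "ocr_raw", "ecar_raw")],
      bg[, c("well_id", "cycle", "time_min", "ocr_raw", "ecar_raw")]
    )
    layout <- dplyr::bind_rows(
      wells |>
        dplyr::transmute(.data$well_id, .data$experiment_id,
                         .data$condition, .data$treatment,
                         .data$sperm_count, is_background = FALSE),
      bg |>
        dplyr::distinct(.data$well_id, .data$experiment_id) |>
        dplyr::mutate(condition = NA_character_, treatment = NA_character_,
                      sperm_count = NA_real_, is_background = TRUE)
    )

    run <- plate_run(
      traces, layout,
      windows = cycle_windows(
        discarded = 1L,
        baseline = seq(2L, cfg$injection_cycle - 1L),
        treatment = seq(cfg$injection_cycle, cfg$ar_cycle - 1L),
        ar = seq(cfg$ar_cycle, cfg$n_cycles)
      ),
      run_id = sprintf("synthetic_seed%d", seed)
    )
    truth <- list(
      config = cfg,
      seed = seed,
      experiment_effects = tibble::tibble(experiment_id = exp_ids,
                                          effect = unname(exp_eff)),
      wells = wells,
      expected = expected,
      observed_per_sperm = obs[, c("well_id", "cycle", "ocr_sperm",
                                   "ecar_sperm")]
    )
    list(run = run, truth = truth)
  })
}

#' Generate replicate null datasets of well-level responses
#'
#' Draws `n_replicates` datasets in which the two conditions share the same
#' true mean, for calibration studies (type-I error of the
#' likelihood-ratio test). Each well's response is
#' `mean x exp(experiment effect) x exp(well noise)` with the configuration's
#' between-experiment SD and well CV: the same hierarchical lognormal model
#' that governs the plate generator's baseline window. Replicate seeds are
#' derived deterministically from the master seed (`seed + replicate`).
#'
#' @param config A [generator_config()]; the non-capacitating OCR mean is
#'   used as the common truth.
#' @param n_replicates Number of replicate datasets (0 gives an empty list).
#' @param n_experiments,wells_per_group Design of each replicate (defaults:
#'   the configuration's experiment count, 5 wells per condition per
#'   experiment).
#' @param level `"well"` (default) for well-level response tibbles, or
#'   `"plate"` for full synthetic plate runs with equal condition means.
#'
#' @return A list of length `n_replicates`: tibbles with columns
#'   `experiment_id`, `condition`, `response` (or `plate_run`s).
#' @export
generate_null_dataset <- function(config, n_replicates,
                                  n_experiments = config$n_experiments,
                                  wells_per_group = 5L,
                                  level = c("well", "plate")) {
  level <- match.arg(level)
  stopifnot(inherits(config, "generator_config"))
  if (n_replicates == 0) return(list())
  base_mean <- config$conditions[[1]][["ocr"]]
  null_conditions <- lapply(config$conditions, function(m) {
    c(ocr = base_mean, ecar = unname(config$conditions[[1]][["ecar"]]))
  })
  sd_well <- cv_to_sdlog(config$well_cv)
  lapply(seq_len(n_replicates), function(i) {
    seed_i <- (config$seed + i) %% .Machine$integer.max
    if (level == "plate") {
      cfg_i <- config
      cfg_i$conditions <- null_conditions
      return(generate_plate(cfg_i, seed = seed_i))
    }
    with_seed(seed_i, {
      exp_ids <- sprintf("E%d", seq_len(n_experiments))
      u <- setNames(rnorm(n_experiments, 0, config$between_experiment_sd),
                    exp_ids)
      grid <- tidyr::expand_grid(
        experiment_id = exp_ids,
        condition = CONDITION_LEVELS,
        w = seq_len(wells_per_group)
      )
      grid |>
        dplyr::mutate(
          response = base_mean * exp(u[.data$experiment_id]) *
            rlnorm(dplyr::n(), 0, sd_well)
        ) |>
        dplyr::select("experiment_id", "condition", "response")
    })
  })
}

#' Species preset configurations
#'
#' Generator presets whose expected pipeline outputs reproduce the two
#' species' qualitative compensation signatures. The steppe-mouse preset
#' (`"spicilegus"`) raises OCR under 2DOG (two-way compensation: respiration
#' rises when glycolysis is blocked); the house-mouse preset (`"musculus"`)
#' lowers it. Both raise ECAR under oligomycin (glycolytic compensation for
#' OXPHOS inhibition).
#'
#' @param name `"spicilegus"` or `"musculus"`.
#' @param ... Overrides passed to [generator_config()].
#'
#' @return A [generator_config()].
#' @export
species_phenotype <- function(name = c("spicilegus", "musculus"), ...) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% c("spicilegus", "musculus")) {
    usage_error("Unknown species preset; use \"spicilegus\" or \"musculus\".")
  }
  treatments <- if (name == "spicilegus") {
    default_treatments()
  } else {
    tibble::tibble(
      treatment = c("baseline", "oligomycin", "fccp", "2dog", "oxamate"),
      ocr_mult = c(1, 0.31, 8.0, 0.32, 0.46),
      ecar_mult = c(1, 1.60, 1.0, 0.40, 0.63)
    )
  }
  conditions <- if (name == "spicilegus") {
    list(non_capacitating = c(ocr = 315, ecar = 18.9),
         capacitating = c(ocr = 231, ecar = 25.7))
  } else {
    list(non_capacitating = c(ocr = 315, ecar = 18.9),
         capacitating = c(ocr = 198, ecar = 28.7))
  }
  generator_config(treatments = treatments, conditions = conditions, ...)
}
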