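#' Aggregate a signal over a cycle window
#'
#' Arithmetic mean, maximum or minimum of the per-sperm OCR and ECAR over
#' exactly the cycles of one window. Discarded cycles are never included.
#'
#' @param data A `normalized_traces` tibble (see [normalize_per_sperm()]).
#' @param window One of `"baseline"`, `"treatment"`, `"ar"`.
#' @param mode One of `"mean"`, `"max"`, `"min"`.
#' @param windows A [cycle_windows()] plan; defaults to the one attached to
#'   `data`.
#'
#' @return A tibble with one row per well: `well_id`, `window`, `mode`,
#'   `ocr`, `ecar`.
#' @export
window_aggregate <- function(data, window = c("baseline", "treatment", "ar"),
                             mode = c("mean", "max", "min"), windows = NULL) {
  window <- match.arg(window)
  mode <- match.arg(mode)
  w <- get_windows(data, windows)
  cycles <- w[[window]]
  if (length(cycles) == 0) {
    validation_error(paste0("The ", window, " window is empty."))
  }
  present <- data |>
    dplyr::summarise(ok = all(cycles %in% .data$cycle), .by = "well_id")
  if (!all(present$ok)) {
    validation_error(paste0(
      "Wells missing cycles of the ", window, " window: ",
      paste(present$well_id[!present$ok], collapse = ", ")
    ))
  }
  f <- switch(mode, mean = mean, max = max, min = min)
  data |>
    dplyr::filter(.data$cycle %in% cycles) |>
    dplyr::summarise(ocr = f(.data$ocr), ecar = f(.data$ecar),
                     .by = "well_id") |>
    dplyr::mutate(window = window, mode = mode,
                  .after = "well_id")
}

# one row per well with every window statistic the panel needs
well_window_stats <- function(data, windows = NULL) {
  w <- get_windows(data, windows)
  need <- c(w$baseline, w$treatment)
  present <- data |>
    dplyr::summarise(ok = all(need %in% .data$cycle), .by = "well_id")
  if (!all(present$ok)) {
    validation_error(paste0(
      "Wells missing baseline/treatment cycles: ",
      paste(present$well_id[!present$ok], collapse = ", ")
    ))
  }
  stat_in <- function(x, cyc, cycles, f) {
    f(x[cyc %in% cycles])
  }
  ar_stat <- function(x, cyc) {
    # A+R window may be absent on truncated runs; NA triggers the fallback
    if (length(w$ar) == 0 || !all(w$ar %in% cyc)) NA_real_
    else mean(x[cyc %in% w$ar])
  }
  data |>
    dplyr::summarise(
      ocr_base = stat_in(.data$ocr, .data$cycle, w$baseline, mean),
      ocr_tr_mean = stat_in(.data$ocr, .data$cycle, w$treatment, mean),
      ocr_tr_max = stat_in(.data$ocr, .data$cycle, w$treatment, max),
      ocr_ar = ar_stat(.data$ocr, .data$cycle),
      ecar_base = stat_in(.data$ecar, .data$cycle, w$baseline, mean),
      ecar_tr_mean = stat_in(.data$ecar, .data$cycle, w$treatment, mean),
      ecar_tr_max = stat_in(.data$ecar, .data$cycle, w$treatment, max),
      ecar_tr_min = stat_in(.data$ecar, .data$cycle, w$treatment, min),
      ecar_ar = ar_stat(.data$ecar, .data$cycle),
      .by = "well_id"
    ) |>
    dplyr::left_join(
      dplyr::distinct(data, .data$well_id, .data$experiment_id,
                      .data$condition, .data$treatment),
      by = "well_id"
    )
}

#' Per-well basal (and non-mitochondrial) respiration
#'
#' Basal respiration is the baseline-window mean OCR minus the A+R-window
#' mean OCR of the same well, i.e. the mitochondrial part of resting oxygen
#' consumption. When the A+R window is absent (truncated run) the
#' uncorrected baseline mean is returned and flagged `nonmito_uncorrected`.
#'
#' @inheritParams window_aggregate
#' @return A tibble: `well_id`, `experiment_id`, `condition`, `treatment`,
#'   `basal_respiration`, `nonmito_respiration`, `nonmito_uncorrected`.
#' @export
basal_respiration <- function(data, windows = NULL) {
  ws <- well_window_stats(data, windows)
  ws |>
    dplyr::mutate(
      nonmito_uncorrected = is.na(.data$ocr_ar),
      nonmito_respiration = ifelse(is.na(.data$ocr_ar), NA_real_,
                                   .data$ocr_ar),
      basal_respiration = .data$ocr_base -
        ifelse(is.na(.data$ocr_ar), 0, .data$ocr_ar)
    ) |>
    dplyr::select("well_id", "experiment_id", "condition", "treatment",
                  "basal_respiration", "nonmito_respiration",
                  "nonmito_uncorrected")
}

#' Proton leak and ATP-linked respiration for a baseline/oligomycin well pair
#'
#' Oligomycin blocks the ATP synthase; the A+R-corrected OCR that persists
#' under oligomycin is proton leak, expressed as a percentage of the pair's
#' basal respiration (taken from the baseline well). ATP-linked respiration
#' is its complement, so the two always sum to 100.
#'
#' @inheritParams window_aggregate
#' @param baseline_well,oligo_well Well ids of the untreated and
#'   oligomycin-treated wells (same experiment and condition).
#'
#' @return A one-row tibble: `basal`, `proton_leak_pct`, `atp_linked_pct`.
#' @export
proton_leak_atp_linked <- function(data, baseline_well, oligo_well,
                                   windows = NULL) {
  ws <- well_window_stats(data, windows)
  b <- ws[ws$well_id == baseline_well, ]
  o <- ws[ws$well_id == oligo_well, ]
  if (nrow(b) != 1 || nrow(o) != 1) {
    validation_error("baseline_well and oligo_well must each match one well.")
  }
  basal <- b$ocr_base - ifelse(is.na(b$ocr_ar), 0, b$ocr_ar)
  if (!is.finite(basal) || basal <= 0) {
    panel_error("Basal respiration of the pair is not positive; panel undefined.")
  }
  leak <- 100 * (o$ocr_tr_mean - ifelse(is.na(o$ocr_ar), 0, o$ocr_ar)) / basal
  tibble::tibble(basal = basal, proton_leak_pct = leak,
                 atp_linked_pct = 100 - leak)
}

#' Maximal respiration and spare respiratory capacity for an FCCP well
#'
#' FCCP uncouples the mitochondria and drives respiration to its maximum.
#' The highest A+R-corrected OCR among the treatment-window cycles is
#' expressed as a percentage of basal respiration; the spare capacity is
#' that percentage minus 100.
#'
#' @inheritParams window_aggregate
#' @param fccp_well Well id of the FCCP-treated well.
#' @param basal Basal respiration (amol O2 min^-1 sperm^-1) of the pair.
#'
#' @return A one-row tibble: `maximal_respiration_pct`, `spare_capacity_pct`.
#' @export
maximal_spare <- function(data, fccp_well, basal, windows = NULL) {
  if (!is.finite(basal) || basal <= 0) {
    panel_error("Basal respiration must be positive; panel undefined.")
  }
  ws <- well_window_stats(data, windows)
  f <- ws[ws$well_id == fccp_well, ]
  if (nrow(f) != 1) validation_error("fccp_well must match exactly one well.")
  maximal <- 100 * (f$ocr_tr_max - ifelse(is.na(f$ocr_ar), 0, f$ocr_ar)) /
    basal
  tibble::tibble(maximal_respiration_pct = maximal,
                 spare_capacity_pct = maximal - 100)
}

#' Basal glycolysis and glycolytic reserve for a baseline/oligomycin pair
#'
#' Basal glycolysis is the baseline-window mean ECAR (no A+R correction;
#' extracellular acidification has no analogous non-glycolytic floor
#' measured here). The glycolytic reserve is the rise of the
#' oligomycin-treated well's peak ECAR (max over the treatment window) above
#' basal glycolysis, as a percentage of basal glycolysis.
#'
#' @inheritParams proton_leak_atp_linked
#' @return A one-row tibble: `basal_glycolysis`, `glycolytic_reserve_pct`.
#' @export
glycolysis_panel <- function(data, baseline_well, oligo_well,
                             windows = NULL) {
  ws <- well_window_stats(data, windows)
  b <- ws[ws$well_id == baseline_well, ]
  o <- ws[ws$well_id == oligo_well, ]
  if (nrow(b) != 1 || nrow(o) != 1) {
    validation_error("baseline_well and oligo_well must each match one well.")
  }
  if (!is.finite(b$ecar_base) || b$ecar_base <= 0) {
    panel_error("Basal glycolysis is not positive; panel undefined.")
  }
  tibble::tibble(
    basal_glycolysis = b$ecar_base,
    glycolytic_reserve_pct =
      100 * (o$ecar_tr_max - b$ecar_base) / b$ecar_base
  )
}

#' Per-well basal OCR/ECAR ratio
#'
#' Ratio of baseline-window mean OCR to baseline-window mean ECAR,
#' uncorrected (the basal state, before any addition). Cohort summaries must
#' average per-well ratios, never divide cohort means.
#'
#' @inheritParams window_aggregate
#' @return A tibble: `well_id`, `experiment_id`, `condition`, `treatment`,
#'   `ocr_ecar_ratio`.
#' @export
ocr_ecar_ratio <- function(data, windows = NULL) {
  ws <- well_window_stats(data, windows)
  if (any(ws$ecar_base == 0)) {
    panel_error(paste0(
      "Zero baseline ECAR; OCR/ECAR undefined for wells: ",
      paste(ws$well_id[ws$ecar_base == 0], collapse = ", ")
    ))
  }
  ws |>
    dplyr::mutate(ocr_ecar_ratio = .data$ocr_base / .data$ecar_base) |>
    dplyr::select("well_id", "experiment_id", "condition", "treatment",
                  "ocr_ecar_ratio")
}

#' Compute the full bioenergetic parameter panel
#'
#' Derives, for every measurement well where the quantity is defined: basal
#' respiration and non-mitochondrial respiration, basal glycolysis and the
#' basal OCR/ECAR ratio (all wells); proton leak, ATP-linked respiration and
#' glycolytic reserve (oligomycin wells); maximal respiration and spare
#' respiratory capacity (FCCP wells). Quantities that need a basal reference
#' pair each modulator well with the baseline wells of the same experiment
#' and condition; with `pairing = "average"` (default) the value is averaged
#' over all such pairs, with `pairing = "first"` only the first baseline
#' well (in well-id order) is used.
#'
#' Wells whose pair basal is non-positive get `NA` with a flag rather than
#' failing the plate. Percent quantities satisfy the exact identities
#' `proton_leak_pct + atp_linked_pct == 100` and
#' `spare_capacity_pct == maximal_respiration_pct - 100`.
#'
#' @inheritParams window_aggregate
#' @param pairing `"average"` or `"first"`; see Details.
#'
#' @return A tibble with one row per well and columns `well_id`,
#'   `experiment_id`, `condition`, `treatment`, the nine panel quantities,
#'   and a `flags` character column.
#' @export
metabolic_panel <- function(data, windows = NULL,
                            pairing = c("average", "first")) {
  pairing <- match.arg(pairing)
  ws <- well_window_stats(data, windows)
  ws <- ws |>
    dplyr::mutate(
      ar_ocr = ifelse(is.na(.data$ocr_ar), 0, .data$ocr_ar),
      basal_respiration = .data$ocr_base - .data$ar_ocr,
      nonmito_respiration = .data$ocr_ar,
      basal_glycolysis = .data$ecar_base,
      ocr_ecar_ratio = ifelse(.data$ecar_base > 0,
                              .data$ocr_base / .data$ecar_base, NA_real_),
      flags = ifelse(is.na(.data$ocr_ar), "nonmito_uncorrected", "")
    )
  ws$flags[ws$ecar_base <= 0] <- paste0(ws$flags[ws$ecar_base <= 0],
                                        ";undefined_ratio")

  # pair each modulator well with baseline wells of its experiment x condition
  pair_stat <- function(mod_row, base_rows, numerator, percent_of) {
    vals <- vapply(seq_len(nrow(base_rows)), function(i) {
      ref <- percent_of(base_rows[i, ])
      if (!is.finite(ref) || ref <= 0) return(NA_real_)
      100 * numerator(mod_row, base_rows[i, ]) / ref
    }, numeric(1))
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0) return(NA_real_)
    if (pairing == "first") vals[1] else mean(vals)
  }

  extra <- purrr::map_dfr(seq_len(nrow(ws)), function(j) {
    row <- ws[j, ]
    out <- tibble::tibble(
      well_id = row$well_id,
      proton_leak_pct = NA_real_, atp_linked_pct = NA_real_,
      maximal_respiration_pct = NA_real_, spare_capacity_pct = NA_real_,
      glycolytic_reserve_pct = NA_real_, pair_flag = ""
    )
    if (!row$treatment %in% c("oligomycin", "fccp")) return(out)
    base_rows <- ws |>
      dplyr::filter(.data$experiment_id == row$experiment_id,
                    .data$condition == row$condition,
                    .data$treatment == "baseline") |>
      dplyr::arrange(.data$well_id)
    if (nrow(base_rows) == 0) {
      out$pair_flag <- "no_baseline_well"
      return(out)
    }
    if (row$treatment == "oligomycin") {
      leak <- pair_stat(
        row, base_rows,
        numerator = function(m, b) m$ocr_tr_mean - m$ar_ocr,
        percent_of = function(b) b$basal_respiration
      )
      out$proton_leak_pct <- leak
      out$atp_linked_pct <- 100 - leak
      reserve <- pair_stat(
        row, base_rows,
        numerator = function(m, b) m$ecar_tr_max - b$ecar_base,
        percent_of = function(b) b$ecar_base
      )
      out$glycolytic_reserve_pct <- reserve
      if (is.na(leak) || is.na(reserve)) out$pair_flag <- "undefined_basal"
    } else {
      maximal <- pair_stat(
        row, base_rows,
        numerator = function(m, b) m$ocr_tr_max - m$ar_ocr,
        percent_of = function(b) b$basal_respiration
      )
      out$maximal_respiration_pct <- maximal
      out$spare_capacity_pct <- maximal - 100
      if (is.na(maximal)) out$pair_flag <- "undefined_basal"
    }
    out
  })

  ws |>
    dplyr::left_join(extra, by = "well_id") |>
    dplyr::mutate(
      flags = trimws(paste0(.data$flags,
                            ifelse(.data$pair_flag == "", "",
                                   paste0(";", .data$pair_flag))),
                     whitespace = ";")
    ) |>
    dplyr::select(
      "well_id", "experiment_id", "condition", "treatment",
      "basal_respiration", "nonmito_respiration", "proton_leak_pct",
      "atp_linked_pct", "maximal_respiration_pct", "spare_capacity_pct",
      "basal_glycolysis", "glycolytic_reserve_pct", "ocr_ecar_ratio",
      "flags"
    )
}

#' Modulator responses as percent of baseline
#'
#' Expresses each well's treatment-window signal as a percentage of its own
#' baseline-window mean. OCR values (both baseline and treatment aggregates)
#' are first corrected by subtracting the well's A+R-window mean, so that
#' only mitochondrial respiration enters the ratio; ECAR is not corrected.
#'
#' Two aggregation conventions are supported: `"table2"` uses the
#' treatment-window mean for both signals; `"table3"` (the interspecific
#' convention) keeps the mean for OCR but uses the treatment-window maximum
#' of ECAR under oligomycin and the minimum under 2DOG. `delta_percent` is
#' `percent_of_baseline - 100`. With `include_ar = TRUE`, ECAR rows for the
#' post-A+R window (cycles 8-9 mean, treatment label `"ar"`) are appended.
#'
#' Wells whose corrected baseline OCR is not positive are flagged
#' `excluded = TRUE` with `NA` responses (a gamma model downstream needs
#' positive values); the exclusion count is reported via a message.
#'
#' @inheritParams window_aggregate
#' @param convention `"table2"` or `"table3"`.
#' @param include_ar Append post-A+R ECAR response rows.
#'
#' @return A tibble with columns `well_id`, `experiment_id`, `condition`,
#'   `treatment`, `signal`, `aggregation`, `ar_corrected`,
#'   `percent_of_baseline`, `delta_percent`, `excluded`.
#' @export
response_percent <- function(data, windows = NULL,
                             convention = c("table2", "table3"),
                             include_ar = TRUE) {
  convention <- match.arg(convention)
  ws <- well_window_stats(data, windows)
  ws <- dplyr::mutate(ws, ar_ocr = ifelse(is.na(.data$ocr_ar), 0,
                                          .data$ocr_ar))

  ocr <- ws |>
    dplyr::mutate(
      signal = "OCR",
      aggregation = "mean_5_7",
      ar_corrected = TRUE,
      base = .data$ocr_base - .data$ar_ocr,
      value = .data$ocr_tr_mean - .data$ar_ocr,
      excluded = !(is.finite(.data$base) & .data$base > 0),
      percent_of_baseline = ifelse(.data$excluded, NA_real_,
                                   100 * .data$value / .data$base)
    )
  ecar <- ws |>
    dplyr::mutate(
      signal = "ECAR",
      ar_corrected = FALSE,
      base = .data$ecar_base,
      value = if (convention == "table2") .data$ecar_tr_mean else
        dplyr::case_when(
          .data$treatment == "oligomycin" ~ .data$ecar_tr_max,
          .data$treatment == "2dog" ~ .data$ecar_tr_min,
          TRUE ~ .data$ecar_tr_mean
        ),
      aggregation = if (convention == "table2") "mean_5_7" else
        dplyr::case_when(
          .data$treatment == "oligomycin" ~ "max_5_7",
          .data$treatment == "2dog" ~ "min_5_7",
          TRUE ~ "mean_5_7"
        ),
      excluded = !(is.finite(.data$base) & .data$base > 0),
      percent_of_baseline = ifelse(.data$excluded, NA_real_,
                                   100 * .data$value / .data$base)
    )
  out <- dplyr::bind_rows(ocr, ecar)

  if (include_ar && !all(is.na(ws$ecar_ar))) {
    ar_rows <- ws |>
      dplyr::filter(!is.na(.data$ecar_ar)) |>
      dplyr::mutate(
        treatment = "ar",
        signal = "ECAR",
        aggregation = "mean_8_9",
        ar_corrected = FALSE,
        base = .data$ecar_base,
        excluded = !(is.finite(.data$base) & .data$base > 0),
        percent_of_baseline = ifelse(.data$excluded, NA_real_,
                                     100 * .data$ecar_ar / .data$base)
      )
    out <- dplyr::bind_rows(out, ar_rows)
  }

  n_excl <- sum(out$excluded)
  if (n_excl > 0) {
    rlang::inform(paste0(
      n_excl, " response value(s) excluded (non-positive corrected baseline): ",
      paste(unique(out$well_id[out$excluded]), collapse = ", ")
    ))
  }
  out |>
    dplyr::mutate(delta_percent = .data$percent_of_baseline - 100) |>
    dplyr::select("well_id", "experiment_id", "condition", "treatment",
                  "signal", "aggregation", "ar_corrected",
                  "percent_of_baseline", "delta_percent", "excluded")
}

#' Percent change between condition means
#'
#' Directional percent change between two cohort means, relative to the
#' non-capacitating (reference) mean: a `"decrease"` is
#' `100 * (nc - cap) / nc`, an `"increase"` is `100 * (cap - nc) / nc`.
#' Full precision is returned; narrative reporting rounds to the integer.
#'
#' @param nc_mean Reference (non-capacitating) cohort mean; must be > 0.
#' @param cap_mean Comparison (capacitating) cohort mean.
#' @param direction `"decrease"` or `"increase"`.
#'
#' @return The percent change as a bare number.
#' @examples
#' condition_percent_change(315, 231, "decrease") # ~27
#' condition_percent_change(18.9, 25.7, "increase") # ~36
#' @export
condition_percent_change <- function(nc_mean, cap_mean,
                                     direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  if (!is.finite(nc_mean) || nc_mean <= 0) {
    panel_error("The reference mean must be positive.")
  }
  if (direction == "decrease") 100 * (nc_mean - cap_mean) / nc_mean
  else 100 * (cap_mean - nc_mean) / nc_mean
}
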