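#' Background-correct raw OCR/ECAR traces
#'
#' Cell-free wells on each plate track the instrument and medium drift. For
#' every measurement cycle, the mean raw OCR (and ECAR) of the background
#' wells of the same experiment is subtracted from each measurement well.
#' Background wells are dropped from the output. Corrected values may be
#' negative; they are retained here and handled by downstream exclusion
#' rules.
#'
#' @param run A [plate_run()] with at least one background well per
#'   experiment.
#'
#' @return A background-corrected [plate_run()] containing only measurement
#'   wells.
#' @export
background_correct <- function(run) {
  stopifnot(inherits(run, "plate_run"))
  if (isTRUE(run$background_corrected)) {
    usage_error("This run is already background-corrected.")
  }
  bg_wells <- run$layout$well_id[run$layout$is_background]
  if (length(bg_wells) == 0) {
    config_error("No background wells in the run; cannot background-correct.")
  }
  missing_bg <- run$layout |>
    dplyr::summarise(has_bg = any(.data$is_background),
                     .by = "experiment_id") |>
    dplyr::filter(!.data$has_bg)
  if (nrow(missing_bg) > 0) {
    config_error(paste0(
      "Experiments without background wells: ",
      paste(missing_bg$experiment_id, collapse = ", ")
    ))
  }

  traces <- dplyr::left_join(
    run$traces,
    run$layout[, c("well_id", "experiment_id", "is_background")],
    by = "well_id"
  )
  bg <- traces |>
    dplyr::filter(.data$is_background) |>
    dplyr::summarise(
      bg_ocr = mean(.data$ocr_raw),
      bg_ecar = mean(.data$ecar_raw),
      .by = c("experiment_id", "cycle")
    )
  corrected <- traces |>
    dplyr::filter(!.data$is_background) |>
    dplyr::left_join(bg, by = c("experiment_id", "cycle")) |>
    dplyr::mutate(
      ocr_raw = .data$ocr_raw - .data$bg_ocr,
      ecar_raw = .data$ecar_raw - .data$bg_ecar
    ) |>
    dplyr::select("well_id", "cycle", "time_min", "ocr_raw", "ecar_raw")

  plate_run(
    traces = corrected,
    layout = dplyr::filter(run$layout, !.data$is_background),
    windows = run$windows,
    run_id = run$run_id,
    background_corrected = TRUE
  )
}

#' Convert background-corrected rates to per-sperm units
#'
#' Divides each well's rates by the number of sperm counted in that well and
#' rescales so OCR is in amol O2 min^-1 sperm^-1 and ECAR in
#' nano-pH min^-1 sperm^-1. With the default scales (10^6 amol per pmol,
#' 10^6 npH per mpH), a well of 10^6 sperm at 1 pmol O2 min^-1 gives
#' 1 amol O2 min^-1 sperm^-1.
#'
#' @param run A background-corrected [plate_run()].
#' @param ocr_scale amol per pmol (default `1e6`).
#' @param ecar_scale nano-pH per milli-pH (default `1e6`).
#'
#' @return A `normalized_traces` tibble with one row per well and cycle:
#'   `well_id`, `experiment_id`, `condition`, `treatment`, `cycle`,
#'   `time_min`, `ocr`, `ecar`, carrying the cycle windows as an attribute.
#' @export
normalize_per_sperm <- function(run, ocr_scale = 1e6, ecar_scale = 1e6) {
  stopifnot(inherits(run, "plate_run"))
  if (!isTRUE(run$background_corrected)) {
    usage_error("Run background_correct() before normalize_per_sperm().")
  }
  if (anyNA(run$layout$sperm_count)) {
    validation_error(paste0(
      "Missing sperm_count for wells: ",
      paste(run$layout$well_id[is.na(run$layout$sperm_count)],
            collapse = ", ")
    ))
  }
  out <- run$traces |>
    dplyr::left_join(
      run$layout[, c("well_id", "experiment_id", "condition", "treatment",
                     "sperm_count")],
      by = "well_id"
    ) |>
    dplyr::mutate(
      ocr = .data$ocr_raw * ocr_scale / .data$sperm_count,
      ecar = .data$ecar_raw * ecar_scale / .data$sperm_count
    ) |>
    dplyr::select("well_id", "experiment_id", "condition", "treatment",
                  "cycle", "time_min", "ocr", "ecar")
  new_normalized(out, run$windows)
}

new_normalized <- function(df, windows) {
  out <- tibble::as_tibble(df)
  attr(out, "windows") <- as_cycle_windows(windows)
  class(out) <- c("normalized_traces", class(out))
  out
}

get_windows <- function(x, windows = NULL) {
  if (!is.null(windows)) return(as_cycle_windows(windows))
  as_cycle_windows(attr(x, "windows", exact = TRUE))
}
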