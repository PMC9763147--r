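CONDITION_LEVELS <- c("non_capacitating", "capacitating")
TREATMENT_LEVELS <- c("baseline", "oligomycin", "fccp", "2dog", "oxamate")

# CSV tokens <-> canonical levels
condition_from_token <- c(NC = "non_capacitating", CAP = "capacitating",
                          non_capacitating = "non_capacitating",
                          capacitating = "capacitating")
condition_to_token <- c(non_capacitating = "NC", capacitating = "CAP")
treatment_from_token <- c(baseline = "baseline", oligo = "oligomycin",
                          oligomycin = "oligomycin", fccp = "fccp",
                          `2dog` = "2dog", oxamate = "oxamate")
treatment_to_token <- c(baseline = "baseline", oligomycin = "oligo",
                        fccp = "fccp", `2dog` = "2dog", oxamate = "oxamate")

#' Construct a validated plate run
#'
#' Bundles well-level kinetic traces with the plate layout and the
#' cycle-window plan. Most users will call [read_plate_kinetics()] or
#' [generate_plate()] instead of building the object directly.
#'
#' @param traces Tibble with columns `well_id`, `cycle`, `time_min`,
#'   `ocr_raw` (pmol O2 min^-1 well^-1), `ecar_raw` (mpH min^-1 well^-1).
#' @param layout Tibble with columns `well_id`, `experiment_id`, `condition`,
#'   `treatment`, `sperm_count`, `is_background`. Background wells may have
#'   `NA` condition, treatment and sperm count.
#' @param windows A [cycle_windows()] plan.
#' @param run_id Identifier carried through outputs.
#' @param background_corrected Internal flag; set by [background_correct()].
#'
#' @return A `plate_run` object: a list with elements `traces`, `layout`,
#'   `windows`, `run_id`, `background_corrected`.
#' @export
plate_run <- function(traces, layout, windows = cycle_windows(),
                      run_id = "run", background_corrected = FALSE) {
  traces <- tibble::as_tibble(traces)
  layout <- tibble::as_tibble(layout)
  windows <- as_cycle_windows(windows)

  need_tr <- c("well_id", "cycle", "time_min", "ocr_raw", "ecar_raw")
  need_ly <- c("well_id", "experiment_id", "condition", "treatment",
               "sperm_count", "is_background")
  check_columns(traces, need_tr, "traces")
  check_columns(layout, need_ly, "layout")
  if (nrow(traces) == 0) format_error("The trace table is empty.")

  dup <- traces |>
    dplyr::count(.data$well_id, .data$cycle) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    consistency_error(paste0(
      "Duplicated (well, cycle) rows: ",
      paste(paste0(dup$well_id, "/cycle ", dup$cycle), collapse = ", ")
    ))
  }

  only_tr <- setdiff(unique(traces$well_id), layout$well_id)
  only_ly <- setdiff(layout$well_id, unique(traces$well_id))
  if (length(only_tr) || length(only_ly)) {
    consistency_error(paste0(
      "Traces and layout disagree on wells.",
      if (length(only_tr)) paste0(" In traces only: ",
                                  paste(only_tr, collapse = ", "), "."),
      if (length(only_ly)) paste0(" In layout only: ",
                                  paste(only_ly, collapse = ", "), ".")
    ))
  }

  if (!all(is.finite(traces$ocr_raw)) || !all(is.finite(traces$ecar_raw))) {
    validation_error("Raw OCR/ECAR values must all be finite.")
  }

  n_cycles <- traces |>
    dplyr::summarise(n = dplyr::n(), .by = "well_id")
  if (length(unique(n_cycles$n)) != 1) {
    consistency_error("All wells must share the same number of cycles.")
  }

  traces <- dplyr::arrange(traces, .data$well_id, .data$cycle)
  bad_time <- traces |>
    dplyr::summarise(
      ok = all(diff(.data$cycle) > 0) && !is.unsorted(.data$time_min),
      .by = "well_id"
    )
  if (!all(bad_time$ok)) {
    validation_error(paste0(
      "Cycle indices must be strictly increasing and time non-decreasing ",
      "within each well: ",
      paste(bad_time$well_id[!bad_time$ok], collapse = ", ")
    ))
  }

  layout$is_background <- as.logical(layout$is_background)
  meas <- dplyr::filter(layout, !.data$is_background)
  if (nrow(meas) > 0) {
    if (anyNA(meas$condition) || anyNA(meas$treatment) ||
        anyNA(meas$sperm_count) || anyNA(meas$experiment_id)) {
      validation_error(
        "Non-background wells must have condition, treatment, sperm_count and experiment_id."
      )
    }
    if (any(meas$sperm_count <= 0)) {
      validation_error(paste0(
        "Non-positive sperm_count for wells: ",
        paste(meas$well_id[meas$sperm_count <= 0], collapse = ", ")
      ))
    }
    bad_cond <- setdiff(unique(meas$condition), CONDITION_LEVELS)
    if (length(bad_cond)) {
      validation_error(paste0("Unknown condition level(s): ",
                              paste(bad_cond, collapse = ", ")))
    }
    bad_tr <- setdiff(unique(meas$treatment), TREATMENT_LEVELS)
    if (length(bad_tr)) {
      validation_error(paste0("Unknown treatment level(s): ",
                              paste(bad_tr, collapse = ", ")))
    }
  }

  structure(
    list(traces = traces, layout = layout, windows = windows,
         run_id = run_id, background_corrected = background_corrected),
    class = "plate_run"
  )
}

check_columns <- function(df, needed, what) {
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    format_error(paste0(
      "The ", what, " table is missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

#' @export
print.plate_run <- function(x, ...) {
  n_wells <- length(unique(x$traces$well_id))
  n_bg <- sum(x$layout$is_background)
  n_cyc <- nrow(x$traces) / max(n_wells, 1)
  cat("<plate_run> ", x$run_id, "\n", sep = "")
  cat("  ", n_wells, " wells (", n_wells - n_bg, " measurement, ", n_bg,
      " background), ", n_cyc, " cycles\n", sep = "")
  cat("  experiments:",
      paste(sort(unique(x$layout$experiment_id)), collapse = ", "), "\n")
  cat("  background corrected:", x$background_corrected, "\n")
  invisible(x)
}

#' Read plate kinetics and layout from CSV
#'
#' Reads the two-file plate format: a long trace table
#' (`well_id,cycle,time_min,ocr_raw,ecar_raw`) and a layout table
#' (`well_id,experiment_id,condition,treatment,sperm_count,is_background`
#' with condition tokens `NC`/`CAP`, treatment tokens
#' `baseline,oligo,fccp,2dog,oxamate` and `is_background` 0/1). If the trace
#' file carries only timestamps, cycles are renumbered 1-based in time order
#' within each well.
#'
#' @param path Path to the traces CSV.
#' @param layout_path Path to the layout CSV.
#' @param windows A [cycle_windows()] plan.
#' @param run_id Identifier for the run; defaults to the trace file name.
#'
#' @return A validated [plate_run()].
#' @export
read_plate_kinetics <- function(path, layout_path, windows = cycle_windows(),
                                run_id = NULL) {
  if (!file.exists(path)) io_error(paste0("Trace file not found: ", path))
  if (!file.exists(layout_path)) {
    io_error(paste0("Layout file not found: ", layout_path))
  }
  traces <- readr::read_csv(path, show_col_types = FALSE,
                            progress = FALSE)
  layout <- readr::read_csv(layout_path, show_col_types = FALSE,
                            progress = FALSE)
  if (nrow(traces) == 0) format_error("The trace file is empty.")
  check_columns(traces, c("well_id", "time_min", "ocr_raw", "ecar_raw"),
                "traces")
  if (!"cycle" %in% names(traces)) {
    traces <- traces |>
      dplyr::mutate(cycle = rank(.data$time_min, ties.method = "first"),
                    .by = "well_id")
  }
  check_columns(layout, c("well_id", "experiment_id", "condition",
                          "treatment", "sperm_count", "is_background"),
                "layout")
  layout <- layout |>
    dplyr::mutate(
      condition = unname(condition_from_token[as.character(.data$condition)]),
      treatment = unname(treatment_from_token[as.character(.data$treatment)]),
      is_background = as.logical(as.integer(.data$is_background))
    )
  plate_run(traces, layout, windows,
            run_id = run_id %||% sub("\\.csv$", "", basename(path)))
}

#' Write a plate run (and optionally a parameter panel) as tidy CSVs
#'
#' Writes `<prefix>_traces.csv` and `<prefix>_layout.csv` in the dialect read
#' by [read_plate_kinetics()], plus `<prefix>_panel.csv` in long format
#' (`well_id,experiment_id,condition,quantity,value`) when a panel is given.
#' Values round-trip losslessly (full double precision is written).
#'
#' @param run A [plate_run()].
#' @param panel Optional panel tibble from [metabolic_panel()].
#' @param out_dir Output directory, created if needed.
#' @param prefix File-name prefix; defaults to the run id.
#'
#' @return Invisibly, a named character vector of the files written.
#' @export
write_tidy_tables <- function(run, panel = NULL, out_dir, prefix = NULL) {
  stopifnot(inherits(run, "plate_run"))
  prefix <- prefix %||% run$run_id
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) io_error(paste0("Cannot create output directory: ", out_dir))
  }
  if (file.access(out_dir, 2) != 0) {
    io_error(paste0("Output directory is not writable: ", out_dir))
  }

  paths <- c(
    traces = file.path(out_dir, paste0(prefix, "_traces.csv")),
    layout = file.path(out_dir, paste0(prefix, "_layout.csv"))
  )
  readr::write_csv(run$traces[, c("well_id", "cycle", "time_min",
                                  "ocr_raw", "ecar_raw")],
                   paths[["traces"]])
  layout_out <- run$layout |>
    dplyr::mutate(
      condition = unname(condition_to_token[.data$condition]),
      treatment = unname(treatment_to_token[.data$treatment]),
      is_background = as.integer(.data$is_background)
    )
  readr::write_csv(layout_out, paths[["layout"]])

  if (!is.null(panel)) {
    unknown <- setdiff(unique(panel$well_id), run$layout$well_id)
    if (length(unknown)) {
      consistency_error(paste0(
        "Panel references wells absent from the run: ",
        paste(unknown, collapse = ", ")
      ))
    }
    panel_long <- panel |>
      tidyr::pivot_longer(
        cols = -dplyr::any_of(c("well_id", "experiment_id", "condition",
                                "treatment", "flags")),
        names_to = "quantity", values_to = "value"
      ) |>
      dplyr::filter(!is.na(.data$value))
    p <- file.path(out_dir, paste0(prefix, "_panel.csv"))
    readr::write_csv(panel_long, p)
    paths <- c(paths, panel = p)
  }
  invisible(paths)
}
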