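md_table <- function(df, digits = 3) {
  fmt <- function(x) {
    if (is.numeric(x)) formatC(x, digits = digits, format = "fg") else
      as.character(x)
  }
  body <- apply(as.data.frame(lapply(df, fmt)), 1, paste, collapse = " | ")
  c(paste("|", paste(names(df), collapse = " | "), "|"),
    paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
    paste("|", body, "|"))
}

normalize_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) io_error(paste0("Config file not found: ",
                                              config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) usage_error("`config` must be a list or a YAML path.")
  has_sim <- !is.null(config$simulate)
  has_inputs <- !is.null(config$inputs)
  if (!has_sim && !has_inputs) {
    config_error("Config needs either a `simulate` block or an `inputs` block.")
  }
  if (has_inputs) {
    if (is.null(config$inputs$traces)) {
      config_error("Config key missing: inputs.traces")
    }
    if (is.null(config$inputs$layout)) {
      config_error("Config key missing: inputs.layout")
    }
  }
  config$seed <- as.integer(config$seed %||% 20221219L)
  config
}

#' Run the full flux-analysis pipeline
#'
#' Orchestrates validate/load -> background-correct -> normalize -> panel ->
#' responses -> summaries -> mixed-model statistics -> report, writing stage
#' CSVs, a Markdown report and a JSON manifest to `out_dir`. The input is
#' either a `simulate` block (generator/preset parameters) or an `inputs`
#' block with `traces` and `layout` CSV paths; `config` may be a list or the
#' path of a YAML file with the same structure. Runs are deterministic under
#' a fixed seed: all outputs except the manifest (which carries a timestamp)
#' are byte-identical on rerun.
#'
#' @param config A list or YAML path. Keys: `seed`; `simulate` (`species`
#'   preset name and/or [generator_config()] overrides) or `inputs`
#'   (`traces`, `layout`); optional `windows` (lists `discarded`, `baseline`,
#'   `treatment`, `ar`).
#' @param out_dir Output directory, created if needed.
#'
#' @return Invisibly, the manifest list (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  config <- normalize_pipeline_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stages <- character(0)
  status <- character(0)
  manifest_path <- file.path(out_dir, "manifest.json")

  note <- function(stage, ok = "ok") {
    stages <<- c(stages, stage)
    status <<- c(status, ok)
  }
  fail <- function(stage, err) {
    note(stage, paste0("failed: ", conditionMessage(err)))
    manifest <- build_manifest(config, stages, status, aborted = TRUE)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    rlang::abort(paste0("Pipeline stage '", stage, "' failed: ",
                        conditionMessage(err)),
                 class = "fluxcap_pipeline_error", parent = err)
  }

  # ---- load / simulate ----
  run <- tryCatch({
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      cfg <- if (!is.null(sim$species)) {
        args <- sim[setdiff(names(sim), "species")]
        do.call(species_phenotype,
                c(list(name = sim$species), args, list(seed = config$seed)))
      } else {
        do.call(generator_config, c(sim, list(seed = config$seed)))
      }
      generate_plate(cfg)$run
    } else {
      w <- if (!is.null(config$windows)) as_cycle_windows(config$windows)
           else cycle_windows()
      read_plate_kinetics(config$inputs$traces, config$inputs$layout, w)
    }
  }, error = function(e) fail("load", e))
  note("load")

  norm <- tryCatch(
    run |> background_correct() |> normalize_per_sperm(),
    error = function(e) fail("normalize", e)
  )
  note("normalize")

  panel <- tryCatch(metabolic_panel(norm),
                    error = function(e) fail("panel", e))
  readr::write_csv(panel, file.path(out_dir, "panel.csv"))
  note("panel")

  responses <- tryCatch(
    suppressMessages(response_percent(norm, convention = "table2")),
    error = function(e) fail("responses", e)
  )
  readr::write_csv(responses, file.path(out_dir, "responses.csv"))
  note("responses")

  # ---- summaries ----
  panel_long <- panel |>
    tidyr::pivot_longer(
      cols = c("basal_respiration", "nonmito_respiration",
               "proton_leak_pct", "atp_linked_pct",
               "maximal_respiration_pct", "spare_capacity_pct",
               "basal_glycolysis", "glycolytic_reserve_pct",
               "ocr_ecar_ratio"),
      names_to = "quantity", values_to = "value"
    ) |>
    dplyr::filter(!is.na(.data$value))
  panel_summary <- panel_long |>
    summarize_groups("value", .data$quantity, .data$condition)
  readr::write_csv(panel_summary, file.path(out_dir, "panel_summary.csv"))

  resp_summary <- responses |>
    dplyr::filter(!.data$excluded) |>
    summarize_groups("percent_of_baseline", .data$signal, .data$treatment,
                     .data$condition)
  readr::write_csv(resp_summary, file.path(out_dir, "response_summary.csv"))
  note("summaries")

  # ---- mixed-model statistics on panel quantities ----
  lmm_quantities <- c("basal_respiration", "basal_glycolysis",
                      "ocr_ecar_ratio")
  glmm_quantities <- c("proton_leak_pct", "atp_linked_pct",
                       "maximal_respiration_pct", "spare_capacity_pct",
                       "glycolytic_reserve_pct")
  stats_tbl <- tryCatch({
    purrr::map_dfr(c(lmm_quantities, glmm_quantities), function(q) {
      d <- panel_long |>
        dplyr::filter(.data$quantity == q, .data$value > 0)
      if (nrow(d) < 4 || length(unique(d$condition)) < 2 ||
          length(unique(d$experiment_id)) < 2) {
        return(tibble::tibble())
      }
      fam <- if (q %in% lmm_quantities) "gaussian_log10" else "gamma_inverse"
      res <- tryCatch(
        lrt_term(d, "value", "condition", "condition", family = fam),
        error = function(e) NULL
      )
      if (is.null(res)) return(tibble::tibble())
      dplyr::mutate(res, quantity = q, family = fam, .before = 1)
    })
  }, error = function(e) fail("stats", e))
  readr::write_csv(stats_tbl, file.path(out_dir, "lrt.csv"))

  contrasts_tbl <- tryCatch({
    d <- responses |>
      dplyr::filter(.data$signal == "OCR", !.data$excluded,
                    .data$percent_of_baseline > 0,
                    .data$treatment != "ar")
    if (nrow(d) >= 8 && length(unique(d$experiment_id)) >= 2 &&
        length(unique(d$treatment)) >= 2) {
      fit <- fit_gamma_glmm(d, "percent_of_baseline",
                            c("condition", "treatment"))
      emm_contrasts(fit, "treatment")
    } else tibble::tibble()
  }, error = function(e) tibble::tibble())
  readr::write_csv(contrasts_tbl, file.path(out_dir, "contrasts.csv"))
  note("stats")

  # ---- report ----
  cond_means <- panel_summary |>
    dplyr::filter(.data$quantity %in% c("basal_respiration",
                                        "basal_glycolysis"))
  pct_lines <- character(0)
  get_mean <- function(q, cond) {
    v <- cond_means$mean[cond_means$quantity == q &
                           cond_means$condition == cond]
    if (length(v) == 1) v else NA_real_
  }
  nc_ocr <- get_mean("basal_respiration", "non_capacitating")
  cap_ocr <- get_mean("basal_respiration", "capacitating")
  nc_ecar <- get_mean("basal_glycolysis", "non_capacitating")
  cap_ecar <- get_mean("basal_glycolysis", "capacitating")
  if (all(is.finite(c(nc_ocr, cap_ocr)))) {
    pct_lines <- c(pct_lines, sprintf(
      "- Basal respiration changed by %d%% (decrease) with capacitation (%.1f -> %.1f amol O2 min^-1 sperm^-1).",
      round(condition_percent_change(nc_ocr, cap_ocr, "decrease")),
      nc_ocr, cap_ocr))
  }
  if (all(is.finite(c(nc_ecar, cap_ecar)))) {
    pct_lines <- c(pct_lines, sprintf(
      "- Basal glycolysis changed by %d%% (increase) with capacitation (%.1f -> %.1f npH min^-1 sperm^-1).",
      round(condition_percent_change(nc_ecar, cap_ecar, "increase")),
      nc_ecar, cap_ecar))
  }

  report <- c(
    "# Extracellular flux analysis report",
    "",
    paste0("Run: ", run$run_id, " | seed: ", config$seed),
    "",
    "## Bioenergetic parameter panel (mean, SD, 95% CI by condition)",
    "",
    md_table(panel_summary[, c("quantity", "condition", "N", "n_wells",
                               "mean", "sd", "ci")]),
    "",
    "## Modulator responses (% of baseline)",
    "",
    md_table(resp_summary[, c("signal", "treatment", "condition", "N",
                              "mean", "sd", "ci")]),
    "",
    "## Condition contrasts (likelihood-ratio tests)",
    "",
    if (nrow(stats_tbl) > 0) md_table(stats_tbl) else "(not estimable)",
    "",
    "## Condition percent changes",
    "",
    if (length(pct_lines)) pct_lines else "(not available)",
    ""
  )
  writeLines(report, file.path(out_dir, "report.md"))
  note("report")

  manifest <- build_manifest(config, stages, status, aborted = FALSE)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

build_manifest <- function(config, stages, status, aborted) {
  cfg_for_hash <- config
  input_digests <- NULL
  if (!is.null(config$inputs)) {
    input_digests <- lapply(config$inputs, function(p) {
      if (file.exists(p)) digest::digest(file = p, algo = "md5") else NA
    })
  }
  list(
    config_hash = digest::digest(cfg_for_hash, algo = "md5"),
    input_digests = input_digests,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("fluxcap")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), tz = "UTC"),
    aborted = aborted,
    stages = data.frame(stage = stages, status = status)
  )
}
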