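#' Plot normalized kinetic traces
#'
#' One panel per signal, mean +/- standard error across wells by cycle,
#' colored by treatment and faceted by condition, with injection and A+R
#' cycle markers. Discarded cycles are omitted.
#'
#' @param object A `normalized_traces` tibble (see [normalize_per_sperm()]).
#' @param signal `"OCR"`, `"ECAR"` or `"both"`.
#' @param windows A [cycle_windows()]; defaults to the one attached to the
#'   data.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
plot_traces <- function(object, signal = c("both", "OCR", "ECAR"),
                        windows = NULL, ...) {
  signal <- match.arg(signal)
  w <- get_windows(object, windows)
  long <- object |>
    dplyr::filter(!.data$cycle %in% w$discarded) |>
    tidyr::pivot_longer(cols = c("ocr", "ecar"), names_to = "signal",
                        values_to = "rate") |>
    dplyr::mutate(signal = toupper(.data$signal))
  if (signal != "both") long <- dplyr::filter(long, .data$signal == !!signal)
  summ <- long |>
    dplyr::summarise(
      mean = mean(.data$rate),
      se = sd(.data$rate) / sqrt(dplyr::n()),
      .by = c("signal", "condition", "treatment", "cycle")
    )
  ggplot2::ggplot(summ, ggplot2::aes(.data$cycle, .data$mean,
                                     color = .data$treatment)) +
    ggplot2::geom_vline(xintercept = min(w$treatment) - 0.5,
                        linetype = "dashed", color = "grey50") +
    ggplot2::geom_vline(xintercept = if (length(w$ar)) min(w$ar) - 0.5 else NA,
                        linetype = "dashed", color = "grey30") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se),
                             size = 0.3) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(signal ~ condition, scales = "free_y") +
    ggplot2::labs(x = "measurement cycle",
                  y = "rate (amol O2 or npH min⁻¹ sperm⁻¹)",
                  color = "treatment") +
    ggplot2::theme_minimal()
}

#' @rdname plot_traces
#' @export
autoplot.normalized_traces <- function(object, ...) plot_traces(object, ...)

#' Plot the bioenergetic parameter panel by condition
#'
#' Bar-and-error plot (mean + standard error over wells) of each panel
#' quantity, faceted with free scales.
#'
#' @param panel A tibble from [metabolic_panel()].
#' @return A ggplot object.
#' @export
plot_panel <- function(panel) {
  long <- panel |>
    tidyr::pivot_longer(
      cols = c("basal_respiration", "proton_leak_pct", "atp_linked_pct",
               "maximal_respiration_pct", "spare_capacity_pct",
               "basal_glycolysis", "glycolytic_reserve_pct",
               "ocr_ecar_ratio"),
      names_to = "quantity", values_to = "value"
    ) |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = sd(.data$value) / sqrt(dplyr::n()),
      .by = c("quantity", "condition")
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$condition, .data$mean,
                                     fill = .data$condition)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.25) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean + SE") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Plot modulator responses as percent of baseline
#'
#' @param responses A tibble from [response_percent()].
#' @return A ggplot object.
#' @export
plot_responses <- function(responses) {
  summ <- responses |>
    dplyr::filter(!.data$excluded) |>
    dplyr::summarise(
      mean = mean(.data$percent_of_baseline),
      se = sd(.data$percent_of_baseline) / sqrt(dplyr::n()),
      .by = c("signal", "treatment", "condition")
    )
  ggplot2::ggplot(summ, ggplot2::aes(.data$treatment, .data$mean,
                                     fill = .data$condition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           position = ggplot2::position_dodge(width = 0.8),
                           width = 0.25) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed",
                        color = "grey40") +
    ggplot2::facet_wrap(~signal, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "% of baseline", fill = "condition") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
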