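#' Fit a luminescence standard curve for ATP quantification
#'
#' Least-squares line of relative light units (RLU) against known ATP amount
#' per well, fitted per plate from standards of known concentration. A
#' log-log fit is available for signals with multiplicative error. Curves
#' whose r-squared falls below `r2_threshold` are rejected with a diagnostic
#' error, since everything downstream inverts this line.
#'
#' @param standards Tibble with columns `known_atp_amol` and `rlu` (>= 3
#'   points; the known amounts should span at least one order of magnitude).
#' @param r2_threshold Minimum acceptable r-squared (default 0.98).
#' @param log_log Fit `log(rlu) ~ log(known_atp)` instead of the linear
#'   form; zero-ATP points are dropped with a warning in this mode.
#'
#' @return An `atp_curve` object with elements `slope`, `intercept`,
#'   `r_squared`, `log_log`, `range` (of known ATP), and the underlying
#'   `lm` fit; has [tidy()] and [glance()] methods.
#' @examples
#' std <- tibble::tibble(known_atp_amol = c(0, 50, 100, 500, 1000),
#'                       rlu = 2 * c(0, 50, 100, 500, 1000))
#' fit_standard_curve(std)
#' @export
fit_standard_curve <- function(standards, r2_threshold = 0.98,
                               log_log = FALSE) {
  check_columns(standards, c("known_atp_amol", "rlu"), "standards")
  standards <- tibble::as_tibble(standards)
  if (nrow(standards) < 3) {
    validation_error("A standard curve needs at least 3 points.")
  }
  if (any(standards$known_atp_amol < 0) || any(standards$rlu < 0)) {
    validation_error("Standards must have non-negative ATP and RLU values.")
  }
  if (sd(standards$known_atp_amol) == 0) {
    validation_error("Standards have zero variance in known ATP.")
  }
  pos <- standards$known_atp_amol[standards$known_atp_amol > 0]
  if (length(pos) >= 2 && max(pos) / min(pos) < 10) {
    rlang::warn("Standards span less than one order of magnitude of ATP.")
  }
  if (log_log) {
    keep <- standards$known_atp_amol > 0 & standards$rlu > 0
    if (sum(!keep) > 0) {
      rlang::warn("Dropping zero points for the log-log fit.")
    }
    df <- standards[keep, ]
    if (nrow(df) < 3) validation_error("Too few positive points for a log-log fit.")
    model <- lm(log(rlu) ~ log(known_atp_amol), data = df)
  } else {
    model <- lm(rlu ~ known_atp_amol, data = standards)
  }
  # suppress the "essentially perfect fit" note on exact standards
  r2 <- suppressWarnings(summary(model)$r.squared)
  if (r2 < r2_threshold) {
    abort_fluxcap(
      paste0("Standard curve rejected: r-squared ", format(r2, digits = 4),
             " below threshold ", r2_threshold, "."),
      "fluxcap_curve_error", r_squared = r2
    )
  }
  structure(
    list(
      slope = unname(coef(model)[2]),
      intercept = unname(coef(model)[1]),
      r_squared = r2,
      log_log = log_log,
      range = range(standards$known_atp_amol),
      rlu_range = range(standards$rlu),
      model = model
    ),
    class = "atp_curve"
  )
}

#' @export
print.atp_curve <- function(x, ...) {
  cat("<atp_curve>", if (x$log_log) "log-log" else "linear", "\n")
  cat("  slope =", format(x$slope, digits = 6),
      " intercept =", format(x$intercept, digits = 6),
      " r^2 =", format(x$r_squared, digits = 4), "\n")
  cat("  standards span", format(x$range[1]), "-", format(x$range[2]),
      "amol\n")
  invisible(x)
}

#' @export
tidy.atp_curve <- function(x, ...) {
  cf <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(cf), estimate = cf[, 1],
                 std.error = cf[, 2], statistic = cf[, 3],
                 p.value = cf[, 4])
}

#' @export
glance.atp_curve <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, log_log = x$log_log,
                 atp_min = x$range[1], atp_max = x$range[2])
}

invert_curve <- function(curve, rlu) {
  if (curve$log_log) {
    exp((log(pmax(rlu, .Machine$double.xmin)) - curve$intercept) /
          curve$slope)
  } else {
    (rlu - curve$intercept) / curve$slope
  }
}

#' ATP content per sperm from luminescence readings
#'
#' Averages each sample's replicate luminescence readings, inverts the
#' plate's standard curve to an ATP amount per well, and divides by the
#' number of sperm represented in the assayed lysate aliquot, yielding
#' amol sperm^-1. Readings below the blank (negative inverted ATP) are
#' clamped to zero and flagged; readings outside the standards' luminescence
#' range are flagged as extrapolated but kept.
#'
#' @param samples Tibble with columns `sample_id`, `condition`, replicate
#'   columns `rlu_1`, `rlu_2`, ... (at least one), and `cells_in_aliquot`
#'   (> 0).
#' @param curve An `atp_curve` from [fit_standard_curve()].
#'
#' @return The `samples` tibble with added columns `rlu_mean`,
#'   `atp_amol_well`, `atp_amol_per_sperm`, `clamped`, `extrapolated`.
#' @export
atp_per_sperm <- function(samples, curve) {
  stopifnot(inherits(curve, "atp_curve"))
  samples <- tibble::as_tibble(samples)
  rep_cols <- grep("^rlu_[0-9]+$", names(samples), value = TRUE)
  if (length(rep_cols) == 0) {
    format_error("No replicate luminescence columns (rlu_1, rlu_2, ...) found.")
  }
  check_columns(samples, c("sample_id", "cells_in_aliquot"), "samples")
  if (any(is.na(samples$cells_in_aliquot)) ||
      any(samples$cells_in_aliquot <= 0)) {
    validation_error("cells_in_aliquot must be positive for every sample.")
  }
  rlu_mean <- rowMeans(as.matrix(samples[rep_cols]), na.rm = TRUE)
  atp_raw <- invert_curve(curve, rlu_mean)
  clamped <- atp_raw < 0
  extrapolated <- rlu_mean < curve$rlu_range[1] |
    rlu_mean > curve$rlu_range[2]
  if (any(clamped)) {
    rlang::warn(paste0(sum(clamped),
                       " sample(s) below blank signal; ATP clamped to 0."))
  }
  samples |>
    dplyr::mutate(
      rlu_mean = rlu_mean,
      atp_amol_well = pmax(atp_raw, 0),
      atp_amol_per_sperm = .data$atp_amol_well / .data$cells_in_aliquot,
      clamped = clamped,
      extrapolated = extrapolated
    )
}
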