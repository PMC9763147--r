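#' Measurement-cycle windows of a flux assay
#'
#' A standard run has 9 measurement cycles of 6 min: cycles 1-4 untreated,
#' modulator injection before cycle 5, antimycin A + rotenone (A+R) before
#' cycle 8. Cycle 1 is kept in the files but excluded from all statistics
#' because the first measurement of a run is unstable; all window arithmetic
#' works on cycle indices, never on clock time.
#'
#' @param discarded Integer cycle indices excluded from every computation.
#' @param baseline Cycles averaged for the basal (pre-injection) level.
#' @param treatment Cycles aggregated for the modulator response.
#' @param ar Cycles after the A+R addition (non-mitochondrial respiration).
#'
#' @return A `cycle_windows` object (a named list of integer vectors).
#' @examples
#' cycle_windows()
#' cycle_windows(discarded = 1L, baseline = 2:4, treatment = 5:7, ar = 8:9)
#' @export
cycle_windows <- function(discarded = 1L, baseline = 2:4, treatment = 5:7,
                          ar = 8:9) {
  w <- list(
    discarded = as.integer(sort(discarded)),
    baseline = as.integer(sort(baseline)),
    treatment = as.integer(sort(treatment)),
    ar = as.integer(sort(ar))
  )
  all_idx <- unlist(w, use.names = FALSE)
  if (any(all_idx < 1L)) {
    validation_error("Cycle indices must be 1-based positive integers.")
  }
  if (anyDuplicated(all_idx)) {
    validation_error("Cycle windows must be pairwise disjoint.")
  }
  if (length(w$baseline) == 0 || length(w$treatment) == 0) {
    validation_error("`baseline` and `treatment` windows must be non-empty.")
  }
  if (max(w$baseline) >= min(w$treatment)) {
    validation_error("The baseline window must precede the treatment window.")
  }
  if (length(w$ar) > 0 && max(w$treatment) >= min(w$ar)) {
    validation_error("The treatment window must precede the A+R window.")
  }
  structure(w, class = "cycle_windows")
}

#' @export
print.cycle_windows <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(v, collapse = ",") else "<none>"
  cat("<cycle_windows>\n")
  cat("  discarded:", fmt(x$discarded), "\n")
  cat("  baseline: ", fmt(x$baseline), "\n")
  cat("  treatment:", fmt(x$treatment), "\n")
  cat("  A+R:      ", fmt(x$ar), "\n")
  invisible(x)
}

as_cycle_windows <- function(x) {
  if (inherits(x, "cycle_windows")) return(x)
  if (is.null(x)) return(cycle_windows())
  if (is.list(x)) {
    return(cycle_windows(
      discarded = x$discarded %||% 1L,
      baseline = x$baseline %||% 2:4,
      treatment = x$treatment %||% 5:7,
      ar = x$ar %||% 8:9
    ))
  }
  usage_error("`windows` must be a cycle_windows object or a list.")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
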