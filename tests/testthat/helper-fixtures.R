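# Build a normalized_traces tibble from per-well cycle vectors.
# wells: named list well_id -> list(ocr = numeric(9), ecar = numeric(9),
#                                   experiment, condition, treatment)
make_normalized <- function(wells, windows = cycle_windows()) {
  rows <- lapply(names(wells), function(id) {
    w <- wells[[id]]
    n <- length(w$ocr)
    tibble::tibble(
      well_id = id,
      experiment_id = w$experiment %||% "E1",
      condition = w$condition %||% "non_capacitating",
      treatment = w$treatment %||% "baseline",
      cycle = seq_len(n),
      time_min = (seq_len(n) - 1) * 6,
      ocr = w$ocr,
      ecar = w$ecar
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "windows") <- windows
  class(out) <- c("normalized_traces", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A flat trace: baseline level `base` on all cycles, `tr` on the treatment
# window, `ar` on the A+R window (signal-specific vectors built explicitly).
flat_cycles <- function(base, tr = base, ar = base, n = 9,
                        tr_idx = 5:7, ar_idx = 8:9) {
  x <- rep(base, n)
  x[tr_idx] <- tr
  x[ar_idx] <- ar
  x
}

# Random multi-well normalized dataset for oracle comparisons.
random_normalized <- function(n_experiments = 2, wells_per_treatment = 1,
                              seed = 1) {
  set.seed(seed)
  wells <- list()
  for (e in seq_len(n_experiments)) {
    for (cond in c("non_capacitating", "capacitating")) {
      for (trt in c("baseline", "oligomycin", "fccp", "2dog", "oxamate")) {
        for (r in seq_len(wells_per_treatment)) {
          id <- sprintf("E%d_%s_%s_%d", e, cond, trt, r)
          wells[[id]] <- list(
            ocr = rlnorm(9, log(300), 0.4),
            ecar = rlnorm(9, log(20), 0.4),
            experiment = sprintf("E%d", e),
            condition = cond, treatment = trt
          )
        }
      }
    }
  }
  make_normalized(wells)
}

# ---------------------------------------------------------------------------
# Brute-force oracle: plain-loop reimplementation of the panel arithmetic,
# working directly on the cycle lists. Kept deliberately naive and
# independent of the package's dplyr pipeline.
# ---------------------------------------------------------------------------
oracle_stats <- function(df_well, w = list(baseline = 2:4, treatment = 5:7,
                                           ar = 8:9)) {
  pickv <- function(v, cyc, idx) v[match(idx, cyc)]
  ocr <- df_well$ocr; ecar <- df_well$ecar; cyc <- df_well$cycle
  list(
    ocr_base = mean(pickv(ocr, cyc, w$baseline)),
    ocr_tr_mean = mean(pickv(ocr, cyc, w$treatment)),
    ocr_tr_max = max(pickv(ocr, cyc, w$treatment)),
    ocr_ar = if (all(w$ar %in% cyc)) mean(pickv(ocr, cyc, w$ar)) else NA,
    ecar_base = mean(pickv(ecar, cyc, w$baseline)),
    ecar_tr_mean = mean(pickv(ecar, cyc, w$treatment)),
    ecar_tr_max = max(pickv(ecar, cyc, w$treatment)),
    ecar_tr_min = min(pickv(ecar, cyc, w$treatment)),
    ecar_ar = if (all(w$ar %in% cyc)) mean(pickv(ecar, cyc, w$ar)) else NA
  )
}

oracle_panel <- function(norm) {
  ids <- unique(norm$well_id)
  meta <- unique(as.data.frame(norm[, c("well_id", "experiment_id",
                                        "condition", "treatment")]))
  rownames(meta) <- meta$well_id
  st <- lapply(ids, function(id) oracle_stats(norm[norm$well_id == id, ]))
  names(st) <- ids
  out <- list()
  for (id in ids) {
    s <- st[[id]]
    ar <- if (is.na(s$ocr_ar)) 0 else s$ocr_ar
    row <- list(
      well_id = id,
      basal_respiration = s$ocr_base - ar,
      nonmito_respiration = s$ocr_ar,
      basal_glycolysis = s$ecar_base,
      ocr_ecar_ratio = if (s$ecar_base > 0) s$ocr_base / s$ecar_base else NA_real_,
      proton_leak_pct = NA_real_, atp_linked_pct = NA_real_,
      maximal_respiration_pct = NA_real_, spare_capacity_pct = NA_real_,
      glycolytic_reserve_pct = NA_real_
    )
    trt <- meta[id, "treatment"]
    if (trt %in% c("oligomycin", "fccp")) {
      partners <- meta$well_id[meta$experiment_id == meta[id, "experiment_id"] &
                                 meta$condition == meta[id, "condition"] &
                                 meta$treatment == "baseline"]
      partners <- sort(partners)
      if (trt == "oligomycin") {
        leaks <- c(); reserves <- c()
        for (p in partners) {
          sp <- st[[p]]
          arp <- if (is.na(sp$ocr_ar)) 0 else sp$ocr_ar
          basal <- sp$ocr_base - arp
          if (is.finite(basal) && basal > 0) {
            leaks <- c(leaks, 100 * (s$ocr_tr_mean - ar) / basal)
          }
          if (is.finite(sp$ecar_base) && sp$ecar_base > 0) {
            reserves <- c(reserves,
                          100 * (s$ecar_tr_max - sp$ecar_base) / sp$ecar_base)
          }
        }
        if (length(leaks)) {
          row$proton_leak_pct <- mean(leaks)
          row$atp_linked_pct <- 100 - mean(leaks)
        }
        if (length(reserves)) row$glycolytic_reserve_pct <- mean(reserves)
      } else {
        maxs <- c()
        for (p in partners) {
          sp <- st[[p]]
          arp <- if (is.na(sp$ocr_ar)) 0 else sp$ocr_ar
          basal <- sp$ocr_base - arp
          if (is.finite(basal) && basal > 0) {
            maxs <- c(maxs, 100 * (s$ocr_tr_max - ar) / basal)
          }
        }
        if (length(maxs)) {
          row$maximal_respiration_pct <- mean(maxs)
          row$spare_capacity_pct <- mean(maxs) - 100
        }
      }
    }
    out[[id]] <- row
  }
  out
}

oracle_responses <- function(norm, convention = "table2") {
  ids <- unique(norm$well_id)
  meta <- unique(as.data.frame(norm[, c("well_id", "treatment")]))
  rownames(meta) <- meta$well_id
  out <- list()
  for (id in ids) {
    s <- oracle_stats(norm[norm$well_id == id, ])
    ar <- if (is.na(s$ocr_ar)) 0 else s$ocr_ar
    base_ocr <- s$ocr_base - ar
    ocr_pct <- if (base_ocr > 0) 100 * (s$ocr_tr_mean - ar) / base_ocr else NA_real_
    trt <- meta[id, "treatment"]
    ecar_val <- if (convention == "table3" && trt == "oligomycin") {
      s$ecar_tr_max
    } else if (convention == "table3" && trt == "2dog") {
      s$ecar_tr_min
    } else s$ecar_tr_mean
    ecar_pct <- if (s$ecar_base > 0) 100 * ecar_val / s$ecar_base else NA_real_
    out[[id]] <- list(ocr = ocr_pct, ecar = ecar_pct)
  }
  out
}

# extract one named panel quantity for one well from the package output
panel_val <- function(panel, id, quantity) {
  panel[[quantity]][panel$well_id == id]
}
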